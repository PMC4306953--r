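#' @title 13C enrichment analysis
#' @description Relative 13C enrichment ratios from NMR intensity tables of
#'   precursor-feeding experiments, and threshold classification of enriched
#'   carbons. The canonical normalization divides each carbon's
#'   labeled/unlabeled intensity quotient by that of a reference carbon known
#'   not to incorporate any fed precursor, so the reference ratio is exactly
#'   1 and the measure is invariant to overall spectrum scaling.
#' @name labeling_analysis
NULL

EXPERIMENTS <- c("acetate_1_13C", "acetate_2_13C", "propionate_1_13C",
                 "succinate_1_4_13C2")

ENRICHMENT_COLUMNS <- c("position", "shift_ppm", "experiment",
                        "labeled_intensity", "unlabeled_intensity", "ratio")

#' Construct an enrichment table for one feeding experiment
#'
#' @param compound Compound name.
#' @param experiment One of `"acetate_1_13C"`, `"acetate_2_13C"`,
#'   `"propionate_1_13C"`, `"succinate_1_4_13C2"`.
#' @param records Data frame with columns `position` (carbon id, unique),
#'   `shift_ppm`, and either both `labeled_intensity` and
#'   `unlabeled_intensity`, or precomputed `ratio` (published-table mode).
#' @param reference_position Carbon id of the unlabeled reference; must occur
#'   among the records.
#' @return An object of class `enrichment_table`.
#' @export
enrichment_table <- function(compound, experiment, records, reference_position) {
  if (!experiment %in% EXPERIMENTS) {
    abort_validation(sprintf("unknown experiment '%s' (expected one of %s)",
                             experiment, paste(EXPERIMENTS, collapse = ", ")))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(ENRICHMENT_COLUMNS, c("experiment", "position"))) {
    if (is.null(records[[col]])) records[[col]] <- NA_real_
    records[[col]] <- as.numeric(records[[col]])
  }
  records$position <- as.character(records$position)
  if (anyDuplicated(records$position)) {
    abort_validation(sprintf("duplicate carbon position '%s' in enrichment records",
                             records$position[duplicated(records$position)][1L]))
  }
  reference_position <- as.character(reference_position)
  if (!reference_position %in% records$position) {
    abort_data(sprintf("reference position '%s' is not among the records",
                       reference_position))
  }
  if (any(!is.na(records$ratio) & records$ratio <= 0)) {
    abort_validation("pre-supplied enrichment ratios must be positive")
  }
  records <- records[, c("position", "shift_ppm", "labeled_intensity",
                         "unlabeled_intensity", "ratio")]
  rownames(records) <- NULL
  structure(list(compound = compound, experiment = experiment,
                 records = records,
                 reference_position = reference_position),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %s / %s: %d carbons, reference C-%s\n",
              x$compound, x$experiment, nrow(x$records), x$reference_position))
  invisible(x)
}

#' Compute per-carbon enrichment ratios
#'
#' In intensity mode the ratio of carbon c is
#' `(L_c / U_c) / (L_ref / U_ref)`, where `L` and `U` are the 13C signal
#' intensities in the labeled and unlabeled spectra; the reference carbon
#' then scores exactly 1. In ratio mode (published tables supply ratios
#' only) the stored ratios pass through, renormalized so the reference keeps
#' its stated value relative to 1. Mode `"auto"` uses ratios when every
#' record carries one, otherwise intensities.
#'
#' @param table An [enrichment_table()].
#' @param threshold Enrichment-call threshold (> 1); a carbon is called
#'   enriched when its ratio is at least this value.
#' @param mode `"auto"`, `"intensities"` or `"ratios"`.
#' @return A data frame of class `label_calls` with columns `position`,
#'   `ratio`, `enriched`, plus attributes `experiment` and `compound`.
#' @export
compute_enrichment <- function(table, threshold = 3,
                               mode = c("auto", "intensities", "ratios")) {
  stopifnot(inherits(table, "enrichment_table"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 1) {
    abort_validation("threshold must be a number > 1")
  }
  rec <- table$records
  if (mode == "auto") {
    mode <- if (all(!is.na(rec$ratio))) "ratios" else "intensities"
  }
  if (mode == "ratios") {
    if (any(is.na(rec$ratio))) {
      abort_data("ratio mode requires a ratio on every record")
    }
    ref <- rec$ratio[rec$position == table$reference_position]
    ratio <- rec$ratio / ref
  } else {
    bad <- is.na(rec$labeled_intensity) | is.na(rec$unlabeled_intensity)
    if (any(bad)) {
      abort_data(sprintf("intensity mode requires both intensities at position %s",
                         rec$position[bad][1L]))
    }
    nonpos <- rec$unlabeled_intensity <= 0
    if (any(nonpos)) {
      abort_data(sprintf("non-positive unlabeled intensity at position %s",
                         rec$position[nonpos][1L]))
    }
    q <- rec$labeled_intensity / rec$unlabeled_intensity
    ratio <- q / q[rec$position == table$reference_position]
  }
  out <- data.frame(position = rec$position, ratio = ratio,
                    enriched = ratio >= threshold, stringsAsFactors = FALSE)
  attr(out, "experiment") <- table$experiment
  attr(out, "compound") <- table$compound
  attr(out, "threshold") <- threshold
  class(out) <- c("label_calls", "data.frame")
  out
}

#' Positions called enriched at a threshold
#'
#' Deterministic threshold classification; raising the threshold never adds
#' positions.
#'
#' @param calls A `label_calls` data frame from [compute_enrichment()] (or
#'   any data frame with `position` and `ratio` columns).
#' @param threshold Classification threshold (> 1).
#' @return Character vector of enriched carbon positions, sorted.
#' @export
classify_enriched <- function(calls, threshold = 3) {
  if (!is.numeric(threshold) || threshold <= 1) {
    abort_validation("threshold must be a number > 1")
  }
  if (length(calls) == 0L || nrow(as.data.frame(calls)) == 0L) return(character(0))
  calls <- as.data.frame(calls)
  sort_ids(calls$position[calls$ratio >= threshold])
}

#' Read enrichment tables from CSV
#'
#' The CSV dialect is comma-separated with header
#' `position,shift_ppm,experiment,labeled_intensity,unlabeled_intensity,ratio`;
#' intensity cells may be empty when ratios are pre-supplied (and vice
#' versa). One file may hold several feeding experiments for the same
#' compound; one `enrichment_table` is returned per experiment.
#'
#' @param path CSV file path.
#' @param compound Compound name attached to the tables.
#' @param reference Reference carbon position (shared across experiments).
#' @return Named list of [enrichment_table()] objects, keyed by experiment.
#' @examples
#' tabs <- read_enrichment_csv(pks_extdata("feeding_lorneic_acid_a.csv"),
#'                             compound = "lorneic acid A", reference = "16")
#' names(tabs)
#' @export
read_enrichment_csv <- function(path, compound = "unknown", reference) {
  if (!file.exists(path)) abort_io(sprintf("enrichment CSV '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort_data(sprintf("'%s': no data rows", path))
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), ENRICHMENT_COLUMNS)) {
    abort_data(sprintf("'%s': header must be '%s'", path,
                       paste(ENRICHMENT_COLUMNS, collapse = ",")))
  }
  nfield <- length(ENRICHMENT_COLUMNS)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    fields <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    if (length(fields) > nfield || length(fields) < 3L) {
      abort_data(sprintf("'%s': malformed row at line %d (expected %d fields)",
                         path, i + 1L, nfield))
    }
    fields <- c(trimws(fields), rep("", nfield - length(fields)))
    num <- suppressWarnings(as.numeric(fields[c(2L, 4L, 5L, 6L)]))
    given <- nzchar(fields[c(2L, 4L, 5L, 6L)])
    if (any(given & is.na(num))) {
      abort_data(sprintf("'%s': malformed numeric field at line %d", path, i + 1L))
    }
    rows[[i]] <- data.frame(position = trimws(fields[1L]),
                            shift_ppm = num[1L], experiment = trimws(fields[3L]),
                            labeled_intensity = num[2L],
                            unlabeled_intensity = num[3L], ratio = num[4L],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- list()
  for (exp in unique(df$experiment)) {
    sub <- df[df$experiment == exp, , drop = FALSE]
    out[[exp]] <- enrichment_table(compound, exp, sub, reference)
  }
  out
}

#' Write enrichment tables to CSV
#'
#' Inverse of [read_enrichment_csv()]; round trips are identities.
#'
#' @param tables A single [enrichment_table()] or a list of them (same
#'   compound, one experiment each).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_csv <- function(tables, path) {
  if (inherits(tables, "enrichment_table")) tables <- list(tables)
  rows <- lapply(tables, function(t) {
    cbind(t$records[, "position", drop = FALSE],
          shift_ppm = t$records$shift_ppm,
          experiment = t$experiment,
          t$records[, c("labeled_intensity", "unlabeled_intensity", "ratio")])
  })
  df <- do.call(rbind, rows)
  fmt <- function(x) ifelse(is.na(x), "",
                            vapply(x, format, character(1), trim = TRUE,
                                   scientific = FALSE, digits = 15L))
  out <- c(paste(ENRICHMENT_COLUMNS, collapse = ","),
           paste(df$position, fmt(df$shift_ppm), df$experiment,
                 fmt(df$labeled_intensity), fmt(df$unlabeled_intensity),
                 fmt(df$ratio), sep = ","))
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write enrichment CSV '%s'", path))
  invisible(path)
}

#' Bar chart of enrichment ratios
#'
#' Simple helper plotting per-carbon ratios with the classification
#' threshold marked.
#'
#' @param calls A `label_calls` data frame.
#' @param threshold Threshold line to draw.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_enrichment <- function(calls, threshold = attr(calls, "threshold") %||% 3, ...) {
  calls <- as.data.frame(calls)
  mids <- graphics::barplot(calls$ratio, names.arg = calls$position,
                            xlab = "carbon position", ylab = "enrichment ratio", ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(mids)
}
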