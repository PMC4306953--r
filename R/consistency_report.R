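#' @title Gene-based vs isotope-based reconciliation
#' @description Compares the extender-unit sequence predicted from a PKS
#'   cluster's domain organization with the unit tiling inferred from
#'   13C-labeling data, position by position, and reports a verdict. A
#'   decomposition that matches at every unit but needs extra C-C bonds
#'   beyond head-to-tail extension is `consistent_with_post_pks_bonds`:
#'   the assembly line explains the skeleton except for tailoring-derived
#'   bond(s).
#' @name consistency_report
NULL

# Comparable unit tokens; alkylmalonyl carries its side size so that a C5
# unit never matches a C3 unit.
tokens_of <- function(x) {
  if (inherits(x, "linear_product")) return(unit_tokens(x$units))
  if (inherits(x, "unit_tiling")) return(x$tokens)
  if (is.character(x)) return(x)
  abort_validation("expected a linear_product, unit_tiling or character vector")
}

#' Compare a cluster-predicted product with a labeling-inferred tiling
#'
#' @param prediction A `linear_product` from [assemble()] (or a character
#'   vector of unit tokens, starter first).
#' @param tiling A `unit_tiling` from [tile()] (or a character vector of
#'   unit tokens).
#' @param cluster_id,compound Optional identifiers carried into the report.
#' @return An object of class `consistency_report` with fields
#'   `predicted_sequence`, `inferred_sequence`, `per_position_match`
#'   (length = the longer of the two; unmatched overhang positions count as
#'   mismatches), `module_count_match`, `anomalous_bonds` and `verdict`
#'   (`consistent`, `consistent_with_post_pks_bonds` or `inconsistent`).
#' @examples
#' lorn <- read_cluster(pks_extdata("lorneic_cluster.txt"))
#' g <- read_carbon_graph(pks_extdata("lorneic_acid_a_graph.txt"))
#' calls <- list(acetate_1_13C = c("1", "3", "5", "9", "11", "13", "15"),
#'               propionate_1_13C = "7")
#' compare_prediction(assemble(lorn), tile(g, calls)[[1]])
#' @export
compare_prediction <- function(prediction, tiling, cluster_id = NULL,
                               compound = NULL) {
  pred <- tokens_of(prediction)
  inf <- tokens_of(tiling)
  if (length(pred) == 0L || length(inf) == 0L) {
    abort_validation("both unit sequences must be non-empty")
  }
  n <- max(length(pred), length(inf))
  match_vec <- vapply(seq_len(n), function(i) {
    i <= length(pred) && i <= length(inf) && pred[i] == inf[i]
  }, logical(1))
  anomalous <- if (inherits(tiling, "unit_tiling")) tiling$anomalous_bonds
    else data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  all_match <- all(match_vec) && length(pred) == length(inf)
  verdict <- if (!all_match) "inconsistent"
    else if (nrow(anomalous) > 0L) "consistent_with_post_pks_bonds"
    else "consistent"
  structure(list(
    cluster_id = cluster_id %||% if (inherits(prediction, "linear_product"))
      prediction$cluster_id else NULL,
    compound = compound,
    predicted_sequence = pred,
    inferred_sequence = inf,
    per_position_match = match_vec,
    module_count_match = length(pred) == length(inf),
    anomalous_bonds = anomalous,
    verdict = verdict
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report>%s verdict: %s\n",
              if (!is.null(x$cluster_id)) paste0(" ", x$cluster_id, ":") else "",
              x$verdict))
  n <- length(x$per_position_match)
  pad <- function(v) c(v, rep("-", n - length(v)))
  df <- data.frame(position = seq_len(n), predicted = pad(x$predicted_sequence),
                   inferred = pad(x$inferred_sequence),
                   match = ifelse(x$per_position_match, "yes", "NO"))
  print(df, row.names = FALSE)
  if (nrow(x$anomalous_bonds) > 0L) {
    cat("post-assembly bond(s):",
        paste(x$anomalous_bonds$a, x$anomalous_bonds$b, sep = "-", collapse = ", "),
        "\n")
  }
  invisible(x)
}

format_report <- function(x) {
  c(paste("report", x$cluster_id %||% "unnamed"),
    paste("verdict", x$verdict),
    paste("module_count_match", tolower(x$module_count_match)),
    paste("predicted", paste(x$predicted_sequence, collapse = ",")),
    paste("inferred", paste(x$inferred_sequence, collapse = ",")),
    paste("match", paste(tolower(x$per_position_match), collapse = ",")),
    if (nrow(x$anomalous_bonds) > 0L)
      paste("anomalous_bond", x$anomalous_bonds$a, x$anomalous_bonds$b))
}
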