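#' @keywords internal
#' @noRd
pks_abort <- function(message, class) {
  cond <- structure(
    class = c(class, "pks_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

abort_validation <- function(message) pks_abort(message, "pks_validation_error")
abort_data <- function(message) pks_abort(message, "pks_data_error")
abort_classification <- function(message) pks_abort(message, "pks_classification_error")
abort_tiling <- function(message) pks_abort(message, "pks_tiling_error")
abort_io <- function(message) pks_abort(message, "pks_io_error")
abort_usage <- function(message) pks_abort(message, "pks_usage_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Sort carbon ids numerically when they look numeric, else lexicographically.
sort_ids <- function(x) {
  if (length(x) == 0L) return(character(0))
  n <- suppressWarnings(as.numeric(x))
  if (anyNA(n)) sort(x) else x[order(n)]
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Path to a packaged example data file
#'
#' Convenience wrapper around [system.file()] for the fixtures shipped under
#' `inst/extdata` (cluster descriptions, carbon graphs, enrichment tables and
#' the default rules file).
#'
#' @param file File name, e.g. `"akaeolide_cluster.txt"`. With no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' pks_extdata()
#' pks_extdata("lorneic_cluster.txt")
#' @export
pks_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "pksretro")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) abort_io(sprintf("no packaged data file '%s'", file))
  path
}
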