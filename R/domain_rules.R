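#' @title Domain prediction rules
#' @description Config-driven lookup rules translating sequence-derived
#'   domain annotations into biosynthetic predictions: AT substrate
#'   signatures to extender units, KR fingerprints to beta-hydroxyl /
#'   alpha-substituent descriptors and double-bond geometry, ER classes to
#'   alpha-methyl configuration. The rule content is data, not code: the
#'   package ships a documented default table and everything can be
#'   overridden from a JSON rules file.
#' @name domain_rules
NULL

EXTENDER_NAMES <- c("acetyl_starter", "malonyl", "methylmalonyl", "alkylmalonyl")
STEREO_DESCRIPTORS <- c("R", "S", "unspecified")

#' Construct an extender-unit type
#'
#' An extender unit contributes two backbone carbons (C1, the carboxyl-derived
#' carbon, and C2, the alpha carbon) plus `side_chain_carbons` side carbons
#' attached at C2: 0 for malonyl, 1 for methylmalonyl, >= 2 for alkylmalonyl
#' (3 for propylmalonyl).
#'
#' @param name One of `"acetyl_starter"`, `"malonyl"`, `"methylmalonyl"`,
#'   `"alkylmalonyl"`.
#' @param side_chain_carbons Number of side-chain carbons; may be `NA` for an
#'   alkylmalonyl unit whose chain length is not yet resolved.
#' @return An object of class `extender_type` with fields `name`,
#'   `carbon_count` and `side_chain_carbons`.
#' @export
extender_type <- function(name, side_chain_carbons = 0L) {
  if (!name %in% EXTENDER_NAMES) {
    abort_validation(sprintf("unknown extender type '%s'", name))
  }
  side <- as.integer(side_chain_carbons)
  if (length(side) == 0L) side <- NA_integer_
  if (!is.na(side)) {
    if (side < 0L) abort_validation("side_chain_carbons must be >= 0")
    if (name == "malonyl" && side != 0L) abort_validation("malonyl units carry no side chain")
    if (name == "methylmalonyl" && side != 1L) abort_validation("methylmalonyl units carry one side carbon")
    if (name == "alkylmalonyl" && side < 2L) abort_validation("alkylmalonyl units carry >= 2 side carbons")
    if (name == "acetyl_starter" && side != 0L) abort_validation("the acetate starter carries no side chain")
  }
  structure(list(name = name, carbon_count = 2L + side, side_chain_carbons = side),
            class = "extender_type")
}

#' Default prediction rule configuration
#'
#' The published record cites, but does not print, the AT signature residues
#' and KR/ER motif tables it relies on, so the defaults here use canonical
#' tokens from the field's AT substrate-prediction literature (`HAFH` for
#' malonyl-CoA, `YASH` for methylmalonyl-CoA) plus a stand-in token `TAGH`
#' for the rarer alkylmalonyl-CoA selectors. KR fingerprints follow the A/B
#' (beta-hydroxyl) x 1/2 (alpha-substituent) classification with B1 mapping
#' to a beta-`S` hydroxyl and alpha-`R` substituent; B-type KRs upstream of
#' an active DH yield `E` (trans) double bonds, A-type `Z`. ER classes use
#' the tyrosine rule: class `Y` gives an `S` alpha-methyl, `V` gives `R`.
#'
#' @return An object of class `rule_config`: a list with elements
#'   `at_signature_table`, `kr_fingerprint_table`, `kr_geometry_table`,
#'   `er_table`, `enrichment_threshold` and `allow_unknown_at`.
#' @seealso [read_rules()] to override any table from a JSON file.
#' @export
default_rules <- function() {
  validate_rules(structure(list(
    at_signature_table = list(
      HAFH = list(name = "malonyl", side_chain_carbons = 0L),
      YASH = list(name = "methylmalonyl", side_chain_carbons = 1L),
      TAGH = list(name = "alkylmalonyl", side_chain_carbons = NA_integer_)
    ),
    kr_fingerprint_table = list(
      A1 = list(beta = "R", alpha = "R"),
      A2 = list(beta = "R", alpha = "S"),
      B1 = list(beta = "S", alpha = "R"),
      B2 = list(beta = "S", alpha = "S")
    ),
    kr_geometry_table = list(A = "Z", B = "E"),
    er_table = list(Y = "S", V = "R"),
    enrichment_threshold = 3,
    allow_unknown_at = FALSE
  ), class = "rule_config"))
}

validate_rules <- function(config) {
  if (!is.list(config)) abort_validation("rules config must be a list")
  for (tab in c("at_signature_table", "kr_fingerprint_table",
                "kr_geometry_table", "er_table")) {
    if (length(config[[tab]]) == 0L) {
      abort_validation(sprintf("rules config: %s must be non-empty", tab))
    }
  }
  for (sig in names(config$at_signature_table)) {
    e <- config$at_signature_table[[sig]]
    sc <- e$side_chain_carbons
    config$at_signature_table[[sig]]$side_chain_carbons <-
      if (is.null(sc) || length(sc) == 0L) NA_integer_ else as.integer(sc)
    if (!e$name %in% setdiff(EXTENDER_NAMES, "acetyl_starter")) {
      abort_validation(sprintf("AT signature '%s' maps to unknown extender '%s'", sig, e$name))
    }
  }
  for (fp in names(config$kr_fingerprint_table)) {
    e <- config$kr_fingerprint_table[[fp]]
    if (!all(c(e$beta, e$alpha) %in% STEREO_DESCRIPTORS)) {
      abort_validation(sprintf("KR fingerprint '%s': descriptors must be R, S or unspecified", fp))
    }
  }
  if (!all(unlist(config$kr_geometry_table) %in% c("E", "Z"))) {
    abort_validation("kr_geometry_table entries must be 'E' or 'Z'")
  }
  if (!all(unlist(config$er_table) %in% STEREO_DESCRIPTORS)) {
    abort_validation("er_table descriptors must be R, S or unspecified")
  }
  thr <- config$enrichment_threshold
  if (!is.numeric(thr) || length(thr) != 1L || thr <= 1) {
    abort_validation("enrichment_threshold must be a single number > 1")
  }
  structure(config, class = "rule_config")
}

#' Read a rules configuration file
#'
#' Loads a JSON rules file and merges it over [default_rules()]: any table or
#' scalar present in the file replaces the default wholesale; omitted entries
#' keep their defaults. See `pks_extdata("default_rules.json")` for the
#' shipped serialization of the defaults.
#'
#' @param path Path to a JSON rules file.
#' @return A validated `rule_config` object.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("rules file '%s' does not exist", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort_data(sprintf("cannot parse rules file: %s",
                                                         conditionMessage(e))))
  config <- unclass(default_rules())
  for (nm in names(raw)) config[[nm]] <- raw[[nm]]
  # JSON scalars arrive as length-1 lists; flatten leaf tables
  config$kr_geometry_table <- lapply(config$kr_geometry_table, function(x) x[[1]] %||% x)
  config$er_table <- lapply(config$er_table, function(x) x[[1]] %||% x)
  if (is.list(config$enrichment_threshold)) {
    config$enrichment_threshold <- config$enrichment_threshold[[1]]
  }
  if (is.list(config$allow_unknown_at)) {
    config$allow_unknown_at <- isTRUE(config$allow_unknown_at[[1]])
  }
  validate_rules(config)
}

#' Predict the extender substrate selected by an AT domain
#'
#' Exact-match lookup of the acyltransferase substrate-signature token in the
#' config's signature table.
#'
#' @param signature Non-empty signature residue token.
#' @param config A `rule_config`, by default [default_rules()].
#' @return An [extender_type()]. For an alkylmalonyl signature the side-chain
#'   length is `NA` (unresolved) unless the caller supplies it elsewhere.
#' @export
predict_substrate <- function(signature, config = default_rules()) {
  if (!is.character(signature) || length(signature) != 1L || !nzchar(signature)) {
    abort_validation("signature must be a non-empty string")
  }
  entry <- config$at_signature_table[[signature]]
  if (is.null(entry)) {
    if (isTRUE(config$allow_unknown_at)) {
      return(extender_type("alkylmalonyl", NA_integer_))
    }
    abort_classification(sprintf("AT signature '%s' not found in signature table", signature))
  }
  extender_type(entry$name, entry$side_chain_carbons)
}

#' Classify a ketoreductase fingerprint
#'
#' Maps a KR fingerprint token to the beta-hydroxyl configuration it
#' installs, the alpha-substituent configuration of its module's extender,
#' and the geometry of the double bond formed if an active DH follows
#' (looked up by the fingerprint's A/B letter).
#'
#' @param fingerprint KR fingerprint token, e.g. `"B1"`.
#' @param config A `rule_config`.
#' @return List with elements `type`, `beta`, `alpha`, `geometry`.
#' @export
classify_kr <- function(fingerprint, config = default_rules()) {
  if (is.null(fingerprint) || !nzchar(fingerprint)) {
    abort_classification("KR fingerprint token is missing")
  }
  entry <- config$kr_fingerprint_table[[fingerprint]]
  if (is.null(entry)) {
    abort_classification(sprintf("unknown KR fingerprint token '%s'", fingerprint))
  }
  letter <- substr(fingerprint, 1L, 1L)
  geometry <- config$kr_geometry_table[[letter]] %||% "E"
  list(type = fingerprint, beta = entry$beta, alpha = entry$alpha, geometry = geometry)
}

#' Classify an enoylreductase domain
#'
#' Maps an ER class token to the configuration of the alpha-methyl (or other
#' alpha substituent) fixed by full reduction of the enoyl intermediate.
#'
#' @param er_class ER class token, e.g. `"Y"`.
#' @param config A `rule_config`.
#' @return A stereo descriptor: `"R"`, `"S"` or `"unspecified"`.
#' @export
classify_er <- function(er_class, config = default_rules()) {
  if (is.null(er_class) || !nzchar(er_class)) abort_classification("ER class token is missing")
  desc <- config$er_table[[er_class]]
  if (is.null(desc)) abort_classification(sprintf("unknown ER class '%s'", er_class))
  desc
}
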