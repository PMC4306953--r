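#' @title PKS cluster model
#' @description Constructors, validators and a reader/writer for declarative
#'   descriptions of modular type I polyketide synthase gene clusters. A
#'   cluster is an ordered list of modules; a module is an ordered list of
#'   typed catalytic domains (KS, AT, KR, DH, ER, ACP, TE) carrying optional
#'   substrate-signature strings, KR stereochemistry fingerprints, ER classes
#'   and activity flags.
#' @name cluster_model
NULL

DOMAIN_KINDS <- c("KS", "AT", "KR", "DH", "ER", "ACP", "TE")

#' Create a PKS domain specification
#'
#' @param kind Domain type, one of `"KS"`, `"AT"`, `"KR"`, `"DH"`, `"ER"`,
#'   `"ACP"`, `"TE"`.
#' @param signature Substrate-signature residue token; required (non-empty)
#'   for AT domains, which select the extender substrate.
#' @param active Logical activity flag. Annotated but catalytically silent
#'   domains (for example a dehydratase whose product retains the
#'   beta-hydroxyl) are encoded with `active = FALSE`.
#' @param kr_fingerprint Stereochemistry fingerprint token (e.g. `"B1"`);
#'   only meaningful, and only allowed, on KR domains.
#' @param er_class Enoylreductase class token (e.g. `"Y"`); only allowed on
#'   ER domains. Determines the alpha-substituent configuration set by full
#'   reduction.
#' @param side_carbons For AT domains whose signature maps to an alkylmalonyl
#'   extender, the number of side-chain carbons of the unit (e.g. 3 for
#'   propylmalonyl).
#' @return An object of class `pks_domain`.
#' @export
domain_spec <- function(kind, signature = "", active = TRUE,
                        kr_fingerprint = NULL, er_class = NULL,
                        side_carbons = NULL) {
  if (length(kind) != 1L || !kind %in% DOMAIN_KINDS) {
    abort_validation(sprintf(
      "domain kind must be one of %s (got '%s')",
      paste(DOMAIN_KINDS, collapse = ", "), paste(kind, collapse = ",")))
  }
  if (!is.character(signature) || length(signature) != 1L || is.na(signature)) {
    abort_validation("domain signature must be a single string")
  }
  if (kind == "AT" && !nzchar(signature)) {
    abort_validation("AT domain requires a non-empty substrate signature")
  }
  if (!is.null(kr_fingerprint) && kind != "KR") {
    abort_validation(sprintf("kr_fingerprint given on a %s domain (KR only)", kind))
  }
  if (!is.null(er_class) && kind != "ER") {
    abort_validation(sprintf("er_class given on a %s domain (ER only)", kind))
  }
  if (!is.null(side_carbons)) {
    if (kind != "AT") abort_validation("side_carbons is only meaningful on AT domains")
    side_carbons <- as.integer(side_carbons)
    if (is.na(side_carbons) || side_carbons < 0L) {
      abort_validation("side_carbons must be a non-negative integer")
    }
  }
  structure(
    list(kind = kind, signature = signature, active = isTRUE(active),
         kr_fingerprint = kr_fingerprint, er_class = er_class,
         side_carbons = side_carbons),
    class = "pks_domain"
  )
}

#' Create a PKS module specification
#'
#' A non-loading (extension) module must contain exactly one KS and exactly
#' one AT domain, and at most one each of KR, DH and ER. The loading module
#' (index 0) primes the starter unit and needs only an AT (plus carrier).
#'
#' @param index Zero-based module index; the loading module has index 0.
#' @param domains List of [domain_spec()] objects, in N- to C-terminal order.
#' @param loading Logical; is this the loading module?
#' @return An object of class `pks_module`.
#' @export
module_spec <- function(index, domains, loading = FALSE) {
  index <- as.integer(index)
  if (is.na(index) || index < 0L) abort_validation("module index must be an integer >= 0")
  if (isTRUE(loading) && index != 0L) {
    abort_validation(sprintf("loading module must have index 0 (got %d)", index))
  }
  if (!is.list(domains) || !all(vapply(domains, inherits, logical(1), "pks_domain"))) {
    abort_validation(sprintf("module %d: domains must be a list of domain_spec objects", index))
  }
  kinds <- vapply(domains, `[[`, character(1), "kind")
  tab <- table(factor(kinds, levels = DOMAIN_KINDS))
  if (!isTRUE(loading)) {
    if (tab[["KS"]] != 1L || tab[["AT"]] != 1L) {
      abort_validation(sprintf(
        "module %d: an extension module needs exactly one KS and one AT (found %d KS, %d AT)",
        index, tab[["KS"]], tab[["AT"]]))
    }
  } else if (tab[["AT"]] != 1L) {
    abort_validation("loading module needs exactly one AT domain")
  }
  for (k in c("KR", "DH", "ER")) {
    if (tab[[k]] > 1L) {
      abort_validation(sprintf("module %d: at most one %s domain allowed", index, k))
    }
  }
  structure(list(index = index, loading = isTRUE(loading), domains = domains),
            class = "pks_module")
}

#' Create a PKS cluster specification
#'
#' @param id Cluster identifier.
#' @param modules List of [module_spec()] objects with strictly increasing
#'   indices starting at 0; exactly one loading module, which comes first.
#' @param compound Optional name of the compound the cluster is thought to
#'   produce.
#' @return An object of class `pks_cluster`.
#' @export
cluster_spec <- function(id, modules, compound = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    abort_validation("cluster id must be a non-empty string")
  }
  if (!is.list(modules) || length(modules) == 0L) {
    abort_validation(sprintf("cluster '%s': module list must be non-empty", id))
  }
  if (!all(vapply(modules, inherits, logical(1), "pks_module"))) {
    abort_validation("modules must be a list of module_spec objects")
  }
  idx <- vapply(modules, `[[`, integer(1), "index")
  if (anyDuplicated(idx)) {
    abort_validation(sprintf("cluster '%s': duplicate module index %d",
                             id, idx[duplicated(idx)][1L]))
  }
  if (idx[1L] != 0L || any(diff(idx) <= 0L)) {
    abort_validation(sprintf("cluster '%s': module indices must increase strictly from 0", id))
  }
  loading <- vapply(modules, `[[`, logical(1), "loading")
  if (sum(loading) != 1L || !loading[1L]) {
    abort_validation(sprintf(
      "cluster '%s': exactly one loading module required, at index 0 (found %d)",
      id, sum(loading)))
  }
  structure(list(id = id, compound = compound, modules = modules),
            class = "pks_cluster")
}

#' @export
print.pks_cluster <- function(x, ...) {
  cat(sprintf("<pks_cluster> %s%s\n", x$id,
              if (!is.null(x$compound)) paste0(" (", x$compound, ")") else ""))
  cat(sprintf("  %d modules (1 loading + %d extension)\n",
              length(x$modules), length(x$modules) - 1L))
  for (m in x$modules) {
    kinds <- vapply(m$domains, function(d) {
      k <- d$kind
      if (!d$active) k <- tolower(k)
      k
    }, character(1))
    cat(sprintf("  %s%d: %s\n", if (m$loading) "LM" else "m", m$index,
                paste(kinds, collapse = "-")))
  }
  invisible(x)
}

extension_modules <- function(cluster) {
  cluster$modules[!vapply(cluster$modules, `[[`, logical(1), "loading")]
}

module_domain <- function(module, kind, active_only = FALSE) {
  for (d in module$domains) {
    if (d$kind == kind && (!active_only || d$active)) return(d)
  }
  NULL
}

has_domain <- function(module, kind, active_only = TRUE) {
  !is.null(module_domain(module, kind, active_only))
}

#' Tally beta-carbon processing profiles over extension modules
#'
#' Each extension module's complement of reductive domains determines the
#' final oxidation level of the beta-carbon it processes: none (beta-keto),
#' KR alone (beta-hydroxyl), DH+KR (enoyl double bond) or DH+ER+KR (fully
#' reduced methylene). A KR-less module counts as `none` whatever else it
#' carries, since DH and ER act downstream of the ketoreduction.
#'
#' @param cluster A [cluster_spec()] object.
#' @param active_only If `TRUE` (default) only domains flagged active are
#'   counted; with `FALSE` the tally reflects the annotated domain
#'   organization regardless of activity.
#' @return Named integer vector with entries `none`, `KR`, `DH+KR`,
#'   `DH+ER+KR`; the counts sum to the number of extension modules.
#' @examples
#' akae <- read_cluster(pks_extdata("akaeolide_cluster.txt"))
#' count_reductive_profiles(akae, active_only = FALSE)
#' @export
count_reductive_profiles <- function(cluster, active_only = TRUE) {
  stopifnot(inherits(cluster, "pks_cluster"))
  out <- c("none" = 0L, "KR" = 0L, "DH+KR" = 0L, "DH+ER+KR" = 0L)
  for (m in extension_modules(cluster)) {
    kr <- has_domain(m, "KR", active_only)
    dh <- has_domain(m, "DH", active_only)
    er <- has_domain(m, "ER", active_only)
    profile <- if (!kr) "none"
      else if (dh && er) "DH+ER+KR"
      else if (dh) "DH+KR"
      else "KR"
    out[[profile]] <- out[[profile]] + 1L
  }
  out
}

# ---- file format ----------------------------------------------------------
#
# Plain-text cluster description, one token stream per line:
#   cluster <id>
#   compound <name>            (optional)
#   module <index> [loading]
#   domain <KIND> [signature=..] [active=true|false] [fingerprint=..]
#                 [er_class=..] [side_carbons=..]
# '#' starts a comment; blank lines are ignored.

parse_kv <- function(tokens, where) {
  out <- list()
  for (tok in tokens) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      abort_validation(sprintf("%s: malformed attribute '%s' (expected key=value)", where, tok))
    }
    out[[kv[1L]]] <- kv[2L]
  }
  out
}

#' Read a PKS cluster description file
#'
#' Parses the plain-text cluster format shipped with the package (see the
#' fixtures under `inst/extdata` for annotated examples) and validates all
#' cluster/module/domain invariants.
#'
#' @param path Path to a cluster description file.
#' @return A validated [cluster_spec()] object.
#' @examples
#' read_cluster(pks_extdata("akaeolide_cluster.txt"))
#' @seealso [write_cluster()]
#' @export
read_cluster <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cluster file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  id <- NULL; compound <- NULL
  modules <- list()
  cur_index <- NULL; cur_loading <- FALSE; cur_domains <- list()
  flush_module <- function() {
    if (is.null(cur_index)) return()
    modules[[length(modules) + 1L]] <<-
      module_spec(cur_index, cur_domains, loading = cur_loading)
  }

  for (ln in lines) {
    tokens <- strsplit(ln, "[[:space:]]+")[[1L]]
    kw <- tokens[1L]
    if (kw == "cluster") {
      id <- tokens[2L]
    } else if (kw == "compound") {
      compound <- paste(tokens[-1L], collapse = " ")
    } else if (kw == "module") {
      flush_module()
      cur_index <- suppressWarnings(as.integer(tokens[2L]))
      if (is.na(cur_index)) abort_validation(sprintf("bad module index in line '%s'", ln))
      cur_loading <- length(tokens) > 2L && tokens[3L] == "loading"
      cur_domains <- list()
    } else if (kw == "domain") {
      if (is.null(cur_index)) abort_validation("domain line before any module line")
      kind <- tokens[2L]
      kv <- parse_kv(tokens[-(1:2)], sprintf("module %s domain %s", cur_index, kind))
      active <- !identical(tolower(kv$active %||% "true"), "false")
      cur_domains[[length(cur_domains) + 1L]] <- domain_spec(
        kind = kind,
        signature = kv$signature %||% "",
        active = active,
        kr_fingerprint = kv$fingerprint,
        er_class = kv$er_class,
        side_carbons = if (!is.null(kv$side_carbons)) as.integer(kv$side_carbons)
      )
    } else {
      abort_validation(sprintf("unrecognized line '%s' in cluster file", ln))
    }
  }
  flush_module()
  if (is.null(id)) abort_validation("cluster file lacks a 'cluster <id>' line")
  cluster_spec(id, modules, compound = compound)
}

#' Write a PKS cluster description file
#'
#' Serializes a cluster in the same plain-text format read by
#' [read_cluster()]; `read_cluster(write_cluster(x, p))` reproduces `x`.
#'
#' @param cluster A [cluster_spec()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cluster <- function(cluster, path) {
  stopifnot(inherits(cluster, "pks_cluster"))
  out <- c(paste("cluster", cluster$id))
  if (!is.null(cluster$compound)) out <- c(out, paste("compound", cluster$compound))
  for (m in cluster$modules) {
    out <- c(out, paste0("module ", m$index, if (m$loading) " loading" else ""))
    for (d in m$domains) {
      attrs <- character(0)
      if (nzchar(d$signature)) attrs <- c(attrs, paste0("signature=", d$signature))
      if (!d$active) attrs <- c(attrs, "active=false")
      if (!is.null(d$kr_fingerprint)) attrs <- c(attrs, paste0("fingerprint=", d$kr_fingerprint))
      if (!is.null(d$er_class)) attrs <- c(attrs, paste0("er_class=", d$er_class))
      if (!is.null(d$side_carbons)) attrs <- c(attrs, paste0("side_carbons=", d$side_carbons))
      out <- c(out, paste(c("domain", d$kind, attrs), collapse = " "))
    }
  }
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write cluster file '%s'", path))
  invisible(path)
}

#' Select clusters whose module count matches a compound's unit count
#'
#' A polyketide assembled from one starter and `k` extender units requires a
#' cluster of `k + 1` PKS modules; this screen shortlists candidate clusters
#' by that count.
#'
#' @param clusters List of [cluster_spec()] objects.
#' @param target_unit_count Required total module count (loading + extension).
#' @return Character vector of matching cluster ids.
#' @export
screen_clusters <- function(clusters, target_unit_count) {
  stopifnot(is.list(clusters))
  n <- vapply(clusters, function(cl) length(cl$modules), integer(1))
  ids <- vapply(clusters, `[[`, character(1), "id")
  ids[n == as.integer(target_unit_count)]
}
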