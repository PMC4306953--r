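#' @title Precursor-unit tiling
#' @description Infers how a compound's carbon skeleton is tiled by
#'   biosynthetic precursor units (acetate starter plus malonate /
#'   methylmalonate / alkylmalonate extenders) consistent with observed
#'   13C-labeling calls, and flags every C-C bond that head-to-tail chain
#'   extension cannot explain. The search walks the graph from a starter
#'   methyl two backbone carbons at a time (C2 then C1 per unit), assigns
#'   side branches to the alpha carbons they hang from, types each unit by
#'   its side-branch size, and ranks complete decompositions by concordance
#'   with the labeling data, then by fewest anomalous bonds.
#' @name unit_tiling
NULL

#' Construct a precursor labeling rule
#'
#' A rule states which carbon of which unit types a feeding experiment
#' labels. `labels_role` `"C1"` marks the carboxyl-derived backbone carbon,
#' `"C2"` the alpha carbon. For alkylmalonyl units `alkyl_role` may differ:
#' `"side_proximal"` marks the side carbon bonded to C2, reflecting that a
#' C5 extender arises from a propionyl primer elongated with acetate, which
#' places the propionate carboxyl carbon at the branch attachment while the
#' unit's own C1/C2 derive from acetate.
#'
#' @param experiment Experiment name (see [enrichment_table()]).
#' @param labels_role `"C1"` or `"C2"`.
#' @param applies_to Character vector of unit type names the rule labels.
#' @param alkyl_role Role used for alkylmalonyl units: `"C1"`, `"C2"` or
#'   `"side_proximal"`; defaults to `labels_role`.
#' @return An object of class `precursor_rule`.
#' @export
precursor_rule <- function(experiment, labels_role, applies_to,
                           alkyl_role = labels_role) {
  if (!experiment %in% EXPERIMENTS) {
    abort_validation(sprintf("unknown experiment '%s'", experiment))
  }
  if (!labels_role %in% c("C1", "C2")) abort_validation("labels_role must be C1 or C2")
  if (!alkyl_role %in% c("C1", "C2", "side_proximal")) {
    abort_validation("alkyl_role must be C1, C2 or side_proximal")
  }
  if (length(applies_to) == 0L || !all(applies_to %in% EXTENDER_NAMES)) {
    abort_validation("applies_to must name at least one extender type")
  }
  structure(list(experiment = experiment, labels_role = labels_role,
                 applies_to = applies_to, alkyl_role = alkyl_role),
            class = "precursor_rule")
}

#' Default precursor labeling rules
#'
#' \itemize{
#'   \item \code{[1-13C]acetate} labels C1 of the starter, of malonyl units
#'     and of alkylmalonyl units (whose C1/C2 are acetate-derived via primer
#'     elongation).
#'   \item \code{[2-13C]acetate} labels C2 of the same units.
#'   \item \code{[1-13C]propionate} labels C1 of methylmalonyl units and the
#'     proximal side carbon of alkylmalonyl units.
#' }
#' The dicarboxylate feeding (`succinate_1_4_13C2`) has no rule: it is not
#' incorporated by chain extension, so an all-unenriched succinate
#' experiment is simply silent evidence.
#'
#' @return List of [precursor_rule()] objects.
#' @export
default_precursor_rules <- function() {
  list(
    precursor_rule("acetate_1_13C", "C1",
                   c("acetyl_starter", "malonyl", "alkylmalonyl")),
    precursor_rule("acetate_2_13C", "C2",
                   c("acetyl_starter", "malonyl", "alkylmalonyl")),
    precursor_rule("propionate_1_13C", "C1",
                   c("methylmalonyl", "alkylmalonyl"),
                   alkyl_role = "side_proximal")
  )
}

predicted_label_nodes <- function(units, rule) {
  out <- character(0)
  for (u in units) {
    if (!u$type %in% rule$applies_to) next
    role <- if (u$type == "alkylmalonyl") rule$alkyl_role else rule$labels_role
    out <- c(out, switch(role,
                         C1 = u$c1, C2 = u$c2,
                         side_proximal = u$side_proximal))
  }
  unique(out)
}

tiling_concordance <- function(units, calls, rules, nodes) {
  exps <- vapply(rules, `[[`, character(1), "experiment")
  use <- intersect(names(calls), exps)
  if (length(use) == 0L) return(1)
  agree <- 0L; total <- 0L
  for (e in use) {
    rule <- rules[[match(e, exps)]]
    pred <- predicted_label_nodes(units, rule)
    obs <- as.character(calls[[e]])
    agree <- agree + sum((nodes %in% pred) == (nodes %in% obs))
    total <- total + length(nodes)
  }
  agree / total
}

tiling_anchors <- function(graph) {
  if (!is.null(graph$terminal_hint)) return(graph$terminal_hint)
  deg <- node_degrees(graph)
  anchors <- names(deg)[deg == 1L]
  if (length(anchors) == 0L) {
    abort_tiling("no candidate chain starter: no degree-1 carbon and no terminal hint")
  }
  anchors
}

# connected components of the subgraph induced by `rest`
components_of <- function(graph, rest) {
  remaining <- rest
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1L]; comp <- character(0)
    remaining <- remaining[-1L]
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- intersect(graph$adj[[v]], remaining)
      remaining <- setdiff(remaining, nb)
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort_ids(comp)
  }
  comps
}

# All ways to hang the non-backbone components off extender alpha carbons.
# Returns list of assignments (each a list of list(nodes, c2)); empty list
# means the backbone admits no complete cover.
side_assignments <- function(graph, path, max_combos = 32L) {
  rest <- setdiff(graph$nodes, path)
  if (length(rest) == 0L) return(list(list()))
  if (length(path) < 4L) return(list())
  ext_c2 <- path[seq(3L, length(path) - 1L, by = 2L)]
  comps <- components_of(graph, rest)
  choices <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    att <- unique(unlist(graph$adj[comps[[i]]], use.names = FALSE))
    att_c2 <- sort_ids(intersect(att, ext_c2))
    if (length(att_c2) == 0L) return(list())
    choices[[i]] <- att_c2
  }
  ncomb <- prod(lengths(choices))
  if (ncomb > max_combos) choices <- lapply(choices, `[`, 1L)
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    asg <- vector("list", length(comps))
    for (i in seq_along(comps)) {
      asg[[i]] <- list(nodes = comps[[i]], c2 = grid[r, i])
    }
    out[[r]] <- asg
  }
  out
}

build_tiling <- function(graph, path, asg, calls, rules) {
  k <- length(path) %/% 2L
  pos_of <- stats::setNames(seq_along(path), path)
  side_of_c2 <- list()
  for (comp in asg) {
    side_of_c2[[comp$c2]] <- sort_ids(c(side_of_c2[[comp$c2]], comp$nodes))
  }
  units <- vector("list", k)
  for (u in seq_len(k)) {
    c2 <- path[2L * u - 1L]; c1 <- path[2L * u]
    side <- side_of_c2[[c2]] %||% character(0)
    if (u == 1L) {
      if (length(side) > 0L) return(NULL)  # starter has no side chain
      type <- "acetyl_starter"
    } else {
      type <- if (length(side) == 0L) "malonyl"
        else if (length(side) == 1L) "methylmalonyl"
        else "alkylmalonyl"
    }
    units[[u]] <- list(unit = u, type = type, c2 = c2, c1 = c1,
                       side = side,
                       side_proximal = sort_ids(intersect(graph$adj[[c2]], side)))
  }
  unit_of <- stats::setNames(rep(NA_integer_, length(graph$nodes)), graph$nodes)
  for (u in seq_len(k)) {
    unit_of[c(units[[u]]$c2, units[[u]]$c1, units[[u]]$side)] <- u
  }
  b <- graph$bonds
  class_of <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    pa <- pos_of[b$a[i]]; pb <- pos_of[b$b[i]]
    if (!is.na(pa) && !is.na(pb)) {
      lo <- min(pa, pb)
      class_of[i] <- if (abs(pa - pb) == 1L) {
        if (lo %% 2L == 1L) "intra_unit" else "inter_unit"
      } else "anomalous"
    } else if (is.na(pa) && is.na(pb)) {
      class_of[i] <- "side_attachment"  # components never span units
    } else {
      s <- if (is.na(pa)) b$a[i] else b$b[i]
      t <- if (is.na(pa)) b$b[i] else b$a[i]
      class_of[i] <- if (identical(t, units[[unit_of[[s]]]]$c2))
        "side_attachment" else "anomalous"
    }
  }
  bond_classes <- cbind(b, class = class_of, stringsAsFactors = FALSE)
  anomalous <- bond_classes[bond_classes$class == "anomalous", c("a", "b")]
  rownames(anomalous) <- NULL
  tokens <- vapply(units, function(u) {
    if (u$type == "alkylmalonyl") paste0(u$type, ":", length(u$side)) else u$type
  }, character(1))
  structure(list(
    units = units,
    backbone = path,
    bond_classes = bond_classes,
    anomalous_bonds = anomalous,
    n_anomalous = nrow(anomalous),
    concordance = tiling_concordance(units, calls, rules, graph$nodes),
    tokens = tokens,
    key = paste0(paste(path, collapse = "-"), "|",
                 paste(vapply(asg, function(x)
                   paste0(x$c2, ":", paste(x$nodes, collapse = ".")), character(1)),
                   collapse = ";"))
  ), class = "unit_tiling")
}

close_path <- function(graph, path, calls, rules) {
  out <- list()
  for (asg in side_assignments(graph, path)) {
    t <- build_tiling(graph, path, asg, calls, rules)
    if (!is.null(t)) out[[length(out) + 1L]] <- t
  }
  out
}

finalize_tilings <- function(acc) {
  if (length(acc) == 0L) {
    abort_tiling("no precursor-unit decomposition covers this carbon graph")
  }
  res <- unname(acc)
  conc <- vapply(res, `[[`, numeric(1), "concordance")
  anom <- vapply(res, `[[`, integer(1), "n_anomalous")
  toks <- vapply(res, function(t) paste(t$tokens, collapse = ","), character(1))
  keys <- vapply(res, `[[`, character(1), "key")
  ord <- order(-conc, anom, toks, keys)
  res <- res[ord]
  top <- sum(conc[ord] == conc[ord][1L] & anom[ord] == anom[ord][1L] &
               toks[ord] == toks[ord][1L])
  structure(res, class = "pks_tilings", n_top_ties = top)
}

check_calls <- function(graph, calls) {
  if (length(calls) == 0L) return(invisible(TRUE))
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    abort_validation("calls must be a named list keyed by experiment")
  }
  pos <- unique(as.character(unlist(calls, use.names = FALSE)))
  missing <- setdiff(pos, graph$nodes)
  if (length(missing)) {
    abort_validation(sprintf("enriched position(s) %s are not graph nodes",
                             paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Tile a carbon skeleton into precursor units
#'
#' Backtracking search over head-to-tail unit decompositions of the carbon
#' graph. The backbone is grown two carbons per unit from a candidate
#' starter methyl (the `terminal_hint` if the graph provides one, otherwise
#' every degree-1 carbon); side branches are assigned to the alpha carbons
#' they attach to and type the unit by size (0 side carbons = malonyl, 1 =
#' methylmalonyl, 2+ = alkylmalonyl). Bonds not used as intra-unit,
#' inter-unit or side-attachment bonds are classed `anomalous`: they must
#' have been formed after chain assembly. Complete decompositions are ranked
#' by concordance with the labeling calls (fraction of experiment-by-carbon
#' observations matching the predicted label positions), then by fewest
#' anomalous bonds, then by the lexicographic unit-type sequence.
#'
#' @param graph A [carbon_graph()].
#' @param calls Named list, experiment name to character vector of enriched
#'   carbon positions (e.g. from [classify_enriched()]). Experiments without
#'   a matching rule are ignored; an empty list makes the ranking vacuous
#'   (concordance 1 everywhere).
#' @param rules List of [precursor_rule()]s; defaults to
#'   [default_precursor_rules()].
#' @return An object of class `pks_tilings`: a list of `unit_tiling`
#'   objects, best first, with attribute `n_top_ties` counting rank-one
#'   ties. Each tiling has `units`, `backbone`, `bond_classes`,
#'   `anomalous_bonds`, `concordance` and `tokens`.
#' @examples
#' g <- read_carbon_graph(pks_extdata("lorneic_acid_a_graph.txt"))
#' calls <- list(acetate_1_13C = c("1", "3", "5", "9", "11", "13", "15"),
#'               propionate_1_13C = "7")
#' best <- tile(g, calls)[[1]]
#' best$tokens
#' @export
tile <- function(graph, calls = list(), rules = default_precursor_rules()) {
  stopifnot(inherits(graph, "carbon_graph"))
  check_calls(graph, calls)
  anchors <- tiling_anchors(graph)
  acc <- new.env(parent = emptyenv())
  acc$res <- list()
  adj <- graph$adj
  dfs <- function(path) {
    for (t in close_path(graph, path, calls, rules)) acc$res[[t$key]] <- t
    last <- path[length(path)]
    for (c2 in setdiff(adj[[last]], path)) {
      for (c1 in setdiff(adj[[c2]], c(path, c2))) {
        dfs(c(path, c2, c1))
      }
    }
  }
  for (a in anchors) {
    for (b in adj[[a]]) dfs(c(a, b))
  }
  finalize_tilings(acc$res)
}

#' Exhaustive reference tiling (test oracle)
#'
#' Same contract and ranking as [tile()], but enumerates candidate
#' backbones by exhaustive simple-path enumeration
#' ([igraph::all_simple_paths()]) rather than the incremental backtracking
#' walk. Intended as an independent oracle for small graphs; refuses graphs
#' above `max_nodes` carbons.
#'
#' @inheritParams tile
#' @param max_nodes Size guard (default 14).
#' @return A `pks_tilings` object.
#' @export
brute_force_tile <- function(graph, calls = list(),
                             rules = default_precursor_rules(), max_nodes = 14L) {
  stopifnot(inherits(graph, "carbon_graph"))
  if (length(graph$nodes) > max_nodes) {
    abort_tiling(sprintf("brute_force_tile refuses graphs with more than %d carbons (got %d)",
                         max_nodes, length(graph$nodes)))
  }
  check_calls(graph, calls)
  g <- igraph::graph_from_data_frame(graph$bonds, directed = FALSE,
                                     vertices = graph$nodes)
  acc <- list()
  for (a in tiling_anchors(graph)) {
    for (target in setdiff(graph$nodes, a)) {
      paths <- igraph::all_simple_paths(g, from = a, to = target)
      for (p in paths) {
        path <- igraph::as_ids(p)
        if (length(path) %% 2L == 1L) next
        for (t in close_path(graph, path, calls, rules)) acc[[t$key]] <- t
      }
    }
  }
  finalize_tilings(acc)
}

#' Unit-type sequence of a tiling
#'
#' @param tiling A `unit_tiling`.
#' @return Character vector of unit type names, starter first.
#' @export
extender_sequence <- function(tiling) {
  stopifnot(inherits(tiling, "unit_tiling"))
  vapply(tiling$units, `[[`, character(1), "type")
}

#' @export
print.unit_tiling <- function(x, ...) {
  cat(sprintf("<unit_tiling> %d units, concordance %.3f, %d anomalous bond(s)\n",
              length(x$units), x$concordance, x$n_anomalous))
  for (u in x$units) {
    cat(sprintf("  unit %d %-16s C2=%s C1=%s%s\n", u$unit, u$type, u$c2, u$c1,
                if (length(u$side)) paste0(" side={", paste(u$side, collapse = ","), "}") else ""))
  }
  if (x$n_anomalous > 0L) {
    cat("  anomalous:", paste(x$anomalous_bonds$a, x$anomalous_bonds$b,
                              sep = "-", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.pks_tilings <- function(x, ...) {
  cat(sprintf("<pks_tilings> %d decomposition(s), %d tied at rank 1\n",
              length(x), attr(x, "n_top_ties")))
  print(x[[1L]])
  invisible(x)
}

format_tiling <- function(tiling, id = "tiling") {
  out <- c(paste("tiling", id),
           sprintf("concordance %.6f", tiling$concordance),
           paste("units", length(tiling$units)))
  for (u in tiling$units) {
    out <- c(out, paste0("unit ", u$unit, " ", u$type, " c2=", u$c2, " c1=", u$c1,
                         if (length(u$side)) paste0(" side=", paste(u$side, collapse = ","))
                         else ""))
  }
  bc <- tiling$bond_classes
  c(out, paste("bond", bc$a, bc$b, bc$class))
}
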