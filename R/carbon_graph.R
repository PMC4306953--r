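#' @title Carbon skeleton graphs
#' @description A compound's carbon skeleton as an undirected graph of
#'   carbon ids and C-C bonds (oxygen atoms and C-O bonds such as lactone or
#'   ether bridges are deliberately absent: only the carbon connectivity is
#'   tiled into precursor units).
#' @name carbon_graph
NULL

canonical_bonds <- function(bonds) {
  a <- as.character(bonds[[1L]]); b <- as.character(bonds[[2L]])
  lo <- ifelse(a < b, a, b); hi <- ifelse(a < b, b, a)
  unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
}

#' Construct a carbon graph
#'
#' @param bonds Two-column data frame (or matrix) of bonded carbon-id pairs.
#' @param nodes Optional extra node ids (bond endpoints are always included).
#' @param terminal_hint Optional id of the known chain-start methyl; when
#'   present, the tiling search anchors there. Useful when post-assembly
#'   ring closure has buried the starter methyl inside a cycle so that it is
#'   no longer a degree-1 carbon.
#' @return An object of class `carbon_graph` with fields `nodes`, `bonds`,
#'   `terminal_hint` and adjacency list `adj`.
#' @export
carbon_graph <- function(bonds, nodes = NULL, terminal_hint = NULL) {
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (ncol(bonds) != 2L) abort_validation("bonds must have two columns")
  bonds <- canonical_bonds(bonds)
  if (any(bonds$a == bonds$b)) abort_validation("self-loop bond not allowed")
  nodes <- sort_ids(unique(c(bonds$a, bonds$b, as.character(nodes %||% character(0)))))
  if (length(nodes) == 0L) abort_validation("carbon graph has no nodes")
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) adj[[n]] <- character(0)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a[i]]] <- c(adj[[bonds$a[i]]], bonds$b[i])
    adj[[bonds$b[i]]] <- c(adj[[bonds$b[i]]], bonds$a[i])
  }
  adj <- lapply(adj, sort_ids)
  # connectivity (BFS)
  if (length(nodes) > 1L) {
    seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
    queue <- nodes[1L]; seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen)) {
      abort_validation(sprintf("carbon graph is disconnected (e.g. node %s unreachable)",
                               nodes[!seen][1L]))
    }
  }
  if (!is.null(terminal_hint)) {
    terminal_hint <- as.character(terminal_hint)
    if (!terminal_hint %in% nodes) {
      abort_validation(sprintf("terminal_hint '%s' is not a node", terminal_hint))
    }
  }
  structure(list(nodes = nodes, bonds = bonds, terminal_hint = terminal_hint,
                 adj = adj),
            class = "carbon_graph")
}

#' @export
print.carbon_graph <- function(x, ...) {
  cat(sprintf("<carbon_graph> %d carbons, %d bonds%s\n",
              length(x$nodes), nrow(x$bonds),
              if (!is.null(x$terminal_hint))
                paste0(", chain start hint C-", x$terminal_hint) else ""))
  invisible(x)
}

#' Read a carbon graph file
#'
#' Plain-text format: `graph <id>` (optional), `terminal <id>` (optional),
#' `bond <a> <b>` per C-C bond, `node <id>` for isolated carbons; `#`
#' comments and blank lines are ignored.
#'
#' @param path Graph file path.
#' @return A [carbon_graph()].
#' @examples
#' read_carbon_graph(pks_extdata("akaeolide_graph.txt"))
#' @export
read_carbon_graph <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("graph file '%s' does not exist", path))
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  bonds <- list(); nodes <- character(0); hint <- NULL; id <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    switch(tok[1L],
      graph = { id <- tok[2L] },
      terminal = { hint <- tok[2L] },
      node = { nodes <- c(nodes, tok[2L]) },
      bond = {
        if (length(tok) != 3L) abort_validation(sprintf("bad bond line '%s'", ln))
        bonds[[length(bonds) + 1L]] <- tok[2:3]
      },
      abort_validation(sprintf("unrecognized line '%s' in graph file", ln))
    )
  }
  if (length(bonds) == 0L && length(nodes) == 0L) {
    abort_validation(sprintf("graph file '%s' defines no carbons", path))
  }
  g <- carbon_graph(data.frame(a = vapply(bonds, `[`, character(1), 1L),
                               b = vapply(bonds, `[`, character(1), 2L),
                               stringsAsFactors = FALSE),
                    nodes = nodes, terminal_hint = hint)
  g$id <- id
  g
}

#' Write a carbon graph file
#'
#' @param graph A [carbon_graph()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_carbon_graph <- function(graph, path) {
  stopifnot(inherits(graph, "carbon_graph"))
  out <- character(0)
  if (!is.null(graph$id)) out <- c(out, paste("graph", graph$id))
  if (!is.null(graph$terminal_hint)) out <- c(out, paste("terminal", graph$terminal_hint))
  isolated <- graph$nodes[!graph$nodes %in% c(graph$bonds$a, graph$bonds$b)]
  out <- c(out, paste("node", isolated),
           paste("bond", graph$bonds$a, graph$bonds$b))
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write graph file '%s'", path))
  invisible(path)
}

node_degrees <- function(graph) {
  vapply(graph$adj, length, integer(1))
}
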