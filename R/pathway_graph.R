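#' @importFrom stats setNames
NULL

# Interaction-type vocabulary used throughout: labels seen in curated KEGG
# exports, everything else is mapped to "other".
PATHSEM_EDGE_TYPES <- c("activation", "inhibition", "binding", "indirect",
                        "phosphorylation", "other")

normalize_edge_type <- function(type) {
  type <- tolower(trimws(type))
  type[type %in% c("binding/association", "association")] <- "binding"
  type[type %in% c("indirect effect", "indirect_effect")] <- "indirect"
  type[!type %in% PATHSEM_EDGE_TYPES] <- "other"
  type
}

#' Construct a typed directed pathway graph
#'
#' A pathway graph is the mixed graph underlying a path diagram: gene nodes,
#' typed directed edges (regulatory relations) and optional bidirected edges
#' (shared hidden causes, realised as error covariances in a SEM).
#'
#' @param edges data.frame with columns `from`, `to`, `type` (character).
#'   Unknown interaction types are mapped to `"other"`.
#' @param nodes optional character vector of node ids; defaults to the edge
#'   endpoints. Extra isolated nodes may be supplied.
#' @param bidirected optional data.frame with columns `a`, `b` of unordered
#'   node pairs.
#' @return An object of class `pathway_graph` with elements `nodes`, `edges`,
#'   `bidirected`.
#' @export
pathway_graph <- function(edges, nodes = NULL, bidirected = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    stopf("edges must have columns 'from' and 'to'")
  }
  if (is.null(edges$type)) edges$type <- "other"
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$type <- normalize_edge_type(as.character(edges$type))
  dup <- duplicated(edges[c("from", "to")])
  if (any(dup)) edges <- edges[!dup, , drop = FALSE]
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  if (!is.null(bidirected) && nrow(bidirected)) {
    bidirected <- as.data.frame(bidirected, stringsAsFactors = FALSE)
    names(bidirected)[1:2] <- c("a", "b")
    bad <- !(bidirected$a %in% nodes & bidirected$b %in% nodes)
    if (any(bad)) stopf("bidirected edge endpoints not in nodes")
  } else {
    bidirected <- data.frame(a = character(), b = character(),
                             stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, bidirected = bidirected),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d nodes, %d directed edges, %d bidirected\n",
              length(x$nodes), nrow(x$edges), nrow(x$bidirected)))
  invisible(x)
}

#' Read a 3-column pathway edge table (SIF-compatible)
#'
#' Each non-comment row is `source <sep> interaction <sep> target`. The `sif`
#' dialect splits on any whitespace, `tsv3col` on tabs only. Duplicate
#' (source, target) rows are collapsed with a warning; interaction labels
#' outside the vocabulary become `"other"`.
#'
#' @param path file path.
#' @param dialect `"tsv3col"` (default) or `"sif"`.
#' @return A [pathway_graph()].
#' @export
read_pathway_table <- function(path, dialect = c("tsv3col", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("pathway file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stopf("pathway file is empty: %s", path)
  split_fun <- if (dialect == "sif") "[ \t]+" else "\t"
  rows <- strsplit(trimws(lines[idx], which = "right"), split_fun)
  nf <- lengths(rows)
  if (any(nf != 3L)) {
    stopf("malformed pathway row at line %d: expected 3 fields, got %d",
          idx[which(nf != 3L)[1]], nf[nf != 3L][1])
  }
  m <- do.call(rbind, rows)
  edges <- data.frame(from = m[, 1], to = m[, 3], type = m[, 2],
                      stringsAsFactors = FALSE)
  ndup <- sum(duplicated(edges[c("from", "to")]))
  if (ndup > 0) warnf("%d duplicate edge row(s) collapsed", ndup)
  pathway_graph(edges)
}

#' Write a pathway graph as a 3-column TSV
#'
#' @param g a [pathway_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(g, path) {
  stopifnot(inherits(g, "pathway_graph"))
  utils::write.table(g$edges[c("from", "type", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Node/edge counts and mean degree of a pathway graph
#'
#' Mean degree is total (in + out) degree averaged over nodes,
#' `2 * n_edges / n_nodes`, counting directed edges only.
#'
#' @param g a [pathway_graph()].
#' @return list with `n_nodes`, `n_edges`, `mean_degree`.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!length(g$nodes)) stopf("empty graph")
  n_nodes <- length(g$nodes)
  n_edges <- nrow(g$edges)
  list(n_nodes = n_nodes, n_edges = n_edges,
       mean_degree = 2 * n_edges / n_nodes)
}

# Sorted adjacency list (successors) excluding self-loops; the sorting fixes
# the BFS tie-break so equally short paths resolve identically on any platform.
adjacency_list <- function(g) {
  e <- g$edges[g$edges$from != g$edges$to, , drop = FALSE]
  adj <- split(e$to, factor(e$from, levels = g$nodes))
  lapply(adj, function(v) sort(unique(v)))
}

# Deterministic BFS geodesic from src to dst following edge direction.
# Returns the node sequence or NULL when dst is unreachable.
bfs_path <- function(adj, nodes, src, dst) {
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  seen <- setNames(logical(length(nodes)), nodes)
  seen[src] <- TRUE
  queue <- src
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <- TRUE
        parent[v] <- u
        if (v == dst) {
          path <- v
          while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, v)
      }
    }
  }
  NULL
}

#' Test directed reachability between two genes
#'
#' True iff a directed path of length at least one leads from `u` to `v`;
#' `u == v` is reachable only through a cycle.
#'
#' @param g a [pathway_graph()].
#' @param u,v node ids.
#' @return logical scalar.
#' @export
directed_path_exists <- function(g, u, v) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!u %in% g$nodes) stopf("unknown node: %s", u)
  if (!v %in% g$nodes) stopf("unknown node: %s", v)
  adj <- adjacency_list(g)
  # start from successors so u -> u requires a genuine cycle
  frontier <- adj[[u]]
  seen <- setNames(logical(length(g$nodes)), g$nodes)
  seen[frontier] <- TRUE
  while (length(frontier)) {
    if (v %in% frontier) return(TRUE)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- nxt[!seen[nxt]]
    seen[frontier] <- TRUE
  }
  FALSE
}

#' Extract the DEG-connecting shortest-path module
#'
#' For every ordered pair of distinct differentially expressed genes (DEGs)
#' present in the graph, computes one minimum-hop directed path (deterministic
#' lexicographic tie-break) and fuses all paths into a single subgraph in
#' which each node and edge occurs once; self-loops are dropped, cycles and
#' reciprocal edges are preserved, and interaction types are inherited.
#'
#' @param g a [pathway_graph()].
#' @param degs character vector of DEG ids; ids absent from the graph are
#'   dropped with a warning.
#' @return An object of class `shortest_path_module`: `subgraph`
#'   (a [pathway_graph()]), `paths` (list of node sequences), `connected_degs`,
#'   `connector_ndegs`, `skipped_pairs` (data.frame of unreachable ordered
#'   pairs).
#' @export
extract_module <- function(g, degs) {
  stopifnot(inherits(g, "pathway_graph"))
  degs <- unique(as.character(degs))
  missing <- setdiff(degs, g$nodes)
  if (length(missing)) {
    warnf("%d DEG(s) not in the pathway graph dropped: %s",
          length(missing), paste(missing, collapse = ", "))
  }
  degs <- sort(intersect(degs, g$nodes))
  if (length(degs) < 2) stopf("nothing to connect: fewer than 2 DEGs in graph")

  adj <- adjacency_list(g)
  paths <- list()
  skipped <- list()
  for (u in degs) {
    for (v in degs) {
      if (u == v) next
      p <- bfs_path(adj, g$nodes, u, v)
      if (is.null(p)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          from = u, to = v, stringsAsFactors = FALSE)
      } else {
        paths[[paste(u, v, sep = "->")]] <- p
      }
    }
  }
  skipped_pairs <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }

  edge_key <- paste(g$edges$from, g$edges$to, sep = "\r")
  used <- character()
  for (p in paths) {
    if (length(p) >= 2) {
      used <- c(used, paste(p[-length(p)], p[-1], sep = "\r"))
    }
  }
  used <- unique(used)
  sub_edges <- g$edges[edge_key %in% used, , drop = FALSE]
  sub_edges <- sub_edges[sub_edges$from != sub_edges$to, , drop = FALSE]
  sub_nodes <- sort(unique(unlist(paths, use.names = FALSE)))
  subgraph <- pathway_graph(sub_edges, nodes = sub_nodes)
  structure(list(
    subgraph = subgraph,
    paths = paths,
    connected_degs = sort(intersect(sub_nodes, degs)),
    connector_ndegs = sort(setdiff(sub_nodes, degs)),
    skipped_pairs = skipped_pairs
  ), class = "shortest_path_module")
}

#' @export
print.shortest_path_module <- function(x, ...) {
  st <- graph_stats(x$subgraph)
  cat(sprintf(paste0("<shortest_path_module> %d nodes, %d edges ",
                     "(mean degree %.3f); %d DEGs, %d connectors, ",
                     "%d unreachable pairs\n"),
              st$n_nodes, st$n_edges, st$mean_degree,
              length(x$connected_degs), length(x$connector_ndegs),
              nrow(x$skipped_pairs)))
  invisible(x)
}

# igraph view of the directed part; used for SCC checks and as a convenience
# for callers wanting igraph's toolbox.
as_igraph <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}

#' Export a pathway graph in DOT format
#'
#' @param g a [pathway_graph()].
#' @param path output file path.
#' @param node_colors optional named character vector of fill colours.
#' @param edge_colors optional character vector parallel to `g$edges` rows.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path, node_colors = NULL, edge_colors = NULL) {
  stopifnot(inherits(g, "pathway_graph"))
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph pathway {", "  node [shape=ellipse, style=filled];")
  fill <- setNames(rep("white", length(g$nodes)), g$nodes)
  if (!is.null(node_colors)) fill[names(node_colors)] <- node_colors
  lines <- c(lines, sprintf("  %s [fillcolor=%s];", q(g$nodes),
                            q(fill[g$nodes])))
  ecol <- edge_colors %||% rep("black", nrow(g$edges))
  if (nrow(g$edges)) {
    style <- ifelse(g$edges$type == "inhibition", "tee", "normal")
    lines <- c(lines, sprintf('  %s -> %s [color=%s, arrowhead=%s, label="%s"];',
                              q(g$edges$from), q(g$edges$to), q(ecol),
                              style, g$edges$type))
  }
  if (nrow(g$bidirected)) {
    lines <- c(lines, sprintf("  %s -> %s [dir=both, style=dashed];",
                              q(g$bidirected$a), q(g$bidirected$b)))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
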