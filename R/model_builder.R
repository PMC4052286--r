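#' Partition module genes into DEGs and non-DEGs
#'
#' The measured genes MG of a module are split as MG = DEG U NDEG with
#' DEG and NDEG disjoint. DEG ids absent from the node set are dropped with a
#' warning.
#'
#' @param graph_nodes character vector of gene ids.
#' @param deg_list character vector of DEG ids.
#' @return list with `all_genes`, `degs`, `ndegs`.
#' @export
classify_genes <- function(graph_nodes, deg_list) {
  graph_nodes <- unique(as.character(graph_nodes))
  deg_list <- unique(as.character(deg_list))
  if (!length(deg_list)) stopf("empty DEG list")
  strays <- setdiff(deg_list, graph_nodes)
  if (length(strays)) {
    warnf("%d DEG(s) not among graph nodes excluded: %s",
          length(strays), paste(strays, collapse = ", "))
  }
  degs <- sort(intersect(deg_list, graph_nodes))
  structure(list(all_genes = sort(graph_nodes), degs = degs,
                 ndegs = sort(setdiff(graph_nodes, degs))),
            class = "gene_classification")
}

#' Read a gene-to-superfamily map (2-column TSV)
#'
#' @param path TSV with columns gene, superfamily (no header, `#` comments).
#' @return named character vector: gene id -> superfamily id.
#' @export
read_superfamily_map <- function(path) {
  if (!file.exists(path)) stopf("superfamily file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- strsplit(lines, "\t")
  if (any(lengths(rows) != 2L)) stopf("superfamily rows must have 2 fields")
  m <- do.call(rbind, rows)
  setNames(m[, 2], m[, 1])
}

#' Build superfamily composite variables by first principal components
#'
#' For each superfamily with at least two member genes in the module, a PCA
#' is run on the member expression profiles and PC1 scores summarise the
#' family. A family is accepted only when PC1 explains at least
#' `min_variance` (default 50%) of the total variance; otherwise its members
#' remain individual nodes. PCA is on the correlation matrix by default so
#' the acceptance rule is scale-free; loadings are unit-norm with the
#' largest-magnitude loading forced positive for reproducibility.
#'
#' @param module a [extract_module()] result, or a character vector of node
#'   ids.
#' @param sfmap named character vector gene -> superfamily id (partial map).
#' @param expr numeric gene x sample matrix with rownames = gene ids.
#' @param min_variance acceptance threshold on the PC1 variance fraction.
#' @param use_correlation standardize member genes before PCA (default TRUE).
#' @return list of `composite_variable` objects (id, members, loadings,
#'   variance_explained, scores, accepted).
#' @export
build_composites <- function(module, sfmap, expr, min_variance = 0.5,
                             use_correlation = TRUE) {
  nodes <- if (inherits(module, "shortest_path_module")) {
    module$subgraph$nodes
  } else {
    as.character(module)
  }
  sfmap <- sfmap[names(sfmap) %in% nodes]
  fams <- split(names(sfmap), sfmap)
  fams <- fams[lengths(fams) >= 2]
  out <- list()
  for (id in sort(names(fams))) {
    members <- sort(fams[[id]])
    miss <- setdiff(members, rownames(expr))
    if (length(miss)) {
      stopf("superfamily %s member(s) without expression rows: %s", id,
            paste(miss, collapse = ", "))
    }
    x <- t(expr[members, , drop = FALSE])   # samples x members
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stopf("constant expression for gene %s breaks standardization",
            members[which(sds == 0)[1]])
    }
    pc <- stats::prcomp(x, center = TRUE, scale. = use_correlation)
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
    load <- pc$rotation[, 1]
    if (load[which.max(abs(load))] < 0) load <- -load
    scores <- drop(scale(x, center = TRUE, scale = use_correlation) %*% load)
    out[[id]] <- structure(list(
      id = id, members = members, loadings = load,
      variance_explained = ve, scores = scores,
      accepted = ve >= min_variance
    ), class = "composite_variable")
  }
  out
}

#' @export
print.composite_variable <- function(x, ...) {
  cat(sprintf("<composite %s> %d members, PC1 variance %.1f%% (%s)\n",
              x$id, length(x$members), 100 * x$variance_explained,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Export composite definitions as JSON
#' @param composites output of [build_composites()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_composites_json <- function(composites, path) {
  payload <- lapply(composites, function(cv) {
    list(id = cv$id, members = cv$members,
         loadings = unname(cv$loadings),
         variance_explained = cv$variance_explained,
         accepted = cv$accepted)
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Collapse superfamily members into composite nodes
#'
#' Member genes of each accepted composite are replaced by the composite node;
#' edges are re-targeted, duplicates merged (first interaction type kept) and
#' self-loops created by merging dropped.
#'
#' @param module a [extract_module()] result or a [pathway_graph()].
#' @param composites list from [build_composites()]; only accepted ones are
#'   applied.
#' @return a [pathway_graph()] over genes + composite ids.
#' @export
collapse_graph <- function(module, composites) {
  g <- if (inherits(module, "shortest_path_module")) module$subgraph else module
  stopifnot(inherits(g, "pathway_graph"))
  composites <- Filter(function(cv) isTRUE(cv$accepted), composites)
  rename <- setNames(g$nodes, g$nodes)
  for (cv in composites) {
    if (cv$id %in% g$nodes) {
      stopf("composite id %s collides with an existing node", cv$id)
    }
    rename[intersect(cv$members, names(rename))] <- cv$id
  }
  e <- g$edges
  e$from <- unname(rename[e$from])
  e$to <- unname(rename[e$to])
  e <- e[e$from != e$to, , drop = FALSE]
  e <- e[!duplicated(e[c("from", "to")]), , drop = FALSE]
  pathway_graph(e, nodes = unique(unname(rename)))
}

#' Construct a path-model specification
#'
#' @param variables ordered character vector of observed variables.
#' @param beta_free p x p logical matrix; `beta_free[i, j]` frees the path
#'   coefficient of variable j in the equation of variable i (edge j -> i).
#' @param psi_free p x p symmetric logical matrix of free error
#'   (co)variances; the diagonal is always forced free.
#' @param edge_types optional p x p character matrix of interaction types.
#' @param provenance optional data.frame(param, type, target, source, origin).
#' @param mean_structure logical; model intercepts when fitting.
#' @return object of class `path_model`.
#' @export
path_model <- function(variables, beta_free, psi_free = NULL,
                       edge_types = NULL, provenance = NULL,
                       mean_structure = FALSE) {
  p <- length(variables)
  stopifnot(is.matrix(beta_free), all(dim(beta_free) == p))
  beta_free <- beta_free & !diag(p)   # no self-loops
  if (is.null(psi_free)) psi_free <- matrix(FALSE, p, p)
  stopifnot(all(dim(psi_free) == p))
  psi_free <- (psi_free | t(psi_free))
  diag(psi_free) <- TRUE
  dimnames(beta_free) <- dimnames(psi_free) <- list(variables, variables)
  if (is.null(edge_types)) {
    edge_types <- matrix(NA_character_, p, p,
                         dimnames = list(variables, variables))
  }
  if (is.null(provenance)) {
    provenance <- data.frame(param = character(), type = character(),
                             target = character(), source = character(),
                             origin = character(), stringsAsFactors = FALSE)
  }
  structure(list(variables = variables, beta_free = beta_free,
                 psi_free = psi_free, edge_types = edge_types,
                 provenance = provenance, mean_structure = mean_structure),
            class = "path_model")
}

#' Number of free parameters of a path model
#'
#' Free path coefficients plus free error variances/covariances; when the
#' mean structure is on, plus one intercept per variable.
#' @param m a [path_model()].
#' @return integer count.
#' @export
n_free_parameters <- function(m) {
  stopifnot(inherits(m, "path_model"))
  p <- length(m$variables)
  t_cov <- sum(m$beta_free) + p + sum(m$psi_free[lower.tri(m$psi_free)])
  if (isTRUE(m$mean_structure)) t_cov + p else t_cov
}

#' @export
print.path_model <- function(x, ...) {
  p <- length(x$variables)
  cat(sprintf(paste0("<path_model> %d variables, %d free paths, ",
                     "%d free error covariances, %d free parameters\n"),
              p, sum(x$beta_free),
              sum(x$psi_free[lower.tri(x$psi_free)]), n_free_parameters(x)))
  invisible(x)
}

#' List bow violations of a path model
#'
#' A model is "bow-free" when no ordered pair of variables has both a free
#' directed edge and a free error covariance; bow-freeness guarantees
#' identifiability for acyclic models.
#'
#' @param m a [path_model()].
#' @return data.frame of violating pairs (empty when bow-free).
#' @export
check_bow_free <- function(m) {
  stopifnot(inherits(m, "path_model"))
  viol <- which((m$beta_free | t(m$beta_free)) & m$psi_free &
                  upper.tri(m$psi_free), arr.ind = TRUE)
  data.frame(a = m$variables[viol[, 1]], b = m$variables[viol[, 2]],
             stringsAsFactors = FALSE)
}

#' Check the block-recursive identification criterion
#'
#' Feedback and reciprocal relations must be segregated into blocks (strongly
#' connected components of the directed part) of no more than two equations.
#'
#' @param m a [path_model()].
#' @return list(pass = logical, blocks = list of variable sets).
#' @export
check_block_recursive <- function(m) {
  stopifnot(inherits(m, "path_model"))
  idx <- which(m$beta_free, arr.ind = TRUE)
  # beta_free[i, j]: edge source j -> target i
  g <- igraph::graph_from_data_frame(
    data.frame(from = m$variables[idx[, 2]], to = m$variables[idx[, 1]],
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = m$variables))
  comp <- igraph::components(g, mode = "strong")
  blocks <- split(m$variables, comp$membership[m$variables])
  names(blocks) <- NULL
  list(pass = all(lengths(blocks) <= 2), blocks = blocks)
}

#' Build the initial SEM model from a pathway (sub)graph
#'
#' One free path coefficient per directed edge (provenance `kegg:<type>`),
#' free error variances, all error covariances and exogenous covariances fixed
#' at zero. The construction is checked against the bow-free and
#' block-recursive identification criteria.
#'
#' @param g a [pathway_graph()] (typically a collapsed module).
#' @param mean_structure model intercepts when fitting (default FALSE).
#' @return a [path_model()].
#' @export
build_initial_model <- function(g, mean_structure = FALSE) {
  stopifnot(inherits(g, "pathway_graph"))
  vars <- g$nodes
  p <- length(vars)
  beta_free <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  edge_types <- matrix(NA_character_, p, p, dimnames = list(vars, vars))
  for (k in seq_len(nrow(g$edges))) {
    beta_free[g$edges$to[k], g$edges$from[k]] <- TRUE
    edge_types[g$edges$to[k], g$edges$from[k]] <- g$edges$type[k]
  }
  psi_free <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  if (nrow(g$bidirected)) {
    for (k in seq_len(nrow(g$bidirected))) {
      psi_free[g$bidirected$a[k], g$bidirected$b[k]] <- TRUE
      psi_free[g$bidirected$b[k], g$bidirected$a[k]] <- TRUE
    }
  }
  prov <- data.frame(
    param = paste0(g$edges$to, "~", g$edges$from),
    type = "beta", target = g$edges$to, source = g$edges$from,
    origin = paste0("kegg:", g$edges$type), stringsAsFactors = FALSE)
  m <- path_model(vars, beta_free, psi_free, edge_types, prov,
                  mean_structure)
  bows <- check_bow_free(m)
  if (nrow(bows)) {
    stopf("model is not bow-free: %s",
          paste(bows$a, bows$b, sep = "~~", collapse = ", "))
  }
  br <- check_block_recursive(m)
  if (!br$pass) {
    bad <- Filter(function(b) length(b) > 2, br$blocks)
    stopf("block-recursive violation: block {%s} has more than 2 equations",
          paste(bad[[1]], collapse = ", "))
  }
  m
}

# Free one fixed parameter in a model, recording provenance. Used by the
# stepwise refinement loop.
model_free_param <- function(m, type = c("beta", "psi"), target, source,
                             origin = "mi_added") {
  type <- match.arg(type)
  if (type == "beta") {
    if (m$beta_free[target, source]) stopf("parameter already free")
    m$beta_free[target, source] <- TRUE
  } else {
    if (m$psi_free[target, source]) stopf("parameter already free")
    m$psi_free[target, source] <- TRUE
    m$psi_free[source, target] <- TRUE
  }
  sep <- if (type == "beta") "~" else "~~"
  m$provenance <- rbind(m$provenance, data.frame(
    param = paste0(target, sep, source), type = type, target = target,
    source = source, origin = origin, stringsAsFactors = FALSE))
  m
}

# Inverse of model_free_param (drops the provenance row too).
model_fix_param <- function(m, type, target, source) {
  if (type == "beta") {
    m$beta_free[target, source] <- FALSE
  } else {
    m$psi_free[target, source] <- FALSE
    m$psi_free[source, target] <- FALSE
    diag(m$psi_free) <- TRUE
  }
  sep <- if (type == "beta") "~" else "~~"
  key <- paste0(target, sep, source)
  m$provenance <- m$provenance[m$provenance$param != key, , drop = FALSE]
  m
}
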