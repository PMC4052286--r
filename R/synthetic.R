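#' Simulate jointly Gaussian data from a SEM
#'
#' Draws U ~ N(0, Psi) and returns Y = (I - B)^-1 (means + U) row-wise, the
#' generating process the ML fit assumes.
#'
#' @param params a [sem_params()]; `means` are intercepts (conditional means
#'   given parents), zero when absent.
#' @param n number of samples.
#' @param seed RNG seed; a fixed seed gives bit-identical output and the
#'   caller's RNG state is preserved.
#' @return n x p matrix with variable column names when `params` carries
#'   dimnames.
#' @export
simulate_sem <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "sem_params"), n >= 1)
  p <- nrow(params$beta)
  A <- tryCatch(solve(diag(p) - params$beta),
                error = function(e) stopf("I - beta is singular"))
  L <- tryCatch(chol(params$psi),
                error = function(e) stopf("psi is not positive definite"))
  alpha <- params$means %||% rep(0, p)
  U <- with_preserved_seed(seed, {
    matrix(stats::rnorm(n * p), n, p) %*% L
  })
  Y <- sweep(U, 2, alpha, `+`) %*% t(A)
  colnames(Y) <- colnames(params$beta)
  Y
}

# Deterministic default true structure for scenarios: two independent gene
# chains (branches) whose every edge lies on a geodesic between the branch
# endpoint DEGs, plus one extra true cross-branch edge that is absent from
# the pathway graph and recoverable only through the evidence set (the
# branches are otherwise independent, so no within-pathway directed path can
# proxy for it).
scenario_backbone <- function(n_genes = 12L) {
  stopifnot(n_genes >= 6)
  genes <- sprintf("v%02d", seq_len(n_genes))
  k <- ceiling(n_genes / 2)
  a <- genes[1:k]
  b <- genes[(k + 1):n_genes]
  chain <- function(gg) data.frame(from = gg[-length(gg)], to = gg[-1],
                                   stringsAsFactors = FALSE)
  edges <- rbind(chain(a), chain(b))
  edges$type <- rep(c("activation", "inhibition"),
                    length.out = nrow(edges))
  list(genes = genes, edges = edges, branch_a = a, branch_b = b,
       degs = unique(c(a[1], a[k], b[1], b[length(b)])),
       extra_edge = c(a[2], b[max(2, length(b) - 2)]),
       diff_edge = c(b[length(b) - 1], b[length(b)]),
       shifted = c(a[k], b[1]))
}

#' Generate a full synthetic study scenario
#'
#' Builds a ground-truth two-group SEM (a gene chain with one extra
#' cross-edge), wraps it in a decoy-padded pathway graph, plants group
#' differences, and emits every input the pipeline needs: DEG list,
#' superfamily map, evidence set and per-group expression data.
#'
#' The planted effects define the study conditions: node mean shifts of
#' `delta_mu` (in residual-SD units, default 1) on the two terminal DEGs and
#' a path-coefficient difference of `delta_beta` (default 0.5) on one edge.
#' The extra true edge is present in both groups but missing from the
#' pathway graph, so only evidence-gated refinement can restore it.
#'
#' @param n_genes number of genes in the true module (>= 6, default 12).
#' @param n_per_group samples per group (default 150).
#' @param delta_mu planted group mean shift (default 1).
#' @param delta_beta planted group path-coefficient difference (default 0.5).
#' @param beta_base baseline path coefficient on chain edges (default 0.6;
#'   inhibition edges get the negated value).
#' @param extra_beta coefficient of the evidence-only extra edge in both
#'   groups (default 0.5; 0 removes it from the truth).
#' @param n_decoys decoy genes padded around the pathway (default 6).
#' @param n_families superfamily groupings emitted over connector genes
#'   (default 2).
#' @param seed scenario seed (drives the expression draws).
#' @return object of class `synthetic_scenario`: `truth` (per-group
#'   [sem_params()]), `model` (the true [path_model()]), `pathway`,
#'   `deg_list`, `sfmap`, `evidence`, `data` (list y1, y2), `planted`
#'   bookkeeping, `n_per_group`, `seed`.
#' @export
make_scenario <- function(n_genes = 12L, n_per_group = 150L,
                          delta_mu = 1, delta_beta = 0.5,
                          beta_base = 0.6, extra_beta = 0.8,
                          n_decoys = 6L, n_families = 2L, seed = 1L) {
  bb <- scenario_backbone(n_genes)
  genes <- bb$genes
  p <- length(genes)
  B <- matrix(0, p, p, dimnames = list(genes, genes))
  for (k in seq_len(nrow(bb$edges))) {
    sgn <- if (bb$edges$type[k] == "inhibition") -1 else 1
    B[bb$edges$to[k], bb$edges$from[k]] <- sgn * beta_base
  }
  true_edges <- bb$edges
  if (extra_beta != 0) {
    B[bb$extra_edge[2], bb$extra_edge[1]] <- extra_beta
    true_edges <- rbind(true_edges, data.frame(
      from = bb$extra_edge[1], to = bb$extra_edge[2], type = "binding",
      stringsAsFactors = FALSE))
  }
  rho <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (rho >= 1) stopf("infeasible config: true beta spectral radius >= 1")
  Psi <- diag(p)
  dimnames(Psi) <- list(genes, genes)
  alpha1 <- alpha2 <- setNames(rep(0, p), genes)
  shifted <- bb$shifted
  alpha1[shifted] <- alpha1[shifted] + delta_mu
  B1 <- B2 <- B
  diff_edge <- c(from = bb$diff_edge[1], to = bb$diff_edge[2])
  B1[diff_edge["to"], diff_edge["from"]] <-
    B1[diff_edge["to"], diff_edge["from"]] + delta_beta

  # pathway: the true branches plus decoys off the geodesics (a detour
  # around branch A strictly longer than its geodesic, plus dead ends), but
  # never the evidence-only cross-branch edge
  pw_edges <- bb$edges
  k <- length(bb$branch_a)
  if (n_decoys > 0) {
    dec <- sprintf("d%02d", seq_len(n_decoys))
    n_detour <- if (n_decoys >= k) k else 0L
    if (n_detour > 0) {
      detour <- c(bb$branch_a[1], dec[seq_len(n_detour)],
                  bb$branch_a[k])
      pw_edges <- rbind(pw_edges, data.frame(
        from = detour[-length(detour)], to = detour[-1], type = "indirect",
        stringsAsFactors = FALSE))
    }
    if (n_decoys > n_detour) {
      pw_edges <- rbind(pw_edges, data.frame(
        from = genes[p], to = dec[(n_detour + 1):n_decoys],
        type = "binding", stringsAsFactors = FALSE))
    }
  }
  pathway <- pathway_graph(pw_edges)

  # superfamilies over connector (non-DEG) genes: chain-adjacent pairs only
  # (so collapsing members never creates long feedback cycles), correlated
  # through the shared edge, and kept clear of planted-effect genes so
  # composite reduction does not mask the planted signals
  special <- unique(c(bb$extra_edge, unname(diff_edge), shifted))
  eligible <- setdiff(genes, c(bb$degs, special))
  sfmap <- character()
  fams <- 0L
  i <- 1L
  while (fams < n_families && i < p) {
    pair <- genes[c(i, i + 1)]
    if (all(pair %in% eligible)) {
      fams <- fams + 1L
      sfmap[pair] <- sprintf("fam%02d", fams)
      eligible <- setdiff(eligible, pair)
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }

  ev_pairs <- data.frame(a = bb$extra_edge[1], b = bb$extra_edge[2],
                         stringsAsFactors = FALSE)
  evidence <- evidence_set(ev_pairs, pathway)

  y1 <- simulate_sem(sem_params(B1, Psi, alpha1), n_per_group, seed = seed)
  y2 <- simulate_sem(sem_params(B2, Psi, alpha2), n_per_group,
                     seed = seed + 10000L)
  model <- build_initial_model(pathway_graph(true_edges, nodes = genes))
  structure(list(
    truth = list(group1 = sem_params(B1, Psi, alpha1),
                 group2 = sem_params(B2, Psi, alpha2)),
    model = model,
    pathway = pathway, deg_list = bb$degs, sfmap = sfmap,
    evidence = evidence, data = list(y1 = y1, y2 = y2),
    planted = list(shifted_nodes = shifted, diff_edge = diff_edge,
                   extra_edge = setNames(bb$extra_edge, c("from", "to")),
                   delta_mu = delta_mu, delta_beta = delta_beta),
    n_per_group = n_per_group, seed = seed
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scenario> %d genes, %d DEGs, ",
                     "%d samples/group, seed %s\n"),
              length(x$model$variables), length(x$deg_list),
              x$n_per_group, format(x$seed)))
  invisible(x)
}

#' Write scenario inputs as plain-text pipeline files
#'
#' Emits the expression TSV (gene x sample, both groups), group label TSV,
#' pathway TSV, DEG list, superfamily TSV and evidence TSV under `dir`.
#'
#' @param sc a [make_scenario()] result.
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_scenario <- function(sc, dir) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  y <- rbind(sc$data$y1, sc$data$y2)
  samples <- c(sprintf("g1_s%03d", seq_len(nrow(sc$data$y1))),
               sprintf("g2_s%03d", seq_len(nrow(sc$data$y2))))
  expr <- t(y)
  colnames(expr) <- samples
  utils::write.table(
    data.frame(gene = rownames(expr), expr, check.names = FALSE),
    pth("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = samples,
               group = rep(c("experimental", "control"),
                           c(nrow(sc$data$y1), nrow(sc$data$y2)))),
    pth("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_pathway_table(sc$pathway, pth("pathway.tsv"))
  writeLines(sc$deg_list, pth("degs.txt"))
  if (length(sc$sfmap)) {
    utils::write.table(
      data.frame(gene = names(sc$sfmap), family = unname(sc$sfmap)),
      pth("superfamilies.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(sc$evidence$string_edges, pth("evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  list(expression = pth("expression.tsv"), groups = pth("groups.tsv"),
       pathway = pth("pathway.tsv"), degs = pth("degs.txt"),
       superfamilies = if (length(sc$sfmap)) pth("superfamilies.tsv"),
       evidence = pth("evidence.tsv"))
}
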