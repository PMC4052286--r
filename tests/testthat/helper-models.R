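# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

chain_model <- function(p = 5, vars = paste0("y", seq_len(p))) {
  bf <- matrix(FALSE, p, p)
  for (i in seq_len(p)[-1]) bf[i, i - 1] <- TRUE
  path_model(vars, bf)
}

chain_params <- function(p = 5, beta = 0.5, psi = 1, means = NULL,
                         vars = paste0("y", seq_len(p))) {
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p)[-1]) B[i, i - 1] <- beta
  P <- diag(psi, p)
  dimnames(P) <- list(vars, vars)
  sem_params(B, P, means)
}

# small typed pathway used by graph tests: a chain a->b->c->d with a
# shortcut a->c and a dead end c->e
toy_pathway <- function() {
  pathway_graph(data.frame(
    from = c("a", "b", "c", "a", "c"),
    to   = c("b", "c", "d", "c", "e"),
    type = c("activation", "inhibition", "activation", "binding",
             "indirect"),
    stringsAsFactors = FALSE))
}

# random directed graph as a pathway_graph (igraph is the generator and the
# independent geodesic oracle in the tests that use this)
random_pathway <- function(n, m, seed) {
  g <- with_seed(seed, igraph::sample_gnm(n, m, directed = TRUE))
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("n%02d", seq_len(n))
  pathway_graph(data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                           type = "other", stringsAsFactors = FALSE),
                nodes = nodes)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# named data matrix from sem parameters
sim_data <- function(params, n, seed, vars = colnames(params$beta)) {
  y <- simulate_sem(params, n, seed = seed)
  if (is.null(colnames(y))) colnames(y) <- vars
  y
}
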