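test_that("gene classification partitions module genes", {
  cl <- classify_genes(c("a", "b", "c"), "a")
  expect_equal(cl$degs, "a")
  expect_setequal(cl$ndegs, c("b", "c"))
  expect_setequal(union(cl$degs, cl$ndegs), cl$all_genes)
  expect_length(intersect(cl$degs, cl$ndegs), 0)

  expect_warning(cl2 <- classify_genes(c("a", "b"), c("a", "z")), "z")
  expect_equal(cl2$degs, "a")
  cl3 <- classify_genes(c("a", "b"), c("a", "b"))
  expect_length(cl3$ndegs, 0)
  expect_error(classify_genes(c("a"), character()), "empty")
})

test_that("composite PC1 variance matches the 2x2 correlation closed form", {
  # for two standardized members, eigenvalues are (1 +/- r)/2
  n <- 200
  y <- sim_data(chain_params(2, beta = 1.2, vars = c("g1", "g2")), n,
                seed = 3)
  expr <- t(y)
  r <- abs(cor(y[, 1], y[, 2]))
  cv <- build_composites(c("g1", "g2"), c(g1 = "fam", g2 = "fam"), expr)
  expect_length(cv, 1)
  expect_equal(cv$fam$variance_explained, (1 + r) / 2, tolerance = 1e-10)
  expect_true(cv$fam$accepted)
  # unit-norm loadings, dominant loading positive
  expect_equal(sum(cv$fam$loadings^2), 1, tolerance = 1e-10)
  expect_gt(cv$fam$loadings[which.max(abs(cv$fam$loadings))], 0)

  # exactly uncorrelated members sit on the 50% acceptance boundary
  expr0 <- rbind(g1 = c(1, 1, -1, -1), g2 = c(1, -1, 1, -1))
  cv0 <- build_composites(c("g1", "g2"), c(g1 = "fam", g2 = "fam"), expr0)
  expect_equal(cv0$fam$variance_explained, 0.5)
  expect_true(cv0$fam$accepted)

  # scale equivariance of correlation-based PCA
  expr_scaled <- expr
  expr_scaled["g1", ] <- 10 * expr_scaled["g1", ]
  cvs <- build_composites(c("g1", "g2"), c(g1 = "fam", g2 = "fam"),
                          expr_scaled)
  expect_equal(cvs$fam$variance_explained, cv$fam$variance_explained)
  expect_equal(cvs$fam$scores, cv$fam$scores, tolerance = 1e-8)

  # constant member is an error naming the gene
  exprc <- rbind(g1 = rep(1, 5), g2 = rnorm(5))
  expect_error(
    build_composites(c("g1", "g2"), c(g1 = "fam", g2 = "fam"), exprc),
    "g1")

  # singleton families are not composites
  expect_length(build_composites(c("g1", "g2"), c(g1 = "fam"), expr), 0)
})

test_that("collapse merges members, drops self-loops and de-duplicates", {
  g <- pathway_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
                                type = "activation"))
  comp <- list(structure(list(id = "F", members = c("b", "c"),
                              accepted = TRUE),
                         class = "composite_variable"))
  cg <- collapse_graph(g, comp)
  expect_setequal(cg$nodes, c("a", "F"))
  expect_equal(paste(cg$edges$from, cg$edges$to), "a F")

  g2 <- pathway_graph(data.frame(from = c("a", "a"), to = c("b", "c"),
                                 type = "activation"))
  cg2 <- collapse_graph(g2, comp)
  expect_equal(nrow(cg2$edges), 1)

  compx <- list(structure(list(id = "a", members = c("b", "c"),
                               accepted = TRUE),
                          class = "composite_variable"))
  expect_error(collapse_graph(g, compx), "collides")

  # node-count conservation: nodes - sum(members - 1) over accepted
  sc <- make_scenario(seed = 5)
  mod <- extract_module(sc$pathway, sc$deg_list)
  expr <- t(rbind(sc$data$y1, sc$data$y2))
  cvs <- build_composites(mod, sc$sfmap, expr)
  acc <- Filter(function(cv) cv$accepted, cvs)
  cg3 <- collapse_graph(mod, cvs)
  expect_equal(length(cg3$nodes),
               length(mod$subgraph$nodes) -
                 sum(vapply(acc, function(cv) length(cv$members) - 1L, 0L)))
})

test_that("bow-free and block-recursive checks flag the right structures", {
  vars <- c("a", "b", "c")
  bf <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
  bf["b", "a"] <- TRUE
  pf <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
  m_ok <- path_model(vars, bf, pf)
  expect_equal(nrow(check_bow_free(m_ok)), 0)
  pf["a", "b"] <- pf["b", "a"] <- TRUE
  m_bow <- path_model(vars, bf, pf)
  viol <- check_bow_free(m_bow)
  expect_equal(nrow(viol), 1)
  expect_setequal(unlist(viol[1, ]), c("a", "b"))
  # covariance without a directed edge is fine
  pf2 <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
  pf2["a", "c"] <- pf2["c", "a"] <- TRUE
  expect_equal(nrow(check_bow_free(path_model(vars, bf, pf2))), 0)

  acyc <- check_block_recursive(chain_model(4))
  expect_true(acyc$pass)
  expect_true(all(lengths(acyc$blocks) == 1))

  bf2 <- matrix(FALSE, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  bf2["a", "b"] <- bf2["b", "a"] <- TRUE
  two <- check_block_recursive(path_model(c("a", "b"), bf2))
  expect_true(two$pass)
  expect_equal(sort(lengths(two$blocks), decreasing = TRUE)[1], 2)

  bf3 <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
  bf3["b", "a"] <- bf3["c", "b"] <- bf3["a", "c"] <- TRUE
  tri <- check_block_recursive(path_model(vars, bf3))
  expect_false(tri$pass)
  expect_true(any(lengths(tri$blocks) == 3))
})

test_that("initial models count free parameters as edges + variances", {
  # 17 variables with 31 directed edges in an acyclic pattern
  vars <- sprintf("g%02d", 1:17)
  set.seed(11)
  bf <- matrix(FALSE, 17, 17, dimnames = list(vars, vars))
  pairs <- which(lower.tri(bf), arr.ind = TRUE)
  take <- pairs[sample.int(nrow(pairs), 31), ]
  bf[take] <- TRUE  # lower triangle only: guaranteed acyclic
  edges <- data.frame(from = vars[take[, 2]], to = vars[take[, 1]],
                      type = "activation")
  m <- build_initial_model(pathway_graph(edges, nodes = vars))
  expect_equal(n_free_parameters(m), 48)
  expect_equal(degrees_of_freedom(m), 105)
  expect_equal(nrow(check_bow_free(m)), 0)

  m1 <- build_initial_model(pathway_graph(
    data.frame(from = "a", to = "b", type = "other")))
  expect_equal(n_free_parameters(m1), 3)
  expect_equal(degrees_of_freedom(m1), 0)

  m0 <- path_model(c("a", "b", "c"), matrix(FALSE, 3, 3))
  expect_equal(n_free_parameters(m0), 3)
  expect_equal(degrees_of_freedom(m0), 3)

  # a 3-cycle pathway is rejected as non-identified
  cyc <- pathway_graph(data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "a"), type = "other"))
  expect_error(build_initial_model(cyc), "block-recursive")
})
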