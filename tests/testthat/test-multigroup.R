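two_group_chain <- function(p = 4, n = 120, beta = 0.5, seed = 1,
                            shift = NULL, dbeta = NULL) {
  vars <- paste0("y", seq_len(p))
  pars1 <- chain_params(p, beta = beta)
  pars2 <- chain_params(p, beta = beta)
  if (!is.null(shift)) {
    mu <- setNames(rep(0, p), vars)
    mu[shift$var] <- shift$delta
    pars1 <- sem_params(pars1$beta, pars1$psi, mu)
  }
  if (!is.null(dbeta)) {
    B1 <- pars1$beta
    B1[dbeta$i, dbeta$j] <- B1[dbeta$i, dbeta$j] + dbeta$delta
    pars1 <- sem_params(B1, pars1$psi, pars1$means)
  }
  grouped_data(sim_data(pars1, n, seed = seed, vars = vars),
               sim_data(pars2, n, seed = seed + 999, vars = vars))
}

test_that("grouped data validates its invariants", {
  y <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_s3_class(grouped_data(y, y), "grouped_data")
  y2 <- y
  colnames(y2) <- c("a", "c", "b")
  expect_error(grouped_data(y, y2), "identical")
  expect_error(grouped_data(y[1:2, ], y), "n >= 3")
})

test_that("identical groups yield equal estimates and null differences", {
  vars <- paste0("y", 1:3)
  y <- sim_data(chain_params(3, 0.5), 100, seed = 2, vars = vars)
  gd <- grouped_data(y, y)
  m <- chain_model(3)
  fit <- fit_two_group(m, gd, "none")
  expect_equal(fit$params[[1]]$B, fit$params[[2]]$B, tolerance = 1e-4)
  expect_equal(fit$params[[1]]$alpha, fit$params[[2]]$alpha,
               tolerance = 1e-4)
  et <- edge_tests(m, gd)
  expect_true(all(abs(et$difference) < 1e-3))
  nt <- node_tests(m, gd)
  expect_true(all(abs(nt$difference) < 1e-3))
})

test_that("constrained two-group fits never beat the free fit", {
  gd <- two_group_chain(p = 3, n = 80, seed = 5,
                        shift = list(var = "y2", delta = 0.7))
  m <- chain_model(3)
  f_free <- fit_two_group(m, gd, "none", compute_vcov = FALSE)
  for (cons in c("equal_means", "equal_cov_structure", "both")) {
    f_c <- fit_two_group(m, gd, cons, compute_vcov = FALSE)
    expect_gte(f_free$loglik, f_c$loglik - 1e-6)
    expect_gte(f_c$chisq, f_free$chisq - 1e-6)
  }
  # equal covariance structure loses almost nothing when only means differ
  f_cov <- fit_two_group(m, gd, "equal_cov_structure",
                         compute_vcov = FALSE)
  expect_lt(f_cov$chisq - f_free$chisq,
            qchisq(0.999, df = f_cov$df - f_free$df))
})

test_that("omnibus tests count constraints correctly and detect effects", {
  gd <- two_group_chain(p = 4, n = 150, seed = 11,
                        shift = list(var = "y3", delta = 2))
  m <- chain_model(4)
  mt <- omnibus_mean_test(m, gd)
  expect_equal(mt$df_diff, 4)           # one mean parameter per variable
  expect_lt(mt$p_value, 0.001)          # a 2-SD shift is detected
  ct <- omnibus_cov_test(m, gd)
  expect_equal(ct$df_diff, 7)           # 3 paths + 4 error variances
  expect_gt(ct$p_value, 0.001)          # no covariance difference planted

  gd2 <- two_group_chain(p = 4, n = 150, seed = 12,
                         dbeta = list(i = 3, j = 2, delta = 0.8))
  ct2 <- omnibus_cov_test(m, gd2)
  expect_lt(ct2$p_value, 0.01)
})

test_that("node screen flags planted shifts with the right sign and CI math", {
  gd <- two_group_chain(p = 4, n = 150, seed = 21,
                        shift = list(var = "y2", delta = 1))
  m <- chain_model(4)
  nt <- node_tests(m, gd)
  row <- nt[nt$variable == "y2", ]
  expect_gt(row$difference, 0)
  expect_lt(row$p_value, 0.01)
  expect_equal(row$label, "up-expressed")
  # CI and P are mutually consistent through the Wald relation
  for (k in seq_len(nrow(nt))) {
    expect_equal(wald_pvalue_from_ci(nt$difference[k], nt$ci_lower[k],
                                     nt$ci_upper[k]),
                 nt$p_value[k], tolerance = 1e-6)
  }
  # difference = est_group1 - est_group2 exactly
  expect_equal(nt$difference, nt$est_group1 - nt$est_group2)
})

test_that("edge screen pinpoints the planted coefficient difference", {
  gd <- two_group_chain(p = 4, n = 150, seed = 31,
                        dbeta = list(i = 3, j = 2, delta = 0.7))
  m <- chain_model(4)
  et <- edge_tests(m, gd)
  expect_equal(et$edge[which.min(et$p_value)], "y3 <- y2")
  row <- et[et$edge == "y3 <- y2", ]
  expect_gt(row$difference, 0)
  expect_equal(row$label, "up-regulated")
  expect_equal(et$difference, et$est_group1 - et$est_group2)
})

test_that("on/off screen reads activation against the a-priori direction", {
  vars <- paste0("y", 1:3)
  B1 <- matrix(0, 3, 3, dimnames = list(vars, vars))
  B1["y2", "y1"] <- 0.8              # active in group 1 only
  B2 <- matrix(0, 3, 3, dimnames = list(vars, vars))
  y1 <- sim_data(sem_params(B1, diag(3)), 150, seed = 41, vars = vars)
  y2 <- sim_data(sem_params(B2, diag(3)), 150, seed = 42, vars = vars)
  gd <- grouped_data(y1, y2)
  g <- pathway_graph(data.frame(from = c("y1", "y2"), to = c("y2", "y3"),
                                type = c("activation", "activation")))
  m <- build_initial_model(g)
  oo <- onoff_tests(m, gd)
  expect_equal(oo$status[oo$edge == "y2 <- y1"], "ON/OFF")
  expect_equal(oo$status[oo$edge == "y3 <- y2"], "OFF/OFF")
})

test_that("swapping group labels negates differences and mirrors labels", {
  gd <- two_group_chain(p = 4, n = 120, seed = 51,
                        shift = list(var = "y4", delta = 0.8),
                        dbeta = list(i = 2, j = 1, delta = 0.6))
  gds <- grouped_data(gd$y2, gd$y1)
  m <- chain_model(4)
  nt <- node_tests(m, gd)
  nts <- node_tests(m, gds)
  expect_equal(nts$difference, -nt$difference, tolerance = 1e-4)
  expect_equal(nts$p_value, nt$p_value, tolerance = 1e-3)
  et <- edge_tests(m, gd)
  ets <- edge_tests(m, gds)
  expect_equal(ets$difference, -et$difference, tolerance = 1e-4)
  expect_equal(ets$p_value, et$p_value, tolerance = 1e-3)
  oo <- onoff_tests(m, gd)
  oos <- onoff_tests(m, gds)
  swap <- vapply(strsplit(oo$status, "/"), function(s)
    paste(rev(s), collapse = "/"), "")
  expect_equal(oos$status, swap)
})

test_that("with no edges the node screen reduces to two-sample mean tests", {
  vars <- paste0("y", 1:3)
  m0 <- path_model(vars, matrix(FALSE, 3, 3))
  gd <- two_group_chain(p = 3, n = 100, seed = 61,
                        shift = list(var = "y1", delta = 0.5))
  nt <- node_tests(m0, gd)
  for (v in vars) {
    d_direct <- mean(gd$y1[, v]) - mean(gd$y2[, v])
    # pooled-variance two-sample z
    sp2 <- (var(gd$y1[, v]) * (gd$n1 - 1) +
              var(gd$y2[, v]) * (gd$n2 - 1)) / (gd$n1 + gd$n2 - 2)
    z_direct <- d_direct / sqrt(sp2 * (1 / gd$n1 + 1 / gd$n2))
    row <- nt[nt$variable == v, ]
    expect_equal(row$difference, d_direct, tolerance = 1e-4)
    expect_equal(row$z, z_direct, tolerance = 0.05)
  }
})

test_that("wald CI inversion reproduces published row P-values", {
  expect_equal(round(wald_pvalue_from_ci(-0.484, -0.87, -0.10), 3), 0.014)
  expect_equal(round(wald_pvalue_from_ci(-1.04, -1.65, -0.43), 3), 0.001)
  expect_equal(wald_pvalue_from_ci(0, -1, 1), 1)
  expect_error(wald_pvalue_from_ci(0, 1, -1), "degenerate")
  expect_error(wald_pvalue_from_ci(5, -1, 1), "outside")
})

test_that("BH adjustment follows the step-up procedure", {
  tb <- data.frame(p_value = c(0.01, 0.02, 0.03, 0.04))
  expect_identical(adjust_pvalues(tb, "none"), tb)
  out <- adjust_pvalues(tb, "bh")
  expect_equal(out$p_adjusted, rep(0.04, 4))
  tb2 <- data.frame(p_value = rep(0.2, 3))
  expect_equal(adjust_pvalues(tb2, "bh")$p_adjusted, rep(0.2, 3))
  expect_error(adjust_pvalues(data.frame(x = 1), "bh"), "p_value")
})

test_that("bootstrap p-values agree with asymptotic ones for clear effects", {
  gd <- two_group_chain(p = 3, n = 120, seed = 71,
                        dbeta = list(i = 2, j = 1, delta = 0.8))
  m <- chain_model(3)
  cfg_b <- fit_config(pvalue_method = "bootstrap", bootstrap_reps = 60,
                      seed = 5)
  et_a <- edge_tests(m, gd)
  et_b <- edge_tests(m, gd, cfg_b)
  strong <- abs(et_a$z) > 2
  expect_true(all(abs(et_a$p_value[strong] - et_b$p_value[strong]) < 0.05))
})
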