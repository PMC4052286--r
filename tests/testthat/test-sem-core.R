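test_that("implied covariance matches direct matrix algebra", {
  p0 <- sem_params(matrix(0, 2, 2), diag(2))
  expect_equal(implied_covariance(p0), diag(2))

  pc <- chain_params(2, beta = 0.5)
  expect_equal(unname(implied_covariance(pc)),
               matrix(c(1, 0.5, 0.5, 1.25), 2, 2))

  # feedback loop: independent (I-B)^-1 Psi (I-B)^-T oracle
  B <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  pf <- sem_params(B, diag(2))
  A <- solve(diag(2) - B)
  expect_equal(implied_covariance(pf), A %*% diag(2) %*% t(A))
  expect_equal(implied_covariance(pf),
               matrix(c(20, 16, 16, 20), 2, 2) / 9)

  # oracle equivalence on random 3- and 4-node acyclic models
  for (p in 3:4) {
    for (seed in 1:3) {
      B <- with_seed(seed, {
        M <- matrix(0, p, p)
        M[lower.tri(M)] <- runif(p * (p - 1) / 2, -0.6, 0.6)
        M
      })
      Psi <- diag(runif(p, 0.5, 2))
      A <- solve(diag(p) - B)
      expect_equal(implied_covariance(sem_params(B, Psi)),
                   A %*% Psi %*% t(A), tolerance = 1e-12)
    }
  }

  expect_error(implied_covariance(sem_params(diag(1, 2), diag(2))),
               "singular")
})

test_that("ML fit reproduces closed-form saturated solutions", {
  m <- chain_model(2)
  S <- matrix(c(2, 1, 1, 2), 2, 2, dimnames = list(c("y1", "y2"),
                                                   c("y1", "y2")))
  f <- fit_ml(m, S = S, n = 100)
  expect_equal(unname(coef(f)["y2~y1"]), 0.5, tolerance = 1e-5)
  expect_equal(unname(coef(f)["y1~~y1"]), 2, tolerance = 1e-4)
  expect_equal(unname(coef(f)["y2~~y2"]), 1.5, tolerance = 1e-4)
  expect_equal(f$df, 0)
  expect_lt(f$chisq, 1e-6)
  expect_lt(f$srmr, 1e-6)
  # log-likelihood identity at the saturated optimum
  logl_sat <- -(f$n / 2) * (determinant(S, TRUE)$modulus[1] + 2 +
                              2 * log(2 * pi))
  expect_equal(f$loglik, logl_sat, tolerance = 1e-6)
})

test_that("chi-square equals the likelihood-ratio against the saturated model", {
  truth <- chain_params(4, beta = 0.6)
  y <- sim_data(truth, 200, seed = 21)
  m <- chain_model(4)
  f <- fit_ml(m, data = y)
  p <- 4
  S <- f$S
  logl_sat <- -(f$n / 2) * (determinant(S, TRUE)$modulus[1] + p +
                              p * log(2 * pi))
  expect_equal(f$chisq, -2 * (f$loglik - logl_sat), tolerance = 1e-6)
  expect_equal(f$df, 3)  # p(p+1)/2 - t = 10 - (3 + 4)
})

test_that("estimates recover the generating parameters within 3 SEs", {
  truth <- chain_params(4, beta = 0.5)
  y <- sim_data(truth, 2000, seed = 9)
  f <- fit_ml(chain_model(4), data = y)
  true_vec <- c(rep(0.5, 3), rep(1, 4))
  names(true_vec) <- names(coef(f))
  expect_true(all(abs(coef(f) - true_vec) <= 3 * f$se))
})

test_that("degrees of freedom guard against over-parameterization", {
  m <- chain_model(2)
  expect_equal(degrees_of_freedom(m), 0)
  vars <- c("a", "b")
  bf <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
               dimnames = list(vars, vars))
  pf <- matrix(TRUE, 2, 2)
  expect_error(degrees_of_freedom(path_model(vars, bf, pf)),
               "over-parameterized")
})

test_that("rmsea follows its closed form under both conventions", {
  expect_equal(round(rmsea(339.410, 105, 27), 3), 0.288)
  expect_equal(rmsea(5, 10, 50), 0)
  cfg <- fit_config(rmsea_n_convention = "N_minus_1")
  expect_equal(rmsea(20, 10, 101, cfg), 0.1)
  expect_error(rmsea(10, 0, 50), "d = 0")
})

test_that("close-fit P behaves like the noncentral chi-square tail", {
  # Monte-Carlo oracle for the noncentral tail probability
  d <- 20; n <- 100
  lambda <- (n - 1) * d * 0.05^2
  draws <- with_seed(4, rchisq(20000, df = d, ncp = lambda))
  q <- 30
  expect_equal(rmsea_pclose(q, d, n), mean(draws >= q), tolerance = 0.02)
  expect_gt(rmsea_pclose(d, d, n), 0.5)          # chisq at its null mean
  expect_lt(rmsea_pclose(10 * d, d, n), 1e-6)    # far tail
  # epsilon -> 0 reduces to the central survival function
  cfg0 <- fit_config(close_fit_epsilon = 1e-12)
  expect_equal(rmsea_pclose(25, d, n, cfg0),
               pchisq(25, d, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("srmr matches hand computation and is scale invariant", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  Sg <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(srmr(S, S), 0)
  expect_equal(srmr(S, Sg), sqrt(0.04 / 3))
  D <- diag(c(2, 5))
  expect_equal(srmr(D %*% S %*% D, D %*% Sg %*% D), srmr(S, Sg))
  expect_error(srmr(S, diag(3)), "dimension")
})

test_that("standard errors match the analytic regression SE and shrink with n", {
  truth <- chain_params(2, beta = 0.7)
  y <- sim_data(truth, 500, seed = 31)
  f <- fit_ml(chain_model(2), data = y)
  # large-sample SE of a simple regression slope: sqrt(psi22 / (n * s11))
  se_ols <- sqrt(coef(f)["y2~~y2"] / (f$n * f$S[1, 1]))
  expect_equal(unname(f$se["y2~y1"]), unname(se_ols), tolerance = 0.05)

  y4 <- sim_data(truth, 2000, seed = 31)
  f4 <- fit_ml(chain_model(2), data = y4)
  expect_equal(unname(f$se["y2~y1"] / f4$se["y2~y1"]), 2, tolerance = 0.35)
})

test_that("a bow pair makes the model empirically under-identified", {
  # y2 <- y1 plus a free error covariance on the same pair: the path
  # coefficient and the covariance trade off one-for-one
  vars <- paste0("y", 1:3)
  bf <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
  bf["y2", "y1"] <- bf["y3", "y2"] <- TRUE
  pf <- matrix(FALSE, 3, 3, dimnames = list(vars, vars))
  pf["y1", "y2"] <- pf["y2", "y1"] <- TRUE
  m <- path_model(vars, bf, pf)
  expect_equal(nrow(check_bow_free(m)), 1)
  y <- sim_data(chain_params(3, 0.5), 300, seed = 2)
  f <- suppressWarnings(fit_ml(m, data = y, compute_se = FALSE))
  expect_error(standard_errors(f), "under-identified")
})

test_that("modification indices approximate the refit chi-square drop", {
  # truth = chain plus a mildly misspecified extra y4 <- y1 edge; the score
  # statistic is a quadratic approximation, so the comparison uses a small
  # planted effect at a large n
  vars <- paste0("y", 1:4)
  B <- matrix(0, 4, 4, dimnames = list(vars, vars))
  B["y2", "y1"] <- B["y3", "y2"] <- B["y4", "y3"] <- 0.5
  B["y4", "y1"] <- 0.1
  y <- sim_data(sem_params(B, diag(4)), 1000, seed = 1, vars = vars)
  m <- chain_model(4)
  f <- fit_ml(m, data = y, compute_se = FALSE)
  mis <- modification_indices(f)
  top <- mis[1, ]
  expect_setequal(c(top$target, top$source), c("y1", "y4"))
  expect_equal(top$type, "beta")
  m2 <- path_model(m$variables,
                   `[<-`(m$beta_free, top$target, top$source, TRUE),
                   m$psi_free)
  f2 <- fit_ml(m2, data = y, compute_se = FALSE)
  drop <- f$chisq - f2$chisq
  expect_lt(abs(top$mi - drop) / drop, 0.2)
  # EPC points in the right direction
  expect_gt(top$epc, 0)
})

test_that("modification indices vanish when the model already fits exactly", {
  truth <- chain_params(3, beta = 0.5)
  S <- implied_covariance(truth)
  dimnames(S) <- list(paste0("y", 1:3), paste0("y", 1:3))
  f <- fit_ml(chain_model(3), S = S, n = 100, compute_se = FALSE)
  expect_lt(f$chisq, 1e-8)
  mis <- modification_indices(f)
  expect_true(all(mis$mi < 1e-4, na.rm = TRUE))
  expect_error(
    modification_indices(f, data.frame(type = "beta", target = "y2",
                                       source = "y1")),
    "already free")
})

test_that("freeing a parameter never increases the chi-square", {
  y <- sim_data(chain_params(4, 0.5), 300, seed = 23)
  m <- chain_model(4)
  f <- fit_ml(m, data = y, compute_se = FALSE)
  cands <- utils::head(modification_indices(f), 3)
  for (k in seq_len(nrow(cands))) {
    if (cands$type[k] != "beta") next
    m2 <- path_model(m$variables,
                     `[<-`(m$beta_free, cands$target[k], cands$source[k],
                           TRUE), m$psi_free)
    f2 <- fit_ml(m2, data = y, compute_se = FALSE)
    expect_lte(f2$chisq, f$chisq + 1e-6)
  }
})

test_that("effect decomposition sums edge products over directed paths", {
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.4
  B[3, 2] <- 0.5
  eff <- effects_decomposition(B)
  expect_equal(eff$TE[3, 1], 0.2)
  expect_equal(eff$DE[3, 1], 0)
  expect_equal(eff$IE[3, 1], 0.2)

  # brute-force path enumeration oracle on a random 4-node DAG
  B4 <- with_seed(2, {
    M <- matrix(0, 4, 4)
    M[lower.tri(M)] <- runif(6, -0.8, 0.8)
    M
  })
  eff4 <- effects_decomposition(B4)
  ig <- igraph::graph_from_adjacency_matrix(t(B4) != 0)
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      paths <- igraph::all_simple_paths(ig, from = j, to = i,
                                        mode = "out")
      te <- sum(vapply(paths, function(pp) {
        idx <- as.integer(pp)
        prod(B4[cbind(idx[-1], idx[-length(idx)])])
      }, numeric(1)))
      expect_equal(eff4$TE[i, j], te, tolerance = 1e-12)
    }
  }

  z <- effects_decomposition(matrix(0, 3, 3))
  expect_true(all(z$TE == 0) && all(z$IE == 0))
  bad <- matrix(c(0, 1.2, 1.2, 0), 2, 2)
  expect_error(effects_decomposition(bad), "divergent")
})

test_that("bootstrap refits are reproducible and centred on the estimate", {
  y <- sim_data(chain_params(3, 0.5), 150, seed = 41)
  m <- chain_model(3)
  b1 <- bootstrap_fit(y, m, reps = 1, seed = 99)
  b2 <- bootstrap_fit(y, m, reps = 1, seed = 99)
  expect_identical(b1$theta, b2$theta)

  bs <- bootstrap_fit(y, m, reps = 60, mode = "nonparametric", seed = 7)
  expect_lt(bs$failure_rate, 0.1)
  bmean <- colMeans(bs$theta, na.rm = TRUE)
  bse <- apply(bs$theta, 2, sd, na.rm = TRUE) / sqrt(sum(!is.na(bs$chisq)))
  expect_true(all(abs(bmean - coef(bs$fit)) <= 4 * bse + 0.05))

  # model-based bootstrap SD tracks the asymptotic SE
  f <- fit_ml(m, data = y)
  bm <- bootstrap_fit(y, m, reps = 100, mode = "model_based", seed = 8)
  sd_b <- apply(bm$theta, 2, sd, na.rm = TRUE)
  expect_equal(unname(sd_b["y2~y1"]), unname(f$se["y2~y1"]),
               tolerance = 0.3)
})
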