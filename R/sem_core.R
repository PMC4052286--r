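#' Fitting configuration for SEM estimation
#'
#' @param chisq_n_convention `"N"` (default) or `"N_minus_1"`: multiplier of
#'   the ML discrepancy giving the chi-square statistic (and the divisor of
#'   the sample covariance computed from raw data). The default total-N
#'   convention reproduces published RMSEA values such as 0.288 from
#'   chi-square 339.410, df 105, N 27.
#' @param rmsea_n_convention denominator convention for RMSEA, `"N"` default.
#' @param close_fit_epsilon RMSEA null value for the close-fit test (0.05).
#' @param alpha significance level for screens and stopping rules (0.05).
#' @param z_threshold one-sided z cut-off for keeping a freed parameter
#'   (1.64, i.e. P < 0.05 one-sided).
#' @param srmr_adequate SRMR value regarded as adequate fit (0.10).
#' @param max_iter optimizer iteration cap per start.
#' @param gradient_tolerance relative convergence tolerance.
#' @param n_restarts jittered restarts tried on non-convergence.
#' @param seed seed for restart jitter and any bootstrap defaults.
#' @param pvalue_method `"asymptotic"` (default) or `"bootstrap"` for the
#'   group-difference screens.
#' @param bootstrap_reps default bootstrap replicate count B.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(chisq_n_convention = c("N", "N_minus_1"),
                       rmsea_n_convention = c("N", "N_minus_1"),
                       close_fit_epsilon = 0.05, alpha = 0.05,
                       z_threshold = 1.64, srmr_adequate = 0.10,
                       max_iter = 1000L, gradient_tolerance = 1e-10,
                       n_restarts = 5L, seed = 1L,
                       pvalue_method = c("asymptotic", "bootstrap"),
                       bootstrap_reps = 1000L) {
  stopifnot(close_fit_epsilon > 0, alpha > 0, z_threshold > 0,
            srmr_adequate > 0)
  structure(list(
    chisq_n_convention = match.arg(chisq_n_convention),
    rmsea_n_convention = match.arg(rmsea_n_convention),
    close_fit_epsilon = close_fit_epsilon, alpha = alpha,
    z_threshold = z_threshold, srmr_adequate = srmr_adequate,
    max_iter = as.integer(max_iter),
    gradient_tolerance = gradient_tolerance,
    n_restarts = as.integer(n_restarts), seed = seed,
    pvalue_method = match.arg(pvalue_method),
    bootstrap_reps = as.integer(bootstrap_reps)
  ), class = "fit_config")
}

chisq_multiplier <- function(n, config) {
  if (config$chisq_n_convention == "N") n else n - 1
}

#' SEM parameter matrices
#'
#' @param beta p x p path-coefficient matrix (`beta[i, j]` is the effect of
#'   variable j on variable i); zero where fixed.
#' @param psi p x p symmetric error covariance matrix with positive diagonal.
#' @param means optional length-p mean (intercept) vector.
#' @return object of class `sem_params`.
#' @export
sem_params <- function(beta, psi, means = NULL) {
  stopifnot(is.matrix(beta), is.matrix(psi),
            nrow(beta) == ncol(beta), all(dim(beta) == dim(psi)))
  if (max(abs(psi - t(psi))) > 1e-10) stopf("psi must be symmetric")
  if (any(diag(psi) <= 0)) stopf("psi diagonal must be positive")
  if (!is.null(means)) stopifnot(length(means) == nrow(beta))
  structure(list(beta = beta, psi = psi, means = means),
            class = "sem_params")
}

#' Model-implied covariance matrix
#'
#' Sigma(theta) = (I - B)^-1 Psi (I - B)^-T for the linear system
#' Y = B Y + U with Cov(U) = Psi.
#'
#' @param params a [sem_params()].
#' @return symmetric positive semi-definite matrix.
#' @export
implied_covariance <- function(params) {
  stopifnot(inherits(params, "sem_params"))
  p <- nrow(params$beta)
  A <- tryCatch(solve(diag(p) - params$beta),
                error = function(e) stopf("non-convergent system: I - beta is singular"))
  S <- A %*% params$psi %*% t(A)
  (S + t(S)) / 2
}

# ---- free-parameter maps ------------------------------------------------
# A map is a data.frame(group, type, i, j, idx, name): one row per model
# slot, idx pointing into the packed parameter vector theta (equality
# constraints make slots share an idx).

map_single_group <- function(model, mean_structure = model$mean_structure,
                             group = 1L) {
  vars <- model$variables
  p <- length(vars)
  rows <- list()
  bi <- which(model$beta_free, arr.ind = TRUE)
  if (nrow(bi)) {
    rows[[1]] <- data.frame(group = group, type = "beta",
                            i = bi[, 1], j = bi[, 2],
                            name = paste0(vars[bi[, 1]], "~", vars[bi[, 2]]),
                            stringsAsFactors = FALSE)
  }
  rows[[2]] <- data.frame(group = group, type = "psi",
                          i = seq_len(p), j = seq_len(p),
                          name = paste0(vars, "~~", vars),
                          stringsAsFactors = FALSE)
  pl <- which(model$psi_free & lower.tri(model$psi_free), arr.ind = TRUE)
  if (nrow(pl)) {
    rows[[3]] <- data.frame(group = group, type = "psi",
                            i = pl[, 1], j = pl[, 2],
                            name = paste0(vars[pl[, 1]], "~~", vars[pl[, 2]]),
                            stringsAsFactors = FALSE)
  }
  if (isTRUE(mean_structure)) {
    rows[[4]] <- data.frame(group = group, type = "alpha",
                            i = seq_len(p), j = 0L,
                            name = paste0(vars, "~1"),
                            stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  map$idx <- seq_len(nrow(map))
  map
}

map_matrices <- function(map, theta, p, group = 1L) {
  B <- matrix(0, p, p)
  Psi <- matrix(0, p, p)
  alpha <- rep(0, p)
  sub <- map[map$group == group, , drop = FALSE]
  for (k in seq_len(nrow(sub))) {
    v <- theta[sub$idx[k]]
    if (sub$type[k] == "beta") {
      B[sub$i[k], sub$j[k]] <- v
    } else if (sub$type[k] == "psi") {
      Psi[sub$i[k], sub$j[k]] <- v
      Psi[sub$j[k], sub$i[k]] <- v
    } else {
      alpha[sub$i[k]] <- v
    }
  }
  list(B = B, Psi = Psi, alpha = alpha)
}

# ML discrepancy and its analytic gradient for one group.
# F = log|Sigma| + tr(S Sigma^-1) - log|S| - p [+ r' Sigma^-1 r], r = ybar - mu,
# mu = A alpha, A = (I - B)^-1.
group_F_grad <- function(B, Psi, alpha, S, logdetS, ybar, want_grad = TRUE) {
  p <- nrow(S)
  A <- tryCatch(solve(diag(p) - B), error = function(e) NULL)
  if (is.null(A)) return(NULL)
  Sigma <- A %*% Psi %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Sigma_inv <- chol2inv(R)
  logdetSigma <- 2 * sum(log(diag(R)))
  Fv <- logdetSigma + sum(Sigma_inv * S) - logdetS - p
  use_mean <- !is.null(ybar)
  if (use_mean) {
    mu <- drop(A %*% alpha)
    r <- ybar - mu
    Fv <- Fv + drop(crossprod(r, Sigma_inv %*% r))
  }
  if (!want_grad) return(list(F = Fv))
  M <- S
  if (use_mean) M <- M + tcrossprod(r)
  G <- Sigma_inv - Sigma_inv %*% M %*% Sigma_inv
  Gbeta <- 2 * t(A) %*% G %*% Sigma
  Gpsi <- t(A) %*% G %*% A
  Galpha <- NULL
  if (use_mean) {
    si_r <- Sigma_inv %*% r
    Galpha <- drop(-2 * t(A) %*% si_r)
    Gbeta <- Gbeta - 2 * (t(A) %*% si_r) %*% t(mu)
  }
  list(F = Fv, Gbeta = Gbeta, Gpsi = Gpsi, Galpha = Galpha)
}

# Objective closure over a map and per-group moments.
# groups: list of list(S, ybar (or NULL), logdetS, p, w) — w multiplies F_g.
sem_objective <- function(map, groups) {
  nth <- max(map$idx)
  list(
    fn = function(theta) {
      total <- 0
      for (g in seq_along(groups)) {
        gd <- groups[[g]]
        mats <- map_matrices(map, theta, gd$p, group = g)
        res <- group_F_grad(mats$B, mats$Psi, mats$alpha, gd$S, gd$logdetS,
                            gd$ybar, want_grad = FALSE)
        if (is.null(res) || !is.finite(res$F)) return(1e10)
        total <- total + gd$w * res$F
      }
      total
    },
    gr = function(theta) {
      grad <- rep(0, nth)
      for (g in seq_along(groups)) {
        gd <- groups[[g]]
        mats <- map_matrices(map, theta, gd$p, group = g)
        res <- group_F_grad(mats$B, mats$Psi, mats$alpha, gd$S, gd$logdetS,
                            gd$ybar, want_grad = TRUE)
        if (is.null(res)) return(grad)
        sub <- map[map$group == g, , drop = FALSE]
        for (k in seq_len(nrow(sub))) {
          gk <- switch(sub$type[k],
            beta = res$Gbeta[sub$i[k], sub$j[k]],
            psi = if (sub$i[k] == sub$j[k]) res$Gpsi[sub$i[k], sub$i[k]]
                  else 2 * res$Gpsi[sub$i[k], sub$j[k]],
            alpha = res$Galpha[sub$i[k]])
          grad[sub$idx[k]] <- grad[sub$idx[k]] + gd$w * gk
        }
      }
      grad
    }
  )
}

# OLS-based start values: regress each endogenous variable on its parents.
start_values <- function(map, model, groups_raw) {
  vars <- model$variables
  p <- length(vars)
  nth <- max(map$idx)
  theta <- rep(0, nth)
  wsum <- rep(0, nth)
  add <- function(idx, val) {
    theta[idx] <<- (theta[idx] * wsum[idx] + val) / (wsum[idx] + 1)
    wsum[idx] <<- wsum[idx] + 1
  }
  for (g in seq_along(groups_raw)) {
    S <- groups_raw[[g]]$S
    ybar <- groups_raw[[g]]$ybar
    sub <- map[map$group == g, , drop = FALSE]
    B0 <- matrix(0, p, p)
    for (i in seq_len(p)) {
      pa <- sub$j[sub$type == "beta" & sub$i == i]
      psi_ii <- S[i, i]
      if (length(pa)) {
        b <- tryCatch(solve(S[pa, pa, drop = FALSE], S[pa, i]),
                      error = function(e) rep(0, length(pa)))
        b <- pmin(pmax(b, -5), 5)
        B0[i, pa] <- b
        psi_ii <- max(S[i, i] - drop(S[i, pa, drop = FALSE] %*% b),
                      0.05 * S[i, i])
      }
      for (k in which(sub$type == "beta" & sub$i == i)) {
        add(sub$idx[k], B0[i, sub$j[k]])
      }
      kd <- which(sub$type == "psi" & sub$i == i & sub$j == i)
      add(sub$idx[kd], psi_ii)
    }
    for (k in which(sub$type == "psi" & sub$i != sub$j)) {
      add(sub$idx[k], 0)
    }
    if (!is.null(ybar)) {
      a0 <- drop((diag(p) - B0) %*% ybar)
      for (k in which(sub$type == "alpha")) add(sub$idx[k], a0[sub$i[k]])
    }
  }
  theta
}

# Quasi-Newton minimisation of the weighted discrepancy; error-variance
# parameters are optimised on the log scale to enforce positivity. Jittered
# restarts (deterministic under config$seed) recover from bad starts.
fit_sem_internal <- function(map, groups, model, config, start = NULL) {
  obj <- sem_objective(map, groups)
  # indices of psi-diagonal parameters in theta
  diag_idx <- sort(unique(map$idx[map$type == "psi" & map$i == map$j]))
  to_opt <- function(theta) {
    theta[diag_idx] <- log(pmax(theta[diag_idx], 1e-8))
    theta
  }
  from_opt <- function(eta) {
    eta[diag_idx] <- exp(pmin(eta[diag_idx], 30))
    eta
  }
  fn_opt <- function(eta) obj$fn(from_opt(eta))
  gr_opt <- function(eta) {
    theta <- from_opt(eta)
    g <- obj$gr(theta)
    g[diag_idx] <- g[diag_idx] * theta[diag_idx]
    g
  }
  if (is.null(start)) start <- start_values(map, model, groups)
  best <- NULL
  attempts <- with_preserved_seed(config$seed, {
    lapply(seq_len(config$n_restarts + 1L), function(a) {
      s <- to_opt(start)
      if (a > 1) s <- s + stats::rnorm(length(s), sd = 0.2 * a)
      s
    })
  })
  for (s in attempts) {
    res <- tryCatch(
      stats::optim(s, fn_opt, gr_opt, method = "BFGS",
                   control = list(maxit = config$max_iter,
                                  reltol = config$gradient_tolerance)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e9) next
    ok <- res$convergence == 0
    if (is.null(best) || res$value < best$value - 1e-10) {
      best <- res
      best$converged <- ok
    }
    if (!is.null(best) && best$converged) break
  }
  if (is.null(best)) {
    stopf("SEM optimization failed to produce any admissible solution")
  }
  theta <- from_opt(best$par)
  names(theta) <- vapply(seq_len(max(map$idx)), function(ix) {
    map$name[map$idx == ix][1]
  }, character(1))
  list(theta = theta, value = best$value, converged = isTRUE(best$converged),
       objective = obj)
}

#' Degrees of freedom of a path model
#'
#' `p (p + 1) / 2` distinct covariance moments minus the number of free
#' covariance-structure parameters. Mean parameters are saturated (one
#' intercept per variable per group) and cancel against the mean moments.
#'
#' @param model a [path_model()].
#' @param p number of observed variables (defaults to the model's).
#' @return integer degrees of freedom.
#' @export
degrees_of_freedom <- function(model, p = length(model$variables)) {
  t_cov <- sum(model$beta_free) + p +
    sum(model$psi_free[lower.tri(model$psi_free)])
  moments <- p * (p + 1) / 2
  if (t_cov > moments) stopf("over-parameterized: t = %d > %d", t_cov, moments)
  as.integer(moments - t_cov)
}

#' Root mean square error of approximation
#'
#' `sqrt(max(0, (chisq - d) / (d * m)))` with `m` the sample-size denominator
#' per `config$rmsea_n_convention` (total N by default).
#'
#' @param chisq chi-square statistic.
#' @param d degrees of freedom (>= 1).
#' @param n sample size.
#' @param config a [fit_config()].
#' @return RMSEA value.
#' @export
rmsea <- function(chisq, d, n, config = fit_config()) {
  if (d < 1) stopf("RMSEA undefined for d = 0")
  if (n < 2) stopf("RMSEA requires n >= 2")
  m <- if (config$rmsea_n_convention == "N") n else n - 1
  sqrt(max(0, (chisq - d) / (d * m)))
}

#' Close-fit probability for the RMSEA
#'
#' P-value of the "close fit" hypothesis (RMSEA <= epsilon) from the
#' noncentral chi-square with noncentrality `lambda = (n - 1) d epsilon^2`:
#' the upper-tail probability of the observed chi-square. Close fit is not
#' rejected when P > alpha.
#'
#' @inheritParams rmsea
#' @return probability in `[0, 1]`.
#' @export
rmsea_pclose <- function(chisq, d, n, config = fit_config()) {
  if (d < 1) stopf("close-fit P undefined for d = 0")
  if (n < 2) stopf("close-fit P requires n >= 2")
  lambda <- (n - 1) * d * config$close_fit_epsilon^2
  stats::pchisq(chisq, df = d, ncp = lambda, lower.tail = FALSE)
}

#' Standardized root mean square residual
#'
#' Root mean square of the correlation-scale residuals between the sample and
#' implied covariance matrices over the `p (p + 1) / 2` distinct moments
#' (diagonal included).
#'
#' @param S sample covariance matrix.
#' @param Sigma implied covariance matrix of the same dimension.
#' @return SRMR value.
#' @export
srmr <- function(S, Sigma) {
  if (!all(dim(S) == dim(Sigma))) stopf("dimension mismatch in srmr")
  p <- nrow(S)
  d <- diag(S)
  if (any(d <= 0)) stopf("non-positive diagonal in S")
  resid2 <- (S - Sigma)^2 / tcrossprod(d)
  sqrt(sum(resid2[lower.tri(resid2, diag = TRUE)]) / (p * (p + 1) / 2))
}

# sample moments with the divisor implied by the chi-square convention
sample_moments <- function(data, config) {
  data <- as.matrix(data)
  drop_rows <- rowSums(is.na(data)) > 0
  if (any(drop_rows)) {
    message(sprintf("listwise deletion: %d incomplete row(s) removed",
                    sum(drop_rows)))
    data <- data[!drop_rows, , drop = FALSE]
  }
  n <- nrow(data)
  ybar <- colMeans(data)
  xc <- sweep(data, 2, ybar)
  m <- chisq_multiplier(n, config)
  S <- crossprod(xc) / m
  list(S = S, ybar = ybar, n = n)
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the Gaussian ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p` over the free
#' parameters; the chi-square statistic is `m * F` at the optimum with `m`
#' per `config$chisq_n_convention`.
#'
#' @param model a [path_model()].
#' @param data optional n x p data matrix (columns matching
#'   `model$variables`); incomplete rows are removed listwise.
#' @param S sample covariance (used with `n` when `data` is absent).
#' @param n sample size when `S` is supplied directly.
#' @param config a [fit_config()].
#' @param compute_se compute observed-information standard errors (default
#'   TRUE).
#' @return object of class `sem_fit` with parameter estimates, standard
#'   errors, log-likelihood, chi-square, df, P, RMSEA (+ close-fit P), SRMR
#'   and the machinery needed for [modification_indices()].
#' @export
fit_ml <- function(model, data = NULL, S = NULL, n = NULL,
                   config = fit_config(), compute_se = TRUE) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$variables
  p <- length(vars)
  ybar <- NULL
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (!all(vars %in% colnames(data))) {
      stopf("data columns missing model variables: %s",
            paste(setdiff(vars, colnames(data)), collapse = ", "))
    }
    mom <- sample_moments(data[, vars, drop = FALSE], config)
    S <- mom$S
    n <- mom$n
    if (isTRUE(model$mean_structure)) ybar <- mom$ybar
  } else {
    if (is.null(S) || is.null(n)) stopf("supply either data or S with n")
    S <- as.matrix(S)
    if (is.null(dimnames(S))) dimnames(S) <- list(vars, vars)
    S <- S[vars, vars]
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stopf("sample covariance is not positive definite")
  if (n <= p) warnf("sample size n = %d not larger than p = %d", n, p)

  m <- chisq_multiplier(n, config)
  map <- map_single_group(model, mean_structure = !is.null(ybar))
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  groups <- list(list(S = S, ybar = ybar, logdetS = logdetS, p = p, w = m))
  res <- fit_sem_internal(map, groups, model, config)
  if (!res$converged) {
    stopf("SEM fit did not converge after %d restarts (best F = %.4g)",
          config$n_restarts, res$value / m)
  }
  theta <- res$theta
  mats <- map_matrices(map, theta, p, group = 1L)
  dimnames(mats$B) <- dimnames(mats$Psi) <- list(vars, vars)
  Sigma <- implied_covariance(sem_params(mats$B, mats$Psi))
  chisq <- max(res$value, 0)
  d <- degrees_of_freedom(model, p)
  loglik <- -(n / 2) * (determinant(Sigma, logarithm = TRUE)$modulus[1] +
                          sum(solve(Sigma) * S) + p * log(2 * pi))
  fit <- structure(list(
    model = model, params = sem_params(mats$B, mats$Psi,
                                       if (!is.null(ybar)) mats$alpha),
    theta = theta, map = map, S = S, ybar = ybar, n = n, m = m,
    config = config, converged = res$converged,
    loglik = loglik, chisq = chisq, df = d,
    p_value = if (d > 0) stats::pchisq(chisq, d, lower.tail = FALSE) else NA_real_,
    rmsea = if (d > 0) rmsea(chisq, d, n, config) else NA_real_,
    rmsea_pclose = if (d > 0) rmsea_pclose(chisq, d, n, config) else NA_real_,
    srmr = srmr(S, Sigma), Sigma = Sigma
  ), class = "sem_fit")
  if (compute_se) {
    fit$se <- tryCatch(standard_errors(fit), error = function(e) {
      warnf("standard errors unavailable: %s", conditionMessage(e))
      setNames(rep(NA_real_, length(theta)), names(theta))
    })
  }
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> p = %d, n = %d\n", nrow(x$S), x$n))
  cat(sprintf("  chisq(df) = %.3f (%d), P = %.4g\n", x$chisq, x$df,
              x$p_value))
  if (!is.na(x$rmsea)) {
    cat(sprintf("  RMSEA = %.3f (P-close = %.3f), SRMR = %.3f\n",
                x$rmsea, x$rmsea_pclose, x$srmr))
  } else {
    cat(sprintf("  saturated model, SRMR = %.3g\n", x$srmr))
  }
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, ...) object$theta

#' Observed-information standard errors
#'
#' Square roots of the diagonal of the inverse observed information, the
#' numerical Hessian of the negative log-likelihood at the optimum.
#'
#' @param fit a [fit_ml()] result.
#' @return named vector of standard errors (one per free parameter).
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  p <- nrow(fit$S)
  logdetS <- determinant(fit$S, logarithm = TRUE)$modulus[1]
  groups <- list(list(S = fit$S, ybar = fit$ybar, logdetS = logdetS,
                      p = p, w = fit$n))
  obj <- sem_objective(fit$map, groups)
  H <- hessian_from_grad(obj$gr, fit$theta)
  info <- H / 2
  if (!all(is.finite(info)) || rcond(info) < 1e-8) {
    stopf("empirically under-identified: singular information matrix")
  }
  V <- tryCatch(solve(info), error = function(e)
    stopf("empirically under-identified: singular information matrix"))
  dv <- diag(V)
  if (any(!is.finite(dv)) || any(dv < -1e-6)) {
    stopf("empirically under-identified: information not positive definite")
  }
  setNames(sqrt(pmax(dv, 0)), names(fit$theta))
}

# default MI candidates: every fixed path coefficient and error covariance
default_candidates <- function(model) {
  vars <- model$variables
  p <- length(vars)
  fixed_b <- which(!model$beta_free & !diag(p), arr.ind = TRUE)
  fixed_p <- which(!model$psi_free & lower.tri(model$psi_free),
                   arr.ind = TRUE)
  rbind(
    if (nrow(fixed_b)) data.frame(type = "beta",
                                  target = vars[fixed_b[, 1]],
                                  source = vars[fixed_b[, 2]],
                                  stringsAsFactors = FALSE),
    if (nrow(fixed_p)) data.frame(type = "psi",
                                  target = vars[fixed_p[, 1]],
                                  source = vars[fixed_p[, 2]],
                                  stringsAsFactors = FALSE)
  )
}

#' Modification indices for fixed parameters
#'
#' Univariate score (Lagrange-multiplier) statistics: for each fixed-at-zero
#' candidate parameter, the 1-df estimate of the chi-square decrease that
#' freeing it would yield, together with the expected parameter change (EPC).
#'
#' @param fit a converged [fit_ml()] result.
#' @param candidates data.frame(type, target, source); defaults to all fixed
#'   path coefficients and error covariances.
#' @return data.frame (param, type, target, source, mi, epc) sorted by
#'   decreasing MI.
#' @export
modification_indices <- function(fit, candidates = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stopf("modification indices require a converged fit")
  model <- fit$model
  vars <- model$variables
  p <- length(vars)
  if (is.null(candidates)) candidates <- default_candidates(model)
  if (is.null(candidates) || !nrow(candidates)) {
    return(data.frame(param = character(), type = character(),
                      target = character(), source = character(),
                      mi = numeric(), epc = numeric(),
                      stringsAsFactors = FALSE))
  }
  for (k in seq_len(nrow(candidates))) {
    ti <- match(candidates$target[k], vars)
    si <- match(candidates$source[k], vars)
    if (is.na(ti) || is.na(si)) stopf("unknown variable in candidate %d", k)
    free <- if (candidates$type[k] == "beta") {
      model$beta_free[ti, si]
    } else {
      model$psi_free[ti, si]
    }
    if (free) {
      stopf("candidate %s is already free",
            paste0(candidates$target[k],
                   if (candidates$type[k] == "beta") "~" else "~~",
                   candidates$source[k]))
    }
  }
  map <- fit$map
  nfree <- max(map$idx)
  sep <- ifelse(candidates$type == "beta", "~", "~~")
  ext <- data.frame(group = 1L, type = candidates$type,
                    i = match(candidates$target, vars),
                    j = match(candidates$source, vars),
                    name = paste0(candidates$target, sep, candidates$source),
                    idx = nfree + seq_len(nrow(candidates)),
                    stringsAsFactors = FALSE)
  map_ext <- rbind(map[c("group", "type", "i", "j", "name", "idx")], ext)
  theta_ext <- c(fit$theta, rep(0, nrow(ext)))
  logdetS <- determinant(fit$S, logarithm = TRUE)$modulus[1]
  groups <- list(list(S = fit$S, ybar = fit$ybar, logdetS = logdetS,
                      p = p, w = 1))
  obj <- sem_objective(map_ext, groups)
  g <- obj$gr(theta_ext)
  H <- hessian_from_grad(obj$gr, theta_ext, h = 1e-4)
  Hff <- H[seq_len(nfree), seq_len(nfree), drop = FALSE]
  mi <- epc <- rep(NA_real_, nrow(ext))
  Hff_inv <- tryCatch(solve(Hff), error = function(e) NULL)
  for (k in seq_len(nrow(ext))) {
    jj <- ext$idx[k]
    schur <- if (is.null(Hff_inv)) NA_real_ else {
      H[jj, jj] - drop(H[jj, seq_len(nfree)] %*% Hff_inv %*%
                         H[seq_len(nfree), jj])
    }
    if (is.finite(schur) && schur > 1e-10) {
      mi[k] <- (fit$m / 2) * g[jj]^2 / schur
      epc[k] <- -g[jj] / schur
    }
  }
  out <- data.frame(param = ext$name, type = candidates$type,
                    target = candidates$target, source = candidates$source,
                    mi = mi, epc = epc, stringsAsFactors = FALSE)
  out <- out[order(-out$mi, out$target, out$source), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total, direct and indirect effects
#'
#' `TE = (I - B)^-1 - I`, `DE = B`, `IE = TE - DE`; the total effect sums the
#' edge-coefficient products over all directed paths, which converges iff the
#' spectral radius of B is below one.
#'
#' @param beta path coefficient matrix.
#' @return list of matrices `TE`, `DE`, `IE`.
#' @export
effects_decomposition <- function(beta) {
  stopifnot(is.matrix(beta), nrow(beta) == ncol(beta))
  rho <- max(Mod(eigen(beta, only.values = TRUE)$values))
  if (rho >= 1) stopf("divergent feedback: spectral radius %.3f >= 1", rho)
  TE <- solve(diag(nrow(beta)) - beta) - diag(nrow(beta))
  list(TE = TE, DE = beta, IE = TE - beta)
}

#' Bootstrap distributions of SEM estimates
#'
#' Nonparametric mode resamples data rows with replacement; model-based mode
#' simulates replicates from the fitted model. Each replicate is refitted;
#' non-convergent replicates are skipped and counted.
#'
#' @param data n x p data matrix.
#' @param model a [path_model()].
#' @param reps number of bootstrap samples B (paper default 100 or 1000).
#' @param mode `"nonparametric"` or `"model_based"`.
#' @param seed RNG seed; fixed seed gives bit-identical reruns.
#' @param config a [fit_config()].
#' @return list with `theta` (reps x t matrix of estimates), `chisq`,
#'   `n_failed`, `failure_rate`, and the point `fit`.
#' @export
bootstrap_fit <- function(data, model, reps = 100L,
                          mode = c("nonparametric", "model_based"),
                          seed = NULL, config = fit_config()) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1)
  data <- as.matrix(data)[, model$variables, drop = FALSE]
  fit <- fit_ml(model, data = data, config = config, compute_se = FALSE)
  n <- fit$n
  sim_params <- sem_params(fit$params$beta, fit$params$psi,
                           if (isTRUE(model$mean_structure)) fit$params$means
                           else colMeans(data))
  draws <- with_preserved_seed(seed, {
    lapply(seq_len(reps), function(b) {
      if (mode == "nonparametric") {
        data[sample.int(n, n, replace = TRUE), , drop = FALSE]
      } else {
        simulate_sem(sim_params, n, seed = NULL)
      }
    })
  })
  theta_mat <- matrix(NA_real_, reps, length(fit$theta),
                      dimnames = list(NULL, names(fit$theta)))
  chisq <- rep(NA_real_, reps)
  failed <- 0L
  for (b in seq_len(reps)) {
    rb <- draws[[b]]
    colnames(rb) <- model$variables
    fb <- tryCatch(fit_ml(model, data = rb, config = config,
                          compute_se = FALSE),
                   error = function(e) NULL)
    if (is.null(fb)) {
      failed <- failed + 1L
    } else {
      theta_mat[b, ] <- fb$theta
      chisq[b] <- fb$chisq
    }
  }
  list(theta = theta_mat, chisq = chisq, n_failed = failed,
       failure_rate = failed / reps, fit = fit, mode = mode)
}
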