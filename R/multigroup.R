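#' Two-group expression data container
#'
#' @param y1 experimental-group n1 x p matrix (coding: experimental = 1).
#' @param y2 control-group n2 x p matrix (coding: control = 0), identical
#'   column set and order.
#' @return object of class `grouped_data`.
#' @export
grouped_data <- function(y1, y2) {
  y1 <- as.matrix(y1)
  y2 <- as.matrix(y2)
  if (is.null(colnames(y1)) || is.null(colnames(y2)) ||
      !identical(colnames(y1), colnames(y2))) {
    stopf("group matrices must share identical, identically ordered columns")
  }
  if (nrow(y1) < 3 || nrow(y2) < 3) stopf("each group needs n >= 3")
  structure(list(y1 = y1, y2 = y2, n1 = nrow(y1), n2 = nrow(y2),
                 coding = c(experimental = 1, control = 0)),
            class = "grouped_data")
}

map_two_group <- function(model, constraints = c("none", "equal_means",
                                                 "equal_cov_structure",
                                                 "both")) {
  constraints <- match.arg(constraints)
  m1 <- map_single_group(model, mean_structure = TRUE, group = 1L)
  m2 <- map_single_group(model, mean_structure = TRUE, group = 2L)
  share_cov <- constraints %in% c("equal_cov_structure", "both")
  share_mean <- constraints %in% c("equal_means", "both")
  nxt <- max(m1$idx)
  for (k in seq_len(nrow(m2))) {
    shared <- if (m2$type[k] == "alpha") share_mean else share_cov
    if (shared) {
      m2$idx[k] <- m1$idx[m1$name == m2$name[k]]
    } else {
      nxt <- nxt + 1L
      m2$idx[k] <- nxt
    }
  }
  m2$name <- ifelse(m2$idx > max(m1$idx), paste0("g2:", m2$name), m2$name)
  m1$name <- ifelse(m1$idx %in% m2$idx, m1$name, paste0("g1:", m1$name))
  map <- rbind(m1, m2)
  rownames(map) <- NULL
  map
}

#' Joint two-group ML fit with equality constraints
#'
#' Fits the path model to both groups simultaneously with the mean structure
#' on, optionally constraining intercepts (`equal_means`), all free path
#' coefficients and error covariances (`equal_cov_structure`), or both, to
#' be equal across groups.
#'
#' @param model a [path_model()].
#' @param gd a [grouped_data()].
#' @param constraints `"none"`, `"equal_means"`, `"equal_cov_structure"` or
#'   `"both"`.
#' @param config a [fit_config()].
#' @param compute_vcov invert the observed information for Wald screens
#'   (default TRUE).
#' @return object of class `sem_fit2g` with joint `theta`, per-group
#'   parameter matrices, combined log-likelihood, chi-square vs the
#'   two-group saturated model, df, and (optionally) the parameter
#'   covariance matrix `vcov`.
#' @export
fit_two_group <- function(model, gd,
                          constraints = c("none", "equal_means",
                                          "equal_cov_structure", "both"),
                          config = fit_config(), compute_vcov = TRUE) {
  stopifnot(inherits(model, "path_model"), inherits(gd, "grouped_data"))
  constraints <- match.arg(constraints)
  vars <- model$variables
  p <- length(vars)
  ylist <- list(gd$y1[, vars, drop = FALSE], gd$y2[, vars, drop = FALSE])
  moms <- lapply(ylist, sample_moments, config = config)
  groups <- lapply(moms, function(mm) {
    ev <- eigen(mm$S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) stopf("group covariance not positive definite")
    list(S = mm$S, ybar = mm$ybar,
         logdetS = determinant(mm$S, logarithm = TRUE)$modulus[1],
         p = p, w = chisq_multiplier(mm$n, config), n = mm$n)
  })
  map <- map_two_group(model, constraints)
  res <- fit_sem_internal(map, groups, model, config)
  if (!res$converged) {
    stopf("two-group fit did not converge (constraints = %s)", constraints)
  }
  theta <- res$theta
  params <- lapply(1:2, function(g) {
    mats <- map_matrices(map, theta, p, group = g)
    dimnames(mats$B) <- dimnames(mats$Psi) <- list(vars, vars)
    names(mats$alpha) <- vars
    mats
  })
  chisq <- max(res$value, 0)
  t_par <- max(map$idx)
  df <- as.integer(2 * (p * (p + 1) / 2 + p) - t_par)
  loglik <- 0
  for (g in 1:2) {
    Sg <- implied_covariance(sem_params(params[[g]]$B, params[[g]]$Psi))
    mu <- drop(solve(diag(p) - params[[g]]$B) %*% params[[g]]$alpha)
    r <- groups[[g]]$ybar - mu
    loglik <- loglik - (groups[[g]]$n / 2) *
      (determinant(Sg, logarithm = TRUE)$modulus[1] +
         sum(solve(Sg) * groups[[g]]$S) +
         drop(crossprod(r, solve(Sg, r))) + p * log(2 * pi))
  }
  out <- structure(list(
    model = model, constraints = constraints, map = map, theta = theta,
    params = params, chisq = chisq, df = df, loglik = loglik,
    n1 = groups[[1]]$n, n2 = groups[[2]]$n, config = config,
    converged = res$converged,
    moments = lapply(groups, function(g) g[c("S", "ybar", "n")])
  ), class = "sem_fit2g")
  if (compute_vcov) {
    wgroups <- groups
    for (g in 1:2) wgroups[[g]]$w <- wgroups[[g]]$n
    obj <- sem_objective(map, wgroups)
    H <- hessian_from_grad(obj$gr, theta)
    out$vcov <- tryCatch(solve(H / 2), error = function(e) {
      warnf("singular information in two-group fit; Wald SEs unavailable")
      NULL
    })
    if (!is.null(out$vcov)) {
      dimnames(out$vcov) <- list(names(theta), names(theta))
    }
  }
  out
}

#' @export
print.sem_fit2g <- function(x, ...) {
  cat(sprintf(paste0("<sem_fit2g> constraints = %s, n = %d + %d, ",
                     "chisq(df) = %.3f (%d)\n"),
              x$constraints, x$n1, x$n2, x$chisq, x$df))
  invisible(x)
}

#' Omnibus test of equal group means
#'
#' Likelihood-ratio comparison of equal vs free intercepts, both fits under
#' an equal covariance structure (H0: mu1 = mu2 subject to Sigma1 = Sigma2);
#' df equals the number of mean parameters (p).
#'
#' @param model a [path_model()].
#' @param gd a [grouped_data()].
#' @param config a [fit_config()].
#' @return list(chisq_diff, df_diff, p_value, fit0, fit1).
#' @export
omnibus_mean_test <- function(model, gd, config = fit_config()) {
  fit1 <- fit_two_group(model, gd, "equal_cov_structure", config,
                        compute_vcov = FALSE)
  fit0 <- fit_two_group(model, gd, "both", config, compute_vcov = FALSE)
  stat <- max(fit0$chisq - fit1$chisq, 0)
  df <- length(model$variables)
  list(chisq_diff = stat, df_diff = as.integer(df),
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       fit0 = fit0, fit1 = fit1)
}

#' Omnibus test of equal group covariance structure
#'
#' Likelihood-ratio comparison of equal vs free covariance-structure
#' parameters with means free in both fits (H0: Sigma1 = Sigma2 subject to
#' mu1 != mu2); df equals the number of constrained parameters (free path
#' coefficients plus free error (co)variances).
#'
#' @inheritParams omnibus_mean_test
#' @return list(chisq_diff, df_diff, p_value, fit0, fit1).
#' @export
omnibus_cov_test <- function(model, gd, config = fit_config()) {
  fit1 <- fit_two_group(model, gd, "none", config, compute_vcov = FALSE)
  fit0 <- fit_two_group(model, gd, "equal_cov_structure", config,
                        compute_vcov = FALSE)
  stat <- max(fit0$chisq - fit1$chisq, 0)
  p <- length(model$variables)
  df <- sum(model$beta_free) + p +
    sum(model$psi_free[lower.tri(model$psi_free)])
  list(chisq_diff = stat, df_diff = as.integer(df),
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       fit0 = fit0, fit1 = fit1)
}

# bootstrap SE of a per-group-difference statistic via within-group
# nonparametric resampling; used when config$pvalue_method == "bootstrap"
bootstrap_diff_se <- function(model, gd, constraints, extract, config) {
  B <- config$bootstrap_reps
  stats_b <- with_preserved_seed(config$seed, {
    draws <- lapply(seq_len(B), function(b) {
      grouped_data(gd$y1[sample.int(gd$n1, gd$n1, replace = TRUE), ,
                         drop = FALSE],
                   gd$y2[sample.int(gd$n2, gd$n2, replace = TRUE), ,
                         drop = FALSE])
    })
    lapply(draws, function(gb) {
      fb <- tryCatch(fit_two_group(model, gb, constraints, config,
                                   compute_vcov = FALSE),
                     error = function(e) NULL)
      if (is.null(fb)) NULL else extract(fb)
    })
  })
  ok <- !vapply(stats_b, is.null, logical(1))
  mat <- do.call(rbind, stats_b[ok])
  apply(mat, 2, stats::sd, na.rm = TRUE)
}

#' Per-node group-difference screen (t_C)
#'
#' Tests, for every variable, the conditional mean difference between the
#' experimental and control group given the variable's parents in the
#' network — the path coefficient of a group indicator coded
#' experimental = 1, control = 0. Fitted as a two-group model with shared
#' covariance structure and free intercepts.
#'
#' @param model a [path_model()].
#' @param gd a [grouped_data()].
#' @param config a [fit_config()]; `pvalue_method = "bootstrap"` replaces the
#'   asymptotic SE of the difference by a nonparametric bootstrap SE.
#' @return data.frame (variable, est_group1, est_group2, difference,
#'   ci_lower, ci_upper, z, p_value, label).
#' @export
node_tests <- function(model, gd, config = fit_config()) {
  fit <- fit_two_group(model, gd, "equal_cov_structure", config)
  vars <- model$variables
  a1 <- fit$params[[1]]$alpha
  a2 <- fit$params[[2]]$alpha
  diff <- a1 - a2
  n1 <- paste0("g1:", vars, "~1")
  n2 <- paste0("g2:", vars, "~1")
  if (config$pvalue_method == "bootstrap") {
    se <- bootstrap_diff_se(model, gd, "equal_cov_structure",
                            function(fb) fb$params[[1]]$alpha -
                              fb$params[[2]]$alpha, config)
  } else {
    if (is.null(fit$vcov)) stopf("no parameter covariance available")
    se <- vapply(seq_along(vars), function(i) {
      v <- fit$vcov[n1[i], n1[i]] + fit$vcov[n2[i], n2[i]] -
        2 * fit$vcov[n1[i], n2[i]]
      sqrt(max(v, 0))
    }, numeric(1))
  }
  z <- diff / se
  pv <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    variable = vars, est_group1 = unname(a1), est_group2 = unname(a2),
    difference = unname(diff),
    ci_lower = unname(diff - 1.96 * se), ci_upper = unname(diff + 1.96 * se),
    se = unname(se), z = unname(z), p_value = unname(pv),
    label = ifelse(pv < config$alpha,
                   ifelse(diff < 0, "down-expressed", "up-expressed"), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

edge_param_table <- function(model) {
  vars <- model$variables
  bi <- which(model$beta_free, arr.ind = TRUE)
  pl <- which(model$psi_free & lower.tri(model$psi_free), arr.ind = TRUE)
  prov <- model$provenance
  origin_of <- function(key) {
    hit <- prov$origin[prov$param == key]
    if (length(hit)) hit[1] else NA_character_
  }
  rbind(
    if (nrow(bi)) data.frame(
      param = paste0(vars[bi[, 1]], "~", vars[bi[, 2]]),
      edge = paste0(vars[bi[, 1]], " <- ", vars[bi[, 2]]),
      kind = "beta", target = vars[bi[, 1]], source = vars[bi[, 2]],
      type = vapply(seq_len(nrow(bi)), function(k) {
        tp <- model$edge_types[bi[k, 1], bi[k, 2]]
        if (!is.na(tp)) tp else
          origin_of(paste0(vars[bi[k, 1]], "~", vars[bi[k, 2]])) %||%
            NA_character_
      }, character(1)),
      stringsAsFactors = FALSE),
    if (nrow(pl)) data.frame(
      param = paste0(vars[pl[, 1]], "~~", vars[pl[, 2]]),
      edge = paste0(vars[pl[, 1]], " <-> ", vars[pl[, 2]]),
      kind = "psi", target = vars[pl[, 1]], source = vars[pl[, 2]],
      type = vapply(seq_len(nrow(pl)), function(k) {
        origin_of(paste0(vars[pl[k, 1]], "~~", vars[pl[k, 2]])) %||%
          NA_character_
      }, character(1)),
      stringsAsFactors = FALSE)
  )
}

#' Per-edge group-difference screen (t_D)
#'
#' Tests, for every free path coefficient (and free error covariance), the
#' difference d_ij = b_ij(experimental) - b_ij(control) from a two-group fit
#' with free per-group parameters; SE(d_ij) adds the independent group
#' variances.
#'
#' @inheritParams node_tests
#' @return data.frame (edge, kind, type, est_group1, est_group2, difference,
#'   ci_lower, ci_upper, z, p_value, label).
#' @export
edge_tests <- function(model, gd, config = fit_config()) {
  fit <- fit_two_group(model, gd, "none", config)
  et <- edge_param_table(model)
  if (is.null(et) || !nrow(et)) {
    return(data.frame(edge = character(), kind = character(),
                      type = character(), est_group1 = numeric(),
                      est_group2 = numeric(), difference = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      se = numeric(), z = numeric(), p_value = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  n1 <- paste0("g1:", et$param)
  n2 <- paste0("g2:", et$param)
  b1 <- fit$theta[n1]
  b2 <- fit$theta[n2]
  diff <- b1 - b2
  if (config$pvalue_method == "bootstrap") {
    se <- bootstrap_diff_se(model, gd, "none", function(fb)
      fb$theta[n1] - fb$theta[n2], config)
  } else {
    if (is.null(fit$vcov)) stopf("no parameter covariance available")
    se <- sqrt(pmax(diag(fit$vcov)[n1] + diag(fit$vcov)[n2], 0))
  }
  z <- diff / se
  pv <- 2 * stats::pnorm(-abs(z))
  lab_up <- ifelse(et$kind == "psi", "up-associated", "up-regulated")
  lab_dn <- ifelse(et$kind == "psi", "down-associated", "down-regulated")
  out <- data.frame(
    edge = et$edge, kind = et$kind, type = et$type,
    est_group1 = unname(b1), est_group2 = unname(b2),
    difference = unname(diff),
    ci_lower = unname(diff - 1.96 * se), ci_upper = unname(diff + 1.96 * se),
    se = unname(se), z = unname(z), p_value = unname(pv),
    label = ifelse(pv < config$alpha, ifelse(diff < 0, lab_dn, lab_up), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-edge per-group activation screen (t1/t2)
#'
#' For every free path coefficient and each group separately, a one-sided
#' test of H0: beta = 0 in the direction implied by the a-priori interaction
#' type (activation/phosphorylation positive, inhibition negative, otherwise
#' the sign of the pooled estimate). An edge is ON in a group when the
#' one-sided P is below alpha, else OFF.
#'
#' @inheritParams node_tests
#' @return data.frame (edge, type, est_group1, p_group1, est_group2,
#'   p_group2, status: e.g. "ON/OFF").
#' @export
onoff_tests <- function(model, gd, config = fit_config()) {
  fit <- fit_two_group(model, gd, "none", config)
  et <- edge_param_table(model)
  et <- et[et$kind == "beta", , drop = FALSE]
  if (!nrow(et)) {
    return(data.frame(edge = character(), type = character(),
                      est_group1 = numeric(), p_group1 = numeric(),
                      est_group2 = numeric(), p_group2 = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  if (is.null(fit$vcov)) stopf("no parameter covariance available")
  n1 <- paste0("g1:", et$param)
  n2 <- paste0("g2:", et$param)
  b1 <- fit$theta[n1]
  b2 <- fit$theta[n2]
  se1 <- sqrt(pmax(diag(fit$vcov)[n1], 0))
  se2 <- sqrt(pmax(diag(fit$vcov)[n2], 0))
  dir <- ifelse(et$type %in% c("activation", "phosphorylation"), 1,
                ifelse(et$type == "inhibition", -1, sign(b1 + b2)))
  dir[dir == 0] <- 1
  p1 <- stats::pnorm(dir * b1 / se1, lower.tail = FALSE)
  p2 <- stats::pnorm(dir * b2 / se2, lower.tail = FALSE)
  status <- paste(ifelse(p1 < config$alpha, "ON", "OFF"),
                  ifelse(p2 < config$alpha, "ON", "OFF"), sep = "/")
  out <- data.frame(edge = et$edge, type = et$type,
                    est_group1 = unname(b1), p_group1 = unname(p1),
                    est_group2 = unname(b2), p_group2 = unname(p2),
                    status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-sided Wald P-value from an estimate and its 95% CI
#'
#' Consistency helper for published tables: recovers SE = (upper - lower) /
#' (2 * 1.96) and returns the two-sided normal P of estimate / SE.
#'
#' @param estimate point estimate.
#' @param ci_low,ci_high 95% confidence limits (ci_low < ci_high, estimate
#'   inside).
#' @return two-sided P-value.
#' @export
wald_pvalue_from_ci <- function(estimate, ci_low, ci_high) {
  if (!(ci_low < ci_high)) stopf("degenerate CI: lower >= upper")
  if (estimate < ci_low || estimate > ci_high) {
    stopf("estimate outside its CI")
  }
  se <- (ci_high - ci_low) / (2 * 1.96)
  if (se <= 0) stopf("degenerate CI: zero width")
  2 * stats::pnorm(-abs(estimate / se))
}

#' Optional multiple-testing adjustment of a screen table
#'
#' @param table data.frame with a `p_value` column.
#' @param method `"none"` (default, matching unadjusted reporting) or
#'   `"bh"` for Benjamini-Hochberg.
#' @return the table, with a `p_adjusted` column appended when `method` is
#'   `"bh"`.
#' @export
adjust_pvalues <- function(table, method = c("none", "bh")) {
  method <- match.arg(method)
  if (!"p_value" %in% names(table)) stopf("table lacks a p_value column")
  if (method == "bh") {
    table$p_adjusted <- stats::p.adjust(table$p_value, method = "BH")
  }
  table
}
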