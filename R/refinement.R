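#' External evidence for candidate model edges
#'
#' Holds interaction pairs exported from an interaction database (e.g.
#' STRING) plus the original pathway graph for directed-path checks.
#'
#' @param string_edges data.frame with two columns of unordered gene pairs.
#' @param pathway the original [pathway_graph()] the module came from.
#' @return object of class `evidence_set`.
#' @export
evidence_set <- function(string_edges, pathway) {
  stopifnot(inherits(pathway, "pathway_graph"))
  if (is.null(string_edges) || !nrow(string_edges)) {
    string_edges <- data.frame(a = character(), b = character(),
                               stringsAsFactors = FALSE)
  } else {
    string_edges <- as.data.frame(string_edges, stringsAsFactors = FALSE)
    names(string_edges)[1:2] <- c("a", "b")
    string_edges$a <- as.character(string_edges$a)
    string_edges$b <- as.character(string_edges$b)
    strays <- setdiff(unique(c(string_edges$a, string_edges$b)),
                      pathway$nodes)
    if (length(strays)) {
      warnf("evidence pair(s) with identifiers outside the pathway: %s",
            paste(strays, collapse = ", "))
    }
  }
  structure(list(string_edges = string_edges, pathway = pathway),
            class = "evidence_set")
}

#' Read an evidence pair list (2-column TSV)
#' @param path TSV with two gene-id columns per row (no header, `#` comments).
#' @param pathway the original [pathway_graph()].
#' @return an [evidence_set()].
#' @export
read_evidence_table <- function(path, pathway) {
  if (!file.exists(path)) stopf("evidence file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(evidence_set(NULL, pathway))
  rows <- strsplit(lines, "\t")
  if (any(lengths(rows) < 2L)) stopf("evidence rows must have 2 fields")
  m <- do.call(rbind, lapply(rows, `[`, 1:2))
  evidence_set(data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE),
               pathway)
}

in_string <- function(ev, x, y) {
  se <- ev$string_edges
  any((se$a == x & se$b == y) | (se$a == y & se$b == x))
}

#' Admissibility of a refinement candidate
#'
#' Path-coefficient candidates are admissible when the pair appears in the
#' evidence pairs or a directed path connects source to target in the
#' original pathway; error-covariance candidates only through evidence
#' pairs. Evidence-pair support is reported in preference to the
#' directed-path criterion when both hold.
#'
#' @param candidate list or one-row data.frame with `type` ("beta" or
#'   "psi"), `target`, `source`.
#' @param ev an [evidence_set()].
#' @return list(admissible = logical, source = one of "string",
#'   "directed_path", "rejected_no_evidence").
#' @export
candidate_evidence <- function(candidate, ev) {
  stopifnot(inherits(ev, "evidence_set"))
  type <- candidate$type
  tgt <- candidate$target
  src <- candidate$source
  if (any(c(tgt, src) %in% c("group", "C"))) {
    stopf("the group indicator is never refined")
  }
  if (in_string(ev, src, tgt)) {
    return(list(admissible = TRUE, source = "string"))
  }
  if (identical(type, "beta") &&
      src %in% ev$pathway$nodes && tgt %in% ev$pathway$nodes &&
      directed_path_exists(ev$pathway, src, tgt)) {
    return(list(admissible = TRUE, source = "directed_path"))
  }
  list(admissible = FALSE, source = "rejected_no_evidence")
}

refine_stop_reason <- function(fit, config) {
  if (is.na(fit$p_value)) return("saturated")
  if (fit$p_value > config$alpha) return("lrt")
  if (!is.na(fit$rmsea_pclose) && fit$rmsea_pclose > config$alpha) {
    return("close_fit")
  }
  if (fit$srmr < config$srmr_adequate) return("srmr")
  NULL
}

empty_refinement_log <- function() {
  data.frame(step = integer(), param = character(), type = character(),
             target = character(), source = character(), mi = numeric(),
             evidence = character(), z = numeric(), accepted = logical(),
             chisq = numeric(), df = integer(), p_value = numeric(),
             rmsea = numeric(), rmsea_pclose = numeric(), srmr = numeric(),
             note = character(), stringsAsFactors = FALSE)
}

#' Heuristic stepwise model refinement
#'
#' Repeats: (1) compute modification indices of all fixed parameters and
#' sort them in descending order; (2) take the highest-MI candidate that is
#' backed by evidence ([candidate_evidence()]) and keeps the model bow-free
#' and block-recursive; (3) free it and refit — when the freed parameter is
#' not significant one-sided (|z| below `config$z_threshold`) it is removed
#' and permanently blacklisted; (4) stop as soon as the model reaches a
#' non-significant LRT, a non-rejected close fit, or an adequate SRMR, or
#' when no admissible candidate remains, or at `max_steps`.
#'
#' @param model the initial [path_model()].
#' @param data n x p data matrix.
#' @param ev an [evidence_set()].
#' @param config a [fit_config()].
#' @param max_steps cap on accepted + rejected freeing attempts (default 50).
#' @return list(model, fit, log, stop_reason); the log replays to the final
#'   model via [replay_refinement()].
#' @export
stepwise_refine <- function(model, data, ev, config = fit_config(),
                            max_steps = 50L) {
  stopifnot(inherits(model, "path_model"), inherits(ev, "evidence_set"))
  data <- as.matrix(data)[, model$variables, drop = FALSE]
  fit <- fit_ml(model, data = data, config = config, compute_se = FALSE)
  log <- empty_refinement_log()
  blacklist <- character()
  step <- 0L
  log_row <- function(step, cand, mi, evsrc, z, accepted, fit, note) {
    data.frame(step = step, param = cand$param, type = cand$type,
               target = cand$target, source = cand$source, mi = mi,
               evidence = evsrc, z = z, accepted = accepted,
               chisq = fit$chisq, df = fit$df,
               p_value = fit$p_value %||% NA_real_, rmsea = fit$rmsea,
               rmsea_pclose = fit$rmsea_pclose, srmr = fit$srmr,
               note = note, stringsAsFactors = FALSE)
  }
  repeat {
    reason <- refine_stop_reason(fit, config)
    if (!is.null(reason)) break
    if (step >= max_steps) {
      reason <- "max_steps"
      break
    }
    mis <- modification_indices(fit)
    mis <- mis[!is.na(mis$mi) & !(mis$param %in% blacklist), , drop = FALSE]
    mis <- mis[order(-mis$mi, mis$target, mis$source), , drop = FALSE]
    chosen <- NULL
    for (k in seq_len(nrow(mis))) {
      cand <- mis[k, ]
      adm <- candidate_evidence(cand, ev)
      if (!adm$admissible) next
      trial <- model_free_param(model, cand$type, cand$target, cand$source,
                                origin = adm$source)
      if (nrow(check_bow_free(trial)) ||
          !check_block_recursive(trial)$pass ||
          degrees_of_freedom(trial) < 0) {
        next
      }
      chosen <- list(cand = cand, adm = adm, trial = trial)
      break
    }
    if (is.null(chosen)) {
      reason <- "no_admissible_candidates"
      break
    }
    step <- step + 1L
    cand <- chosen$cand
    new_fit <- tryCatch(
      fit_ml(chosen$trial, data = data, config = config, compute_se = TRUE),
      error = function(e) NULL)
    if (is.null(new_fit)) {
      blacklist <- c(blacklist, cand$param)
      log <- rbind(log, log_row(step, cand, cand$mi, chosen$adm$source,
                                NA_real_, FALSE, fit, "non_convergent"))
      next
    }
    est <- new_fit$theta[cand$param]
    se <- new_fit$se[cand$param]
    z <- if (is.finite(se) && se > 0) est / se else NA_real_
    if (!is.finite(z) || abs(z) < config$z_threshold) {
      blacklist <- c(blacklist, cand$param)
      log <- rbind(log, log_row(step, cand, cand$mi, chosen$adm$source, z,
                                FALSE, fit, "not_significant"))
      next
    }
    model <- chosen$trial
    fit <- new_fit
    log <- rbind(log, log_row(step, cand, cand$mi, chosen$adm$source, z,
                              TRUE, fit, ""))
  }
  rownames(log) <- NULL
  list(model = model, fit = fit, log = log, stop_reason = reason)
}

#' Replay a refinement log onto an initial model
#'
#' Applies the accepted steps of a [stepwise_refine()] log in order,
#' reproducing the final model specification exactly.
#'
#' @param model the initial [path_model()].
#' @param log the refinement log.
#' @return the refined [path_model()].
#' @export
replay_refinement <- function(model, log) {
  acc <- log[log$accepted, , drop = FALSE]
  for (k in seq_len(nrow(acc))) {
    model <- model_free_param(model, acc$type[k], acc$target[k],
                              acc$source[k], origin = acc$evidence[k])
  }
  model
}
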