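#' Pipeline configuration
#'
#' Collects the file paths and options driving [run_pipeline()]. Expression
#' is a gene x sample TSV with a `gene` id column; group labels are a
#' 2-column TSV (sample, label) whose first level in `experimental_label`
#' order is coded 1.
#'
#' @param expression path to the expression TSV.
#' @param groups path to the sample/group TSV (2 columns, header allowed).
#' @param pathway path to the 3-column pathway TSV.
#' @param degs path to the DEG list (one id per line).
#' @param superfamilies optional gene/family TSV enabling composite
#'   reduction.
#' @param evidence optional 2-column evidence-pair TSV enabling refinement.
#' @param experimental_label group label coded as experimental (= 1);
#'   defaults to the first label in sorted order.
#' @param output_dir directory for the report bundle.
#' @param config a [fit_config()].
#' @param max_steps refinement step cap.
#' @param verbose print stage progress (default TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, groups, pathway, degs,
                            superfamilies = NULL, evidence = NULL,
                            experimental_label = NULL,
                            output_dir = "pathsem_report",
                            config = fit_config(), max_steps = 50L,
                            verbose = TRUE) {
  for (f in c(expression, groups, pathway, degs, superfamilies, evidence)) {
    if (!is.null(f) && !file.exists(f)) stopf("input file not found: %s", f)
  }
  structure(list(expression = expression, groups = groups,
                 pathway = pathway, degs = degs,
                 superfamilies = superfamilies, evidence = evidence,
                 experimental_label = experimental_label,
                 output_dir = output_dir, config = config,
                 max_steps = as.integer(max_steps), verbose = verbose),
            class = "pipeline_config")
}

read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  storage.mode(mat) <- "double"
  mat
}

read_group_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("group file needs 2 columns: sample, label")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[pathsem] ", fmt), ...))
}

#' Run the full module-extraction / SEM / two-group pipeline
#'
#' Executes extract -> composites/collapse -> initial model -> ML fit ->
#' evidence-gated refinement -> two-group omnibus and node/edge/on-off
#' screens, writing a report bundle: `summary.json` (graph stats and fit
#' indices per stage), `nodes.tsv`, `edges.tsv`, `onoff.tsv`,
#' `refinement_log.tsv`, `module.tsv`, `model.dot` (nodes coloured by
#' up/down expression, edges by up/down regulation) and `composites.json`.
#'
#' @param pc a [pipeline_config()], or a [make_scenario()] result (inputs
#'   are then taken in-memory and `output_dir` must be given).
#' @param output_dir overrides the configured output directory.
#' @return list with the final model, fits, tables and file paths,
#'   invisibly.
#' @export
run_pipeline <- function(pc, output_dir = NULL) {
  if (inherits(pc, "synthetic_scenario")) {
    if (is.null(output_dir)) stopf("output_dir required for scenario input")
    files <- write_scenario(pc, file.path(output_dir, "inputs"))
    pc <- pipeline_config(
      expression = files$expression, groups = files$groups,
      pathway = files$pathway, degs = files$degs,
      superfamilies = files$superfamilies, evidence = files$evidence,
      experimental_label = "experimental", output_dir = output_dir)
  }
  stopifnot(inherits(pc, "pipeline_config"))
  out_dir <- output_dir %||% pc$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- pc$config
  vb <- pc$verbose
  summary <- list()

  stage <- "read_inputs"
  result <- tryCatch({
    expr <- read_expression_tsv(pc$expression)
    labels <- read_group_labels(pc$groups)
    lvls <- sort(unique(labels))
    if (length(lvls) != 2) stopf("group labels must have exactly two levels")
    exp_lab <- pc$experimental_label %||% lvls[1]
    if (!exp_lab %in% lvls) stopf("unknown experimental label: %s", exp_lab)
    ctrl_lab <- setdiff(lvls, exp_lab)
    common <- intersect(colnames(expr), names(labels))
    if (!length(common)) stopf("no samples shared by expression and labels")
    expr <- expr[, common, drop = FALSE]
    labels <- labels[common]
    pathway <- read_pathway_table(pc$pathway)
    degs <- readLines(pc$degs, warn = FALSE)
    degs <- trimws(degs[nzchar(trimws(degs))])

    stage <- "extract_module"
    module <- extract_module(pathway, degs)
    st0 <- graph_stats(pathway)
    st1 <- graph_stats(module$subgraph)
    stage_msg(vb, "pathway %d(%d) -> module %d(%d)", st0$n_nodes,
              st0$n_edges, st1$n_nodes, st1$n_edges)
    summary$pathway <- st0
    summary$module <- st1
    cls <- classify_genes(module$subgraph$nodes, degs)

    stage <- "composites"
    composites <- list()
    graph <- module$subgraph
    data_mat <- t(expr[intersect(rownames(expr), graph$nodes), ,
                       drop = FALSE])
    if (!is.null(pc$superfamilies)) {
      sfmap <- read_superfamily_map(pc$superfamilies)
      sfmap <- sfmap[names(sfmap) %in% cls$ndegs]
      composites <- build_composites(module, sfmap, expr)
      accepted <- Filter(function(cv) cv$accepted, composites)
      if (length(accepted)) {
        graph <- collapse_graph(module, composites)
        comp_scores <- do.call(cbind, lapply(accepted, `[[`, "scores"))
        colnames(comp_scores) <- vapply(accepted, `[[`, "", "id")
        keep <- setdiff(graph$nodes, colnames(comp_scores))
        data_mat <- cbind(data_mat[, intersect(colnames(data_mat), keep),
                                   drop = FALSE], comp_scores)
      }
      write_composites_json(composites, file.path(out_dir,
                                                  "composites.json"))
      summary$collapsed <- graph_stats(graph)
    }
    missing_expr <- setdiff(graph$nodes, colnames(data_mat))
    if (length(missing_expr)) {
      stopf("no expression for model node(s): %s",
            paste(missing_expr, collapse = ", "))
    }

    stage <- "initial_model"
    model <- build_initial_model(graph)
    fit0 <- fit_ml(model, data = data_mat[, model$variables, drop = FALSE],
                   config = cfg, compute_se = FALSE)
    summary$initial_fit <- list(chisq = fit0$chisq, df = fit0$df,
                                p_value = fit0$p_value, rmsea = fit0$rmsea,
                                rmsea_pclose = fit0$rmsea_pclose,
                                srmr = fit0$srmr)
    stage_msg(vb, "initial fit chisq(df) = %.2f (%d), SRMR = %.3f",
              fit0$chisq, fit0$df, fit0$srmr)

    stage <- "refinement"
    ref_log <- empty_refinement_log()
    fit <- fit0
    if (!is.null(pc$evidence)) {
      ev <- read_evidence_table(pc$evidence, pathway)
      ref <- stepwise_refine(model, data_mat, ev, cfg,
                             max_steps = pc$max_steps)
      model <- ref$model
      fit <- ref$fit
      ref_log <- ref$log
      summary$refinement <- list(
        steps = nrow(ref_log), accepted = sum(ref_log$accepted),
        stop_reason = ref$stop_reason,
        final = list(chisq = fit$chisq, df = fit$df,
                     p_value = fit$p_value, rmsea = fit$rmsea,
                     rmsea_pclose = fit$rmsea_pclose, srmr = fit$srmr))
      stage_msg(vb, "refinement: %d accepted edge(s), stop = %s, SRMR %.3f",
                sum(ref_log$accepted), ref$stop_reason, fit$srmr)
    }
    utils::write.table(ref_log, file.path(out_dir, "refinement_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "two_group"
    y1 <- data_mat[labels == exp_lab, model$variables, drop = FALSE]
    y2 <- data_mat[labels == ctrl_lab, model$variables, drop = FALSE]
    gd <- grouped_data(y1, y2)
    mt <- omnibus_mean_test(model, gd, cfg)
    ct <- omnibus_cov_test(model, gd, cfg)
    nodes <- node_tests(model, gd, cfg)
    edges <- edge_tests(model, gd, cfg)
    onoff <- onoff_tests(model, gd, cfg)
    summary$omnibus <- list(
      mean = mt[c("chisq_diff", "df_diff", "p_value")],
      covariance = ct[c("chisq_diff", "df_diff", "p_value")])
    stage_msg(vb, "omnibus mean chisq(df) = %.2f (%d), cov = %.2f (%d)",
              mt$chisq_diff, mt$df_diff, ct$chisq_diff, ct$df_diff)

    stage <- "report"
    utils::write.table(nodes, file.path(out_dir, "nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(onoff, file.path(out_dir, "onoff.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    final_graph <- model_as_graph(model)
    write_pathway_table(final_graph, file.path(out_dir, "module.tsv"))
    node_col <- setNames(ifelse(nodes$label == "down-expressed", "lightblue",
                                ifelse(nodes$label == "up-expressed",
                                       "salmon", "white")),
                         nodes$variable)
    edge_key <- paste(final_graph$edges$from, final_graph$edges$to)
    beta_rows <- edges[edges$kind == "beta", , drop = FALSE]
    emap <- setNames(ifelse(grepl("down", beta_rows$label), "blue",
                            ifelse(grepl("up", beta_rows$label), "red",
                                   "gray40")),
                     paste(beta_rows$edge))
    ecol <- rep("gray40", nrow(final_graph$edges))
    for (k in seq_len(nrow(final_graph$edges))) {
      key <- paste0(final_graph$edges$to[k], " <- ",
                    final_graph$edges$from[k])
      if (key %in% names(emap)) ecol[k] <- emap[key]
    }
    write_dot(final_graph, file.path(out_dir, "model.dot"),
              node_colors = node_col, edge_colors = ecol)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(model = model, fit = fit, initial_fit = fit0, module = module,
         composites = composites, mean_test = mt, cov_test = ct,
         node_table = nodes, edge_table = edges, onoff_table = onoff,
         refinement_log = ref_log, summary = summary, output_dir = out_dir)
  }, error = function(e) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}

# pathway_graph view of a fitted model specification (directed free paths
# plus bidirected free covariances)
model_as_graph <- function(model) {
  vars <- model$variables
  bi <- which(model$beta_free, arr.ind = TRUE)
  prov <- model$provenance
  type <- vapply(seq_len(nrow(bi)), function(k) {
    tp <- model$edge_types[bi[k, 1], bi[k, 2]]
    if (!is.na(tp)) return(tp)
    key <- paste0(vars[bi[k, 1]], "~", vars[bi[k, 2]])
    hit <- prov$origin[prov$param == key]
    if (length(hit)) hit[1] else "other"
  }, character(1))
  pl <- which(model$psi_free & lower.tri(model$psi_free), arr.ind = TRUE)
  pathway_graph(
    data.frame(from = vars[bi[, 2]], to = vars[bi[, 1]], type = type,
               stringsAsFactors = FALSE),
    nodes = vars,
    bidirected = if (nrow(pl)) data.frame(a = vars[pl[, 1]],
                                          b = vars[pl[, 2]],
                                          stringsAsFactors = FALSE))
}
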