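#' @name pipeline
#' @title End-to-end corticomuscular coupling pipeline
#'
#' @description
#' Per task condition: preprocess, fit per-channel GARCH margins,
#' PIT-transform, build the R-vine, export the Kendall heatmap matrix and
#' first-tree summary; then select one network threshold shared across
#' conditions (node degrees averaged over the condition networks before
#' applying the \eqn{K \ge 2\ln N} rule), binarize, compute graph
#' metrics, and run the spectral-GC baseline networks.
NULL

pipe_fail <- function(stage, context, msg) {
  stop(sprintf("[%s] %s: %s", stage, context, msg), call. = FALSE)
}

#' Run the full coupling pipeline
#'
#' @param conditions named list of [channel_matrix()] objects (or paths to
#'   CSV/TSV files), one per task condition.
#' @param manifest channel manifest (named vector or YAML path) used when
#'   `conditions` holds file paths.
#' @param fs sampling rate for file inputs.
#' @param preproc apply [preprocess()] first (`TRUE` for raw recordings;
#'   set `FALSE` for already-filtered or synthetic inputs).
#' @param candidates,criterion pair-copula menu and selector for
#'   [build_rvine()].
#' @param threshold_step grid step of the threshold scan.
#' @param gc_band,gc_max_order spectral-GC settings.
#' @param run_gc compute the Granger baseline networks (quadratic in the
#'   channel count; disable for quick runs).
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @param seed integer seed recorded in the run manifest and used for any
#'   stochastic step.
#' @return A list with one entry per condition (`vine`, `tau`, `garch`,
#'   `Wn`, `A`, `metrics`, `core_nodes`, `tree1`, and optionally GC
#'   analogues), plus `threshold`, `curve`, `gc_threshold` and `manifest`.
#' @export
run_pipeline <- function(conditions, manifest = NULL, fs = 1000,
                         preproc = FALSE,
                         candidates = default_candidates,
                         criterion = "aic", threshold_step = 0.05,
                         gc_band = c(8, 30), gc_max_order = 10,
                         run_gc = TRUE, out_dir = NULL, seed = 1) {
  if (!length(conditions)) stop("at least one task condition required")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    names(conditions) <- paste0("cond", seq_along(conditions))
  set.seed(seed)

  res <- list()
  for (cond in names(conditions)) {
    cmi <- conditions[[cond]]
    if (is.character(cmi))
      cmi <- tryCatch(load_signals(cmi, manifest, fs),
                      error = function(e)
                        pipe_fail("load", cond, conditionMessage(e)))
    if (preproc)
      cmi <- tryCatch(preprocess(cmi),
                      error = function(e)
                        pipe_fail("preprocess", cond, conditionMessage(e)))

    margins <- lapply(seq_len(nrow(cmi$data)), function(i) {
      tryCatch(fit_garch(cmi$data[i, ]),
               error = function(e)
                 pipe_fail("garch", paste0(cond, "/", cmi$channel_ids[i]),
                           conditionMessage(e)))
    })
    names(margins) <- cmi$channel_ids
    Upit <- vapply(margins, pit_transform, numeric(length(margins[[1]]$pit)),
                   check_converged = FALSE)
    colnames(Upit) <- cmi$channel_ids

    vine <- tryCatch(build_rvine(Upit, candidates, criterion),
                     error = function(e)
                       pipe_fail("rvine", cond, conditionMessage(e)))
    tau <- vine$tau1; diag(tau) <- 1
    Wn <- normalize_blocks(vine$tau1, cmi$modalities)
    res[[cond]] <- list(cm = cmi, garch = margins, pit = Upit, vine = vine,
                        tau = tau, Wn = Wn,
                        tree1 = first_tree_summary(vine, cmi$modalities))
  }

  sel <- threshold_select(lapply(res, `[[`, "Wn"), step = threshold_step)
  for (cond in names(res)) {
    A <- binarize_adjacency(res[[cond]]$Wn, sel$threshold)
    res[[cond]]$A <- A
    res[[cond]]$metrics <- graph_metrics(A)
    res[[cond]]$core_nodes <- core_nodes(A)
  }

  gc_threshold <- NULL
  if (run_gc) {
    for (cond in names(res)) {
      cmi <- res[[cond]]$cm
      G <- tryCatch(gc_matrix(cmi, max_order = gc_max_order, band = gc_band,
                              symmetrize = TRUE),
                    error = function(e)
                      pipe_fail("granger", cond, conditionMessage(e)))
      res[[cond]]$gc <- G
      res[[cond]]$gc_Wn <- normalize_blocks(G, cmi$modalities)
    }
    gsel <- threshold_select(lapply(res, `[[`, "gc_Wn"),
                             step = threshold_step)
    gc_threshold <- gsel$threshold
    for (cond in names(res)) {
      A <- binarize_adjacency(res[[cond]]$gc_Wn, gc_threshold)
      res[[cond]]$gc_A <- A
      res[[cond]]$gc_metrics <- graph_metrics(A)
    }
  }

  manifest_out <- list(
    package = "vinecmc",
    version = as.character(utils::packageVersion("vinecmc")),
    seed = seed, criterion = criterion, threshold = sel$threshold,
    gc_threshold = gc_threshold, threshold_step = threshold_step,
    conditions = names(res),
    selected_families = lapply(res, function(r)
      vapply(r$vine$trees[[1]], function(e) e$copula$family, "")))

  out <- list(conditions = res, threshold = sel$threshold,
              curve = sel$curve, gc_threshold = gc_threshold,
              manifest = manifest_out)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_matrix_tsv <- function(M, path) {
  df <- data.frame(node = rownames(M) %||% seq_len(nrow(M)), M,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Serialize pair copulas / vines to plain lists for JSON export.
copula_record <- function(pc) {
  list(family = pc$family, rotation = pc$rotation,
       params = as.list(pc$params), tau = pc$tau, loglik = pc$loglik,
       aic = pc$aic, bic = pc$bic, n_obs = pc$n_obs)
}

#' Serialize a vine model to a plain list (JSON-ready)
#'
#' @param vm a `vine_model`.
#' @return nested list with the tree structure and per-edge copula records.
#' @export
vine_to_list <- function(vm) {
  list(n_vars = vm$n_vars, names = vm$names,
       loglik = vm$loglik, aic = vm$aic, bic = vm$bic,
       trees = lapply(vm$trees, function(tr) lapply(tr, function(e)
         list(conditioned = e$conditioned, conditioning = e$conditioning,
              copula = copula_record(e$copula)))))
}

write_pipeline_artifacts <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(out$conditions)) {
    r <- out$conditions[[cond]]
    write_matrix_tsv(r$tau, file.path(out_dir, paste0(cond, "_tau.tsv")))
    write_matrix_tsv(r$Wn, file.path(out_dir, paste0(cond, "_Wn.tsv")))
    write_matrix_tsv(r$A, file.path(out_dir, paste0(cond, "_adjacency.tsv")))
    jsonlite::write_json(
      list(vine = vine_to_list(r$vine),
           garch = lapply(r$garch, function(m)
             list(params = as.list(m$params), loglik = m$loglik,
                  converged = m$converged)),
           metrics = r$metrics[c("L", "C", "n_disconnected_pairs")],
           core_nodes = names(r$core_nodes) %||% r$core_nodes),
      file.path(out_dir, paste0(cond, "_model.json")),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(r$gc)) {
      write_matrix_tsv(r$gc, file.path(out_dir, paste0(cond, "_gc.tsv")))
      write_matrix_tsv(r$gc_A,
                       file.path(out_dir, paste0(cond, "_gc_adjacency.tsv")))
    }
  }
  utils::write.table(out$curve, file.path(out_dir, "degree_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
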