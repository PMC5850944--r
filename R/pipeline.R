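#' Run the full stratification pipeline
#'
#' Orchestrates the four stages — preprocess, select, learn (per class),
#' classify — from a flat configuration, writing every intermediate artifact
#' plus a manifest with content hashes under `outdir`. Reruns with the same
#' configuration and seed reproduce the manifest byte for byte.
#'
#' @param config a named list or the path of a YAML file with keys: `pkn`
#'   (SIF path), `patients` (CSV path), `outdir`, `k`, and optionally
#'   `sif_dialect`, `input_scope`, `readout_scope`, `fit_tolerance`,
#'   `size_tolerance`, `exhaustive_cap`, `method`, `low`, `high`, `mode`,
#'   `seed`.
#' @return invisible list with the run's objects (`selection`, `families`,
#'   `predictions`, `accuracy`, `manifest_path`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(sif_dialect = "numeric", input_scope = "global",
                   readout_scope = "global", fit_tolerance = 0,
                   size_tolerance = 0, exhaustive_cap = 20, method = 1,
                   low = 0.25, high = 0.6, mode = "all", seed = 1)
  config <- utils::modifyList(defaults, config)
  for (key in c("pkn", "patients", "outdir", "k")) {
    if (is.null(config[[key]])) stop("config misses `", key, "`",
                                     call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)
  stage <- "preprocess"
  on_fail <- function(e) {
    stop("stage `", stage, "` failed: ", conditionMessage(e),
         if (length(artifacts) > 0L) {
           paste0(" (last good artifact: ", utils::tail(artifacts, 1), ")")
         },
         call. = FALSE)
  }
  tryCatch({
    net <- read_sif(config$pkn, dialect = config$sif_dialect)
    patients <- read_patients(config$patients)
    proc <- process_patients(patients, net,
                             input_scope = config$input_scope,
                             readout_scope = config$readout_scope,
                             seed = config$seed)
    utils::write.csv(as.data.frame(proc$inputs),
                     file.path(outdir, "binarized_inputs.csv"))
    add(file.path(outdir, "binarized_inputs.csv"))
    utils::write.csv(as.data.frame(proc$readouts),
                     file.path(outdir, "normalized_readouts.csv"))
    add(file.path(outdir, "normalized_readouts.csv"))
  }, error = on_fail)

  stage <- "select"
  tryCatch({
    sel_set <- select_proteins(proc, k = config$k)
    if (length(sel_set) == 0L) stop("no couples for k = ", config$k)
    sel <- sel_set[[1L]]
    jsonlite::write_json(
      list(k = sel$k, proteins = sel$proteins, couples = sel$couples,
           n_couples = sel$n_couples, affinity_count = sel$affinity_count,
           n_redundant = sel$n_redundant, readout_gap = sel$readout_gap,
           n_co_optimal = length(sel_set)),
      file.path(outdir, "selection.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    add(file.path(outdir, "selection.json"))
    reduced <- build_reduced_datasets(proc, sel)
    for (cl in c("CR", "PR")) {
      p <- file.path(outdir, paste0("reduced_", tolower(cl), ".csv"))
      write_midas(proc, sel$couples, class = cl, path = p,
                  proteins = sel$proteins)
      add(p)
    }
  }, error = on_fail)

  stage <- "learn"
  tryCatch({
    hg <- expand_hypergraph(net)
    families <- lapply(reduced, function(exp_cl) {
      learn_networks(hg, exp_cl, fit_tolerance = config$fit_tolerance,
                     size_tolerance = config$size_tolerance,
                     exhaustive_cap = config$exhaustive_cap)
    })
    families <- lapply(families, classify_behaviors)
    report_rows <- list()
    for (cl in c("CR", "PR")) {
      fam <- families[[cl]]
      write_network_json(fam, file.path(outdir,
                                        paste0("family_", tolower(cl),
                                               ".json")))
      add(file.path(outdir, paste0("family_", tolower(cl), ".json")))
      utils::write.csv(clause_frequencies(fam),
                       file.path(outdir, paste0("frequencies_", tolower(cl),
                                                ".csv")),
                       row.names = FALSE)
      add(file.path(outdir, paste0("frequencies_", tolower(cl), ".csv")))
      report_rows[[cl]] <- dplyr::bind_cols(tibble::tibble(class = cl),
                                            glance(fam))
    }
    utils::write.csv(dplyr::bind_rows(report_rows),
                     file.path(outdir, "family_report.csv"),
                     row.names = FALSE)
    add(file.path(outdir, "family_report.csv"))
  }, error = on_fail)

  stage <- "classify"
  tryCatch({
    preds <- classify_patients(families$CR, families$PR, proc,
                               method = config$method, low = config$low,
                               high = config$high, mode = config$mode)
    utils::write.csv(preds, file.path(outdir, "predictions.csv"),
                     row.names = FALSE)
    add(file.path(outdir, "predictions.csv"))
    acc <- evaluate_predictions(preds)
    jsonlite::write_json(as.list(acc), file.path(outdir, "accuracy.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(file.path(outdir, "accuracy.json"))
  }, error = on_fail)

  manifest <- list(
    package = "bnstrat",
    version = as.character(utils::packageVersion("bnstrat")),
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    stages = c("preprocess", "select", "learn", "classify"),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(selection = sel, families = families, predictions = preds,
                 accuracy = acc, manifest_path = manifest_path))
}

#' Human-readable summary of a completed pipeline run
#'
#' Renders a learning summary (search space, MSE, size, networks, behaviors
#' per class) and an accuracy summary (per-class and balanced accuracy with
#' analyzed counts in parentheses) from a run directory's artifacts.
#'
#' @param outdir a directory written by [run_pipeline()].
#' @return the summary lines, invisibly; printed as a side effect.
#' @export
pipeline_report <- function(outdir) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest in ", outdir, " (incomplete or missing run)",
         call. = FALSE)
  }
  lines <- character(0)
  fam_path <- file.path(outdir, "family_report.csv")
  if (file.exists(fam_path)) {
    fam <- utils::read.csv(fam_path)
    lines <- c(lines, "Learning summary")
    for (i in seq_len(nrow(fam))) {
      lines <- c(lines, sprintf(
        "  %s: search space 2^%d, MSE %.4g, size %d, %d network(s), %s I/O behavior(s)",
        fam$class[i], fam$search_space_log2[i], fam$mse[i], fam$size[i],
        fam$n_networks[i], fam$n_behaviors[i]))
    }
  } else {
    warning("family report missing: partial report", call. = FALSE)
  }
  acc_path <- file.path(outdir, "accuracy.json")
  if (file.exists(acc_path)) {
    acc <- jsonlite::read_json(acc_path)
    fmt <- function(a, n) {
      if (is.null(a) || is.na(a)) sprintf("NA (%d)", n)
      else sprintf("%.1f%% (%d)", a, n)
    }
    lines <- c(lines, "Classification accuracy",
               sprintf("  CR %s  PR %s  balanced %s  excluded %d",
                       fmt(acc$acc_cr, acc$n_cr), fmt(acc$acc_pr, acc$n_pr),
                       fmt(acc$balanced, acc$n_cr + acc$n_pr),
                       acc$n_excluded))
  } else {
    warning("accuracy report missing: partial report", call. = FALSE)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
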