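# End-to-end orchestration: a single run configuration with one master
# seed fanned out per stage, a staged pipeline driver
# (simulate -> train -> evaluate -> explain -> survival) writing CSV/PNG
# artifacts plus a content-hash manifest, and stage-level resume.

#' Assemble a run configuration
#'
#' Bundles the generator, model and training configurations with output
#' options under one master seed. Every stage derives its own seed
#' deterministically from the master via [derive_seed()], so stages are
#' reproducible independently of each other.
#'
#' @param synth a [synth_config()].
#' @param model a [duonet_config()].
#' @param train a [train_config()].
#' @param k number of cross-validation folds.
#' @param modes modality modes evaluated.
#' @param target_fn_pct screening FN% bound for operating-point selection.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), model = duonet_config(),
                       train = train_config(), k = 5L,
                       modes = c("DUET", "HE_ONLY", "IHC_ONLY"),
                       target_fn_pct = 2, seed = 1L) {
  structure(list(synth = synth, model = model, train = train, k = as.integer(k),
                 modes = modes, target_fn_pct = target_fn_pct,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' The YAML round trip is lossless: loading re-runs the constructors so all
#' invariants are re-validated.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `load_run_config` returns the reconstructed `run_config`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  pl <- yaml::read_yaml(path)
  sy <- pl$synth
  sy$outcome_params <- do.call(outcome_params, sy$outcome_params)
  run_config(synth = do.call(synth_config, sy),
             model = do.call(duonet_config, pl$model),
             train = do.call(train_config, pl$train),
             k = pl$k, modes = unlist(pl$modes),
             target_fn_pct = pl$target_fn_pct, seed = pl$seed)
}

stage_marker <- function(out_dir, stage) file.path(out_dir, sprintf(".done_%s", stage))

stage_fresh <- function(out_dir, stage, files) {
  mk <- stage_marker(out_dir, stage)
  if (!file.exists(mk)) return(FALSE)
  rec <- utils::read.csv(mk, stringsAsFactors = FALSE)
  paths <- file.path(out_dir, rec$file)
  all(file.exists(paths)) &&
    all(unname(tools::md5sum(paths)) == rec$md5)
}

stage_done <- function(out_dir, stage, files) {
  rel <- files
  md5 <- unname(tools::md5sum(file.path(out_dir, files)))
  utils::write.csv(data.frame(file = rel, md5 = md5),
                   stage_marker(out_dir, stage), row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate, train, evaluate, explain and survival stages into
#' `out_dir`, writing CSV tables, PNG figures and a `manifest.csv` of
#' artifact content hashes. Stages whose outputs already exist with
#' matching hashes are skipped, so deleting a downstream artifact and
#' re-running resumes without recomputing upstream stages. Any stage
#' failure aborts with the stage named.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param force re-run all stages even when outputs are fresh.
#' @return invisibly, `out_dir`; the manifest is attached as an attribute.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, files, fn) {
    if (!force && stage_fresh(out_dir, stage, files)) {
      message(sprintf("[%s] up to date, skipping", stage))
      return(invisible(NULL))
    }
    message(sprintf("[%s] running", stage))
    tryCatch(fn(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
    stage_done(out_dir, stage, files)
  }

  run_stage("simulate", c("manifest.csv", "cohort.rds"), function() {
    sy <- config$synth
    sy$seed <- derive_seed(config$seed, "simulate")
    cohort <- exclude_indeterminate(generate_cohort(sy))
    utils::write.csv(cohort_manifest(cohort),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
    saveRDS(cohort, file.path(out_dir, "cohort.rds"))
  })
  cohort <- readRDS(file.path(out_dir, "cohort.rds"))

  run_stage("train", c("predictions.csv", "fold_aurocs.csv", "cv.rds"), function() {
    manifest <- utils::read.csv(file.path(out_dir, "manifest.csv"))
    required <- c("case_id", "label", "scanner", "site")
    missing <- setdiff(required, names(manifest))
    if (length(missing)) {
      stopf("manifest missing column(s): %s", paste(missing, collapse = ", "))
    }
    tc <- config$train
    tc$seed <- derive_seed(config$seed, "train")
    cv <- duonet_cv(cohort, config$model, tc, k = config$k,
                    modes = config$modes, keep_fits = TRUE)
    utils::write.csv(cv$records, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$fold_aurocs, file.path(out_dir, "fold_aurocs.csv"),
                     row.names = FALSE)
    saveRDS(cv, file.path(out_dir, "cv.rds"))
  })
  cv <- readRDS(file.path(out_dir, "cv.rds"))

  run_stage("evaluate", c("auroc_summary.csv", "stratified.csv",
                          "tradeoff.csv", "operating_point.csv",
                          "probability_histogram.csv"), function() {
    utils::write.csv(summary(cv), file.path(out_dir, "auroc_summary.csv"),
                     row.names = FALSE)
    duet <- cv$records[cv$records$mode == "DUET", ]
    strat <- rbind(cbind(key = "scanner", stratified_auroc(duet, "scanner")),
                   cbind(key = "site", stratified_auroc(duet, "site")),
                   cbind(key = "mode", stratified_auroc(cv$records, "mode")))
    utils::write.csv(strat, file.path(out_dir, "stratified.csv"),
                     row.names = FALSE)
    curve <- tradeoff_curve(duet)
    utils::write.csv(curve, file.path(out_dir, "tradeoff.csv"),
                     row.names = FALSE)
    op <- pick_operating_point(curve, config$target_fn_pct)
    utils::write.csv(op, file.path(out_dir, "operating_point.csv"),
                     row.names = FALSE)
    hist_ <- probability_histogram(duet)
    utils::write.csv(as.data.frame(hist_$counts),
                     file.path(out_dir, "probability_histogram.csv"))
  })

  run_stage("explain", c("contribution_scores.csv", "heatmap.png"), function() {
    sp <- cv$splits[[1]]
    fit <- cv$fits[[1]]
    pos_ids <- sp$test_ids[case_labels(cohort, sp$test_ids) == 1]
    if (length(pos_ids) == 0) pos_ids <- sp$test_ids[1]
    case <- cohort$cases[[pos_ids[1]]]
    maps <- explain_case(fit, case)
    rows <- do.call(rbind, lapply(names(maps), function(mdl) {
      cbind(case_id = case$case_id, modality = mdl, as.data.frame(maps[[mdl]]))
    }))
    utils::write.csv(rows, file.path(out_dir, "contribution_scores.csv"),
                     row.names = FALSE)
    m <- maps[[1]]
    dims <- c(max(m$y0 + m$height), max(m$x0 + m$width))
    render_heatmap(m, dims, file.path(out_dir, "heatmap.png"), scale = 8L)
  })

  run_stage("survival", c("cox.csv", "km_actual.png", "km_predicted.png"), function() {
    duet <- cv$records[cv$records$mode == "DUET", ]
    actual <- survival_by_status(cohort)
    # degenerate thresholds (all predictions on one side of 0.5) fall back
    # to the median probability so two groups always exist
    thr <- 0.5
    if (length(unique(duet$probability >= thr)) < 2) {
      thr <- stats::median(duet$probability)
      message(sprintf("threshold 0.5 degenerate; using median %.3f", thr))
    }
    predicted <- survival_by_status(cohort, predictions = duet, threshold = thr)
    km_plot(actual$records, file.path(out_dir, "km_actual.png"),
            main = "OS by actual status")
    km_plot(predicted$records, file.path(out_dir, "km_predicted.png"),
            main = "OS by predicted status")
    cox_tab <- rbind(
      data.frame(grouping = "actual", hr = actual$cox$hr,
                 ci_lower = actual$cox$ci[1], ci_upper = actual$cox$ci[2],
                 p = actual$cox$p, logrank_p = actual$logrank$p),
      data.frame(grouping = "predicted", hr = predicted$cox$hr,
                 ci_lower = predicted$cox$ci[1], ci_upper = predicted$cox$ci[2],
                 p = predicted$cox$p, logrank_p = predicted$logrank$p))
    utils::write.csv(cox_tab, file.path(out_dir, "cox.csv"), row.names = FALSE)
  })

  arts <- setdiff(list.files(out_dir), "run_manifest.csv")
  manifest <- data.frame(file = arts,
                         md5 = unname(tools::md5sum(file.path(out_dir, arts))))
  utils::write.csv(manifest, file.path(out_dir, "run_manifest.csv"),
                   row.names = FALSE)
  out <- out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}
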