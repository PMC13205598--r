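# Experiment orchestration: the two robustness designs and the Table-1-style
# aggregation.
#
# SSMR (Single Split, Multiple Replica): one fixed train/test split, several
# generator seeds — isolates generator stochasticity. MSSR (Multiple Split,
# Single Replica): several splits, one generator run each — isolates split
# dependence. Per run the pipeline is: split -> train DAAE -> sample raw ->
# refine -> fidelity/privacy/bias metrics (raw and refined) vs the run's real
# training data -> trajectory audit -> TSTR on the real test split. Metrics
# are aggregated as median [min - max] across runs.

#' Experiment plan
#'
#' @param design `"SSMR"` or `"MSSR"`.
#' @param n_runs number of generative runs (default 5).
#' @param split_fraction training fraction of the 80/20 split (default 0.8).
#' @param sim a [sim_config()] for the ground-truth cohort.
#' @param daae a [daae_config()].
#' @param n_synth synthetic records sampled per run (default: training size).
#' @param seed master seed; per-run generator and split seeds derive from it
#'   (SSMR: one shared split seed, distinct generator seeds; MSSR: distinct
#'   split seeds, one generator seed each).
#' @return an `experiment_plan` list.
#' @export
experiment_plan <- function(design = c("SSMR", "MSSR"), n_runs = 5,
                            split_fraction = 0.8, sim = sim_config(),
                            daae = daae_config(), n_synth = NULL, seed = 1L) {
  design <- match.arg(design)
  stopifnot(n_runs >= 1, split_fraction > 0, split_fraction < 1)
  gen_seeds <- vapply(seq_len(n_runs), function(k) child_seed(seed, k), 0L)
  split_seeds <- if (design == "SSMR") rep(child_seed(seed, 0L), n_runs) else
    vapply(seq_len(n_runs), function(k) child_seed(seed, 100L + k), 0L)
  structure(list(design = design, n_runs = n_runs,
                 split_fraction = split_fraction, sim = sim, daae = daae,
                 n_synth = n_synth, seed = seed, gen_seeds = gen_seeds,
                 split_seeds = split_seeds),
            class = "experiment_plan")
}

#' Patient-level train/test split, stratified by endpoint status
#'
#' @param x an `ehr_cohort`.
#' @param fraction training fraction.
#' @param seed RNG seed.
#' @return list with `train` and `test` cohorts.
#' @export
split_cohort <- function(x, fraction = 0.8, seed = 1L) {
  set.seed(seed)
  has_end <- vapply(x$records, record_has_code, TRUE, code = x$endpoint_code)
  idx_train <- unlist(lapply(c(TRUE, FALSE), function(lab) {
    pool <- which(has_end == lab)
    sample(pool, round(length(pool) * fraction))
  }))
  keep <- seq_along(x$records) %in% idx_train
  list(train = cohort(x$records[keep], x$vocabulary, x$anchor_code,
                      x$endpoint_code),
       test = cohort(x$records[!keep], x$vocabulary, x$anchor_code,
                     x$endpoint_code))
}

run_one <- function(real, plan, k) {
  sp <- split_cohort(real, plan$split_fraction, plan$split_seeds[k])
  cfg <- plan$daae
  cfg$seed <- plan$gen_seeds[k]
  gen <- daae(sp$train, cfg)
  n_synth <- plan$n_synth %||% length(sp$train$records)
  raw <- sample_cohort(gen, n_synth, seed = child_seed(plan$gen_seeds[k], 7L))
  ref <- refine_cohort(raw)
  metrics_for <- function(synth) {
    fid <- fidelity_report(sp$train, synth, n_directions = 200,
                           seed = plan$gen_seeds[k])
    priv <- privacy_report(sp$train, sp$test, synth, seed = plan$gen_seeds[k])
    traj <- tryCatch(trajectory_report(sp$train, list(run = synth))$dtw,
                     error = function(e) NA_real_)
    c(BAS = fid$BAS, CAS = fid$CAS, KSS = fid$KSS, TVS = fid$TVS,
      CrSS = fid$CrSS, CtSS = fid$CtSS, SWD = fid$SWD, CoC = fid$CoC,
      DTW = traj, NRS = priv$NRS, DPeS = priv$DPeS,
      MIA_AUROC = priv$MIA_auroc)
  }
  m_raw <- metrics_for(raw)
  m_ref <- metrics_for(ref$cohort)
  bias <- sex_bias_delta(sp$train, ref$cohort)
  tstr <- tryCatch({
    tr_real <- build_task(refine_for_prediction(sp$train)$cohort)
    tr_syn <- build_task(refine_for_prediction(ref$cohort)$cohort)
    te <- build_task(refine_for_prediction(sp$test)$cohort)
    list(real = run_tstr(tr_real, NULL, te, "real",
                         cv = list(repeats = 2, folds = 5),
                         seed = plan$gen_seeds[k]),
         synthetic = run_tstr(tr_real, tr_syn, te, "synthetic",
                              cv = list(repeats = 2, folds = 5),
                              seed = plan$gen_seeds[k]))
  }, error = function(e) e)
  list(run = k, raw = m_raw, refined = m_ref, discard = ref$report,
       sex_bias_delta = bias, tstr = tstr,
       seeds = c(gen = plan$gen_seeds[k], split = plan$split_seeds[k]))
}

#' Run an experiment plan
#'
#' Executes every run of the plan end to end; a failing run is recorded and
#' excluded from the summary with a warning.
#'
#' @param plan an [experiment_plan()].
#' @param real optional pre-simulated real cohort (defaults to
#'   `simulate_cohort(plan$sim)`).
#' @return an `experiment_result`: per-run artifacts plus a [summarize_runs()]
#'   table.
#' @export
run_experiment <- function(plan, real = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(real)) real <- simulate_cohort(plan$sim)
  runs <- vector("list", plan$n_runs)
  for (k in seq_len(plan$n_runs)) {
    runs[[k]] <- tryCatch(run_one(real, plan, k), error = function(e) {
      warning("run ", k, " failed: ", conditionMessage(e))
      structure(list(run = k, error = conditionMessage(e)),
                class = "failed_run")
    })
  }
  ok <- !vapply(runs, inherits, TRUE, "failed_run")
  summary <- if (any(ok)) list(
    raw = summarize_runs(do.call(rbind, lapply(runs[ok], `[[`, "raw"))),
    refined = summarize_runs(do.call(rbind, lapply(runs[ok], `[[`, "refined"))))
  else NULL
  structure(list(plan = plan, runs = runs, summary = summary,
                 n_failed = sum(!ok)),
            class = "experiment_result")
}

#' Median (min-max) aggregation across runs
#'
#' @param m matrix of per-run metric values (runs in rows).
#' @return data frame with metric, median, min, max.
#' @export
summarize_runs <- function(m) {
  m <- as.matrix(m)
  safe <- function(f) apply(m, 2, function(v)
    if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE))
  data.frame(metric = colnames(m),
             median = safe(stats::median),
             min = safe(min),
             max = safe(max),
             row.names = NULL)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s, %d runs (%d failed)\n",
              x$plan$design, x$plan$n_runs, x$n_failed))
  if (!is.null(x$summary)) {
    cat("refined cohort metrics, median [min - max]:\n")
    s <- x$summary$refined
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-10s %.3f [%.3f, %.3f]\n", s$metric[i], s$median[i],
                  s$min[i], s$max[i]))
  }
  invisible(x)
}
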