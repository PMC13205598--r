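# Train-Synthetic / Test-Real predictive-utility harness.
#
# Task: predict chronic-kidney-disease onset after the diabetes diagnosis from
# the pre-diagnosis history only. Three training scenarios (real, synthetic,
# hybrid = concatenation) are evaluated on a fixed held-out real test set with
# repeated k-fold cross-validated fits, plus feature-rank stability
# (hyperbolic weighted Kendall tau) and prediction-distribution stability.

#' Build the endpoint-prediction task
#'
#' Features: sex (female indicator), age at diabetes diagnosis, and for each
#' non-anchor, non-endpoint vocabulary code a presence flag and first-
#' diagnosis age restricted to the pre-anchor history (a comorbidity first
#' diagnosed strictly after the anchor age contributes neither flag nor age).
#' Missing ages use a -1 sentinel; the companion flag column marks validity.
#' Label: endpoint code occurring after the anchor age. Records should have
#' passed [refine_for_prediction()].
#'
#' @param x an `ehr_cohort`.
#' @return a `prediction_task`: list with feature matrix `X`, logical label
#'   `y`, and per-patient `sex` and `diagnosis_year` for stratified scoring.
#' @export
build_task <- function(x) {
  stopifnot(inherits(x, "ehr_cohort"))
  codes <- setdiff(x$vocabulary, c(x$anchor_code, x$endpoint_code))
  n <- length(x$records)
  long <- cohort_long(x)
  first <- if (nrow(long))
    long[, .(age = age[which.min(vidx)]), by = .(row, code)] else
      data.table::data.table(row = integer(), code = character(), age = numeric())
  anchor_age <- rep(NA_real_, n)
  aa <- first[code == x$anchor_code]
  anchor_age[aa$row] <- aa$age
  end_age <- rep(NA_real_, n)
  ea <- first[code == x$endpoint_code]
  end_age[ea$row] <- ea$age
  y <- !is.na(end_age) & !is.na(anchor_age) & end_age >= anchor_age
  sexes <- vapply(x$records, `[[`, "", "sex")
  X <- matrix(0, n, 2 + 2 * length(codes))
  colnames(X) <- c("sex_female", "age_at_diabetes",
                   paste0("flag_", codes), paste0("age_", codes))
  X[, "sex_female"] <- as.numeric(sexes == "female")
  X[, "age_at_diabetes"] <- anchor_age
  X[, paste0("age_", codes)] <- -1
  pre <- first[code %in% codes]
  if (nrow(pre)) {
    pre <- pre[age <= anchor_age[row]]          # leakage guard
    if (nrow(pre)) {
      X[cbind(pre$row, match(paste0("flag_", pre$code), colnames(X)))] <- 1
      X[cbind(pre$row, match(paste0("age_", pre$code), colnames(X)))] <- pre$age
    }
  }
  structure(list(X = X, y = y, sex = sexes,
                 diagnosis_year = vapply(x$records, `[[`, NA_integer_,
                                         "diagnosis_year")),
            class = "prediction_task")
}

# ---- cyclic-boosted additive classifier --------------------------------------

#' Cyclic-boosted additive classifier
#'
#' A glass-box additive model in the explainable-boosting family: each feature
#' is discretized (quantile bins for continuous features), and boosting sweeps
#' cyclically over features applying damped per-bin Newton updates on the
#' logistic loss. The model exposes per-feature global importance as the mean
#' absolute score contribution over the training rows. Returned as a pluggable
#' classifier interface (`fit`, `predict_prob`, `importance`) accepted by
#' [run_tstr()]; any object with the same three functions can be substituted.
#'
#' @param n_sweeps boosting sweeps over all features (default 8).
#' @param learning_rate damping of each Newton update (default 0.5).
#' @param n_bins maximum bins per continuous feature (default 8; coarse bins
#'   keep the per-bin estimates stable at moderate sample sizes).
#' @return a `synthehr_classifier` list.
#' @export
cyclic_boost_classifier <- function(n_sweeps = 8, learning_rate = 0.5,
                                    n_bins = 8) {
  fit <- function(X, y) {
    y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    # bins = regions around the unique quantile cut points (midpoint edges),
    # so binary features get two bins and unseen values clamp to the outermost
    breaks <- vector("list", p)
    B <- matrix(1L, n, p)
    for (j in seq_len(p)) {
      v <- X[, j]
      u <- sort(unique(stats::quantile(v, probs = seq(0, 1,
                                                      length.out = n_bins + 1),
                                       names = FALSE, type = 1)))
      edges <- if (length(u) < 2) numeric() else (u[-1] + u[-length(u)]) / 2
      breaks[[j]] <- edges
      B[, j] <- findInterval(v, edges) + 1L
    }
    pbar <- mean(y)
    intercept <- stats::qlogis(min(max(pbar, 1e-6), 1 - 1e-6))
    g <- lapply(seq_len(p), function(j) numeric(length(breaks[[j]]) + 1L))
    eta <- rep(intercept, n)
    for (sweep in seq_len(n_sweeps)) {
      for (j in seq_len(p)) {
        ph <- stats::plogis(eta)
        grad <- y - ph
        hess <- ph * (1 - ph)
        num <- rowsum(grad, B[, j])
        den <- rowsum(hess, B[, j]) + 1e-3
        delta <- learning_rate * as.numeric(num / den)
        bins_here <- as.integer(rownames(num))
        upd <- numeric(length(g[[j]]))
        upd[bins_here] <- delta
        step <- upd[B[, j]]
        ctr <- mean(step)
        g[[j]] <- g[[j]] + upd - ctr
        intercept <- intercept + ctr
        eta <- eta + step
      }
    }
    list(intercept = intercept, g = g, breaks = breaks,
         contrib_scale = vapply(seq_len(p), function(j)
           mean(abs(g[[j]][B[, j]])), 0.0),
         feature_names = colnames(X))
  }
  predict_prob <- function(model, X) {
    eta <- rep(model$intercept, nrow(X))
    for (j in seq_along(model$g)) {
      b <- findInterval(X[, j], model$breaks[[j]]) + 1L
      eta <- eta + model$g[[j]][b]
    }
    stats::plogis(eta)
  }
  importance <- function(model)
    stats::setNames(model$contrib_scale, model$feature_names)
  structure(list(fit = fit, predict_prob = predict_prob,
                 importance = importance, label = "cyclic_boost"),
            class = "synthehr_classifier")
}

#' Ridge-logistic classifier (pluggable alternative)
#'
#' L2-regularized logistic regression via glmnet with absolute-coefficient
#' importance on standardized features.
#'
#' @param lambda ridge penalty (default `1e-3`).
#' @return a `synthehr_classifier` list.
#' @export
ridge_classifier <- function(lambda = 1e-3) {
  fit <- function(X, y) {
    mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    m <- glmnet::glmnet(Z, factor(y), family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
    list(m = m, mu = mu, sdv = sdv, feature_names = colnames(X))
  }
  predict_prob <- function(model, X) {
    Z <- sweep(sweep(X, 2, model$mu), 2, model$sdv, "/")
    as.numeric(stats::predict(model$m, Z, type = "response"))
  }
  importance <- function(model)
    stats::setNames(abs(as.numeric(stats::coef(model$m))[-1]),
                    model$feature_names)
  structure(list(fit = fit, predict_prob = predict_prob,
                 importance = importance, label = "ridge_logistic"),
            class = "synthehr_classifier")
}

# descending-importance feature ranking with name-lexicographic tie-break
importance_ranking <- function(imp) {
  names(imp)[order(-imp, names(imp), method = "radix")]
}

#' Run one TSTR scenario
#'
#' Builds the scenario's training pool (`real`, `synthetic`, or `hybrid` =
#' plain concatenation of real and synthetic rows), performs `repeats` x
#' `folds` cross-validated fits (each fit trains on the pool minus one fold)
#' and evaluates every fit on the fixed real test set, plus one fit on the
#' full pool. Folds degenerate to a single class are skipped and counted.
#'
#' @param real_train,synth_train,real_test `prediction_task`s
#'   (`synth_train` may be `NULL` for the `real` scenario).
#' @param scenario `"real"`, `"synthetic"`, or `"hybrid"`.
#' @param cv list with `repeats` and `folds` (defaults 10 and 10).
#' @param model a classifier from e.g. [cyclic_boost_classifier()].
#' @param seed RNG seed for fold assignment.
#' @return a `tstr_fit` list: per-fit AUROCs (`auroc_cv`), `auroc_mean`,
#'   `auroc_sd`, the full-pool model's `auroc_full`, per-fit test prediction
#'   matrix, full-model predictions, per-fit importance rankings, and the test
#'   metadata needed for stratified scoring.
#' @export
run_tstr <- function(real_train, synth_train = NULL, real_test,
                     scenario = c("real", "synthetic", "hybrid"),
                     cv = list(repeats = 10, folds = 10),
                     model = cyclic_boost_classifier(), seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario != "real" && is.null(synth_train))
    stop("synthetic training task required for scenario ", scenario)
  pool <- switch(scenario,
                 real = real_train,
                 synthetic = synth_train,
                 hybrid = list(X = rbind(real_train$X, synth_train$X),
                               y = c(real_train$y, synth_train$y)))
  if (length(unique(pool$y)) < 2)
    stop("training pool has no endpoint variation")
  n <- length(pool$y)
  set.seed(seed)
  preds <- list(); aucs <- numeric(); ranks <- list(); skipped <- 0L
  for (r in seq_len(cv$repeats)) {
    fold_id <- sample(rep(seq_len(cv$folds), length.out = n))
    for (f in seq_len(cv$folds)) {
      idx <- which(fold_id != f)
      if (length(unique(pool$y[idx])) < 2) { skipped <- skipped + 1L; next }
      m <- model$fit(pool$X[idx, , drop = FALSE], pool$y[idx])
      p <- model$predict_prob(m, real_test$X)
      preds[[length(preds) + 1L]] <- p
      aucs <- c(aucs, auroc(p, real_test$y))
      ranks[[length(ranks) + 1L]] <- importance_ranking(model$importance(m))
    }
  }
  m_full <- model$fit(pool$X, pool$y)
  p_full <- model$predict_prob(m_full, real_test$X)
  structure(list(scenario = scenario,
                 auroc_cv = aucs, auroc_mean = mean(aucs),
                 auroc_sd = stats::sd(aucs),
                 auroc_full = auroc(p_full, real_test$y),
                 cv_predictions = do.call(cbind, preds),
                 full_predictions = p_full,
                 rankings = ranks,
                 full_ranking = importance_ranking(model$importance(m_full)),
                 skipped_folds = skipped,
                 test_sex = real_test$sex,
                 test_year = real_test$diagnosis_year,
                 test_y = real_test$y),
            class = "tstr_fit")
}

#' Stratified AUROC table
#'
#' AUROC of the cross-validated fits within each stratum (calendar year of
#' diabetes diagnosis, or sex) of the real test set. Strata with fewer than
#' two classes are flagged.
#'
#' @param fit a `tstr_fit` from [run_tstr()].
#' @param grouping `"diagnosis_year"` or `"sex"`.
#' @return data frame with stratum, n, mean and SD of per-fit AUROC, and a
#'   `degenerate` flag.
#' @export
auroc_by_group <- function(fit, grouping = c("diagnosis_year", "sex")) {
  grouping <- match.arg(grouping)
  grp <- if (grouping == "diagnosis_year") fit$test_year else fit$test_sex
  strata <- sort(unique(grp[!is.na(grp)]))
  rows <- lapply(strata, function(g) {
    in_g <- !is.na(grp) & grp == g
    if (length(unique(fit$test_y[in_g])) < 2)
      return(data.frame(stratum = as.character(g), n = sum(in_g),
                        auroc_mean = NA_real_, auroc_sd = NA_real_,
                        degenerate = TRUE))
    a <- apply(fit$cv_predictions[in_g, , drop = FALSE], 2, auroc,
               labels = fit$test_y[in_g])
    data.frame(stratum = as.character(g), n = sum(in_g),
               auroc_mean = mean(a), auroc_sd = stats::sd(a),
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Hyperbolic weighted Kendall tau
#'
#' Rank correlation between two ordered feature lists with additive hyperbolic
#' weights `w(r) = 1 / (1 + r)` over zero-based ranks: an exchanged pair
#' `(i, j)` contributes `w(i) + w(j)`, the statistic is the weighted sum of
#' pair signs normalized by the total pair weight, and the result is
#' symmetrized by averaging the statistic computed with each list as the
#' reference ranking. With `weights = "equal"` it reduces to the unweighted
#' Kendall tau. Ranges from -1 (reversed ranks) to 1 (perfect agreement).
#'
#' @param rank_a,rank_b character vectors, best-ranked feature first; must
#'   contain the same feature set.
#' @param weights `"hyperbolic"` or `"equal"`.
#' @return a score in `[-1, 1]`.
#' @export
hyperbolic_weighted_tau <- function(rank_a, rank_b,
                                    weights = c("hyperbolic", "equal")) {
  weights <- match.arg(weights)
  if (!setequal(rank_a, rank_b) || anyDuplicated(rank_a) || anyDuplicated(rank_b))
    stop("rankings must be permutations of the same feature set")
  wfun <- if (weights == "hyperbolic") function(r) 1 / (1 + r) else
    function(r) rep(1, length(r))
  one_side <- function(ref, other) {
    items <- ref
    pa <- match(items, ref) - 1
    pb <- match(items, other) - 1
    n <- length(items)
    ij <- utils::combn(n, 2)
    sa <- sign(pa[ij[1, ]] - pa[ij[2, ]])
    sb <- sign(pb[ij[1, ]] - pb[ij[2, ]])
    w <- wfun(pa[ij[1, ]]) + wfun(pa[ij[2, ]])
    sum(w * sa * sb) / sum(w)
  }
  (one_side(rank_a, rank_b) + one_side(rank_b, rank_a)) / 2
}

#' Prediction distribution stability
#'
#' Per test patient and cross-validated model, the difference between the
#' model's predicted probability and the full-pool model's; summarized by
#' quantiles.
#'
#' @param fit a `tstr_fit` from [run_tstr()].
#' @param probs quantiles to report (default 1, 25, 50, 75, 99 percent).
#' @return list with the quantile summary and the difference matrix.
#' @export
prediction_distribution_stability <- function(fit,
                                              probs = c(.01, .25, .5, .75, .99)) {
  d <- fit$cv_predictions - fit$full_predictions
  list(quantiles = stats::quantile(d, probs = probs, names = TRUE),
       differences = d)
}

#' Feature-rank stability across fits
#'
#' Pairwise hyperbolic weighted tau, either within one scenario's CV fits or
#' between the fits of two scenarios.
#'
#' @param fit_a a `tstr_fit`.
#' @param fit_b optional second `tstr_fit`; when supplied, taus are computed
#'   between the two scenarios' fits, otherwise within `fit_a`.
#' @param max_pairs cap on the number of ranking pairs evaluated.
#' @return numeric vector of tau values.
#' @export
rank_stability <- function(fit_a, fit_b = NULL, max_pairs = 100) {
  if (is.null(fit_b)) {
    pr <- utils::combn(length(fit_a$rankings), 2)
    if (ncol(pr) > max_pairs) pr <- pr[, seq_len(max_pairs), drop = FALSE]
    apply(pr, 2, function(k)
      hyperbolic_weighted_tau(fit_a$rankings[[k[1]]], fit_a$rankings[[k[2]]]))
  } else {
    pr <- expand.grid(a = seq_along(fit_a$rankings),
                      b = seq_along(fit_b$rankings))
    if (nrow(pr) > max_pairs) pr <- pr[seq_len(max_pairs), , drop = FALSE]
    mapply(function(i, j)
      hyperbolic_weighted_tau(fit_a$rankings[[i]], fit_b$rankings[[j]]),
      pr$a, pr$b)
  }
}
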