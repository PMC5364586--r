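# Evaluation protocol: stratified 75/25 partitioning, multi-run
# aggregation, confusion matrices, burden-bin error rates, and burden
# recovery metrics (Pearson correlation, RMSE).

#' Stratified train/test partition of reference samples
#'
#' Splits the samples of every class into a training fraction (used to fit
#' the panel) and a disjoint test fraction (used to draw simulation
#' profiles), at the same proportion per class.
#'
#' @param manifest data.frame (`sample_id`, `class_label`).
#' @param train_frac training fraction (default 0.75).
#' @param seed optional integer seed.
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
partition_samples <- function(manifest, train_frac = 0.75, seed = NULL) {
  stopifnot(train_frac > 0, train_frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  train <- character()
  test <- character()
  for (cl in unique(manifest$class_label)) {
    ids <- manifest$sample_id[manifest$class_label == cl]
    n_tr <- round(train_frac * length(ids))
    pick <- sample(ids, n_tr)
    train <- c(train, pick)
    test <- c(test, setdiff(ids, pick))
  }
  if (length(test) == 0L)
    warning("train_frac leaves an empty test set")
  list(train = train, test = test)
}

#' Burden recovery metrics
#'
#' Pearson correlation and root mean squared error between true and
#' predicted tumor burdens.
#'
#' @param true_theta,pred_theta numeric vectors of equal length (>= 2).
#' @return list with `pcc` and `rmse`.
#' @export
burden_metrics <- function(true_theta, pred_theta) {
  stopifnot(length(true_theta) == length(pred_theta))
  if (length(true_theta) < 2L)
    stop("need at least two pairs", call. = FALSE)
  list(pcc = cor(true_theta, pred_theta),
       rmse = sqrt(mean((true_theta - pred_theta)^2)))
}

#' Burden bin of a true tumor fraction
#'
#' Ten left-open, right-closed decade bins `(theta, theta + 10%]`,
#' `theta = 0, 10, ..., 90%`, partitioning `(0, 1]`; a burden of exactly 0
#' (normal plasma) maps to `NA`.
#'
#' @param theta numeric vector of burdens.
#' @return ordered factor of bin labels like `"(0,0.1]"`.
#' @export
burden_bin <- function(theta) {
  cut(theta, breaks = seq(0, 1, by = 0.1), right = TRUE,
      include.lowest = FALSE)
}

#' Score a set of class/burden predictions
#'
#' Builds the `(T+1)`-class confusion matrix (rows = true class, columns =
#' predicted class), the overall error rate (fraction of incorrect class
#' predictions), burden recovery metrics over the cancer samples, and --
#' when `truth` carries a `bin` column -- the per-bin error rates.
#'
#' @param truth data.frame with `sample_id`, `true_class`, `true_theta`,
#'   optionally `bin`.
#' @param pred data.frame with `sample_id`, `pred_class`, `theta_hat` (as
#'   returned by [predict_burden()]).
#' @param classes factor levels for the confusion matrix (normal class
#'   first); defaults to the labels present.
#' @param normal_class label of the non-cancer class.
#' @return object of class `eval_report`: list with `confusion`,
#'   `error_rate`, `n`, `pcc`, `rmse`, `per_bin`.
#' @export
score_predictions <- function(truth, pred, classes = NULL,
                              normal_class = "normal") {
  df <- merge(truth, pred, by = "sample_id", sort = FALSE)
  if (nrow(df) != nrow(truth))
    stop("predictions do not cover the truth table", call. = FALSE)
  if (is.null(classes))
    classes <- union(normal_class,
                     sort(unique(c(df$true_class, df$pred_class))))
  tf <- factor(df$true_class, levels = classes)
  pf <- factor(df$pred_class, levels = classes)
  confusion <- table(true = tf, predicted = pf)
  err <- mean(df$true_class != df$pred_class)
  cancer <- df$true_class != normal_class
  bm <- if (sum(cancer) >= 2L) {
    burden_metrics(df$true_theta[cancer], df$theta_hat[cancer])
  } else list(pcc = NA_real_, rmse = NA_real_)
  per_bin <- NULL
  if ("bin" %in% names(df)) {
    per_bin <- vapply(split(df, df$bin),
                      function(d) mean(d$true_class != d$pred_class),
                      numeric(1))
  }
  structure(list(confusion = confusion, error_rate = err, n = nrow(df),
                 pcc = bm$pcc, rmse = bm$rmse, per_bin = per_bin),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report (", x$n, " predictions)\n", sep = "")
  cat(sprintf("  error rate: %.3f\n", x$error_rate))
  if (!is.na(x$pcc))
    cat(sprintf("  burden PCC: %.3f   RMSE: %.3f\n", x$pcc, x$rmse))
  if (!is.null(x$per_bin)) {
    cat("  per-bin error rates:\n")
    for (b in names(x$per_bin))
      cat(sprintf("    %-10s %.3f\n", b, x$per_bin[b]))
  }
  print(x$confusion)
  invisible(x)
}

#' Combine evaluation reports
#'
#' Pools predictions across runs: confusion matrices add, the error rate is
#' recomputed from the pooled confusion, per-bin errors are sample-weighted
#' means.
#'
#' @param reports list of `eval_report`s with identical class sets.
#' @return pooled `eval_report` (PCC/RMSE are sample-weighted means of the
#'   per-run values).
#' @export
combine_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  confusion <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  n <- sum(vapply(reports, `[[`, numeric(1), "n"))
  err <- 1 - sum(diag(confusion)) / sum(confusion)
  wt <- vapply(reports, `[[`, numeric(1), "n")
  wmean <- function(f) {
    v <- vapply(reports, `[[`, numeric(1), f)
    if (all(is.na(v))) NA_real_ else sum(v * wt, na.rm = TRUE) /
      sum(wt[!is.na(v)])
  }
  per_bin <- NULL
  if (!is.null(reports[[1]]$per_bin)) {
    mat <- vapply(reports, `[[`, numeric(length(reports[[1]]$per_bin)),
                  "per_bin")
    per_bin <- rowMeans(as.matrix(mat))
  }
  structure(list(confusion = confusion, error_rate = err, n = n,
                 pcc = wmean("pcc"), rmse = wmean("rmse"),
                 per_bin = per_bin),
            class = "eval_report")
}

#' Default likelihood predictor
#'
#' The standard prediction hook for [run_experiment()]: wraps
#' [predict_burden()].
#'
#' @param profiles named list of count profiles.
#' @param panel a `meth_panel`.
#' @param ... passed to [predict_burden()].
#' @export
mixture_predictor <- function(profiles, panel, ...) {
  predict_burden(profiles, panel, ...)
}

#' Uniform random-guess predictor (stub baseline)
#'
#' Predicts a uniformly random class for every sample; its expected
#' error rate on balanced classes is `(C - 1) / C` (5/6 for six classes).
#'
#' @inheritParams mixture_predictor
#' @export
random_guess_predictor <- function(profiles, panel, ...) {
  classes <- panel$class_names
  data.frame(sample_id = names(profiles),
             pred_class = sample(classes, length(profiles), replace = TRUE),
             theta_hat = NA_real_, stringsAsFactors = FALSE)
}

#' Nearest-mean baseline classifier
#'
#' A deliberately simple comparison baseline: each sample's observed
#' cluster levels (`m/n`, unusable clusters dropped) are compared with the
#' fitted per-class mean levels `alpha / (alpha + beta)` of the panel's
#' selected features, and the class with the smallest mean squared
#' difference wins.  It ignores the mixture structure entirely, which is
#' exactly why it fails at low tumor burden.
#'
#' @inheritParams mixture_predictor
#' @export
nearest_mean_baseline <- function(profiles, panel, ...) {
  mu <- panel$alpha / (panel$alpha + panel$beta)
  mu <- mu[panel$selected, , drop = FALSE]
  pred <- vapply(profiles, function(p) {
    idx <- match(panel$selected, p$cluster_id)
    ok <- !is.na(idx) & p$total_count[idx] > 0
    obs <- p$meth_count[idx][ok] / p$total_count[idx][ok]
    d <- colMeans((mu[ok, , drop = FALSE] - obs)^2)
    names(d)[which.min(d)]
  }, character(1))
  data.frame(sample_id = names(profiles), pred_class = unname(pred),
             theta_hat = NA_real_, stringsAsFactors = FALSE)
}

#' Run the full simulation evaluation protocol
#'
#' For each of `n_runs` runs: partition the reference pools per class
#' (75/25 by default), fit a panel on the training split, build a
#' simulation scenario from the held-out split, simulate
#' `n_per_class_per_bin` cancer profiles per tumor class for every burden
#' decade bin plus the same number of normal profiles per bin, predict
#' every profile, and score.  Runs are pooled into a single report.
#'
#' @param reference a `synth_reference` (or any list with `levels`,
#'   `manifest`, `clusters`).
#' @param n_runs number of independent partition/fit/simulate runs
#'   (default 10).
#' @param n_per_class_per_bin samples per class per burden bin (default
#'   20).
#' @param bins integer vector of decade bins to simulate (default `1:10`,
#'   i.e. `(0, 0.1]` through `(0.9, 1]`).
#' @param train_frac training fraction (default 0.75).
#' @param mr_cutoff feature selection cutoff (default 0.25).
#' @param coverage mean cytosines per cluster in the simulation (default
#'   150).
#' @param cna copy-number model (default 30% CNA).
#' @param J theta-grid resolution (default 100).
#' @param lambda_threshold cancer-call threshold (default 0.023).
#' @param G likelihood discretization cells (default 200).
#' @param predictor prediction hook (default [mixture_predictor()]).
#' @param seed optional integer seed; run `r` uses `seed + r`.
#' @param normal_class normal-plasma label (default `"normal"`).
#' @return pooled `eval_report`, with the per-run reports attached as
#'   attribute `"runs"`.
#' @export
run_experiment <- function(reference, n_runs = 10L,
                           n_per_class_per_bin = 20L, bins = 1:10,
                           train_frac = 0.75, mr_cutoff = 0.25,
                           coverage = 150, cna = cna_model(0.3),
                           J = 100L, lambda_threshold = 0.023, G = 200L,
                           predictor = mixture_predictor, seed = NULL,
                           normal_class = "normal") {
  reports <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- if (is.null(seed)) NULL else seed + r
    if (!is.null(run_seed)) set.seed(run_seed)
    part <- partition_samples(reference$manifest, train_frac)
    train_lv <- reference$levels[, part$train, drop = FALSE]
    panel <- build_panel(train_lv, reference$manifest, reference$clusters,
                         normal_class = normal_class,
                         mr_cutoff = mr_cutoff)
    test_manifest <- reference$manifest[
      reference$manifest$sample_id %in% part$test, ]
    sel <- panel$selected
    test_lv <- reference$levels[sel, part$test, drop = FALSE]
    tumor_classes <- panel$class_names[-1]
    pools <- lapply(tumor_classes, function(cl)
      test_lv[, test_manifest$sample_id[test_manifest$class_label == cl],
              drop = FALSE])
    names(pools) <- tumor_classes
    normal_pool <- test_lv[, test_manifest$sample_id[
      test_manifest$class_label == normal_class], drop = FALSE]
    profiles <- list()
    truth <- list()
    for (b in bins) {
      lo <- (b - 1) / 10
      hi <- b / 10
      scen <- sim_scenario(normal_pool, pools, reference$clusters,
                           coverage = coverage, theta_range = c(lo, hi),
                           cna = cna)
      coh <- simulate_cohort(scen, c(normal_class, tumor_classes),
                             n_per_class_per_bin,
                             normal_class = normal_class,
                             prefix = sprintf("run%d_bin%d", r, b))
      coh$truth$bin <- sprintf("(%g,%g]", lo, hi)
      profiles <- c(profiles, coh$profiles)
      truth[[length(truth) + 1L]] <- coh$truth
    }
    truth <- do.call(rbind, truth)
    pred <- predictor(profiles, panel, J = J,
                      lambda_threshold = lambda_threshold, G = G)
    reports[[r]] <- score_predictions(truth, pred,
                                      classes = panel$class_names,
                                      normal_class = normal_class)
  }
  out <- combine_reports(reports)
  attr(out, "runs") <- reports
  out
}
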