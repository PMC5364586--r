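test_that("stratified partitions split each class at the requested fraction", {
  man <- data.frame(sample_id = sprintf("s%03d", 1:120),
                    class_label = rep(c("normal", "liver", "lung"), 40))
  p <- partition_samples(man, 0.75, seed = 261)
  expect_length(p$train, 90L)
  expect_length(p$test, 30L)
  expect_length(intersect(p$train, p$test), 0L)
  for (cl in unique(man$class_label)) {
    ids <- man$sample_id[man$class_label == cl]
    expect_equal(sum(ids %in% p$train), 30L)
  }
  p2 <- partition_samples(man, 0.75, seed = 261)
  expect_identical(p, p2)
  expect_warning(partition_samples(man, 1.0), "empty test set")
})

test_that("burden metrics match their definitions", {
  th <- c(0.1, 0.4, 0.8)
  expect_equal(burden_metrics(th, th), list(pcc = 1, rmse = 0))
  m <- burden_metrics(th, th + 0.1)
  expect_equal(m$pcc, 1)
  expect_equal(m$rmse, 0.1)
  set.seed(271)
  a <- runif(50); b <- runif(50)
  m2 <- burden_metrics(a, b)
  expect_equal(m2$pcc, cor(a, b), tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(mean((a - b)^2)), tolerance = 1e-12)
  expect_error(burden_metrics(0.5, 0.5), "two pairs")
})

test_that("burden bins partition (0, 1] into left-open decades", {
  expect_true(is.na(burden_bin(0)))
  expect_equal(as.character(burden_bin(c(0.05, 0.1, 0.1000001, 1))),
               c("(0,0.1]", "(0,0.1]", "(0.1,0.2]", "(0.9,1]"))
  set.seed(281)
  th <- runif(500, 1e-9, 1)
  expect_false(anyNA(burden_bin(th)))
  expect_equal(nlevels(burden_bin(th)), 10L)
})

test_that("scoring builds a consistent confusion matrix", {
  truth <- data.frame(sample_id = sprintf("s%d", 1:6),
                      true_class = c("normal", "normal", "liver", "liver",
                                     "lung", "lung"),
                      true_theta = c(0, 0, 0.3, 0.5, 0.2, 0.9))
  pred <- data.frame(sample_id = truth$sample_id,
                     pred_class = c("normal", "lung", "liver", "normal",
                                    "lung", "lung"),
                     theta_hat = c(0, 0.1, 0.28, 0.01, 0.22, 0.8))
  rep <- score_predictions(truth, pred,
                           classes = c("normal", "liver", "lung"))
  expect_equal(sum(rep$confusion), 6)
  expect_equal(rep$error_rate, 2 / 6)
  expect_equal(rep$confusion["normal", "lung"], 1)
  expect_equal(unname(diag(rep$confusion)), c(1, 1, 2))
  # pooling reports equals summing confusions
  pooled <- combine_reports(list(rep, rep))
  expect_equal(pooled$confusion, rep$confusion + rep$confusion)
  expect_equal(pooled$error_rate, rep$error_rate)
})

test_that("a perfect predictor scores zero error and perfect burden recovery", {
  truth <- data.frame(sample_id = sprintf("s%d", 1:8),
                      true_class = rep(c("normal", "breast"), 4),
                      true_theta = c(0, 0.2, 0, 0.4, 0, 0.6, 0, 0.8))
  pred <- data.frame(sample_id = truth$sample_id,
                     pred_class = truth$true_class,
                     theta_hat = truth$true_theta)
  rep <- score_predictions(truth, pred)
  expect_equal(rep$error_rate, 0)
  expect_equal(rep$pcc, 1)
  expect_equal(rep$rmse, 0)
})

test_that("uniform guessing over six classes approaches the 5/6 error floor", {
  set.seed(291)
  classes <- c("normal", "breast", "colon", "kidney", "liver", "lung")
  n_per <- 300L
  truth <- data.frame(sample_id = sprintf("s%04d", seq_len(6 * n_per)),
                      true_class = rep(classes, each = n_per),
                      true_theta = c(rep(0, n_per), runif(5 * n_per)))
  pred <- data.frame(sample_id = truth$sample_id,
                     pred_class = sample(classes, 6 * n_per, replace = TRUE),
                     theta_hat = NA_real_)
  rep <- score_predictions(truth, pred, classes = classes)
  se <- sqrt(5 / 6 * 1 / 6 / (6 * n_per))
  expect_lt(abs(rep$error_rate - 5 / 6), 4 * se)
})

test_that("run_experiment aggregates runs into a pooled report", {
  ref <- generate_reference(T_classes = 2L, K_total = 150L,
                            frac_informative = 0.7, pool_size = 16L,
                            seed = 301)
  rep <- run_experiment(ref, n_runs = 2L, n_per_class_per_bin = 2L,
                        bins = c(3L, 8L), coverage = 25, J = 25L,
                        seed = 302)
  runs <- attr(rep, "runs")
  expect_length(runs, 2L)
  expect_equal(rep$confusion, runs[[1]]$confusion + runs[[2]]$confusion)
  expect_equal(rep$n, 2 * 2 * 2 * 3)  # runs x bins x per-class x classes
  expect_length(rep$per_bin, 2L)
  expect_true(rep$error_rate >= 0 && rep$error_rate <= 1)
  # n_runs = 1 equals its single run's report
  rep1 <- run_experiment(ref, n_runs = 1L, n_per_class_per_bin = 2L,
                         bins = 5L, coverage = 25, J = 25L, seed = 303)
  expect_equal(rep1$confusion, attr(rep1, "runs")[[1]]$confusion)
  expect_equal(rep1$error_rate, attr(rep1, "runs")[[1]]$error_rate)
})

test_that("predictor hooks plug into the experiment harness", {
  ref <- generate_reference(T_classes = 2L, K_total = 120L,
                            frac_informative = 0.7, pool_size = 12L,
                            seed = 311)
  rep <- run_experiment(ref, n_runs = 1L, n_per_class_per_bin = 4L,
                        bins = 6L, coverage = 25, J = 10L, seed = 312,
                        predictor = random_guess_predictor)
  expect_gt(rep$error_rate, 0.3)
  rep2 <- run_experiment(ref, n_runs = 1L, n_per_class_per_bin = 4L,
                         bins = 6L, coverage = 40, J = 10L, seed = 312,
                         predictor = nearest_mean_baseline)
  expect_true(is.finite(rep2$error_rate))
})
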