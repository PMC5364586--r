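# Reference fitting: per-class, per-cluster Beta(alpha, beta) models by the
# method of moments, and methylation-range (MR) feature selection.

EPS_LEVEL <- 1e-6
MIN_VAR <- 1e-6

#' Methylation range of a cluster
#'
#' The MR of a cluster is the spread of its per-class mean methylation
#' levels: the difference between the largest and smallest class means.
#' Features with large MR discriminate among classes.
#'
#' @param class_means numeric vector of per-class mean levels (`NA` allowed).
#' @return `max - min` of the non-`NA` means, or `NA` when fewer than two
#'   classes have a usable mean.
#' @examples
#' compute_mr(c(0.1, 0.9, 0.5))  # 0.8
#' @export
compute_mr <- function(class_means) {
  v <- class_means[!is.na(class_means)]
  if (length(v) < 2L) return(NA_real_)
  max(v) - min(v)
}

#' Fit a beta distribution by the method of moments
#'
#' Given methylation levels of one cluster in one class, matches the sample
#' mean and variance: with mean `mu` and variance `s2`,
#' `c = mu * (1 - mu) / s2 - 1`, `alpha = mu * c`, `beta = (1 - mu) * c`.
#' Degenerate inputs are regularized so the parameters stay finite and
#' positive: levels are clamped to `[1e-6, 1 - 1e-6]`, the variance is
#' floored at `1e-6`, and a variance at or above the Bernoulli bound
#' `mu * (1 - mu)` is shrunk to `0.999` of it.
#'
#' @param values numeric vector of levels in `[0, 1]`; `NA`s are dropped.
#' @param min_samples minimum number of usable values (default 5); fewer
#'   yield an `NA` fit.
#' @return named numeric vector `c(alpha = , beta = )`, or `NA`s.
#' @examples
#' # Beta(3, 12) has mean 0.2 and variance 0.01
#' fit_beta_moments(c(0.2 + 0.1 * c(-1, 1, 0, 0), 0.2))  # near (3, 12)
#' @export
fit_beta_moments <- function(values, min_samples = 5L) {
  x <- values[!is.na(values)]
  if (length(x) < min_samples)
    return(c(alpha = NA_real_, beta = NA_real_))
  x <- pmin(pmax(x, EPS_LEVEL), 1 - EPS_LEVEL)
  mu <- mean(x)
  s2 <- var(x)
  p <- moments_to_beta(mu, s2)
  c(alpha = p[[1]], beta = p[[2]])
}

# shared moment -> (alpha, beta) mapping with the clamping rules; vectorized
moments_to_beta <- function(mu, s2) {
  mu <- pmin(pmax(mu, EPS_LEVEL), 1 - EPS_LEVEL)
  s2 <- pmax(s2, MIN_VAR)
  bound <- mu * (1 - mu)
  s2 <- ifelse(s2 >= bound, 0.999 * bound, s2)
  cc <- bound / s2 - 1
  list(alpha = mu * cc, beta = (1 - mu) * cc)
}

#' Select informative features by methylation range
#'
#' @param mr named numeric vector of per-cluster MR values (`NA` allowed).
#' @param mr_cutoff minimum MR (inclusive, default 0.25).
#' @param usable optional logical vector (same order) marking clusters whose
#'   beta fits succeeded in every class; non-usable clusters are excluded.
#' @return character vector of selected cluster ids.
#' @export
select_features <- function(mr, mr_cutoff = 0.25, usable = NULL) {
  keep <- !is.na(mr) & mr >= mr_cutoff
  if (!is.null(usable)) keep <- keep & usable
  names(mr)[keep]
}

new_meth_panel <- function(clusters, class_names, alpha, beta, mr, selected,
                           mr_cutoff, min_samples) {
  structure(list(clusters = clusters, class_names = class_names,
                 alpha = alpha, beta = beta, mr = mr, selected = selected,
                 mr_cutoff = mr_cutoff, min_samples = min_samples),
            class = "meth_panel")
}

#' Fit a reference panel from labeled methylation pools
#'
#' For every cluster and class, fits `Beta(alpha, beta)` to the training
#' levels by the method of moments ([fit_beta_moments()]), computes the
#' methylation range over class means, and selects the features whose MR
#' reaches `mr_cutoff` and whose fits succeeded in all classes.  The first
#' entry of `class_names` (default the label `"normal"`) is the normal-plasma
#' component of the mixture model; all other classes are tumor types.
#'
#' @param levels matrix (clusters x samples) of methylation levels with
#'   cluster ids as `rownames` and sample ids as `colnames`.
#' @param manifest data.frame (`sample_id`, `class_label`) covering the
#'   columns of `levels`.
#' @param clusters cluster table ([build_clusters()]); rows matching
#'   `rownames(levels)`.
#' @param normal_class label of the normal-plasma class (default
#'   `"normal"`).
#' @param mr_cutoff MR selection threshold (default 0.25).
#' @param min_samples minimum usable samples per class per cluster
#'   (default 5).
#' @return object of class `meth_panel`.
#' @export
build_panel <- function(levels, manifest, clusters,
                        normal_class = "normal", mr_cutoff = 0.25,
                        min_samples = 5L) {
  stopifnot(is.matrix(levels), !is.null(rownames(levels)))
  if (!normal_class %in% manifest$class_label)
    stop("no samples labeled '", normal_class, "' in the manifest",
         call. = FALSE)
  miss <- setdiff(colnames(levels), manifest$sample_id)
  if (length(miss))
    stop("samples absent from manifest: ", paste(head(miss), collapse = ", "),
         call. = FALSE)
  cls <- manifest$class_label[match(colnames(levels), manifest$sample_id)]
  class_names <- c(normal_class,
                   sort(setdiff(unique(cls), normal_class)))
  K <- nrow(levels)
  C <- length(class_names)
  alpha <- matrix(NA_real_, K, C, dimnames = list(rownames(levels),
                                                  class_names))
  beta <- alpha
  means <- alpha
  ok <- matrix(FALSE, K, C)
  for (i in seq_len(C)) {
    sub <- levels[, cls == class_names[i], drop = FALSE]
    cnt <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    s2 <- rowSums((sub - mu)^2, na.rm = TRUE) / pmax(cnt - 1L, 1L)
    p <- moments_to_beta(mu, s2)
    usable <- cnt >= min_samples
    alpha[usable, i] <- p$alpha[usable]
    beta[usable, i] <- p$beta[usable]
    means[cnt >= 1L, i] <- mu[cnt >= 1L]
    ok[, i] <- usable
  }
  mr <- setNames(apply(means, 1, compute_mr), rownames(levels))
  selected <- select_features(mr, mr_cutoff, usable = rowSums(ok) == C)
  cl <- clusters[match(rownames(levels), clusters$cluster_id), , drop = FALSE]
  new_meth_panel(cl, class_names, alpha, beta, mr, selected,
                 mr_cutoff, as.integer(min_samples))
}

#' @export
print.meth_panel <- function(x, ...) {
  cat("Reference methylation panel\n")
  cat("  classes:  ", paste(x$class_names, collapse = ", "), "\n")
  cat("  clusters: ", nrow(x$clusters), " total, ", length(x$selected),
      " selected (MR >= ", x$mr_cutoff, ")\n", sep = "")
  invisible(x)
}

# Parameter matrices restricted to the selected features, normal class first.
panel_params <- function(panel, feature_ids = panel$selected) {
  idx <- match(feature_ids, rownames(panel$alpha))
  if (anyNA(idx)) stop("unknown feature ids", call. = FALSE)
  list(a0 = panel$alpha[idx, 1], b0 = panel$beta[idx, 1],
       aT = panel$alpha[idx, -1, drop = FALSE],
       bT = panel$beta[idx, -1, drop = FALSE],
       tumor_classes = panel$class_names[-1])
}
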