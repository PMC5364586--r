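# Synthetic reference pools: class-structured beta-distributed cluster
# methylation emulating array-based tumor references plus a normal-plasma
# pool, with controllable between-class separation.  Used to exercise the
# whole pipeline (training, simulation, inference) without external data.

#' Generate a synthetic labeled reference
#'
#' Builds `K_total` synthetic CpG clusters and, for each cluster and class,
#' a true `Beta(alpha, beta)` methylation model, then draws a pool of
#' per-sample levels from it.  A fraction `frac_informative` of clusters is
#' informative: a single "deviant" class has its mean offset from the
#' shared baseline by exactly `separation` (direction chosen to stay inside
#' `[0.02, 0.98]`), so the true methylation range of these clusters equals
#' `separation`; all other clusters share one mean across classes.  Real
#' tumor methylomes are dominated by a shared tumor-versus-plasma axis
#' (global hypomethylation, promoter hypermethylation common to many
#' cancers), so the deviant class is the normal-plasma class with
#' probability `p_deviant_normal` and otherwise a uniformly chosen tumor
#' class.
#'
#' The per-cluster, per-class beta precision `alpha + beta` is drawn
#' uniformly from `precision_range`, spanning tight tissue-specific and
#' noisy clusters.
#'
#' @param T_classes number of tumor classes (default 5).
#' @param K_total number of clusters (default 2000).
#' @param frac_informative fraction of informative clusters (default 0.75).
#' @param separation target methylation range of informative clusters
#'   (default 0.5); must be at most 0.9.
#' @param precision_range range of `alpha + beta` (default `c(20, 200)`).
#' @param pool_size samples per class; a scalar or a vector of length
#'   `T_classes + 1` (normal first; default 80).
#' @param p_deviant_normal probability that the normal class is the deviant
#'   one for an informative cluster (default 0.5).
#' @param class_names optional class labels (normal first); defaults to
#'   `"normal"` plus organ-style tumor names.
#' @param seed optional integer seed (deterministic output per seed).
#' @return object of class `synth_reference`: list with `levels` (matrix,
#'   clusters x samples), `manifest`, `clusters`, and `truth` (per-class
#'   true means, `alpha`, `beta`, `informative`, `deviant_class`).
#' @export
generate_reference <- function(T_classes = 5L, K_total = 2000L,
                               frac_informative = 0.75, separation = 0.5,
                               precision_range = c(20, 200),
                               pool_size = 80L, p_deviant_normal = 0.5,
                               class_names = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(T_classes >= 1L, K_total >= 1L,
            frac_informative > 0, frac_informative <= 1,
            p_deviant_normal >= 0, p_deviant_normal <= 1)
  if (separation <= 0 || separation > 0.9)
    stop("separation must lie in (0, 0.9]: the offset must fit between ",
         "a baseline in [0.05, 0.95] and the clipped level range ",
         "[0.02, 0.98]", call. = FALSE)
  if (is.null(class_names)) {
    tumor_names <- c("breast", "colon", "kidney", "liver", "lung",
                     sprintf("tumor%02d", seq_len(max(0, T_classes - 5L))))
    class_names <- c("normal", tumor_names[seq_len(T_classes)])
  }
  stopifnot(length(class_names) == T_classes + 1L)
  C <- T_classes + 1L
  pool_size <- as.integer(pool_size)
  if (length(pool_size) == 1L) pool_size <- rep(pool_size, C)
  stopifnot(length(pool_size) == C)
  if (any(pool_size < 1L)) stop("empty class pool requested", call. = FALSE)

  # synthetic cluster coordinates: consecutive intervals on one chromosome,
  # probed-site counts mimicking array density (>= 3 per cluster)
  site_count <- 3L + rpois(K_total, 2.3)
  width <- 200L + 40L * site_count
  start <- cumsum(c(0L, head(width, -1L) + 1000L))
  clusters <- data.frame(
    cluster_id = sprintf("chr1:%d-%d", start, start + width),
    chrom = "chr1", start = start, end = start + width,
    site_count = site_count, stringsAsFactors = FALSE)

  K_inf <- round(frac_informative * K_total)
  informative <- c(rep(TRUE, K_inf), rep(FALSE, K_total - K_inf))
  base_mean <- runif(K_total, 0.05, 0.95)
  deviant <- rep(NA_character_, K_total)
  if (K_inf > 0) {
    dev_idx <- ifelse(runif(K_inf) < p_deviant_normal, 1L,
                      1L + sample.int(T_classes, K_inf, replace = TRUE))
    # pick the offset direction first, then a baseline from its feasible
    # interval, so the deviant mean never needs clipping and the true MR
    # equals `separation` exactly
    dir <- sample(c(-1, 1), K_inf, replace = TRUE)
    lo <- ifelse(dir > 0, 0.05, max(0.05, 0.02 + separation))
    hi <- ifelse(dir > 0, min(0.95, 0.98 - separation), 0.95)
    base_mean[seq_len(K_inf)] <- lo + runif(K_inf) * (hi - lo)
    deviant[seq_len(K_inf)] <- class_names[dev_idx]
  }
  means <- matrix(base_mean, K_total, C,
                  dimnames = list(clusters$cluster_id, class_names))
  if (K_inf > 0) {
    for (i in seq_len(K_inf))
      means[i, dev_idx[i]] <- base_mean[i] + dir[i] * separation
  }
  means <- pmin(pmax(means, 0.02), 0.98)

  prec <- matrix(runif(K_total * C, precision_range[1], precision_range[2]),
                 K_total, C)
  alpha <- means * prec
  beta <- (1 - means) * prec
  dimnames(alpha) <- dimnames(beta) <- dimnames(means)

  sample_ids <- unlist(lapply(seq_len(C), function(i)
    sprintf("%s_%03d", class_names[i], seq_len(pool_size[i]))))
  manifest <- data.frame(sample_id = sample_ids,
                         class_label = rep(class_names, pool_size),
                         stringsAsFactors = FALSE)
  levels <- matrix(NA_real_, K_total, sum(pool_size),
                   dimnames = list(clusters$cluster_id, sample_ids))
  off <- 0L
  for (i in seq_len(C)) {
    n <- pool_size[i]
    levels[, off + seq_len(n)] <-
      matrix(rbeta(K_total * n, alpha[, i], beta[, i]), K_total, n)
    off <- off + n
  }

  structure(list(levels = levels, manifest = manifest, clusters = clusters,
                 class_names = class_names,
                 truth = list(means = means, alpha = alpha, beta = beta,
                              informative = informative,
                              deviant_class = deviant)),
            class = "synth_reference")
}

#' @export
print.synth_reference <- function(x, ...) {
  cat("Synthetic methylation reference\n")
  cat("  classes: ", paste(x$class_names, collapse = ", "), "\n")
  cat("  clusters:", nrow(x$levels), " (",
      sum(x$truth$informative), " informative)\n")
  cat("  samples: ", ncol(x$levels), "\n")
  invisible(x)
}

#' Export synthetic reference pools to disk
#'
#' Writes the level matrix, the sample manifest, and the cluster table in
#' the formats read by [read_level_matrix()], [read_manifest()] and
#' [read_clusters()]; round-trips are exact.
#'
#' @param reference a `synth_reference`.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
export_pools <- function(reference, dir) {
  stopifnot(inherits(reference, "synth_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(levels = file.path(dir, "pool_levels.tsv"),
             manifest = file.path(dir, "pool_manifest.tsv"),
             clusters = file.path(dir, "clusters.tsv"))
  write_level_matrix(reference$levels, paths[["levels"]])
  write_manifest(reference$manifest, paths[["manifest"]])
  write_clusters(reference$clusters, paths[["clusters"]])
  invisible(paths)
}
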