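# Copy-number-aware simulation of plasma cfDNA methylation sequencing data.
#
# One simulated cancer plasma sample: draw a burden theta, a per-cluster
# copy number c_k, one normal-plasma and one tumor methylation profile from
# the reference pools; mix them with the copy-number-adjusted burden
# theta'_k; distribute a total cytosine budget Z over clusters by the
# (copy-number-rescaled) alignment bias B_k via Poisson coverage; and draw
# the methylated counts binomially.

#' Copy-number model for simulated tumors
#'
#' A categorical distribution over integer copy numbers 0..5.  The
#' probabilities must sum to one and average to the diploid copy number 2;
#' the default vector `(0.005, 0.16, 0.7, 0.105, 0.025, 0.005)` gives a 30%
#' chance of a copy-number aberration (copy number != 2) per cluster.
#' Alternative aberration rates keep the two moment constraints by rescaling
#' the non-diploid part of the default vector (its conditional mean is
#' exactly 2).
#'
#' @param cna_rate probability of a CNA event per cluster (used when
#'   `probs` is `NULL`); the presets 0.1, 0.3 and 0.5 are typical choices.
#' @param probs optional explicit length-6 probability vector `p_0..p_5`.
#' @return object of class `cna_model` with element `probs`.
#' @examples
#' cna_model()            # 30% CNA
#' cna_model(0.1)$probs
#' @export
cna_model <- function(cna_rate = 0.3, probs = NULL) {
  if (is.null(probs)) {
    stopifnot(cna_rate >= 0, cna_rate < 1)
    base <- c(0.005, 0.16, 0, 0.105, 0.025, 0.005) / 0.3
    probs <- cna_rate * base
    probs[3] <- 1 - cna_rate
  }
  stopifnot(length(probs) == 6, all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-9)
    stop("copy-number probabilities must sum to 1", call. = FALSE)
  if (abs(sum(0:5 * probs) - 2) > 1e-9)
    stop("mean copy number must equal 2", call. = FALSE)
  structure(list(probs = probs), class = "cna_model")
}

#' Draw per-cluster copy numbers
#'
#' @param cna a [cna_model()].
#' @param K number of clusters.
#' @return integer vector of copy numbers in `0..5`.
#' @export
sample_copy_numbers <- function(cna, K) {
  stopifnot(inherits(cna, "cna_model"))
  sample(0:5, K, replace = TRUE, prob = cna$probs)
}

#' Copy-number-adjusted tumor fraction
#'
#' At a locus with tumor copy number `c`, the locally observed ctDNA
#' fraction becomes `theta' = theta * c / (theta * c + 2 * (1 - theta))`:
#' amplified loci contribute proportionally more tumor-derived fragments,
#' deleted loci (`c = 0`) none.
#'
#' @param theta global tumor burden in `[0, 1]`.
#' @param c integer copy number(s).
#' @return adjusted fraction(s) in `[0, 1]`; equals `theta` at `c = 2`.
#' @export
adjust_theta <- function(theta, c) {
  denom <- theta * c + 2 * (1 - theta)
  out <- ifelse(denom > 0, theta * c / denom, 0)
  out
}

#' Copy-number-adjusted alignment bias
#'
#' Rescales the background per-cluster read bias `b_k` by the relative DNA
#' dosage `1 - theta + theta * c_k / 2` and renormalizes to sum one, giving
#' the effective probability `B_k` that a sequenced cytosine falls in
#' cluster `k`.
#'
#' @param bias numeric vector `b_1..b_K` summing to 1.
#' @param theta tumor burden.
#' @param c integer copy numbers per cluster.
#' @return numeric vector `B_1..B_K` summing to 1.
#' @export
adjust_bias <- function(bias, theta, c) {
  w <- bias * (1 - theta + theta * c / 2)
  s <- sum(w)
  if (s <= 0) stop("degenerate bias adjustment (all mass lost)",
                   call. = FALSE)
  w / s
}

#' Simulation scenario
#'
#' Bundles everything one simulated cohort needs: reference pools of
#' per-cluster methylation levels, the cluster table (for the default
#' CpG-density bias), the total cytosine budget, the burden range, and the
#' copy-number model.
#'
#' The default alignment bias is proportional to each cluster's probed-site
#' count (denser clusters attract more reads); `bias_concentration` draws a
#' Dirichlet perturbation around it (larger = closer to the unperturbed
#' bias; `Inf`, the default, disables the perturbation — note the draw uses
#' the session RNG).
#'
#' @param normal_pool matrix (clusters x samples) of normal-plasma levels.
#' @param tumor_pools named list of such matrices, one per tumor class.
#' @param clusters cluster table covering the pool rows.
#' @param coverage mean total cytosines per cluster; the budget is
#'   `Z = coverage * K` (default 150, emulating low-pass whole-genome
#'   bisulfite sequencing of CpG-dense clusters).
#' @param Z explicit total cytosine budget (overrides `coverage`).
#' @param theta_range burden range `(theta_L, theta_U)` (default `c(0, 1)`).
#' @param cna a [cna_model()] (default 30% CNA).
#' @param bias optional explicit bias vector summing to 1.
#' @param bias_concentration Dirichlet concentration for the bias
#'   perturbation (default `Inf` = none).
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(normal_pool, tumor_pools, clusters,
                         coverage = 150, Z = NULL, theta_range = c(0, 1),
                         cna = cna_model(0.3), bias = NULL,
                         bias_concentration = Inf) {
  stopifnot(is.matrix(normal_pool), is.list(tumor_pools),
            length(names(tumor_pools)) == length(tumor_pools))
  ids <- rownames(normal_pool)
  for (p in tumor_pools) {
    stopifnot(identical(rownames(p), ids))
    if (ncol(p) == 0L) stop("empty tumor pool", call. = FALSE)
  }
  if (ncol(normal_pool) == 0L) stop("empty normal pool", call. = FALSE)
  K <- length(ids)
  if (is.null(bias)) {
    sc <- clusters$site_count[match(ids, clusters$cluster_id)]
    if (anyNA(sc)) stop("clusters table does not cover the pool rows",
                        call. = FALSE)
    w <- as.numeric(sc)
    if (is.finite(bias_concentration)) {
      g <- stats::rgamma(K, shape = bias_concentration * w / sum(w))
      w <- if (sum(g) > 0) g else w
    }
    bias <- w / sum(w)
  }
  stopifnot(length(bias) == K, abs(sum(bias) - 1) < 1e-8)
  if (is.null(Z)) Z <- round(coverage * K)
  stopifnot(Z > 0, theta_range[1] <= theta_range[2],
            theta_range[1] >= 0, theta_range[2] <= 1)
  structure(list(cluster_ids = ids, normal_pool = normal_pool,
                 tumor_pools = tumor_pools, bias = bias / sum(bias),
                 Z = as.numeric(Z), theta_range = theta_range, cna = cna),
            class = "sim_scenario")
}

# counts for one sample given mixed levels x (NA allowed) and bias B
draw_counts <- function(scenario, x, B) {
  keep <- !is.na(x)
  B <- B[keep] / sum(B[keep])
  n <- rpois(sum(keep), scenario$Z * B)
  m <- rbinom(sum(keep), n, x[keep])
  data.frame(cluster_id = scenario$cluster_ids[keep],
             meth_count = m, total_count = n, stringsAsFactors = FALSE)
}

#' Simulate one cancer plasma profile
#'
#' Implements the full generative procedure: `theta ~ U(theta_L, theta_U)`;
#' per-cluster copy numbers from the scenario's [cna_model()]; one normal
#' and one tumor profile drawn uniformly from the pools; mixture level
#' `x_k = (1 - theta'_k) v_k + theta'_k u_k` with [adjust_theta()];
#' coverage `n_k ~ Poisson(Z * B_k)` with [adjust_bias()]; and counts
#' `m_k ~ Binomial(n_k, x_k)`.  Clusters where either drawn profile is `NA`
#' are dropped from the output (and recorded in the truth record).
#' Randomness comes from the session RNG; seed upstream for
#' reproducibility.
#'
#' @param scenario a [sim_scenario()].
#' @param tumor_class name of the tumor pool to draw from.
#' @return list with `profile` (count data.frame), and `truth` (list:
#'   `theta`, `tumor_class`, `copy_number`, `dropped` cluster ids, source
#'   sample columns).
#' @export
simulate_cancer_plasma <- function(scenario, tumor_class) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!tumor_class %in% names(scenario$tumor_pools))
    stop("no tumor pool for class '", tumor_class, "'", call. = FALSE)
  theta <- runif(1, scenario$theta_range[1], scenario$theta_range[2])
  K <- length(scenario$cluster_ids)
  ck <- sample_copy_numbers(scenario$cna, K)
  vi <- sample.int(ncol(scenario$normal_pool), 1)
  pool <- scenario$tumor_pools[[tumor_class]]
  ui <- sample.int(ncol(pool), 1)
  v <- scenario$normal_pool[, vi]
  u <- pool[, ui]
  thp <- adjust_theta(theta, ck)
  x <- (1 - thp) * v + thp * u
  B <- adjust_bias(scenario$bias, theta, ck)
  prof <- draw_counts(scenario, x, B)
  list(profile = prof,
       truth = list(theta = theta, tumor_class = tumor_class,
                    copy_number = ck,
                    dropped = scenario$cluster_ids[is.na(x)],
                    normal_source = colnames(scenario$normal_pool)[vi],
                    tumor_source = colnames(pool)[ui]))
}

#' Simulate one normal plasma profile
#'
#' Mixes two distinct normal-pool samples at a ratio `r ~ U(0, 1)` (no CNA:
#' all copy numbers fixed at 2, so the bias is unadjusted), then draws
#' Poisson coverage and binomial methylated counts as in
#' [simulate_cancer_plasma()].
#'
#' @param scenario a [sim_scenario()].
#' @return list with `profile` and `truth` (`theta = 0`, mixing ratio,
#'   source columns).
#' @export
simulate_normal_plasma <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  np <- ncol(scenario$normal_pool)
  if (np < 2L)
    stop("normal pool needs at least two samples for mixing", call. = FALSE)
  idx <- sample.int(np, 2)
  r <- runif(1)
  v1 <- scenario$normal_pool[, idx[1]]
  v2 <- scenario$normal_pool[, idx[2]]
  x <- (1 - r) * v1 + r * v2
  prof <- draw_counts(scenario, x, scenario$bias)
  list(profile = prof,
       truth = list(theta = 0, tumor_class = NA_character_, ratio = r,
                    dropped = scenario$cluster_ids[is.na(x)],
                    sources = colnames(scenario$normal_pool)[idx]))
}

#' Simulate a labeled cohort
#'
#' Convenience wrapper drawing `n_per_class` samples for each requested
#' class (the scenario's tumor classes and/or `"normal"`), with an optional
#' seed for full reproducibility.
#'
#' @param scenario a [sim_scenario()].
#' @param classes character vector of class names; `normal_class` entries
#'   use [simulate_normal_plasma()].
#' @param n_per_class samples per class.
#' @param normal_class label treated as normal plasma (default `"normal"`).
#' @param seed optional integer seed.
#' @param prefix sample-id prefix.
#' @return list with `profiles` (named list of count data.frames) and
#'   `truth` (data.frame: `sample_id`, `true_class`, `true_theta`).
#' @export
simulate_cohort <- function(scenario, classes, n_per_class,
                            normal_class = "normal", seed = NULL,
                            prefix = "sim") {
  if (!is.null(seed)) set.seed(seed)
  profiles <- list()
  truth <- list()
  i <- 0L
  for (cl in classes) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      sid <- sprintf("%s_%s_%03d", prefix, cl, r)
      sim <- if (identical(cl, normal_class)) {
        simulate_normal_plasma(scenario)
      } else {
        simulate_cancer_plasma(scenario, cl)
      }
      profiles[[sid]] <- sim$profile
      truth[[i]] <- data.frame(sample_id = sid,
                               true_class = cl,
                               true_theta = sim$truth$theta,
                               stringsAsFactors = FALSE)
    }
  }
  list(profiles = profiles, truth = do.call(rbind, truth))
}
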