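# Mixture-likelihood inference of ctDNA burden and tissue of origin.
#
# The model: the plasma methylation level of cluster k is
# x_k = (1 - theta) v_k + theta u_k with v_k ~ Beta(a_k0, b_k0) (normal
# plasma) and u_k ~ Beta(a_kt, b_kt) (tumor class t).  The density of x_k
# is the convolution psi(x | theta, t); the observed methylated count is
# m_k ~ Binomial(n_k, x_k), so the per-cluster likelihood marginalizes the
# binomial over psi.  The total log-likelihood sums over features, and
# (theta, t) is estimated by exhaustive search over a theta grid.

#' Theta search grid
#'
#' The candidate burden values `{0, 1/J, ..., (J-1)/J}`.  Higher resolution
#' `J` gives more precise burden estimates at linear cost.
#'
#' @param J grid resolution, an integer `>= 2` (default 100: 1% burden
#'   steps).
#' @return numeric vector of length `J`, starting at 0, strictly increasing.
#' @export
theta_grid <- function(J = 100L) {
  J <- as.integer(J)
  if (is.na(J) || J < 2L) stop("J must be an integer >= 2", call. = FALSE)
  seq.int(0L, J - 1L) / J
}

#' Mixture methylation level
#'
#' The plasma level implied by normal component `v`, tumor component `u`,
#' and tumor fraction `theta`: `(1 - theta) * v + theta * u`.
#'
#' @param v,u methylation levels in `[0, 1]`.
#' @param theta tumor burden in `[0, 1]`.
#' @export
mixture_level <- function(v, u, theta) (1 - theta) * v + theta * u

#' Density of the plasma methylation level
#'
#' Evaluates the convolution density of `x = (1 - theta) v + theta u`, with
#' `v ~ Beta(normal[1], normal[2])` and `u ~ Beta(tumor[1], tumor[2])`, at
#' the points `x`.  For `theta = 0` this is the normal beta density; for
#' `theta = 1` the tumor beta density.  For intermediate `theta` the inner
#' integral runs over the `u` sub-interval where `(x - theta u)/(1 - theta)`
#' stays inside `[0, 1]`.
#'
#' @param x numeric vector of evaluation points in `[0, 1]`.
#' @param theta tumor burden in `[0, 1]`.
#' @param normal,tumor length-2 vectors `(alpha, beta)`, both positive.
#' @param method `"adaptive"` (default) integrates each point with
#'   [stats::integrate()], which tolerates endpoint-singular betas;
#'   `"simpson"` uses composite Simpson quadrature on `nodes` points of the
#'   clipped sub-interval.
#' @param nodes odd number of Simpson nodes (default 201).
#' @param eps endpoint clipping for the Simpson rule (default 1e-6).
#' @return numeric vector of density values (non-negative; integrates to 1
#'   over `[0, 1]`).
#' @export
psi_density <- function(x, theta, normal, tumor,
                        method = c("adaptive", "simpson"),
                        nodes = 201L, eps = 1e-6) {
  method <- match.arg(method)
  stopifnot(theta >= 0, theta <= 1, length(normal) == 2, length(tumor) == 2)
  if (theta == 0) return(dbeta(x, normal[1], normal[2]))
  if (theta == 1) return(dbeta(x, tumor[1], tumor[2]))
  vapply(x, function(xi) {
    lo <- max(0, (xi - (1 - theta)) / theta)
    hi <- min(1, xi / theta)
    if (lo >= hi) return(0)
    f <- function(u) {
      dbeta((xi - theta * u) / (1 - theta), normal[1], normal[2]) /
        (1 - theta) * dbeta(u, tumor[1], tumor[2])
    }
    if (method == "adaptive") {
      val <- tryCatch(
        integrate(f, lo, hi, rel.tol = 1e-8, abs.tol = 1e-12,
                  stop.on.error = FALSE)$value,
        error = function(e) NA_real_)
      if (is.na(val)) val <- simpson_quad(f, lo, hi, nodes, eps)
      val
    } else {
      simpson_quad(f, lo, hi, nodes, eps)
    }
  }, numeric(1))
}

# composite Simpson on an eps-clipped interval; nodes forced odd
simpson_quad <- function(f, lo, hi, nodes = 201L, eps = 1e-6) {
  lo <- lo + eps * (hi - lo)
  hi <- hi - eps * (hi - lo)
  nodes <- as.integer(nodes)
  if (nodes %% 2L == 0L) nodes <- nodes + 1L
  u <- seq(lo, hi, length.out = nodes)
  w <- rep(c(2, 4), length.out = nodes)
  w[1] <- w[nodes] <- 1
  hstep <- (hi - lo) / (nodes - 1L)
  sum(w * f(u)) * hstep / 3
}

#' Per-cluster marginal log-likelihood
#'
#' `log f(m | theta, t, n)`, the log of the binomial mass averaged over the
#' mixture density: `f = int Binom(m | n, x) psi(x | theta, t) dx`.  A
#' cluster with `n = 0` carries no information and contributes 0.
#'
#' This is the reference (adaptive-quadrature) implementation used for
#' verification and single evaluations; [predict_burden()] and [grid_mle()]
#' use an equivalent batched discretization in compiled code.
#'
#' @inheritParams psi_density
#' @param m methylated cytosine count, `0 <= m <= n`.
#' @param n total cytosine count.
#' @return finite log-likelihood value.
#' @export
cluster_loglik <- function(m, n, theta, normal, tumor,
                           method = c("adaptive", "simpson"),
                           nodes = 201L, eps = 1e-6) {
  method <- match.arg(method)
  stopifnot(m >= 0, n >= 0, m <= n)
  if (n == 0) return(0)
  f <- function(x) {
    dbinom(m, n, x) * psi_density(x, theta, normal, tumor,
                                  method = method, nodes = nodes, eps = eps)
  }
  val <- if (method == "adaptive") {
    integrate(f, 0, 1, rel.tol = 1e-7, abs.tol = 1e-300,
              stop.on.error = FALSE)$value
  } else {
    simpson_quad(f, 0, 1, nodes, eps)
  }
  log(max(val, 1e-300))
}

#' Total log-likelihood of a profile under one (theta, t)
#'
#' Sums [cluster_loglik()] over the panel's selected features, assuming the
#' features are independent.  Clusters absent from the profile or with zero
#' total count are skipped (they are also excluded from `K_used` in
#' [grid_mle()]).
#'
#' @param profile data.frame (`cluster_id`, `meth_count`, `total_count`).
#' @param panel a `meth_panel`.
#' @param theta tumor burden in `[0, 1)`.
#' @param t tumor class label (one of `panel$class_names[-1]`); ignored at
#'   `theta = 0`.
#' @param ... passed to [cluster_loglik()].
#' @export
total_loglik <- function(profile, panel, theta, t = NULL, ...) {
  pp <- panel_params(panel)
  if (theta > 0) {
    if (is.null(t) || !t %in% pp$tumor_classes)
      stop("t must name a tumor class of the panel", call. = FALSE)
    tc <- match(t, pp$tumor_classes)
  }
  idx <- match(panel$selected, profile$cluster_id)
  ll <- 0
  for (i in seq_along(panel$selected)) {
    j <- idx[i]
    if (is.na(j)) next
    n <- profile$total_count[j]
    if (n < 1L) next
    m <- profile$meth_count[j]
    tum <- if (theta > 0) c(pp$aT[i, tc], pp$bT[i, tc]) else c(1, 1)
    ll <- ll + cluster_loglik(m, n, theta,
                              normal = c(pp$a0[i], pp$b0[i]), tumor = tum,
                              ...)
  }
  ll
}

# Internal batched engine.  profiles: named list of count data.frames.
# Returns per-sample log-likelihood arrays dim (J, T) (theta = 0 row is
# shared across t), plus K_used.
batch_loglik <- function(profiles, panel, J = 100L, G = 200L) {
  pp <- panel_params(panel)
  K <- length(pp$a0)
  if (K == 0L) stop("panel has no selected features", call. = FALSE)
  S <- length(profiles)
  M <- matrix(0L, S, K)
  N <- matrix(0L, S, K)
  for (s in seq_len(S)) {
    p <- profiles[[s]]
    j <- match(panel$selected, p$cluster_id)
    ok <- !is.na(j)
    N[s, ok] <- as.integer(p$total_count[j[ok]])
    M[s, ok] <- as.integer(p$meth_count[j[ok]])
  }
  res <- .loglik_grid_cpp(M, N, pp$a0, pp$b0, pp$aT, pp$bT,
                          as.integer(J), as.integer(G))
  Tn <- length(pp$tumor_classes)
  list(loglik = res$loglik, K_used = res$K_used, Tn = Tn, J = as.integer(J),
       tumor_classes = pp$tumor_classes)
}

# Reshape one sample's rows of the batched output into a (J x T) matrix
ll_array <- function(bl, s) {
  J <- bl$J; Tn <- bl$Tn
  out <- matrix(NA_real_, J, Tn,
                dimnames = list(NULL, bl$tumor_classes))
  out[1, ] <- bl$loglik[1, s]
  if (J > 1L)
    out[-1, ] <- matrix(bl$loglik[-1, s], J - 1L, Tn)
  out
}

# argmax with deterministic tie-breaking: smallest theta, then first class
pick_argmax <- function(ll) {
  mx <- max(ll)
  cand <- which(ll == mx, arr.ind = TRUE)
  ord <- order(cand[, 1], cand[, 2])
  list(j = cand[ord[1], 1], t = cand[ord[1], 2], max = mx,
       n_ties = nrow(cand))
}

#' Predict ctDNA burden and tumor class for a batch of samples
#'
#' Evaluates the total log-likelihood on the full `(theta, t)` grid for every
#' profile, takes the maximum-likelihood `(theta_hat, t_hat)`, and computes
#' the prediction score
#' `lambda = (logL(theta_hat, t_hat) - logL(theta = 0)) / K_used`,
#' the per-feature log-likelihood gain of the best mixture over the pure
#' normal model.  A sample is called cancer when `lambda` exceeds
#' `lambda_threshold`.
#'
#' @param profiles a single count data.frame or a (preferably named) list of
#'   them (`cluster_id`, `meth_count`, `total_count`).
#' @param panel a `meth_panel`.
#' @param J theta-grid resolution (default 100).
#' @param lambda_threshold cancer-call threshold on the score (default
#'   0.023; advisory, originally tuned on plasma data).
#' @param G discretization cells for the likelihood integrals (default 200).
#' @param keep_grid if `TRUE`, attach each sample's full `(J x T)`
#'   log-likelihood grid as attribute `"grids"` (a list).
#' @return data.frame with one row per sample: `sample_id`, `theta_hat`,
#'   `t_hat` (`NA` when the sample is called non-cancer), `pred_class`
#'   (`t_hat` or the normal class), `lambda`, `is_cancer`, `K_used`,
#'   `n_ties`.
#' @export
predict_burden <- function(profiles, panel, J = 100L,
                           lambda_threshold = 0.023, G = 200L,
                           keep_grid = FALSE) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  if (is.null(names(profiles)))
    names(profiles) <- sprintf("sample_%d", seq_along(profiles))
  bl <- batch_loglik(profiles, panel, J = J, G = G)
  if (any(bl$K_used == 0L))
    stop("sample(s) with no usable feature: ",
         paste(names(profiles)[bl$K_used == 0L], collapse = ", "),
         call. = FALSE)
  thetas <- theta_grid(J)
  normal_class <- panel$class_names[1]
  S <- length(profiles)
  out <- data.frame(sample_id = names(profiles), theta_hat = NA_real_,
                    t_hat = NA_character_, pred_class = NA_character_,
                    lambda = NA_real_, is_cancer = NA, K_used = bl$K_used,
                    n_ties = NA_integer_, stringsAsFactors = FALSE)
  grids <- if (keep_grid) vector("list", S) else NULL
  for (s in seq_len(S)) {
    ll <- ll_array(bl, s)
    am <- pick_argmax(ll)
    lam <- (am$max - ll[1, 1]) / bl$K_used[s]
    cancer <- lam > lambda_threshold
    out$theta_hat[s] <- thetas[am$j]
    out$lambda[s] <- lam
    out$is_cancer[s] <- cancer
    out$n_ties[s] <- am$n_ties
    out$t_hat[s] <- if (am$j > 1L) bl$tumor_classes[am$t] else NA_character_
    out$pred_class[s] <- if (cancer && am$j > 1L) bl$tumor_classes[am$t]
                         else normal_class
    if (keep_grid) {
      g <- ll
      rownames(g) <- fmt_num(thetas)
      grids[[s]] <- g
    }
  }
  if (keep_grid) {
    names(grids) <- names(profiles)
    attr(out, "grids") <- grids
  }
  out
}

#' Grid-search maximum likelihood for one sample
#'
#' Single-sample interface around the batched engine of [predict_burden()],
#' returning the full inference result including the log-likelihood grid.
#'
#' @inheritParams predict_burden
#' @param profile count data.frame (`cluster_id`, `meth_count`,
#'   `total_count`).
#' @return object of class `ctdna_fit`: a list with `theta_hat`, `t_hat`,
#'   `lambda`, `is_cancer`, `K_used`, `n_ties`, the theta grid `thetas`, and
#'   `loglik_grid` (a `J x T` matrix; the `theta = 0` row is identical
#'   across classes).
#' @export
grid_mle <- function(profile, panel, J = 100L, lambda_threshold = 0.023,
                     G = 200L) {
  res <- predict_burden(list(sample = profile), panel, J = J,
                        lambda_threshold = lambda_threshold, G = G,
                        keep_grid = TRUE)
  grid <- attr(res, "grids")[[1]]
  structure(list(theta_hat = res$theta_hat, t_hat = res$t_hat,
                 lambda = res$lambda, is_cancer = res$is_cancer,
                 K_used = res$K_used, n_ties = res$n_ties,
                 thetas = theta_grid(J), loglik_grid = grid,
                 lambda_threshold = lambda_threshold),
            class = "ctdna_fit")
}

#' @export
print.ctdna_fit <- function(x, ...) {
  cat("ctDNA mixture fit\n")
  cat(sprintf("  theta_hat: %.3f\n", x$theta_hat))
  cat(sprintf("  t_hat:     %s\n", ifelse(is.na(x$t_hat), "-", x$t_hat)))
  cat(sprintf("  lambda:    %.4f (threshold %.3f)\n", x$lambda,
              x$lambda_threshold))
  cat(sprintf("  call:      %s  [K_used = %d]\n",
              if (x$is_cancer) "cancer" else "non-cancer", x$K_used))
  invisible(x)
}
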