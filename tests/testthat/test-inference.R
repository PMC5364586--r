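test_that("theta grid and mixture level behave as defined", {
  g <- theta_grid(100)
  expect_length(g, 100L)
  expect_equal(g[1], 0)
  expect_true(all(diff(g) > 0))
  expect_error(theta_grid(1), ">= 2")

  expect_equal(mixture_level(0.3, 0.9, 0), 0.3)
  expect_equal(mixture_level(0.3, 0.9, 1), 0.9)
  expect_equal(mixture_level(0.2, 0.8, 0.5), 0.5)
})

test_that("psi collapses to the component betas at theta = 0 and 1", {
  x <- seq(0.01, 0.99, by = 0.07)
  expect_equal(psi_density(x, 0, c(2, 5), c(9, 1)), dbeta(x, 2, 5))
  expect_equal(psi_density(x, 1, c(2, 5), c(9, 1)), dbeta(x, 9, 1))
})

test_that("psi of two uniform components is the triangular density", {
  # (1-theta) v + theta u with v, u ~ U(0,1), theta = 0.5: sum of two
  # U(0, 0.5), density 4 * min(x, 1 - x)
  x <- c(0.1, 0.25, 0.5, 0.6, 0.9)
  got <- psi_density(x, 0.5, c(1, 1), c(1, 1))
  expect_equal(got, 4 * pmin(x, 1 - x), tolerance = 1e-6)
})

test_that("psi integrates to one and has the mixture mean", {
  cases <- list(list(th = 0.3, nb = c(50, 50), tb = c(90, 10)),
                list(th = 0.6, nb = c(2, 8), tb = c(5, 1)),
                list(th = 0.15, nb = c(0.8, 3), tb = c(4, 0.7)))
  for (cs in cases) {
    total <- integrate(function(x) psi_density(x, cs$th, cs$nb, cs$tb),
                       0, 1, rel.tol = 1e-6)$value
    expect_equal(total, 1, tolerance = 1e-3)
    mn <- integrate(function(x) x * psi_density(x, cs$th, cs$nb, cs$tb),
                    0, 1, rel.tol = 1e-6)$value
    want <- (1 - cs$th) * cs$nb[1] / sum(cs$nb) +
      cs$th * cs$tb[1] / sum(cs$tb)
    expect_equal(mn, want, tolerance = 1e-3)
  }
})

test_that("cluster log-likelihood handles analytic special cases", {
  # n = 1, m = 1: f = E[x] = 0.5 for symmetric uniform components
  expect_equal(cluster_loglik(1, 1, 0.37, c(1, 1), c(1, 1)), log(0.5),
               tolerance = 1e-6)
  expect_equal(cluster_loglik(0, 0, 0.5, c(2, 3), c(4, 1)), 0)
  # theta = 0: beta-binomial closed form
  bb <- function(m, n, a, b) {
    lchoose(n, m) + lbeta(a + m, b + n - m) - lbeta(a, b)
  }
  expect_equal(cluster_loglik(3, 10, 0, c(2, 5), c(1, 1)), bb(3, 10, 2, 5),
               tolerance = 1e-6)
})

test_that("the binomial marginal sums to one over m", {
  set.seed(61)
  for (i in 1:8) {
    n <- sample(1:20, 1)
    theta <- runif(1, 0, 0.95)
    nb <- c(runif(1, 0.5, 60), runif(1, 0.5, 60))
    tb <- c(runif(1, 0.5, 60), runif(1, 0.5, 60))
    tot <- sum(exp(sapply(0:n, function(m)
      cluster_loglik(m, n, theta, nb, tb))))
    expect_equal(tot, 1, tolerance = 1e-3)
  }
})

test_that("quadrature agrees with the Monte-Carlo oracle across regimes", {
  set.seed(71)
  # random regimes, deliberately including endpoint-singular betas
  draw_shape <- function() exp(runif(1, log(0.4), log(60)))
  for (i in 1:25) {
    n <- sample(1:80, 1)
    m <- sample(0:n, 1)
    theta <- runif(1, 0.02, 0.95)
    nb <- c(draw_shape(), draw_shape())
    tb <- c(draw_shape(), draw_shape())
    mc <- mc_cluster_lik(m, n, theta, nb, tb, R = 1e5)
    tol <- 3 * mc$se + 0.015 * mc$mean
    got <- exp(cluster_loglik(m, n, theta, nb, tb))
    expect_lt(abs(got - mc$mean), max(tol, 1e-6))
  }
})

test_that("batched engine matches the reference quadrature", {
  panel <- small_panel()
  ref <- small_reference()
  scen <- make_scenario(ref, panel, coverage = 60,
                        theta_range = c(0.35, 0.35))
  set.seed(81)
  sim <- simulate_cancer_plasma(scen, panel$class_names[2])
  fit <- grid_mle(sim$profile, panel, J = 20)
  K <- fit$K_used
  for (th in c(0, 0.35, 0.7)) {
    tlab <- panel$class_names[2]
    ll_ref <- total_loglik(sim$profile, panel, th,
                           if (th > 0) tlab else NULL)
    j <- which(abs(fit$thetas - th) < 1e-9)
    expect_equal(fit$loglik_grid[j, tlab] / K, ll_ref / K,
                 tolerance = 0.01)
  }
})

test_that("total log-likelihood is additive and t-free at theta zero", {
  panel <- small_panel()
  sel <- panel$selected[1:4]
  prof <- data.frame(cluster_id = sel, meth_count = c(2L, 5L, 0L, 7L),
                     total_count = c(9L, 12L, 4L, 7L))
  t1 <- panel$class_names[2]
  t2 <- panel$class_names[3]
  expect_equal(total_loglik(prof, panel, 0, t1),
               total_loglik(prof, panel, 0, t2))
  # independence: the total is the sum of per-cluster contributions
  ll12 <- total_loglik(prof[1:2, ], panel, 0.3, t1)
  expect_equal(ll12, total_loglik(prof[1, ], panel, 0.3, t1) +
                 total_loglik(prof[2, ], panel, 0.3, t1))
  # a single usable cluster gives exactly that cluster's log-likelihood
  pp <- cfMethMix:::panel_params(panel)
  i <- match(sel[1], panel$selected)
  tc <- match(t1, pp$tumor_classes)
  expect_equal(total_loglik(prof[1, ], panel, 0.3, t1),
               cluster_loglik(prof$meth_count[1], prof$total_count[1], 0.3,
                              c(pp$a0[i], pp$b0[i]),
                              c(pp$aT[i, tc], pp$bT[i, tc])))
})

test_that("grid MLE recovers burden and class on well-separated data", {
  ref <- small_reference()
  panel <- small_panel()
  scen <- make_scenario(ref, panel, coverage = 50,
                        theta_range = c(0.4, 0.4))
  set.seed(91)
  cls <- panel$class_names[3]
  sim <- simulate_cancer_plasma(scen, cls)
  fit <- grid_mle(sim$profile, panel, J = 100)
  expect_lt(abs(fit$theta_hat - 0.4), 0.05)
  expect_identical(fit$t_hat, cls)
  expect_true(fit$is_cancer)

  # lambda = 0 exactly when the argmax sits at theta = 0
  nsim <- simulate_normal_plasma(scen)
  nfit <- grid_mle(nsim$profile, panel, J = 100)
  expect_gte(nfit$lambda, 0)
  if (nfit$theta_hat == 0) expect_identical(nfit$lambda, 0)
  expect_false(nfit$is_cancer)
})

test_that("lambda is non-negative across random profiles", {
  ref <- small_reference()
  panel <- small_panel()
  scen <- make_scenario(ref, panel, coverage = 8)
  set.seed(101)
  coh <- simulate_cohort(scen, c("normal", panel$class_names[-1]), 3)
  res <- predict_burden(coh$profiles, panel, J = 25)
  expect_true(all(res$lambda >= 0))
  expect_true(all(res$K_used > 0))
  expect_identical(res$is_cancer, res$lambda > 0.023)
})

test_that("burden precision improves with coverage", {
  ref <- small_reference()
  panel <- small_panel()
  set.seed(111)
  med_err <- sapply(c(5, 20, 80), function(cov) {
    scen <- make_scenario(ref, panel, coverage = cov)
    errs <- replicate(12, {
      cls <- sample(panel$class_names[-1], 1)
      sim <- simulate_cancer_plasma(scen, cls)
      fit <- predict_burden(sim$profile, panel, J = 50)
      abs(fit$theta_hat - sim$truth$theta)
    })
    median(errs)
  })
  expect_lt(med_err[3], med_err[1])
})

test_that("degenerate inputs fail loudly", {
  panel <- small_panel()
  empty <- data.frame(cluster_id = "nope", meth_count = 1L,
                      total_count = 5L)
  expect_error(predict_burden(empty, panel), "no usable feature")
})
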