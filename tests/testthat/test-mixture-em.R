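test_that("mixture density degenerates correctly at the weight boundaries", {
  ta <- sn_params(-2, 1, 0.5)
  tn <- sn_params(1, 1.2, -0.3)
  s <- seq(-4, 3, length.out = 21)
  expect_equal(mixture_pdf(s, 0, ta, tn), sn_pdf(s, tn), tolerance = 1e-12)
  expect_equal(mixture_pdf(s, 1, ta, tn), sn_pdf(s, ta), tolerance = 1e-12)
  expect_equal(mixture_pdf(s, 0.5, ta, ta), sn_pdf(s, ta), tolerance = 1e-12)
  expect_error(mixture_pdf(0, 1.2, ta, tn), "\\[0, 1\\]")
})

test_that("initialization finds the clusters, obeys the seed contract and the constraint", {
  set.seed(2)
  blobs <- sample_set(plp = rnorm(150, -3, 0.4), blb = rnorm(150, 3, 0.4),
                      ref = rnorm(100, 3, 0.4))
  init <- initialize_mixture(blobs, seed = 5)
  # k-means oracle: the two point clouds sit at -3 and +3
  km <- with(stats::kmeans(unlist(blobs, use.names = FALSE), 2, nstart = 10), centers)
  expect_lt(abs(init$theta_abnormal$location - (-3)), 0.5)
  expect_lt(abs(init$theta_normal$location - 3), 0.5)
  expect_lt(abs(min(km) - (-3)), 0.5)

  again <- initialize_mixture(blobs, seed = 5)
  other <- initialize_mixture(blobs, seed = 6)
  expect_identical(init, again)
  expect_false(init$theta_abnormal$skew == other$theta_abnormal$skew)

  # initial parameters always satisfy the monotone-ratio grid check
  for (s in 1:5) {
    ini <- initialize_mixture(small_samples(), seed = s)
    chk <- enforce_monotone_ratio(ini$theta_abnormal, ini$theta_normal,
                                  range(unlist(small_samples())))
    expect_false(chk$adjusted)
  }
  expect_error(
    initialize_mixture(sample_set(rep(1, 5), rep(1, 5), rep(1, 5))),
    "degenerate")
})

test_that("monotone density-ratio enforcement matches the grid-check oracle", {
  # two equal-variance Gaussians: log-ratio is linear decreasing -> untouched
  res <- enforce_monotone_ratio(sn_params(-2, 1, 0), sn_params(2, 1, 0),
                                c(-5, 5))
  expect_false(res$adjusted)
  expect_equal(res$theta_abnormal$location, -2)

  # same location, unequal variance: ratio is non-monotone -> adjusted
  grid_check <- function(ta, tn, rng) {
    g <- seq(rng[1], rng[2], length.out = 512)
    lr <- sn_logpdf(g, ta) - sn_logpdf(g, tn)
    all(diff(lr) <= 1e-9)
  }
  expect_false(grid_check(sn_params(0, 1, 0), sn_params(0, 2, 0), c(-5, 5)))
  res2 <- enforce_monotone_ratio(sn_params(0, 1, 0), sn_params(0, 2, 0),
                                 c(-5, 5))
  expect_true(res2$adjusted)
  expect_true(grid_check(res2$theta_abnormal, res2$theta_normal, c(-5, 5)))
  # locations moved in opposing directions
  expect_lt(res2$theta_abnormal$location, 0)
  expect_gt(res2$theta_normal$location, 0)

  # binary-search projection from a feasible anchor also passes the oracle
  res3 <- enforce_monotone_ratio(sn_params(0, 1, 0), sn_params(0, 2, 0),
                                 c(-5, 5),
                                 feasible_abnormal = sn_params(-2, 1, 0),
                                 feasible_normal = sn_params(2, 1, 0))
  expect_true(res3$adjusted)
  expect_true(grid_check(res3$theta_abnormal, res3$theta_normal, c(-5, 5)))
})

test_that("EM step reproduces the closed-form weight update and ascends the likelihood", {
  ss <- small_samples()
  state <- initialize_mixture(ss, seed = 7)

  # direct-summation oracle for the weight update on each sample: the new
  # weight is the mean abnormal responsibility under the OLD parameters
  resp <- function(x, w) {
    la <- log(w) + sn_logpdf(x, state$theta_abnormal)
    ln <- log1p(-w) + sn_logpdf(x, state$theta_normal)
    1 / (1 + exp(ln - la))
  }
  new <- em_step(state, ss)
  for (k in c("P", "B", "G")) {
    expect_equal(new$weights[[k]], mean(resp(ss[[k]], state$weights[[k]])),
                 tolerance = 1e-10)
  }

  # observed-data log-likelihood does not decrease over consecutive steps
  ll <- function(st) {
    sum(vapply(names(ss), function(k) {
      sum(mixture_pdf(ss[[k]], st$weights[[k]], st$theta_abnormal,
                      st$theta_normal, log = TRUE))
    }, numeric(1)))
  }
  st <- state
  prev <- ll(st)
  for (i in 1:5) {
    st <- em_step(st, ss)
    expect_gte(st$log_likelihood, prev - 1e-8)
    expect_equal(st$log_likelihood, ll(st), tolerance = 1e-8)
    prev <- st$log_likelihood
  }

  # a sample with weight exactly 0 is a fixed point of the weight update
  st0 <- state
  st0$weights[] <- c(0.5, 0, 0.5)
  new0 <- em_step(st0, ss)
  expect_equal(new0$weights[["B"]], 0)
})

test_that("each M-step coordinate update maximizes the EM objective (1-D oracle)", {
  ss <- small_samples()
  state <- initialize_mixture(ss, seed = 11)
  x <- unlist(ss, use.names = FALSE)
  w_obs <- rep(unname(state$weights[c("P", "B", "G")]), lengths(ss))
  la <- log(w_obs) + sn_logpdf(x, state$theta_abnormal)
  ln <- log1p(-w_obs) + sn_logpdf(x, state$theta_normal)
  p <- 1 / (1 + exp(ln - la))

  va <- canonical_to_alternate(state$theta_abnormal)
  mu <- va$location; d <- va$delta; g <- va$gamma
  # conditional truncated-normal moments at the old parameters
  prec <- g + d^2
  v <- g / prec
  m <- d * (x - mu) / prec
  h <- m / sqrt(v)
  e1 <- m + sqrt(v) * exp(dnorm(h, log = TRUE) - pnorm(h, log.p = TRUE))
  e2 <- m * e1 + v

  q_of <- function(mu_, d_, g_) {
    sum(p * (-0.5 * log(g_) -
               ((x - mu_)^2 - 2 * d_ * (x - mu_) * e1 + d_^2 * e2) / (2 * g_)))
  }
  mu_hat <- sum(p * (x - d * e1)) / sum(p)
  expect_equal(mu_hat, optimize(function(z) q_of(z, d, g), mu + c(-3, 3),
                                maximum = TRUE, tol = 1e-10)$maximum,
               tolerance = 1e-5)
  d_hat <- sum(p * (x - mu_hat) * e1) / sum(p * e2)
  expect_equal(d_hat, optimize(function(z) q_of(mu_hat, z, g), d + c(-3, 3),
                               maximum = TRUE, tol = 1e-10)$maximum,
               tolerance = 1e-5)
  g_hat <- sum(p * ((x - mu_hat)^2 - 2 * d_hat * (x - mu_hat) * e1 +
                      d_hat^2 * e2)) / sum(p)
  expect_equal(g_hat, optimize(function(z) q_of(mu_hat, d_hat, z),
                               c(g_hat / 10, g_hat * 10),
                               maximum = TRUE, tol = 1e-10)$maximum,
               tolerance = 1e-4)
})

test_that("full fit recovers a well-separated mixture and honors the argmax contract", {
  fit <- ws_fit(1)
  expect_s3_class(fit, "mixture_fit")
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_gt(fit$weights[["P"]], fit$weights[["B"]])
  expect_lt(abs(fit$weights[["P"]] - 0.9), 0.05)
  expect_lt(abs(fit$weights[["B"]] - 0.05), 0.05)
  expect_lt(abs(fit$weights[["G"]] - 0.135), 0.05)
  # returned fit is the best of all restarts
  expect_gte(fit$log_likelihood, max(fit$restart_logliks) - 1e-10)
  # component identity: abnormal is the lower-location component
  expect_lt(fit$theta_abnormal$location, fit$theta_normal$location)
  # density-ratio invariant on a dense grid over the observed range
  g <- seq(fit$score_range[1], fit$score_range[2], length.out = 512)
  lr <- sn_logpdf(g, fit$theta_abnormal) - sn_logpdf(g, fit$theta_normal)
  expect_true(all(diff(lr) <= 1e-9))
  expect_error(fit_mixture(sample_set(rep(1, 3), rep(1, 3), rep(1, 3))),
               "degenerate")
})

test_that("the synonymous sample enters the likelihood like any other sample", {
  ss <- ws_samples(2)
  fit <- ws_fit(2, n_restarts = 3L)
  expect_true("S" %in% names(fit$weights))
  manual <- sum(vapply(names(ss), function(k) {
    sum(mixture_pdf(ss[[k]], fit$weights[[k]], fit$theta_abnormal,
                    fit$theta_normal, log = TRUE))
  }, numeric(1)))
  expect_equal(fit$log_likelihood, manual, tolerance = 1e-8)
})
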