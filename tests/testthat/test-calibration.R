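test_that("posterior probability follows the odds identity", {
  expect_equal(posterior_probability(1, 0.3), 0.3, tolerance = 1e-12)
  expect_equal(posterior_probability(1e12, 0.1), 1, tolerance = 1e-6)
  # posterior odds = lr * prior odds, exactly
  lr <- 350^(6 / 8)
  post <- posterior_probability(lr, 0.1)
  expect_equal(post / (1 - post), lr * (0.1 / 0.9), tolerance = 1e-10)
  expect_equal(post, 0.900, tolerance = 0.002)
  # eight supporting lines equal one very-strong line (multiplicative points)
  cc <- 350
  expect_equal((cc^(1 / 8))^8, cc^1, tolerance = 1e-12)
  expect_error(posterior_probability(-1, 0.5), "positive")
})

test_that("c-solver reproduces the closed form of the binding constraint", {
  # single likely-pathogenic rule 1S+1M (6 points): c = (9 / prior odds)^(8/6)
  rule <- data.frame(rule = "1S+1M", target = "likely_pathogenic",
                     nsu = 0, nmo = 1, nst = 1, nvs = 0, points = 6)
  for (prior in c(0.1, 0.25, 0.044)) {
    odds <- prior / (1 - prior)
    expect_equal(solve_c(prior, rule), (9 / odds)^(8 / 6), tolerance = 2e-4)
  }
  # with the default rule set the same combinations are binding
  expect_equal(solve_c(0.1), (9 / (0.1 / 0.9))^(4 / 3), tolerance = 2e-4)
  # retaining the discordant two-strong rule forces c to 99 * prior odds^-1
  expect_equal(solve_c(0.1, default_acmg_rules(include_two_strong = TRUE)),
               99 * 9, tolerance = 2e-4 * 891)
  expect_error(solve_c(1.2), "\\(0, 1\\)")
})

test_that("prior estimation implements the mixture identity and flags invalid cases", {
  expect_equal(estimate_prior(c(P = 0.8, B = 0.1, G = 0.17))$prior, 0.1,
               tolerance = 1e-12)
  # generator inversion is the exact algebraic inverse
  w <- c(P = 0.77, B = 0.03)
  for (prior in c(0.02, 0.1, 0.6)) {
    wg <- prior * w[["P"]] + (1 - prior) * w[["B"]]
    expect_equal(estimate_prior(c(w, G = wg))$prior, prior, tolerance = 1e-12)
  }
  expect_false(estimate_prior(c(P = 0.8, B = 0.1, G = 0.1))$valid)  # prior 0
  expect_false(estimate_prior(c(P = 0.8, B = 0.1, G = 0.8))$valid)  # prior 1
  expect_false(estimate_prior(c(P = 0.1, B = 0.1, G = 0.2))$valid)  # wP = wB
  expect_false(estimate_prior(c(P = 0.05, B = 0.6, G = 0.3))$valid) # wP < wB
})

test_that("local lr+ is unity for uninformative fits and saturates at wP/wB", {
  base <- ws_fit(1)
  s <- seq(-6, 3, length.out = 25)

  same_w <- base
  same_w$weights[c("P", "B")] <- 0.4
  expect_equal(local_lr_plus(s, same_w), rep(1, length(s)), tolerance = 1e-12)

  same_theta <- base
  same_theta$theta_normal <- same_theta$theta_abnormal
  expect_equal(local_lr_plus(s, same_theta), rep(1, length(s)), tolerance = 1e-12)

  # dominant-component limit far below the abnormal location
  lo <- base$theta_abnormal$location - 10 * base$theta_abnormal$scale
  expect_equal(local_lr_plus(lo, base),
               base$weights[["P"]] / base$weights[["B"]], tolerance = 1e-3)
})

test_that("thresholds match the closed-form Gaussian log-ratio roots", {
  # wP = 1, wB = 0, zero skews: log lr+(s) is an explicit quadratic in s
  fit <- structure(list(
    theta_abnormal = sn_params(-3, 1, 0),
    theta_normal = sn_params(3, 1.5, 0),
    weights = c(P = 1, B = 0, G = 0.5),
    score_range = c(-6, 4)), class = "mixture_fit")
  scale <- evidence_scale(0.1, levels = c(1, 2, 3, 4, 8))
  calib <- thresholds_from_fit(fit, scale)
  quad_root <- function(target) {
    # log(omega_n/omega_a) - z_a^2/2 + z_n^2/2 = target
    f <- function(s) log(1.5) - (s + 3)^2 / 2 + (s - 3)^2 / (2 * 1.5^2) - target
    uniroot(f, c(-6, 4), tol = 1e-12)$root
  }
  for (lv in names(calib$pathogenic_thresholds)) {
    expect_equal(calib$pathogenic_thresholds[[lv]],
                 quad_root(as.numeric(lv) / 8 * log(scale$c)),
                 tolerance = 1e-6)
  }
  # ordering invariant: stronger pathogenic levels sit at lower scores
  pt <- calib$pathogenic_thresholds[order(as.integer(names(calib$pathogenic_thresholds)))]
  expect_true(all(diff(unname(pt)) <= 0))
  bt <- calib$benign_thresholds[order(as.integer(names(calib$benign_thresholds)))]
  expect_true(all(diff(unname(bt)) >= 0))
})

test_that("unreachable evidence levels are absent from the threshold maps", {
  # nearly identical mixtures: lr+ stays close to 1 everywhere
  fit <- structure(list(
    theta_abnormal = sn_params(-0.2, 1, 0),
    theta_normal = sn_params(0.2, 1, 0),
    weights = c(P = 0.6, B = 0.4, G = 0.5),
    score_range = c(-3, 3)), class = "mixture_fit")
  calib <- thresholds_from_fit(fit, evidence_scale(0.1))
  expect_length(calib$pathogenic_thresholds, 0)
  expect_length(calib$benign_thresholds, 0)
})

test_that("evidence assignment is strongest-level-first and monotone in score", {
  calib <- new_calib <- structure(list(
    prior = 0.1, c = 350, levels = c(1, 2, 3, 4, 8),
    pathogenic_thresholds = c(`1` = -1, `2` = -1.5, `4` = -2.5, `8` = -3.5),
    benign_thresholds = c(`1` = 0.5, `2` = 1.5),
    direction = "low_scores_abnormal"), class = "calibration_result")
  expect_identical(assign_evidence(-4, calib), 8L)
  expect_identical(assign_evidence(-2.5, calib), 4L)
  expect_identical(assign_evidence(-0.2, calib), 0L)  # between +1 and -1
  expect_identical(assign_evidence(0.7, calib), -1L)
  expect_identical(assign_evidence(2, calib), -2L)
  # never returns a level absent from the maps (here +3 is absent)
  sweep <- assign_evidence(seq(-5, 3, length.out = 1000), calib)
  expect_false(any(sweep == 3L))
  expect_true(all(diff(sweep) <= 0))  # points non-increasing as score rises
  expect_error(assign_evidence(NaN, calib), "finite")
})

test_that("degenerate bootstrap reproduces the point-estimate thresholds exactly", {
  ss <- small_samples()
  n_restarts <- 4L
  bs <- bootstrap_calibrate(ss, n_boot = 1L, n_restarts = n_restarts,
                            seed = 42L, resample = FALSE)
  fit <- fit_mixture(ss, n_restarts = n_restarts, seed = 42L)
  pr <- estimate_prior(fit)
  calib <- thresholds_from_fit(fit, evidence_scale(pr$prior))
  expect_identical(bs$valid_iterations, 1L)
  expect_equal(bs$final_thresholds$pathogenic, calib$pathogenic_thresholds)
  expect_equal(bs$final_thresholds$benign, calib$benign_thresholds)
})

test_that("bootstrap aggregation excludes invalid priors and applies the reach rule", {
  mk <- function(valid, path, ben, prior = 0.1) {
    list(valid = valid, prior = prior, c = 350,
         pathogenic_thresholds = path, benign_thresholds = ben,
         members = list(P = character(0)))
  }
  iters <- c(
    lapply(1:19, function(i) mk(TRUE, c(`1` = -1 - i / 100), c(`1` = 1 + i / 100))),
    list(mk(TRUE, c(`1` = -2, `4` = -3), c(`1` = 0.9))),    # only 1/20 reaches +4
    list(mk(FALSE, numeric(0), numeric(0), prior = NaN)),   # excluded
    list(mk(FALSE, numeric(0), numeric(0), prior = 1.4))    # excluded
  )
  agg <- aggregate_bootstrap(iters, levels = c(1, 2, 3, 4, 8))
  expect_identical(agg$n_iterations, 22L)
  expect_identical(agg$valid_iterations, 20L)
  expect_equal(unname(agg$reach_fraction$pathogenic["1"]), 1)
  expect_equal(unname(agg$reach_fraction$pathogenic["4"]), 0.05)
  # +4 reached by 5% of valid iterations only -> not reported
  expect_false("4" %in% names(agg$final_thresholds$pathogenic))
  expect_true("1" %in% names(agg$final_thresholds$pathogenic))
  # 5th percentile for pathogenic, 95th for benign
  p1 <- vapply(iters[1:20], function(r) r$pathogenic_thresholds[["1"]], numeric(1))
  b1 <- vapply(iters[1:20], function(r) r$benign_thresholds[["1"]], numeric(1))
  expect_equal(unname(agg$final_thresholds$pathogenic["1"]),
               unname(quantile(p1, 0.05)))
  expect_equal(unname(agg$final_thresholds$benign["1"]),
               unname(quantile(b1, 0.95)))
  expect_error(aggregate_bootstrap(list(mk(FALSE, numeric(0), numeric(0)))),
               "no valid-prior iterations")
})

test_that("out-of-bag assignment takes the mode over excluding iterations, ties toward 0", {
  mk <- function(path, ben, members) {
    list(valid = TRUE, prior = 0.1, c = 350,
         pathogenic_thresholds = path, benign_thresholds = ben,
         members = members)
  }
  # 5-iteration toy trace; variant v1 is in iterations 1 and 2 only
  iters <- list(
    mk(c(`4` = -1), c(`1` = 1), list(P = "v1")),
    mk(c(`4` = -1), c(`1` = 1), list(P = c("v1", "v2"))),
    mk(c(`4` = -2.5), c(`1` = 1), list(P = "v3")),
    mk(c(`4` = -1.8), c(`1` = 1), list(P = "v3")),
    mk(c(`4` = -1.9), c(`1` = 1), list(P = "v3"))
  )
  summ <- aggregate_bootstrap(iters, levels = c(1, 4))
  scores <- c(v1 = -2, v2 = -2, v9 = 5)
  oob <- oob_assign(scores, summ)
  # brute-force counting oracle for v1: iterations 3-5 assign 0, +4, +4
  expect_identical(oob$points[oob$variant_id == "v1"], 4L)
  expect_identical(oob$n_models[oob$variant_id == "v1"], 3L)
  # v2: iterations 1,3,4,5 -> +4, 0, +4, +4
  expect_identical(oob$points[oob$variant_id == "v2"], 4L)
  # v9 never resampled: all five iterations contribute, all -1
  expect_identical(oob$points[oob$variant_id == "v9"], -1L)

  # explicit tie-break checks on the modal rule
  expect_identical(mavecal:::modal_points(c(rep(4L, 10), rep(-1L, 10))), -1L)
  expect_identical(mavecal:::modal_points(c(rep(2L, 3), rep(-2L, 3))), 0L)
  expect_identical(mavecal:::modal_points(c(1L, 1L, 8L)), 1L)
})
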