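#' Labeled score samples for mixture fitting
#'
#' Bundles the per-label assay-score vectors that enter the multi-sample
#' mixture model: pathogenic/likely-pathogenic controls (`P`),
#' benign/likely-benign controls (`B`), a population-reference sample (`G`,
#' e.g. gnomAD missense variants) and, when the assay reports them, synonymous
#' variants (`S`). Vectors may carry variant identifiers as names; unnamed
#' vectors are auto-named so bootstrap membership can be tracked.
#'
#' @param plp,blb,ref Nonempty finite numeric score vectors.
#' @param syn Optional finite numeric score vector (may be `NULL`).
#' @return An object of class `sample_set` with elements `P`, `B`, `G` and
#'   (when supplied) `S`.
#' @export
sample_set <- function(plp, blb, ref, syn = NULL) {
  chk <- function(v, label) {
    if (!is.numeric(v) || length(v) == 0L) {
      stop(sprintf("sample '%s' must be a nonempty numeric vector", label),
           call. = FALSE)
    }
    if (!all(is.finite(v))) {
      stop(sprintf("sample '%s' contains non-finite scores", label),
           call. = FALSE)
    }
    if (is.null(names(v)) || anyNA(names(v)) || any(names(v) == "")) {
      names(v) <- paste0(label, "_", seq_along(v))
    }
    v
  }
  out <- list(P = chk(plp, "P"), B = chk(blb, "B"), G = chk(ref, "G"))
  if (!is.null(syn)) out$S <- chk(syn, "S")
  structure(out, class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set:",
      paste(sprintf("%s (n=%d)", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}

ss_pooled <- function(ss) {
  keys <- names(ss)
  list(x = unlist(ss, use.names = FALSE),
       g = rep.int(keys, lengths(ss)),
       keys = keys)
}

#' Two-component mixture density
#'
#' The score distribution of every labeled sample is the same pair of
#' skew-normal components mixed with a sample-specific abnormal-component
#' weight: `w * SN(s; theta_a) + (1 - w) * SN(s; theta_n)`.
#'
#' @param s Numeric vector of scores.
#' @param weight Abnormal-component mixing weight in `[0, 1]`.
#' @param theta_abnormal,theta_normal `sn_params` for the functionally
#'   abnormal and functionally normal components.
#' @param log Return the log-density?
#' @return Numeric vector of (log-)densities.
#' @export
mixture_pdf <- function(s, weight, theta_abnormal, theta_normal, log = FALSE) {
  assert_scalar_number(weight, "weight")
  if (weight < 0 || weight > 1) stop("'weight' must lie in [0, 1]", call. = FALSE)
  la <- if (weight > 0) log(weight) + sn_logpdf(s, theta_abnormal) else rep(-Inf, length(s))
  ln <- if (weight < 1) log1p(-weight) + sn_logpdf(s, theta_normal) else rep(-Inf, length(s))
  out <- logsumexp2(la, ln)
  if (log) out else exp(out)
}

## ---- monotone density-ratio constraint -------------------------------------

make_ratio_grid <- function(x, n = 2048L, pad = 0.05) {
  r <- range(x)
  spread <- diff(r)
  if (spread == 0) spread <- max(abs(r[1]), 1)
  seq(r[1] - pad * spread, r[2] + pad * spread, length.out = n)
}

log_ratio_alt <- function(grid, va, vn) {
  sn_logpdf_alt(grid, va) - sn_logpdf_alt(grid, vn)
}

ratio_is_monotone <- function(va, vn, grid, tol = 1e-12) {
  lr <- log_ratio_alt(grid, va, vn)
  all(diff(lr) <= tol)
}

# Binary search along the segment from a feasible parameter vector to a
# proposed one; returns the last feasible point (full alternate vector of
# both components is projected). 50 bisection steps per the package default.
project_ratio <- function(feasible, proposed, grid, steps = 50L) {
  if (ratio_is_monotone(proposed[1:3], proposed[4:6], grid)) return(proposed)
  lo <- 0; hi <- 1
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    cand <- feasible + mid * (proposed - feasible)
    if (ratio_is_monotone(cand[1:3], cand[4:6], grid)) lo <- mid else hi <- mid
  }
  out <- feasible + lo * (proposed - feasible)
  if (!ratio_is_monotone(out[1:3], out[4:6], grid)) {
    # lo = 0 still violating would mean the anchor itself was infeasible
    stop("monotone density-ratio projection failed: infeasible anchor",
         call. = FALSE)
  }
  out
}

#' Impose the monotone density-ratio constraint
#'
#' The calibration model requires the component density ratio
#' `SN(s; theta_abnormal) / SN(s; theta_normal)` to be non-increasing in `s`
#' over the observed score range (lower scores = more abnormal). Together
#' with `wP > wB` this guarantees a monotone local likelihood ratio and hence
#' a monotone evidence map. When a feasible anchor pair is supplied the
#' adjustment is a binary search along the segment from the anchor to the
#' proposal (the EM projection); without an anchor the component locations
#' are iteratively moved apart (the initialization repair).
#'
#' @param theta_abnormal,theta_normal Proposed `sn_params` pair.
#' @param score_range Numeric vector whose range defines where the constraint
#'   is checked (a padded 2048-point grid is used).
#' @param feasible_abnormal,feasible_normal Optional `sn_params` pair already
#'   satisfying the constraint, used as the binary-search anchor.
#' @return List with elements `theta_abnormal`, `theta_normal` and `adjusted`
#'   (logical: was the proposal modified?).
#' @export
enforce_monotone_ratio <- function(theta_abnormal, theta_normal, score_range,
                                   feasible_abnormal = NULL,
                                   feasible_normal = NULL) {
  grid <- make_ratio_grid(score_range)
  va <- alt_vec(theta_abnormal)
  vn <- alt_vec(theta_normal)
  if (ratio_is_monotone(va, vn, grid)) {
    return(list(theta_abnormal = theta_abnormal, theta_normal = theta_normal,
                adjusted = FALSE))
  }
  if (!is.null(feasible_abnormal)) {
    anchor <- c(alt_vec(feasible_abnormal), alt_vec(feasible_normal))
    out <- project_ratio(anchor, c(va, vn), grid)
    return(list(theta_abnormal = alt_vec_to_canonical(out[1:3]),
                theta_normal = alt_vec_to_canonical(out[4:6]),
                adjusted = TRUE))
  }
  sep <- separate_locations(va, vn, grid)
  list(theta_abnormal = alt_vec_to_canonical(sep[1:3]),
       theta_normal = alt_vec_to_canonical(sep[4:6]),
       adjusted = TRUE)
}

# Move component locations in opposing directions (abnormal down, normal up)
# until the density ratio is monotone on the grid.
separate_locations <- function(va, vn, grid, max_iter = 400L) {
  step <- 0.02 * diff(range(grid))
  for (i in seq_len(max_iter)) {
    if (ratio_is_monotone(va, vn, grid)) return(c(va, vn))
    va[1] <- va[1] - step
    vn[1] <- vn[1] + step
  }
  stop("could not separate component locations to satisfy the density-ratio constraint",
       call. = FALSE)
}

## ---- initialization --------------------------------------------------------

#' Initialize the mixture parameters
#'
#' K-means (K = 2) is run on the pooled observations; per-cluster Gaussian
#' fits give the component locations and scales, skews are drawn from
#' Uniform(-0.25, 0.25), and the component with the lower location is labeled
#' "abnormal". Initial per-sample weights are the fraction of each sample
#' assigned to the abnormal cluster (clipped away from 0/1). If the initial
#' pair violates the monotone density-ratio constraint, the locations are
#' moved apart until it holds.
#'
#' @param samples A `sample_set`.
#' @param seed Optional integer seed (controls both k-means and the skew draw).
#' @return List with `theta_abnormal`, `theta_normal` (`sn_params`) and
#'   `weights` (named numeric over the samples present).
#' @export
initialize_mixture <- function(samples, seed = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  pool <- ss_pooled(samples)
  x <- pool$x
  if (length(x) < 4L) stop("need at least 4 pooled observations", call. = FALSE)
  if (length(unique(x)) < 2L) stop("degenerate data: all scores identical", call. = FALSE)
  with_seed(seed, {
    km <- stats::kmeans(x, centers = 2L, nstart = 10L)
    lam <- stats::runif(2L, -0.25, 0.25)
    ab_cluster <- which.min(km$centers)
    sd_floor <- 1e-3 * stats::sd(x)
    comp <- function(k) {
      xs <- x[km$cluster == k]
      s <- if (length(xs) > 1L) stats::sd(xs) else sd_floor
      list(mu = mean(xs), omega = max(s, sd_floor))
    }
    ca <- comp(ab_cluster)
    cn <- comp(3L - ab_cluster)
    theta_a <- sn_params(ca$mu, ca$omega, lam[1])
    theta_n <- sn_params(cn$mu, cn$omega, lam[2])
    adj <- enforce_monotone_ratio(theta_a, theta_n, x)
    w <- vapply(pool$keys, function(k) {
      mean(km$cluster[pool$g == k] == ab_cluster)
    }, numeric(1))
    w <- pmin(pmax(w, 0.02), 0.98)
    list(theta_abnormal = adj$theta_abnormal,
         theta_normal = adj$theta_normal,
         weights = w)
  })
}

## ---- EM --------------------------------------------------------------------

# Observed-data log-likelihood for flattened state.
loglik_state <- function(x, w_obs, va, vn) {
  la <- ifelse(w_obs > 0, log(w_obs) + sn_logpdf_alt(x, va), -Inf)
  ln <- ifelse(w_obs < 1, log1p(-w_obs) + sn_logpdf_alt(x, vn), -Inf)
  sum(logsumexp2(la, ln))
}

# Conditional truncated-normal moments e1 = E[t | x], e2 = E[t^2 | x] of the
# latent half-normal factor, given component alternate parameters v.
trunc_moments <- function(x, v) {
  prec <- v[3] + v[2]^2
  vv <- v[3] / prec
  m <- v[2] * (x - v[1]) / prec
  sdv <- sqrt(vv)
  h <- m / sdv
  r <- exp(stats::dnorm(h, log = TRUE) - stats::pnorm(h, log.p = TRUE))
  e1 <- m + sdv * r
  list(e1 = e1, e2 = m * e1 + vv)
}

# Binary search for one coordinate of the 6-parameter vector
# (mu_a, d_a, g_a, mu_n, d_n, g_n): move as far as possible from the current
# feasible value toward the proposed one while the density ratio stays
# monotone on the grid. Along a single coordinate the expected complete-data
# log-likelihood is unimodal between the current value and its maximizer, so
# every accepted partial move preserves the EM ascent property.
project_coord <- function(th, idx, value, grid, steps = 50L) {
  cand <- th
  cand[idx] <- value
  if (ratio_is_monotone(cand[1:3], cand[4:6], grid)) return(cand)
  old <- th[idx]
  lo <- 0; hi <- 1
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    cand[idx] <- old + mid * (value - old)
    if (ratio_is_monotone(cand[1:3], cand[4:6], grid)) lo <- mid else hi <- mid
  }
  cand[idx] <- old + lo * (value - old)
  cand
}

# Sequential constrained M-step for one component (comp 1 = abnormal,
# comp 2 = normal); p are this component's responsibilities across the
# pooled observations, and e1/e2 are the conditional truncated-normal
# moments at the pre-update parameters (E-step quantities).
update_component <- function(x, p, th, comp, grid) {
  off <- if (comp == 1L) 0L else 3L
  v <- th[off + 1:3]
  sp <- sum(p)
  if (sp < 1e-10) {
    stop("component collapse: vanishing total responsibility", call. = FALSE)
  }
  tm <- trunc_moments(x, v)
  mu_new <- sum(p * (x - v[2] * tm$e1)) / sp
  th <- project_coord(th, off + 1L, mu_new, grid)
  d_new <- sum(p * (x - th[off + 1L]) * tm$e1) / sum(p * tm$e2)
  th <- project_coord(th, off + 2L, d_new, grid)
  mu <- th[off + 1L]; d <- th[off + 2L]
  g_new <- sum(p * ((x - mu)^2 - 2 * d * (x - mu) * tm$e1 + d^2 * tm$e2)) / sp
  project_coord(th, off + 3L, max(g_new, 1e-10), grid)
}

#' One EM iteration of the constrained multi-sample mixture
#'
#' E-step: per-observation abnormal responsibilities using each observation's
#' own sample weight. M-step: location/Delta/Gamma of each component updated
#' pooling responsibilities across all samples, with the monotone
#' density-ratio constraint re-imposed by binary search after each of the six
#' parameter updates; each sample's weight is then the mean abnormal
#' responsibility within that sample.
#'
#' @param state List with `theta_abnormal`, `theta_normal` (`sn_params`) and
#'   named `weights`, as produced by [initialize_mixture()].
#' @param samples A `sample_set`.
#' @return Updated state, with `log_likelihood` evaluated at the updated
#'   parameters.
#' @export
em_step <- function(state, samples) {
  pool <- ss_pooled(samples)
  grid <- make_ratio_grid(pool$x)
  st <- list(va = alt_vec(state$theta_abnormal),
             vn = alt_vec(state$theta_normal),
             w = state$weights[pool$keys])
  out <- em_step_core(pool, grid, st)
  list(theta_abnormal = alt_vec_to_canonical(out$va),
       theta_normal = alt_vec_to_canonical(out$vn),
       weights = out$w,
       log_likelihood = out$ll)
}

em_step_core <- function(pool, grid, st) {
  x <- pool$x
  w_obs <- unname(st$w[pool$g])
  la <- ifelse(w_obs > 0, log(w_obs) + sn_logpdf_alt(x, st$va), -Inf)
  ln <- ifelse(w_obs < 1, log1p(-w_obs) + sn_logpdf_alt(x, st$vn), -Inf)
  lse <- logsumexp2(la, ln)
  p_a <- exp(la - lse)
  p_a[is.na(p_a)] <- 0

  th <- c(st$va, st$vn)
  th <- update_component(x, p_a, th, 1L, grid)
  th <- update_component(x, 1 - p_a, th, 2L, grid)

  w_new <- vapply(pool$keys, function(k) mean(p_a[pool$g == k]), numeric(1))
  list(va = th[1:3], vn = th[4:6], w = w_new,
       ll = loglik_state(x, unname(w_new[pool$g]), th[1:3], th[4:6]))
}

#' Fit the constrained multi-sample skew-normal mixture
#'
#' Runs EM from `n_restarts` random initializations and keeps the fit with
#' the highest observed-data log-likelihood. Convergence is declared when the
#' relative change in log-likelihood falls below `tol`. If an iteration under
#' the density-ratio projection would decrease the log-likelihood, the
#' iteration is rejected and the run stops at the previous parameters, so the
#' per-iteration log-likelihood trace is always non-decreasing.
#'
#' @param samples A `sample_set`. The synonymous sample, when present,
#'   contributes to the likelihood exactly like the other samples.
#' @param n_restarts Number of random restarts (default 100).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Optional master seed; restart `r` uses `seed + r - 1`.
#' @return A `mixture_fit` object: `theta_abnormal`, `theta_normal`
#'   (`sn_params`), per-sample `weights`, `log_likelihood`, the per-iteration
#'   `loglik_trace` of the winning restart, all `restart_logliks`,
#'   `converged`, `n_iterations` and the padded `score_range` on which the
#'   density-ratio constraint was enforced.
#' @export
fit_mixture <- function(samples, n_restarts = 100L, tol = 1e-6,
                        max_iter = 500L, seed = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  pool <- ss_pooled(samples)
  if (length(unique(pool$x)) < 2L) {
    stop("degenerate data: fewer than 2 distinct score values", call. = FALSE)
  }
  grid <- make_ratio_grid(pool$x)
  best <- NULL
  restart_lls <- rep(-Inf, n_restarts)
  for (r in seq_len(n_restarts)) {
    seed_r <- if (is.null(seed)) NULL else seed + r - 1L
    res <- tryCatch(em_run(samples, pool, grid, seed_r, tol, max_iter),
                    error = function(e) NULL)
    if (is.null(res)) next
    restart_lls[r] <- res$ll
    if (is.null(best) || res$ll > best$ll) best <- res
  }
  if (is.null(best)) stop("all EM restarts failed", call. = FALSE)
  structure(list(
    theta_abnormal = alt_vec_to_canonical(best$va),
    theta_normal = alt_vec_to_canonical(best$vn),
    weights = best$w,
    log_likelihood = best$ll,
    loglik_trace = best$trace,
    restart_logliks = restart_lls,
    converged = best$converged,
    n_iterations = best$n_iter,
    score_range = range(grid),
    n_obs = lengths(samples)
  ), class = "mixture_fit")
}

em_run <- function(samples, pool, grid, seed, tol, max_iter) {
  init <- initialize_mixture(samples, seed = seed)
  st <- list(va = alt_vec(init$theta_abnormal),
             vn = alt_vec(init$theta_normal),
             w = init$weights[pool$keys])
  ll <- loglik_state(pool$x, unname(st$w[pool$g]), st$va, st$vn)
  trace <- ll
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    new <- em_step_core(pool, grid, st)
    if (new$ll < ll - 1e-9) {
      # projection clamped the ascent; keep the previous parameters
      converged <- TRUE
      break
    }
    delta <- new$ll - ll
    st <- list(va = new$va, vn = new$vn, w = new$w)
    ll <- new$ll
    trace <- c(trace, ll)
    n_iter <- it
    if (abs(delta) / (abs(ll) + 1e-12) < tol) {
      converged <- TRUE
      break
    }
  }
  list(va = st$va, vn = st$vn, w = st$w, ll = ll, trace = trace,
       converged = converged, n_iter = n_iter)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Constrained two-component skew-normal mixture fit\n")
  cat(sprintf("  abnormal: location %.4g, scale %.4g, skew %.4g\n",
              x$theta_abnormal$location, x$theta_abnormal$scale,
              x$theta_abnormal$skew))
  cat(sprintf("  normal:   location %.4g, scale %.4g, skew %.4g\n",
              x$theta_normal$location, x$theta_normal$scale,
              x$theta_normal$skew))
  cat("  abnormal weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "),
      "\n")
  cat(sprintf("  log-likelihood %.4f (%s after %d iterations)\n",
              x$log_likelihood,
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$n_iterations))
  invisible(x)
}
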