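#' Default ACMG/AMP evidence-combining rules
#'
#' The constraint system used to solve for the evidence scaling constant `c`:
#' every pathogenic combination must reach posterior probability of
#' pathogenicity 0.99 and every likely-pathogenic combination 0.90, with a
#' combination's likelihood ratio given by the exponential point system
#' `LR+ = c^(nsu/8 + nmo/4 + nst/2 + nvs)`.
#'
#' The shipped default excludes the "two strong lines" pathogenic
#' combination: under the exponential point system that combination (8
#' points) is the well-known discordant rule — retaining it forces `c` far
#' above the established values (891 rather than about 350 at prior 0.1),
#' inconsistent with how the scaling constant is conventionally derived. Set
#' `include_two_strong = TRUE` to restore it. Benign combinations do not
#' constrain `c`; benign evidence floors are `c^(-points/8)`.
#'
#' @param include_two_strong Include the ">= 2 strong => pathogenic" rule?
#' @return Data frame with columns `rule`, `target` ("pathogenic" or
#'   "likely_pathogenic"), `nsu`, `nmo`, `nst`, `nvs` and derived `points`.
#' @export
default_acmg_rules <- function(include_two_strong = FALSE) {
  r <- rbind(
    data.frame(rule = "1VS+1S",     target = "pathogenic",        nsu = 0, nmo = 0, nst = 1, nvs = 1),
    data.frame(rule = "1VS+2M",     target = "pathogenic",        nsu = 0, nmo = 2, nst = 0, nvs = 1),
    data.frame(rule = "1VS+1M+1Su", target = "pathogenic",        nsu = 1, nmo = 1, nst = 0, nvs = 1),
    data.frame(rule = "1VS+2Su",    target = "pathogenic",        nsu = 2, nmo = 0, nst = 0, nvs = 1),
    data.frame(rule = "2S",         target = "pathogenic",        nsu = 0, nmo = 0, nst = 2, nvs = 0),
    data.frame(rule = "1S+3M",      target = "pathogenic",        nsu = 0, nmo = 3, nst = 1, nvs = 0),
    data.frame(rule = "1S+2M+2Su",  target = "pathogenic",        nsu = 2, nmo = 2, nst = 1, nvs = 0),
    data.frame(rule = "1S+1M+4Su",  target = "pathogenic",        nsu = 4, nmo = 1, nst = 1, nvs = 0),
    data.frame(rule = "1VS+1M",     target = "likely_pathogenic", nsu = 0, nmo = 1, nst = 0, nvs = 1),
    data.frame(rule = "1S+1M",      target = "likely_pathogenic", nsu = 0, nmo = 1, nst = 1, nvs = 0),
    data.frame(rule = "1S+2M",      target = "likely_pathogenic", nsu = 0, nmo = 2, nst = 1, nvs = 0),
    data.frame(rule = "1S+2Su",     target = "likely_pathogenic", nsu = 2, nmo = 0, nst = 1, nvs = 0),
    data.frame(rule = "3M",         target = "likely_pathogenic", nsu = 0, nmo = 3, nst = 0, nvs = 0),
    data.frame(rule = "2M+2Su",     target = "likely_pathogenic", nsu = 2, nmo = 2, nst = 0, nvs = 0),
    data.frame(rule = "1M+4Su",     target = "likely_pathogenic", nsu = 4, nmo = 1, nst = 0, nvs = 0)
  )
  if (!include_two_strong) r <- r[r$rule != "2S", ]
  r$points <- r$nsu + 2 * r$nmo + 4 * r$nst + 8 * r$nvs
  rownames(r) <- NULL
  r
}

#' Read a combining-rule set from a delimited text file
#'
#' Expects columns `rule`, `target`, `nsu`, `nmo`, `nst`, `nvs` (comma- or
#' tab-separated), the same schema as [default_acmg_rules()].
#'
#' @param path Path to the rules file.
#' @return Rules data frame with derived `points` column.
#' @export
read_acmg_rules <- function(path) {
  r <- read_delim_auto(path)
  need <- c("rule", "target", "nsu", "nmo", "nst", "nvs")
  missing <- setdiff(need, names(r))
  if (length(missing)) {
    stop("rules file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  r$points <- r$nsu + 2 * r$nmo + 4 * r$nst + 8 * r$nvs
  r
}

#' Posterior probability of pathogenicity from a likelihood ratio
#'
#' `P(Y=1 | E) = lr * prior / ((lr - 1) * prior + 1)`; strictly increasing in
#' both arguments.
#'
#' @param lr Positive likelihood ratio(s).
#' @param prior Prior probability of pathogenicity in `(0, 1)`.
#' @return Posterior probabilities in `(0, 1)`.
#' @export
posterior_probability <- function(lr, prior) {
  if (any(lr <= 0)) stop("'lr' must be positive", call. = FALSE)
  assert_scalar_number(prior, "prior")
  if (prior <= 0 || prior >= 1) stop("'prior' must lie in (0, 1)", call. = FALSE)
  lr * prior / ((lr - 1) * prior + 1)
}

#' Solve for the evidence scaling constant c
#'
#' Finds the smallest `c >= 1` such that, at the given prior, every
#' pathogenic combining rule attains posterior probability at least 0.99 and
#' every likely-pathogenic rule at least 0.90, where a rule with `p` points
#' has `LR+ = c^(p/8)`. The feasible set is an interval `[c*, Inf)`; `c*` is
#' located by bisection to a relative precision of `1e-4`.
#'
#' @param prior Prior probability of pathogenicity in `(0, 1)`.
#' @param rules Combining-rule data frame (see [default_acmg_rules()]).
#' @param rel_tol Relative bisection tolerance.
#' @return The scaling constant `c` (numeric scalar).
#' @examples
#' solve_c(0.1)    # about 350
#' solve_c(0.044)  # about 1124
#' @export
solve_c <- function(prior, rules = default_acmg_rules(), rel_tol = 1e-4) {
  assert_scalar_number(prior, "prior")
  if (prior <= 0 || prior >= 1) stop("'prior' must lie in (0, 1)", call. = FALSE)
  targets <- ifelse(rules$target == "pathogenic", 0.99, 0.90)
  feasible <- function(cc) {
    all(posterior_probability(cc^(rules$points / 8), prior) >= targets)
  }
  lo <- 1
  hi <- 10
  while (!feasible(hi)) {
    lo <- hi
    hi <- hi * 10
    if (hi > 1e15) stop("no feasible c found below 1e15", call. = FALSE)
  }
  if (feasible(lo)) return(lo)
  while ((hi - lo) / hi > rel_tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Estimate the prior probability of pathogenicity from a mixture fit
#'
#' The reference (gnomAD) sample's score distribution is itself a mixture of
#' the pathogenic and benign score distributions, which gives
#' `P(Y=1) = (wG - wB) / (wP - wB)` in terms of the fitted per-sample
#' abnormal-component weights. Estimates outside the open interval `(0, 1)`,
#' or fits with `wP <= wB`, are flagged invalid rather than raised as errors
#' (the bootstrap excludes such iterations).
#'
#' @param fit A `mixture_fit`, or a named numeric vector of weights with
#'   entries `P`, `B`, `G`.
#' @return List with `prior` (numeric, possibly NaN), `valid` (logical) and
#'   `reason` (`NA` or a short diagnostic string).
#' @export
estimate_prior <- function(fit) {
  w <- if (inherits(fit, "mixture_fit")) fit$weights else fit
  if (!all(c("P", "B", "G") %in% names(w))) {
    stop("fit must provide weights for samples P, B and G", call. = FALSE)
  }
  denom <- w[["P"]] - w[["B"]]
  prior <- if (denom == 0) NaN else (w[["G"]] - w[["B"]]) / denom
  reason <- NA_character_
  valid <- TRUE
  if (w[["P"]] <= w[["B"]]) {
    valid <- FALSE
    reason <- "wP <= wB"
  } else if (!is.finite(prior) || prior <= 0 || prior >= 1) {
    valid <- FALSE
    reason <- "prior outside (0, 1)"
  }
  list(prior = unname(prior), valid = valid, reason = reason)
}

#' Local positive likelihood ratio of an assay score
#'
#' `lr+(s)` is the ratio of the fitted P-sample mixture density to the
#' fitted B-sample mixture density at score `s`. Under the monotone
#' density-ratio constraint and `wP > wB` it is non-increasing in `s`
#' (lower scores give stronger pathogenic evidence). Computed in log space;
#' as `s` decreases far below the abnormal component, `lr+` tends to
#' `wP / wB`.
#'
#' @param s Numeric vector of scores.
#' @param fit A `mixture_fit`.
#' @param log Return `log lr+` instead of `lr+`?
#' @return Numeric vector.
#' @export
local_lr_plus <- function(s, fit, log = FALSE) {
  stopifnot(inherits(fit, "mixture_fit"))
  lp <- mixture_pdf(s, fit$weights[["P"]], fit$theta_abnormal,
                    fit$theta_normal, log = TRUE)
  lb <- mixture_pdf(s, fit$weights[["B"]], fit$theta_abnormal,
                    fit$theta_normal, log = TRUE)
  out <- lp - lb
  if (log) out else exp(out)
}

#' Evidence scale: point levels, scaling constant and prior
#'
#' Evidence strengths are measured in points on the `log LR+` scale:
#' supporting/moderate/strong/very strong = 1/2/4/8, with the intermediate
#' level 3 included by default, and a level of `x` points requires
#' `lr+ >= c^(x/8)` (pathogenic) or `lr+ <= c^(-x/8)` (benign).
#'
#' @param prior Prior probability of pathogenicity in `(0, 1)`.
#' @param c Optional scaling constant; solved from `rules` when `NULL`.
#' @param levels Point levels considered, default `c(1, 2, 3, 4, 8)`.
#' @param rules Combining rules used when solving for `c`.
#' @return An `evidence_scale` object.
#' @export
evidence_scale <- function(prior, c = NULL, levels = c(1, 2, 3, 4, 8),
                           rules = default_acmg_rules()) {
  if (is.null(c)) c <- solve_c(prior, rules)
  if (c <= 1) stop("'c' must exceed 1", call. = FALSE)
  structure(list(prior = prior, c = c, levels = sort(unique(as.integer(levels)))),
            class = "evidence_scale")
}

#' Score thresholds for each evidence level from a point-estimate fit
#'
#' For each pathogenic level `x`, the threshold is the largest score `s`
#' with `lr+(s) >= c^(x/8)` (every score at or below it then meets the
#' floor, by monotonicity); for each benign level, the smallest score with
#' `lr+(s) <= c^(-x/8)`. Levels whose floor is never met within the score
#' range are absent from the maps. Roots are located by `uniroot` on the
#' monotone log-`lr+` curve with a `1e-8` score tolerance.
#'
#' @param fit A `mixture_fit` with `wP > wB` (otherwise both maps are empty
#'   and a warning is raised).
#' @param scale An `evidence_scale`.
#' @param score_range Interval searched; defaults to the fit's padded
#'   observed range.
#' @return A `calibration_result`: `prior`, `c`, named numeric
#'   `pathogenic_thresholds` and `benign_thresholds` (names are point
#'   levels), and `direction = "low_scores_abnormal"`.
#' @export
thresholds_from_fit <- function(fit, scale, score_range = fit$score_range) {
  stopifnot(inherits(fit, "mixture_fit"), inherits(scale, "evidence_scale"))
  lo <- score_range[1]
  hi <- score_range[2]
  if (fit$weights[["P"]] <= fit$weights[["B"]]) {
    warning("wP <= wB: no pathogenic evidence assignable from this fit")
    return(new_calibration_result(scale, numeric(0), numeric(0)))
  }
  llr <- function(s) local_lr_plus(s, fit, log = TRUE)
  llr_lo <- llr(lo)
  llr_hi <- llr(hi)
  logc <- log(scale$c)

  path <- vapply(scale$levels, function(x) {
    floor_log <- x / 8 * logc
    if (llr_lo < floor_log) return(NA_real_)   # floor never met
    if (llr_hi >= floor_log) return(hi)        # whole range qualifies
    stats::uniroot(function(s) llr(s) - floor_log, lower = lo, upper = hi,
                   tol = 1e-8)$root
  }, numeric(1))
  names(path) <- scale$levels

  ben <- vapply(scale$levels, function(x) {
    ceil_log <- -x / 8 * logc
    if (llr_hi > ceil_log) return(NA_real_)
    if (llr_lo <= ceil_log) return(lo)
    stats::uniroot(function(s) llr(s) - ceil_log, lower = lo, upper = hi,
                   tol = 1e-8)$root
  }, numeric(1))
  names(ben) <- scale$levels

  new_calibration_result(scale, path[!is.na(path)], ben[!is.na(ben)])
}

new_calibration_result <- function(scale, path, ben) {
  structure(list(prior = scale$prior, c = scale$c,
                 levels = scale$levels,
                 pathogenic_thresholds = path,
                 benign_thresholds = ben,
                 direction = "low_scores_abnormal"),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration (prior = %.4g, c = %.4g, %s)\n",
              x$prior, x$c, x$direction))
  fmt <- function(thr, sign) {
    if (!length(thr)) return("  (no level reached)\n")
    paste0(sprintf("  %+d points: score %s %.4g\n", sign * as.integer(names(thr)),
                   if (sign > 0) "<=" else ">=", thr), collapse = "")
  }
  cat("pathogenic:\n", fmt(x$pathogenic_thresholds, 1L), sep = "")
  cat("benign:\n", fmt(x$benign_thresholds, -1L), sep = "")
  invisible(x)
}

## ---- evidence assignment ---------------------------------------------------

threshold_maps <- function(object) {
  if (inherits(object, "calibration_result")) {
    list(path = object$pathogenic_thresholds, ben = object$benign_thresholds)
  } else if (inherits(object, "bootstrap_summary")) {
    list(path = object$final_thresholds$pathogenic,
         ben = object$final_thresholds$benign)
  } else {
    stop("expected a 'calibration_result' or 'bootstrap_summary'", call. = FALSE)
  }
}

assign_points_maps <- function(score, path, ben) {
  for (lv in sort(as.integer(names(path)), decreasing = TRUE)) {
    if (score <= path[[as.character(lv)]]) return(lv)
  }
  for (lv in sort(as.integer(names(ben)), decreasing = TRUE)) {
    if (score >= ben[[as.character(lv)]]) return(-lv)
  }
  0L
}

#' Assign evidence points to assay scores
#'
#' Returns, for each score, the strongest pathogenic level whose threshold
#' the score meets (score at or below the threshold, under the
#' low-scores-abnormal convention), else the strongest benign level met
#' (score at or above), else 0 (indeterminate). Levels a calibration does not
#' reach are never returned.
#'
#' @param score Numeric vector of assay scores (no NAs).
#' @param calibration A `calibration_result` or `bootstrap_summary`.
#' @return Integer vector of signed points (positive pathogenic, negative
#'   benign, 0 indeterminate).
#' @export
assign_evidence <- function(score, calibration) {
  if (any(!is.finite(score))) stop("'score' must be finite", call. = FALSE)
  maps <- threshold_maps(calibration)
  vapply(score, assign_points_maps, integer(1),
         path = maps$path, ben = maps$ben)
}

## ---- bootstrap -------------------------------------------------------------

#' Bootstrap calibration with percentile thresholds
#'
#' Repeats the whole modeling procedure on stratified bootstrap resamples:
#' each labeled sample is resampled with replacement independently, the
#' constrained mixture is refitted, the iteration's prior is estimated, `c`
#' is solved for that prior, and the iteration's evidence thresholds are
#' computed. Iterations with invalid priors are excluded from aggregation.
#' Final thresholds are the 5th percentile (pathogenic) and 95th percentile
#' (benign) of the per-iteration thresholds; a level is reported only when
#' at least `reach` (default 95%) of the valid iterations reach it.
#'
#' @param samples A `sample_set`.
#' @param n_boot Number of bootstrap iterations (default 5000; a reduced mode
#'   of a few hundred is appropriate for exploratory runs).
#' @param n_restarts EM restarts per iteration.
#' @param seed Master seed; iteration `k` derives its resampling and fitting
#'   seeds from it deterministically.
#' @param resample Set `FALSE` to fit the original data in every iteration
#'   (with `n_boot = 1` this reproduces the point-estimate thresholds).
#' @param levels,rules Passed to [evidence_scale()].
#' @param tol,max_iter EM controls, as in [fit_mixture()].
#' @param reach Minimum fraction of valid iterations that must reach a level
#'   for it to be reported.
#' @return A `bootstrap_summary`; see [aggregate_bootstrap()] for the
#'   aggregated fields. `iterations` holds the per-iteration records
#'   (prior, validity, `c`, threshold maps, resampled membership, fit
#'   diagnostics including per-sample CDF distances).
#' @export
bootstrap_calibrate <- function(samples, n_boot = 5000L, n_restarts = 100L,
                                seed = 1L, resample = TRUE,
                                levels = c(1, 2, 3, 4, 8),
                                rules = default_acmg_rules(),
                                tol = 1e-6, max_iter = 500L, reach = 0.95) {
  stopifnot(inherits(samples, "sample_set"))
  if (n_boot < 1L) stop("'n_boot' must be at least 1", call. = FALSE)
  iterations <- vector("list", n_boot)
  for (k in seq_len(n_boot)) {
    fit_seed <- seed + (k - 1L) * (n_restarts + 1L)
    boot <- if (resample) {
      resampled <- with_seed(seed + 500000L + k, {
        lapply(samples, function(v) v[sample.int(length(v), replace = TRUE)])
      })
      do.call(sample_set, list(plp = resampled$P, blb = resampled$B,
                               ref = resampled$G, syn = resampled$S))
    } else {
      samples
    }
    members <- lapply(boot, function(v) unique(names(v)))
    rec <- list(members = members, valid = FALSE, prior = NA_real_,
                c = NA_real_, pathogenic_thresholds = numeric(0),
                benign_thresholds = numeric(0), log_likelihood = NA_real_,
                reason = NA_character_, distances = NULL)
    fit <- tryCatch(
      fit_mixture(boot, n_restarts = n_restarts, tol = tol,
                  max_iter = max_iter, seed = fit_seed),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rec$log_likelihood <- fit$log_likelihood
      rec$distances <- vapply(names(boot), function(nm) {
        cdf_distance(boot[[nm]], fit, sample = nm)
      }, numeric(1))
      pr <- estimate_prior(fit)
      rec$prior <- pr$prior
      if (pr$valid) {
        scale <- evidence_scale(pr$prior, levels = levels, rules = rules)
        thr <- thresholds_from_fit(fit, scale)
        rec$valid <- TRUE
        rec$c <- scale$c
        rec$pathogenic_thresholds <- thr$pathogenic_thresholds
        rec$benign_thresholds <- thr$benign_thresholds
      } else {
        rec$reason <- pr$reason
      }
    } else {
      rec$reason <- "fit failed"
    }
    iterations[[k]] <- rec
  }
  aggregate_bootstrap(iterations, levels = levels, reach = reach)
}

#' Aggregate per-iteration bootstrap records into final thresholds
#'
#' Valid-prior iterations are aggregated; for each point level the reach
#' fraction is the share of valid iterations whose threshold map contains
#' the level, and levels with reach fraction of at least `reach` get a final
#' threshold: the 5th percentile of the per-iteration pathogenic thresholds
#' or the 95th percentile of the benign thresholds (the conservative tail in
#' each direction).
#'
#' @param iterations List of per-iteration records as produced by
#'   [bootstrap_calibrate()] (fields `valid`, `prior`, `c`,
#'   `pathogenic_thresholds`, `benign_thresholds`, optionally `members`).
#' @param levels Point levels under consideration.
#' @param reach Minimum reach fraction for a level to be reported.
#' @return A `bootstrap_summary` with `n_iterations`, `valid_iterations`,
#'   `priors`, `c_values`, per-level threshold vectors
#'   (`per_level_thresholds`), `reach_fraction` (per direction),
#'   `final_thresholds` and the raw `iterations`.
#' @export
aggregate_bootstrap <- function(iterations, levels = c(1, 2, 3, 4, 8),
                                reach = 0.95) {
  valid <- vapply(iterations, function(r) isTRUE(r$valid), logical(1))
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    reasons <- table(vapply(iterations, function(r) r$reason %||% NA_character_,
                            character(1)), useNA = "ifany")
    stop("bootstrap calibration failed: no valid-prior iterations (",
         paste(sprintf("%s: %d", names(reasons), reasons), collapse = "; "),
         ")", call. = FALSE)
  }
  lv <- as.character(sort(unique(as.integer(levels))))
  grab <- function(field) {
    m <- vapply(iterations[valid], function(r) {
      out <- rep(NA_real_, length(lv))
      names(out) <- lv
      thr <- r[[field]]
      out[intersect(names(thr), lv)] <- thr[intersect(names(thr), lv)]
      out
    }, numeric(length(lv)))
    matrix(m, nrow = length(lv), dimnames = list(lv, NULL))
  }
  path_m <- grab("pathogenic_thresholds")
  ben_m <- grab("benign_thresholds")
  reach_path <- rowMeans(!is.na(path_m))
  reach_ben <- rowMeans(!is.na(ben_m))
  pct <- function(m, keep, p) {
    out <- vapply(lv[keep], function(l) {
      stats::quantile(m[l, ], p, na.rm = TRUE, names = FALSE)
    }, numeric(1))
    names(out) <- lv[keep]
    out
  }
  final_path <- pct(path_m, reach_path >= reach, 0.05)
  final_ben <- pct(ben_m, reach_ben >= reach, 0.95)
  priors <- vapply(iterations, function(r) r$prior, numeric(1))
  structure(list(
    n_iterations = length(iterations),
    valid_iterations = n_valid,
    priors = priors,
    c_values = vapply(iterations, function(r) r$c, numeric(1)),
    per_level_thresholds = list(pathogenic = path_m, benign = ben_m),
    reach_fraction = list(pathogenic = reach_path, benign = reach_ben),
    final_thresholds = list(pathogenic = final_path, benign = final_ben),
    reach = reach,
    iterations = iterations
  ), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap calibration: %d iterations (%d valid)\n",
              x$n_iterations, x$valid_iterations))
  pr <- x$priors[!is.na(x$priors)]
  if (length(pr)) {
    cat(sprintf("  prior: median %.4g (90%% interval %.4g-%.4g)\n",
                stats::median(pr), stats::quantile(pr, 0.05, names = FALSE),
                stats::quantile(pr, 0.95, names = FALSE)))
  }
  show <- function(thr, dir, sign) {
    if (!length(thr)) {
      cat(sprintf("  %s: no level reached\n", dir))
    } else {
      cat(sprintf("  %s: %s\n", dir,
                  paste(sprintf("%+d -> %.4g", sign * as.integer(names(thr)), thr),
                        collapse = ", ")))
    }
  }
  show(x$final_thresholds$pathogenic, "pathogenic", 1L)
  show(x$final_thresholds$benign, "benign", -1L)
  invisible(x)
}

#' Out-of-bag modal evidence assignment
#'
#' For each variant, evidence points are collected from every valid bootstrap
#' iteration whose resample did not include the variant, each using that
#' iteration's own thresholds; the variant's out-of-bag assignment is the
#' mode of those points. Ties are broken toward 0 (the tied value with the
#' smallest magnitude; an exact cross-direction magnitude tie returns 0).
#'
#' @param scores Named numeric vector: assay score per variant identifier.
#' @param summary A `bootstrap_summary` whose iterations retained `members`.
#' @return Data frame with `variant_id`, `points` (NA when the variant was in
#'   every valid iteration) and `n_models` (number of contributing
#'   iterations).
#' @export
oob_assign <- function(scores, summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  if (is.null(names(scores)) || any(names(scores) == "")) {
    stop("'scores' must be a named vector of variant scores", call. = FALSE)
  }
  valid_iters <- Filter(function(r) isTRUE(r$valid), summary$iterations)
  if (!length(valid_iters) || is.null(valid_iters[[1]]$members)) {
    stop("bootstrap summary lacks per-iteration membership records", call. = FALSE)
  }
  res <- lapply(names(scores), function(id) {
    pts <- integer(0)
    for (r in valid_iters) {
      if (id %in% unlist(r$members, use.names = FALSE)) next
      pts <- c(pts, assign_points_maps(scores[[id]],
                                       r$pathogenic_thresholds,
                                       r$benign_thresholds))
    }
    if (!length(pts)) return(c(NA_integer_, 0L))
    c(modal_points(pts), length(pts))
  })
  data.frame(variant_id = names(scores),
             points = vapply(res, `[`, integer(1), 1L),
             n_models = vapply(res, `[`, integer(1), 2L),
             row.names = NULL)
}

# Mode with ties broken toward 0; a residual +x / -x tie yields 0.
modal_points <- function(pts) {
  tab <- table(pts)
  cand <- as.integer(names(tab)[tab == max(tab)])
  if (length(cand) == 1L) return(cand)
  amin <- min(abs(cand))
  cand <- cand[abs(cand) == amin]
  if (length(cand) == 1L) cand else 0L
}
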