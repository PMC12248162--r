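#' Configuration for the synthetic assay-data generator
#'
#' Describes the exact sampling model the calibration assumes: every labeled
#' sample draws from a shared pair of skew-normal components with a
#' sample-specific abnormal weight. Setting `target_prior` overrides the
#' reference-sample weight via the mixture identity
#' `wG = prior * wP + (1 - prior) * wB`, so the generator's implied prior of
#' pathogenicity is exactly `target_prior`.
#'
#' @param theta_abnormal,theta_normal `sn_params` of the two components.
#' @param weights Named numeric in `[0, 1]` with entries `P`, `B`, `G` and
#'   optionally `S`; must satisfy `weights["P"] > weights["B"]` (the assay
#'   validity assumption).
#' @param sizes Named positive integers: number of variants per sample.
#' @param seed Integer seed; generation is byte-reproducible.
#' @param target_prior Optional prior in `(0, 1)` used to derive `wG`.
#' @return A `generator_config`.
#' @export
generator_config <- function(theta_abnormal, theta_normal,
                             weights, sizes, seed = 1L, target_prior = NULL) {
  stopifnot(inherits(theta_abnormal, "sn_params"),
            inherits(theta_normal, "sn_params"))
  need <- c("P", "B", "G")
  if (!all(need %in% names(weights))) {
    stop("weights must name samples P, B and G", call. = FALSE)
  }
  if (any(weights < 0 | weights > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (weights[["P"]] <= weights[["B"]]) {
    stop("weights must satisfy P > B (pathogenic variants more often abnormal)",
         call. = FALSE)
  }
  if (!is.null(target_prior)) {
    assert_scalar_number(target_prior, "target_prior")
    if (target_prior <= 0 || target_prior >= 1) {
      stop("'target_prior' must lie in (0, 1)", call. = FALSE)
    }
    weights[["G"]] <- target_prior * weights[["P"]] +
      (1 - target_prior) * weights[["B"]]
  }
  keys <- intersect(c("P", "B", "G", "S"), names(sizes))
  if (!all(need %in% keys)) stop("sizes must name samples P, B and G", call. = FALSE)
  if (any(sizes[keys] < 1 | sizes[keys] != floor(sizes[keys]))) {
    stop("sizes must be positive integers", call. = FALSE)
  }
  keys <- keys[keys != "S" | "S" %in% names(weights)]
  structure(list(theta_abnormal = theta_abnormal, theta_normal = theta_normal,
                 weights = weights[intersect(c("P", "B", "G", "S"), names(weights))],
                 sizes = sizes[keys], seed = as.integer(seed)),
            class = "generator_config")
}

SAMPLE_TO_LABEL <- c(P = "PLP", B = "BLB", G = "REF", S = "SYN")

#' Generate a labeled synthetic assay dataset
#'
#' For each sample, each variant's score is drawn from the abnormal component
#' with the sample's weight and from the normal component otherwise, using
#' the constructive skew-normal representation. The returned truth sidecar
#' records the per-variant component indicators, the true weights and the
#' implied prior, and is kept separate from the dataset so the fitting
#' pipeline can never consume it accidentally.
#'
#' @param config A `generator_config`.
#' @return List with `dataset` (an `assay_dataset` with columns
#'   `variant_id`, `score`, `label`) and `truth` (list: `component` data
#'   frame, `weights`, `prior`, `seed`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  va <- alt_vec(config$theta_abnormal)
  vn <- alt_vec(config$theta_normal)
  with_seed(config$seed, {
    parts <- lapply(names(config$sizes), function(k) {
      n <- config$sizes[[k]]
      abnormal <- stats::runif(n) < config$weights[[k]]
      t0 <- abs(stats::rnorm(n))
      u <- stats::rnorm(n)
      score <- ifelse(abnormal,
                      va[1] + va[2] * t0 + sqrt(va[3]) * u,
                      vn[1] + vn[2] * t0 + sqrt(vn[3]) * u)
      data.frame(variant_id = sprintf("%s_%04d", SAMPLE_TO_LABEL[[k]], seq_len(n)),
                 score = score,
                 label = SAMPLE_TO_LABEL[[k]],
                 abnormal = abnormal,
                 stringsAsFactors = FALSE)
    })
    all <- do.call(rbind, parts)
    w <- config$weights
    prior <- (w[["G"]] - w[["B"]]) / (w[["P"]] - w[["B"]])
    list(dataset = new_assay_dataset(all[, c("variant_id", "score", "label")],
                                     metadata = list(source = "synthetic")),
         truth = list(component = all[, c("variant_id", "abnormal")],
                      weights = w, prior = unname(prior), seed = config$seed))
  })
}

#' Write a synthetic dataset and its truth sidecar
#'
#' @param generated Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the two files (`<name>.csv`,
#'   `<name>_truth.yaml`).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_synthetic <- function(generated, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, paste0(name, ".csv"))
  truth_path <- file.path(dir, paste0(name, "_truth.yaml"))
  write_dataset(generated$dataset, data_path)
  tr <- generated$truth
  yaml::write_yaml(list(seed = tr$seed,
                        prior = tr$prior,
                        weights = as.list(tr$weights),
                        abnormal_ids = tr$component$variant_id[tr$component$abnormal]),
                   truth_path)
  invisible(c(data = data_path, truth = truth_path))
}

#' Canonical synthetic study configurations
#'
#' Four generator configurations spanning the regimes the calibration must
#' handle:
#' \describe{
#'   \item{well_separated}{Cleanly separated components, 2000 variants per
#'     sample, weights `wP = 0.9`, `wB = 0.05`, `wG = 0.135` (implied prior
#'     0.1) and `wS = 0.02` — the reference study condition used throughout
#'     the test suite.}
#'   \item{overlapping_pathogenic}{Same components but `wP = 0.45`: more than
#'     half of the pathogenic variants score like synonymous variants
#'     (an assay blind to part of the disease mechanism), so the calibration
#'     should assign no benign evidence level.}
#'   \item{tiny_blb}{Only 8 benign controls (with 205 pathogenic and 267
#'     reference variants, the shape of a real lipid-phosphatase activity
#'     dataset), no synonymous sample.}
#'   \item{no_synonymous}{Moderate sizes with the synonymous sample absent.}
#' }
#'
#' @param seed Base seed; each fixture offsets it deterministically.
#' @return Named list of `generator_config` objects (length at least 4).
#' @export
make_fixture_suite <- function(seed = 1L) {
  theta_a <- sn_params(-3, 1, 0.2)
  theta_n <- sn_params(0, 1, -0.2)
  list(
    well_separated = generator_config(
      theta_a, theta_n,
      weights = c(P = 0.9, B = 0.05, G = 0.135, S = 0.02),
      sizes = c(P = 2000, B = 2000, G = 2000, S = 2000),
      seed = seed),
    overlapping_pathogenic = generator_config(
      theta_a, theta_n,
      weights = c(P = 0.45, B = 0.05, G = 0.09, S = 0.02),
      sizes = c(P = 2000, B = 2000, G = 2000, S = 2000),
      seed = seed + 1L),
    tiny_blb = generator_config(
      theta_a, theta_n,
      weights = c(P = 0.9, B = 0.05, G = 0.135),
      sizes = c(P = 205, B = 8, G = 267),
      seed = seed + 2L),
    no_synonymous = generator_config(
      theta_a, theta_n,
      weights = c(P = 0.9, B = 0.05, G = 0.135),
      sizes = c(P = 1000, B = 1000, G = 1000),
      seed = seed + 3L)
  )
}
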