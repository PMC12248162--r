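# Shared fixtures, memoized so expensive fits are computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(value), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

truth_theta_a <- function() sn_params(-3, 1, 0.2)
truth_theta_n <- function() sn_params(0, 1, -0.2)

# Reference study condition: well-separated components, 2000 variants per
# sample, weights implying a prior of 0.1.
ws_config <- function(seed = 1L) {
  generator_config(truth_theta_a(), truth_theta_n(),
                   weights = c(P = 0.9, B = 0.05, G = 0.135, S = 0.02),
                   sizes = c(P = 2000, B = 2000, G = 2000, S = 2000),
                   seed = seed)
}

ws_samples <- function(seed = 1L) {
  memo(paste0("ws_samples_", seed), {
    gen <- generate_dataset(ws_config(seed))
    ds <- gen$dataset
    sample_set(
      plp = stats::setNames(ds$score[ds$label == "PLP"], ds$variant_id[ds$label == "PLP"]),
      blb = stats::setNames(ds$score[ds$label == "BLB"], ds$variant_id[ds$label == "BLB"]),
      ref = stats::setNames(ds$score[ds$label == "REF"], ds$variant_id[ds$label == "REF"]),
      syn = stats::setNames(ds$score[ds$label == "SYN"], ds$variant_id[ds$label == "SYN"]))
  })
}

ws_fit <- function(seed = 1L, n_restarts = 5L) {
  memo(paste0("ws_fit_", seed, "_", n_restarts),
       fit_mixture(ws_samples(seed), n_restarts = n_restarts, seed = 100L + seed))
}

# Fits of 20 generator replicates under the reference condition (reduced
# restarts); used by the recovery, monotonicity and ascent checks.
recovery_fits <- function(n_rep = 20L) {
  memo(paste0("recovery_fits_", n_rep), {
    lapply(seq_len(n_rep), function(r) {
      ss <- ws_samples(100L + r)
      fit_mixture(ss, n_restarts = 10L, seed = 5000L + r * 11L)
    })
  })
}

# Small non-synonymous sample set for cheap unit tests.
small_samples <- function(seed = 3L) {
  memo(paste0("small_samples_", seed), {
    cfg <- generator_config(truth_theta_a(), truth_theta_n(),
                            weights = c(P = 0.9, B = 0.05, G = 0.135),
                            sizes = c(P = 300, B = 300, G = 300), seed = seed)
    gen <- generate_dataset(cfg)
    ds <- gen$dataset
    sample_set(
      plp = ds$score[ds$label == "PLP"],
      blb = ds$score[ds$label == "BLB"],
      ref = ds$score[ds$label == "REF"])
  })
}

toy_scores_csv <- function(path) {
  writeLines(c(
    "variant_id,rep1,rep2,label,spliceai,annotation",
    "p.V1A,0.10,0.30,P/LP,0.10,abnormal",
    "p.V2A,1.00,,B/LB,0.50,normal",
    "p.V3A,0.80,1.20,gnomAD,0.51,normal",
    "p.V4A,0.95,1.05,synonymous,,normal",
    "p.V5A,0.40,0.60,VUS,0.20,indeterminate"
  ), path)
  path
}

toy_mapping <- function() {
  list(variant_id = "variant_id", scores = c("rep1", "rep2"),
       label = "label", splice_score = "spliceai",
       author_annotation = "annotation")
}
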