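CANONICAL_LABELS <- c("PLP", "BLB", "REF", "SYN", "VUS", "UNLABELED")
LABEL_PRECEDENCE <- c(PLP = 1, BLB = 2, SYN = 3, REF = 4, VUS = 5, UNLABELED = 6)

normalize_label <- function(x) {
  y <- toupper(gsub("[ /._-]", "", as.character(x)))
  map <- c(PLP = "PLP", PATHOGENIC = "PLP", LP = "PLP",
           BLB = "BLB", BENIGN = "BLB", LB = "BLB",
           REF = "REF", GNOMAD = "REF", REFERENCE = "REF", POPULATION = "REF",
           SYN = "SYN", SYNONYMOUS = "SYN",
           VUS = "VUS", UNCERTAIN = "VUS",
           UNLABELED = "UNLABELED", NONE = "UNLABELED")
  out <- unname(map[y])
  out[is.na(x) | y == ""] <- "UNLABELED"
  bad <- is.na(out)
  if (any(bad)) {
    stop("unrecognized label value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

# Delimited-text reader with comma/tab auto-detection.
read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    na.strings = c("NA", ""))
}

#' Read an assay score table
#'
#' Parses a delimited text file (comma or tab, auto-detected unless `sep` is
#' given) of per-variant assay scores, with one or more replicate score
#' columns, into an `assay_dataset`. Replicate scores may be missing for
#' individual replicates but not for all replicates of a variant.
#'
#' @param path Path to the score table.
#' @param mapping Column mapping: a list with `variant_id` (column name),
#'   `scores` (character vector of replicate score columns), and optional
#'   `label`, `splice_score` and `author_annotation` column names.
#' @param sep Optional field separator override.
#' @param metadata Optional named list (gene, assay, provenance) stored on
#'   the dataset.
#' @return An `assay_dataset`: a data frame with columns `variant_id`,
#'   `score_<i>` replicates and any mapped optional columns.
#' @export
read_scores <- function(path, mapping, sep = NULL, metadata = list()) {
  raw <- read_delim_auto(path, sep)
  need <- c(mapping$variant_id, mapping$scores, mapping$label,
            mapping$splice_score, mapping$author_annotation)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("score table is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "),
         " (available: ", paste(names(raw), collapse = ", "), ")",
         call. = FALSE)
  }
  ids <- as.character(raw[[mapping$variant_id]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate variant_id value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  score_mat <- vapply(mapping$scores, function(col) {
    v <- raw[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric score in column '%s', row %d ('%s')",
                     col, bad[1], v[bad[1]]), call. = FALSE)
      }
      num
    } else {
      as.numeric(v)
    }
  }, numeric(nrow(raw)))
  score_mat <- matrix(score_mat, nrow = nrow(raw))
  all_missing <- rowSums(is.finite(score_mat)) == 0L
  if (any(all_missing)) {
    stop("variant(s) with no finite replicate score: ",
         paste(ids[all_missing], collapse = ", "), call. = FALSE)
  }
  ds <- data.frame(variant_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(mapping$scores)) ds[[paste0("score_", i)]] <- score_mat[, i]
  if (!is.null(mapping$label)) ds$label <- normalize_label(raw[[mapping$label]])
  if (!is.null(mapping$splice_score)) {
    sp <- as.numeric(raw[[mapping$splice_score]])
    if (any(sp < 0 | sp > 1, na.rm = TRUE)) {
      stop("splice scores must lie in [0, 1]", call. = FALSE)
    }
    ds$splice_score <- sp
  }
  if (!is.null(mapping$author_annotation)) {
    ds$author_annotation <- as.character(raw[[mapping$author_annotation]])
  }
  new_assay_dataset(ds, metadata)
}

new_assay_dataset <- function(df, metadata = list()) {
  structure(df, metadata = metadata,
            class = c("assay_dataset", "data.frame"))
}

#' @export
print.assay_dataset <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("assay_dataset: %d variants%s\n", nrow(x),
              if (length(md)) paste0(" (", paste(names(md), unlist(md),
                                                 sep = "=", collapse = ", "), ")")
              else ""))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

score_columns <- function(ds) grep("^score(_[0-9]+)?$", names(ds), value = TRUE)

#' Average replicate scores
#'
#' Collapses the replicate score columns into a single `score` column, the
#' arithmetic mean over the finite replicates of each variant (missing
#' replicates are ignored).
#'
#' @param dataset An `assay_dataset`.
#' @return The dataset with a single `score` column.
#' @export
average_replicates <- function(dataset) {
  cols <- score_columns(dataset)
  if (!length(cols)) stop("dataset has no score columns", call. = FALSE)
  m <- as.matrix(as.data.frame(dataset)[, cols, drop = FALSE])
  sc <- rowMeans(m, na.rm = TRUE)
  ds <- as.data.frame(dataset)
  ds <- ds[, setdiff(names(ds), cols), drop = FALSE]
  ds$score <- sc
  ds <- ds[, c("variant_id", "score",
               setdiff(names(ds), c("variant_id", "score"))), drop = FALSE]
  new_assay_dataset(ds, attr(dataset, "metadata"))
}

#' Remove likely splice-disrupting variants
#'
#' Drops variants whose precomputed splice-effect score (e.g. the maximum
#' SpliceAI delta over acceptor/donor loss and gain) is strictly greater
#' than `threshold`. Variants without a splice score are retained; if the
#' dataset has no splice-score column at all, it is returned unchanged with
#' a warning.
#'
#' @param dataset An `assay_dataset`.
#' @param threshold Removal threshold in `[0, 1]`, default 0.5.
#' @return The filtered dataset; the number of removed records is reported
#'   via `message()`.
#' @export
splice_filter <- function(dataset, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) {
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  }
  if (!"splice_score" %in% names(dataset)) {
    warning("no splice_score column present; dataset returned unchanged")
    return(dataset)
  }
  drop <- !is.na(dataset$splice_score) & dataset$splice_score > threshold
  if (any(drop)) {
    message(sprintf("splice_filter: removed %d variant(s) with splice score > %g",
                    sum(drop), threshold))
  }
  new_assay_dataset(as.data.frame(dataset)[!drop, , drop = FALSE],
                    attr(dataset, "metadata"))
}

#' Read a variant label table
#'
#' @param path Delimited text file of per-variant labels.
#' @param mapping List with `variant_id` and `label` column names.
#' @param sep Optional separator override.
#' @return Data frame with `variant_id` and canonical `label` columns (a
#'   variant may appear several times; see [attach_labels()]).
#' @export
read_labels <- function(path, mapping = list(variant_id = "variant_id",
                                             label = "label"), sep = NULL) {
  raw <- read_delim_auto(path, sep)
  missing_cols <- setdiff(c(mapping$variant_id, mapping$label), names(raw))
  if (length(missing_cols)) {
    stop("label table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data.frame(variant_id = as.character(raw[[mapping$variant_id]]),
             label = normalize_label(raw[[mapping$label]]),
             stringsAsFactors = FALSE)
}

#' Attach labels to a dataset, resolving conflicts by precedence
#'
#' A variant carrying several labels (e.g. a population-reference variant
#' that is also benign in ClinVar) receives the highest-precedence one,
#' `PLP > BLB > SYN > REF > VUS`, so that every variant belongs to exactly
#' one sample (the bootstrap requires the observation sets to be disjoint).
#' Relabeling is reported via `message()`.
#'
#' @param dataset An `assay_dataset`.
#' @param labels Data frame from [read_labels()].
#' @return The dataset with a `label` column; unmatched variants are
#'   `UNLABELED`.
#' @export
attach_labels <- function(dataset, labels) {
  lab <- labels
  lab$rank <- LABEL_PRECEDENCE[lab$label]
  lab <- lab[order(lab$variant_id, lab$rank), ]
  multi <- unique(lab$variant_id[duplicated(lab$variant_id)])
  if (length(multi)) {
    message(sprintf(
      "attach_labels: %d variant(s) had multiple labels; kept the highest-precedence label (PLP > BLB > SYN > REF)",
      length(multi)))
  }
  lab <- lab[!duplicated(lab$variant_id), ]
  idx <- match(dataset$variant_id, lab$variant_id)
  ds <- as.data.frame(dataset)
  ds$label <- ifelse(is.na(idx), "UNLABELED", lab$label[idx])
  new_assay_dataset(ds, attr(dataset, "metadata"))
}

#' Assemble the mixture-model samples from a labeled dataset
#'
#' Partitions the (replicate-averaged) scores by canonical label into the
#' `P` (P/LP), `B` (B/LB), `G` (reference) and optional `S` (synonymous)
#' samples. VUS and unlabeled variants are never used for fitting; their
#' scores are attached as the `"holdout"` attribute for downstream evidence
#' assignment.
#'
#' @param dataset A labeled `assay_dataset` (averaged automatically if it
#'   still carries replicate columns).
#' @return A `sample_set` with named score vectors.
#' @export
build_sample_set <- function(dataset) {
  if (!"label" %in% names(dataset)) {
    stop("dataset has no 'label' column; attach labels first", call. = FALSE)
  }
  if (!"score" %in% names(dataset)) dataset <- average_replicates(dataset)
  ds <- as.data.frame(dataset)
  take <- function(lbl) {
    sub <- ds[ds$label == lbl, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    stats::setNames(sub$score, sub$variant_id)
  }
  plp <- take("PLP"); blb <- take("BLB"); ref <- take("REF")
  if (is.null(plp)) stop("empty mandatory sample: P/LP", call. = FALSE)
  if (is.null(blb)) stop("empty mandatory sample: B/LB", call. = FALSE)
  if (is.null(ref)) stop("empty mandatory sample: reference (REF)", call. = FALSE)
  ss <- sample_set(plp, blb, ref, syn = take("SYN"))
  hold <- ds[ds$label %in% c("VUS", "UNLABELED"), , drop = FALSE]
  attr(ss, "holdout") <- stats::setNames(hold$score, hold$variant_id)
  ss
}

#' Write an assay dataset as delimited text
#'
#' @param dataset An `assay_dataset`.
#' @param path Output path (CSV).
#' @return `path`, invisibly. Reading the file back with [read_scores()]
#'   reproduces the records.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
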