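#' Normalized L2 distance between two CDF vectors
#'
#' `d(F, G) = ||F - G||_2 / (||F||_2 + ||G||_2)`, evaluated on two vectors of
#' CDF values at common points; bounded in `[0, 1]`, and 0 iff the vectors
#' are identical.
#'
#' @param f,g Numeric vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
normalized_cdf_distance <- function(f, g) {
  if (length(f) != length(g)) stop("'f' and 'g' must have equal length", call. = FALSE)
  if (!length(f)) stop("empty CDF vectors", call. = FALSE)
  num <- sqrt(sum((f - g)^2))
  den <- sqrt(sum(f^2)) + sqrt(sum(g^2))
  if (den == 0) return(0)
  num / den
}

#' Fit-quality distance between a sample and its fitted mixture CDF
#'
#' Evaluates the empirical CDF of a labeled sample and the fitted mixture
#' CDF for that sample at all unique observed scores, and returns their
#' normalized L2 (p = 2) distance. Values are in `[0, 1]`; on well-specified
#' data the distances computed on the reference and synonymous samples are
#' small (rule of thumb: median below 0.2 across bootstrap fits indicates an
#' acceptable fit).
#'
#' @param scores Numeric score vector of one sample (at least 2 unique
#'   values).
#' @param fit A `mixture_fit`.
#' @param sample Which sample's mixing weight to use: `"P"`, `"B"`, `"G"`
#'   or `"S"`.
#' @return Scalar distance in `[0, 1]`.
#' @export
cdf_distance <- function(scores, fit, sample = c("G", "S", "P", "B")) {
  sample <- match.arg(sample)
  if (!length(scores)) stop("empty sample", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("need at least 2 unique scores", call. = FALSE)
  stopifnot(inherits(fit, "mixture_fit"))
  w <- fit$weights[[sample]]
  if (is.null(w)) stop("fit has no weight for sample ", sample, call. = FALSE)
  emp <- stats::ecdf(scores)(u)
  mod <- w * sn_cdf(u, fit$theta_abnormal) +
    (1 - w) * sn_cdf(u, fit$theta_normal)
  normalized_cdf_distance(emp, mod)
}

#' Build a 2x3 clinical-class contingency table
#'
#' Rows are the clinical classes (P/LP, B/LB); columns are the assigned
#' evidence direction (pathogenic, indeterminate, benign).
#'
#' @param plp,blb Length-3 nonnegative integer vectors of counts in column
#'   order (pathogenic, indeterminate, benign).
#' @return Integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(plp, blb) {
  m <- rbind(PLP = plp, BLB = blb)
  if (any(m < 0) || any(m != floor(m))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  colnames(m) <- c("pathogenic", "indeterminate", "benign")
  structure(m, class = c("contingency_table", class(m)))
}

#' Contingency table from per-variant evidence points and labels
#'
#' @param points Integer vector of signed evidence points.
#' @param labels Character vector of canonical labels (`PLP`/`BLB`; other
#'   labels are dropped).
#' @return A `contingency_table`.
#' @export
contingency_from_assignments <- function(points, labels) {
  keep <- labels %in% c("PLP", "BLB") & !is.na(points)
  points <- points[keep]; labels <- labels[keep]
  direction <- ifelse(points > 0, "pathogenic",
                      ifelse(points < 0, "benign", "indeterminate"))
  cnt <- function(lbl) {
    vapply(c("pathogenic", "indeterminate", "benign"),
           function(d) sum(labels == lbl & direction == d), numeric(1))
  }
  contingency_table(cnt("PLP"), cnt("BLB"))
}

#' Global LR+ and diagnostic odds ratio of a dichotomized table
#'
#' Dichotomizes the three-way direction columns as the positive direction
#' versus the rest. For `positive_class = "pathogenic"` the positive clinical
#' row is P/LP; for `"benign"` it is B/LB. Then
#' `LR+ = (TP / positives) / (FP / negatives)` and
#' `DOR = TP * TN / (FN * FP)`.
#'
#' @param table A `contingency_table` (or 2x3 matrix with rows PLP, BLB and
#'   columns pathogenic, indeterminate, benign).
#' @param positive_class `"pathogenic"` or `"benign"`.
#' @param continuity Add 0.5 to every cell before computing the ratios
#'   (off by default); without it a zero denominator yields `NA` with a
#'   warning.
#' @return List with `lr_plus` and `dor`.
#' @export
lr_dor <- function(table, positive_class = c("pathogenic", "benign"),
                   continuity = FALSE) {
  positive_class <- match.arg(positive_class)
  m <- unclass(table)
  stopifnot(nrow(m) == 2L, ncol(m) == 3L)
  pos_row <- if (positive_class == "pathogenic") 1L else 2L
  neg_row <- 3L - pos_row
  pos_col <- match(positive_class, colnames(m))
  tp <- m[pos_row, pos_col]
  fn <- sum(m[pos_row, -pos_col])
  fp <- m[neg_row, pos_col]
  tn <- sum(m[neg_row, -pos_col])
  if (continuity) {
    tp <- tp + 0.5; fn <- fn + 0.5; fp <- fp + 0.5; tn <- tn + 0.5
  }
  n_pos <- tp + fn
  n_neg <- fp + tn
  if (n_pos == 0 || n_neg == 0 || fp == 0 || fn == 0) {
    if (fp == 0 || n_pos == 0 || n_neg == 0) {
      warning("undefined LR+/DOR: zero denominator (consider continuity = TRUE)")
      return(list(lr_plus = NA_real_, dor = NA_real_))
    }
    warning("undefined DOR: zero denominator (consider continuity = TRUE)")
    return(list(lr_plus = (tp / n_pos) / (fp / n_neg), dor = NA_real_))
  }
  list(lr_plus = (tp / n_pos) / (fp / n_neg),
       dor = (tp * tn) / (fn * fp))
}
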