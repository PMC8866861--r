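#' Quantile normalization across samples
#'
#' Forces every sample column onto a common reference distribution: the mean
#' of the per-sample sorted intensity vectors. Rank order within each column
#' is preserved; tied values within a column receive the mean of the
#' reference values their rank range spans. Idempotent: applying it twice
#' equals applying it once.
#'
#' @param x an [expr_set()] at stage `"raw"`, or a bare numeric matrix
#'   (genes x samples) for ad-hoc use.
#' @return same shape as the input; the `expr_set` method returns stage
#'   `"quantile"`.
#' @examples
#' quantile_normalize(cbind(a = c(1, 3), b = c(2, 4)))  # both cols 1.5, 3.5
#' @export
quantile_normalize <- function(x) UseMethod("quantile_normalize")

#' @export
quantile_normalize.expr_set <- function(x) {
  stopifnot_stage(x, "raw")
  x$values <- quantile_normalize(x$values)
  x$stage <- "quantile"
  x
}

#' @export
quantile_normalize.matrix <- function(x) {
  if (ncol(x) < 2L)
    stop("quantile normalization undefined for a single sample",
         call. = FALSE)
  ref <- rowMeans(apply(x, 2, sort))
  csum <- c(0, cumsum(ref))
  out <- x
  for (j in seq_len(ncol(x))) {
    rmin <- rank(x[, j], ties.method = "min")
    rmax <- rank(x[, j], ties.method = "max")
    out[, j] <- (csum[rmax + 1L] - csum[rmin]) / (rmax - rmin + 1L)
  }
  out
}

#' Per-gene z-score transformation
#'
#' Centers and scales each gene row to mean 0 and sample standard deviation
#' 1 (denominator n-1), so genes can be compared on one scale. Constant rows
#' map to all-zero rather than NaN and flow through as trivially
#' non-significant.
#'
#' @param x an [expr_set()] at stage `"quantile"`, or a numeric matrix.
#' @return same shape; the `expr_set` method returns stage `"zscored"`.
#' @export
zscore_genes <- function(x) UseMethod("zscore_genes")

#' @export
zscore_genes.expr_set <- function(x) {
  stopifnot_stage(x, "quantile")
  x$values <- zscore_genes(x$values)
  x$stage <- "zscored"
  x
}

#' @export
zscore_genes.matrix <- function(x) {
  if (ncol(x) < 2L) stop("z-scoring needs >= 2 samples", call. = FALSE)
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Signed logarithmic scaling
#'
#' Variance-stabilizing transform applied to the z-scored matrix:
#' `x -> sign(x) * log(1 + |x|)`. Strictly monotone, odd, and therefore
#' sign- and rank-preserving per gene and per sample -- downstream rank
#' tests are unchanged by this step.
#'
#' @param x an [expr_set()] at stage `"zscored"`, or a numeric vector or
#'   matrix.
#' @return same shape; the `expr_set` method returns stage `"logscaled"`.
#' @export
signed_log_scale <- function(x) UseMethod("signed_log_scale")

#' @export
signed_log_scale.expr_set <- function(x) {
  stopifnot_stage(x, "zscored")
  x$values <- signed_log_scale(x$values)
  x$stage <- "logscaled"
  x
}

#' @export
signed_log_scale.default <- function(x) sign(x) * log1p(abs(x))

#' Run the full normalization chain
#'
#' `raw -> quantile -> zscored -> logscaled` in the fixed pipeline order.
#'
#' @param es an [expr_set()] at stage `"raw"`.
#' @return an [expr_set()] at stage `"logscaled"`.
#' @export
normalize_chain <- function(es) {
  signed_log_scale(zscore_genes(quantile_normalize(es)))
}

#' Per-condition log2 fold changes against the untreated control
#'
#' Computed on raw intensities (ratio of arithmetic condition means to the
#' control mean); z-scores have no ratio interpretation. Also reports, per
#' arm, the signed entry of greatest magnitude across the dose series
#' (max-|log2FC|), the convention used when a single fold change is quoted
#' per gene per arm.
#'
#' @param es an [expr_set()] at stage `"raw"`.
#' @return object of class `fold_change_table`: list with `log2fc` (gene x
#'   treatment-condition matrix), `arm_max` (gene x arm matrix of the
#'   signed max-magnitude entries) and `conditions` (condition/arm/dose
#'   lookup).
#' @export
fold_changes <- function(es) {
  stopifnot_stage(es, "raw")
  design <- es$design
  ctrl <- design_samples(design, arm = "control")
  if (!length(ctrl)) stop("control condition absent", call. = FALSE)
  ctrl_mean <- rowMeans(es$values[, ctrl, drop = FALSE])
  conds <- design_conditions(design)
  treat <- conds[conds$arm != "control", , drop = FALSE]
  l2 <- sapply(treat$condition, function(cc) {
    m <- rowMeans(es$values[, design_samples(design, condition = cc),
                            drop = FALSE])
    log2(m / ctrl_mean)
  })
  l2 <- matrix(l2, nrow = nrow(es$values),
               dimnames = list(rownames(es$values), treat$condition))
  arm_max <- sapply(design$arms, function(a) {
    sub <- l2[, treat$condition[treat$arm == a], drop = FALSE]
    sub[cbind(seq_len(nrow(sub)), max.col(abs(sub), ties.method = "first"))]
  })
  arm_max <- matrix(arm_max, nrow = nrow(es$values),
                    dimnames = list(rownames(es$values), design$arms))
  structure(list(log2fc = l2, arm_max = arm_max,
                 conditions = treat), class = "fold_change_table")
}
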