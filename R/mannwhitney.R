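#' Mann-Whitney U test (exact or normal approximation)
#'
#' Rank-sum test of two independent samples with tie mid-ranks. Exact mode
#' enumerates the full permutation null of the rank sum over all
#' `choose(n1 + n2, n1)` group labelings of the observed (tied) ranks; the
#' two-sided p-value is `min(1, 2 * min(lower tail, upper tail))`, both
#' tails including the observed statistic. Approximate mode uses the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction. `"auto"` picks exact when `n1 + n2 <= 20`.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param mode `"exact"`, `"approx"` or `"auto"`.
#' @return list with `U` (the U statistic of `a`), `p` (two-sided),
#'   `method` used.
#' @examples
#' mann_whitney(1:3, 4:15)$p  # 2/455, the most extreme 3-vs-12 labeling
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "approx"
  r2 <- as.integer(round(2 * rank(c(a, b))))  # doubled mid-ranks: integers
  W2 <- sum(r2[seq_len(n1)])
  U <- (W2 - n1 * (n1 + 1L)) / 2  # W - n1(n1+1)/2 on the original scale

  if (mode == "exact") {
    combos <- mw_combos(n1, n)
    tied <- anyDuplicated(r2) > 0L
    if (!tied) {
      null2 <- mw_null_untied(n1, n)  # cached: doubled rank-sums 2*(1..n)
    } else {
      null2 <- colSums(matrix(r2[combos], nrow = n1))
    }
    lo <- sum(null2 <= W2) / length(null2)
    hi <- sum(null2 >= W2) / length(null2)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- n1 * n2 / 2
    tab <- tabulate(r2, nbins = max(r2))
    ties <- tab[tab > 1L]
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "approx"))
    d <- U - mu
    z <- sign(d) * max(0, abs(d) - 0.5) / sqrt(sigma2)  # continuity corr.
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p, method = mode)
}

# caches for exact enumeration, keyed by "n1:n"
.mw_cache <- new.env(parent = emptyenv())

mw_combos <- function(n1, n) {
  key <- paste0("c", n1, ":", n)
  if (is.null(.mw_cache[[key]]))
    .mw_cache[[key]] <- utils::combn(n, n1)
  .mw_cache[[key]]
}

mw_null_untied <- function(n1, n) {
  key <- paste0("u", n1, ":", n)
  if (is.null(.mw_cache[[key]]))
    .mw_cache[[key]] <- colSums(matrix((2L * seq_len(n))[mw_combos(n1, n)],
                                       nrow = n1))
  .mw_cache[[key]]
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `p_adj(i) = min over j >= i of min(1, m * p(j) / j)` over the ascending
#' order, mapped back to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}
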