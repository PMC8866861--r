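#' One-way ANOVA with Fisher LSD post hoc and compact letter display
#'
#' Omnibus one-way ANOVA followed by all-pairs Fisher least-significant-
#' difference comparisons: pairwise t statistics using the pooled error
#' mean square with the error degrees of freedom. By default the LSD is
#' unprotected (pairwise comparisons run regardless of the omnibus F, the
#' behaviour of classic desktop statistics packages); set
#' `protected = TRUE` to gate on the omnibus p-value. Letters are assigned
#' by insert-and-absorb in descending-mean order: two groups share a letter
#' iff their pairwise comparison is non-significant at `alpha`.
#'
#' @param value numeric response vector.
#' @param group group labels (coerced to factor, order of appearance).
#' @param alpha pairwise significance level (default 0.05).
#' @param protected run pairwise tests only if the omnibus p <= alpha.
#' @return list with `F`, `p`, `df`, `pairwise` (matrix of pairwise
#'   p-values) and `display` (data.frame group, n, mean, se, letters).
#' @export
anova_lsd <- function(value, group, alpha = 0.05, protected = FALSE) {
  group <- factor(group, levels = unique(group))
  if (nlevels(group) < 2L) stop("need >= 2 groups", call. = FALSE)
  n_i <- tabulate(group)
  if (any(n_i < 2L))
    stop("every group needs >= 2 replicates", call. = FALSE)
  g <- nlevels(group); N <- length(value)
  means <- tapply(value, group, mean)
  ss_within <- sum(tapply(value, group, function(v) sum((v - mean(v))^2)))
  ss_between <- sum(n_i * (means - mean(value))^2)
  df1 <- g - 1L; df2 <- N - g
  mse <- ss_within / df2
  Fstat <- if (mse > 0) (ss_between / df1) / mse else
    if (ss_between > 0) Inf else 0
  p_omni <- if (is.infinite(Fstat)) 0 else
    stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  pw <- matrix(1, g, g, dimnames = list(levels(group), levels(group)))
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    se <- sqrt(mse * (1 / n_i[i] + 1 / n_i[j]))
    pij <- if (se == 0) as.numeric(means[i] == means[j]) else
      2 * stats::pt(-abs((means[i] - means[j]) / se), df2)
    pw[i, j] <- pw[j, i] <- pij
  }
  run_pairs <- !protected || p_omni <= alpha
  sig <- if (run_pairs) pw < alpha else pw < 0  # all FALSE when protected out
  diag(sig) <- FALSE

  letters <- cld_insert_absorb(sig, order(means, decreasing = TRUE))
  se_i <- sqrt(mse / n_i)
  display <- data.frame(group = levels(group), n = n_i,
                        mean = as.numeric(means), se = se_i,
                        letters = letters, stringsAsFactors = FALSE)
  list(F = Fstat, p = p_omni, df = c(df1, df2), mse = mse,
       pairwise = pw, display = display)
}

# Compact letter display by insert-and-absorb over a logical significance
# matrix. `order_idx` fixes the letter order (typically descending means;
# ties broken by group order). Guarantees: significant pairs share no
# letter; non-significant pairs share at least one.
cld_insert_absorb <- function(sig, order_idx) {
  g <- nrow(sig)
  cols <- list(seq_len(g))
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    if (!sig[i, j]) next
    hit <- which(vapply(cols, function(cc) all(c(i, j) %in% cc), logical(1)))
    for (h in hit) {
      col <- cols[[h]]
      cols[[h]] <- setdiff(col, i)
      cols[[length(cols) + 1L]] <- setdiff(col, j)
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          !(all(cols[[b]] %in% cols[[a]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  pos <- match(seq_len(g), order_idx)  # rank of each group in display order
  first <- vapply(cols, function(cc) min(pos[cc]), numeric(1))
  cols <- cols[order(first)]
  out <- character(g)
  for (ci in seq_along(cols))
    for (gi in cols[[ci]])
      out[gi] <- paste0(out[gi], letters[ci])
  out
}

#' Independent two-sample t-tests with Bonferroni correction
#'
#' Two-sided pooled-variance t-test per pair; corrected p = `min(1, m * p)`
#' with `m` at least the number of pairs tested.
#'
#' @param pairs list of two-element lists/vectors: each element
#'   `list(a, b)` with >= 2 values per side.
#' @param m number of tests in the family (default: `length(pairs)`).
#' @return data.frame: pair, t, df, p, p_bonferroni.
#' @export
ttest_bonferroni <- function(pairs, m = length(pairs)) {
  if (m < length(pairs))
    stop("m must be >= the number of pairs", call. = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    a <- pairs[[i]][[1]]; b <- pairs[[i]][[2]]
    if (length(a) < 2L || length(b) < 2L)
      stop("each side needs >= 2 values", call. = FALSE)
    df <- length(a) + length(b) - 2L
    sp2 <- ((length(a) - 1) * stats::var(a) +
            (length(b) - 1) * stats::var(b)) / df
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    tstat <- if (se == 0) 0 else (mean(a) - mean(b)) / se
    p <- if (se == 0) as.numeric(mean(a) != mean(b)) else
      2 * stats::pt(-abs(tstat), df)
    if (se == 0 && mean(a) == mean(b)) p <- 1
    data.frame(pair = i, t = tstat, df = df, p = p,
               p_bonferroni = min(1, m * p))
  })
  do.call(rbind, rows)
}

#' Per-sample Na+/K+ ratios with group summaries
#'
#' The ratio is computed per sample (paired Na and K measurements), then
#' summarized per group as mean and standard error -- the per-sample
#' convention, which differs from the ratio of group means on skewed data.
#'
#' @param na,k paired numeric vectors of Na+ and K+ concentrations.
#' @param group optional group labels.
#' @return list with `ratios` (per sample; NA where k == 0, flagged) and
#'   `summary` (data.frame group, n, mean, se) when groups are given.
#' @export
na_k_ratio <- function(na, k, group = NULL) {
  if (length(na) != length(k)) stop("na and k must be paired", call. = FALSE)
  bad <- k == 0
  if (any(bad)) warning(sum(bad), " samples with K = 0 flagged as NA")
  r <- ifelse(bad, NA_real_, na / k)
  out <- list(ratios = r)
  if (!is.null(group)) {
    group <- factor(group, levels = unique(group))
    out$summary <- do.call(rbind, lapply(levels(group), function(gl) {
      v <- r[group == gl & !is.na(r)]
      data.frame(group = gl, n = length(v), mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Fold-change summary of a metabolite table against the control mean
#'
#' Fold = mean(condition) / mean(control) per analyte and condition; also
#' reports the arm-wise maximum fold (the single number quoted per analyte
#' per arm).
#'
#' @param metab data.frame as produced by [generate_metabolites()]:
#'   analyte, condition, arm, dose, replicate, concentration.
#' @return list with `folds` (data.frame analyte, condition, arm, dose,
#'   fold) and `arm_max` (data.frame analyte, arm, max_fold).
#' @export
fold_summary <- function(metab) {
  if (any(metab$concentration <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (!"control" %in% metab$condition)
    stop("control condition absent", call. = FALSE)
  folds <- list(); arm_max <- list()
  for (an in unique(metab$analyte)) {
    sub <- metab[metab$analyte == an, , drop = FALSE]
    ctrl_mean <- mean(sub$concentration[sub$condition == "control"])
    cc <- unique(sub$condition[sub$condition != "control"])
    f <- vapply(cc, function(x)
      mean(sub$concentration[sub$condition == x]) / ctrl_mean, numeric(1))
    info <- sub[match(cc, sub$condition), c("arm", "dose")]
    folds[[an]] <- data.frame(analyte = an, condition = cc,
                              arm = info$arm, dose = info$dose, fold = f,
                              stringsAsFactors = FALSE)
    arm_max[[an]] <- do.call(rbind, lapply(unique(info$arm), function(a)
      data.frame(analyte = an, arm = a,
                 max_fold = max(f[info$arm == a]),
                 stringsAsFactors = FALSE)))
  }
  list(folds = do.call(rbind, c(folds, make.row.names = FALSE)),
       arm_max = do.call(rbind, c(arm_max, make.row.names = FALSE)))
}
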