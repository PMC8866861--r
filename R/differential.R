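#' Grouped differential call for one treatment arm
#'
#' For every gene, tests the untreated control replicates against all
#' pooled samples of one treatment arm (all doses together; 3 vs 12 in the
#' default design) with the Mann-Whitney U test on the fully normalized
#' matrix, adjusts p-values by Benjamini-Hochberg, and calls significance
#' at adjusted p below `alpha` (raw-p thresholding available via
#' `use_adjusted = FALSE`). Direction is the sign of the treated-minus-
#' control median difference on the normalized matrix and is `"none"` for
#' non-significant genes.
#'
#' @param es an [expr_set()] at stage `"logscaled"`.
#' @param arm `"NaCl"` or `"sorbitol"` (must exist in the design).
#' @param fc optional [fold_changes()] table; its signed per-arm
#'   max-|log2FC| column is carried into the result.
#' @param alpha significance threshold (default 0.01).
#' @param mode Mann-Whitney mode, see [mann_whitney()]. Note that with the
#'   default 3-vs-12 design the exact two-sided p floor is 2/455 ~ 0.0044,
#'   which caps how small BH-adjusted values can get when many genes are
#'   tested; `"approx"` reproduces the behaviour of large-array pipelines.
#' @param use_adjusted threshold the BH-adjusted p (default) or the raw p.
#' @return object of class `differential_result`: data.frame with gene, U,
#'   p, padj, significant, direction, max_abs_log2fc; attributes `arm`,
#'   `alpha`.
#' @export
call_arm <- function(es, arm, fc = NULL, alpha = 0.01,
                     mode = c("auto", "exact", "approx"),
                     use_adjusted = TRUE) {
  mode <- match.arg(mode)
  stopifnot_stage(es, "logscaled")
  design <- es$design
  if (!arm %in% design$arms)
    stop("arm not present in design: ", arm, call. = FALSE)
  ctrl <- design_samples(design, arm = "control")
  trt <- design_samples(design, arm = arm)
  if (length(trt) < 2L) stop("arm has < 2 samples", call. = FALSE)
  x <- es$values
  genes <- rownames(x)
  n1 <- length(ctrl)

  U <- p <- numeric(length(genes))
  med_diff <- numeric(length(genes))
  xc <- x[, ctrl, drop = FALSE]
  xt <- x[, trt, drop = FALSE]
  for (i in seq_along(genes)) {
    mw <- mann_whitney(xc[i, ], xt[i, ], mode = mode)
    U[i] <- mw$U; p[i] <- mw$p
    med_diff[i] <- stats::median(xt[i, ]) - stats::median(xc[i, ])
  }
  padj <- bh_adjust(p)
  sig <- (if (use_adjusted) padj else p) < alpha
  direction <- ifelse(!sig, "none", ifelse(med_diff > 0, "up", "down"))
  # a significant call with an exactly-zero median difference cannot be
  # oriented; demote it (possible only with heavy ties)
  direction[sig & med_diff == 0] <- "none"
  sig <- sig & direction != "none"

  res <- data.frame(gene = genes, U = U, p = p, padj = padj,
                    significant = sig, direction = direction,
                    stringsAsFactors = FALSE)
  res$max_abs_log2fc <- if (!is.null(fc)) fc$arm_max[genes, arm] else NA_real_
  structure(res, arm = arm, alpha = alpha, class = c("differential_result",
                                                     "data.frame"))
}

#' Decompose two arm-level gene lists into salt-specific and osmotic sets
#'
#' With A = significant genes of the NaCl arm and B = significant genes of
#' the sorbitol arm: salt-specific = A \ B, osmotic = A intersect B,
#' sorbitol-only = B \ A (reported, not headline). Up/down splits follow
#' the NaCl-arm direction; osmotic genes whose two arms disagree in
#' direction are placed by their NaCl direction and listed in
#' `discordant`.
#'
#' @param res_nacl,res_sorbitol [call_arm()] results over the same gene
#'   universe for the NaCl and sorbitol arms.
#' @return object of class `decomposition`: list with `salt_specific_up`,
#'   `salt_specific_down`, `osmotic_up`, `osmotic_down`, `sorbitol_only`,
#'   `discordant` (character vectors of gene ids) and `go_input` (empty
#'   until [fc_filter()]).
#' @export
decompose <- function(res_nacl, res_sorbitol) {
  if (!setequal(res_nacl$gene, res_sorbitol$gene) ||
      nrow(res_nacl) != nrow(res_sorbitol))
    stop("mismatched gene universes", call. = FALSE)
  dirA <- setNames(res_nacl$direction, res_nacl$gene)
  A <- res_nacl$gene[res_nacl$significant]
  B <- res_sorbitol$gene[res_sorbitol$significant]
  dirB <- setNames(res_sorbitol$direction, res_sorbitol$gene)
  salt <- setdiff(A, B)
  osmo <- intersect(A, B)
  structure(list(
    salt_specific_up   = salt[dirA[salt] == "up"],
    salt_specific_down = salt[dirA[salt] == "down"],
    osmotic_up         = osmo[dirA[osmo] == "up"],
    osmotic_down       = osmo[dirA[osmo] == "down"],
    sorbitol_only      = setdiff(B, A),
    discordant         = osmo[dirA[osmo] != dirB[osmo]],
    go_input           = list()
  ), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("decomposition: salt-specific", length(x$salt_specific_up), "up /",
      length(x$salt_specific_down), "down; osmotic", length(x$osmotic_up),
      "up /", length(x$osmotic_down), "down; sorbitol-only",
      length(x$sorbitol_only), "\n")
  invisible(x)
}

#' All genes of one headline set
#' @param dec a [decompose()] result.
#' @param set `"salt_specific"` or `"osmotic"`.
#' @return character vector of gene ids (up and down combined).
#' @export
decomposition_set <- function(dec, set = c("salt_specific", "osmotic")) {
  set <- match.arg(set)
  c(dec[[paste0(set, "_up")]], dec[[paste0(set, "_down")]])
}

#' Two-fold-change filter producing the enrichment input subsets
#'
#' Keeps a gene iff its expression changed by `threshold`-fold or more
#' (|log2FC| >= log2(threshold)) in at least one dose of its relevant
#' arm(s): the NaCl arm for salt-specific genes, either arm for osmotic
#' genes.
#'
#' @param dec a [decompose()] result.
#' @param fc a [fold_changes()] table.
#' @param threshold fold threshold (> 1; default 2).
#' @return `dec` with `go_input` filled: per headline set, the filtered
#'   gene subset.
#' @export
fc_filter <- function(dec, fc, threshold = 2) {
  if (!is.numeric(threshold) || threshold <= 1)
    stop("fold threshold must be > 1", call. = FALSE)
  cut <- log2(threshold)
  l2 <- abs(fc$log2fc)
  arm_of <- setNames(fc$conditions$arm, fc$conditions$condition)
  pass_arm <- function(genes, arms) {
    cols <- fc$conditions$condition[arm_of[fc$conditions$condition] %in% arms]
    genes[apply(l2[genes, cols, drop = FALSE] >= cut, 1, any)]
  }
  dec$go_input <- list(
    salt_specific_up   = pass_arm(dec$salt_specific_up, "NaCl"),
    salt_specific_down = pass_arm(dec$salt_specific_down, "NaCl"),
    osmotic_up         = pass_arm(dec$osmotic_up, c("NaCl", "sorbitol")),
    osmotic_down       = pass_arm(dec$osmotic_down, c("NaCl", "sorbitol"))
  )
  dec$fc_threshold <- threshold
  dec
}

#' Ordered matrix export for heatmapping one gene set
#'
#' Returns the normalized per-condition mean matrix for the genes of one
#' set, rows ordered by NaCl-arm max fold change, for external heatmap
#' tools.
#'
#' @param es an [expr_set()] (any normalized stage).
#' @param genes character vector of gene ids.
#' @return matrix genes x conditions of per-condition means.
#' @export
ordered_matrix <- function(es, genes) {
  conds <- design_conditions(es$design)
  m <- sapply(conds$condition, function(cc)
    rowMeans(es$values[genes, design_samples(es$design, condition = cc),
                       drop = FALSE]))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, conds$condition))
  m[order(rowMeans(m), decreasing = TRUE), , drop = FALSE]
}
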