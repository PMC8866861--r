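#' Stage-tagged expression matrix
#'
#' Minimal container for a gene-by-sample intensity matrix tied to a
#' [study_design()]. Every normalization step consumes a set at one stage
#' and emits the next, so a mis-ordered pipeline fails loudly:
#' `raw -> quantile -> zscored -> logscaled`.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids matching the design).
#' @param design a [study_design()] covering every column.
#' @param stage one of `"raw"`, `"quantile"`, `"zscored"`, `"logscaled"`.
#' @return object of class `expr_set`.
#' @export
expr_set <- function(values, design, stage = "raw") {
  stage <- match.arg(stage, c("raw", "quantile", "zscored", "logscaled"))
  design <- as_study_design(design)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames", call. = FALSE)
  if (anyNA(values))
    stop("missing values are not allowed in an expr_set", call. = FALSE)
  missing_design <- setdiff(colnames(values), design$samples$sample)
  if (length(missing_design))
    stop("samples absent from design: ",
         paste(missing_design, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(design$samples$sample, colnames(values))
  if (length(missing_cols))
    stop("design samples absent from matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  values <- values[, design$samples$sample, drop = FALSE]
  if (stage == "raw" && any(values <= 0))
    stop("raw intensities must be strictly positive", call. = FALSE)
  structure(list(values = values, design = design, stage = stage),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set [", x$stage, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

stopifnot_stage <- function(es, stage) {
  if (!inherits(es, "expr_set"))
    stop("expected an expr_set", call. = FALSE)
  if (!identical(es$stage, stage))
    stop(sprintf("expected an expr_set at stage '%s' but got '%s'",
                 stage, es$stage), call. = FALSE)
  invisible(es)
}
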