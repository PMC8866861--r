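#' Read an expression matrix TSV plus its design CSV
#'
#' The TSV carries genes in rows (first column = gene id, header row =
#' sample ids); the design CSV has columns sample, arm, dose, replicate.
#' Every matrix column must be covered by the design. Missing values are
#' rejected by default (`missing = "error"`); `missing = "drop_gene"`
#' removes affected genes.
#'
#' @param expression_tsv,design_csv file paths.
#' @param stage stage tag of the stored matrix (default `"raw"`). If a
#'   sidecar JSON written by [write_expression()] exists it is consulted
#'   and a mismatch is an error.
#' @param missing `"error"` or `"drop_gene"`.
#' @return an [expr_set()].
#' @export
read_expression <- function(expression_tsv, design_csv, stage = "raw",
                            missing = c("error", "drop_gene")) {
  missing <- match.arg(missing)
  sidecar <- paste0(expression_tsv, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!identical(meta$stage, stage))
      stop(sprintf("stage mismatch: sidecar says '%s', caller expects '%s'",
                   meta$stage, stage), call. = FALSE)
  }
  d <- utils::read.csv(design_csv, stringsAsFactors = FALSE)
  design <- design_from_table(d)
  x <- utils::read.table(expression_tsv, sep = "\t", header = TRUE,
                         row.names = 1, check.names = FALSE)
  x <- as.matrix(x)
  if (anyNA(x)) {
    if (missing == "error")
      stop("missing values in expression matrix (use missing='drop_gene')",
           call. = FALSE)
    x <- x[stats::complete.cases(x), , drop = FALSE]
  }
  extra <- setdiff(colnames(x), design$samples$sample)
  if (length(extra))
    stop("samples absent from design: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (stage == "raw" && any(x <= 0))
    stop("non-positive intensity in raw matrix", call. = FALSE)
  expr_set(x, design, stage)
}

# Rebuild a study_design from a long-format sample table
design_from_table <- function(d) {
  need <- c("sample", "arm", "dose", "replicate")
  if (!all(need %in% names(d)))
    stop("design table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  nacl <- sort(unique(d$dose[d$arm == "NaCl"]))
  sorb <- sort(unique(d$dose[d$arm == "sorbitol"]))
  reps <- max(d$replicate[d$arm != "control"])
  ctrl <- sum(d$arm == "control")
  des <- study_design(nacl, sorb, reps, ctrl)
  missing <- setdiff(des$samples$sample, d$sample)
  extra <- setdiff(d$sample, des$samples$sample)
  if (length(missing) || length(extra))
    stop("design table is not a complete two-arm dose series layout",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  des
}

#' Write an expression set as TSV (+ design CSV + stage sidecar JSON)
#'
#' @param es an [expr_set()].
#' @param expression_tsv,design_csv output paths.
#' @return `expression_tsv`, invisibly.
#' @export
write_expression <- function(es, expression_tsv, design_csv = NULL) {
  df <- data.frame(gene = rownames(es$values), es$values,
                   check.names = FALSE)
  utils::write.table(df, expression_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(stage = es$stage),
                       paste0(expression_tsv, ".json"), auto_unbox = TRUE)
  if (!is.null(design_csv))
    utils::write.csv(es$design$samples, design_csv, row.names = FALSE)
  invisible(expression_tsv)
}

#' Run configuration
#'
#' Flat `key: value` configuration (a YAML subset: scalar keys only,
#' comments with `#`). Unknown keys are rejected; every parameter is
#' validated against its documented range.
#'
#' @param path optional config file; values there are overridden by `...`.
#' @param ... named overrides (e.g. `alpha = 0.01`).
#' @return validated named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    alpha = 0.01,            # BH-adjusted significance threshold
    fold_threshold = 2,      # fold filter before enrichment (> 1)
    elim_cutoff = 0.01,      # elim elimination threshold, (0,1)
    min_genes = 10,          # strict k filter of the enrichment report
    exact_limit = 20,        # auto mode: exact Mann-Whitney up to this n
    mw_mode = "auto",        # auto | exact | approx
    use_adjusted = TRUE,     # threshold BH-adjusted p (FALSE: raw p)
    seed = 1,
    n_genes = 500,           # simulate: matrix size
    n_terms = 50             # simulate: ontology size
  )
  vals <- defaults
  if (!is.null(path)) {
    file_vals <- parse_kv_config(path)
    bad <- setdiff(names(file_vals), names(defaults))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    vals[names(file_vals)] <- file_vals
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  vals[names(dots)] <- dots

  num <- function(x) suppressWarnings(as.numeric(x))
  vals$alpha <- num(vals$alpha); vals$fold_threshold <- num(vals$fold_threshold)
  vals$elim_cutoff <- num(vals$elim_cutoff); vals$min_genes <- num(vals$min_genes)
  vals$exact_limit <- num(vals$exact_limit); vals$seed <- num(vals$seed)
  vals$n_genes <- num(vals$n_genes); vals$n_terms <- num(vals$n_terms)
  ok <- function(cond, what) if (!isTRUE(cond))
    stop("invalid config: ", what, call. = FALSE)
  ok(!is.na(vals$alpha) && vals$alpha > 0 && vals$alpha < 1,
     "alpha must be in (0,1)")
  ok(!is.na(vals$fold_threshold) && vals$fold_threshold > 1,
     "fold_threshold must be > 1")
  ok(!is.na(vals$elim_cutoff) && vals$elim_cutoff > 0 && vals$elim_cutoff < 1,
     "elim_cutoff must be in (0,1)")
  ok(!is.na(vals$min_genes) && vals$min_genes >= 0,
     "min_genes must be >= 0")
  ok(!is.na(vals$seed) && vals$seed == round(vals$seed),
     "seed must be an integer")
  ok(!is.na(vals$n_genes) && vals$n_genes >= 1, "n_genes must be >= 1")
  ok(!is.na(vals$n_terms) && vals$n_terms >= 2, "n_terms must be >= 2")
  ok(vals$mw_mode %in% c("auto", "exact", "approx"),
     "mw_mode must be auto|exact|approx")
  if (is.character(vals$use_adjusted))
    vals$use_adjusted <- tolower(vals$use_adjusted) %in% c("true", "yes", "1")
  ok(is.logical(vals$use_adjusted) && !is.na(vals$use_adjusted),
     "use_adjusted must be logical")
  structure(vals, class = "run_config")
}

parse_kv_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("config parse error at line: ", ln, call. = FALSE)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}
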