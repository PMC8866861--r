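#' Two-arm dose-series study design
#'
#' Describes the layout of a salinity-stress dose series: one untreated
#' control condition plus two treatment arms (NaCl and an iso-osmolar
#' osmoticum, by default sorbitol), each arm a series of doses with a fixed
#' number of biological replicates. The default instance reproduces the
#' canonical layout: 3 control samples, 4 NaCl doses x 3 replicates and
#' 4 sorbitol doses x 3 replicates, 27 samples in total.
#'
#' @param nacl_doses numeric vector of NaCl doses (mM), increasing.
#' @param sorbitol_doses numeric vector of sorbitol doses (mM), increasing;
#'   chosen iso-osmolar to `nacl_doses` in the default design.
#' @param replicates biological replicates per treatment condition.
#' @param control_replicates replicates of the untreated control.
#' @return An object of class `study_design`: a list with `samples`
#'   (data.frame: sample, arm, dose, replicate, condition) and `arms`.
#' @examples
#' d <- study_design()
#' nrow(d$samples)  # 27
#' @export
study_design <- function(nacl_doses = c(50, 75, 100, 125),
                         sorbitol_doses = c(100, 150, 200, 250),
                         replicates = 3L,
                         control_replicates = 3L) {
  replicates <- as.integer(replicates)
  control_replicates <- as.integer(control_replicates)
  if (replicates < 1L || control_replicates < 1L)
    stop("invalid design: replicate counts must be positive", call. = FALSE)
  if (length(nacl_doses) < 1L || length(sorbitol_doses) < 1L)
    stop("invalid design: each arm needs at least one dose", call. = FALSE)
  if (anyDuplicated(nacl_doses) || anyDuplicated(sorbitol_doses))
    stop("invalid design: duplicated dose within an arm", call. = FALSE)

  arm_block <- function(arm, doses, reps) {
    data.frame(
      sample    = paste0(arm, "_", rep(doses, each = reps), "_r",
                         rep(seq_len(reps), times = length(doses))),
      arm       = arm,
      dose      = rep(doses, each = reps),
      replicate = rep(seq_len(reps), times = length(doses)),
      condition = paste0(arm, "_", rep(doses, each = reps)),
      stringsAsFactors = FALSE
    )
  }
  ctrl <- data.frame(
    sample = paste0("control_r", seq_len(control_replicates)),
    arm = "control", dose = 0,
    replicate = seq_len(control_replicates),
    condition = "control", stringsAsFactors = FALSE
  )
  samples <- rbind(ctrl,
                   arm_block("NaCl", nacl_doses, replicates),
                   arm_block("sorbitol", sorbitol_doses, replicates))
  if (anyDuplicated(samples$sample))
    stop("invalid design: sample labels not unique", call. = FALSE)
  structure(list(samples = samples,
                 arms = c("NaCl", "sorbitol"),
                 replicates = replicates,
                 control_replicates = control_replicates),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x$samples), "samples;",
      length(unique(x$samples$condition)) - 1L, "treatment conditions",
      "across arms", paste(x$arms, collapse = ", "), "\n")
  invisible(x)
}

#' Treatment/control conditions of a design
#'
#' @param design a `study_design`.
#' @return data.frame with one row per condition: condition, arm, dose.
#' @export
design_conditions <- function(design) {
  s <- design$samples
  u <- !duplicated(s$condition)
  data.frame(condition = s$condition[u], arm = s$arm[u], dose = s$dose[u],
             stringsAsFactors = FALSE)
}

#' Sample names belonging to a condition or arm
#' @param design a `study_design`.
#' @param arm arm name ("control", "NaCl", "sorbitol") or NULL.
#' @param condition condition label or NULL.
#' @return character vector of sample names.
#' @export
design_samples <- function(design, arm = NULL, condition = NULL) {
  s <- design$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(arm)) keep <- keep & s$arm %in% arm
  if (!is.null(condition)) keep <- keep & s$condition %in% condition
  s$sample[keep]
}

as_study_design <- function(x) {
  if (inherits(x, "study_design")) return(x)
  stop("expected a study_design object", call. = FALSE)
}
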