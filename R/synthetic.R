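#' @name synthetic
#' @title Synthetic study bundles with planted truth
#' @description
#' The generators in this file emulate the structure of the two-arm
#' dose-series experiment (control vs NaCl vs iso-osmolar sorbitol) with
#' known planted structure, so that every downstream stage -- normalization,
#' grouped rank tests, set decomposition, GO enrichment and the phenotype /
#' metabolite statistics -- has a no-download test surface with exact ground
#' truth. All randomness flows from a single integer seed through
#' [derive_seed()].
NULL

#' Derive a stream-specific RNG seed from a master seed
#'
#' Documented splitting scheme so subcommands run independently yet
#' reproducibly: `(seed + 1000003 * offset) mod (2^31 - 1)`.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer identifying the consumer stream.
#' @return an integer seed `< 2^31`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647)
}

GENE_CLASSES <- c("salt_up", "salt_down", "osmotic_up", "osmotic_down",
                  "sorbitol_only_up", "sorbitol_only_down")

# dose-profile multiplier in (0, 1], reaching 1 at the top dose
profile_weight <- function(profile, idx, n_doses) {
  switch(profile,
    flat       = rep(1, length(idx)),
    linear     = idx / n_doses,
    saturating = (idx / (idx + 1)) / (n_doses / (n_doses + 1)),
    stop("unknown effect profile: ", profile, call. = FALSE)
  )
}

#' Generate a planted-truth expression matrix
#'
#' Intensities follow `2^(baseline + effect + N(0, sd))` per gene/sample:
#' strictly positive, as quantile normalization and fold changes require.
#' Gene classes are assigned deterministically (a seeded shuffle, then the
#' first `ceiling(p * n)` genes per class) so truth counts are exact.
#' `salt_*` classes respond only in the NaCl arm, `sorbitol_only_*` only in
#' the sorbitol arm, and `osmotic_*` with the same sign in both arms.
#'
#' @param n_genes number of genes (one probe per gene).
#' @param design a [study_design()]; needs >= 2 replicates per condition.
#' @param proportions named numeric vector over
#'   `salt_up, salt_down, osmotic_up, osmotic_down, sorbitol_only_up,
#'   sorbitol_only_down` (missing names = 0); must sum to <= 1, the
#'   remainder being unresponsive (`null`) genes.
#' @param effect_size log2 effect at the top dose for responsive genes.
#' @param profile dose-response shape of the planted effect: `"saturating"`
#'   (default: stress responses plateau), `"linear"`, or `"flat"`.
#' @param baseline_mean,baseline_sd log2-scale distribution of per-gene
#'   baseline intensities.
#' @param noise_sd log2-scale residual standard deviation (> 0).
#' @param seed integer seed.
#' @return list with `expression` (an [expr_set()] at stage `"raw"`) and
#'   `truth` (class `planted_truth`: data.frame `genes` with per-gene class,
#'   baseline and noise sd, plus `effects`, a gene x condition log2-effect
#'   matrix).
#' @export
generate_expression <- function(n_genes,
                                design = study_design(),
                                proportions = c(salt_up = 0.05,
                                                salt_down = 0.05,
                                                osmotic_up = 0.05,
                                                osmotic_down = 0.05),
                                effect_size = 2,
                                profile = c("saturating", "linear", "flat"),
                                baseline_mean = 8,
                                baseline_sd = 2,
                                noise_sd = 0.25,
                                seed = 1L) {
  profile <- match.arg(profile)
  design <- as_study_design(design)
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L)
    stop("invalid design: n_genes must be a positive integer", call. = FALSE)
  if (design$replicates < 2L)
    stop("invalid design: need >= 2 replicates per condition", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  bad <- setdiff(names(proportions), GENE_CLASSES)
  if (length(bad))
    stop("unknown gene classes: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(proportions < 0) || sum(proportions) > 1 + 1e-12)
    stop("class proportions must be >= 0 and sum to <= 1", call. = FALSE)

  set.seed(derive_seed(seed, 1L))
  genes <- sprintf("G%05d", seq_len(n_genes))
  shuffled <- sample(genes)
  class <- setNames(rep("null", n_genes), shuffled)
  cursor <- 0L
  for (cl in names(proportions)) {
    k <- min(ceiling(proportions[[cl]] * n_genes), n_genes - cursor)
    if (k > 0L) class[shuffled[cursor + seq_len(k)]] <- cl
    cursor <- cursor + k
  }
  class <- class[genes]

  conds <- design_conditions(design)
  treat <- conds[conds$arm != "control", , drop = FALSE]
  effects <- matrix(0, n_genes, nrow(treat),
                    dimnames = list(genes, treat$condition))
  for (arm in design$arms) {
    rows <- which(treat$arm == arm)
    w <- profile_weight(profile, order(order(treat$dose[rows])), length(rows))
    responds <- switch(arm,
      NaCl     = class %in% c("salt_up", "salt_down",
                              "osmotic_up", "osmotic_down"),
      sorbitol = class %in% c("sorbitol_only_up", "sorbitol_only_down",
                              "osmotic_up", "osmotic_down"))
    sign <- ifelse(grepl("_up$", class), 1, -1)
    for (j in seq_along(rows))
      effects[responds, rows[j]] <- effect_size * w[j] * sign[responds]
  }

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  smp <- design$samples
  log2v <- matrix(baseline, n_genes, nrow(smp))
  for (j in seq_len(nrow(smp)))
    if (smp$condition[j] %in% colnames(effects))
      log2v[, j] <- log2v[, j] + effects[, smp$condition[j]]
  log2v <- log2v + matrix(stats::rnorm(n_genes * nrow(smp), 0, noise_sd),
                          n_genes, nrow(smp))
  values <- 2^log2v
  dimnames(values) <- list(genes, smp$sample)

  truth <- structure(
    list(genes = data.frame(gene = genes, class = unname(class),
                            baseline = baseline, noise_sd = noise_sd,
                            stringsAsFactors = FALSE),
         effects = effects, term_plan = NULL),
    class = "planted_truth")
  list(expression = expr_set(values, design, "raw"), truth = truth)
}

#' Generate a random single-rooted ontology DAG with planted annotations
#'
#' Builds an acyclic, single-rooted term DAG (edges only ever point from a
#' term to earlier-generated terms, so cycles are structurally impossible)
#' and draws direct (pre-propagation) gene annotations. Planted terms
#' over-annotate a target gene class at a stated fraction, giving the
#' enrichment stage a recoverable signal.
#'
#' @param n_terms number of terms including the root (>= 2).
#' @param max_depth maximum generation depth of any term.
#' @param genes character vector of gene ids to annotate.
#' @param truth optional `planted_truth` from [generate_expression()]; gene
#'   classes are read from it for planted terms.
#' @param planted_terms list of lists with fields `term` (index into the
#'   generated terms, 2..n_terms), `class` (a gene class in `truth`), and
#'   `fraction` (fraction of that class to annotate directly).
#' @param mean_extra_terms Poisson mean of additional random direct
#'   annotations per gene (every gene gets at least one).
#' @param seed integer seed.
#' @return list with `ontology` (class `ontology_graph`) and `annotations`
#'   (data.frame gene/term of direct annotations) and `planted` (data.frame
#'   of planted term ids with their class and fraction).
#' @export
generate_ontology <- function(n_terms = 50, max_depth = 4, genes,
                              truth = NULL, planted_terms = list(),
                              mean_extra_terms = 2, seed = 1L) {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 2L)
    stop("n_terms must be >= 2 (root alone is not a usable ontology)",
         call. = FALSE)
  set.seed(derive_seed(seed, 2L))
  ids <- sprintf("GO:S%06d", seq_len(n_terms))
  depth <- integer(n_terms)  # generation depth; term 1 is the root
  edges <- list()
  for (i in seq_len(n_terms)[-1]) {
    depth[i] <- sample.int(min(max_depth, max(depth[seq_len(i - 1L)]) + 1L), 1L)
    shallower <- which(depth[seq_len(i - 1L)] < depth[i])
    n_par <- min(length(shallower), sample(1:2, 1L))
    parents <- if (length(shallower) == 1L) shallower else
      sample(shallower, n_par)
    edges[[i]] <- data.frame(child = ids[i], parent = ids[parents],
                             relation = "is_a", stringsAsFactors = FALSE)
  }
  graph <- ontology_graph(
    terms = data.frame(id = ids,
                       name = c("root", paste0("synthetic term ", ids[-1])),
                       namespace = "biological_process",
                       stringsAsFactors = FALSE),
    edges = do.call(rbind, edges))

  # background annotations: >= 1 random non-root term per gene
  n_extra <- 1L + stats::rpois(length(genes), mean_extra_terms)
  ann <- data.frame(
    gene = rep(genes, n_extra),
    term = ids[1L + sample.int(n_terms - 1L, sum(n_extra), replace = TRUE)],
    stringsAsFactors = FALSE)

  planted <- NULL
  if (length(planted_terms)) {
    if (is.null(truth))
      stop("planted_terms require a planted_truth object", call. = FALSE)
    rows <- lapply(planted_terms, function(p) {
      ti <- as.integer(p$term)
      if (is.na(ti) || ti < 2L || ti > n_terms)
        stop("planted term index out of range", call. = FALSE)
      cls_genes <- truth$genes$gene[truth$genes$class == p$class]
      k <- ceiling(p$fraction * length(cls_genes))
      if (k > 0L)
        ann <<- rbind(ann, data.frame(gene = cls_genes[seq_len(k)],
                                      term = ids[ti],
                                      stringsAsFactors = FALSE))
      data.frame(term = ids[ti], class = p$class, fraction = p$fraction,
                 stringsAsFactors = FALSE)
    })
    planted <- do.call(rbind, rows)
  }
  ann <- unique(ann)
  ann <- ann[order(ann$gene, ann$term), , drop = FALSE]
  rownames(ann) <- NULL
  list(ontology = graph, annotations = ann, planted = planted)
}

#' Generate per-plate survival and mass phenotype data
#'
#' Survivors per plate are Binomial(seeds_per_plate, p(condition)); plate
#' mass is survivors x per-plant mass with lognormal noise.
#'
#' @param design a [study_design()].
#' @param survival named numeric vector of survival probabilities per
#'   condition label (must cover every condition incl. `"control"`).
#' @param mass_per_plant named numeric vector (mg) per condition.
#' @param plates plates per condition (default 4).
#' @param seeds_per_plate seeds sown per plate (default 50).
#' @param mass_cv lognormal coefficient of variation of per-plant mass.
#' @param seed integer seed.
#' @return data.frame: condition, arm, dose, plate, sown, survivors,
#'   mass_total (mg).
#' @export
generate_phenotype <- function(design = study_design(),
                               survival = default_survival(design),
                               mass_per_plant = default_mass(design),
                               plates = 4L, seeds_per_plate = 50L,
                               mass_cv = 0.15, seed = 1L) {
  design <- as_study_design(design)
  plates <- as.integer(plates); seeds_per_plate <- as.integer(seeds_per_plate)
  if (plates < 1L || seeds_per_plate < 1L)
    stop("plates and seeds_per_plate must be >= 1", call. = FALSE)
  conds <- design_conditions(design)
  missing <- setdiff(conds$condition, names(survival))
  if (length(missing))
    stop("survival probabilities missing for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(survival < 0 | survival > 1))
    stop("invalid parameter: survival probability outside [0,1]",
         call. = FALSE)
  if (any(mass_per_plant[conds$condition] < 0))
    stop("invalid parameter: negative mass", call. = FALSE)

  set.seed(derive_seed(seed, 3L))
  sdlog <- sqrt(log(1 + mass_cv^2))
  out <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    p <- survival[[conds$condition[i]]]
    surv <- stats::rbinom(plates, seeds_per_plate, p)
    m <- mass_per_plant[[conds$condition[i]]]
    mass <- surv * m * stats::rlnorm(plates, -sdlog^2 / 2, sdlog)
    data.frame(condition = conds$condition[i], arm = conds$arm[i],
               dose = conds$dose[i], plate = seq_len(plates),
               sown = seeds_per_plate, survivors = surv,
               mass_total = mass, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default dose-survival and mass profiles
#'
#' Survival declines dose-dependently under NaCl and more mildly under
#' iso-osmolar sorbitol; per-plant mass declines under both, more steeply
#' under sorbitol at the top doses -- the qualitative pattern of the
#' emulated experiment.
#' @param design a [study_design()].
#' @return named numeric vector over condition labels.
#' @export
default_survival <- function(design = study_design()) {
  conds <- design_conditions(design)
  p <- numeric(nrow(conds))
  for (i in seq_len(nrow(conds))) {
    p[i] <- switch(conds$arm[i],
      control  = 0.97,
      NaCl     = max(0.05, 0.97 - 0.9 * (conds$dose[i] / 150)^2),
      sorbitol = max(0.05, 0.97 - 0.4 * (conds$dose[i] / 300)^2))
  }
  setNames(p, conds$condition)
}

#' @rdname default_survival
#' @export
default_mass <- function(design = study_design()) {
  conds <- design_conditions(design)
  m <- numeric(nrow(conds))
  for (i in seq_len(nrow(conds))) {
    m[i] <- switch(conds$arm[i],
      control  = 3.0,
      NaCl     = max(0.2, 3.0 * (1 - 0.8 * conds$dose[i] / 150)),
      sorbitol = max(0.2, 3.0 * (1 - 0.9 * conds$dose[i] / 280)))
  }
  setNames(m, conds$condition)
}

#' Generate replicated metabolite concentration tables
#'
#' Concentrations are lognormal around condition means given by per-analyte
#' fold profiles over the control mean (arithmetic means match the planted
#' targets exactly in expectation). Defaults emulate an auxin (IAA) panel in
#' nmol per g dry weight with a strong salt-specific IAA increase.
#'
#' @param design a [study_design()].
#' @param profiles named list: per analyte a list with `control` (mean
#'   concentration, > 0) and `fold`, a named numeric vector of fold changes
#'   per treatment condition (missing conditions default to 1).
#' @param replicates biological replicates (default 5, >= 2).
#' @param cv lognormal coefficient of variation.
#' @param seed integer seed.
#' @return data.frame: analyte, condition, arm, dose, replicate,
#'   concentration.
#' @export
generate_metabolites <- function(design = study_design(),
                                 profiles = default_metabolites(design),
                                 replicates = 5L, cv = 0.15, seed = 1L) {
  design <- as_study_design(design)
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  conds <- design_conditions(design)
  set.seed(derive_seed(seed, 4L))
  sdlog <- sqrt(log(1 + cv^2))
  out <- list()
  for (an in names(profiles)) {
    p <- profiles[[an]]
    if (!is.numeric(p$control) || p$control <= 0)
      stop("invalid parameter: non-positive control mean for ", an,
           call. = FALSE)
    for (i in seq_len(nrow(conds))) {
      fold <- if (conds$condition[i] == "control") 1 else {
        f <- unname(p$fold[conds$condition[i]])
        if (length(f) != 1L || is.na(f)) 1 else f
      }
      mu <- p$control * fold
      if (mu <= 0)
        stop("invalid parameter: non-positive mean concentration",
             call. = FALSE)
      conc <- stats::rlnorm(replicates, log(mu) - sdlog^2 / 2, sdlog)
      out[[length(out) + 1L]] <- data.frame(
        analyte = an, condition = conds$condition[i], arm = conds$arm[i],
        dose = conds$dose[i], replicate = seq_len(replicates),
        concentration = conc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname generate_metabolites
#' @export
default_metabolites <- function(design = study_design()) {
  conds <- design_conditions(design)
  nacl <- conds$condition[conds$arm == "NaCl"]
  sorb <- conds$condition[conds$arm == "sorbitol"]
  fold_vec <- function(nacl_folds, sorb_folds)
    setNames(c(nacl_folds, sorb_folds), c(nacl, sorb))
  list(
    # salt-specific auxin surge: max 6.6-fold at the second NaCl dose,
    # max 3.4-fold under sorbitol (planted values, not ground truth)
    IAA  = list(control = 1.5,
                fold = fold_vec(c(5.5, 6.6, 6.0, 5.8), c(2.0, 2.8, 3.2, 3.4))),
    IAN  = list(control = 4.0,
                fold = fold_vec(c(3.0, 4.5, 4.0, 3.8), c(1.5, 1.8, 2.0, 2.2))),
    oxIAA = list(control = 2.0,
                 fold = fold_vec(rep(1, 4), rep(1, 4)))
  )
}

#' Generate a complete synthetic study bundle
#'
#' One call producing every input the end-to-end pipeline consumes:
#' expression + truth, ontology + annotations, phenotype and metabolite
#' tables, all sharing gene identifiers and condition labels, all
#' reproducible bit-identically from `seed`.
#'
#' @param n_genes genes in the expression matrix.
#' @param design a [study_design()].
#' @param seed master integer seed.
#' @param ... passed to [generate_expression()].
#' @param n_terms,planted_terms passed to [generate_ontology()].
#' @return list of class `synthetic_bundle` with components `expression`,
#'   `truth`, `ontology`, `annotations`, `planted`, `phenotype`,
#'   `metabolites`, `design`, `seed`.
#' @export
synthetic_bundle <- function(n_genes = 500, design = study_design(),
                             seed = 1L, n_terms = 50,
                             planted_terms = list(), ...) {
  ex <- generate_expression(n_genes, design, seed = seed, ...)
  onto <- generate_ontology(n_terms = n_terms, genes = rownames(ex$expression$values),
                            truth = ex$truth, planted_terms = planted_terms,
                            seed = seed)
  phen <- generate_phenotype(design, seed = seed)
  metab <- generate_metabolites(design, seed = seed)
  structure(list(expression = ex$expression, truth = ex$truth,
                 ontology = onto$ontology, annotations = onto$annotations,
                 planted = onto$planted, phenotype = phen,
                 metabolites = metab, design = design, seed = seed),
            class = "synthetic_bundle")
}
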