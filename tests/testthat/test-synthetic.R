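test_that("default design has the canonical 27-sample layout", {
  d <- study_design()
  expect_equal(nrow(d$samples), 27L)
  expect_equal(sum(d$samples$arm == "control"), 3L)
  expect_equal(sum(d$samples$arm == "NaCl"), 12L)
  expect_equal(sum(d$samples$arm == "sorbitol"), 12L)
  expect_false(anyDuplicated(d$samples$sample) > 0)
  ex <- generate_expression(10, seed = 5)
  expect_equal(ncol(ex$expression$values), 27L)
})

test_that("invalid designs and truth specs are rejected", {
  expect_error(study_design(replicates = 0), "positive")
  expect_error(generate_expression(0, seed = 1), "positive")
  expect_error(generate_expression(10, study_design(replicates = 1)),
               ">= 2 replicates")
  expect_error(generate_expression(10, proportions = c(salt_up = 0.7,
                                                       osmotic_up = 0.5)),
               "sum to <= 1")
  expect_error(generate_expression(10, noise_sd = 0), "noise_sd")
  expect_error(generate_expression(10, proportions = c(bogus = 0.1)),
               "unknown gene classes")
})

test_that("class assignment is a deterministic exact partition", {
  ex <- generate_expression(100, proportions = c(salt_up = 0.2,
                                                 osmotic_down = 0.1),
                            seed = 11)
  tab <- table(ex$truth$genes$class)
  expect_equal(unname(tab["salt_up"]), 20L)
  expect_equal(unname(tab["osmotic_down"]), 10L)
  expect_equal(unname(tab["null"]), 70L)
  # null genes have all-zero effect rows; salt genes zero in sorbitol
  eff <- ex$truth$effects
  nulls <- ex$truth$genes$gene[ex$truth$genes$class == "null"]
  expect_true(all(eff[nulls, ] == 0))
  sorb_cols <- grep("^sorbitol", colnames(eff), value = TRUE)
  salts <- ex$truth$genes$gene[ex$truth$genes$class == "salt_up"]
  expect_true(all(eff[salts, sorb_cols] == 0))
  osmo <- ex$truth$genes$gene[ex$truth$genes$class == "osmotic_down"]
  expect_true(all(eff[osmo, ] < 0))
})

test_that("all-zero proportions give a pure-null bundle", {
  ex <- generate_expression(50, proportions = numeric(0), noise_sd = 0.3,
                            seed = 2)
  expect_true(all(ex$truth$genes$class == "null"))
  expect_true(all(ex$truth$effects == 0))
})

test_that("per-condition means follow the generative model as sd -> 0", {
  ex <- generate_expression(100, proportions = c(salt_up = 0.2),
                            effect_size = 2, profile = "flat",
                            noise_sd = 1e-12, seed = 7)
  es <- ex$expression
  d <- es$design
  ctrl <- rowMeans(log2(es$values[, design_samples(d, arm = "control")]))
  salt <- ex$truth$genes$class == "salt_up"
  for (cc in design_conditions(d)$condition[-1]) {
    m <- rowMeans(log2(es$values[, design_samples(d, condition = cc)]))
    expected <- ctrl + if (startsWith(cc, "NaCl")) salt * 2 else 0
    expect_equal(m, expected, tolerance = 1e-9)
  }
  # flat +2 effect = 4x control on the intensity scale
  nacl <- rowMeans(es$values[, design_samples(d, arm = "NaCl")])
  expect_equal(nacl[salt] / rowMeans(es$values[, design_samples(d,
    arm = "control")])[salt], rep(4, sum(salt)),
    tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("saturating and linear profiles are monotone and hit the top dose", {
  for (prof in c("saturating", "linear")) {
    ex <- generate_expression(20, proportions = c(salt_up = 0.5),
                              effect_size = 2, profile = prof, seed = 3)
    eff <- ex$truth$effects
    nacl_cols <- paste0("NaCl_", c(50, 75, 100, 125))
    salts <- ex$truth$genes$gene[ex$truth$genes$class == "salt_up"]
    e <- eff[salts[1], nacl_cols]
    expect_true(all(diff(e) > 0))
    expect_equal(unname(e[4]), 2)
  }
})

test_that("same seed reproduces the full bundle bit-identically", {
  b1 <- synthetic_bundle(n_genes = 40, seed = 123, n_terms = 15)
  b2 <- synthetic_bundle(n_genes = 40, seed = 123, n_terms = 15)
  expect_identical(b1$expression$values, b2$expression$values)
  expect_identical(b1$annotations, b2$annotations)
  expect_identical(b1$phenotype, b2$phenotype)
  expect_identical(b1$metabolites, b2$metabolites)
  b3 <- synthetic_bundle(n_genes = 40, seed = 124, n_terms = 15)
  expect_false(identical(b1$expression$values, b3$expression$values))
})

test_that("ontology generator output is acyclic and single-rooted", {
  # ontology_graph() itself validates acyclicity + unique root; 1000 seeds
  genes <- sprintf("G%03d", 1:20)
  for (seed in 1:1000) {
    g <- generate_ontology(n_terms = 25, genes = genes, seed = seed)$ontology
    expect_s3_class(g, "ontology_graph")
  }
  expect_error(generate_ontology(n_terms = 1, genes = genes), "n_terms")
})

test_that("two-term ontology is a root-leaf chain reachable from root", {
  g <- generate_ontology(n_terms = 2, genes = sprintf("G%02d", 1:5),
                         seed = 9)
  expect_equal(nrow(g$ontology$edges), 1L)
  expect_equal(unname(g$ontology$depth[g$ontology$edges$child]), 1L)
  ann <- propagate(g$ontology, g$annotations)
  expect_equal(length(ann$term_genes[[g$ontology$root]]), ann$N)
})

test_that("planted term with fraction 1.0 covers its class after propagation", {
  ex <- generate_expression(100, proportions = c(salt_up = 0.1), seed = 5)
  g <- generate_ontology(n_terms = 30, genes = ex$truth$genes$gene,
                         truth = ex$truth,
                         planted_terms = list(list(term = 2, class = "salt_up",
                                                   fraction = 1.0)),
                         seed = 5)
  ann <- propagate(g$ontology, g$annotations)
  salts <- ex$truth$genes$gene[ex$truth$genes$class == "salt_up"]
  expect_length(salts, 10L)
  expect_true(all(salts %in% ann$term_genes[[g$planted$term[1]]]))
})

test_that("phenotype generator honours degenerate survival probabilities", {
  d <- study_design()
  conds <- design_conditions(d)$condition
  all1 <- setNames(rep(1, length(conds)), conds)
  ph <- generate_phenotype(d, survival = all1, seed = 4)
  expect_true(all(ph$survivors == 50L))
  all0 <- setNames(rep(0, length(conds)), conds)
  ph0 <- generate_phenotype(d, survival = all0, seed = 4)
  expect_true(all(ph0$survivors == 0L))
  expect_true(all(ph0$mass_total == 0))
  bad <- all1; bad[2] <- 1.5
  expect_error(generate_phenotype(d, survival = bad), "outside \\[0,1\\]")
})

test_that("binomial survival matches its Monte Carlo expectation", {
  d <- study_design()
  conds <- design_conditions(d)$condition
  half <- setNames(rep(0.5, length(conds)), conds)
  # 20 plates x 50 seeds = 1000 Bernoulli draws per condition
  ph <- generate_phenotype(d, survival = half, plates = 20,
                           seeds_per_plate = 50, seed = 8)
  frac <- sum(ph$survivors[ph$condition == "control"]) / 1000
  mc_sd <- sqrt(0.25 / 1000)
  expect_lt(abs(frac - 0.5), 3 * mc_sd)
})

test_that("metabolite tables have the right shape and planted folds", {
  d <- study_design()
  met <- generate_metabolites(d, replicates = 5, seed = 6)
  per_cell <- table(met$analyte, met$condition)
  expect_true(all(per_cell == 5L))
  expect_error(generate_metabolites(d, replicates = 1), ">= 2")
  expect_error(generate_metabolites(
    d, profiles = list(X = list(control = -1, fold = c()))),
    "non-positive")
  # flat profile: all condition means near control within the noise band
  flat <- list(X = list(control = 2, fold = c()))
  m2 <- generate_metabolites(d, profiles = flat, replicates = 200,
                             cv = 0.05, seed = 10)
  means <- tapply(m2$concentration, m2$condition, mean)
  expect_true(all(abs(means / means["control"] - 1) < 0.05))
})
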