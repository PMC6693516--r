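# Generators: fixed fixtures, determinism, connectivity of random models,
# and the statistical contract of the simulated DE tables.

test_that("diamond fixture is fixed, seed-independent, and correctly shaped", {
  m1 <- make_toy_model("diamond", seed = 1)
  m2 <- make_toy_model("diamond", seed = 999)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$reactions), 8)
  expect_equal(nrow(m1$metabolites), 5)
  expect_equal(length(m1$genes), 6)
  expect_gte(length(unique(m1$reactions$subsystem)), 2)
  expect_true(any(m1$reactions$exchange & m1$stoichiometry["A", ] > 0))
  expect_true(any(m1$reactions$exchange & m1$stoichiometry["E", ] < 0))
  # every internal reaction carries a gene association
  internal <- !m1$reactions$exchange
  expect_true(all(nzchar(m1$reactions$gpr[internal])))
})

test_that("random models are deterministic under a fixed seed and size-guarded", {
  expect_identical(make_toy_model("random", size = 20, seed = 1),
                   make_toy_model("random", size = 20, seed = 1))
  expect_false(identical(make_toy_model("random", size = 20, seed = 1),
                         make_toy_model("random", size = 20, seed = 2)))
  expect_error(make_toy_model("random", size = 3), "size")
})

test_that("every internal reaction of a random model can carry steady-state flux", {
  # LP feasibility oracle: force each reaction to at least half a unit of
  # flux and ask for any steady-state vector within bounds
  for (seed in 1:3) {
    m <- make_toy_model("random", size = 20, seed = seed)
    S <- m$stoichiometry
    for (j in seq_len(nrow(m$reactions))) {
      lb <- m$reactions$lower_bound
      ub <- m$reactions$upper_bound
      lb[j] <- max(lb[j], 0.5)
      feas <- ctxmetanet:::lp_feasible_point(A_eq = S, b_eq = rep(0, nrow(S)),
                                             lb = lb, ub = ub)
      expect_false(is.null(feas),
                   label = sprintf("reaction %s (seed %d) can carry flux",
                                   m$reactions$id[j], seed))
    }
  }
})

test_that("DE tables cover exactly the comparisons the design requires", {
  design <- study_design()
  comps <- design_comparisons(design)
  n_cond <- length(design$conditions)
  n_tp <- nrow(design$timepoints)
  expect_equal(nrow(comps), choose(n_cond, 2) * n_tp + n_cond * (n_tp - 1))
  truth <- plant_truth(paste0("g", 1:5), design, seed = 3)
  de <- simulate_de_tables(design, truth, seed = 4)
  expect_equal(nrow(de), 5 * nrow(comps))
  expect_s3_class(de, "de_table")
})

test_that("regenerating a bundle with the same seed is byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(make_synthetic_bundle(seed = 11), d1, force = TRUE)
  write_bundle(make_synthetic_bundle(seed = 11), d2, force = TRUE)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = sprintf("file %s identical across regenerations", f))
  }
})

test_that("planted ON/OFF contrasts yield significant, correctly signed comparisons", {
  # Monte-Carlo check of the emission model at the default parameters: a
  # gene ON on side a and OFF on side b must come out padj < 0.05 with the
  # fold-change signed toward the ON side in effectively all draws.
  design <- small_design()
  genes <- paste0("g", 1:400)
  grid <- expand.grid(gene = genes, condition = design$conditions,
                      timepoint = design$timepoints$label,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$state <- ifelse(grid$condition == "MYb71", "ON", "OFF")
  truth <- structure(list(states = grid, mediator_genes = character(0),
                          cluster_assignment = NULL, effect_size = 3,
                          noise_sd = 0.3), class = "planted_truth")
  de <- simulate_de_tables(design, truth, seed = 5)
  cross <- de$time_a == de$time_b
  sig_a <- de[cross & de$cond_a == "MYb71", ]   # ON side is side a
  sig_b <- de[cross & de$cond_b == "MYb71", ]   # ON side is side b
  expect_gt(nrow(sig_a) + nrow(sig_b), 2000)
  ok <- c(sig_a$padj < 0.05 & sig_a$log2fc > 0,
          sig_b$padj < 0.05 & sig_b$log2fc < 0)
  expect_gte(mean(ok), 0.99)
})

test_that("all-UNKNOWN truth yields the configured false-positive fraction", {
  design <- small_design()
  genes <- paste0("g", 1:300)
  truth <- plant_truth(genes, design, signal_fraction = 0, seed = 2)
  de <- simulate_de_tables(design, truth, seed = 6, fp_rate = 0.01)
  phat <- mean(de$padj < 0.05)
  n <- nrow(de)
  ci <- 0.01 + c(-4, 4) * sqrt(0.01 * 0.99 / n)
  expect_gte(phat, ci[1])
  expect_lte(phat, ci[2])
  expect_identical(de, simulate_de_tables(design, truth, seed = 6, fp_rate = 0.01))
})

test_that("generated bundles pass model validation and write/read cleanly", {
  b <- make_synthetic_bundle(variant = "random", size = 14, seed = 9)
  expect_silent(validate_model(b$model))
  d <- withr::local_tempdir()
  write_bundle(b, d, force = TRUE)
  expect_error(write_bundle(b, d), "force")
  de2 <- read_de_table(file.path(d, "de_transcriptome.tsv"))
  expect_equal(nrow(de2), nrow(b$de_tables$transcriptome))
  expect_equal(de2$log2fc, b$de_tables$transcriptome$log2fc, tolerance = 1e-12)
})

test_that("the diamond scenario plants gA as the structural mediator", {
  b <- plant_transformation_scenario("diamond", seed = 7)
  m <- b$model
  expect_equal(b$truth$mediator_genes, "gA")
  expect_equal(blocked_reactions_by_knockout(m, "gA"),
               m$reactions$id[m$reactions$subsystem == "branch_A"])
  # knocking out gA still leaves a feasible route with nonzero secretion
  lb <- m$reactions$lower_bound
  ub <- m$reactions$upper_bound
  ko <- match(blocked_reactions_by_knockout(m, "gA"), m$reactions$id)
  lb[ko] <- 0; ub[ko] <- 0
  lb[match("R_sec", m$reactions$id)] <- 1
  feas <- ctxmetanet:::lp_feasible_point(A_eq = m$stoichiometry,
                                         b_eq = rep(0, 5), lb = lb, ub = ub)
  expect_false(is.null(feas))
})
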