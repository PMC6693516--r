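# Transformation scoring: change-set derivation, knockout scoring against
# the planted diamond scenario, rank normalization, bootstrap mechanics,
# aggregation and the signed overall score.

diamond_scenario <- function(seed = 7) {
  b <- plant_transformation_scenario("diamond", seed = seed)
  st <- discretize_states(b$de_tables$transcriptome, b$design)
  src <- list(condition = "MYb71", timepoint = "L4")
  tgt <- list(condition = "OP50", timepoint = "L4")
  sl <- state_slice(st, src$condition, src$timepoint)
  nw <- imat_solve(b$model, map_states_to_reactions(b$model, sl))
  v_ref <- reference_flux(b$model, nw)
  sets <- derive_change_sets(b$de_tables$transcriptome, src, tgt,
                             b$model, v_ref)
  list(bundle = b, model = b$model, de = b$de_tables$transcriptome,
       src = src, tgt = tgt, v_ref = v_ref, sets = sets)
}

test_that("change sets mark branch B up, branch A down, and the rest steady", {
  sc <- diamond_scenario()
  expect_setequal(sc$sets$r_forward_up, c("R_b1", "R_b2"))
  expect_setequal(sc$sets$r_forward_down, c("R_a1", "R_a2"))
  expect_setequal(sc$sets$r_steady, c("R_up", "R_j1", "R_j2", "R_sec"))
  # the three sets partition the reactions
  expect_setequal(unlist(sc$sets), sc$model$reactions$id)
})

test_that("change-set derivation applies the conflict rule and the reference-flux floor", {
  sc <- diamond_scenario()
  # no significant genes -> everything steady
  de_null <- sc$de
  de_null$padj <- 0.9
  s <- derive_change_sets(de_null, sc$src, sc$tgt, sc$model, sc$v_ref)
  expect_setequal(s$r_steady, sc$model$reactions$id)
  # a reaction marked by both an up- and a down-gene goes steady: make gA
  # (down, marks R_a1/R_a2) share R_a2 with an up-gene by relabeling gJ2
  m2 <- sc$model
  m2$reactions$gpr[m2$reactions$id == "R_a2"] <- "gA and gB"
  m2$gpr[["R_a2"]] <- parse_gpr("gA and gB")
  s2 <- derive_change_sets(sc$de, sc$src, sc$tgt, m2, sc$v_ref)
  expect_true("R_a2" %in% s2$r_steady)
  expect_false("R_a2" %in% c(s2$r_forward_up, s2$r_forward_down))
  # down-requirements below the flux floor are dropped: zero reference flux
  v0 <- sc$v_ref * 0
  s3 <- derive_change_sets(sc$de, sc$src, sc$tgt, sc$model, v0)
  expect_length(s3$r_forward_down, 0)
  expect_error(derive_change_sets(sc$de, list(condition = "MYb71", timepoint = "L4"),
                                  list(condition = "OP50", timepoint = "Ad1"),
                                  sc$model, sc$v_ref),
               "share a time point")
})

test_that("the null knockout scores zero and defines the threshold", {
  sc <- diamond_scenario()
  null <- mta_score_knockout(sc$model, sc$v_ref, sc$sets, character(0))
  expect_equal(null$ts, 0, tolerance = 1e-9)
  expect_equal(null$n_succ, 0)
  expect_equal(null$deviation_steady, 0, tolerance = 1e-9)
})

test_that("the mediator knockout scores strictly above the threshold", {
  sc <- diamond_scenario()
  ko <- mta_score_knockout(sc$model, sc$v_ref, sc$sets,
                           blocked_reactions_by_knockout(sc$model, "gA"))
  null <- mta_score_knockout(sc$model, sc$v_ref, sc$sets, character(0))
  expect_gt(ko$ts, null$ts)
  # the forced re-route achieves every change requirement with no steady
  # deviation: TS = 1 exactly
  expect_equal(ko$n_succ, 4)
  expect_equal(ko$ts, 1, tolerance = 1e-6)
})

test_that("blocking only steady reactions that carry no reference flux leaves TS at the threshold", {
  sc <- diamond_scenario()
  expect_equal(sc$v_ref[["R_j2"]], 0)
  ko <- mta_score_knockout(sc$model, sc$v_ref, sc$sets, "R_j2")
  null <- mta_score_knockout(sc$model, sc$v_ref, sc$sets, character(0))
  expect_equal(ko$ts, null$ts, tolerance = 1e-9)
})

test_that("under the literal maximize policy no knockout exceeds the null score", {
  sc <- diamond_scenario()
  pars <- mta_params(policy = "maximize")
  null <- mta_score_knockout(sc$model, sc$v_ref, sc$sets, character(0), pars)
  for (g in sc$model$genes) {
    ko <- mta_score_knockout(sc$model, sc$v_ref, sc$sets,
                             blocked_reactions_by_knockout(sc$model, g), pars)
    expect_lte(ko$ts, null$ts + 1e-9)
  }
})

test_that("mta_all_genes ranks the mediator first and treats unassociated genes as null", {
  sc <- diamond_scenario()
  run <- mta_all_genes(sc$model, sc$v_ref, sc$sets)
  ts <- setNames(run$ts, run$gene)
  expect_equal(names(which.max(ts)), "gA")
  thr <- attr(run, "threshold")
  expect_equal(ts[["gX1"]], thr)
  expect_equal(ts[["gX2"]], thr)
  expect_equal(ts[["gX1"]], ts[["gX2"]])   # identical blocked sets
  # scoring is invariant to gene enumeration order
  m_rev <- sc$model
  m_rev$genes <- rev(m_rev$genes)
  run_rev <- mta_all_genes(m_rev, sc$v_ref, sc$sets)
  ts_rev <- setNames(run_rev$ts, run_rev$gene)
  expect_equal(ts_rev[names(ts)], ts)
})

test_that("rank normalization matches the formula on forced examples", {
  mk <- function(ts, thr) {
    structure(data.frame(gene = names(ts), ts = as.numeric(ts),
                         n_blocked = 1L, stringsAsFactors = FALSE),
              class = c("mta_run", "data.frame"), threshold = thr,
              metadata = list())
  }
  expect_equal(rank_normalize(mk(c(a = 5, b = 3, c = 1), 2)),
               c(a = 1.0, b = 0.5, c = 0))
  expect_equal(rank_normalize(mk(c(a = 1, b = 2, c = 3), 5)),
               c(a = 0, b = 0, c = 0))
  expect_equal(rank_normalize(mk(c(a = 4, b = 4, c = 3), 0)),
               c(a = 2.5 / 3, b = 2.5 / 3, c = 1 / 3))
  # scores at the threshold are zeroed (ties with the null are not wins)
  expect_equal(rank_normalize(mk(c(a = 2, b = 3), 2)), c(a = 0, b = 1))
  # output stays within [0, 1] and is monotone above the threshold
  set.seed(1)
  ts <- rnorm(20)
  r <- rank_normalize(mk(setNames(ts, paste0("g", 1:20)), 0))
  expect_true(all(r >= 0 & r <= 1))
  above <- ts > 0
  expect_true(all(diff(r[above][order(ts[above])]) >= 0))
})

test_that("bootstrap runs are reproducible and remove the configured gene count", {
  sc <- diamond_scenario()
  pars <- mta_params(bootstrap_runs = 3, seed = 21)
  r1 <- bootstrap_runs(sc$de, sc$model, sc$bundle$design, sc$src, sc$tgt, pars)
  r2 <- bootstrap_runs(sc$de, sc$model, sc$bundle$design, sc$src, sc$tgt, pars)
  expect_length(r1, 4)   # full-data run + 3 bootstraps
  for (i in seq_along(r1)) expect_equal(r1[[i]]$ts, r2[[i]]$ts)
  expect_equal(attr(r1[[1]], "metadata")$bootstrap, 0L)
  # fraction 0.10 of 6 genes rounds to 1 removed gene per bootstrap
  n_genes <- length(unique(sc$de$gene))
  expect_equal(round(pars$bootstrap_fraction * n_genes), 1)
})

test_that("removing genes outside all GPRs and all significant rows leaves scores unchanged", {
  sc <- diamond_scenario()
  de_aug <- rbind(sc$de,
                  de_rows(list("bystander", "MYb71", "L4", "OP50", "L4", 0.05, 0.9)))
  de_aug <- as_de_table(de_aug)
  run_with <- bootstrap_runs(de_aug, sc$model, sc$bundle$design, sc$src, sc$tgt,
                             mta_params(bootstrap_runs = 1))[[1]]
  run_without <- bootstrap_runs(sc$de, sc$model, sc$bundle$design, sc$src, sc$tgt,
                                mta_params(bootstrap_runs = 1))[[1]]
  expect_equal(run_with$ts, run_without$ts)
})

test_that("aggregation averages rank-normalized runs and rescales the top gene to 1", {
  v1 <- c(a = 1.0, b = 0.5, c = 0)
  v2 <- c(a = 0.5, b = 1.0, c = 0)
  agg <- aggregate_scores(list(v1, v2))
  expect_equal(agg[["a"]], 1)           # mean 0.75 rescaled by the max mean
  expect_equal(agg[["b"]], 1)
  expect_equal(agg[["c"]], 0)
  expect_equal(aggregate_scores(list(v1)), v1)
  expect_equal(unname(aggregate_scores(list(c(a = 0, b = 0)))), c(0, 0))
})

test_that("overall score sums forward layers, subtracts reverse layers, and is antisymmetric", {
  fwd <- list(t = c(g1 = 0.8, g2 = 0.1), p = c(g1 = 0.6))
  rev <- list(t = c(g1 = 0.1, g3 = 0.4), p = c(g1 = 0.0))
  ov <- overall_score(fwd, rev)
  expect_equal(ov[["g1"]], 0.8 + 0.6 - 0.1)
  expect_equal(ov[["g2"]], 0.1)
  expect_equal(ov[["g3"]], -0.4)
  ov_swapped <- overall_score(rev, fwd)
  expect_equal(ov_swapped[names(ov)], -ov[names(ov)])
})
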