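# Context-network extraction: evidence mapping, MILP versus the
# enumeration oracle, flux quality, and the reference flux.

test_that("evidence mapping follows GPR min/max semantics", {
  m <- make_toy_model("two_pathway")
  # "gQ1 or gQ2": one ON isozyme is enough
  sets <- map_states_to_reactions(m, c(gQ1 = 1, gQ2 = -1))
  expect_true("R_q" %in% sets$r_high)
  # "gP1 and gP2": one OFF subunit silences the complex
  sets <- map_states_to_reactions(m, c(gP1 = 1, gP2 = -1))
  expect_true("R_p" %in% sets$r_low)
  # empty-GPR reactions carry no evidence
  expect_false(any(c("R_upP", "R_secP") %in% c(sets$r_high, sets$r_low)))
  expect_length(intersect(sets$r_high, sets$r_low), 0)
})

test_that("consistent diamond evidence reaches full agreement with the expected active set", {
  m <- make_toy_model("diamond")
  sets <- state_sets(r_high = c("R_a1", "R_a2", "R_j1"),
                     r_low = c("R_b1", "R_b2", "R_j2"))
  nw <- imat_solve(m, sets)
  oracle <- imat_bruteforce(m, sets)
  expect_equal(nw$objective, oracle$objective)
  expect_equal(nw$objective, length(sets$r_high) + length(sets$r_low))
  expect_setequal(nw$active_reactions, c("R_up", "R_a1", "R_a2", "R_j1", "R_sec"))
})

test_that("a low-evidence bottleneck with downstream high evidence satisfies only one label", {
  chain <- chain_model()
  sets <- state_sets(r_high = "R_d", r_low = "R_m")
  nw <- imat_solve(chain, sets)
  expect_equal(nw$objective, imat_bruteforce(chain, sets)$objective)
  expect_equal(nw$objective, 1)
})

test_that("conflicting diamond evidence loses exactly one label", {
  m <- make_toy_model("diamond")
  sets <- state_sets(r_high = c("R_a1", "R_a2", "R_b1", "R_b2"), r_low = "R_j1")
  nw <- imat_solve(m, sets)
  oracle <- imat_bruteforce(m, sets)
  expect_equal(nw$objective, oracle$objective)
  expect_equal(oracle$objective, 4)  # total evidence is 5
})

test_that("empty evidence gives objective zero and an all-zero optimal flux", {
  m <- make_toy_model("diamond")
  nw <- imat_solve(m, state_sets())
  expect_equal(nw$objective, 0)
  expect_equal(unname(nw$flux), rep(0, 8))
  expect_length(nw$active_reactions, 0)
})

test_that("solver and oracle agree across random models and evidence sets", {
  for (seed in 1:6) {
    m <- make_toy_model("random", size = 12, seed = seed)
    sets <- random_sets(m, seed + 50)
    nw <- imat_solve(m, sets)
    oracle <- imat_bruteforce(m, sets)
    expect_equal(nw$objective, oracle$objective,
                 label = sprintf("seed %d objective", seed))
    # returned flux satisfies steady state and bounds
    resid <- max(abs(m$stoichiometry %*% nw$flux))
    expect_lt(resid, 1e-6)
    expect_true(all(nw$flux >= m$reactions$lower_bound - 1e-6))
    expect_true(all(nw$flux <= m$reactions$upper_bound + 1e-6))
    # active set is the delta-thresholded flux support
    expect_setequal(nw$active_reactions,
                    names(nw$flux)[abs(nw$flux) > imat_params()$delta])
  }
})

test_that("the oracle refuses oversized evidence sets", {
  m <- make_toy_model("random", size = 24, seed = 3)
  ids <- m$reactions$id[m$reactions$gpr != ""]
  skip_if(length(ids) < 17)
  sets <- state_sets(r_high = ids[1:17])
  expect_error(imat_bruteforce(m, sets), "16")
})

test_that("flux-activity optimization validates bounds up front", {
  m <- make_toy_model("diamond")
  m$reactions$lower_bound[1] <- 5   # excludes v = 0
  expect_error(imat_solve(m, state_sets(r_high = "R_a1")), "0 within")
})

test_that("reference flux is supported on the committed active route and scale-invariant", {
  b <- plant_transformation_scenario("diamond", seed = 3)
  st <- discretize_states(b$de_tables$transcriptome, b$design)
  sl <- state_slice(st, "MYb71", "L2")
  nw <- imat_solve(b$model, map_states_to_reactions(b$model, sl))
  v <- reference_flux(b$model, nw)
  on_route <- c("R_up", "R_a1", "R_a2", "R_j1", "R_sec")
  expect_true(all(abs(v[on_route]) >= 1 - 1e-9))
  expect_true(all(abs(v[setdiff(names(v), on_route)]) < 1e-9))
  # scaling all bounds x10 leaves the support unchanged
  m10 <- b$model
  m10$reactions$lower_bound <- m10$reactions$lower_bound * 10
  m10$reactions$upper_bound <- m10$reactions$upper_bound * 10
  nw10 <- imat_solve(m10, map_states_to_reactions(m10, sl))
  v10 <- reference_flux(m10, nw10)
  expect_setequal(names(v10)[abs(v10) > 1e-9], names(v)[abs(v) > 1e-9])
})

test_that("a context with an empty active set has a zero reference flux", {
  m <- make_toy_model("diamond")
  nw <- imat_solve(m, state_sets())
  expect_equal(unname(reference_flux(m, nw)), rep(0, 8))
})
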