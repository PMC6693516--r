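# GPR grammar, tri-valued evaluation, knockout blocking, validation, and
# the JSON/SBML serialization round trips.

test_that("parse_gpr builds the expected trees", {
  g <- parse_gpr("g1 and g2")
  expect_equal(g$type, "and")
  expect_equal(vapply(g$children, `[[`, "", "gene"), c("g1", "g2"))

  g <- parse_gpr("g1 or (g2 and g3)")
  expect_equal(g$type, "or")
  expect_equal(g$children[[1]]$gene, "g1")
  expect_equal(g$children[[2]]$type, "and")

  expect_equal(parse_gpr("")$type, "empty")
  expect_equal(parse_gpr("   ")$type, "empty")

  # operators are case-insensitive; deparse emits a canonical form whose
  # re-parse evaluates identically on every gene assignment
  txt <- "gA AND (gB or (gC and gD))"
  g1 <- parse_gpr(txt)
  g2 <- parse_gpr(deparse_gpr(g1))
  genes <- c("gA", "gB", "gC", "gD")
  for (mask in 0:15) {
    states <- setNames(ifelse(as.logical(intToBits(mask)[1:4]), 1, -1), genes)
    expect_equal(evaluate_gpr_state(g2, states), evaluate_gpr_state(g1, states))
  }
})

test_that("parse_gpr reports malformed rules with positions", {
  expect_error(parse_gpr("g1 and (g2"), "unbalanced")
  expect_error(parse_gpr("g1 and and g2"), "position")
  expect_error(parse_gpr("g1 g2"), "unexpected")
  expect_error(parse_gpr("g1 and gZ", genes = c("g1", "g2")), "gZ")
})

test_that("tri-valued GPR evaluation follows the min/max lattice rules", {
  expect_equal(evaluate_gpr_state(parse_gpr("g1 and g2"), c(g1 = 1, g2 = -1)), -1)
  expect_equal(evaluate_gpr_state(parse_gpr("g1 or g2"), c(g1 = -1, g2 = 0)), 0)
  expect_equal(evaluate_gpr_state(parse_gpr(""), c(g1 = 1)), 0)
  # absent genes default to UNKNOWN
  expect_equal(evaluate_gpr_state(parse_gpr("g1 and g2"), c(g1 = 1)), 0)
})

test_that("tri-valued evaluation restricted to definite states is boolean evaluation", {
  bool_eval <- function(g, on) {          # independent boolean evaluator
    switch(g$type,
           gene = g$gene %in% on,
           and = all(vapply(g$children, bool_eval, logical(1), on = on)),
           or = any(vapply(g$children, bool_eval, logical(1), on = on)))
  }
  genes <- paste0("g", 1:4)
  rules <- c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or (g3 and g4)",
             "g1 and (g2 or g3) and g4", "g1 or g2 or (g3 and g4)")
  for (rule in rules) {
    g <- parse_gpr(rule, genes)
    for (mask in 0:15) {
      on <- genes[as.logical(intToBits(mask)[1:4])]
      states <- setNames(ifelse(genes %in% on, 1, -1), genes)
      expect_equal(evaluate_gpr_state(g, states),
                   if (bool_eval(g, on)) 1 else -1)
    }
  }
})

test_that("knockout blocking matches AND/OR semantics and skips empty GPRs", {
  m <- make_toy_model("two_pathway")
  # "gP1 and gP2": either gene alone blocks the reaction
  expect_equal(blocked_reactions_by_knockout(m, "gP1"), "R_p")
  expect_equal(blocked_reactions_by_knockout(m, "gP2"), "R_p")
  # "gQ1 or gQ2": single knockout leaves the isozyme route
  expect_equal(blocked_reactions_by_knockout(m, "gQ1"), character(0))
  d <- make_toy_model("diamond")
  expect_equal(blocked_reactions_by_knockout(d, "gA"), c("R_a1", "R_a2"))
  expect_equal(blocked_reactions_by_knockout(d, "gX1"), character(0))
  expect_error(blocked_reactions_by_knockout(d, "nope"), "unknown gene")
  # across every gene, empty-GPR reactions are never blocked
  for (g in d$genes) {
    expect_false(any(c("R_up", "R_sec") %in% blocked_reactions_by_knockout(d, g)))
  }
})

test_that("model validation lists offending identifiers", {
  m <- make_toy_model("diamond")
  bad <- m
  bad$reactions$gpr[2] <- "ghost"
  bad$gpr[[2]] <- parse_gpr("ghost")
  expect_error(validate_model(bad), "ghost")
  bad2 <- m
  bad2$reactions$lower_bound[3] <- 10
  bad2$reactions$upper_bound[3] <- -10
  expect_error(validate_model(bad2), "R_a2")
  bad3 <- m
  bad3$reactions$subsystem[1] <- ""
  expect_error(validate_model(bad3), "subsystem")
})

test_that("native JSON round trip preserves the model exactly", {
  m <- make_toy_model("diamond")
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, p)
  m2 <- load_model(p)
  expect_equal(m2$reactions, m$reactions)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$stoichiometry, m$stoichiometry)
  expect_equal(m2$genes, m$genes)
})

test_that("load_model rejects missing files, bad schema, and unknown genes", {
  expect_error(load_model("no/such/file.json"), "not found")
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other"), p, auto_unbox = TRUE)
  expect_error(load_model(p), "schema")
  # a GPR referencing an undeclared gene is named in the error
  m <- make_toy_model("diamond")
  doc <- jsonlite::read_json(ctxmetanet::write_model_json(m, p))
  doc$reactions[[2]]$gpr <- "gGhost"
  jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(p), "gGhost")
})

test_that("SBML round trip preserves structure and GPR truth tables", {
  for (variant in c("diamond", "two_pathway")) {
    m <- make_toy_model(variant)
    p <- withr::local_tempfile(fileext = ".xml")
    write_model_sbml(m, p)
    m2 <- load_model(p, "sbml")
    expect_equal(m2$reactions$id, m$reactions$id)
    expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
    expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
    expect_equal(m2$reactions$subsystem, m$reactions$subsystem)
    expect_equal(m2$reactions$exchange, m$reactions$exchange)
    expect_equal(m2$stoichiometry, m$stoichiometry)
    expect_setequal(m2$genes, m$genes)
    # exhaustive truth-table comparison of every GPR (<= 6 genes)
    genes <- m$genes
    for (rid in m$reactions$id) {
      for (mask in 0:(2^length(genes) - 1)) {
        states <- setNames(
          ifelse(as.logical(intToBits(mask)[seq_along(genes)]), 1, -1), genes)
        expect_equal(evaluate_gpr_state(m2$gpr[[rid]], states),
                     evaluate_gpr_state(m$gpr[[rid]], states))
      }
    }
  }
})
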