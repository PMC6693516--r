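# DE table I/O and the tri-valued discretization rule.

test_that("read_de_table round-trips and enforces the schema", {
  de <- de_rows(
    list("g1", "MYb71", "L4", "OP50", "L4", 2.5, 0.001),
    list("g1", "MYb71", "Ad1", "MYb71", "L4", -1.0, 0.2),
    list("g2", "MYb237", "L4", "OP50", "L4", 0.4, 0.7))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de, p)
  de2 <- read_de_table(p)
  expect_equal(nrow(de2), 3)
  expect_equal(de2$log2fc, de$log2fc)
  expect_equal(de2$cond_a, de$cond_a)

  # empty file with header is a valid empty table
  writeLines("gene\tside_a\tside_b\tlog2fc\tpadj", p)
  expect_equal(nrow(read_de_table(p)), 0)

  # missing column
  writeLines(c("gene\tside_a\tlog2fc\tpadj", "g1\tA:L2\t1\t0.1"), p)
  expect_error(read_de_table(p), "side_b")

  # padj outside [0,1] cites the row
  writeLines(c("gene\tside_a\tside_b\tlog2fc\tpadj",
               "g1\tMYb71:L4\tOP50:L4\t1\t1.2"), p)
  expect_error(read_de_table(p), "row")
})

test_that("de_table validation rejects self-comparisons and mixed comparisons", {
  expect_error(de_rows(list("g1", "OP50", "L4", "OP50", "L4", 1, 0.1)),
               "side_a equals side_b")
  expect_error(de_rows(list("g1", "MYb71", "L4", "OP50", "Ad1", 1, 0.1)),
               "mixes condition and time")
  expect_error(
    as_de_table(rbind(
      data.frame(gene = "g1", cond_a = "A", time_a = "L4", cond_b = "B",
                 time_b = "L4", log2fc = 1, padj = 0.1),
      data.frame(gene = "g1", cond_a = "A", time_a = "L4", cond_b = "B",
                 time_b = "L4", log2fc = 2, padj = 0.2))),
    "duplicated")
})

test_that("eligibility uses a strict threshold", {
  de <- de_rows(
    list("g1", "MYb71", "L4", "OP50", "L4", 1, 0.04),
    list("g2", "MYb71", "L4", "OP50", "L4", 1, 0.05),
    list("g3", "MYb71", "L4", "OP50", "L4", 1, 0.051))
  expect_equal(eligible_genes(de), "g1")
  expect_equal(eligible_genes(de, alpha = 0.06), c("g1", "g2", "g3"))
  empty <- de[0, ]
  expect_equal(eligible_genes(empty), character(0))
})

test_that("a single significant comparison assigns ON/OFF to its two sides only", {
  design <- small_design()
  de <- de_rows(
    list("g1", "MYb71", "L4", "OP50", "L4", 2.5, 0.01),
    list("g1", "MYb237", "L4", "OP50", "L4", 0.1, 0.8))
  st <- discretize_states(de, design)
  expect_equal(state_slice(st, "MYb71", "L4")[["g1"]], 1)
  expect_equal(state_slice(st, "OP50", "L4")[["g1"]], -1)
  for (ctx in list(c("MYb237", "L4"), c("MYb71", "L2"), c("OP50", "Ad1"))) {
    expect_equal(state_slice(st, ctx[1], ctx[2])[["g1"]], 0)
  }
})

test_that("opposing votes tie to UNKNOWN and ineligible genes stay UNKNOWN", {
  design <- small_design()
  de <- de_rows(
    list("g1", "MYb71", "L4", "OP50", "L4", 2.0, 0.01),    # ON vote MYb71@L4
    list("g1", "MYb71", "Ad1", "MYb71", "L4", 2.0, 0.01),  # OFF vote MYb71@L4
    list("g2", "MYb71", "L4", "OP50", "L4", 3.0, 0.5))     # never significant
  st <- discretize_states(de, design)
  expect_equal(state_slice(st, "MYb71", "L4")[["g1"]], 0)
  expect_equal(state_slice(st, "MYb71", "Ad1")[["g1"]], 1)
  states_g2 <- st[st$gene == "g2", "state"]
  expect_true(all(states_g2 == "UNKNOWN"))
})

test_that("non-adjacent within-condition comparisons never vote", {
  design <- small_design()  # timepoints L2, L4, Ad1
  de <- de_rows(list("g1", "MYb71", "Ad1", "MYb71", "L2", 2.0, 0.001),
                list("g1", "MYb71", "L4", "OP50", "L4", 2.0, 0.001))
  st <- discretize_states(de, design)
  # the L2-vs-Ad1 jump spans two steps and must abstain
  expect_equal(state_slice(st, "MYb71", "Ad1")[["g1"]], 0)
  expect_equal(state_slice(st, "MYb71", "L2")[["g1"]], 0)
  expect_equal(state_slice(st, "MYb71", "L4")[["g1"]], 1)
})

test_that("discretization is sign-symmetric", {
  for (seed in 1:3) {
    b <- make_synthetic_bundle(variant = "random", size = 12,
                               n_extra_genes = 10, seed = seed)
    de <- b$de_tables$transcriptome
    st1 <- discretize_states(de, b$design)
    de_neg <- de
    de_neg$log2fc <- -de_neg$log2fc
    st2 <- discretize_states(de_neg, b$design)
    swap <- c(ON = "OFF", OFF = "ON", UNKNOWN = "UNKNOWN")
    expect_identical(unname(swap[st1$state]), st2$state)
  }
})

test_that("genes with assigned states are always eligible", {
  b <- make_synthetic_bundle(variant = "random", size = 12, seed = 4)
  de <- b$de_tables$transcriptome
  st <- discretize_states(de, b$design)
  assigned <- unique(st$gene[st$state != "UNKNOWN"])
  expect_true(all(assigned %in% eligible_genes(de)))
})

test_that("contexts missing from the design are rejected", {
  design <- small_design()
  de <- de_rows(list("g1", "Lactobacillus", "L4", "OP50", "L4", 1, 0.01))
  expect_error(discretize_states(de, design), "Lactobacillus")
})

test_that("state tables serialize with their parameter sidecar", {
  b <- make_synthetic_bundle(variant = "random", size = 12, seed = 5)
  st <- discretize_states(b$de_tables$transcriptome, b$design, alpha = 0.01)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_state_table(st, p)
  side <- jsonlite::read_json(paste0(p, ".params.json"))
  expect_equal(side$alpha, 0.01)
  expect_equal(nrow(utils::read.delim(p)), nrow(st))
})
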