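# Fixtures shared across test files; everything is built in code.

# Linear chain A -> B -> C with uptake and secretion; the middle reaction
# is the only route between the exchanges.
chain_model <- function(bound = 1000) {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("R_up", "R_m", "R_d", "R_sec"),
                     lower_bound = 0, upper_bound = bound,
                     subsystem = c("uptake", "mid", "down", "secretion"),
                     exchange = c(TRUE, FALSE, FALSE, TRUE),
                     gpr = c("", "g1", "g2", ""), stringsAsFactors = FALSE)
  S <- matrix(0, 3, 4, dimnames = list(mets$id, rxns$id))
  S["A", "R_up"] <- 1
  S["A", "R_m"] <- -1; S["B", "R_m"] <- 1
  S["B", "R_d"] <- -1; S["C", "R_d"] <- 1
  S["C", "R_sec"] <- -1
  metabolic_model(mets, rxns, S, c("g1", "g2"))
}

state_sets <- function(r_high = character(0), r_low = character(0)) {
  structure(list(r_high = r_high, r_low = r_low),
            class = "reaction_state_sets")
}

# Random evidence sets over a model's gene-associated reactions.
random_sets <- function(model, seed) {
  set.seed(seed)
  cand <- model$reactions$id[model$reactions$gpr != ""]
  lab <- sample(c("high", "low", "none"), length(cand), replace = TRUE)
  state_sets(cand[lab == "high"], cand[lab == "low"])
}

# Minimal DE table builder: rows as list(gene, cond_a, time_a, cond_b,
# time_b, log2fc, padj).
de_rows <- function(...) {
  rows <- list(...)
  as_de_table(do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], cond_a = r[[2]], time_a = r[[3]],
               cond_b = r[[4]], time_b = r[[5]],
               log2fc = as.numeric(r[[6]]), padj = as.numeric(r[[7]]),
               stringsAsFactors = FALSE)
  })))
}

small_design <- function() {
  study_design(conditions = c("OP50", "MYb71", "MYb237"),
               timepoints = data.frame(label = c("L2", "L4", "Ad1"),
                                       hours = c(6, 48, 72)),
               replicates = 2)
}
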