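# Synthetic-data generators. The defaults emulate the study design the
# package targets: three bacterial conditions (an E. coli OP50 control and
# two Ochrobactrum microbiota isolates) sampled at six time points from the
# second larval stage to day-7 adults, with planted per-context activity
# states, fold-change cluster structure, and a planted "mediator" gene
# whose knockout re-routes a toy network from one dietary flux state to the
# other.

#' Describe a colonization study design
#'
#' @param conditions Ordered character vector of bacterial conditions. The
#'   first entry is treated as the control diet by downstream helpers.
#' @param timepoints data.frame with columns `label` and `hours`, ordered
#'   by time.
#' @param replicates Replicates per condition x timepoint cell.
#' @return An object of class `study_design`.
#' @export
study_design <- function(conditions = c("OP50", "MYb71", "MYb237"),
                         timepoints = default_timepoints(),
                         replicates = 3L) {
  timepoints <- as.data.frame(timepoints, stringsAsFactors = FALSE)
  stopifnot(length(conditions) >= 2, nrow(timepoints) >= 2, replicates >= 2,
            all(c("label", "hours") %in% names(timepoints)))
  structure(list(conditions = as.character(conditions),
                 timepoints = timepoints,
                 replicates = as.integer(replicates)),
            class = "study_design")
}

#' Default developmental time points (larval L2 through day-7 adults)
#' @return data.frame with columns `label`, `hours`.
#' @export
default_timepoints <- function() {
  data.frame(label = c("L2", "L3", "L4", "Ad1", "Ad3", "Ad7"),
             hours = c(6, 24, 48, 72, 120, 216), stringsAsFactors = FALSE)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %s; timepoints %s; %d replicates\n",
              paste(x$conditions, collapse = "/"),
              paste(x$timepoints$label, collapse = ","), x$replicates))
  invisible(x)
}

# Run code under a private, seeded RNG stream, restoring global state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a toy metabolic model
#'
#' Three variants are available:
#' * `"diamond"`: a fixed 8-reaction, 5-metabolite, 6-gene network --
#'   uptake of A, two alternative two-step branches A->B->D (subsystem
#'   `branch_A`, gated by gene `gA`) and A->C->D (`branch_B`, gated by
#'   `gB`), a join D->E plus a futile reverse E->D (`core`, genes `gJ`,
#'   `gJ2`), and secretion of E. Genes `gX1`/`gX2` are carried in the gene
#'   list but appear in no rule (negative controls for knockout scoring).
#'   The fixture is seed-independent.
#' * `"two_pathway"`: two disconnected linear pathways with their own
#'   uptake/secretion and subsystems.
#' * `"random"`: a seeded random chain with shortcut reactions; every
#'   internal reaction is GPR-annotated and can carry steady-state flux.
#'
#' @param variant `"diamond"`, `"two_pathway"` or `"random"`.
#' @param size Reaction count for the random variant (>= 4).
#' @param seed Integer seed (random variant only).
#' @param default_bound Flux bound magnitude used for all reactions.
#' @return A validated `metabolic_model`.
#' @export
make_toy_model <- function(variant = c("diamond", "two_pathway", "random"),
                           size = 12L, seed = 1L, default_bound = 1000) {
  variant <- match.arg(variant)
  switch(variant,
         diamond = diamond_model(default_bound),
         two_pathway = two_pathway_model(default_bound),
         random = random_model(size, seed, default_bound))
}

diamond_model <- function(bound = 1000) {
  mets <- data.frame(id = c("A", "B", "C", "D", "E"),
                     name = paste("metabolite", c("A", "B", "C", "D", "E")),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("R_up", "R_a1", "R_a2", "R_b1", "R_b2", "R_j1", "R_j2", "R_sec"),
    lower_bound = 0, upper_bound = bound,
    subsystem = c("uptake", "branch_A", "branch_A", "branch_B", "branch_B",
                  "core", "core", "secretion"),
    exchange = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    gpr = c("", "gA", "gA", "gB", "gB", "gJ", "gJ2", ""),
    stringsAsFactors = FALSE)
  S <- matrix(0, 5, 8, dimnames = list(mets$id, rxns$id))
  S["A", "R_up"] <- 1
  S["A", "R_a1"] <- -1; S["B", "R_a1"] <- 1
  S["B", "R_a2"] <- -1; S["D", "R_a2"] <- 1
  S["A", "R_b1"] <- -1; S["C", "R_b1"] <- 1
  S["C", "R_b2"] <- -1; S["D", "R_b2"] <- 1
  S["D", "R_j1"] <- -1; S["E", "R_j1"] <- 1
  S["E", "R_j2"] <- -1; S["D", "R_j2"] <- 1
  S["E", "R_sec"] <- -1
  metabolic_model(mets, rxns, S, c("gA", "gB", "gJ", "gJ2", "gX1", "gX2"))
}

two_pathway_model <- function(bound = 1000) {
  mets <- data.frame(id = c("P1", "P2", "Q1", "Q2"),
                     name = c("P1", "P2", "Q1", "Q2"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("R_upP", "R_p", "R_secP", "R_upQ", "R_q", "R_secQ"),
    lower_bound = 0, upper_bound = bound,
    subsystem = c("uptake", "pathway_P", "secretion",
                  "uptake", "pathway_Q", "secretion"),
    exchange = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    gpr = c("", "gP1 and gP2", "", "", "gQ1 or gQ2", ""),
    stringsAsFactors = FALSE)
  S <- matrix(0, 4, 6, dimnames = list(mets$id, rxns$id))
  S["P1", "R_upP"] <- 1
  S["P1", "R_p"] <- -1; S["P2", "R_p"] <- 1
  S["P2", "R_secP"] <- -1
  S["Q1", "R_upQ"] <- 1
  S["Q1", "R_q"] <- -1; S["Q2", "R_q"] <- 1
  S["Q2", "R_secQ"] <- -1
  metabolic_model(mets, rxns, S, c("gP1", "gP2", "gQ1", "gQ2"))
}

random_model <- function(size, seed, bound = 1000) {
  size <- as.integer(size)
  if (size < 4L) stop("random toy models need size >= 4", call. = FALSE)
  with_seed(seed, {
    # Backbone: uptake -> M1 -> ... -> Mm -> secretion; extra reactions are
    # forward shortcuts Mi -> Mj (i < j), so every internal reaction can
    # carry steady-state flux.
    n_internal <- size - 2L
    n_mets <- n_internal  # chain of m metabolites needs m-1 steps; extras are shortcuts
    n_chain <- n_mets - 1L
    if (n_chain < 1L) n_chain <- 1L
    n_extra <- n_internal - n_chain
    mets <- data.frame(id = paste0("M", seq_len(n_mets)),
                       name = paste0("metabolite ", seq_len(n_mets)),
                       compartment = "c", stringsAsFactors = FALSE)
    n_genes <- max(4L, ceiling(n_internal * 1.2))
    genes <- paste0("g", seq_len(n_genes))
    rand_gpr <- function() {
      k <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
      gs <- sample(genes, k)
      if (k == 1) gs else paste(gs, collapse = if (stats::runif(1) < 0.5) " and " else " or ")
    }
    ids <- c("R_up")
    subsys <- c("uptake")
    gprs <- c("")
    exch <- c(TRUE)
    edges <- list(c(0L, 1L))  # 0 encodes the exterior
    for (i in seq_len(n_chain)) {
      ids <- c(ids, sprintf("R_c%d", i))
      subsys <- c(subsys, if (i <= n_chain / 2) "upper_chain" else "lower_chain")
      gprs <- c(gprs, rand_gpr())
      exch <- c(exch, FALSE)
      edges <- c(edges, list(c(i, i + 1L)))
    }
    pick <- function(x) x[sample.int(length(x), 1L)]  # length-1 safe
    for (i in seq_len(n_extra)) {
      from <- pick(seq_len(n_mets - 1L))
      to <- pick((from + 1L):n_mets)
      ids <- c(ids, sprintf("R_s%d", i))
      subsys <- c(subsys, "shortcut")
      gprs <- c(gprs, rand_gpr())
      exch <- c(exch, FALSE)
      edges <- c(edges, list(c(from, to)))
    }
    ids <- c(ids, "R_sec")
    subsys <- c(subsys, "secretion")
    gprs <- c(gprs, "")
    exch <- c(exch, TRUE)
    edges <- c(edges, list(c(n_mets, 0L)))
    rxns <- data.frame(id = ids, lower_bound = 0, upper_bound = bound,
                       subsystem = subsys, exchange = exch, gpr = gprs,
                       stringsAsFactors = FALSE)
    S <- matrix(0, n_mets, length(ids), dimnames = list(mets$id, ids))
    for (k in seq_along(edges)) {
      e <- edges[[k]]
      if (e[1] > 0L) S[e[1], k] <- S[e[1], k] - 1
      if (e[2] > 0L) S[e[2], k] <- S[e[2], k] + 1
    }
    metabolic_model(mets, rxns, S, genes)
  })
}

#' Plant per-context gene activity states
#'
#' Every "signal" gene is given a contrastive activity pattern: ON in a
#' random non-empty subset of conditions and OFF in the rest, over a random
#' contiguous window of time points (UNKNOWN outside the window). The
#' remaining genes are UNKNOWN everywhere. Contrastive patterns guarantee
#' that each planted ON/OFF state participates in at least one informative
#' comparison, which is what makes state recovery a meaningful target.
#'
#' @param genes Character vector of gene ids to plant states for.
#' @param design A [study_design()].
#' @param signal_fraction Fraction of genes receiving a contrastive
#'   pattern (default 0.6).
#' @param effect_size Planted absolute log2 fold-change between ON and OFF
#'   contexts (default 3).
#' @param noise_sd Log2-scale noise standard deviation (default 0.3).
#' @param mediator_genes Optional gene ids recorded as planted mediators.
#' @param cluster_assignment Optional named integer vector of planted
#'   fold-change cluster ids.
#' @param seed Integer seed.
#' @return An object of class `planted_truth` with elements `states`
#'   (data.frame gene/condition/timepoint/state), `mediator_genes`,
#'   `cluster_assignment`, `effect_size`, `noise_sd`.
#' @export
plant_truth <- function(genes, design, signal_fraction = 0.6,
                        effect_size = 3, noise_sd = 0.3,
                        mediator_genes = character(0),
                        cluster_assignment = NULL, seed = 1L) {
  tps <- design$timepoints$label
  conds <- design$conditions
  grid <- expand.grid(gene = genes, condition = conds, timepoint = tps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$state <- "UNKNOWN"
  with_seed(seed, {
    n_signal <- round(signal_fraction * length(genes))
    signal <- sample(genes, n_signal)
    for (g in signal) {
      n_on <- sample(seq_len(length(conds) - 1L), 1)
      on_conds <- sample(conds, n_on)
      w <- sort(sample(seq_along(tps), 2, replace = TRUE))
      window <- tps[w[1]:w[2]]
      sel <- grid$gene == g & grid$timepoint %in% window
      grid$state[sel] <- ifelse(grid$condition[sel] %in% on_conds, "ON", "OFF")
    }
  })
  structure(list(states = grid, mediator_genes = mediator_genes,
                 cluster_assignment = cluster_assignment,
                 effect_size = effect_size, noise_sd = noise_sd),
            class = "planted_truth")
}

truth_state <- function(truth, gene, condition, timepoint) {
  s <- truth$states
  hit <- s$gene == gene & s$condition == condition & s$timepoint == timepoint
  if (!any(hit)) {
    stop(sprintf("planted truth is missing context (%s, %s, %s)",
                 gene, condition, timepoint), call. = FALSE)
  }
  s$state[hit][1]
}

#' Enumerate the comparisons a design requires
#'
#' All condition pairs at each time point, plus adjacent time points within
#' each condition; per gene this is `choose(C,2)*T + C*(T-1)` rows.
#'
#' @param design A [study_design()].
#' @return data.frame with columns `cond_a`, `time_a`, `cond_b`, `time_b`.
#' @export
design_comparisons <- function(design) {
  conds <- design$conditions
  tps <- design$timepoints$label
  rows <- list()
  for (t in tps) {
    for (i in seq_along(conds)) {
      for (j in seq_along(conds)) {
        if (j > i) {
          rows[[length(rows) + 1L]] <- data.frame(
            cond_a = conds[j], time_a = t, cond_b = conds[i], time_b = t,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (cond in conds) {
    for (k in seq_len(length(tps) - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cond_a = cond, time_a = tps[k + 1L], cond_b = cond, time_b = tps[k],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate differential-expression summary tables from planted truth
#'
#' For every required comparison and gene, emits a log2 fold-change and an
#' FDR-adjusted p-value. When the planted states on the two sides differ
#' (ON vs OFF), the log2 fold-change is drawn from
#' `Normal(+/-effect_size, noise_sd)` signed toward the ON side and the
#' adjusted p-value from `Uniform(0, 0.01)`. Otherwise (states agree or
#' either side is UNKNOWN) the comparison is null: fold-change
#' `Normal(0, noise_sd)`, p-value `Uniform(0.2, 1)`, except that a fraction
#' `fp_rate` of null comparisons receives a false-positive p-value drawn
#' from `Uniform(0, 0.05)`.
#'
#' @param design A [study_design()].
#' @param truth A [plant_truth()] result covering all genes and contexts.
#' @param seed Integer seed.
#' @param fp_rate False-positive fraction among null comparisons
#'   (default 0.01).
#' @return A `de_table` data.frame (see [as_de_table()]).
#' @export
simulate_de_tables <- function(design, truth, seed = 1L, fp_rate = 0.01) {
  comps <- design_comparisons(design)
  genes <- unique(truth$states$gene)
  key <- function(g, cond, tp) paste(g, cond, tp, sep = "\r")
  smap <- stats::setNames(truth$states$state,
                          key(truth$states$gene, truth$states$condition,
                              truth$states$timepoint))
  n <- nrow(comps) * length(genes)
  out <- data.frame(
    gene = rep(genes, each = nrow(comps)),
    cond_a = rep(comps$cond_a, times = length(genes)),
    time_a = rep(comps$time_a, times = length(genes)),
    cond_b = rep(comps$cond_b, times = length(genes)),
    time_b = rep(comps$time_b, times = length(genes)),
    log2fc = numeric(n), padj = numeric(n), stringsAsFactors = FALSE)
  sa <- smap[key(out$gene, out$cond_a, out$time_a)]
  sb <- smap[key(out$gene, out$cond_b, out$time_b)]
  if (anyNA(sa) || anyNA(sb)) {
    stop("planted truth does not cover every gene x context of the design",
         call. = FALSE)
  }
  signal <- (sa == "ON" & sb == "OFF") | (sa == "OFF" & sb == "ON")
  sign_a <- ifelse(sa == "ON", 1, -1)
  with_seed(seed, {
    out$log2fc <- stats::rnorm(n, mean = ifelse(signal, sign_a * truth$effect_size, 0),
                               sd = truth$noise_sd)
    out$padj <- ifelse(signal, stats::runif(n, 0, 0.01), stats::runif(n, 0.2, 1))
    null_idx <- which(!signal)
    fp <- null_idx[stats::runif(length(null_idx)) < fp_rate]
    out$padj[fp] <- stats::runif(length(fp), 0, 0.05)
  })
  as_de_table(out)
}

#' Assemble a full synthetic bundle
#'
#' A toy model, planted truth over its genes (plus optional non-metabolic
#' genes), and the matching DE table. The bundle is the standard input for
#' discretization-recovery tests.
#'
#' @param variant Toy model variant passed to [make_toy_model()].
#' @param size Reaction count for the random variant.
#' @param n_extra_genes Non-metabolic genes appended to the DE table.
#' @param design A [study_design()].
#' @param effect_size,noise_sd,signal_fraction,fp_rate See
#'   [plant_truth()] and [simulate_de_tables()].
#' @param seed Integer seed controlling model, truth and tables.
#' @return An object of class `synthetic_bundle`: list with `model`,
#'   `design`, `de_tables` (named list of `de_table`s per omics layer),
#'   `truth`, `seed`.
#' @export
make_synthetic_bundle <- function(variant = "random", size = 12L,
                                  n_extra_genes = 20L,
                                  design = study_design(),
                                  effect_size = 3, noise_sd = 0.3,
                                  signal_fraction = 0.6, fp_rate = 0.01,
                                  seed = 1L) {
  model <- make_toy_model(variant, size = size, seed = seed)
  genes <- c(model$genes,
             if (n_extra_genes > 0) paste0("x", seq_len(n_extra_genes)))
  truth <- plant_truth(genes, design, signal_fraction = signal_fraction,
                       effect_size = effect_size, noise_sd = noise_sd,
                       seed = seed + 1L)
  de <- simulate_de_tables(design, truth, seed = seed + 2L, fp_rate = fp_rate)
  structure(list(model = model, design = design,
                 de_tables = list(transcriptome = de), truth = truth,
                 seed = as.integer(seed)),
            class = "synthetic_bundle")
}

#' Plant the diamond transformation scenario
#'
#' Builds the fixed diamond model and a truth table in which the two
#' microbiota conditions route flux through branch A (`gA` ON, `gB` OFF at
#' every time point) while the control condition routes through branch B
#' (`gA` OFF, `gB` ON). By construction the knockout of `gA` blocks both
#' branch-A reactions and forces all feasible steady-state flux through
#' branch B, so `gA` is the planted mediator of the microbiota-to-control
#' transition (and `gB` of the reverse).
#'
#' @param variant Only `"diamond"` is supported.
#' @param seed Integer seed for the simulated DE tables.
#' @param design A [study_design()]; must have >= 2 conditions, where the
#'   first condition is the control diet and all others are microbiota
#'   isolates.
#' @return A `synthetic_bundle` whose `truth$mediator_genes` is `"gA"`.
#' @export
plant_transformation_scenario <- function(variant = "diamond", seed = 1L,
                                          design = study_design()) {
  variant <- match.arg(variant, "diamond")
  model <- diamond_model()
  conds <- design$conditions
  tps <- design$timepoints$label
  genes <- model$genes
  grid <- expand.grid(gene = genes, condition = conds, timepoint = tps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$state <- "UNKNOWN"
  microbiota <- grid$condition != conds[1]
  grid$state[grid$gene == "gA"] <- ifelse(microbiota[grid$gene == "gA"], "ON", "OFF")
  grid$state[grid$gene == "gB"] <- ifelse(microbiota[grid$gene == "gB"], "OFF", "ON")
  # gJ carries flux under both diets; gJ2 is a futile loop kept off. Both
  # are planted without cross-condition contrast, hence stay UNKNOWN after
  # discretization -- deliberately: the flux-activity step must work with
  # evidence on the branches alone.
  truth <- structure(list(states = grid, mediator_genes = "gA",
                          cluster_assignment = NULL,
                          effect_size = 3, noise_sd = 0.3),
                     class = "planted_truth")
  de <- simulate_de_tables(design, truth, seed = seed)
  structure(list(model = model, design = design,
                 de_tables = list(transcriptome = de), truth = truth,
                 seed = as.integer(seed)),
            class = "synthetic_bundle")
}

#' Simulate a fold-change matrix with planted cluster structure
#'
#' Generates `n_genes` rows over `n_contrasts` columns, split evenly into
#' `n_clusters` groups. Cluster mean profiles are mutually orthogonal
#' block profiles of amplitude `amplitude`; rows add Gaussian noise of
#' standard deviation `noise_sd`.
#'
#' @param n_genes Number of genes (rows).
#' @param n_clusters Number of planted clusters (default 8).
#' @param n_contrasts Number of fold-change columns (default 12: two
#'   microbiota isolates x six time points).
#' @param amplitude Absolute mean log2 fold-change of a cluster's active
#'   block (default 3).
#' @param noise_sd Noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return list with `fc` (matrix with gene rownames and contrast
#'   colnames) and `assignment` (named integer vector).
#' @export
simulate_fold_change_matrix <- function(n_genes = 200L, n_clusters = 8L,
                                        n_contrasts = 12L, amplitude = 3,
                                        noise_sd = 0.3, seed = 1L) {
  stopifnot(n_clusters >= 1, n_genes >= n_clusters)
  profiles <- matrix(0, n_clusters, n_contrasts)
  for (k in seq_len(n_clusters)) {
    cols <- seq.int(from = 1L + ((k - 1L) %% n_contrasts), to = n_contrasts,
                    by = n_clusters)
    if (!length(cols)) cols <- 1L + ((k - 1L) %% n_contrasts)
    profiles[k, cols] <- amplitude * if (k %% 2 == 0) -1 else 1
  }
  assignment <- rep(seq_len(n_clusters), length.out = n_genes)
  with_seed(seed, {
    fc <- profiles[assignment, , drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_contrasts, 0, noise_sd), n_genes)
  })
  rownames(fc) <- paste0("gene", seq_len(n_genes))
  colnames(fc) <- paste0("contrast", seq_len(n_contrasts))
  names(assignment) <- rownames(fc)
  list(fc = fc, assignment = assignment)
}

#' Write a synthetic bundle to a directory
#'
#' Writes the model (native JSON), one DE table TSV per omics layer, the
#' planted truth (JSON) and a ready-to-run pipeline configuration (YAML).
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory.
#' @param force Overwrite an existing directory.
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop(sprintf("output directory '%s' exists; use force = TRUE to overwrite", dir),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_json(bundle$model, file.path(dir, "model.json"))
  for (layer in names(bundle$de_tables)) {
    write_de_table(bundle$de_tables[[layer]],
                   file.path(dir, paste0("de_", layer, ".tsv")))
  }
  truth <- bundle$truth
  jsonlite::write_json(
    list(states = truth$states, mediator_genes = truth$mediator_genes,
         cluster_assignment = as.list(truth$cluster_assignment),
         effect_size = truth$effect_size, noise_sd = truth$noise_sd,
         seed = bundle$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  cfg <- list(
    model = "model.json",
    de_tables = as.list(stats::setNames(
      paste0("de_", names(bundle$de_tables), ".tsv"), names(bundle$de_tables))),
    design = list(conditions = bundle$design$conditions,
                  timepoints = bundle$design$timepoints$label,
                  hours = bundle$design$timepoints$hours,
                  replicates = bundle$design$replicates),
    seed = bundle$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
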