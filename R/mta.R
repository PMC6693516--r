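# Gene-level metabolic transformation scoring. Given a source flux state
# (the reference flux of a context network) and a desired target state
# (reaction-level change requirements derived from differential
# expression), every metabolic gene's knockout is scored for how strongly
# it pushes the network from the source toward the target.

#' Parameters of the transformation scoring
#'
#' @param epsilon_change Minimum required flux-magnitude change for a
#'   target reaction to count as transformed (default 0.5 flux units,
#'   half the activity threshold of [imat_params()]).
#' @param lambda Weight of the steady-deviation penalty in the score
#'   (default 1).
#' @param bootstrap_fraction Fraction of genes removed per bootstrap run
#'   (default 0.10).
#' @param bootstrap_runs Number of bootstrap runs per comparison
#'   (default 5).
#' @param seed Integer seed for the bootstrap gene removal.
#' @param policy Scoring policy. `"anchor"` (default): the knocked-out
#'   network first settles into the flux state of minimal total L1
#'   adjustment from the source (the metabolic response a minimal-
#'   readjustment cell would show), and desired changes are counted on
#'   that minimal-adjustment face. `"maximize"`: desired changes are
#'   maximized outright; under this policy no knockout can exceed the
#'   null score, so it is useful only for diagnostic comparison.
#' @return A list of class `mta_params`.
#' @export
mta_params <- function(epsilon_change = 0.5, lambda = 1,
                       bootstrap_fraction = 0.10, bootstrap_runs = 5L,
                       seed = 1L, policy = c("anchor", "maximize")) {
  stopifnot(epsilon_change > 0, bootstrap_fraction > 0, bootstrap_fraction < 1,
            bootstrap_runs >= 1)
  structure(list(epsilon_change = epsilon_change, lambda = lambda,
                 bootstrap_fraction = bootstrap_fraction,
                 bootstrap_runs = as.integer(bootstrap_runs),
                 seed = as.integer(seed), policy = match.arg(policy)),
            class = "mta_params")
}

#' Derive target change sets from differential expression
#'
#' Uses the source-versus-target comparison at the shared time point.
#' Genes significantly higher in the target condition mark their
#' associated reactions (GPR leaf membership) as required to increase in
#' flux magnitude (`r_forward_up`); genes significantly lower mark theirs
#' as required to decrease (`r_forward_down`), restricted to reactions
#' whose reference flux magnitude is at least `epsilon_change` (a
#' decrease below that floor is not measurable). Reactions marked in both
#' directions, and all unmarked reactions, form `r_steady`.
#'
#' @param de A `de_table`.
#' @param source,target Contexts as `list(condition =, timepoint =)` (or
#'   length-2 vectors condition/timepoint); time points must agree.
#' @param model A `metabolic_model`.
#' @param v_ref Named reference flux vector (see [reference_flux()]).
#' @param alpha Significance threshold (default 0.05).
#' @param epsilon_change Flux floor for down-requirements (default 0.5).
#' @return list of class `target_change_sets` with `r_forward_up`,
#'   `r_forward_down`, `r_steady` partitioning the reaction ids.
#' @export
derive_change_sets <- function(de, source, target, model, v_ref,
                               alpha = 0.05, epsilon_change = 0.5) {
  source <- as_context(source)
  target <- as_context(target)
  if (!identical(source$timepoint, target$timepoint)) {
    stop("source and target must share a time point", call. = FALSE)
  }
  tp <- source$timepoint
  rows <- de[de$time_a == tp & de$time_b == tp &
               ((de$cond_a == source$condition & de$cond_b == target$condition) |
                  (de$cond_a == target$condition & de$cond_b == source$condition)), ,
             drop = FALSE]
  if (!nrow(rows)) {
    stop(sprintf("DE table has no %s vs %s comparison at %s",
                 source$condition, target$condition, tp), call. = FALSE)
  }
  sig <- rows[rows$padj < alpha & rows$log2fc != 0, , drop = FALSE]
  higher_in_target <- (sig$cond_a == target$condition) == (sig$log2fc > 0)
  up_genes <- unique(sig$gene[higher_in_target])
  down_genes <- unique(sig$gene[!higher_in_target])

  rxn_genes <- lapply(model$gpr, gpr_genes)
  rids <- model$reactions$id
  up_rxns <- rids[vapply(rxn_genes, function(g) any(g %in% up_genes), logical(1))]
  down_rxns <- rids[vapply(rxn_genes, function(g) any(g %in% down_genes), logical(1))]
  down_rxns <- down_rxns[abs(v_ref[down_rxns]) >= epsilon_change]
  conflict <- intersect(up_rxns, down_rxns)
  up_rxns <- setdiff(up_rxns, conflict)
  down_rxns <- setdiff(down_rxns, conflict)
  structure(list(r_forward_up = up_rxns, r_forward_down = down_rxns,
                 r_steady = setdiff(rids, c(up_rxns, down_rxns))),
            class = "target_change_sets")
}

as_context <- function(x) {
  if (is.list(x) && all(c("condition", "timepoint") %in% names(x))) {
    return(list(condition = x$condition, timepoint = x$timepoint))
  }
  if (length(x) == 2) return(list(condition = x[[1]], timepoint = x[[2]]))
  stop("a context is list(condition=, timepoint=) or a length-2 vector",
       call. = FALSE)
}

# Build the change-success constraint rows. Variables are laid out as
# v (n), d (n, L1 deviations |v - v_ref|), then one binary per achievable
# success indicator.
mta_build <- function(model, v_ref, sets, blocked, params) {
  rxns <- model$reactions
  n <- nrow(rxns)
  idx <- stats::setNames(seq_len(n), rxns$id)
  lb <- rxns$lower_bound
  ub <- rxns$upper_bound
  lb[idx[blocked]] <- 0
  ub[idx[blocked]] <- 0
  ec <- params$epsilon_change

  bins <- list()  # list(rxn, kind = up_fwd / up_rev / down, weighted share)
  for (r in sets$r_forward_up) {
    t <- abs(v_ref[[r]]) + ec
    if (ub[idx[r]] >= t) bins[[length(bins) + 1L]] <- list(rxn = r, kind = "up_fwd", t = t)
    if (lb[idx[r]] <= -t) bins[[length(bins) + 1L]] <- list(rxn = r, kind = "up_rev", t = t)
  }
  for (r in sets$r_forward_down) {
    t <- max(abs(v_ref[[r]]) - ec, 0)
    bins[[length(bins) + 1L]] <- list(rxn = r, kind = "down", t = t)
  }
  nb <- length(bins)
  nvar <- 2L * n + nb
  S <- model$stoichiometry
  A_eq <- cbind(S, matrix(0, nrow(S), n + nb))
  b_eq <- rep(0, nrow(S))
  rows <- list(); rhs <- numeric(0)
  add <- function(cols, vals, r) {
    row <- rep(0, nvar)
    row[cols] <- vals
    rows[[length(rows) + 1L]] <<- row
    rhs <<- c(rhs, r)
  }
  # deviation linkage: d_j >= v_j - ref, d_j >= ref - v_j
  for (j in seq_len(n)) {
    add(c(j, n + j), c(1, -1), v_ref[[j]])    # v - d <= ref
    add(c(j, n + j), c(-1, -1), -v_ref[[j]])  # -v - d <= -ref
  }
  for (k in seq_len(nb)) {
    b <- bins[[k]]
    j <- idx[b$rxn]
    col <- 2L * n + k
    if (b$kind == "up_fwd") {        # s=1 => v_j >= t
      add(c(j, col), c(-1, b$t - lb[j]), -lb[j])
    } else if (b$kind == "up_rev") { # s=1 => v_j <= -t
      add(c(j, col), c(1, b$t + ub[j]), ub[j])
    } else {                         # s=1 => -t <= v_j <= t
      add(c(j, col), c(1, ub[j] - b$t), ub[j])
      add(c(j, col), c(-1, -lb[j] - b$t), -lb[j])
    }
  }
  kinds <- vapply(bins, `[[`, "", "kind")
  brxn <- vapply(bins, `[[`, "", "rxn")
  for (r in unique(brxn[kinds %in% c("up_fwd", "up_rev")])) {
    ks <- which(brxn == r & kinds != "down")
    if (length(ks) == 2) add(2L * n + ks, c(1, 1), 1)
  }
  dev_ub <- pmax(abs(lb - v_ref), abs(ub - v_ref))
  list(n = n, nb = nb, nvar = nvar, bins = bins, idx = idx,
       A_eq = A_eq, b_eq = b_eq,
       A_ub = if (length(rows)) do.call(rbind, rows) else NULL, b_ub = rhs,
       lb = c(lb, rep(0, n), rep(0, nb)),
       ub = c(ub, dev_ub, rep(1, nb)))
}

#' Score one knockout's transformation ability
#'
#' Blocks the given reactions (flux forced to zero) and scores how far
#' the network is pushed from the source flux state `v_ref` toward the
#' target change requirements. Under the default `"anchor"` policy the
#' network first settles into the minimal total L1 flux adjustment
#' compatible with the knockout (stage 1, LP); the number of satisfied
#' change requirements `n_succ` is then maximized over that
#' minimal-adjustment face (stage 2, MILP), and the deviation of
#' steady-set reactions is minimized given the successes (stage 3, LP).
#' The transformation score is
#' `TS = n_succ / |r_forward| - lambda * D / (sum |v_ref[r_steady]| + 1)`
#' with `D` the steady-set L1 deviation (and `TS` equal to the penalty
#' term alone when there are no change requirements). The null knockout
#' (no blocked reactions) stays exactly at `v_ref`, giving the threshold
#' score `TS = 0`.
#'
#' @param model A `metabolic_model`.
#' @param v_ref Named reference flux (source state).
#' @param sets A `target_change_sets`.
#' @param blocked Character vector of reaction ids forced to zero flux.
#' @param params An [mta_params()].
#' @return list with `ts`, `n_succ`, `n_forward`, `deviation_steady`,
#'   `adjustment` (stage-1 total L1 adjustment), `flux`.
#' @export
mta_score_knockout <- function(model, v_ref, sets, blocked = character(0),
                               params = mta_params()) {
  v_ref <- v_ref[model$reactions$id]
  prob <- mta_build(model, v_ref, sets, blocked, params)
  n <- prob$n; nb <- prob$nb
  obj_dev <- c(rep(0, n), rep(1, n), rep(0, nb))
  obj_succ <- c(rep(0, 2L * n), rep(1, nb))

  budget_row <- NULL
  if (params$policy == "anchor") {
    st1 <- lp_solve(obj_dev, prob$A_eq, prob$b_eq, prob$A_ub, prob$b_ub,
                    prob$lb, prob$ub, maximize = FALSE)
    if (st1$status != "optimal") {
      stop("knockout leaves no feasible steady-state flux (bound pathology)",
           call. = FALSE)
    }
    budget <- st1$value + 1e-6 * (1 + abs(st1$value))
    budget_row <- list(A = matrix(obj_dev, 1), b = budget)
    adjustment <- st1$value
  } else {
    adjustment <- NA_real_
  }
  A_ub2 <- rbind(prob$A_ub, if (!is.null(budget_row)) budget_row$A)
  b_ub2 <- c(prob$b_ub, if (!is.null(budget_row)) budget_row$b)

  if (nb > 0) {
    st2 <- milp_solve(obj_succ, prob$A_eq, prob$b_eq, A_ub2, b_ub2,
                      prob$lb, prob$ub, binary_idx = 2L * n + seq_len(nb),
                      maximize = TRUE, integer_objective = TRUE)
    if (st2$status != "optimal") {
      stop("transformation MILP infeasible after knockout", call. = FALSE)
    }
    svals <- round(st2$x[2L * n + seq_len(nb)])
    n_succ <- sum(svals)
    # fix binaries, minimize steady deviation for a deterministic report
    lb3 <- prob$lb; ub3 <- prob$ub
    lb3[2L * n + seq_len(nb)] <- svals
    ub3[2L * n + seq_len(nb)] <- svals
    steady_idx <- prob$idx[sets$r_steady]
    obj_steady <- rep(0, prob$nvar)
    obj_steady[n + steady_idx] <- 1
    st3 <- lp_solve(obj_steady, prob$A_eq, prob$b_eq, A_ub2, b_ub2,
                    lb3, ub3, maximize = FALSE)
    sol <- if (st3$status == "optimal") st3 else st2
  } else {
    st2 <- lp_solve(obj_dev, prob$A_eq, prob$b_eq, A_ub2, b_ub2,
                    prob$lb, prob$ub, maximize = FALSE)
    if (st2$status != "optimal") {
      stop("transformation LP infeasible after knockout", call. = FALSE)
    }
    n_succ <- 0
    sol <- st2
  }
  v <- stats::setNames(sol$x[seq_len(n)], model$reactions$id)
  if (params$policy == "maximize" && nb > 0) adjustment <- sum(abs(v - v_ref))
  D <- sum(abs(v[sets$r_steady] - v_ref[sets$r_steady]))
  n_forward <- length(sets$r_forward_up) + length(sets$r_forward_down)
  denom <- sum(abs(v_ref[sets$r_steady])) + 1
  ts <- if (n_forward > 0) n_succ / n_forward - params$lambda * D / denom
        else -params$lambda * D / denom
  list(ts = ts, n_succ = n_succ, n_forward = n_forward,
       deviation_steady = D, adjustment = adjustment, flux = v)
}

#' Score every gene's knockout
#'
#' Computes, for each model gene, the reactions its knockout blocks
#' ([blocked_reactions_by_knockout()]) and the transformation score of
#' blocking them. Genes blocking no reaction score exactly the null
#' (no-knockout) score, which is also the significance threshold.
#' Identical blocked sets are solved once and shared.
#'
#' @inheritParams mta_score_knockout
#' @param metadata Optional named list recorded on the result (run labels
#'   such as comparison, timepoint, bootstrap index, omics layer).
#' @return An object of class `mta_run`: data.frame with columns `gene`,
#'   `ts`, `n_blocked`, plus attributes `threshold` (the null score) and
#'   `metadata`.
#' @export
mta_all_genes <- function(model, v_ref, sets, params = mta_params(),
                          metadata = list()) {
  null_score <- mta_score_knockout(model, v_ref, sets, character(0), params)
  cache <- new.env(parent = emptyenv())
  score_one <- function(blocked) {
    if (!length(blocked)) return(null_score$ts)
    key <- paste(sort(blocked), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    ts <- mta_score_knockout(model, v_ref, sets, blocked, params)$ts
    cache[[key]] <- ts
    ts
  }
  blocked_sets <- lapply(model$genes, blocked_reactions_by_knockout,
                         model = model)
  out <- data.frame(gene = model$genes,
                    ts = vapply(blocked_sets, score_one, 0),
                    n_blocked = lengths(blocked_sets),
                    stringsAsFactors = FALSE)
  structure(out, class = c("mta_run", "data.frame"),
            threshold = null_score$ts, metadata = metadata)
}

#' Rank-normalize one run's transformation scores
#'
#' Scores at or below the run's threshold (the null-knockout score) are
#' set to zero; the remaining genes are ranked ascending by score (ties
#' receive their average rank) and divided by their count, so the
#' top-scoring gene gets 1.
#'
#' @param run An `mta_run`.
#' @param tol Numerical slack when comparing against the threshold.
#' @return Named numeric vector in `[0, 1]` over the run's genes.
#' @export
rank_normalize <- function(run, tol = 1e-9) {
  thr <- attr(run, "threshold")
  out <- stats::setNames(rep(0, nrow(run)), run$gene)
  above <- run$ts > thr + tol
  m <- sum(above)
  if (m > 0) out[above] <- rank(run$ts[above], ties.method = "average") / m
  out
}

#' Full-data plus bootstrap transformation runs for one comparison
#'
#' Runs the complete scoring chain -- discretize states, extract the
#' source context network, derive its reference flux and the target
#' change sets, score all gene knockouts -- on the full DE table and on
#' `bootstrap_runs` resampled tables in which a random fraction of genes
#' (all their rows) has been removed. Removal sets depend only on
#' `params$seed`, so runs are reproducible.
#'
#' @param de A `de_table`.
#' @param model A `metabolic_model`.
#' @param design A [study_design()].
#' @param source,target Contexts (`list(condition=, timepoint=)`), sharing
#'   a time point.
#' @param params An [mta_params()].
#' @param imat_par An [imat_params()].
#' @param alpha,lfc_min Discretization thresholds.
#' @return list of `mta_run` objects: the full-data run (bootstrap index
#'   0) followed by the bootstrap runs.
#' @export
bootstrap_runs <- function(de, model, design, source, target,
                           params = mta_params(), imat_par = imat_params(),
                           alpha = 0.05, lfc_min = 0) {
  source <- as_context(source)
  target <- as_context(target)
  genes <- unique(de$gene)
  n_remove <- round(params$bootstrap_fraction * length(genes))
  removal <- with_seed(params$seed, {
    lapply(seq_len(params$bootstrap_runs), function(i) sample(genes, n_remove))
  })
  run_one <- function(de_run, boot_index) {
    states <- discretize_states(de_run, design, alpha = alpha, lfc_min = lfc_min)
    sl <- state_slice(states, source$condition, source$timepoint)
    nets <- imat_solve(model, map_states_to_reactions(model, sl),
                       params = imat_par,
                       context = c(source$condition, source$timepoint))
    v_ref <- reference_flux(model, nets)
    sets <- derive_change_sets(de_run, source, target, model, v_ref,
                               alpha = alpha,
                               epsilon_change = params$epsilon_change)
    mta_all_genes(model, v_ref, sets, params,
                  metadata = list(source = source, target = target,
                                  bootstrap = boot_index))
  }
  runs <- list(run_one(de, 0L))
  for (i in seq_len(params$bootstrap_runs)) {
    de_b <- de[!de$gene %in% removal[[i]], , drop = FALSE]
    runs[[i + 1L]] <- run_one(de_b, i)
  }
  runs
}

#' Aggregate rank-normalized scores across the runs of a set
#'
#' Each run is rank-normalized, the per-gene scores are averaged across
#' all runs of the set, and the means are rescaled so the top gene scores
#' 1 (when any mean is positive).
#'
#' @param runs list of `mta_run` objects (or of already rank-normalized
#'   named vectors).
#' @return Named numeric vector in `[0, 1]`.
#' @export
aggregate_scores <- function(runs) {
  if (!length(runs)) stop("aggregate_scores() needs at least one run",
                          call. = FALSE)
  norm <- lapply(runs, function(r) if (inherits(r, "mta_run")) rank_normalize(r) else r)
  genes <- unique(unlist(lapply(norm, names)))
  M <- vapply(norm, function(v) {
    out <- stats::setNames(rep(0, length(genes)), genes)
    out[names(v)] <- v
    out
  }, numeric(length(genes)))
  M <- matrix(M, nrow = length(genes), dimnames = list(genes, NULL))
  means <- rowMeans(M)
  mx <- max(means)
  if (mx > 0) means <- means / mx
  means
}

#' Signed overall transformation score
#'
#' Sums the aggregated forward-transition scores over omics layers and
#' subtracts the aggregated reverse-transition scores: positive overall
#' scores mark genes mediating the forward transition (for the
#' colonization study, microbiota diet to control diet), negative scores
#' the reverse. Exactly antisymmetric under exchanging the two inputs.
#'
#' @param forward,reverse A named score vector, or a (possibly named)
#'   list of such vectors, one per omics layer. Genes absent from a
#'   vector contribute 0.
#' @return Named numeric vector over the union of genes, sorted by
#'   decreasing score.
#' @export
overall_score <- function(forward, reverse) {
  as_layers <- function(x) if (is.list(x)) x else list(x)
  fwd <- as_layers(forward)
  rev <- as_layers(reverse)
  genes <- unique(unlist(lapply(c(fwd, rev), names)))
  total <- stats::setNames(rep(0, length(genes)), genes)
  for (m in fwd) total[names(m)] <- total[names(m)] + m
  for (m in rev) total[names(m)] <- total[names(m)] - m
  sort(total, decreasing = TRUE)
}
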