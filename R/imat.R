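# Step 2 of the network analysis: context-specific subnetwork extraction.
# Reactions inherit ON/OFF evidence from gene states through their GPR
# rules; a mixed-integer program then selects a steady-state flux
# distribution that activates as many ON-evidence reactions (|v| >= eps)
# and silences as many OFF-evidence reactions (v = 0) as possible.

#' Parameters of the flux-activity optimization
#'
#' @param epsilon Minimum flux magnitude (in the model's flux units) for a
#'   reaction to count as active (default 1, matching default bound
#'   magnitudes of 1000 so that big-M constants stay moderate).
#' @param delta Zero-flux tolerance when classifying activity from the
#'   returned optimum (default 1e-6); must satisfy `0 < delta < epsilon`.
#' @param node_limit Branch-and-bound node budget.
#' @return A list of class `imat_params`.
#' @export
imat_params <- function(epsilon = 1, delta = 1e-6, node_limit = 100000L) {
  stopifnot(delta > 0, delta < epsilon)
  structure(list(epsilon = epsilon, delta = delta,
                 node_limit = as.integer(node_limit)),
            class = "imat_params")
}

#' Map gene states to reaction evidence sets
#'
#' Each reaction's GPR rule is evaluated under the tri-valued gene states
#' ([evaluate_gpr_state()]); evidence +1 places the reaction in `r_high`,
#' -1 in `r_low`, 0 (including all reactions without a gene association)
#' in neither.
#'
#' @param model A `metabolic_model`.
#' @param states Named numeric vector of gene states in `{-1,0,1}` (see
#'   [state_slice()]); absent genes default to 0.
#' @return list of class `reaction_state_sets` with character vectors
#'   `r_high`, `r_low`.
#' @export
map_states_to_reactions <- function(model, states) {
  ev <- vapply(model$gpr, evaluate_gpr_state, 0, states = states)
  structure(list(r_high = model$reactions$id[ev > 0],
                 r_low = model$reactions$id[ev < 0]),
            class = "reaction_state_sets")
}

# Shared MILP scaffolding: returns constraint blocks and binary metadata
# for the iMAT problem. Variables: v (n reactions), then for each r_high
# reaction a forward indicator y+ (v >= eps) and, if reversible enough, a
# backward indicator y- (v <= -eps), then one z per r_low (v = 0).
imat_build <- function(model, sets, params) {
  rxns <- model$reactions
  n <- nrow(rxns)
  if (any(!is.finite(rxns$lower_bound)) || any(!is.finite(rxns$upper_bound))) {
    stop("flux-activity optimization requires finite bounds", call. = FALSE)
  }
  if (any(rxns$lower_bound > 0) || any(rxns$upper_bound < 0)) {
    stop("flux-activity optimization requires 0 within every bound interval (v = 0 must be feasible)",
         call. = FALSE)
  }
  eps <- params$epsilon
  idx <- stats::setNames(seq_len(n), rxns$id)
  bin <- list()   # each: list(rxn, kind)
  for (r in sets$r_high) {
    if (rxns$upper_bound[idx[r]] >= eps) {
      bin[[length(bin) + 1L]] <- list(rxn = r, kind = "y_fwd")
    }
    if (rxns$lower_bound[idx[r]] <= -eps) {
      bin[[length(bin) + 1L]] <- list(rxn = r, kind = "y_rev")
    }
  }
  for (r in sets$r_low) bin[[length(bin) + 1L]] <- list(rxn = r, kind = "z")
  nb <- length(bin)
  nvar <- n + nb
  A_eq <- cbind(model$stoichiometry, matrix(0, nrow(model$stoichiometry), nb))
  b_eq <- rep(0, nrow(A_eq))
  A_ub <- NULL; b_ub <- NULL
  add_row <- function(row, rhs) {
    A_ub <<- rbind(A_ub, row)
    b_ub <<- c(b_ub, rhs)
  }
  for (k in seq_len(nb)) {
    b <- bin[[k]]
    j <- idx[b$rxn]
    lbj <- rxns$lower_bound[j]; ubj <- rxns$upper_bound[j]
    row <- rep(0, nvar)
    if (b$kind == "y_fwd") {       # v_j >= lb + y (eps - lb)
      row[j] <- -1; row[n + k] <- eps - lbj
      add_row(row, -lbj)
    } else if (b$kind == "y_rev") { # v_j <= ub + y (-eps - ub)
      row[j] <- 1; row[n + k] <- eps + ubj
      add_row(row, ubj)
    } else {                        # z: v_j <= ub(1-z), v_j >= lb(1-z)
      row[j] <- 1; row[n + k] <- ubj
      add_row(row, ubj)
      row <- rep(0, nvar)
      row[j] <- -1; row[n + k] <- -lbj
      add_row(row, -lbj)
    }
  }
  # y_fwd + y_rev <= 1 for reactions carrying both indicators
  kinds <- vapply(bin, `[[`, "", "kind")
  brxn <- vapply(bin, `[[`, "", "rxn")
  for (r in unique(brxn[kinds != "z"])) {
    ks <- which(brxn == r & kinds != "z")
    if (length(ks) == 2) {
      row <- rep(0, nvar)
      row[n + ks] <- 1
      add_row(row, 1)
    }
  }
  list(n = n, nb = nb, nvar = nvar, bin = bin,
       A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
       lb = c(rxns$lower_bound, rep(0, nb)),
       ub = c(rxns$upper_bound, rep(1, nb)),
       obj = c(rep(0, n), rep(1, nb)), idx = idx)
}

# Parsimonious flux for a fixed satisfaction pattern: minimize sum |v|
# subject to steady state, bounds, |v_r| >= eps in the committed direction
# for satisfied high reactions, and v_r = 0 for satisfied low reactions.
imat_cleanup_flux <- function(model, params, sat_fwd, sat_rev, sat_zero) {
  rxns <- model$reactions
  n <- nrow(rxns)
  lb <- rxns$lower_bound; ub <- rxns$upper_bound
  idx <- stats::setNames(seq_len(n), rxns$id)
  eps <- params$epsilon
  lb[idx[sat_fwd]] <- pmax(lb[idx[sat_fwd]], eps)
  ub[idx[sat_rev]] <- pmin(ub[idx[sat_rev]], -eps)
  lb[idx[sat_zero]] <- 0; ub[idx[sat_zero]] <- 0
  if (any(lb > ub)) return(NULL)
  # Split v = p - m with p in [max(lb,0), max(ub,0)], m in [max(-ub,0),
  # max(-lb,0)]: the box reproduces lb <= v <= ub and minimizing sum(p + m)
  # drives p*m = 0, so the optimum value is the minimal total |v|.
  obj <- rep(1, 2 * n)
  A_eq <- cbind(model$stoichiometry, -model$stoichiometry)
  res <- lp_solve(obj, A_eq, rep(0, nrow(A_eq)),
                  lb = c(pmax(lb, 0), pmax(-ub, 0)),
                  ub = c(pmax(ub, 0), pmax(-lb, 0)),
                  maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  stats::setNames(v, rxns$id)
}

#' Extract a context-specific network by flux-activity optimization
#'
#' Solves the integrative flux-activity MILP: over steady-state flux
#' vectors `v` within bounds, maximize the number of `r_high` reactions
#' carrying `|v| >= epsilon` plus the number of `r_low` reactions with
#' `v = 0`. Indicator constraints are encoded as big-M rows with M taken
#' from the bound magnitudes. Among the optimal satisfaction patterns the
#' reported flux is the parsimonious one (minimum total `|v|` with the
#' pattern's activity commitments held fixed), so futile cycles that the
#' objective cannot see are not reported as active.
#'
#' @param model A `metabolic_model` with finite bounds containing 0.
#' @param sets A `reaction_state_sets` from [map_states_to_reactions()].
#' @param params An [imat_params()].
#' @param context Optional context label stored on the result.
#' @return An object of class `context_network`: list with `context`,
#'   `objective` (satisfied evidence count), `active_reactions`, `flux`
#'   (named vector), `sets`, `satisfied` (per-evidence logical), `params`.
#' @export
imat_solve <- function(model, sets, params = imat_params(), context = NULL) {
  prob <- imat_build(model, sets, params)
  if (prob$nb == 0) {
    flux <- stats::setNames(rep(0, prob$n), model$reactions$id)
    return(new_context_network(model, context, 0, flux, sets, params,
                               character(0), character(0), character(0)))
  }
  sol <- milp_solve(prob$obj, prob$A_eq, prob$b_eq, prob$A_ub, prob$b_ub,
                    prob$lb, prob$ub, binary_idx = prob$n + seq_len(prob$nb),
                    maximize = TRUE, integer_objective = TRUE,
                    node_limit = params$node_limit)
  if (sol$status != "optimal") {
    stop("flux-activity MILP reported infeasible; model bounds exclude v = 0?",
         call. = FALSE)
  }
  yz <- round(sol$x[prob$n + seq_len(prob$nb)])
  kinds <- vapply(prob$bin, `[[`, "", "kind")
  brxn <- vapply(prob$bin, `[[`, "", "rxn")
  sat_fwd <- brxn[kinds == "y_fwd" & yz == 1]
  sat_rev <- brxn[kinds == "y_rev" & yz == 1]
  sat_zero <- brxn[kinds == "z" & yz == 1]
  flux <- imat_cleanup_flux(model, params, sat_fwd, sat_rev, sat_zero)
  if (is.null(flux)) flux <- stats::setNames(sol$x[seq_len(prob$n)],
                                             model$reactions$id)
  new_context_network(model, context, round(sol$value), flux, sets, params,
                      sat_fwd, sat_rev, sat_zero)
}

new_context_network <- function(model, context, objective, flux, sets, params,
                                sat_fwd, sat_rev, sat_zero) {
  active <- names(flux)[abs(flux) > params$delta]
  structure(list(context = context, objective = objective,
                 active_reactions = active, flux = flux, sets = sets,
                 satisfied = list(forward = sat_fwd, reverse = sat_rev,
                                  zero = sat_zero),
                 params = params),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat(sprintf("<context_network> %s: objective %d, %d active reactions\n",
              if (is.null(x$context)) "(unlabeled)" else paste(x$context, collapse = "/"),
              x$objective, length(x$active_reactions)))
  invisible(x)
}

#' Brute-force oracle for the flux-activity optimization
#'
#' Enumerates every satisfaction assignment (direction-resolved for
#' `r_high`, zero-flux for `r_low`), checks each by LP feasibility, and
#' returns a maximal feasible assignment. Intended as an independent check
#' of [imat_solve()] on small fixtures; refuses more than 16 evidence
#' labels.
#'
#' @inheritParams imat_solve
#' @return A `context_network` (flux taken parsimonious, as in
#'   [imat_solve()]).
#' @export
imat_bruteforce <- function(model, sets, params = imat_params(), context = NULL) {
  n_ev <- length(sets$r_high) + length(sets$r_low)
  if (n_ev > 16) {
    stop("imat_bruteforce() refuses more than 16 evidence labels", call. = FALSE)
  }
  rxns <- model$reactions
  idx <- stats::setNames(seq_len(nrow(rxns)), rxns$id)
  eps <- params$epsilon
  items <- c(lapply(sets$r_high, function(r) list(rxn = r, high = TRUE)),
             lapply(sets$r_low, function(r) list(rxn = r, high = FALSE)))
  S <- model$stoichiometry
  feasible <- function(lb, ub) {
    !is.null(lp_feasible_point(A_eq = S, b_eq = rep(0, nrow(S)), lb = lb, ub = ub))
  }
  best <- list(score = -1L, fwd = character(0), rev = character(0),
               zero = character(0))
  recurse <- function(k, lb, ub, score, fwd, rev, zero) {
    if (score + (length(items) - k + 1L) <= best$score) return()
    if (k > length(items)) {
      if (score > best$score) {
        best <<- list(score = score, fwd = fwd, rev = rev, zero = zero)
      }
      return()
    }
    it <- items[[k]]
    j <- idx[it$rxn]
    if (it$high) {
      if (ub[j] >= eps) {       # satisfy forward
        lb2 <- lb; lb2[j] <- max(lb[j], eps)
        if (feasible(lb2, ub)) {
          recurse(k + 1L, lb2, ub, score + 1L, c(fwd, it$rxn), rev, zero)
        }
      }
      if (lb[j] <= -eps) {      # satisfy backward
        ub2 <- ub; ub2[j] <- min(ub[j], -eps)
        if (feasible(lb, ub2)) {
          recurse(k + 1L, lb, ub2, score + 1L, fwd, c(rev, it$rxn), zero)
        }
      }
    } else {
      lb2 <- lb; ub2 <- ub; lb2[j] <- 0; ub2[j] <- 0
      if (feasible(lb2, ub2)) {
        recurse(k + 1L, lb2, ub2, score + 1L, fwd, rev, c(zero, it$rxn))
      }
    }
    recurse(k + 1L, lb, ub, score, fwd, rev, zero)  # leave unsatisfied
  }
  recurse(1L, rxns$lower_bound, rxns$upper_bound, 0L,
          character(0), character(0), character(0))
  flux <- imat_cleanup_flux(model, params, best$fwd, best$rev, best$zero)
  if (is.null(flux)) flux <- stats::setNames(rep(0, nrow(rxns)), rxns$id)
  new_context_network(model, context, best$score, flux, sets, params,
                      best$fwd, best$rev, best$zero)
}

#' Reference flux vector of a context network
#'
#' The L1-norm-minimal steady-state flux that keeps every satisfied
#' high-evidence reaction active (|v| >= epsilon, in the direction the
#' optimization committed to). This is the deterministic source state
#' consumed by the transformation scoring.
#'
#' @param model The `metabolic_model` the context was extracted from.
#' @param context A `context_network` from [imat_solve()].
#' @return Named flux vector over all reactions.
#' @export
reference_flux <- function(model, context) {
  flux <- imat_cleanup_flux(model, context$params,
                            intersect(context$satisfied$forward,
                                      context$active_reactions),
                            intersect(context$satisfied$reverse,
                                      context$active_reactions),
                            character(0))
  if (is.null(flux)) {
    stop("reference flux LP unexpectedly infeasible", call. = FALSE)
  }
  flux
}
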