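# Pathway-level summaries of context-specific networks: active-reaction
# counts per subsystem, between-diet differences with top-k selection, and
# an ordination (PCA) of the binary reaction-activity profiles.

#' Count active reactions per subsystem and context
#'
#' @param model The shared `metabolic_model`.
#' @param networks Named list of `context_network`s (names become column
#'   labels; unnamed lists use their `context` fields).
#' @return Integer matrix, subsystems x contexts; each column sums to the
#'   size of that context's active set.
#' @export
count_active_by_subsystem <- function(model, networks) {
  labels <- names(networks)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(seq_along(networks), function(i) {
      ctx <- networks[[i]]$context
      if (is.null(ctx)) paste0("context", i) else paste(ctx, collapse = ":")
    }, "")
  }
  subs <- sort(unique(model$reactions$subsystem))
  sub_of <- stats::setNames(model$reactions$subsystem, model$reactions$id)
  out <- matrix(0L, length(subs), length(networks),
                dimnames = list(subs, labels))
  for (i in seq_along(networks)) {
    act <- networks[[i]]$active_reactions
    unknown <- setdiff(act, model$reactions$id)
    if (length(unknown)) {
      stop("context network references reactions absent from the model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (length(act)) {
      tab <- table(sub_of[act])
      out[names(tab), i] <- as.integer(tab)
    }
  }
  out
}

#' Between-group differences in subsystem activity
#'
#' Signed difference of mean active-reaction counts between two groups of
#' contexts (for the colonization study: the two microbiota conditions
#' versus the control diet), plus the `top_k` subsystems with the largest
#' absolute difference (ties broken by subsystem name).
#'
#' @param table Count matrix from [count_active_by_subsystem()].
#' @param group_a,group_b Disjoint, non-empty character vectors of column
#'   labels.
#' @param top_k How many subsystems to flag (default 8; clamped to the
#'   subsystem count).
#' @return data.frame with columns `subsystem`, `mean_a`, `mean_b`,
#'   `diff` (`mean_a - mean_b`) and logical `top`; rows ordered by
#'   decreasing `|diff|` then subsystem name.
#' @export
pathway_differences <- function(table, group_a, group_b, top_k = 8L) {
  if (!length(group_a) || !length(group_b)) {
    stop("both context groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("context groups must be disjoint", call. = FALSE)
  }
  unknown <- setdiff(c(group_a, group_b), colnames(table))
  if (length(unknown)) {
    stop("unknown context label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mean_a <- rowMeans(table[, group_a, drop = FALSE])
  mean_b <- rowMeans(table[, group_b, drop = FALSE])
  d <- mean_a - mean_b
  ord <- order(-abs(d), rownames(table))
  out <- data.frame(subsystem = rownames(table)[ord], mean_a = mean_a[ord],
                    mean_b = mean_b[ord], diff = d[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$top <- seq_len(nrow(out)) <= min(top_k, nrow(out))
  out
}

#' Ordination of context networks by binary reaction activity
#'
#' Principal component analysis of the contexts x reactions 0/1 activity
#' matrix (centered, not scaled). Contexts with similar active subnetworks
#' co-locate; the first components separate the dominant activity shifts.
#'
#' @param networks Named list of >= 3 `context_network`s.
#' @return list with `scores` (contexts x 2 matrix of PC scores) and
#'   `explained` (variance fractions of the two components). Identical
#'   networks yield zero coordinates with a warning.
#' @export
activity_pca <- function(networks) {
  if (length(networks) < 3) {
    stop("activity_pca() needs at least 3 context networks", call. = FALSE)
  }
  rxn_ids <- names(networks[[1]]$flux)
  M <- t(vapply(networks, function(nw) {
    as.numeric(rxn_ids %in% nw$active_reactions)
  }, numeric(length(rxn_ids))))
  labels <- names(networks)
  if (is.null(labels)) labels <- paste0("context", seq_along(networks))
  rownames(M) <- labels
  Mc <- scale(M, center = TRUE, scale = FALSE)
  if (max(abs(Mc)) < 1e-12) {
    warning("all context networks are identical; PCA is degenerate")
    return(list(scores = matrix(0, nrow(M), 2,
                                dimnames = list(labels, c("PC1", "PC2"))),
                explained = c(PC1 = 0, PC2 = 0)))
  }
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  scores <- matrix(0, nrow(M), 2, dimnames = list(labels, c("PC1", "PC2")))
  scores[, seq_len(k)] <- p$x[, seq_len(k)]
  ev <- p$sdev^2 / sum(p$sdev^2)
  explained <- c(PC1 = ev[1], PC2 = if (length(ev) >= 2) ev[2] else 0)
  list(scores = scores, explained = explained)
}
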