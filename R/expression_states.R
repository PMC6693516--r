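# Step 1 of the network analysis: turn differential-expression summaries
# into tri-valued (ON / OFF / UNKNOWN) per-context gene activity states.

DE_COLUMNS <- c("gene", "cond_a", "time_a", "cond_b", "time_b", "log2fc", "padj")

#' Coerce and validate a differential-expression table
#'
#' A DE table has one row per (gene, comparison): columns `gene`,
#' `cond_a`, `time_a`, `cond_b`, `time_b`, `log2fc` (positive when higher
#' on side a) and `padj` (FDR-adjusted p-value in `[0,1]`). Comparisons are
#' either cross-condition at a shared time point or within-condition
#' between time points.
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame with class `de_table` prepended.
#' @export
as_de_table <- function(df) {
  missing_cols <- setdiff(DE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("DE table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[DE_COLUMNS]
  bad <- which(!is.finite(df$padj) | df$padj < 0 | df$padj > 1)
  if (length(bad)) {
    stop("DE table: padj outside [0,1] at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$log2fc))
  if (length(bad)) {
    stop("DE table: non-finite log2fc at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  same_side <- which(df$cond_a == df$cond_b & df$time_a == df$time_b)
  if (length(same_side)) {
    stop("DE table: side_a equals side_b at row(s) ",
         paste(utils::head(same_side, 10), collapse = ", "), call. = FALSE)
  }
  mixed <- which(df$cond_a != df$cond_b & df$time_a != df$time_b)
  if (length(mixed)) {
    stop("DE table: comparison mixes condition and time at row(s) ",
         paste(utils::head(mixed, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$gene, df$cond_a, df$time_a, df$cond_b, df$time_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("DE table: duplicated (gene, side_a, side_b) at row(s) ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("de_table", class(df))
  df
}

#' Read a differential-expression table from TSV
#'
#' Expects the five-column on-disk schema `gene`, `side_a`, `side_b`,
#' `log2fc`, `padj`, where a side is encoded `condition:timepoint`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `de_table`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("DE table not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "side_a", "side_b", "log2fc", "padj")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("DE table '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  split_side <- function(x, col) {
    parts <- regmatches(x, regexpr(":", x), invert = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      stop(sprintf("DE table '%s': malformed %s (expected condition:timepoint) at row(s) %s",
                   path, col, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
    do.call(rbind, parts)
  }
  if (nrow(raw) == 0) {
    return(as_de_table(data.frame(gene = character(0), cond_a = character(0),
                                  time_a = character(0), cond_b = character(0),
                                  time_b = character(0), log2fc = numeric(0),
                                  padj = numeric(0), stringsAsFactors = FALSE)))
  }
  a <- split_side(raw$side_a, "side_a")
  b <- split_side(raw$side_b, "side_b")
  as_de_table(data.frame(gene = raw$gene, cond_a = a[, 1], time_a = a[, 2],
                         cond_b = b[, 1], time_b = b[, 2],
                         log2fc = as.numeric(raw$log2fc),
                         padj = as.numeric(raw$padj), stringsAsFactors = FALSE))
}

#' Write a differential-expression table as TSV
#'
#' @param de A `de_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(gene = de$gene,
                    side_a = paste(de$cond_a, de$time_a, sep = ":"),
                    side_b = paste(de$cond_b, de$time_b, sep = ":"),
                    log2fc = de$log2fc, padj = de$padj,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genes eligible for state assignment
#'
#' A gene enters the discretization only when at least one of its
#' comparisons has an adjusted p-value strictly below `alpha`; all other
#' genes are left UNKNOWN in every context.
#'
#' @param de A `de_table`.
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of eligible gene ids.
#' @export
eligible_genes <- function(de, alpha = 0.05) {
  unique(de$gene[de$padj < alpha])
}

#' Discretize gene activity states per condition and time point
#'
#' For each eligible gene and each context (condition, timepoint), all
#' comparisons involving that context are collected: cross-condition
#' comparisons at the context's time point and within-condition
#' comparisons to the adjacent (preceding and following) time points. A
#' comparison with `padj < alpha` and `|log2fc| >= lfc_min` casts an ON
#' vote for its higher side and an OFF vote for its lower side; all other
#' comparisons abstain. The state is the vote majority; ties and zero
#' votes give UNKNOWN, and ineligible genes are UNKNOWN in every context.
#' The rule is sign-symmetric: negating all fold-changes swaps ON and OFF.
#'
#' @param de A `de_table` whose conditions/timepoints appear in `design`.
#' @param design A [study_design()].
#' @param alpha Significance threshold (default 0.05).
#' @param lfc_min Minimum absolute log2 fold-change for a vote
#'   (default 0: every significant comparison votes).
#' @return An object of class `gene_state_table`: data.frame with columns
#'   `gene`, `condition`, `timepoint`, `state` and attributes `alpha`,
#'   `lfc_min`.
#' @export
discretize_states <- function(de, design, alpha = 0.05, lfc_min = 0) {
  conds <- design$conditions
  tps <- design$timepoints$label
  bad_cond <- setdiff(unique(c(de$cond_a, de$cond_b)), conds)
  bad_tp <- setdiff(unique(c(de$time_a, de$time_b)), tps)
  if (length(bad_cond) || length(bad_tp)) {
    stop("DE table contains contexts absent from the design: ",
         paste(c(bad_cond, bad_tp), collapse = ", "), call. = FALSE)
  }
  genes <- unique(de$gene)
  elig <- eligible_genes(de, alpha)

  votes <- de[de$padj < alpha & abs(de$log2fc) >= lfc_min & de$log2fc != 0 &
                de$gene %in% elig, , drop = FALSE]
  # Within-condition comparisons must be between adjacent time points to
  # count as evidence for either side.
  tp_idx <- stats::setNames(seq_along(tps), tps)
  within <- votes$cond_a == votes$cond_b
  adjacent <- abs(tp_idx[votes$time_a] - tp_idx[votes$time_b]) == 1L
  votes <- votes[!within | adjacent, , drop = FALSE]

  up_a <- votes$log2fc > 0
  ballots <- data.frame(
    gene = c(votes$gene, votes$gene),
    condition = c(votes$cond_a, votes$cond_b),
    timepoint = c(votes$time_a, votes$time_b),
    on = c(up_a, !up_a), stringsAsFactors = FALSE)

  grid <- expand.grid(gene = genes, condition = conds, timepoint = tps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$state <- "UNKNOWN"
  if (nrow(ballots)) {
    key <- paste(ballots$gene, ballots$condition, ballots$timepoint, sep = "\r")
    net <- tapply(ifelse(ballots$on, 1L, -1L), key, sum)
    gkey <- paste(grid$gene, grid$condition, grid$timepoint, sep = "\r")
    m <- as.vector(net[gkey])
    m[is.na(m)] <- 0L
    grid$state <- ifelse(m > 0, "ON", ifelse(m < 0, "OFF", "UNKNOWN"))
  }
  structure(grid, class = c("gene_state_table", "data.frame"),
            alpha = alpha, lfc_min = lfc_min)
}

#' Extract one context's gene states as a numeric vector
#'
#' @param states A `gene_state_table`.
#' @param condition,timepoint Context labels.
#' @return Named numeric vector over genes with ON = +1, UNKNOWN = 0,
#'   OFF = -1, suitable for [evaluate_gpr_state()].
#' @export
state_slice <- function(states, condition, timepoint) {
  sel <- states$condition == condition & states$timepoint == timepoint
  if (!any(sel)) {
    stop(sprintf("no states for context (%s, %s)", condition, timepoint),
         call. = FALSE)
  }
  s <- states$state[sel]
  stats::setNames(ifelse(s == "ON", 1, ifelse(s == "OFF", -1, 0)),
                  states$gene[sel])
}

#' Write a gene state table (TSV plus JSON sidecar with parameters)
#'
#' @param states A `gene_state_table`.
#' @param path Output TSV path; the sidecar is written as
#'   `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(states, path) {
  utils::write.table(as.data.frame(states), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(alpha = attr(states, "alpha"),
                            lfc_min = attr(states, "lfc_min")),
                       paste0(path, ".params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
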