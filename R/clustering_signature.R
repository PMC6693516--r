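# Transcriptome-side stages: K-means clustering of log2 fold-changes with
# AIC-based choice of the cluster number, core-signature overlap counts,
# transcriptome/proteome concordance, and expression PCA.

#' K-means clustering with AIC-based cluster-number selection
#'
#' For each candidate `k`, runs Lloyd's K-means (best of `restarts`
#' seeded starts, Euclidean distance) on the genes x contrasts
#' fold-change matrix and evaluates an information criterion built on the
#' spherical Gaussian likelihood with shared variance,
#' `-2 log L = n*d*log(RSS/(n*d))` with `n` genes, `d` contrasts and
#' `RSS` the total within-cluster sum of squares (floored at 1e-12),
#' using `p = k*d` mean parameters:
#' * `"aicc"` (default): `-2 log L + 2p + 2p(p+1)/(n-p-1)`, the
#'   small-sample corrected AIC (`Inf` when `p + 1 >= n`). The
#'   correction matters here: K-means optimizes assignments as well as
#'   means, so the uncorrected penalty `2p` is too weak to stop cluster
#'   splitting that only chases noise.
#' * `"aic"`: `-2 log L + 2p`.
#' * `"bic"`: `-2 log L + log(n*d) * p`.
#'
#' The reported clustering is the one with the lowest criterion value.
#'
#' @param fc Numeric matrix of log2 fold-changes, genes in rows.
#' @param k_range Candidate cluster numbers (default `2:15`); must stay
#'   below the number of distinct rows.
#' @param restarts Random restarts per `k` (default 25).
#' @param seed Integer seed making the restarts reproducible.
#' @param criterion `"aicc"` (default), `"aic"` or `"bic"`.
#' @return An object of class `kmeans_aic` with elements `k` (chosen),
#'   `assignment` (named vector), `aic` (data.frame k/rss/aic), `centers`
#'   (chosen k's mean profiles) and `order` (row order for heatmap
#'   export: clusters contiguous, genes by decreasing correlation with
#'   their cluster profile).
#' @export
kmeans_aic <- function(fc, k_range = 2:15, restarts = 25L, seed = 1L,
                       criterion = c("aicc", "aic", "bic")) {
  criterion <- match.arg(criterion)
  fc <- as.matrix(fc)
  if (nrow(fc) < 2) stop("need at least 2 genes to cluster", call. = FALSE)
  if (!all(is.finite(fc))) stop("fold-change matrix has non-finite entries",
                                call. = FALSE)
  if (!length(k_range)) stop("k_range is empty", call. = FALSE)
  n <- nrow(fc); d <- ncol(fc)
  n_distinct <- nrow(unique(fc))
  if (n_distinct == 1) {
    warning("all fold-change rows are identical; returning a single cluster")
    assignment <- stats::setNames(rep(1L, n), rownames(fc))
    return(structure(list(k = 1L, assignment = assignment,
                          aic = data.frame(k = 1L, rss = 0,
                                           aic = kmeans_aic_value(0, n, d, 1L,
                                                                  criterion)),
                          centers = fc[1, , drop = FALSE],
                          order = seq_len(n), criterion = criterion),
                     class = "kmeans_aic"))
  }
  k_range <- k_range[k_range >= 1 & k_range <= n_distinct]
  if (!length(k_range)) {
    stop("k_range has no usable values below the distinct row count",
         call. = FALSE)
  }
  fits <- with_seed(seed, {
    lapply(k_range, function(k) {
      best <- NULL
      for (r in seq_len(restarts)) {
        fit <- tryCatch(
          stats::kmeans(fc, centers = k, iter.max = 100L,
                        algorithm = "Lloyd", nstart = 1L),
          error = function(e) NULL, warning = function(w) {
            tryCatch(suppressWarnings(
              stats::kmeans(fc, centers = k, iter.max = 200L,
                            algorithm = "Lloyd", nstart = 1L)),
              error = function(e) NULL)
          })
        if (!is.null(fit) &&
            (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
          best <- fit
        }
      }
      best
    })
  })
  ok <- !vapply(fits, is.null, logical(1))
  k_range <- k_range[ok]; fits <- fits[ok]
  if (!length(fits)) stop("K-means failed for every k in k_range", call. = FALSE)
  rss <- vapply(fits, function(f) f$tot.withinss, 0)
  aic <- vapply(seq_along(fits), function(i) {
    kmeans_aic_value(rss[i], n, d, k_range[i], criterion)
  }, 0)
  pick <- which.min(aic)
  fit <- fits[[pick]]
  assignment <- stats::setNames(fit$cluster, rownames(fc))
  ord <- order_for_heatmap(fc, assignment, fit$centers)
  structure(list(k = k_range[pick], assignment = assignment,
                 aic = data.frame(k = k_range, rss = rss, aic = aic),
                 centers = fit$centers, order = ord, criterion = criterion),
            class = "kmeans_aic")
}

kmeans_aic_value <- function(rss, n, d, k, criterion = "aicc") {
  neg2ll <- n * d * log(max(rss, 1e-12) / (n * d))
  p <- k * d
  switch(criterion,
         aic = neg2ll + 2 * p,
         bic = neg2ll + log(n * d) * p,
         aicc = if (n - p - 1 <= 0) Inf
                else neg2ll + 2 * p + 2 * p * (p + 1) / (n - p - 1))
}

order_for_heatmap <- function(fc, assignment, centers) {
  ord <- integer(0)
  for (k in sort(unique(assignment))) {
    rows <- which(assignment == k)
    if (length(rows) > 1) {
      ctr <- centers[k, ]
      cors <- apply(fc[rows, , drop = FALSE], 1, function(x) {
        if (stats::sd(x) < 1e-12 || stats::sd(ctr) < 1e-12) 0
        else stats::cor(x, ctr)
      })
      rows <- rows[order(-cors)]
    }
    ord <- c(ord, rows)
  }
  ord
}

#' @export
print.kmeans_aic <- function(x, ...) {
  cat(sprintf("<kmeans_aic> chose k = %d (AIC %.1f) over k in {%s}\n",
              x$k, min(x$aic$aic), paste(range(x$aic$k), collapse = "..")))
  invisible(x)
}

#' Overlap counts of two responsive-gene sets
#'
#' Standard two-set (Venn) arithmetic for core-signature comparisons,
#' e.g. the genes responding to each of two microbiota isolates.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return list with `only_a`, `only_b`, `both`, `union` counts.
#' @export
core_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- length(intersect(set_a, set_b))
  list(only_a = length(set_a) - both, only_b = length(set_b) - both,
       both = both, union = length(union(set_a, set_b)))
}

#' Transcriptome-proteome concordance
#'
#' Pearson correlation of log2 fold-changes over the shared genes, plus
#' direction-consistency counts: among proteins with increased abundance,
#' how many transcripts also go up (and likewise for decreases).
#' `protein_fc` is expected to contain the significantly changed proteins
#' only; consistency percentages are relative to the up- and
#' down-regulated protein counts.
#'
#' @param transcript_fc Named numeric vector of transcript log2
#'   fold-changes.
#' @param protein_fc Named numeric vector of log2 fold-changes of
#'   significantly changed proteins.
#' @return list with `n_shared`, `pearson_r`, `r_squared`,
#'   `n_protein_up`, `n_protein_down`, `n_consistent_up`,
#'   `n_consistent_down`, `pct_consistent_up`, `pct_consistent_down`
#'   (percentages on 0-100, exact; round to one decimal for display).
#' @export
omics_concordance <- function(transcript_fc, protein_fc) {
  shared <- intersect(names(transcript_fc), names(protein_fc))
  if (length(shared) < 3) {
    stop("omics_concordance() needs at least 3 shared genes", call. = FALSE)
  }
  t_fc <- transcript_fc[shared]
  p_fc <- protein_fc[shared]
  r <- stats::cor(t_fc, p_fc, method = "pearson")
  up <- p_fc > 0
  down <- p_fc < 0
  n_up <- sum(up); n_down <- sum(down)
  n_cons_up <- sum(up & t_fc > 0)
  n_cons_down <- sum(down & t_fc < 0)
  list(n_shared = length(shared), pearson_r = r, r_squared = r^2,
       n_protein_up = n_up, n_protein_down = n_down,
       n_consistent_up = n_cons_up, n_consistent_down = n_cons_down,
       pct_consistent_up = if (n_up) 100 * n_cons_up / n_up else NA_real_,
       pct_consistent_down = if (n_down) 100 * n_cons_down / n_down else NA_real_)
}

#' PCA of expression sample profiles
#'
#' Principal component analysis of (optionally log-transformed) sample
#' expression profiles, centered per gene; used to check which design
#' factors dominate transcriptomic variation.
#'
#' @param expr Numeric matrix, genes x samples (>= 4 samples).
#' @param n_components Components to return (default 3; reduced with a
#'   warning when fewer are available).
#' @param log_transform Apply `log2(x + 1)` first (default TRUE; set
#'   FALSE for matrices already on log scale).
#' @return list with `scores` (samples x components) and `explained`
#'   (variance fractions, non-increasing).
#' @export
expression_pca <- function(expr, n_components = 3L, log_transform = TRUE) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stop("expression_pca() needs at least 4 samples",
                           call. = FALSE)
  if (log_transform) expr <- log2(expr + 1)
  k_max <- min(ncol(expr) - 1L, nrow(expr))
  if (n_components > k_max) {
    warning(sprintf("only %d components available; reducing", k_max))
    n_components <- k_max
  }
  p <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)])
}
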