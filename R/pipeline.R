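# End-to-end orchestration: one configuration drives discretization,
# per-context network extraction, pathway summaries, transformation
# scoring in both directions with bootstraps, and (optionally) the
# clustering stage; every artifact lands in an output directory together
# with a manifest recording parameters, seed and content hashes.

#' Build a pipeline configuration
#'
#' @param model_path Path to a model file readable by [load_model()].
#' @param de_paths Named character vector/list of DE table TSVs, one per
#'   omics layer (e.g. `c(transcriptome = "de_transcriptome.tsv")`).
#' @param out_dir Output directory for all artifacts.
#' @param design A [study_design()].
#' @param alpha,lfc_min Discretization thresholds.
#' @param imat An [imat_params()].
#' @param mta An [mta_params()].
#' @param k_range Candidate cluster numbers for the clustering stage.
#' @param seed Global seed; recorded in the manifest and used to derive
#'   all stage seeds.
#' @param stages Character vector of stage toggles, any of
#'   `"discretize"`, `"imat"`, `"pathways"`, `"mta"`, `"cluster"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(model_path, de_paths, out_dir,
                            design = study_design(),
                            alpha = 0.05, lfc_min = 0,
                            imat = imat_params(), mta = mta_params(),
                            k_range = 2:15, seed = 1L,
                            stages = c("discretize", "imat", "pathways",
                                       "mta", "cluster")) {
  structure(list(model_path = model_path, de_paths = as.list(de_paths),
                 out_dir = out_dir, design = design, alpha = alpha,
                 lfc_min = lfc_min, imat = imat, mta = mta,
                 k_range = k_range, seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the YAML layout written by [simulate_command()] / [write_bundle()]
#' (paths are resolved relative to the YAML's directory) and returns a
#' [pipeline_config()].
#'
#' @param path Path to a `config.yaml`.
#' @param out_dir Output directory (default: `<bundle>/results`).
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, ...) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  design <- study_design(
    conditions = cfg$design$conditions,
    timepoints = data.frame(label = cfg$design$timepoints,
                            hours = cfg$design$hours,
                            stringsAsFactors = FALSE),
    replicates = cfg$design$replicates)
  pipeline_config(
    model_path = file.path(base, cfg$model),
    de_paths = lapply(cfg$de_tables, function(p) file.path(base, p)),
    out_dir = out_dir %||% file.path(base, "results"),
    design = design, seed = cfg$seed %||% 1L, ...)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: state discretization per omics
#' layer; context-network extraction for every condition x time point;
#' pathway activity counts, differences and ordination; transformation
#' scoring for both diet-transition directions (all microbiota-vs-control
#' comparisons at every time point, full data plus bootstraps) combined
#' into the signed overall score; and fold-change clustering. Every
#' artifact is a TSV/JSON file in `config$out_dir`; a `manifest.json`
#' lists the artifacts with MD5 hashes, the effective parameters and the
#' seed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list with `artifacts`, `parameters`,
#'   `seed`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- load_model(config$model_path)
  layers <- lapply(config$de_paths, read_de_table)
  design <- config$design
  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)
  on_stage <- function(s) s %in% config$stages

  states_by_layer <- list()
  if (on_stage("discretize")) {
    for (layer in names(layers)) {
      st <- discretize_states(layers[[layer]], design,
                              alpha = config$alpha, lfc_min = config$lfc_min)
      states_by_layer[[layer]] <- st
      p <- file.path(config$out_dir, sprintf("states_%s.tsv", layer))
      write_state_table(st, p)
      note(p); note(paste0(p, ".params.json"))
    }
  }

  networks <- list()
  if (on_stage("imat") && length(states_by_layer)) {
    st <- states_by_layer[[1]]
    for (cond in design$conditions) {
      for (tp in design$timepoints$label) {
        sl <- state_slice(st, cond, tp)
        nw <- imat_solve(model, map_states_to_reactions(model, sl),
                         params = config$imat, context = c(cond, tp))
        networks[[paste(cond, tp, sep = ":")]] <- nw
      }
    }
    p <- file.path(config$out_dir, "context_networks.json")
    jsonlite::write_json(
      lapply(networks, function(nw) {
        list(context = nw$context, objective = nw$objective,
             active_reactions = nw$active_reactions, flux = as.list(nw$flux))
      }), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(p)
  }

  if (on_stage("pathways") && length(networks)) {
    counts <- count_active_by_subsystem(model, networks)
    p <- file.path(config$out_dir, "pathway_activity_counts.tsv")
    utils::write.table(data.frame(subsystem = rownames(counts), counts,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p)
    ctrl <- design$conditions[1]
    grp_b <- grep(paste0("^", ctrl, ":"), colnames(counts), value = TRUE)
    grp_a <- setdiff(colnames(counts), grp_b)
    diffs <- pathway_differences(counts, grp_a, grp_b)
    p <- file.path(config$out_dir, "pathway_differences.tsv")
    utils::write.table(diffs, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p)
    if (length(networks) >= 3) {
      pca <- activity_pca(networks)
      p <- file.path(config$out_dir, "activity_pca.tsv")
      utils::write.table(data.frame(context = rownames(pca$scores),
                                    pca$scores, check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      note(p)
    }
  }

  overall <- NULL
  if (on_stage("mta")) {
    ctrl <- design$conditions[1]
    microbiota <- design$conditions[-1]
    fwd_maps <- list(); rev_maps <- list()
    for (layer in names(layers)) {
      de <- layers[[layer]]
      fwd_runs <- list(); rev_runs <- list()
      for (iso in microbiota) {
        for (tp in design$timepoints$label) {
          src <- list(condition = iso, timepoint = tp)
          tgt <- list(condition = ctrl, timepoint = tp)
          fwd_runs <- c(fwd_runs, bootstrap_runs(
            de, model, design, src, tgt, params = config$mta,
            imat_par = config$imat, alpha = config$alpha,
            lfc_min = config$lfc_min))
          rev_runs <- c(rev_runs, bootstrap_runs(
            de, model, design, tgt, src, params = config$mta,
            imat_par = config$imat, alpha = config$alpha,
            lfc_min = config$lfc_min))
        }
      }
      fwd_maps[[layer]] <- aggregate_scores(fwd_runs)
      rev_maps[[layer]] <- aggregate_scores(rev_runs)
    }
    overall <- overall_score(fwd_maps, rev_maps)
    p <- file.path(config$out_dir, "mta_overall.tsv")
    out <- data.frame(gene = names(overall), overall = as.numeric(overall))
    for (layer in names(fwd_maps)) {
      out[[paste0("forward_", layer)]] <- fwd_maps[[layer]][out$gene]
      out[[paste0("reverse_", layer)]] <- rev_maps[[layer]][out$gene]
    }
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p)
  }

  if (on_stage("cluster")) {
    de <- layers[[1]]
    ctrl <- design$conditions[1]
    cross <- de[de$time_a == de$time_b & de$cond_b == ctrl & de$cond_a != ctrl, ]
    if (nrow(cross)) {
      contrast <- paste(cross$cond_a, cross$time_a, sep = ":")
      fc <- tapply(cross$log2fc, list(cross$gene, contrast), mean)
      keep <- unique(cross$gene[cross$padj < config$alpha])
      fc <- fc[rownames(fc) %in% keep, , drop = FALSE]
      fc[is.na(fc)] <- 0
      if (nrow(fc) >= 3) {
        cl <- kmeans_aic(fc, k_range = config$k_range,
                         seed = config$seed + 17L)
        p <- file.path(config$out_dir, "clusters.tsv")
        utils::write.table(
          data.frame(gene = names(cl$assignment), cluster = cl$assignment),
          p, sep = "\t", quote = FALSE, row.names = FALSE)
        note(p)
        p <- file.path(config$out_dir, "cluster_aic.tsv")
        utils::write.table(cl$aic, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note(p)
        p <- file.path(config$out_dir, "heatmap_matrix.tsv")
        utils::write.table(
          data.frame(gene = rownames(fc)[cl$order],
                     cluster = cl$assignment[cl$order],
                     fc[cl$order, , drop = FALSE], check.names = FALSE),
          p, sep = "\t", quote = FALSE, row.names = FALSE)
        note(p)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctxmetanet")),
    seed = config$seed,
    parameters = list(alpha = config$alpha, lfc_min = config$lfc_min,
                      imat = unclass(config$imat), mta = unclass(config$mta),
                      k_range = config$k_range, stages = config$stages),
    artifacts = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate a synthetic bundle on disk with a ready-to-run configuration
#'
#' @param out_dir Output directory for the bundle.
#' @param variant `"diamond"` for the planted transformation scenario, or
#'   any [make_toy_model()] variant for a generic bundle.
#' @param seed Integer seed.
#' @param force Overwrite an existing non-empty directory.
#' @param ... Passed to [make_synthetic_bundle()] for generic variants.
#' @return The bundle directory path, invisibly.
#' @export
simulate_command <- function(out_dir, variant = "diamond", seed = 1L,
                             force = FALSE, ...) {
  bundle <- if (identical(variant, "diamond")) {
    plant_transformation_scenario("diamond", seed = seed)
  } else {
    make_synthetic_bundle(variant = variant, seed = seed, ...)
  }
  write_bundle(bundle, out_dir, force = force)
  invisible(out_dir)
}
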