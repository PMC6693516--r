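#' Construct a metabolic model
#'
#' A small S3 container for a constraint-based metabolic model: a
#' stoichiometric matrix, flux bounds, pathway (subsystem) labels and a
#' gene-protein-reaction (GPR) boolean rule per reaction.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `exchange` (logical), `gpr` (rule text).
#' @param stoichiometry Numeric matrix, metabolites x reactions, with
#'   dimnames matching the id columns. Negative entries are consumed,
#'   positive produced.
#' @param genes Character vector of gene identifiers; must contain every
#'   gene referenced by a GPR rule.
#' @return An object of class `metabolic_model` with elements
#'   `metabolites`, `reactions`, `stoichiometry`, `genes` and `gpr` (a
#'   named list of parsed rules).
#' @seealso [load_model()], [validate_model()]
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry, genes) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"exchange" %in% names(reactions)) reactions$exchange <- FALSE
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  stoichiometry <- as.matrix(stoichiometry)
  gpr <- lapply(reactions$gpr, parse_gpr)
  names(gpr) <- reactions$id
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = as.character(genes),
         gpr = gpr),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks identifier uniqueness, bound ordering, stoichiometry/GPR
#' consistency with the declared metabolite and gene lists, and non-empty
#' subsystem labels. Called by every constructor and loader; useful
#' directly after manual edits.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly. Errors list all offending identifiers.
#' @export
validate_model <- function(model) {
  errs <- character(0)
  mids <- model$metabolites$id
  rids <- model$reactions$id
  if (anyDuplicated(mids)) {
    errs <- c(errs, paste0("duplicated metabolite ids: ",
                           paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  }
  if (anyDuplicated(rids)) {
    errs <- c(errs, paste0("duplicated reaction ids: ",
                           paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  }
  if (any(!nzchar(mids))) errs <- c(errs, "empty metabolite id")
  bad_bounds <- rids[model$reactions$lower_bound > model$reactions$upper_bound]
  if (length(bad_bounds)) {
    errs <- c(errs, paste0("lower_bound > upper_bound for: ",
                           paste(bad_bounds, collapse = ", ")))
  }
  bad_sub <- rids[is.na(model$reactions$subsystem) |
                    !nzchar(model$reactions$subsystem)]
  if (length(bad_sub)) {
    errs <- c(errs, paste0("empty subsystem for: ",
                           paste(bad_sub, collapse = ", ")))
  }
  S <- model$stoichiometry
  if (!identical(rownames(S), mids) || !identical(colnames(S), rids)) {
    errs <- c(errs, "stoichiometry dimnames do not match metabolite/reaction ids")
  } else {
    n_mets <- colSums(S != 0)
    empty <- rids[n_mets == 0 & !model$reactions$exchange]
    if (length(empty)) {
      errs <- c(errs, paste0("empty stoichiometry for non-exchange reaction(s): ",
                             paste(empty, collapse = ", ")))
    }
  }
  for (rid in rids) {
    unknown <- setdiff(gpr_genes(model$gpr[[rid]]), model$genes)
    if (length(unknown)) {
      errs <- c(errs, sprintf("reaction %s: GPR references undeclared gene(s): %s",
                              rid, paste(unknown, collapse = ", ")))
    }
  }
  if (length(errs)) {
    stop("invalid metabolic model:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions, %d metabolites, %d genes, %d subsystems\n",
              nrow(x$reactions), nrow(x$metabolites), length(x$genes),
              length(unique(x$reactions$subsystem))))
  invisible(x)
}

#' Reactions blocked by a single-gene knockout
#'
#' A reaction is blocked when its GPR rule, evaluated with the knocked-out
#' gene FALSE and every other gene TRUE, is FALSE -- i.e. no isozyme route
#' remains. Reactions without a gene association are never blocked.
#'
#' @param model A `metabolic_model`.
#' @param gene A gene identifier present in `model$genes`.
#' @return Character vector of blocked reaction ids (possibly empty).
#' @export
blocked_reactions_by_knockout <- function(model, gene) {
  if (!gene %in% model$genes) {
    stop(sprintf("unknown gene id: %s", gene), call. = FALSE)
  }
  states <- stats::setNames(rep(1, length(model$genes)), model$genes)
  states[gene] <- -1
  blocked <- vapply(model$gpr, function(g) {
    g$type != "empty" && evaluate_gpr_state(g, states) == -1
  }, logical(1))
  model$reactions$id[blocked]
}

# ---------------------------------------------------------------------------
# Serialization: native JSON dialect ("ctxmetanet-model-v1") and SBML L3/fbc.

MODEL_SCHEMA_VERSION <- "ctxmetanet-model-v1"

#' Load a metabolic model from disk
#'
#' Two formats are supported: the package's native JSON dialect (schema
#' `ctxmetanet-model-v1`, see [write_model_json()]) and SBML Level 3 with
#' the `fbc` package for flux bounds and gene-product associations.
#' Subsystem labels are read from COBRA-style `SUBSYSTEM:` notes when
#' present in SBML, else default to `"unassigned"`.
#'
#' @param path Path to the model file.
#' @param format `"json"` or `"sbml"`; defaults from the file extension.
#' @return A validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop(sprintf(
                    "failed to parse model JSON '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  if (!identical(doc$schema, MODEL_SCHEMA_VERSION)) {
    stop(sprintf("model JSON '%s': missing or unsupported schema (expected '%s')",
                 path, MODEL_SCHEMA_VERSION), call. = FALSE)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c", stringsAsFactors = FALSE)
  }))
  rxn_list <- doc$reactions
  rxns <- do.call(rbind, lapply(rxn_list, function(r) {
    data.frame(id = r$id, lower_bound = as.numeric(r$lower_bound),
               upper_bound = as.numeric(r$upper_bound),
               subsystem = r$subsystem %||% "unassigned",
               exchange = isTRUE(r$exchange), gpr = r$gpr %||% "",
               stringsAsFactors = FALSE)
  }))
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (r in rxn_list) {
    for (met in names(r$stoichiometry)) {
      if (!met %in% mets$id) {
        stop(sprintf("model JSON '%s': reaction %s references unknown metabolite %s",
                     path, r$id, met), call. = FALSE)
      }
      S[met, r$id] <- as.numeric(r$stoichiometry[[met]])
    }
  }
  metabolic_model(mets, rxns, S, unlist(doc$genes))
}

#' Write a metabolic model as native JSON
#'
#' The dialect (schema id `ctxmetanet-model-v1`) stores genes, metabolites
#' and reactions with explicit stoichiometry maps, bounds, subsystem
#' labels, an exchange flag and GPR rule text. It round-trips all model
#' fields exactly.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    s <- model$stoichiometry[, r$id]
    s <- s[s != 0]
    list(id = r$id, stoichiometry = as.list(s),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem, exchange = r$exchange, gpr = r$gpr)
  })
  doc <- list(schema = MODEL_SCHEMA_VERSION,
              genes = as.list(model$genes),
              metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
                as.list(model$metabolites[i, c("id", "name", "compartment")])
              }),
              reactions = rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a metabolic model as SBML Level 3 with fbc annotations
#'
#' Bounds are encoded as fbc flux-bound parameters, GPR rules as fbc
#' gene-product associations, and subsystem labels as COBRA-style
#' `SUBSYSTEM:` notes (SBML core has no subsystem concept).
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments>')
  for (cmp in unique(model$metabolites$compartment)) {
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>', esc(cmp)))
  }
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      '      <species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m$id), esc(m$name), esc(m$compartment)))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lines <- c(lines,
      sprintf('      <parameter id="lb_R_%s" value="%.17g" constant="true"/>', esc(r$id), r$lower_bound),
      sprintf('      <parameter id="ub_R_%s" value="%.17g" constant="true"/>', esc(r$id), r$upper_bound))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lines <- c(lines, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_R_%s" fbc:upperFluxBound="ub_R_%s">',
      esc(r$id), tolower(r$lower_bound < 0), esc(r$id), esc(r$id)))
    lines <- c(lines,
      '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('          <p>SUBSYSTEM: %s</p>', esc(r$subsystem)),
      sprintf('          <p>EXCHANGE: %s</p>', tolower(r$exchange)),
      '        </body></notes>')
    s <- model$stoichiometry[, r$id]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>')
      for (met in names(reac)) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
          esc(met), -reac[[met]]))
      }
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>')
      for (met in names(prod)) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
          esc(met), prod[[met]]))
      }
      lines <- c(lines, '        </listOfProducts>')
    }
    gpa <- sbml_gpa_xml(model$gpr[[r$id]], indent = "        ")
    if (length(gpa)) lines <- c(lines, gpa)
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '    <fbc:listOfGeneProducts>')
  for (g in model$genes) {
    lines <- c(lines, sprintf(
      '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>', esc(g), esc(g)))
  }
  lines <- c(lines, '    </fbc:listOfGeneProducts>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

sbml_gpa_xml <- function(gpr, indent) {
  node_xml <- function(g, ind) {
    switch(g$type,
           gene = sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', ind, g$gene),
           and = c(sprintf("%s<fbc:and>", ind),
                   unlist(lapply(g$children, node_xml, ind = paste0(ind, "  "))),
                   sprintf("%s</fbc:and>", ind)),
           or = c(sprintf("%s<fbc:or>", ind),
                  unlist(lapply(g$children, node_xml, ind = paste0(ind, "  "))),
                  sprintf("%s</fbc:or>", ind)))
  }
  if (gpr$type == "empty") return(character(0))
  c(sprintf("%s<fbc:geneProductAssociation>", indent),
    node_xml(gpr, paste0(indent, "  ")),
    sprintf("%s</fbc:geneProductAssociation>", indent))
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "failed to parse SBML '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)

  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_ids <- strip(xml2::xml_attr(gp_nodes, "fbc:id", ns = ns), "G_")

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp_nodes, "id"), "M_"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rxn_nodes)
  rxns <- data.frame(id = character(n), lower_bound = numeric(n),
                     upper_bound = numeric(n), subsystem = character(n),
                     exchange = logical(n), gpr = character(n),
                     stringsAsFactors = FALSE)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, NULL))
  for (i in seq_len(n)) {
    node <- rxn_nodes[[i]]
    rid <- strip(xml2::xml_attr(node, "id"), "R_")
    rxns$id[i] <- rid
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    rxns$lower_bound[i] <- par_vals[[lb_ref]]
    rxns$upper_bound[i] <- par_vals[[ub_ref]]
    notes <- xml2::xml_text(
      xml2::xml_find_all(node, ".//s:notes//*[local-name()='p']", ns))
    sub_line <- grep("^\\s*SUBSYSTEM:", notes, value = TRUE)
    rxns$subsystem[i] <- if (length(sub_line)) {
      trimws(sub("^\\s*SUBSYSTEM:", "", sub_line[1]))
    } else "unassigned"
    ex_line <- grep("^\\s*EXCHANGE:", notes, value = TRUE)
    rxns$exchange[i] <- length(ex_line) > 0 &&
      identical(trimws(sub("^\\s*EXCHANGE:", "", ex_line[1])), "true")
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(sr, "species"), "M_")
      S[met, i] <- S[met, i] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      met <- strip(xml2::xml_attr(sr, "species"), "M_")
      S[met, i] <- S[met, i] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    rxns$gpr[i] <- if (inherits(gpa, "xml_missing")) "" else {
      deparse_gpr(sbml_parse_gpa(xml2::xml_children(gpa)[[1]], ns))
    }
  }
  colnames(S) <- rxns$id
  metabolic_model(mets, rxns, S, unname(gene_ids))
}

sbml_parse_gpa <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- sub("^G_", "", xml2::xml_attr(node, "fbc:geneProduct", ns = ns))
    return(structure(list(type = "gene", gene = g), class = "gpr"))
  }
  kids <- lapply(xml2::xml_children(node), sbml_parse_gpa, ns = ns)
  structure(list(type = if (nm == "and") "and" else "or", children = kids),
            class = "gpr")
}
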