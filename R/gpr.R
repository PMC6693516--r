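#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules state which gene products must be present for a reaction's
#' catalyst to be available. The grammar accepts gene identifiers,
#' parentheses and the case-insensitive operators `and` / `or`. An empty or
#' whitespace-only rule denotes "no gene association" and parses to a
#' distinct empty expression.
#'
#' @param text Rule text, e.g. `"g1 and (g2 or g3)"`.
#' @param genes Optional character vector of known gene identifiers. When
#'   supplied, any leaf not contained in it raises an error.
#' @return An object of class `gpr`: a nested list with `type` one of
#'   `"empty"`, `"gene"`, `"and"`, `"or"`.
#' @examples
#' parse_gpr("g1 and g2")
#' parse_gpr("g1 or (g2 and g3)")
#' parse_gpr("")
#' @export
parse_gpr <- function(text, genes = NULL) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    return(structure(list(type = "empty"), class = "gpr"))
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st, text)
  if (st$pos <= nrow(st$toks)) {
    stop(sprintf("GPR parse error at position %d in '%s': unexpected '%s'",
                 st$toks$start[st$pos], text, st$toks$value[st$pos]),
         call. = FALSE)
  }
  if (!is.null(genes)) {
    unknown <- setdiff(gpr_genes(expr), genes)
    if (length(unknown)) {
      stop(sprintf("GPR rule '%s' references undeclared gene(s): %s",
                   text, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  expr
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("empty GPR tokenizer input", call. = FALSE)
  vals <- regmatches(text, gregexpr(pat, text))[[1]]
  type <- ifelse(vals == "(", "lpar",
          ifelse(vals == ")", "rpar",
          ifelse(tolower(vals) == "and", "and",
          ifelse(tolower(vals) == "or", "or", "gene"))))
  data.frame(value = vals, type = type, start = as.integer(m),
             stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

gpr_parse_or <- function(st, text) {
  kids <- list(gpr_parse_and(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_and(st, text)))
  }
  if (length(kids) == 1L) kids[[1L]]
  else structure(list(type = "or", children = kids), class = "gpr")
}

gpr_parse_and <- function(st, text) {
  kids <- list(gpr_parse_atom(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_atom(st, text)))
  }
  if (length(kids) == 1L) kids[[1L]]
  else structure(list(type = "and", children = kids), class = "gpr")
}

gpr_parse_atom <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error at end of '%s': expected gene or '('", text),
         call. = FALSE)
  }
  if (tk$type == "lpar") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != "rpar") {
      stop(sprintf("GPR parse error in '%s': unbalanced parentheses (opened at position %d)",
                   text, tk$start), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(structure(list(type = "gene", gene = tk$value), class = "gpr"))
  }
  stop(sprintf("GPR parse error at position %d in '%s': unexpected '%s'",
               tk$start, text, tk$value), call. = FALSE)
}

#' Genes referenced by a GPR expression
#'
#' @param gpr A `gpr` object from [parse_gpr()].
#' @return Character vector of distinct gene identifiers (empty for the
#'   empty expression).
#' @export
gpr_genes <- function(gpr) {
  switch(gpr$type,
         empty = character(0),
         gene = gpr$gene,
         unique(unlist(lapply(gpr$children, gpr_genes))))
}

#' Deparse a GPR expression back to rule text
#'
#' @param gpr A `gpr` object.
#' @return A single string; `""` for the empty expression.
#' @export
deparse_gpr <- function(gpr) {
  switch(gpr$type,
         empty = "",
         gene = gpr$gene,
         and = paste(vapply(gpr$children, deparse_gpr_atom, "", within = "and"),
                     collapse = " and "),
         or = paste(vapply(gpr$children, deparse_gpr_atom, "", within = "or"),
                    collapse = " or "))
}

deparse_gpr_atom <- function(gpr, within) {
  txt <- deparse_gpr(gpr)
  if (within == "and" && gpr$type == "or") paste0("(", txt, ")") else txt
}

#' Evaluate a GPR rule under tri-valued gene activity states
#'
#' States take values in `{+1 = ON, 0 = UNKNOWN, -1 = OFF}`. The evaluation
#' is the conservative lattice extension of boolean logic: `and` takes the
#' minimum over its children, `or` the maximum, so definite (+1/-1) states
#' reproduce ordinary boolean evaluation and UNKNOWN propagates only when
#' the definite inputs leave the outcome open. The empty expression
#' evaluates to 0.
#'
#' @param gpr A `gpr` object.
#' @param states Named numeric vector of gene states in `{-1, 0, 1}`.
#'   Genes absent from `states` default to 0 (UNKNOWN).
#' @return A single value in `{-1, 0, 1}`: the reaction-level evidence.
#' @examples
#' evaluate_gpr_state(parse_gpr("g1 and g2"), c(g1 = 1, g2 = -1))  # -1
#' evaluate_gpr_state(parse_gpr("g1 or g2"), c(g1 = -1, g2 = 0))   # 0
#' @export
evaluate_gpr_state <- function(gpr, states) {
  switch(gpr$type,
         empty = 0,
         gene = {
           s <- if (gpr$gene %in% names(states)) states[[gpr$gene]] else 0
           if (is.na(s)) 0 else as.numeric(s)
         },
         and = min(vapply(gpr$children, evaluate_gpr_state, 0, states = states)),
         or = max(vapply(gpr$children, evaluate_gpr_state, 0, states = states)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gpr <- function(x, ...) {
  txt <- deparse_gpr(x)
  cat("<gpr> ", if (nzchar(txt)) txt else "(no gene association)", "\n", sep = "")
  invisible(x)
}
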