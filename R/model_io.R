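#' Construct a metabolic model
#'
#' A `metabolic_model` holds the stoichiometric matrix `S` (internal
#' metabolites in rows, reactions in columns) together with per-reaction
#' reversibility flags and the designated target (and optionally biomass)
#' reactions. Exchange reactions appear as single-ended columns: the boundary
#' side of the reaction is implicit, so `S` contains internal metabolites
#' only.
#'
#' @param S numeric matrix, metabolites x reactions. Row and column names are
#'   taken as metabolite and reaction identifiers when `metabolites` /
#'   `reactions` are not given.
#' @param metabolites character vector of metabolite ids (unique).
#' @param reactions character vector of reaction ids (unique).
#' @param reversible logical vector, one flag per reaction.
#' @param target_id id of the engineering target reaction.
#' @param biomass_id optional id of the biomass reaction.
#' @param vmax optional named numeric vector of maximal velocities (flux
#'   units); entries may cover only a subset of reactions.
#' @param split_pairs named character vector mapping forward-component ids to
#'   backward-component ids; present only on models produced by
#'   [split_reversible()].
#' @return an object of class `metabolic_model`.
#' @seealso [read_model()], [split_reversible()]
#' @export
metabolic_model <- function(S, metabolites = rownames(S), reactions = colnames(S),
                            reversible = rep(FALSE, ncol(S)), target_id = NULL,
                            biomass_id = NULL, vmax = NULL,
                            split_pairs = character(0)) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  m <- structure(list(
    metabolites = as.character(metabolites),
    reactions = as.character(reactions),
    S = S,
    reversible = as.logical(reversible),
    target_id = target_id,
    biomass_id = biomass_id,
    vmax = vmax,
    split_pairs = split_pairs
  ), class = "metabolic_model")
  validate_model(m)
}

validate_model <- function(m) {
  if (anyDuplicated(m$metabolites))
    stop("duplicate metabolite ids: ",
         paste(unique(m$metabolites[duplicated(m$metabolites)]), collapse = ", "))
  if (anyDuplicated(m$reactions))
    stop("duplicate reaction ids: ",
         paste(unique(m$reactions[duplicated(m$reactions)]), collapse = ", "))
  if (nrow(m$S) != length(m$metabolites))
    stop("stoichiometric matrix has ", nrow(m$S), " rows but ",
         length(m$metabolites), " metabolites")
  if (ncol(m$S) != length(m$reactions))
    stop("stoichiometric matrix has ", ncol(m$S), " columns but ",
         length(m$reactions), " reactions")
  if (length(m$reversible) != length(m$reactions))
    stop("reversible flags do not match the reaction count")
  empty <- which(colSums(abs(m$S)) == 0)
  if (length(empty))
    stop("reaction column(s) with all-zero stoichiometry: ",
         paste(m$reactions[empty], collapse = ", "))
  for (fld in c("target_id", "biomass_id")) {
    id <- m[[fld]]
    if (!is.null(id) && !id %in% m$reactions)
      stop(fld, " '", id, "' is not a reaction in the model")
  }
  if (length(m$split_pairs)) {
    ids <- c(names(m$split_pairs), unname(m$split_pairs))
    if (anyDuplicated(ids) || !all(ids %in% m$reactions))
      stop("split_pairs must be a one-to-one map between distinct reaction ids")
  }
  dimnames(m$S) <- list(m$metabolites, m$reactions)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model: ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", sum(x$reversible), " reversible)\n",
      sep = "")
  if (!is.null(x$target_id)) cat("  target: ", x$target_id, "\n", sep = "")
  if (!is.null(x$biomass_id)) cat("  biomass: ", x$biomass_id, "\n", sep = "")
  if (length(x$split_pairs))
    cat("  split pairs: ", length(x$split_pairs), "\n", sep = "")
  invisible(x)
}

#' Read a metabolic model from disk
#'
#' Three formats are supported. `canonical-json` is the package's native
#' schema: a JSON object
#' `{metabolites: [id, ...], reactions: [{id, stoich: {met: coef, ...},
#' reversible, vmax?}, ...], biomass?, target}`. `tsv` reads a reactions
#' table with columns `id`, `reversible` and `formula` (e.g.
#' `"A + 2 B -> C"`; `<->` marks reversible reactions) plus a designations
#' table naming the target and optional biomass reactions. `sbml` imports an
#' SBML Level 3 file; species flagged `boundaryCondition="true"` are dropped
#' so exchange reactions become single-ended columns.
#'
#' @param path file path (for `tsv`, the reactions table; the designations
#'   table is looked up as `<stem>_designations.tsv` or passed via
#'   `designations`).
#' @param format one of `"canonical-json"`, `"tsv"`, `"sbml"`; default guessed
#'   from the file extension.
#' @param designations optional path to the TSV designations table.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("canonical-json", "tsv", "sbml"),
                       designations = NULL) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "canonical-json", tsv = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess model format from extension '.", ext, "'"))
  }
  format <- match.arg(format)
  switch(format,
         "canonical-json" = read_model_json(path),
         "tsv" = read_model_tsv(path, designations),
         "sbml" = read_model_sbml(path))
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse '", path, "' as JSON: ",
                                           conditionMessage(e)))
  for (fld in c("metabolites", "reactions"))
    if (is.null(doc[[fld]])) stop("model JSON lacks required field '", fld, "'")
  mets <- unlist(doc$metabolites)
  rxns <- vapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("a reaction record lacks an 'id' field")
    as.character(r$id)
  }, "")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  rev <- logical(length(rxns))
  vmax <- numeric(0)
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    st <- r$stoich
    if (is.null(st) || !length(st))
      stop("reaction '", r$id, "' has empty stoichiometry")
    bad <- setdiff(names(st), mets)
    if (length(bad))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    S[names(st), k] <- unlist(st)
    rev[k] <- isTRUE(r$reversible)
    if (!is.null(r$vmax)) vmax[r$id] <- as.numeric(r$vmax)
  }
  metabolic_model(S, mets, rxns, rev,
                  target_id = doc$target, biomass_id = doc$biomass,
                  vmax = if (length(vmax)) vmax else NULL)
}

#' Write a model in the canonical JSON schema
#'
#' Inverse of [read_model()] for `canonical-json`; `read_model(write_model(m))`
#' reproduces `m` field-by-field.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rxns <- lapply(seq_along(model$reactions), function(k) {
    col <- model$S[, k]
    st <- as.list(col[col != 0])
    r <- list(id = model$reactions[k], stoich = st,
              reversible = model$reversible[k])
    if (!is.null(model$vmax) && model$reactions[k] %in% names(model$vmax))
      r$vmax <- unname(model$vmax[model$reactions[k]])
    r
  })
  doc <- list(metabolites = as.list(model$metabolites), reactions = rxns)
  if (!is.null(model$biomass_id)) doc$biomass <- model$biomass_id
  doc$target <- model$target_id
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

parse_formula <- function(formula, id) {
  sep <- if (grepl("<->", formula, fixed = TRUE)) "<->" else "->"
  sides <- strsplit(formula, sep, fixed = TRUE)[[1]]
  if (length(sides) > 2)
    stop("reaction '", id, "': malformed formula '", formula, "'")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "" || is.na(s)) return(numeric(0))
    out <- numeric(0)
    for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1]])) {
      if (term == "") stop("reaction '", id, "': malformed formula '", formula, "'")
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1) {
        out[toks] <- sign
      } else if (length(toks) == 2 && !is.na(suppressWarnings(as.numeric(toks[1])))) {
        out[toks[2]] <- sign * as.numeric(toks[1])
      } else stop("reaction '", id, "': cannot parse term '", term, "'")
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2) parse_side(sides[2], 1) else numeric(0)
  st <- lhs
  for (met in names(rhs)) st[met] <- (if (met %in% names(st)) st[met] else 0) + rhs[met]
  list(stoich = st[st != 0], reversible = sep == "<->")
}

read_model_tsv <- function(path, designations = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "reversible", "formula")
  if (!all(need %in% names(tab)))
    stop("reactions TSV must have columns: ", paste(need, collapse = ", "))
  parsed <- lapply(seq_len(nrow(tab)),
                   function(i) parse_formula(tab$formula[i], tab$id[i]))
  mets <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  S <- matrix(0, length(mets), nrow(tab), dimnames = list(mets, tab$id))
  for (i in seq_len(nrow(tab))) S[names(parsed[[i]]$stoich), i] <- parsed[[i]]$stoich
  rev <- as.logical(tab$reversible) | vapply(parsed, `[[`, TRUE, "reversible")
  vmax <- if ("vmax" %in% names(tab)) {
    v <- stats::setNames(tab$vmax, tab$id); v[!is.na(v)]
  } else NULL
  if (is.null(designations)) {
    cand <- file.path(dirname(path),
                      paste0(tools::file_path_sans_ext(basename(path)),
                             "_designations.tsv"))
    if (file.exists(cand)) designations <- cand
  }
  target <- biomass <- NULL
  if (!is.null(designations)) {
    des <- utils::read.delim(designations, stringsAsFactors = FALSE)
    if (!all(c("role", "reaction") %in% names(des)))
      stop("designations TSV must have columns: role, reaction")
    target <- des$reaction[des$role == "target"][1]
    biomass <- des$reaction[des$role == "biomass"][1]
    if (is.na(target)) target <- NULL
    if (is.na(biomass)) biomass <- NULL
  }
  metabolic_model(S, mets, tab$id, rev, target_id = target,
                  biomass_id = biomass,
                  vmax = if (length(vmax)) vmax else NULL)
}

read_model_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML import requires the 'xml2' package")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- sp_id[!boundary]
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) stop("SBML file contains no reactions")
  rxn_id <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, rxn_id))
  rev <- xml2::xml_attr(rx, "reversible") %in% "true"
  for (k in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx[[k]], paste0("./", side, "/speciesReference"))
      sgn <- if (side == "listOfReactants") -1 else 1
      for (ref in refs) {
        species <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        if (species %in% mets)
          S[species, k] <- S[species, k] + sgn * coef
      }
    }
  }
  keep <- colSums(abs(S)) > 0
  metabolic_model(S[, keep, drop = FALSE], mets, rxn_id[keep], rev[keep])
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Each reversible reaction `j` is replaced by its original column (forward,
#' keeping the id) and the negated column (backward, id suffixed `"_b"`).
#' Backward components are appended after the original columns in original
#' order, and the forward-to-backward mapping is recorded in `split_pairs`.
#' Idempotent: a model with no reversible reactions is returned unchanged.
#'
#' @param model a [metabolic_model()].
#' @return a [metabolic_model()] with all reactions irreversible.
#' @export
split_reversible <- function(model) {
  rev_idx <- which(model$reversible)
  if (!length(rev_idx)) {
    if (!length(model$split_pairs)) model$split_pairs <- character(0)
    return(model)
  }
  bwd_ids <- paste0(model$reactions[rev_idx], "_b")
  clash <- intersect(bwd_ids, model$reactions)
  if (length(clash))
    stop("backward-component id(s) collide with existing reactions: ",
         paste(clash, collapse = ", "))
  S2 <- cbind(model$S, -model$S[, rev_idx, drop = FALSE])
  rxns2 <- c(model$reactions, bwd_ids)
  vmax2 <- model$vmax
  if (!is.null(vmax2)) {
    has <- model$reactions[rev_idx] %in% names(vmax2)
    if (any(has))
      vmax2[bwd_ids[has]] <- vmax2[model$reactions[rev_idx][has]]
  }
  metabolic_model(S2, model$metabolites, rxns2,
                  reversible = rep(FALSE, length(rxns2)),
                  target_id = model$target_id, biomass_id = model$biomass_id,
                  vmax = vmax2,
                  split_pairs = stats::setNames(bwd_ids, model$reactions[rev_idx]))
}
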