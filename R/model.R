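#' Stoichiometric models
#'
#' A `stoich_model` is the minimal constraint-based description of a
#' metabolic network: a stoichiometric matrix `S` (metabolites x
#' reactions), flux bounds, a designated biomass (target) reaction whose
#' maximal steady-state flux defines growth, and the set of exchange
#' reactions across the model boundary through which the growth medium is
#' applied.
#'
#' @param S numeric matrix, metabolites in rows, reactions in columns; both
#'   dimensions must be named.
#' @param lb,ub numeric flux bounds per reaction (lower / upper); a
#'   reaction is reversible iff `lb < 0`.
#' @param biomass id of the biomass reaction.
#' @param exchanges character vector of exchange reaction ids. `NULL`
#'   auto-detects boundary reactions (columns with a single nonzero
#'   coefficient), excluding the biomass reaction.
#' @return An object of class `stoich_model`.
#' @seealso [read_model()], [growth_test()], [make_consistent()]
#' @export
stoich_model <- function(S, lb, ub, biomass, exchanges = NULL) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("S must have metabolite row names and reaction column names")
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("lower bound above upper bound")
  if (!biomass %in% colnames(S))
    stop("biomass reaction '", biomass, "' not in model")
  if (is.null(exchanges)) {
    nz <- colSums(S != 0)
    exchanges <- setdiff(colnames(S)[nz == 1L], biomass)
  } else if (!all(exchanges %in% colnames(S)))
    stop("unknown exchange reaction(s): ",
         paste(setdiff(exchanges, colnames(S)), collapse = ", "))
  lb <- as.numeric(lb)
  ub <- as.numeric(ub)
  names(lb) <- names(ub) <- colnames(S)
  structure(list(S = S, lb = lb, ub = ub, biomass = biomass,
                 exchanges = exchanges),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Stoichiometric model:", ncol(x$S), "reactions,", nrow(x$S),
      "metabolites\n")
  cat("  biomass:", x$biomass, "\n")
  cat("  exchanges:", paste(x$exchanges, collapse = ", "), "\n")
  cat("  reversible reactions:", sum(x$lb < 0), "\n")
  invisible(x)
}

#' @export
dim.stoich_model <- function(x) dim(x$S)

reactions <- function(model) colnames(model$S)

#' Read a stoichiometric model
#'
#' Two on-disk dialects are supported. `"json"` is a cobrapy-style layout:
#' an object with a `reactions` array (each with `id`, a `metabolites`
#' map of stoichiometric coefficients, `lower_bound`, `upper_bound` and
#' optionally `objective_coefficient`) and optionally a top-level
#' `biomass` id. `"sbml"` reads SBML Level 3 with the FBC package: species,
#' reactions with reactant/product stoichiometry, flux bounds referencing
#' `listOfParameters`, and the active FBC objective. In both dialects the
#' biomass reaction is taken from the explicit field, or else from the
#' (unique) reaction with a nonzero objective coefficient; a model without
#' either is an error.
#'
#' @param path file to read.
#' @param dialect `"json"` or `"sbml"`; default guesses from the extension.
#' @return a [stoich_model()].
#' @export
read_model <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (dialect == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$reactions)) stop("no 'reactions' array in ", path)
  rxn_ids <- vapply(doc$reactions, function(r) r$id, "")
  met_ids <- if (!is.null(doc$metabolites))
    vapply(doc$metabolites, function(m) m$id, "")
  else sort(unique(unlist(lapply(doc$reactions,
                                 function(r) names(r$metabolites)))))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rxn_ids))
  objc <- numeric(length(rxn_ids))
  for (i in seq_along(doc$reactions)) {
    rx <- doc$reactions[[i]]
    co <- unlist(rx$metabolites)
    if (length(co)) {
      unknown <- setdiff(names(co), met_ids)
      if (length(unknown))
        stop("reaction '", rx$id, "' references unknown metabolite(s): ",
             paste(unknown, collapse = ", "))
      S[names(co), i] <- co
    }
    lb[i] <- if (is.null(rx$lower_bound)) 0 else rx$lower_bound
    ub[i] <- if (is.null(rx$upper_bound)) 1000 else rx$upper_bound
    objc[i] <- if (is.null(rx$objective_coefficient)) 0
    else rx$objective_coefficient
  }
  biomass <- doc$biomass
  if (is.null(biomass)) {
    hit <- which(objc != 0)
    if (length(hit) != 1L)
      stop("no biomass reaction: set a top-level 'biomass' id or exactly ",
           "one nonzero 'objective_coefficient'")
    biomass <- rxn_ids[hit]
  }
  stoich_model(S, lb, ub, biomass = biomass)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_boundary]
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxns)) stop("no reactions in ", path)
  rxn_ids <- xml2::xml_attr(rxns, "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxn_ids))
  lb <- ub <- numeric(length(rxns))
  for (i in seq_along(rxns)) {
    rx <- rxns[[i]]
    for (ref in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(st)) st <- 1
      if (sp %in% mets) S[sp, i] <- S[sp, i] - st
    }
    for (ref in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(st)) st <- 1
      if (sp %in% mets) S[sp, i] <- S[sp, i] + st
    }
    rev <- xml2::xml_attr(rx, "reversible") %in% "true"
    lbid <- xml2::xml_attr(rx, "lowerFluxBound",
                           ns = character()) # plain attr lookup first
    if (is.na(lbid)) lbid <- xml2::xml_attr(rx, "fbc:lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound", ns = character())
    if (is.na(ubid)) ubid <- xml2::xml_attr(rx, "fbc:upperFluxBound")
    lb[i] <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]]
    else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]]
    else 1000
  }
  obj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj, "xml_missing"))
    stop("no FBC objective in ", path, "; cannot identify biomass reaction")
  biomass <- xml2::xml_attr(obj, "reaction")
  if (is.na(biomass)) biomass <- xml2::xml_attr(obj, "fbc:reaction")
  stoich_model(S, lb, ub, biomass = biomass)
}

#' Write a stoichiometric model to the JSON dialect
#'
#' @param model a [stoich_model()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "stoich_model"))
  rxns <- lapply(seq_len(ncol(model$S)), function(i) {
    co <- model$S[, i]
    co <- co[co != 0]
    list(id = colnames(model$S)[i],
         metabolites = as.list(co),
         lower_bound = model$lb[[i]],
         upper_bound = model$ub[[i]])
  })
  doc <- list(metabolites = lapply(rownames(model$S),
                                   function(id) list(id = id)),
              reactions = rxns,
              biomass = model$biomass,
              exchanges = as.list(model$exchanges))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read / write a growth medium
#'
#' A medium is a named numeric vector mapping exchange reaction ids to the
#' non-negative uptake bound allowed for the corresponding nutrient. On
#' disk it is a two-column TSV (`exchange`, `uptake`), comment lines
#' starting with `#`.
#'
#' @param path file to read or write.
#' @param medium named numeric vector of uptake bounds.
#' @return `read_medium()`: named numeric vector; `write_medium()`: `path`.
#' @export
read_medium <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("exchange", "uptake"),
                           comment.char = "#",
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$uptake, tab$exchange)
}

#' @rdname read_medium
#' @export
write_medium <- function(medium, path) {
  writeLines(c("# exchange\tuptake",
               sprintf("%s\t%.10g", names(medium), medium)), path)
  invisible(path)
}

# apply a medium to the model's exchange bounds: the uptake direction of an
# exchange is the one that produces its metabolite (inflow). Exchanges named
# in the medium get their uptake bound set to the stated magnitude; all
# other exchanges have uptake blocked. Secretion is never restricted.
apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  unknown <- setdiff(names(medium), model$exchanges)
  if (length(unknown))
    stop("medium refers to non-exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  if (any(medium < 0)) stop("uptake bounds must be non-negative magnitudes")
  for (ex in model$exchanges) {
    co <- model$S[, ex]
    inflow_forward <- sum(co) > 0   # forward flux produces the metabolite
    allowed <- if (ex %in% names(medium)) medium[[ex]] else 0
    if (inflow_forward) {
      model$ub[[ex]] <- allowed
      if (model$lb[[ex]] > allowed) model$lb[[ex]] <- allowed
    } else {
      model$lb[[ex]] <- -allowed
      if (model$ub[[ex]] < -allowed) model$ub[[ex]] <- -allowed
    }
  }
  model
}
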