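#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` is the package's lightweight container for a
#' stoichiometric reconstruction: metabolites (with compartment and optional
#' elemental formula), reactions (sparse stoichiometry maps with finite flux
#' bounds, in mmol/gDW/h by convention) and a biomass objective. Exchange
#' reactions follow the standard constraint-based convention: a single
#' extracellular metabolite with coefficient -1, so negative flux is uptake
#' and positive flux is export.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (`NA` allowed for formula).
#' @param reactions list of lists, each with `id`, `stoich` (named numeric,
#'   names are metabolite ids, negative = consumed), `lb`, `ub`.
#' @param objective id of the (biomass) reaction to optimize.
#' @param extracellular compartment id of the shared environment
#'   (default `"e"`).
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective,
                            extracellular = "e") {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, name = metabolites,
                              compartment = "c", formula = NA_character_,
                              stringsAsFactors = FALSE)
  }
  for (col in c("name", "formula"))
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA_character_
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  metabolites <- metabolites[, c("id", "name", "compartment", "formula")]
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective = objective, extracellular = extracellular),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's internal consistency
#'
#' Checks id uniqueness, that every metabolite referenced by a reaction
#' exists, that bounds are ordered and finite, and that the objective
#' reaction exists.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids))
    stop("duplicated metabolite id: ", met_ids[duplicated(met_ids)][1])
  rxn_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicated reaction id: ", rxn_ids[duplicated(rxn_ids)][1])
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), met_ids)
    if (length(unknown) > 0)
      stop("reaction ", r$id, " references unknown metabolite ", unknown[1])
    if (!is.finite(r$lb) || !is.finite(r$ub) || r$lb > r$ub)
      stop("reaction ", r$id, " has invalid bounds [", r$lb, ", ", r$ub, "]")
  }
  if (!model$objective %in% rxn_ids)
    stop("objective reaction not found: ", model$objective)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  exchanges: ", length(exchange_reactions(x)), "\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

#' Exchange reactions of a model
#'
#' An exchange is a boundary reaction touching exactly one metabolite, in
#' the extracellular compartment, with coefficient -1 (negative flux =
#' uptake). Demand sinks (`DM__` prefix, e.g. those added by
#' [producible()]) are never classified as exchanges.
#'
#' @param model a `metabolic_model`.
#' @return named character vector: exchange reaction ids named by the
#'   metabolite they exchange.
#' @export
exchange_reactions <- function(model) {
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  out <- character(0)
  for (r in model$reactions) {
    if (startsWith(r$id, "DM__")) next
    s <- r$stoich
    if (length(s) == 1 && abs(s + 1) < 1e-12 &&
        comp[names(s)] == model$extracellular) {
      out[names(s)] <- r$id
    }
  }
  out
}

#' Flux balance analysis
#'
#' Maximizes the flux through a target reaction subject to steady-state
#' mass balance (`S v = 0`) and the model's flux bounds, via the package's
#' deterministic simplex solver.
#'
#' @param model a `metabolic_model`.
#' @param maximize reaction id to maximize; defaults to the model objective.
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value` and named `fluxes`.
#' @examples
#' m <- toy_chain_model()
#' fba(m)$objective_value
#' @export
fba <- function(model, maximize = model$objective) {
  rxns <- names(model$reactions)
  if (!maximize %in% rxns) stop("unknown reaction: ", maximize)
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  obj <- as.numeric(rxns == maximize)
  sol <- solve_lp(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                  maximize = TRUE)
  structure(list(status = sol$status,
                 objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
                 fluxes = stats::setNames(sol$x, rxns)),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective: ", format(x$objective_value, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' Set the growth medium of a model
#'
#' Opens uptake (lower bound `-uptake_bound`) for the exchange reactions of
#' the listed extracellular metabolites and closes uptake (lower bound 0)
#' for every other exchange. Export bounds are untouched. Applying the same
#' medium twice is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param open_uptakes character vector of extracellular metabolite ids.
#' @param uptake_bound positive uptake capacity (default 10 mmol/gDW/h).
#' @return the modified model.
#' @export
set_medium <- function(model, open_uptakes, uptake_bound = 10) {
  ex <- exchange_reactions(model)
  unknown <- setdiff(open_uptakes, names(ex))
  if (length(unknown) > 0)
    stop("no exchange reaction for metabolite: ",
         paste(unknown, collapse = ", "))
  for (met in names(ex)) {
    rid <- ex[[met]]
    model$reactions[[rid]]$lb <-
      if (met %in% open_uptakes) -abs(uptake_bound) else 0
  }
  model
}

# Parse an elemental formula ("C6H12O6") into a named count vector.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

# Canonical "El:count" signature of a formula, independent of element order.
.formula_signature <- function(formula) {
  counts <- parse_formula(formula)
  counts <- counts[order(names(counts))]
  paste(names(counts), counts, sep = ":", collapse = ",")
}

# Fixed inorganic carbon species never counted as organic substrates:
# CO2, bicarbonate, carbonate, cyanide, carbon monoxide.
.inorganic_carbon <- c("CO2", "HCO3", "CO3", "CN", "CO")

#' Predicted carbon-utilization width of a model
#'
#' Counts exchange reactions whose extracellular metabolite is an organic
#' carbon compound, as a genome-derived analogue of the experimental
#' resource-utilization width. A compound is organic when its formula
#' contains both carbon and hydrogen (or its id is on `organic_list`), and
#' a fixed inorganic-carbon blocklist (CO2, bicarbonate, carbonate,
#' cyanide, carbon monoxide) is always excluded. With `rule = "carbon"`
#' every carbon-containing exchanged compound outside the blocklist is
#' counted instead.
#'
#' @param model a `metabolic_model` with formulas on extracellular species.
#' @param rule `"organic"` (default) or `"carbon"`.
#' @param organic_list extra metabolite ids treated as organic regardless of
#'   formula.
#' @return integer count; metabolites without a formula are skipped with a
#'   warning.
#' @export
predicted_width <- function(model, rule = c("organic", "carbon"),
                            organic_list = character(0)) {
  rule <- match.arg(rule)
  ex <- exchange_reactions(model)
  if (length(ex) == 0) return(0L)
  forms <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  n <- 0L
  skipped <- character(0)
  for (met in names(ex)) {
    f <- forms[[met]]
    if (is.na(f) || !nzchar(f)) {
      if (!met %in% organic_list) { skipped <- c(skipped, met); next }
      n <- n + 1L
      next
    }
    counts <- parse_formula(f)
    if (.formula_signature(f) %in%
        vapply(.inorganic_carbon, .formula_signature, "")) next
    has_c <- "C" %in% names(counts)
    has_h <- "H" %in% names(counts)
    hit <- switch(rule,
                  organic = (has_c && has_h) || met %in% organic_list,
                  carbon  = has_c)
    if (hit) n <- n + 1L
  }
  if (length(skipped) > 0)
    warning("no formula for exchanged metabolite(s), skipped: ",
            paste(skipped, collapse = ", "))
  n
}
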