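# Flux-balance primitives: all growth decisions in the package funnel
# through fba() so that solver behaviour and the growth threshold are
# defined in exactly one place.

# maximize (or minimize) an objective over the steady-state flux polytope
fba <- function(model, medium = NULL, knockouts = character(),
                objective = NULL, maximize = TRUE, extra_lb = NULL) {
  stopifnot(inherits(model, "stoich_model"))
  model <- apply_medium(model, medium)
  unknown <- setdiff(knockouts, reactions(model))
  if (length(unknown))
    stop("unknown knockout reaction(s): ", paste(unknown, collapse = ", "))
  lb <- model$lb
  ub <- model$ub
  lb[knockouts] <- 0   # both directions of a reversible reaction are lost
  ub[knockouts] <- 0
  if (!is.null(extra_lb)) {
    lb[names(extra_lb)] <- pmax(lb[names(extra_lb)], extra_lb)
  }
  if (is.null(objective)) objective <- model$biomass
  cc <- numeric(ncol(model$S))
  names(cc) <- reactions(model)
  if (is.character(objective)) cc[objective] <- 1 else cc <- objective
  if (!maximize) cc <- -cc
  sol <- lp_solve(model$S, rep(0, nrow(model$S)), unname(cc),
                  unname(lb), unname(ub))
  if (sol$status == "infeasible")
    return(list(feasible = FALSE, value = NA_real_, flux = NULL))
  if (sol$status != "optimal")
    stop("linear solver failed (status: ", sol$status, ")")
  list(feasible = TRUE,
       value = if (maximize) sol$value else -sol$value,
       flux = stats::setNames(sol$x, reactions(model)))
}

#' Does the network still grow after a set of reaction knockouts?
#'
#' Solves the flux-balance problem: steady state `S v = 0`, flux bounds
#' with every knocked-out reaction fixed to zero in both directions, the
#' medium applied to the exchange bounds; growth means the maximal biomass
#' flux reaches the threshold. An infeasible problem (no steady state at
#' all) counts as no growth; a genuine solver breakdown raises an error
#' instead, so the two cannot be confused.
#'
#' @param model a [stoich_model()].
#' @param medium named uptake-bound vector (see [read_medium()]); `NULL`
#'   leaves the model's exchange bounds as they are.
#' @param knockouts character vector of reaction ids to delete.
#' @param threshold minimal biomass flux that counts as growth. The default
#'   `1e-6` (absolute, appropriate for media on a unit-to-tens uptake
#'   scale) is configurable because lethality is a threshold question.
#' @return `TRUE` if the network grows, else `FALSE`.
#' @examples
#' net <- toy_network()
#' growth_test(net$model, net$medium)                      # TRUE
#' growth_test(net$model, net$medium, knockouts = "r6")    # FALSE
#' @export
growth_test <- function(model, medium = NULL, knockouts = character(),
                        threshold = 1e-6) {
  sol <- fba(model, medium, knockouts)
  sol$feasible && sol$value >= threshold
}

#' Flux variability analysis
#'
#' Minimal and maximal steady-state flux of every reaction, optionally with
#' the biomass flux pinned to a fraction of its maximum (`fraction = 0`:
#' any growth; `fraction = 1`: only optimal-growth flux patterns).
#'
#' @param model a [stoich_model()].
#' @param medium named uptake-bound vector or `NULL`.
#' @param fraction biomass fraction in `[0, 1]`.
#' @return matrix with columns `min` and `max`, one row per reaction.
#' @export
fva <- function(model, medium = NULL, fraction = 0) {
  stopifnot(fraction >= 0, fraction <= 1)
  extra <- NULL
  if (fraction > 0) {
    opt <- fba(model, medium)
    if (!opt$feasible) stop("model infeasible; cannot fix biomass fraction")
    # back off a sliver so the pinned problem stays numerically feasible
    extra <- stats::setNames(fraction * opt$value * (1 - 1e-9),
                             model$biomass)
  }
  out <- matrix(NA_real_, ncol(model$S), 2,
                dimnames = list(reactions(model), c("min", "max")))
  for (rx in reactions(model)) {
    out[rx, "max"] <- fba(model, medium, objective = rx, maximize = TRUE,
                          extra_lb = extra)$value
    out[rx, "min"] <- fba(model, medium, objective = rx, maximize = FALSE,
                          extra_lb = extra)$value
  }
  out
}

#' Remove flux-incapable reactions
#'
#' Flux variability analysis identifies every reaction that cannot carry
#' flux on the given medium (`mode = "any-growth"`), or cannot participate
#' in any optimal-growth flux pattern (`mode = "optimal-growth"`, biomass
#' pinned at its maximum); those reactions are removed, together with
#' metabolites left without reactions. The medium is baked into the
#' returned model's exchange bounds.
#'
#' Consistency does not change the network's minimal cut sets: a blocked
#' reaction can never be part of a lethal combination, so the PoF before
#' and after is identical (any-growth mode).
#'
#' @param model a [stoich_model()].
#' @param medium named uptake-bound vector or `NULL`.
#' @param mode `"any-growth"` (default) or `"optimal-growth"`.
#' @param tol absolute flux below which a reaction counts as blocked.
#' @return a consistent [stoich_model()].
#' @export
make_consistent <- function(model, medium = NULL,
                            mode = c("any-growth", "optimal-growth"),
                            tol = 1e-6) {
  mode <- match.arg(mode)
  model <- apply_medium(model, medium)
  if (!growth_test(model)) stop("model does not grow on this medium")
  rng <- fva(model, fraction = if (mode == "any-growth") 0 else 1)
  blocked <- pmax(abs(rng[, "min"]), abs(rng[, "max"])) < tol
  blocked[model$biomass] <- FALSE
  keep <- !blocked
  S <- model$S[, keep, drop = FALSE]
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  stoich_model(S, model$lb[keep], model$ub[keep], biomass = model$biomass,
               exchanges = intersect(model$exchanges, colnames(S)))
}

#' Scale a carbon uptake bound to hit a reference growth rate
#'
#' Bisects the uptake bound of one exchange reaction until the maximal
#' biomass flux matches `reference_rate`. Used to put models growing on
#' different substrates on an equal footing before comparing robustness.
#' If the rate is unreachable even at `max_bound` (the conventional
#' +/-10,000 relaxation ceiling), an error is raised.
#'
#' @param model a [stoich_model()].
#' @param medium named uptake-bound vector containing `carbon_exchange`.
#' @param carbon_exchange id of the exchange to rescale.
#' @param reference_rate target maximal biomass flux (> 0).
#' @param tol relative tolerance on the matched rate.
#' @param max_bound uptake ceiling.
#' @return the adjusted medium.
#' @export
match_growth_rate <- function(model, medium, carbon_exchange,
                              reference_rate, tol = 1e-6,
                              max_bound = 10000) {
  stopifnot(carbon_exchange %in% names(medium), reference_rate > 0)
  rate_at <- function(bound) {
    med <- medium
    med[carbon_exchange] <- bound
    v <- fba(model, med)
    if (!v$feasible) 0 else v$value
  }
  hi <- medium[[carbon_exchange]]
  cur <- rate_at(hi)
  if (abs(cur - reference_rate) <= tol * reference_rate) return(medium)
  while (cur < reference_rate && hi < max_bound) {
    hi <- min(hi * 2, max_bound)
    cur <- rate_at(hi)
  }
  if (cur < reference_rate * (1 - tol))
    stop("reference rate ", reference_rate, " unreachable within uptake ",
         "ceiling ", max_bound, " (max achievable: ", signif(cur, 6), ")")
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- rate_at(mid)
    if (abs(v - reference_rate) <= tol * reference_rate) {
      medium[carbon_exchange] <- mid
      return(medium)
    }
    if (v < reference_rate) lo <- mid else hi <- mid
  }
  medium[carbon_exchange] <- (lo + hi) / 2
  medium
}
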