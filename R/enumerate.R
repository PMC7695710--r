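#' Enumerate minimal cut sets by exhaustive knockout testing
#'
#' Finds every minimal cut set of cardinality up to `d_m` by testing
#' deletion subsets in order of increasing size: a subset is an MCS iff
#' growth fails for it and it contains no smaller MCS -- which the level
#' order guarantees automatically, since any lethal proper subset would
#' already have been recorded. Subsets containing a known MCS are skipped
#' without solving.
#'
#' This brute-force enumerator is intended for small (desk-scale) or
#' compressed networks; the number of candidate subsets
#' \eqn{\sum_d C(n, d)} is guarded by `budget`.
#'
#' All reactions are knockable by default, including exchanges and the
#' biomass reaction itself (whose deletion is trivially lethal, making it
#' an essential reaction). Pass `exclude` to restrict the candidate set,
#' e.g. when boundary reactions are modeled as nutrient availability
#' rather than enzymes; reported cut set counts depend on this convention.
#'
#' @param model a [stoich_model()].
#' @param medium named uptake-bound vector or `NULL`.
#' @param d_m maximal cardinality to enumerate.
#' @param exclude reaction ids never knocked out.
#' @param budget refuse enumerations needing more candidate subsets than
#'   this; raise it explicitly for larger runs, or compress the model
#'   first ([linear_compress()]).
#' @param threshold growth threshold, see [growth_test()].
#' @return an [mcs_collection()] with `n_reactions = ncol(S)` and the
#'   requested `d_m`.
#' @examples
#' net <- toy_network()
#' enumerate_mcs(net$model, net$medium, d_m = 3)
#' @export
enumerate_mcs <- function(model, medium = NULL, d_m, exclude = character(),
                          budget = 50000, threshold = 1e-6) {
  stopifnot(inherits(model, "stoich_model"), d_m >= 1)
  model <- apply_medium(model, medium)
  if (!growth_test(model, threshold = threshold))
    stop("baseline model does not grow; nothing to cut")
  cand <- sort(setdiff(reactions(model), exclude), method = "radix")
  n <- length(cand)
  d_m <- as.integer(min(d_m, n))
  total <- sum(choose(n, seq_len(d_m)))
  if (total > budget)
    stop("enumeration would test up to ", format(total, big.mark = ","),
         " subsets (budget ", format(budget, big.mark = ","),
         "); compress the network first or raise 'budget'")
  found <- list()
  for (d in seq_len(d_m)) {
    if (d > n) break
    utils::combn(cand, d, function(sub) {
      for (s in found) if (all(s %in% sub)) return(invisible(NULL))
      if (!growth_test(model, knockouts = sub, threshold = threshold))
        found[[length(found) + 1L]] <<- sub
      invisible(NULL)
    }, simplify = FALSE)
  }
  mcs_collection(found, n_reactions = ncol(model$S), d_m = d_m)
}

#' Essential reactions
#'
#' Single-knockout scan: the reactions whose lone deletion abolishes
#' growth, i.e. the cardinality-1 minimal cut sets (`m_1`).
#'
#' @inheritParams enumerate_mcs
#' @return character vector of reaction ids.
#' @export
essential_reactions <- function(model, medium = NULL, exclude = character(),
                                threshold = 1e-6) {
  model <- apply_medium(model, medium)
  if (!growth_test(model, threshold = threshold))
    stop("baseline model does not grow")
  cand <- sort(setdiff(reactions(model), exclude), method = "radix")
  cand[!vapply(cand, function(rx)
    growth_test(model, knockouts = rx, threshold = threshold), TRUE)]
}
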