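#' Pairwise network similarity
#'
#' Similarity of two metabolic networks judged by their reaction
#' complements: \eqn{\sigma_{i,j} = r^2_{M_i \cap M_j} / (r_{M_i}
#' r_{M_j})}, the squared shared-reaction count over the product of the
#' network sizes. Equal reaction sets give 1, disjoint ones 0; the
#' complement \eqn{1 - \sigma} is the network dissimilarity.
#'
#' @param reactions_i,reactions_j non-empty character vectors of reaction
#'   ids (duplicates ignored).
#' @return object of class `similarity_score`: list with `sigma` and
#'   `dissimilarity`.
#' @examples
#' network_similarity(c("a", "b", "c", "d"), c("a", "b", "x", "y", "z"))
#' @export
network_similarity <- function(reactions_i, reactions_j) {
  reactions_i <- unique(reactions_i)
  reactions_j <- unique(reactions_j)
  if (!length(reactions_i) || !length(reactions_j))
    stop("reaction sets must be non-empty")
  shared <- length(intersect(reactions_i, reactions_j))
  sigma <- shared^2 / (length(reactions_i) * length(reactions_j))
  structure(list(sigma = sigma, dissimilarity = 1 - sigma),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("network similarity sigma = %.6g (dissimilarity %.6g)\n",
              x$sigma, x$dissimilarity))
  invisible(x)
}

#' Shared reactome of a panel of models
#'
#' The set of reactions present in every model of a panel, reported with
#' both the intersection and union sizes so that either normalization
#' convention (shared over union, or shared over a single model's size)
#' can be recovered. The `fraction` field is intersection over union.
#'
#' @param models list of character vectors of reaction ids (one per
#'   model), or of [stoich_model()]s.
#' @return list with `shared` (character vector), `n_shared`, `n_union`,
#'   and `fraction`.
#' @export
shared_reactome <- function(models) {
  if (!length(models)) stop("empty model list")
  sets <- lapply(models, function(m)
    if (inherits(m, "stoich_model")) reactions(m) else unique(as.character(m)))
  shared <- Reduce(intersect, sets)
  all_rx <- Reduce(union, sets)
  list(shared = sort(shared, method = "radix"),
       n_shared = length(shared), n_union = length(all_rx),
       fraction = length(shared) / length(all_rx))
}

#' Robustness scan across single carbon sources
#'
#' For each candidate carbon source, opens that source alone (on top of
#' the carbon-free base medium), checks growth, optionally rescales the
#' uptake to a reference growth rate, enumerates minimal cut sets up to
#' `d_m`, and computes the truncated PoF. One row per source; sources that
#' do not support growth are flagged and skipped, and per-source solver
#' failures are reported as messages without stopping the scan.
#'
#' @param model a [stoich_model()].
#' @param base_medium named uptake vector of the non-carbon medium
#'   components (may be empty).
#' @param carbon_exchanges named numeric vector (exchange id -> uptake
#'   bound) or character vector (default bound 10) of the sources to scan.
#' @param d_m enumeration depth.
#' @param p,d_0 PoF settings, see [pof()].
#' @param match_rate if non-`NULL`, rescale each source's uptake with
#'   [match_growth_rate()] to this biomass rate before enumeration.
#' @param exclude reaction ids never knocked out (see [enumerate_mcs()]).
#' @param budget passed to [enumerate_mcs()].
#' @return data.frame with columns `source`, `growth`, `m_1 .. m_<d_m>`,
#'   `estimate`, `max_error`.
#' @export
carbon_source_scan <- function(model, base_medium, carbon_exchanges,
                               d_m = 3, p = 1e-4, d_0 = 10,
                               match_rate = NULL, exclude = character(),
                               budget = 50000) {
  if (is.null(names(carbon_exchanges))) {
    carbon_exchanges <- stats::setNames(rep(10, length(carbon_exchanges)),
                                        carbon_exchanges)
  }
  rows <- vector("list", length(carbon_exchanges))
  for (i in seq_along(carbon_exchanges)) {
    src <- names(carbon_exchanges)[i]
    med <- base_medium[setdiff(names(base_medium), names(carbon_exchanges))]
    med[src] <- carbon_exchanges[[i]]
    row <- stats::setNames(
      as.list(c(NA, rep(NA_real_, d_m + 2))),
      c("growth", paste0("m_", seq_len(d_m)), "estimate", "max_error"))
    row$source <- src
    res <- tryCatch({
      grows <- growth_test(model, med)
      row$growth <- grows
      if (grows) {
        if (!is.null(match_rate))
          med <- match_growth_rate(model, med, src, match_rate)
        coll <- enumerate_mcs(model, med, d_m = d_m, exclude = exclude,
                              budget = budget)
        est <- pof(coll, p = p, d_0 = d_0)
        for (k in seq_len(d_m)) row[[paste0("m_", k)]] <- coll$m_i[k]
        row$estimate <- est$estimate
        row$max_error <- est$max_error
      }
      row
    }, error = function(e) {
      message("carbon source '", src, "' failed: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[c("source", "growth", paste0("m_", seq_len(d_m)),
                      "estimate", "max_error")])))
  rownames(out) <- NULL
  out
}
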