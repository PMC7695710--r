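# run code with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' The six-reaction toy network
#'
#' A minimal branched network with two substrate inlets feeding a common
#' biomass precursor: `r1: -> A`, `r2: -> B`, `r3: A <-> B` (the single
#' reversible reaction), `r4: A -> C`, `r5: B -> C`, `r6: C ->` (biomass).
#' Its minimal cut sets up to cardinality 3 are exactly the essential
#' reaction `{r6}`, the synthetic lethal pairs `{r1, r2}` and `{r4, r5}`,
#' and the synthetic lethal triplets `{r1, r3, r5}` and `{r2, r3, r4}`;
#' the exact PoF at `p = 0.1` is
#' \eqn{p + 2p^2 - 7p^4 + 7p^5 - 2p^6 = 0.11936}.
#'
#' @return list with `model` (a [stoich_model()]) and `medium` (both
#'   inlets open at uptake 10).
#' @examples
#' net <- toy_network()
#' coll <- enumerate_mcs(net$model, net$medium, d_m = 3)
#' exact_pof(coll, p = 0.1)
#' @export
toy_network <- function() {
  S <- matrix(0, 3, 6, dimnames = list(c("A", "B", "C"), paste0("r", 1:6)))
  S["A", "r1"] <- 1
  S["B", "r2"] <- 1
  S["A", "r3"] <- -1
  S["B", "r3"] <- 1
  S["A", "r4"] <- -1
  S["C", "r4"] <- 1
  S["B", "r5"] <- -1
  S["C", "r5"] <- 1
  S["C", "r6"] <- -1
  lb <- c(0, 0, -10, 0, 0, 0)
  ub <- rep(10, 6)
  model <- stoich_model(S, lb, ub, biomass = "r6")
  list(model = model, medium = c(r1 = 10, r2 = 10))
}

#' Random minimal cut set collection
#'
#' Seeded generator of valid [mcs_collection()]s with prescribed numbers
#' of essential reactions, synthetic lethal pairs and triplets, for
#' property testing of the PoF machinery. Members of pairs and triplets
#' are drawn from the non-essential reactions; `overlap` is the
#' probability that a member is reused from an earlier pair/triplet rather
#' than drawn fresh, steering how strongly the cut sets overlap (and hence
#' how much inclusion-exclusion cancellation occurs). Candidate sets that
#' would violate minimality are rejected and redrawn.
#'
#' @param m_1,m_2,m_3 requested counts of cardinality 1, 2, 3 cut sets.
#' @param r total reactions in the network.
#' @param overlap reuse probability in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the same collection.
#' @return an [mcs_collection()] with `d_m = 3` (or the largest requested
#'   cardinality) and reactions labeled `R01, R02, ...`.
#' @export
random_mcs_collection <- function(m_1, m_2, m_3, r, overlap = 0.25,
                                  seed = NULL) {
  stopifnot(m_1 >= 0, m_2 >= 0, m_3 >= 0, r >= 1,
            overlap >= 0, overlap <= 1)
  pool <- sprintf("R%0*d", nchar(r), seq_len(r))
  if (m_1 > r) stop("more essentials than reactions")
  nfree <- r - m_1
  if ((m_2 > 0 && (nfree < 2 || choose(nfree, 2) < m_2)) ||
      (m_3 > 0 && (nfree < 3 || choose(nfree, 3) < m_3)))
    stop("requested counts infeasible for r = ", r)
  with_seed(seed, {
    ess <- sample(pool, m_1)
    free <- setdiff(pool, ess)
    sets <- as.list(ess)
    used <- character(0)
    draw_set <- function(k) {
      members <- character(0)
      for (j in seq_len(k)) {
        from_used <- length(setdiff(used, members)) > 0 &&
          stats::runif(1) < overlap
        src <- if (from_used) setdiff(used, members)
        else setdiff(free, members)
        if (!length(src)) src <- setdiff(free, members)
        members <- c(members, src[sample.int(length(src), 1L)])
      }
      sort(members, method = "radix")
    }
    for (k in c(rep(2L, m_2), rep(3L, m_3))) {
      for (attempt in 1:2000) {
        cand <- draw_set(k)
        clash <- any(vapply(sets, function(s)
          all(s %in% cand) || all(cand %in% s), TRUE))
        if (!clash) break
        cand <- NULL
      }
      if (is.null(cand))
        stop("could not place a cardinality-", k,
             " cut set without violating minimality; lower 'overlap' ",
             "or the requested counts")
      sets[[length(sets) + 1L]] <- cand
      used <<- union(used, cand)
    }
    mcs_collection(sets, n_reactions = r,
                   d_m = max(1L, (m_2 > 0) * 2L, (m_3 > 0) * 3L,
                             if (m_1 + m_2 + m_3 == 0) 3L else 1L))
  })
}

#' Random layered metabolic network
#'
#' Seeded generator of growing stoichiometric models with tunable
#' parallel-path redundancy: a chain of metabolites `M1 .. Mn` where each
#' layer `i` holds `width` parallel reactions converting `M(i-1)` to
#' `M(i)` (layer 1 reactions are substrate inlets), closed by a single
#' biomass reaction draining `Mn`. With probability `redundancy` a
#' skip-layer reaction `M(i-1) -> M(i+1)` is added per interior layer,
#' creating bypasses. With `width = 1` and `redundancy = 0` the network is
#' a pure chain and every reaction is essential; with `width = k` the
#' minimal cut sets (biomass aside) are the per-layer k-tuples.
#'
#' @param n_layers number of conversion layers (>= 1).
#' @param width parallel reactions per layer (>= 1).
#' @param redundancy probability of a skip-layer bypass per interior
#'   layer, in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `model` and `medium` (all inlets open at uptake 10).
#' @export
random_layered_network <- function(n_layers, width, redundancy = 0,
                                   seed = NULL) {
  stopifnot(n_layers >= 1, width >= 1, redundancy >= 0, redundancy <= 1)
  with_seed(seed, {
    mets <- sprintf("M%d", seq_len(n_layers))
    rx <- list()
    for (i in seq_len(n_layers)) {
      for (j in seq_len(width)) {
        col <- stats::setNames(numeric(length(mets)), mets)
        if (i > 1) col[mets[i - 1]] <- -1
        col[mets[i]] <- 1
        rx[[sprintf("L%d_%d", i, j)]] <- col
      }
    }
    if (n_layers >= 3) {
      for (i in seq_len(n_layers - 2)) {
        if (stats::runif(1) < redundancy) {
          col <- stats::setNames(numeric(length(mets)), mets)
          col[mets[i]] <- -1
          col[mets[i + 2]] <- 1
          rx[[sprintf("X%d", i)]] <- col
        }
      }
    }
    col <- stats::setNames(numeric(length(mets)), mets)
    col[mets[n_layers]] <- -1
    rx[["BM"]] <- col
    S <- do.call(cbind, rx)
    model <- stoich_model(S, lb = rep(0, ncol(S)), ub = rep(10, ncol(S)),
                          biomass = "BM")
    medium <- stats::setNames(rep(10, width), sprintf("L1_%d", seq_len(width)))
    stopifnot(growth_test(model, medium))
    list(model = model, medium = medium)
  })
}
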