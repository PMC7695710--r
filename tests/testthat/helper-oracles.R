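# Independent oracles used to cross-check the package's computational
# routes. They share no code with the implementation: subsets are
# enumerated as bitmasks, unions by direct power-set walks.

# lethal d-subset counts for d = 0..r by exhaustive bitmask enumeration
# (uncompressed collections, r <= ~16)
oracle_lethal_counts <- function(coll) {
  r <- coll$n_reactions
  ids <- names(coll$weights)
  mcs_masks <- vapply(coll$mcs, function(s) sum(2^(match(s, ids) - 1)), 0)
  masks <- seq_len(2^r) - 1
  lethal <- rep(FALSE, length(masks))
  for (mm in mcs_masks)
    lethal <- lethal | (bitwAnd(masks, mm) == mm)
  bits <- matrix(as.integer(intToBits(masks)), nrow = length(masks),
                 byrow = TRUE)[, 1:r, drop = FALSE]
  popcount <- rowSums(bits)
  vapply(0:r, function(d) sum(lethal[popcount == d]), 0)
}

# full power-set union profile by direct 2^m - 1 enumeration (m <= ~14);
# returns named signed counts in the same key format as union_profile()
oracle_union_profile <- function(coll, d_0 = Inf) {
  m <- coll$m
  ids <- names(coll$weights)
  w <- unname(coll$weights)
  sets <- lapply(coll$mcs, function(s) match(s, ids))
  acc <- new.env(parent = emptyenv())
  for (mask in seq_len(2^m - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    u <- sort(unique(unlist(sets[members])))
    if (length(u) > d_0) next
    key <- paste(sort(w[u]), collapse = ",")
    sgn <- if (length(members) %% 2 == 1) 1 else -1
    cur <- acc[[key]]
    acc[[key]] <- (if (is.null(cur)) 0 else cur) + sgn
  }
  keys <- ls(acc)
  counts <- vapply(keys, function(k) acc[[k]], 0)
  counts[counts != 0]
}

# minimal cut sets by the definition: a subset is an MCS iff it is lethal
# and every maximal proper subset is viable
oracle_enumerate_mcs <- function(model, medium, d_m,
                                 exclude = character()) {
  model <- pofkit:::apply_medium(model, medium)
  cand <- sort(setdiff(colnames(model$S), exclude), method = "radix")
  lethal <- function(ko) !growth_test(model, knockouts = ko)
  found <- list()
  for (d in seq_len(min(d_m, length(cand)))) {
    for (sub in utils::combn(cand, d, simplify = FALSE)) {
      if (!lethal(sub)) next
      proper_ok <- all(!vapply(seq_along(sub), function(i)
        length(sub) > 1 && lethal(sub[-i]), TRUE))
      if (proper_ok) found[[length(found) + 1L]] <- sub
    }
  }
  found
}

# exact rational identity helpers: with p = a/b, both PoF routes reduce to
# integer sums that must agree exactly.
#   Eq-2 route (frequencies): sum_d N_d a^d (b-a)^(r-d)
#   Eq-4 route (union profile polynomial): sum_u S_u a^u b^(r-u)
rational_pof_from_counts <- function(N, r, a, b) {
  sum(N[-1] * a^(1:r) * (b - a)^(r - (1:r)))
}
rational_pof_from_poly <- function(S, r, a, b) {
  sum(S * a^(seq_along(S)) * b^(r - seq_along(S)))
}

set_key <- function(sets) sort(vapply(sets, paste, "", collapse = "+"))

# deterministic instance recipe for the randomized property suites
acceptance_instance <- function(seed) {
  m_1 <- seed %% 3
  m_2 <- (seed %/% 3) %% 4
  m_3 <- (seed %/% 12) %% 3
  if (m_1 + m_2 + m_3 == 0) m_1 <- 1
  r <- 10 + seed %% 3
  overlap <- (seed %% 5) / 5
  random_mcs_collection(m_1, m_2, m_3, r = r, overlap = overlap,
                        seed = seed)
}
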