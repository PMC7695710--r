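#' Signed union profile of a cut set collection
#'
#' The inclusion-exclusion expression for the probability of failure sums,
#' over every non-empty subset J of the m known MCSs, the term
#' \eqn{(-1)^{|J|-1} p^{|M_J|}} where \eqn{M_J} is the union of the member
#' cut sets. Distinct subsets with equal unions only differ in sign, so all
#' the PoF machinery needs is the *net signed count* per union descriptor:
#' for uncompressed collections the descriptor is the union's cardinality;
#' for compressed (weighted) collections it is the multiset of lump weights
#' in the union.
#'
#' The power set is walked by a canonical recursion: cut sets are sorted by
#' ascending original cardinality (ties keep input order) and every subset
#' is reached exactly once by extending with indices strictly below the
#' subset's current minimum. Two shortcuts keep the walk tractable:
#' \itemize{
#' \item *pruning*: unions only grow, so once a union needs more than `d_0`
#'   deletions (one per lump) the whole branch is dropped;
#' \item *cancellation*: if some cut set with index below the subset's
#'   minimum is contained in the current union, the branch contributes a net
#'   zero -- adding or removing that index pairs every descendant with a
#'   twin of opposite sign and identical union -- and is skipped.
#' }
#' Counts are accumulated as exact integers.
#'
#' @param x an [mcs_collection()].
#' @param d_0 truncation depth: unions needing more than `d_0` deletions are
#'   discarded. `Inf` keeps every union (full power set; exact PoF).
#' @param shortcut logical; disable the cancellation shortcut (for testing
#'   its equivalence only -- results are identical).
#' @param max_m refuse collections with more cut sets than this when
#'   `d_0 = Inf`, since the full power set has `2^m - 1` members.
#' @return An object of class `union_profile`: a named numeric vector
#'   `counts` (descriptor key -> net signed count, key = comma-joined sorted
#'   lump weights), plus `d_0`, `m`, and `all_unit` (no weights above 1).
#' @seealso [pof()], [exact_pof()], [pof_polynomial()]
#' @export
union_profile <- function(x, d_0 = Inf, shortcut = TRUE, max_m = 25L) {
  stopifnot(inherits(x, "mcs_collection"))
  if (is.infinite(d_0) && x$m > max_m)
    stop("full power set over ", x$m, " cut sets is intractable; ",
         "use the truncated estimator (finite d_0) or raise 'max_m'")
  ids <- names(x$weights)
  G <- length(ids)
  w <- unname(x$weights)
  sets <- lapply(x$mcs, function(s) match(s, ids))
  ord <- order(mcs_cardinality(x), method = "radix")  # stable: ties keep input order
  sets <- sets[ord]
  m <- length(sets)

  env <- new.env(parent = emptyenv())
  record <- function(U, sgn) {
    key <- paste(sort(w[U]), collapse = ",")
    cur <- env[[key]]
    env[[key]] <- (if (is.null(cur)) 0 else cur) + sgn
  }
  # is any cut set with index < k contained in union U?
  dominated <- function(U, k) {
    for (kk in seq_len(k - 1L)) if (all(U[sets[[kk]]])) return(TRUE)
    FALSE
  }
  recurse <- function(U, q, minidx, sgn) {
    for (k in seq_len(minidx - 1L)) {
      U2 <- U
      U2[sets[[k]]] <- TRUE
      q2 <- sum(U2)
      if (q2 > d_0) next                      # union can only grow
      if (shortcut && dominated(U2, k)) next  # net-zero branch
      record(which(U2), -sgn)
      recurse(U2, q2, k, -sgn)
    }
  }
  for (j in seq_len(m)) {
    U <- rep(FALSE, G)
    U[sets[[j]]] <- TRUE
    q <- sum(U)
    if (q > d_0) next
    record(which(U), 1)
    recurse(U, q, j, 1)
  }

  keys <- ls(env)
  counts <- vapply(keys, function(k) env[[k]], 0)
  counts <- counts[counts != 0]
  structure(list(counts = counts, d_0 = d_0, m = m,
                 all_unit = all(w == 1L)),
            class = "union_profile")
}

#' @export
print.union_profile <- function(x, ...) {
  cat("Union profile over", x$m, "cut sets (d_0 =", x$d_0, ")\n")
  if (!length(x$counts)) {
    cat("  empty\n")
    return(invisible(x))
  }
  keys <- names(x$counts)
  ord <- order(vapply(strsplit(keys, ","), function(s) sum(as.numeric(s)), 0),
               keys, method = "radix")
  for (k in ord)
    cat(sprintf("  {%s}: %+d\n", keys[k], as.integer(x$counts[k])))
  invisible(x)
}

# parse a descriptor key back into its integer lump weights
descriptor_weights <- function(keys) {
  lapply(strsplit(keys, ",", fixed = TRUE), as.integer)
}

#' Polynomial form of the probability of failure
#'
#' Expands the inclusion-exclusion sum into a polynomial in the per-reaction
#' mutation rate `p` with exact integer coefficients. For an uncompressed
#' collection the term of a union of cardinality `u` is \eqn{p^u}; for a
#' lump of weight `w` the factor \eqn{1-(1-p)^w} is expanded binomially and
#' the per-union factors convolved. `exact_pof(x, p)` equals the polynomial
#' evaluated at `p`.
#'
#' @param x a [union_profile()] (use `d_0 = Inf` for the exact PoF
#'   polynomial) or an [mcs_collection()], which is profiled first.
#' @return numeric vector of coefficients; element `u` is the coefficient
#'   of \eqn{p^u} (the constant term is always zero and not included).
#' @examples
#' toy <- mcs_collection(list("r6", c("r1", "r2"), c("r4", "r5"),
#'                            c("r1", "r3", "r5"), c("r2", "r3", "r4")),
#'                       n_reactions = 6, d_m = 3)
#' pof_polynomial(toy)  # 1 2 0 -7 7 -2
#' @export
pof_polynomial <- function(x) {
  if (inherits(x, "mcs_collection")) x <- union_profile(x, d_0 = Inf)
  stopifnot(inherits(x, "union_profile"))
  if (!length(x$counts)) return(numeric(0))
  descs <- descriptor_weights(names(x$counts))
  deg <- max(vapply(descs, sum, 0))
  out <- numeric(deg)
  for (i in seq_along(descs)) {
    poly <- 1
    for (wt in descs[[i]]) {
      # 1 - (1-p)^wt = sum_{t=1..wt} (-1)^(t+1) C(wt,t) p^t
      fac <- c(0, (-1)^(seq_len(wt) + 1) * choose(wt, seq_len(wt)))
      poly <- convolve_poly(poly, fac)
    }
    poly <- poly * x$counts[i]
    out[seq_along(poly[-1])] <- out[seq_along(poly[-1])] + poly[-1]
  }
  out
}

# exact polynomial product, coefficient vectors with constant term first
convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}
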