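#' Binomial deletion-count weights
#'
#' Probability that exactly `d` of the network's `r` reactions acquire a
#' loss-of-function mutation when each is hit independently at rate `p`:
#' \eqn{w_d = C(r,d) p^d (1-p)^{r-d}}. Evaluated in log space via
#' [stats::dbinom()], so there is no overflow for large `r` (tested to
#' `r = 1e5`) and \eqn{\sum_{d=0}^r w_d = 1} to machine precision.
#'
#' @param r number of reactions (trials).
#' @param p per-reaction loss-of-function rate, in (0, 1).
#' @param d number of deletions; vectorized, each in `0..r`.
#' @return numeric vector of probabilities.
#' @export
binomial_weight <- function(r, p, d) {
  stopifnot(r >= 1, p > 0, p < 1)
  if (any(d < 0 | d > r)) stop("'d' must lie in 0..r")
  stats::dbinom(d, size = r, prob = p)
}

#' Exhaustive lethal deletion-set count (oracle)
#'
#' Counts, by explicit enumeration of all `C(r, d)` subsets, how many sets
#' of `d` reaction deletions are lethal, i.e. contain at least one minimal
#' cut set. This is the definitional numerator of the failure frequency and
#' serves as an independent check of the union-profile computation; it is
#' only tractable for small networks.
#'
#' @param x an uncompressed [mcs_collection()] (all weights 1).
#' @param d number of deletions.
#' @param max_r refuse enumeration beyond this many reactions.
#' @return integer count of lethal `d`-subsets.
#' @seealso [failure_frequencies()] for the scalable computation.
#' @export
lethal_subset_count <- function(x, d, max_r = 22L) {
  stopifnot(inherits(x, "mcs_collection"))
  if (any(x$weights > 1L))
    stop("oracle enumeration requires an uncompressed collection")
  r <- x$n_reactions
  if (r > max_r)
    stop("r = ", r, " too large for exhaustive enumeration; ",
         "use failure_frequencies()")
  if (d < 0 || d > r) stop("'d' must lie in 0..r")
  if (x$m == 0L || d == 0L) return(0L)
  ids <- names(x$weights)
  sets <- lapply(x$mcs, function(s) match(s, ids))
  # reactions outside any cut set are anonymous: indices beyond length(ids)
  hits <- utils::combn(r, d, function(sub) {
    for (s in sets) if (all(s %in% sub)) return(TRUE)
    FALSE
  })
  sum(hits)
}

# per-descriptor count of d-subsets of r reactions covering the union,
# divided by C(r,d); exact integer numerators when representable.
# Descriptor = integer lump weights ws. Covering means >= 1 deletion in
# every lump: by inclusion-exclusion over untouched lumps,
#   N(d) = sum_{T subset of lumps} (-1)^|T| C(r - w(T), d).
# For unit weights this collapses to C(r-q, d-q).
descriptor_subset_sums <- function(ws) {
  sums <- 0
  signs <- 1
  for (w in ws) {
    sums <- c(sums, sums + w)
    signs <- c(signs, -signs)
  }
  list(sums = sums, signs = signs)
}

descriptor_count <- function(ws, r, d, exact) {
  q <- length(ws)
  if (all(ws == 1L)) {
    if (d < q) return(0)
    if (exact) return(choose(r - q, d - q))
    i <- seq_len(q) - 1
    return(prod((d - i) / (r - i)))
  }
  ss <- descriptor_subset_sums(ws)
  if (exact) {
    sum(ss$signs * choose(r - ss$sums, d))
  } else {
    sum(ss$signs * vapply(ss$sums, function(s) {
      if (s == 0) return(1)
      if (s > r - d) return(0)
      i <- seq_len(s) - 1
      prod((r - d - i) / (r - i))
    }, 0))
  }
}

#' Failure frequencies from a union profile
#'
#' The failure frequency \eqn{f_d} is the fraction of all `C(r, d)` sets of
#' `d` reaction deletions that are lethal. By inclusion-exclusion over the
#' unions recorded in the profile,
#' \eqn{f_d = \sum_u S_u \, C(r-u, d-u) / C(r,d)} for uncompressed
#' collections with net signed count \eqn{S_u} per union cardinality `u`;
#' for weighted (compressed) unions the per-union subset count runs
#' inclusion-exclusion over untouched lumps. When the profile was built
#' from all MCSs up to cardinality `d_m`, the result is the truncated
#' frequency \eqn{f_d^{d_m} \le f_d}, exact for `d <= d_m`.
#'
#' Whenever `C(r, d)` is exactly representable, numerator and denominator
#' are carried as exact integers and the quotient taken once at the end;
#' otherwise a numerically stable falling-factorial product is used. Values
#' must land in `[0, 1]` and be non-decreasing in `d` by construction --
#' a violation beyond rounding noise is treated as an internal error, not
#' clipped away.
#'
#' @param x a [union_profile()].
#' @param r total number of reactions in the (uncompressed) network.
#' @param d_0 compute `f_d` for `d = 1..d_0`; defaults to the profile's
#'   depth, capped at `r`.
#' @return An object of class `failure_profile`: list with `r`, `d_0`,
#'   `f` (numeric, index = d), and when exact arithmetic applied,
#'   `numerator` and `denominator` (both exactly representable integers).
#' @export
failure_frequencies <- function(x, r, d_0 = NULL) {
  stopifnot(inherits(x, "union_profile"))
  r <- as.integer(r)
  if (is.null(d_0)) d_0 <- min(x$d_0, r)
  d_0 <- as.integer(min(d_0, r))
  if (d_0 < 1L) stop("'d_0' must be >= 1")
  descs <- descriptor_weights(names(x$counts))
  if (length(descs)) {
    need <- max(vapply(descs, sum, 0))
    if (need > r) stop("profile refers to more reactions than r = ", r)
  }
  exact <- is.finite(choose(r, d_0)) && choose(r, d_0) <= 2^52
  f <- numeric(d_0)
  num <- if (exact) numeric(d_0) else NULL
  den <- if (exact) choose(r, seq_len(d_0)) else NULL
  for (d in seq_len(d_0)) {
    contrib <- vapply(descs, descriptor_count, 0, r = r, d = d, exact = exact)
    if (exact) {
      num[d] <- sum(x$counts * contrib)
      f[d] <- num[d] / den[d]
    } else {
      f[d] <- sum(x$counts * contrib)
    }
  }
  tol <- 1e-9
  if (any(f < -tol) || any(f > 1 + tol) || any(diff(f) < -tol))
    stop("internal error: failure frequencies out of range or decreasing ",
         "(this is a bug, please report)")
  f <- pmin(pmax(f, 0), 1)
  structure(list(r = r, d_0 = d_0, f = f, numerator = num, denominator = den),
            class = "failure_profile")
}

#' Exact probability of failure by full inclusion-exclusion
#'
#' Evaluates \eqn{F = \sum_{J} (-1)^{|J|-1} p^{|M_J|}} over every non-empty
#' subset of the collection's cut sets. For weighted (compressed)
#' collections the summand generalizes to
#' \eqn{\prod_{\mathrm{lumps}} (1-(1-p)^{w})}, which reduces to
#' \eqn{p^{|M_J|}} at unit weights. `F` depends only on the cut sets and
#' how they overlap -- not on the number of reactions in the network.
#'
#' Exact here means the full power set is covered (no truncation); the
#' collection must therefore contain *all* MCSs of the network for the
#' result to be the true PoF, and the subset count `2^m` must be tractable.
#'
#' @param x an [mcs_collection()].
#' @param p per-reaction loss-of-function rate, in (0, 1).
#' @param max_m passed to [union_profile()]: refuse larger collections and
#'   point to the truncated estimator [pof()] instead.
#' @return the probability of failure, a number in `[0, 1]`.
#' @examples
#' toy <- mcs_collection(list("r6", c("r1", "r2"), c("r4", "r5"),
#'                            c("r1", "r3", "r5"), c("r2", "r3", "r4")),
#'                       n_reactions = 6, d_m = 3)
#' exact_pof(toy, p = 0.1)  # 0.11936
#' @export
exact_pof <- function(x, p, max_m = 25L) {
  stopifnot(inherits(x, "mcs_collection"), p > 0, p < 1)
  prof <- union_profile(x, d_0 = Inf, max_m = max_m)
  if (!length(prof$counts)) return(0)
  descs <- descriptor_weights(names(prof$counts))
  terms <- vapply(seq_along(descs), function(i) {
    ws <- descs[[i]]
    prod(-expm1(ws * log1p(-p)))  # prod over lumps of 1-(1-p)^w
  }, 0)
  val <- sum(prof$counts * terms)
  if (val < -1e-12 || val > 1 + 1e-12)
    stop("internal error: exact PoF out of [0, 1]")
  min(max(val, 0), 1)
}

#' Essential-reaction closed form for the PoF
#'
#' When only the `m_1` essential reactions (cardinality-1 MCSs) are known
#' and they are the dominant failure modes, the PoF collapses to
#' \eqn{F \approx 1-(1-p)^{m_1}}, with first-order linearization
#' \eqn{m_1 p}.
#'
#' @param m_1 number of essential reactions (non-negative).
#' @param p per-reaction loss-of-function rate, in (0, 1).
#' @param linearized return the linearization `m_1 * p` instead.
#' @return a probability (or its linearization).
#' @export
essential_only_pof <- function(m_1, p, linearized = FALSE) {
  stopifnot(m_1 >= 0, p > 0, p < 1)
  if (linearized) return(m_1 * p)
  -expm1(m_1 * log1p(-p))
}

#' Worst-case truncation error of the PoF estimate
#'
#' Cut sets of cardinality above `d_m` are unknown, so for `d > d_m` the
#' truncated frequencies only bound the truth from below; in the worst case
#' every remaining combination of `d_m + 1` deletions is lethal and all
#' \eqn{f_d} with `d > d_m` jump to 1. The gap to that worst case is
#' \deqn{\varepsilon_{max} = 1 - \tilde F - \sum_{d=0}^{d_m} w_d (1 - f_d),}
#' which depends on the known frequencies only through `d <= d_m` and is
#' therefore independent of `d_0`. The true PoF always lies in
#' \eqn{[\tilde F, \tilde F + \varepsilon_{max}]}.
#'
#' @param estimate the truncated estimate \eqn{\tilde F}.
#' @param f failure frequencies, index = d, of length at least `d_m`.
#' @param r reaction count.
#' @param p per-reaction loss-of-function rate.
#' @param d_m cardinality up to which the frequencies are exact.
#' @return the error bound, a non-negative number.
#' @export
error_bound <- function(estimate, f, r, p, d_m) {
  stopifnot(d_m >= 1, length(f) >= d_m)
  w <- binomial_weight(r, p, 0:d_m)
  eps <- 1 - estimate - sum(w * (1 - c(0, f[seq_len(d_m)])))
  max(eps, 0)
}

#' Probability of failure of a metabolic network
#'
#' Estimates the probability that random loss-of-function mutations,
#' striking each of the network's `r` reactions independently at rate `p`,
#' include a lethal combination. The estimate is the binomially weighted
#' truncated sum \eqn{\tilde F_{d_0}^{d_m} = \sum_{d=1}^{d_0} w_d
#' f_d^{d_m}} over the failure frequencies computed from the cut sets known
#' up to cardinality `d_m`, together with the worst-case truncation bound
#' \eqn{\varepsilon_{max}} (see [error_bound()]): the true PoF lies in
#' `[estimate, estimate + max_error]` whenever the collection really
#' contains all MCSs up to `d_m`.
#'
#' Defaults `p = 1e-4` and `d_0 = 10` are the conventional settings for
#' comparative robustness analyses of genome-scale models.
#'
#' @param x an [mcs_collection()].
#' @param p per-reaction loss-of-function rate, in (0, 1).
#' @param d_0 truncation depth of the weighted sum (capped at `r`). Must be
#'   at least the collection's `d_m`; lower values discard known cut sets
#'   and trigger a warning.
#' @return An object of class `pof`: list with `estimate`, `max_error`,
#'   `f` (failure frequencies 1..d_0), `w` (binomial weights 1..d_0),
#'   `settings` (`p`, `d_0`, `d_m`, `r`), and the collection's `m`/`m_i`.
#' @examples
#' toy <- mcs_collection(list("r6", c("r1", "r2"), c("r4", "r5"),
#'                            c("r1", "r3", "r5"), c("r2", "r3", "r4")),
#'                       n_reactions = 6, d_m = 3)
#' pof(toy, p = 0.1, d_0 = 6)
#' @export
pof <- function(x, p = 1e-4, d_0 = 10L) {
  stopifnot(inherits(x, "mcs_collection"), p > 0, p < 1, d_0 >= 1)
  r <- x$n_reactions
  if (d_0 < x$d_m)
    warning("d_0 = ", d_0, " is below the collection's d_m = ", x$d_m,
            "; known cut sets are being discarded")
  d_0 <- min(as.integer(d_0), r)
  prof <- union_profile(x, d_0 = d_0)
  fp <- failure_frequencies(prof, r = r, d_0 = d_0)
  w <- binomial_weight(r, p, seq_len(d_0))
  estimate <- sum(w * fp$f)
  d_m_eff <- min(x$d_m, d_0)
  eps <- error_bound(estimate, fp$f, r, p, d_m_eff)
  structure(
    list(estimate = estimate, max_error = eps, f = fp$f, w = w,
         settings = list(p = p, d_0 = d_0, d_m = x$d_m, r = r),
         m = x$m, m_i = x$m_i),
    class = "pof")
}

#' @export
print.pof <- function(x, digits = 6, ...) {
  s <- x$settings
  cat("Probability of failure (truncated inclusion-exclusion estimate)\n")
  cat(sprintf("  F~ = %.*g   (d_m = %d, d_0 = %d, p = %g, r = %d)\n",
              digits, x$estimate, s$d_m, s$d_0, s$p, s$r))
  cat(sprintf("  worst-case truncation error <= %.*g\n", digits, x$max_error))
  cat(sprintf("  true PoF in [%.*g, %.*g]\n", digits, x$estimate,
              digits, x$estimate + x$max_error))
  invisible(x)
}

#' @export
summary.pof <- function(object, ...) {
  s <- object$settings
  tab <- data.frame(d = seq_along(object$f),
                    weight = object$w,
                    failure_frequency = object$f,
                    contribution = object$w * object$f)
  out <- list(table = tab, estimate = object$estimate,
              max_error = object$max_error, settings = s,
              m = object$m, m_i = object$m_i)
  class(out) <- "summary.pof"
  out
}

#' @export
print.summary.pof <- function(x, digits = 6, ...) {
  cat("PoF estimate", format(x$estimate, digits = digits),
      "+ at most", format(x$max_error, digits = digits), "\n")
  cat("cut sets: m =", x$m, "(",
      paste0("m_", seq_along(x$m_i), "=", x$m_i, collapse = ", "), ")\n\n")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}
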