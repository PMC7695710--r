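# Dense bounded-variable two-phase primal simplex.
#
# Solves  max c'x  s.t.  A x = b,  l <= x <= u  with all bounds finite,
# which is the shape of every flux-balance problem in this package
# (steady state S v = 0 plus box constraints on fluxes). Bland's rule is
# used for both the entering and the leaving variable, so the method
# cannot cycle; the basis inverse is recomputed from scratch at every
# iteration, trading speed for numerical robustness, which is the right
# trade at the problem sizes handled here (tens of reactions).

lp_solve <- function(A, b, cc, lb, ub, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(cc) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite bounds on all variables")
  if (any(ub < lb)) return(list(status = "infeasible"))
  if (m == 0L) {
    x <- ifelse(cc > 0, ub, lb)
    return(list(status = "optimal", value = sum(cc * x), x = x))
  }
  scale <- max(abs(A), abs(b), 1)
  tolx <- tol * scale

  # structural variables start nonbasic at the bound nearest zero
  at_upper <- abs(lb) > abs(ub)
  x <- ifelse(at_upper, ub, lb)
  r <- b - as.vector(A %*% x)

  # one artificial per row: column sign(r_i) * e_i, value |r_i|
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, abs(r))
  xe <- c(x, abs(r))
  upe <- c(at_upper, rep(TRUE, m))
  basis <- n + seq_len(m)

  run <- function(obj, basis, xe, upe, ube, art_can_enter) {
    for (it in seq_len(max_iter)) {
      B <- Aext[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(n + m), basis)
      cand <- if (art_can_enter) nonbasic else nonbasic[nonbasic <= n]
      piv <- as.vector(crossprod(Binv, obj[basis]))
      rc <- obj[cand] - as.vector(crossprod(Aext[, cand, drop = FALSE], piv))
      fav <- (!upe[cand] & rc > tolx) | (upe[cand] & rc < -tolx)
      if (!any(fav))
        return(list(status = "optimal", basis = basis, xe = xe, upe = upe))
      j <- cand[fav][1L]                       # Bland: smallest index enters
      dir <- if (upe[j]) -1 else 1
      dB <- -dir * as.vector(Binv %*% Aext[, j])
      xB <- xe[basis]
      # ratio test; the entering variable's own bound flip is a candidate too
      best_t <- ube[j] - lbe[j]
      best_k <- 0L
      best_up <- FALSE
      best_idx <- j
      for (k in seq_len(m)) {
        if (dB[k] > tol) {
          tk <- (ube[basis[k]] - xB[k]) / dB[k]
          up <- TRUE
        } else if (dB[k] < -tol) {
          tk <- (lbe[basis[k]] - xB[k]) / dB[k]
          up <- FALSE
        } else next
        if (tk < 0) tk <- 0
        if (tk < best_t - tolx ||
            (tk < best_t + tolx && basis[k] < best_idx)) {
          if (tk < best_t) best_t <- tk
          best_k <- k
          best_up <- up
          best_idx <- basis[k]
        }
      }
      if (best_t < 0) best_t <- 0
      xe[basis] <- xB + best_t * dB
      xe[j] <- xe[j] + dir * best_t
      if (best_k == 0L) {
        upe[j] <- !upe[j]                      # pure bound flip
      } else {
        lv <- basis[best_k]
        xe[lv] <- if (best_up) ube[lv] else lbe[lv]
        upe[lv] <- best_up
        basis[best_k] <- j
      }
    }
    list(status = "maxiter")
  }

  # phase 1: drive the artificials to zero
  obj1 <- c(rep(0, n), rep(-1, m))
  r1 <- run(obj1, basis, xe, upe, ube, art_can_enter = TRUE)
  if (r1$status != "optimal") return(list(status = r1$status))
  if (sum(r1$xe[n + seq_len(m)]) > 1e-7 * scale)
    return(list(status = "infeasible"))

  # phase 2: artificials pinned at zero and barred from re-entering
  ube2 <- ube
  ube2[n + seq_len(m)] <- 0
  xe2 <- r1$xe
  xe2[n + seq_len(m)] <- 0
  obj2 <- c(cc, rep(0, m))
  r2 <- run(obj2, r1$basis, xe2, r1$upe, ube2, art_can_enter = FALSE)
  if (r2$status != "optimal") return(list(status = r2$status))
  x <- r2$xe[seq_len(n)]
  list(status = "optimal", value = sum(cc * x), x = x)
}
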