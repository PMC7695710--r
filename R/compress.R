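# orthonormal basis of the right nullspace of A (flux modes of S)
right_nullspace <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  s <- svd(A, nu = 0, nv = ncol(A))
  rank <- sum(s$d > tol * max(s$d, 1))
  if (rank == ncol(A)) return(matrix(0, ncol(A), 0))
  s$v[, seq(rank + 1, ncol(A)), drop = FALSE]
}

#' Linear compression of a stoichiometric model
#'
#' Reactions whose steady-state fluxes are fully coupled -- forced to a
#' fixed ratio in every flux distribution, as in an unbranched chain or an
#' enzyme subset -- carry no independent failure information: deleting any
#' one of them silences all. They are merged into single lumped reactions
#' whose weight is the number of original reactions they absorb, shrinking
#' both the network and its cut set list without changing the PoF.
#'
#' Full coupling is detected on the nullspace of the stoichiometric
#' matrix: two reactions are coupled iff their nullspace rows are
#' proportional. The model must be consistent (no blocked reactions, see
#' [make_consistent()]) -- a blocked reaction has a zero nullspace row and
#' is reported as an error. The biomass reaction is exempt from
#' compression.
#'
#' @param model a consistent [stoich_model()] (medium already applied).
#' @param tol tolerance on flux-ratio proportionality.
#' @return list with `model` (the compressed [stoich_model()]) and `map`
#'   (a `compression_map`: fields `lumps`, lump id -> member reaction ids,
#'   and `ratios`, the fixed flux ratios relative to the first member).
#' @export
linear_compress <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "stoich_model"))
  K <- right_nullspace(model$S)
  rn <- sqrt(rowSums(K^2))
  if (any(rn < tol))
    stop("blocked reaction(s) present (",
         paste(reactions(model)[rn < tol], collapse = ", "),
         "); run make_consistent() first")
  n <- ncol(model$S)
  Rn <- K / rn   # unit rows
  grp <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (reactions(model)[i] != model$biomass) {
      for (g in seq_along(reps)) {
        j <- reps[g]
        if (reactions(model)[j] == model$biomass) next
        if (abs(sum(Rn[i, ] * Rn[j, ])) > 1 - tol) {
          grp[i] <- g
          assigned <- TRUE
          break
        }
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      grp[i] <- length(reps)
    }
  }
  ids <- reactions(model)
  lumps <- list()
  ratios <- list()
  cols <- NULL
  lb <- ub <- numeric(0)
  lump_names <- character(0)
  n_multi <- 0L
  for (g in seq_along(reps)) {
    members <- which(grp == g)
    first <- members[1L]
    rho <- vapply(members, function(i) {
      sgn <- if (sum(Rn[i, ] * Rn[first, ]) >= 0) 1 else -1
      sgn * rn[i] / rn[first]
    }, 0)
    if (length(members) > 1L) {
      n_multi <- n_multi + 1L
      id <- sprintf("LMP_%03d", n_multi)
    } else id <- ids[first]
    lump_names <- c(lump_names, id)
    lumps[[id]] <- ids[members]
    ratios[[id]] <- rho
    cols <- cbind(cols, as.vector(model$S[, members, drop = FALSE] %*% rho))
    lo <- -Inf
    hi <- Inf
    for (k in seq_along(members)) {
      i <- members[k]
      if (rho[k] > 0) {
        lo <- max(lo, model$lb[i] / rho[k])
        hi <- min(hi, model$ub[i] / rho[k])
      } else {
        lo <- max(lo, model$ub[i] / rho[k])
        hi <- min(hi, model$lb[i] / rho[k])
      }
    }
    lb <- c(lb, lo)
    ub <- c(ub, hi)
  }
  dimnames(cols) <- list(rownames(model$S), lump_names)
  cols[abs(cols) < tol] <- 0
  cols <- cols[rowSums(cols != 0) > 0, , drop = FALSE]
  cmodel <- stoich_model(cols, lb, ub, biomass = model$biomass)
  map <- structure(list(lumps = lumps, ratios = ratios),
                   class = "compression_map")
  list(model = cmodel, map = map)
}

#' @export
print.compression_map <- function(x, ...) {
  multi <- lengths(x$lumps) > 1L
  cat("Compression map:", length(x$lumps), "lumps,",
      sum(multi), "with > 1 member\n")
  for (id in names(x$lumps)[multi])
    cat("  ", id, "<-", paste(x$lumps[[id]], collapse = " + "), "\n")
  invisible(x)
}

#' Serialize a compression map
#'
#' Three-column TSV: lump id, member reaction id, flux ratio relative to
#' the lump's first member.
#'
#' @param map a `compression_map` from [linear_compress()].
#' @param path file to write or read.
#' @return `write_compression_map()`: `path`; `read_compression_map()`:
#'   a `compression_map`.
#' @export
write_compression_map <- function(map, path) {
  lines <- c("# lump\tmember\tratio")
  for (id in names(map$lumps))
    lines <- c(lines, sprintf("%s\t%s\t%.12g", id, map$lumps[[id]],
                              map$ratios[[id]]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_compression_map
#' @export
read_compression_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#",
                           col.names = c("lump", "member", "ratio"),
                           colClasses = c("character", "character", "numeric"))
  ids <- unique(tab$lump)
  structure(list(
    lumps = lapply(stats::setNames(ids, ids),
                   function(id) tab$member[tab$lump == id]),
    ratios = lapply(stats::setNames(ids, ids),
                    function(id) tab$ratio[tab$lump == id])),
    class = "compression_map")
}

#' Rewrite cut sets over compressed reaction groups
#'
#' Translates an uncompressed MCS collection into the lump space of a
#' [linear_compress()] map: the `w` single-member cut sets of a chain
#' collapse into one weighted cut set, and in general each cut set maps to
#' the set of lumps its members belong to. The mapping is validated: an
#' original cut set may touch each lump at most once (two members in one
#' lump would make it non-minimal), and every combination of one member
#' per lump of a compressed cut set must be present in the original
#' collection -- otherwise the collection and the map disagree.
#'
#' @param x an uncompressed [mcs_collection()].
#' @param map a `compression_map`.
#' @return a weighted [mcs_collection()] over lump ids, with
#'   `n_reactions` and `d_m` unchanged. `decompress(compress_mcs(x, map),
#'   map)` reproduces `x`.
#' @export
compress_mcs <- function(x, map) {
  stopifnot(inherits(x, "mcs_collection"))
  if (inherits(map, "compression_map")) {
    lumps <- map$lumps
  } else lumps <- map
  if (any(x$weights > 1L))
    stop("collection is already compressed")
  member2lump <- rep(names(lumps), lengths(lumps))
  names(member2lump) <- unlist(lumps)
  mapped <- vector("list", x$m)
  for (i in seq_len(x$m)) {
    s <- x$mcs[[i]]
    unknown <- setdiff(s, names(member2lump))
    if (length(unknown))
      stop("reaction(s) not covered by the compression map: ",
           paste(unknown, collapse = ", "))
    ls <- member2lump[s]
    if (anyDuplicated(ls))
      stop("cut set ", i, " hits lump '", ls[duplicated(ls)][1L],
           "' more than once; inconsistent with full coupling")
    mapped[[i]] <- sort(unname(ls), method = "radix")
  }
  key <- vapply(mapped, paste, "", collapse = "\r")
  counts <- table(key)
  uniq <- mapped[!duplicated(key)]
  wts <- lengths(lumps)
  for (s in uniq) {
    expect <- prod(wts[s])
    got <- counts[[paste(s, collapse = "\r")]]
    if (got != expect)
      stop("cut sets straddle lump(s) {", paste(s, collapse = ", "),
           "} inconsistently: expected ", expect,
           " original cut set(s), found ", got)
  }
  mcs_collection(uniq, n_reactions = x$n_reactions, d_m = x$d_m,
                 weights = wts[unique(unlist(uniq))])
}
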