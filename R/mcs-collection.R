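#' Minimal cut set collections
#'
#' An `mcs_collection` holds the minimal cut sets (MCSs) of a metabolic
#' network that are known up to some cardinality `d_m`, together with the
#' total number of reactions `n_reactions` in the (uncompressed) network.
#' An MCS is a minimal set of reaction deletions that abolishes growth:
#' essential reactions are MCSs of cardinality 1, synthetic lethal pairs of
#' cardinality 2, and so on.
#'
#' Cut sets may be expressed over *reaction groups* rather than single
#' reactions when the network has been linearly compressed (see
#' [linear_compress()]): a group of weight `w` stands for `w` fully coupled
#' reactions, any one of which disables the whole group. One deletion per
#' group therefore suffices, so a cut set's cardinality -- the quantity
#' bounded by `d_m` and tallied in `m_i` -- is its group count, while
#' [mcs_cardinality()] reports the number of original reactions it spans
#' (the weight sum). The two coincide at unit weights.
#'
#' @param mcs list of character vectors, each a set of group (reaction) ids.
#' @param n_reactions total number of reactions in the uncompressed network.
#' @param d_m cardinality up to which the listed MCSs are complete.
#' @param weights named integer vector of group weights; ids missing from it
#'   get weight 1. `NULL` means all weights are 1.
#' @param minimize if `TRUE`, raw cut sets are accepted and reduced to their
#'   minimal elements (with a message); if `FALSE` (default), a cut set that
#'   is a superset of another is an error, since the inclusion-exclusion
#'   theory presumes minimality.
#'
#' @return An object of class `mcs_collection` with fields `mcs`, `weights`,
#'   `n_reactions`, `d_m`, and the derived counts `m` (total) and `m_i`
#'   (MCSs per original cardinality `1..d_m`).
#' @seealso [read_mcs()], [write_mcs()], [decompress()], [pof()]
#' @examples
#' mcs_collection(list("r6", c("r1", "r2"), c("r4", "r5"),
#'                     c("r1", "r3", "r5"), c("r2", "r3", "r4")),
#'                n_reactions = 6, d_m = 3)
#' @export
mcs_collection <- function(mcs, n_reactions, d_m, weights = NULL,
                           minimize = FALSE) {
  stopifnot(is.list(mcs))
  if (length(mcs)) {
    mcs <- lapply(mcs, function(s) sort(as.character(s), method = "radix"))
    dup <- vapply(mcs, anyDuplicated, 0L) > 0L
    if (any(dup))
      stop("duplicate reaction id within cut set(s) ",
           paste(which(dup), collapse = ", "))
    if (any(lengths(mcs) == 0L)) stop("empty cut set")
  }
  all_ids <- unlist(mcs)
  ids <- if (is.null(all_ids)) character(0)
  else sort(unique(all_ids), method = "radix")
  w <- rep(1L, length(ids))
  names(w) <- ids
  if (!is.null(weights)) {
    if (is.null(names(weights)) && length(weights) > 0)
      stop("'weights' must be named by group id")
    weights <- weights[names(weights) %in% ids]
    w[names(weights)] <- as.integer(weights)
  }
  if (any(w < 1L)) stop("group weights must be >= 1")
  n_reactions <- as.integer(n_reactions)
  d_m <- as.integer(d_m)
  if (n_reactions < 1L) stop("'n_reactions' must be a positive integer")
  if (d_m < 1L) stop("'d_m' must be a positive integer")
  if (sum(w) > n_reactions)
    stop("group weights sum to more than 'n_reactions'")

  if (minimize && length(mcs) > 1L) {
    keep <- minimal_sets(mcs)
    if (!all(keep)) {
      message("dropped ", sum(!keep), " non-minimal cut set(s)")
      mcs <- mcs[keep]
    }
    mcs <- unique(mcs)
  } else if (length(mcs) > 1L) {
    if (anyDuplicated(vapply(mcs, paste, "", collapse = "\r")))
      stop("duplicate cut sets in collection")
    keep <- minimal_sets(mcs)
    if (!all(keep)) {
      bad <- which(!keep)[1L]
      over <- which(vapply(mcs, function(s)
        !identical(s, mcs[[bad]]) && all(s %in% mcs[[bad]]), TRUE))[1L]
      stop("cut set ", bad, " is a superset of cut set ", over,
           "; not minimal (use minimize = TRUE to reduce raw cut sets)")
    }
  }

  # cardinality of a cut set in original-reaction space: one deletion per
  # group suffices (any member silences a fully coupled lump), so it is the
  # group count -- which coincides with the reaction count at unit weights
  card <- lengths(mcs)
  if (any(card > d_m))
    stop("cut set(s) with cardinality above 'd_m'")

  structure(
    list(mcs = mcs, weights = w, n_reactions = n_reactions, d_m = d_m,
         m = length(mcs),
         m_i = vapply(seq_len(d_m), function(i) sum(card == i), 0L)),
    class = "mcs_collection")
}

# which sets in a list are minimal (not a strict superset of another)
minimal_sets <- function(sets) {
  n <- length(sets)
  keep <- rep(TRUE, n)
  ord <- order(lengths(sets))
  for (a in seq_len(n)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_len(n)) {
      j <- ord[b]
      if (i == j || !keep[j]) next
      if (length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]]))
        keep[j] <- FALSE
      else if (length(sets[[i]]) == length(sets[[j]]) && j != i &&
               identical(sets[[i]], sets[[j]]) && a < b)
        keep[j] <- FALSE
    }
  }
  keep
}

#' @export
print.mcs_collection <- function(x, ...) {
  cat("Minimal cut set collection\n")
  cat("  reactions (r):", x$n_reactions, "\n")
  cat("  complete up to cardinality (d_m):", x$d_m, "\n")
  cat("  cut sets (m):", x$m,
      if (x$m) paste0("[", paste0("m_", seq_along(x$m_i), "=", x$m_i,
                                  collapse = ", "), "]"),
      "\n")
  if (any(x$weights > 1L))
    cat("  compressed groups with weight > 1:", sum(x$weights > 1L), "\n")
  invisible(x)
}

#' Original reactions spanned by each cut set
#'
#' Sum of group weights per cut set: how many original reactions the set
#' covers once lumps are expanded. Equals the cut set cardinality for
#' uncompressed collections.
#'
#' @param x an [mcs_collection()].
#' @return integer vector of length `x$m`.
#' @export
mcs_cardinality <- function(x) {
  stopifnot(inherits(x, "mcs_collection"))
  vapply(x$mcs, function(s) sum(x$weights[s]), 0)
}

#' Read a minimal cut set file
#'
#' The plain-text format is one cut set per line, tokens separated by
#' whitespace, each token `id` or `id:weight` (weight only written when it
#' exceeds 1). The first line is a header `#r=<int> dm=<int>` declaring the
#' network's reaction count and the completeness bound.
#'
#' @param path file to read.
#' @param minimize passed to [mcs_collection()]: accept raw (non-minimal)
#'   cut sets and reduce them.
#' @return an [mcs_collection()].
#' @export
read_mcs <- function(path, minimize = FALSE) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#r=[0-9]+ dm=[0-9]+$", lines[1L]))
    stop("line 1: expected header '#r=<int> dm=<int>' in ", path)
  hdr <- regmatches(lines[1L], regexec("^#r=([0-9]+) dm=([0-9]+)$", lines[1L]))[[1L]]
  r <- as.integer(hdr[2L])
  d_m <- as.integer(hdr[3L])
  body <- lines[-1L]
  keep <- !grepl("^\\s*(#.*)?$", body)
  sets <- list()
  weights <- integer()
  for (i in which(keep)) {
    toks <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    ok <- grepl("^[^\\s:]+(:[0-9]+)?$", toks)
    if (!all(ok))
      stop("line ", i + 1L, ": malformed token '", toks[!ok][1L], "'")
    ids <- sub(":[0-9]+$", "", toks)
    if (anyDuplicated(ids))
      stop("line ", i + 1L, ": duplicate reaction id '",
           ids[duplicated(ids)][1L], "'")
    wt <- rep(1L, length(toks))
    has_w <- grepl(":", toks, fixed = TRUE)
    wt[has_w] <- as.integer(sub("^.*:", "", toks[has_w]))
    names(wt) <- ids
    for (id in names(wt)) {
      if (id %in% names(weights) && weights[[id]] != wt[[id]])
        stop("line ", i + 1L, ": weight of '", id,
             "' conflicts with an earlier line")
    }
    weights <- c(weights, wt[!(names(wt) %in% names(weights))])
    sets[[length(sets) + 1L]] <- ids
  }
  coll <- tryCatch(
    mcs_collection(sets, n_reactions = r, d_m = d_m, weights = weights,
                   minimize = minimize),
    error = function(e) {
      msg <- conditionMessage(e)
      hit <- regmatches(msg, regexec("cut set ([0-9]+) is a superset of cut set ([0-9]+)", msg))[[1L]]
      if (length(hit)) {
        ln <- which(keep)[as.integer(hit[2:3])] + 1L
        stop("line ", ln[1L], ": cut set is a superset of the cut set on line ",
             ln[2L], call. = FALSE)
      }
      stop(msg, call. = FALSE)
    })
  coll
}

#' Write a minimal cut set file
#'
#' Inverse of [read_mcs()]; `read_mcs(write_mcs(x, path))` reproduces `x`.
#' Output is deterministic: cut sets are ordered by original cardinality,
#' then lexicographically, so files are diffable.
#'
#' @param x an [mcs_collection()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_mcs <- function(x, path) {
  stopifnot(inherits(x, "mcs_collection"))
  fmt <- vapply(x$mcs, function(s) {
    w <- x$weights[s]
    paste(ifelse(w > 1L, paste0(s, ":", w), s), collapse = " ")
  }, "")
  ord <- order(mcs_cardinality(x), fmt, method = "radix")
  writeLines(c(sprintf("#r=%d dm=%d", x$n_reactions, x$d_m), fmt[ord]), path)
  invisible(path)
}

#' Expand a compressed cut set collection back to single reactions
#'
#' A group (lump) of weight `w` stands for a chain of `w` fully coupled
#' reactions: deleting any one member stops flux through all of them. A
#' compressed MCS over lumps therefore expands to all combinations of one
#' member per lump. The expansion is minimized (subset-dominated sets are
#' dropped) and all weights in the result are 1.
#'
#' @param x an [mcs_collection()].
#' @param map named list: group id -> character vector of member reaction
#'   ids (a [linear_compress()] map's `lumps` field). If `NULL`, synthetic
#'   member names `<id>` (weight 1) or `<id>#1 .. <id>#w` are used.
#' @param n_reactions reaction count of the expanded collection; defaults
#'   to `x$n_reactions`, but must be supplied when `x` came from
#'   enumerating a compressed model (where the count is in lump units).
#' @return an uncompressed [mcs_collection()].
#' @export
decompress <- function(x, map = NULL, n_reactions = x$n_reactions) {
  stopifnot(inherits(x, "mcs_collection"))
  if (inherits(map, "compression_map")) map <- map$lumps
  if (is.null(map)) {
    map <- lapply(names(x$weights), function(id) {
      w <- x$weights[[id]]
      if (w == 1L) id else paste0(id, "#", seq_len(w))
    })
    names(map) <- names(x$weights)
  }
  missing_ids <- setdiff(names(x$weights), names(map))
  if (length(missing_ids))
    stop("group id(s) not in compression map: ",
         paste(missing_ids, collapse = ", "))
  # a collection carrying explicit weights must agree with the map; one
  # produced over lump labels without weights (e.g. by enumerating the
  # compressed model) is expanded by the map alone
  if (any(x$weights > 1L)) {
    bad_w <- names(x$weights)[lengths(map[names(x$weights)]) != x$weights]
    if (length(bad_w))
      stop("map size disagrees with group weight for: ",
           paste(bad_w, collapse = ", "))
  }
  expanded <- list()
  for (s in x$mcs) {
    combos <- expand.grid(map[s], stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    for (k in seq_len(nrow(combos)))
      expanded[[length(expanded) + 1L]] <- unlist(combos[k, ], use.names = FALSE)
  }
  expanded <- unique(lapply(expanded, sort, method = "radix"))
  if (length(expanded) > 1L) expanded <- expanded[minimal_sets(expanded)]
  mcs_collection(expanded, n_reactions = n_reactions, d_m = x$d_m)
}
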