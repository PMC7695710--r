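# Seeded "chain of chains" model: serial segments that are either an
# unbranched chain (lumpable by linear compression) or a pair of parallel
# routes (not lumpable), closed by a biomass drain. MCSs are any single
# reaction of a chain segment and the route pairs of parallel segments
# (plus the biomass reaction itself).
random_chain_network <- function(seed, n_segments = NULL) {
  pofkit:::with_seed(seed, {
    if (is.null(n_segments)) n_segments <- sample(2:3, 1)
    kinds <- sample(c("chain", "parallel"), n_segments, replace = TRUE)
    lens <- ifelse(kinds == "chain", sample(1:3, n_segments, replace = TRUE), 1)
    mets <- character(0)
    cols <- list()
    prev <- NULL   # metabolite feeding the next segment (NULL = boundary)
    met_count <- 0
    for (s in seq_len(n_segments)) {
      if (kinds[s] == "chain") {
        for (k in seq_len(lens[s])) {
          met_count <- met_count + 1
          cur <- sprintf("m%d", met_count)
          mets <- c(mets, cur)
          col <- c(stats::setNames(1, cur),
                   if (!is.null(prev)) stats::setNames(-1, prev))
          cols[[sprintf("c%d_%d", s, k)]] <- col
          prev <- cur
        }
      } else {
        met_count <- met_count + 1
        cur <- sprintf("m%d", met_count)
        mets <- c(mets, cur)
        for (j in 1:2) {
          col <- c(stats::setNames(1, cur),
                   if (!is.null(prev)) stats::setNames(-1, prev))
          cols[[sprintf("p%d_%d", s, j)]] <- col
        }
        prev <- cur
      }
    }
    S <- matrix(0, length(mets), length(cols),
                dimnames = list(mets, names(cols)))
    for (rx in names(cols)) S[names(cols[[rx]]), rx] <- cols[[rx]]
    bm <- stats::setNames(numeric(length(mets)), mets)
    S <- cbind(S, BM = -as.numeric(mets == prev) )
    model <- stoich_model(S, rep(0, ncol(S)), rep(10, ncol(S)),
                          biomass = "BM")
    sources <- colnames(S)[colSums(S != 0) == 1 & colnames(S) != "BM"]
    medium <- stats::setNames(rep(10, length(sources)), sources)
    stopifnot(growth_test(model, medium))
    list(model = model, medium = medium)
  })
}
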