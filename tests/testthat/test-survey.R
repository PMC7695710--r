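test_that("network similarity follows the squared-overlap formula", {
  s <- network_similarity(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(s$sigma, 1)
  expect_equal(s$dissimilarity, 0)
  expect_equal(network_similarity(c("a", "b"), c("x", "y"))$sigma, 0)
  expect_equal(network_similarity(letters[1:4],
                                  c("a", "b", "v", "w", "x"))$sigma,
               2^2 / (4 * 5))
  expect_error(network_similarity(character(0), "a"), "non-empty")
})

test_that("shared reactome reports intersection, union and fraction", {
  one <- shared_reactome(list(c("a", "b")))
  expect_equal(one$fraction, 1)
  two <- shared_reactome(list(c("a", "b"), c("x", "y")))
  expect_equal(two$fraction, 0)
  three <- shared_reactome(list(c("a", "b", "c", "d"),
                                c("a", "b", "c", "e"),
                                c("a", "b", "f")))
  expect_setequal(three$shared, c("a", "b"))
  expect_equal(three$n_shared, 2)
  expect_equal(three$n_union, 6)
  expect_equal(three$fraction, 2 / 6)
  expect_error(shared_reactome(list()), "empty")
  # models are accepted directly
  net <- toy_network()
  expect_equal(shared_reactome(list(net$model, net$model))$fraction, 1)
})

test_that("carbon scans match direct per-source PoF calls", {
  net <- toy_network()
  tab <- carbon_source_scan(net$model, c(), c(r1 = 10, r2 = 10),
                            d_m = 3, p = 0.1, d_0 = 6)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$growth))
  for (i in 1:2) {
    src <- tab$source[i]
    med <- stats::setNames(10, src)
    coll <- enumerate_mcs(net$model, med, d_m = 3)
    direct <- pof(coll, p = 0.1, d_0 = 6)
    expect_equal(tab$estimate[i], direct$estimate)
    expect_equal(tab$max_error[i], direct$max_error)
    expect_equal(unlist(tab[i, paste0("m_", 1:3)], use.names = FALSE),
                 as.numeric(coll$m_i))
  }
  # both inlets usable as alternatives buffer each other: the PoF on the
  # full medium is lower than on either single source
  both <- pof(enumerate_mcs(net$model, net$medium, d_m = 3),
              p = 0.1, d_0 = 6)
  expect_true(all(both$estimate < tab$estimate))
})

test_that("non-growth-supporting sources are flagged without a PoF", {
  net <- toy_network()
  # r2 alone cannot feed the network if the A branch is removed... use a
  # model where one inlet is disconnected: drop r3 and r5 so B is a dead end
  m <- net$model
  keep <- setdiff(colnames(m$S), c("r3", "r5"))
  m2 <- stoich_model(m$S[, keep], m$lb[keep], m$ub[keep], biomass = "r6",
                     exchanges = c("r1", "r2"))
  tab <- carbon_source_scan(m2, c(), c(r1 = 10, r2 = 10),
                            d_m = 2, p = 0.1, d_0 = 4)
  expect_true(tab$growth[tab$source == "r1"])
  expect_false(tab$growth[tab$source == "r2"])
  expect_true(is.na(tab$estimate[tab$source == "r2"]))
})

test_that("more parallel routes on a substrate mean a lower PoF", {
  # substrate A reaches biomass through one route, substrate B through two
  S <- matrix(0, 4, 6,
              dimnames = list(c("A", "B", "P", "Q"),
                              c("upA", "upB", "a1", "b1", "b2", "bm")))
  S["A", "upA"] <- 1
  S["B", "upB"] <- 1
  S["A", "a1"] <- -1; S["P", "a1"] <- 1
  S["B", "b1"] <- -1; S["P", "b1"] <- 1
  S["B", "b2"] <- -1; S["P", "b2"] <- 1
  S["P", "bm"] <- -1
  S <- S[c("A", "B", "P"), ]
  m <- stoich_model(S, rep(0, 6), rep(10, 6), biomass = "bm")
  tab <- carbon_source_scan(m, c(), c(upA = 10, upB = 10),
                            d_m = 3, p = 1e-2, d_0 = 5)
  expect_lt(tab$estimate[tab$source == "upB"],
            tab$estimate[tab$source == "upA"])
})

test_that("nested cut set collections give monotone estimates", {
  # opening extra growth-supporting routes can only remove cut sets /
  # enlarge them; with nested collections the estimate never increases
  for (seed in c(4, 13)) {
    coll <- acceptance_instance(seed)
    r <- coll$n_reactions
    sub <- mcs_collection(coll$mcs[seq_len(max(1, coll$m - 2))],
                          n_reactions = r, d_m = coll$d_m,
                          minimize = TRUE)
    expect_lte(pof(sub, p = 1e-3, d_0 = r)$estimate,
               pof(coll, p = 1e-3, d_0 = r)$estimate + 1e-15)
  }
})

test_that("PoF differences are bounded by the next-cardinality layer", {
  # two collections equal up to cardinality k differ at most by the total
  # probability that a deletion set covers some cardinality-(k+1) set
  for (seed in c(7, 13, 22)) {
    coll <- acceptance_instance(seed)
    if (coll$m_i[1] == 0 || sum(coll$m_i[-1]) == 0) next
    r <- coll$n_reactions
    k <- 1
    base <- mcs_collection(coll$mcs[lengths(coll$mcs) <= k],
                           n_reactions = r, d_m = k)
    p <- 1e-3
    delta <- pof(coll, p = p, d_0 = r)$estimate -
      pof(base, p = p, d_0 = r)$estimate
    higher <- lengths(coll$mcs)[lengths(coll$mcs) > k]
    cap <- sum(p^higher)   # union bound on the added lethal coverage
    expect_gte(delta, -1e-15)
    expect_lte(delta, cap + 1e-15)
  }
})
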