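toy <- mcs_collection(list("r6", c("r1", "r2"), c("r4", "r5"),
                           c("r1", "r3", "r5"), c("r2", "r3", "r4")),
                      n_reactions = 6, d_m = 3)

test_that("binomial weights match the closed form and normalize", {
  expect_equal(binomial_weight(6, 0.1, 0), 0.9^6)
  expect_equal(sum(binomial_weight(50, 0.37, 0:50)), 1, tolerance = 1e-12)
  # large-r evaluation agrees with the log-space closed form
  expect_equal(binomial_weight(3000, 1e-4, 1),
               exp(log(3000) + log(1e-4) + 2999 * log1p(-1e-4)),
               tolerance = 1e-12)
  expect_silent(binomial_weight(1e5, 1e-4, 50))
  expect_error(binomial_weight(6, 0.1, 7), "0..r")
  expect_error(binomial_weight(6, 0.1, -1), "0..r")
})

test_that("exhaustive lethal-subset oracle reproduces the toy counts", {
  expect_equal(lethal_subset_count(toy, 3), 18)   # f_3 = 18/20 = 0.9
  expect_equal(lethal_subset_count(toy, 4), choose(6, 4))  # f_4 = 1
  empty <- mcs_collection(list(), n_reactions = 8, d_m = 3)
  expect_equal(lethal_subset_count(empty, 3), 0)
  big <- mcs_collection(list("a"), n_reactions = 50, d_m = 1)
  expect_error(lethal_subset_count(big, 2), "too large")
  wtd <- mcs_collection(list("L"), n_reactions = 5, d_m = 2,
                        weights = c(L = 2L))
  expect_error(lethal_subset_count(wtd, 2), "uncompressed")
})

test_that("the union profile of the toy collection is its printed polynomial", {
  prof <- union_profile(toy, d_0 = 6)
  expect_equal(pof_polynomial(prof), c(1, 2, 0, -7, 7, -2))
  single <- union_profile(mcs_collection(list("a"), 3, 1), d_0 = 3)
  expect_equal(unname(single$counts["1"]), 1)
  expect_length(single$counts, 1)
})

test_that("recursion with pruning+cancellation equals the full power set walk", {
  for (seed in 1:40) {
    coll <- pofkit:::with_seed(seed,
      acceptance_instance(sample.int(1000, 1)))
    full <- union_profile(coll, d_0 = Inf)
    base <- oracle_union_profile(coll)
    expect_mapequal(as.list(full$counts), as.list(base))
    # the cancellation shortcut changes nothing
    plain <- union_profile(coll, d_0 = Inf, shortcut = FALSE)
    expect_mapequal(as.list(plain$counts), as.list(full$counts))
    # truncation at d_0 equals truncating the oracle
    d0 <- coll$n_reactions %/% 2
    expect_mapequal(as.list(union_profile(coll, d_0 = d0)$counts),
                    as.list(oracle_union_profile(coll, d_0 = d0)))
  }
})

test_that("exact_pof matches its documented values", {
  p <- 0.1
  # closed form from the toy polynomial p + 2p^2 - 7p^4 + 7p^5 - 2p^6
  expect_equal(exact_pof(toy, p),
               p + 2 * p^2 - 7 * p^4 + 7 * p^5 - 2 * p^6,
               tolerance = 1e-14)
  expect_equal(exact_pof(toy, p), 0.11936, tolerance = 1e-4)
  one <- mcs_collection(list("a"), n_reactions = 4, d_m = 1)
  for (p in c(0.01, 0.3, 0.9)) expect_equal(exact_pof(one, p), p)
  pairs <- mcs_collection(list(c("a", "b"), c("c", "d")),
                          n_reactions = 4, d_m = 2)
  # two disjoint pairs: 1 - (1 - p^2)^2 = 2p^2 - p^4
  expect_equal(exact_pof(pairs, 0.1), 0.0199, tolerance = 1e-12)
  big <- mcs_collection(as.list(sprintf("e%d", 1:30)), 40, 1)
  expect_error(exact_pof(big, 0.1), "intractable")
})

test_that("failure frequencies equal exhaustive counts on the toy network", {
  prof <- union_profile(toy, d_0 = 6)
  fp <- failure_frequencies(prof, r = 6)
  expect_equal(fp$f[1], 1 / 6)
  expect_equal(fp$f[3], 0.9)
  expect_equal(fp$f[4:6], c(1, 1, 1))
  expect_equal(fp$numerator,
               oracle_lethal_counts(toy)[-1])
  expect_error(failure_frequencies(prof, r = 4), "more reactions")
})

test_that("truncated estimator: toy value, essential-only agreement, warning", {
  res <- pof(toy, p = 0.1, d_0 = 6)
  expect_equal(res$estimate, exact_pof(toy, 0.1), tolerance = 1e-14)
  expect_equal(res$estimate, 0.11936, tolerance = 1e-4)
  expect_equal(res$max_error, 0, tolerance = 1e-12)

  ess <- mcs_collection(as.list(c("a", "b", "c")), n_reactions = 9, d_m = 1)
  full <- pof(ess, p = 0.02, d_0 = 9)
  expect_equal(full$estimate, essential_only_pof(3, 0.02), tolerance = 1e-12)

  expect_warning(pof(toy, p = 0.1, d_0 = 2), "d_m")
})

test_that("essential-only closed form and its linearization", {
  expect_equal(essential_only_pof(1, 0.1), 0.1)
  expect_equal(essential_only_pof(0, 0.37), 0)
  expect_equal(essential_only_pof(298, 1e-4), 1 - (1 - 1e-4)^298,
               tolerance = 1e-12)
  expect_equal(essential_only_pof(298, 1e-4, linearized = TRUE), 0.0298)
})

test_that("error bound: empty collection closed form and sandwich", {
  empty <- mcs_collection(list(), n_reactions = 30, d_m = 3)
  res <- pof(empty, p = 0.01, d_0 = 10)
  expect_equal(res$estimate, 0)
  expect_equal(res$max_error, 1 - sum(binomial_weight(30, 0.01, 0:3)),
               tolerance = 1e-12)
  for (seed in 1:20) {
    coll <- acceptance_instance(seed)
    exact <- exact_pof(coll, 0.05)
    est <- pof(coll, p = 0.05, d_0 = 4)
    expect_lte(est$estimate, exact + 1e-12)
    expect_gte(est$estimate + est$max_error, exact - 1e-12)
    expect_lte(est$estimate + est$max_error, 1 + 1e-12)
  }
})

test_that("estimate is monotone in p, d_0 and added cut sets", {
  coll <- acceptance_instance(17)
  r <- coll$n_reactions
  est <- function(coll, p, d0) pof(coll, p = p, d_0 = d0)$estimate
  vals_p <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 0.3), est, 0,
                   coll = coll, d0 = r)
  expect_true(all(diff(vals_p) > 0))
  vals_d0 <- vapply(coll$d_m:r, est, 0, coll = coll, p = 0.05)
  expect_true(all(diff(vals_d0) >= -1e-15))
  # adding a fresh, non-superset cut set can only raise the estimate
  grown <- mcs_collection(c(coll$mcs, list(c("Z1", "Z2"))),
                          n_reactions = r + 2, d_m = coll$d_m)
  base <- mcs_collection(coll$mcs, n_reactions = r + 2, d_m = coll$d_m)
  expect_gt(est(grown, 0.05, r), est(base, 0.05, r))
})

test_that("truncated frequencies never exceed the full ones", {
  for (seed in c(3, 9, 23)) {
    coll <- acceptance_instance(seed)
    r <- coll$n_reactions
    f_full <- failure_frequencies(union_profile(coll, d_0 = r), r = r)$f
    for (dm in 1:2) {
      sub <- mcs_collection(coll$mcs[mcs_cardinality(coll) <= dm],
                            n_reactions = r, d_m = dm)
      f_trunc <- failure_frequencies(union_profile(sub, d_0 = r), r = r)$f
      expect_true(all(f_trunc <= f_full + 1e-12))
      expect_true(all(diff(f_trunc) >= -1e-12))
    }
  }
})

test_that("weighted collections equal their decompressed expansions", {
  for (seed in 1:15) {
    coll <- pofkit:::with_seed(seed, {
      ids <- c("La", "Lb", "Lc")
      w <- stats::setNames(sample(1:3, 3, replace = TRUE), ids)
      sets <- unique(lapply(1:3, function(i)
        sort(sample(ids, sample(1:2, 1)))))
      sets <- sets[pofkit:::minimal_sets(sets)]
      mcs_collection(sets, n_reactions = sum(w) + 1,
                     d_m = max(vapply(sets, function(s) sum(w[s]), 0)),
                     weights = w)
    })
    flat <- decompress(coll)
    for (p in c(1e-3, 0.05, 0.3))
      expect_equal(exact_pof(coll, p), exact_pof(flat, p),
                   tolerance = 1e-13)
  }
})
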