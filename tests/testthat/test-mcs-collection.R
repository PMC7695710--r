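toy_sets <- list("r6", c("r1", "r2"), c("r4", "r5"),
                 c("r1", "r3", "r5"), c("r2", "r3", "r4"))

test_that("collections validate counts, weights and minimality", {
  coll <- mcs_collection(toy_sets, n_reactions = 6, d_m = 3)
  expect_equal(coll$m, 5)
  expect_equal(coll$m_i, c(1L, 2L, 2L))
  expect_equal(unname(mcs_cardinality(coll)), c(1, 2, 2, 3, 3))

  empty <- mcs_collection(list(), n_reactions = 10, d_m = 3)
  expect_equal(empty$m, 0)

  wtd <- mcs_collection(list("a"), n_reactions = 5, d_m = 3,
                        weights = c(a = 3L))
  expect_equal(unname(mcs_cardinality(wtd)), 3)

  expect_error(mcs_collection(list(c("a", "a")), 5, 2), "duplicate")
  expect_error(mcs_collection(list("a", c("a", "b")), 5, 2), "superset")
  expect_error(mcs_collection(list(c("a", "b", "c")), 5, 2), "cardinality")
  expect_error(mcs_collection(list("a"), 5, 2, weights = c(a = 0L)),
               "weights")
  expect_error(mcs_collection(list(c("a", "b")), 1, 2), "n_reactions")
  expect_message(
    red <- mcs_collection(list("a", c("a", "b"), c("b", "c")), 5, 2,
                          minimize = TRUE),
    "non-minimal")
  expect_equal(red$m, 2)
})

test_that("the MCS text format parses the documented examples", {
  tf <- withr::local_tempfile(lines = c(
    "#r=6 dm=3", "r6", "r1 r2", "r4 r5", "r1 r3 r5", "r2 r3 r4"))
  coll <- read_mcs(tf)
  expect_equal(coll$m, 5)
  expect_equal(coll$m_i, c(1L, 2L, 2L))
  expect_equal(coll$n_reactions, 6)

  tf2 <- withr::local_tempfile(lines = "#r=10 dm=3")
  expect_equal(read_mcs(tf2)$m, 0)

  tf3 <- withr::local_tempfile(lines = c("#r=5 dm=3", "a:3"))
  coll3 <- read_mcs(tf3)
  expect_equal(coll3$m, 1)
  expect_equal(unname(mcs_cardinality(coll3)), 3)
})

test_that("parse and validation errors carry line numbers", {
  tf <- withr::local_tempfile(lines = c("#r=5 dm=3", "a b", "c:x"))
  expect_error(read_mcs(tf), "line 3.*malformed")
  tf2 <- withr::local_tempfile(lines = c("#r=5 dm=3", "a a"))
  expect_error(read_mcs(tf2), "line 2.*duplicate")
  tf3 <- withr::local_tempfile(lines = c("#r=5 dm=3", "a", "a b"))
  expect_error(read_mcs(tf3), "line 3.*superset.*line 2")
  tf4 <- withr::local_tempfile(lines = c("r=5", "a"))
  expect_error(read_mcs(tf4), "line 1.*header")
})

test_that("write/read round-trips collections bit-exactly", {
  cases <- list(
    mcs_collection(toy_sets, n_reactions = 6, d_m = 3),
    mcs_collection(list(c("L", "z"), "q"), n_reactions = 9, d_m = 4,
                   weights = c(L = 3L)),
    mcs_collection(list(), n_reactions = 10, d_m = 3))
  for (coll in cases) {
    tf <- withr::local_tempfile()
    write_mcs(coll, tf)
    back <- read_mcs(tf)
    expect_equal(back$n_reactions, coll$n_reactions)
    expect_equal(back$d_m, coll$d_m)
    expect_equal(back$weights[sort(names(back$weights))],
                 coll$weights[sort(names(coll$weights))])
    expect_setequal(set_key(back$mcs), set_key(coll$mcs))
    # deterministic output: a second write is byte-identical
    tf2 <- withr::local_tempfile()
    write_mcs(back, tf2)
    expect_identical(readLines(tf), readLines(tf2))
  }
})

test_that("decompress expands lumps by one-member-per-lump choice", {
  chain <- mcs_collection(list("L"), n_reactions = 3, d_m = 3,
                          weights = c(L = 3L))
  out <- decompress(chain, map = list(L = c("r1", "r2", "r3")))
  expect_setequal(set_key(out$mcs), c("r1", "r2", "r3"))
  expect_true(all(out$weights == 1))

  two <- mcs_collection(list(c("La", "Lb")), n_reactions = 3, d_m = 3,
                        weights = c(La = 2L, Lb = 1L))
  out2 <- decompress(two, map = list(La = c("x1", "x2"), Lb = "y1"))
  expect_setequal(set_key(out2$mcs), c("x1+y1", "x2+y1"))

  plain <- mcs_collection(toy_sets, n_reactions = 6, d_m = 3)
  out3 <- decompress(plain)
  expect_setequal(set_key(out3$mcs), set_key(plain$mcs))

  expect_error(decompress(chain, map = list(Q = "r1")), "not in")
})

test_that("decompression preserves minimality on random chain lumpings", {
  for (seed in 1:25) {
    coll <- pofkit:::with_seed(seed, {
      n_lump <- sample(2:4, 1)
      w <- sample(1:3, n_lump, replace = TRUE)
      ids <- sprintf("G%d", seq_len(n_lump))
      sets <- unique(lapply(1:4, function(i) {
        k <- sample(seq_len(n_lump), sample(1:2, 1))
        sort(ids[k])
      }))
      sets <- sets[minimal_ok <- pofkit:::minimal_sets(sets)]
      mcs_collection(sets, n_reactions = sum(w) + 2,
                     d_m = max(vapply(sets, function(s)
                       sum(w[match(s, ids)]), 0)),
                     weights = stats::setNames(as.integer(w), ids))
    })
    out <- decompress(coll)
    # constructor validates minimality; reaching here means it held
    expect_s3_class(out, "mcs_collection")
    expect_true(all(out$weights == 1))
  }
})
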