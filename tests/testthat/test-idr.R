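test_that("binarize_track run-length encodes, keeping length-1 IDRs", {
  i1 <- binarize_track(c(0, 1, 1, 0, 1))
  expect_equal(i1$start, c(2L, 5L))
  expect_equal(i1$end, c(3L, 5L))

  i2 <- binarize_track(c(0.4, 0.6, 0.5), threshold = 0.5)  # >= threshold
  expect_equal(i2$start, 2L)
  expect_equal(i2$end, 3L)

  i0 <- binarize_track(c(0, 0, 0, 0))
  expect_length(i0$start, 0L)
  expect_equal(disorder_fraction(i0), 0)
})

test_that("interval normalization merges overlaps and adjacency", {
  a <- idr_set("P", c(1, 4), c(5, 8), 10)
  expect_equal(a$start, 1L)
  expect_equal(a$end, 8L)
  b <- idr_set("P", c(1, 3), c(2, 4), 10)  # adjacent merge
  expect_equal(b$start, 1L)
  expect_equal(b$end, 4L)
  expect_error(idr_set("P", 2, 12, 10), "beyond protein length")
})

test_that("combine_union merges at residue level and joins labels", {
  u <- combine_union(idr_set("P", 1, 5, 20, "VSL2b"),
                     idr_set("P", 4, 8, 20, "IUPred-L"))
  expect_equal(u$start, 1L)
  expect_equal(u$end, 8L)
  expect_equal(u$caller, "VSL2b_IUPred-L")
  # identity with the empty set
  x <- idr_set("P", c(2, 9), c(4, 9), 20)
  e <- idr_set("P", length = 20)
  xe <- combine_union(x, e)
  expect_equal(xe$start, x$start)
  expect_equal(xe$end, x$end)
  expect_error(combine_union(x, idr_set("Q", length = 20)),
               "accession mismatch")
})

test_that("union algebra laws hold and match the IRanges oracle", {
  skip_if_not_installed("IRanges")
  set.seed(404)
  for (rep in 1:100) {
    L <- sample(20:80, 1L)
    a <- random_idr_set(L); b <- random_idr_set(L); c <- random_idr_set(L)
    ab <- combine_union(a, b); ba <- combine_union(b, a)
    expect_equal(ab$start, ba$start)
    expect_equal(ab$end, ba$end)
    abc1 <- combine_union(ab, c)
    abc2 <- combine_union(a, combine_union(b, c))
    expect_equal(abc1$start, abc2$start)
    expect_equal(abc1$end, abc2$end)
    aa <- combine_union(a, a)
    expect_equal(aa$start, a$start)
    expect_equal(aa$end, a$end)
    # independent oracle: IRanges reduce of the pooled intervals
    ir <- IRanges::reduce(IRanges::IRanges(
      start = c(a$start, b$start), end = c(a$end, b$end)))
    expect_equal(ab$start, IRanges::start(ir))
    expect_equal(ab$end, IRanges::end(ir))
    # round trip through the binary mask
    rt <- binarize_track(as.numeric(idr_mask(a)), a$accession, a$caller)
    expect_equal(rt$start, a$start)
    expect_equal(rt$end, a$end)
  }
})

test_that("quorum consensus counts callers with an inclusive threshold", {
  L <- 10L
  mk <- function(on) idr_set("P", if (on) 5 else integer(0),
                             if (on) 5 else integer(0), L)
  sets7 <- lapply(rep(c(TRUE, FALSE), c(7, 2)), mk)   # 7 of 9 call residue 5
  expect_true(in_idr(combine_consensus(sets7, 0.75), 5))
  sets6 <- lapply(rep(c(TRUE, FALSE), c(6, 3)), mk)   # 6 of 9 do not reach 75%
  expect_false(in_idr(combine_consensus(sets6, 0.75), 5))
  expect_error(combine_consensus(list(), 0.75), "at least one")

  # quorum 1 is the residue-level intersection
  s1 <- idr_set("P", 2, 6, L); s2 <- idr_set("P", 4, 9, L)
  q1 <- combine_consensus(list(s1, s2), 1)
  expect_equal(q1$start, 4L)
  expect_equal(q1$end, 6L)
})

test_that("consensus shrinks monotonically as the quorum rises", {
  set.seed(405)
  for (rep in 1:50) {
    L <- sample(30:60, 1L)
    sets <- lapply(1:5, function(i) random_idr_set(L))
    qs <- sort(runif(3, 0.2, 1))
    masks <- lapply(qs, function(q) idr_mask(combine_consensus(sets, q)))
    for (j in 2:3)
      expect_true(all(masks[[j]] <= masks[[j - 1L]]))
  }
})

test_that("disorder_fraction is covered residues over length", {
  expect_equal(disorder_fraction(idr_set("P", 1, 10, 100)), 0.10)
  expect_equal(disorder_fraction(idr_set("P", length = 57)), 0)
  expect_equal(disorder_fraction(idr_set("P", 1, 64, 64)), 1)
  # union fraction bounds: >= max of inputs, <= their sum
  set.seed(406)
  for (rep in 1:50) {
    L <- sample(30:60, 1L)
    a <- random_idr_set(L); b <- random_idr_set(L)
    fu <- disorder_fraction(combine_union(a, b))
    fa <- disorder_fraction(a); fb <- disorder_fraction(b)
    expect_gte(fu, max(fa, fb) - 1e-12)
    expect_lte(fu, fa + fb + 1e-12)
  }
})

test_that("in_idr is inclusive on both interval ends", {
  idr <- idr_set("P", 2, 3, 6)
  expect_true(in_idr(idr, 2))
  expect_true(in_idr(idr, 3))
  expect_false(in_idr(idr, 4))
  expect_equal(in_idr(idr, c(1, 2, 3, 4)), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(in_idr(idr, 7), "out of range")
  expect_error(in_idr(idr, 0), "out of range")
})

test_that("call_idrs applies single, union and consensus policies", {
  tracks <- list(A = list(VSL2b = c(1, 1, 0, 0, 1),
                          `IUPred-L` = c(0, 1, 1, 0, 1),
                          pred3 = c(0, 0, 0, 0, 1)))
  one <- call_idrs(tracks, caller = "VSL2b")
  expect_equal(one$A$start, c(1L, 5L))
  uni <- call_idrs(tracks, caller = "union",
                   predictors = c("VSL2b", "IUPred-L"))
  expect_equal(uni$A$start, c(1L, 5L))
  expect_equal(uni$A$end, c(3L, 5L))
  cons <- call_idrs(tracks, caller = "consensus", quorum = 2 / 3)
  expect_equal(cons$A$start, c(2L, 5L))  # residues called by >= 2 of 3
  expect_equal(cons$A$end, c(2L, 5L))
  expect_error(call_idrs(tracks, caller = "nope"), "no track")
})
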