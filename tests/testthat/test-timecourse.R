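make_tmt <- function(n = 6, seed = 1, sd = 0.3) {
  set.seed(seed)
  d <- data.frame(peptide_id = sprintf("p%02d", 1:n),
                  accession = "RP01", site = seq_len(n) + 10,
                  is_biotinylated = TRUE, is_ribosomal = TRUE)
  for (ch in c(paste0("10s_", 1:3), paste0("120s_", 1:3),
               paste0("300s_", 1:3), "carrier_1"))
    d[[ch]] <- 2^rnorm(n, 10, sd)
  as_tmt_matrix(d)
}

test_that("peptide filtering drops by reason and reports counts", {
  tmt <- make_tmt(5)
  tmt$`10s_2`[1] <- NA
  tmt$`300s_3`[2] <- NA
  tmt$is_biotinylated[3] <- FALSE
  tmt$is_ribosomal[4] <- FALSE
  flt <- filter_peptides(tmt)
  expect_equal(nrow(flt), 1L)
  rep_ <- attr(flt, "filter_report")
  expect_equal(unname(rep_[c("missing_value", "non_biotinylated",
                             "non_ribosomal", "retained")]),
               c(2L, 1L, 1L, 1L))
  # carrier channels are removed from the analysis
  expect_false("carrier_1" %in% names(flt))
  # clean input passes through unchanged
  clean <- make_tmt(4)
  flt2 <- filter_peptides(clean)
  expect_equal(nrow(flt2), 4L)
  expect_equal(flt2$`120s_1`, clean$`120s_1`)
  # all rows bad -> error naming the reasons
  allbad <- make_tmt(3)
  allbad$is_ribosomal <- FALSE
  expect_error(filter_peptides(allbad), "non_ribosomal=3")
})

test_that("optional median normalization equalizes channel medians", {
  tmt <- make_tmt(30, seed = 4)
  nrm <- filter_peptides(tmt, normalize = TRUE)
  med <- vapply(nrm[attr(nrm, "channels")], median, numeric(1))
  expect_lt(diff(range(med)) / mean(med), 1e-10)
  # and it is off by default
  raw <- filter_peptides(tmt)
  medr <- vapply(raw[attr(raw, "channels")], median, numeric(1))
  expect_gt(diff(range(medr)) / mean(medr), 1e-3)
})

test_that("d0 = 0 reproduces the ordinary two-sample t-test exactly", {
  tmt <- filter_peptides(make_tmt(40, seed = 5))
  res <- moderated_test(tmt, "300s", d0 = 0)
  ordinary <- vapply(seq_len(nrow(tmt)), function(i) {
    a <- log2(unlist(tmt[i, paste0("10s_", 1:3)]))
    b <- log2(unlist(tmt[i, paste0("300s_", 1:3)]))
    t.test(b, a, var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(res$p, ordinary, tolerance = 1e-10)
})

test_that("d0 -> Inf shrinks every posterior variance to s0^2", {
  tmt <- filter_peptides(make_tmt(40, seed = 6))
  res <- moderated_test(tmt, "120s", d0 = Inf, s0_sq = 0.04)
  # all moderated t use the same prior variance: t = logFC / sqrt(0.04 * 2/3)
  expect_equal(res$t_mod, res$logFC / sqrt(0.04 * 2 / 3),
               tolerance = 1e-12)
})

test_that("the default empirical-Bayes fit matches the limma pipeline", {
  tmt <- filter_peptides(make_tmt(60, seed = 7))
  res <- moderated_test(tmt, "300s")
  y <- log2(as.matrix(tmt[c(paste0("10s_", 1:3), paste0("300s_", 1:3))]))
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(y, design))
  expect_equal(res$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  # deterministic: identical rerun
  expect_identical(res, moderated_test(tmt, "300s"))
})

test_that("empirical-Bayes prior recovery at 2000 peptides", {
  set.seed(8)
  d0_true <- 4; s0_true <- 0.25
  n <- 2000
  s2g <- s0_true * d0_true / rchisq(n, d0_true)   # scaled inverse chi-sq
  d <- data.frame(peptide_id = sprintf("p%04d", 1:n), accession = "RP01",
                  site = 1, is_biotinylated = TRUE, is_ribosomal = TRUE)
  for (ch in c(paste0("10s_", 1:3), paste0("120s_", 1:3),
               paste0("300s_", 1:3)))
    d[[ch]] <- 2^rnorm(n, 10, sqrt(s2g))
  res <- moderated_test(filter_peptides(as_tmt_matrix(d)), "120s")
  expect_lt(abs(attr(res, "d0") - d0_true) / d0_true, 0.30)
  expect_lt(abs(attr(res, "s0_sq") - s0_true) / s0_true, 0.10)
})

test_that("kinetics labels: strict alpha, increase required, either contrast", {
  mk <- function(p_adj, lfc, contrast) {
    out <- data.frame(peptide_id = c("a", "b", "c", "d"),
                      logFC = lfc, t_mod = 1, df = 4, p = p_adj,
                      p_adj = p_adj)
    attr(out, "contrast") <- contrast
    class(out) <- c("moderated_tests", "data.frame")
    out
  }
  t120 <- mk(c(0.049, 0.049, 0.050, 0.20), c(1, -1, 1, 1), "120s-10s")
  t300 <- mk(c(0.900, 0.900, 0.900, 0.01), c(1, 1, 1, 1), "300s-10s")
  kc <- classify_kinetics(t120, t300)
  expect_equal(as.character(kc$label), c("late", "early", "early", "late"))
  expect_equal(kc$triggered_by, c("120s-10s", "", "", "300s-10s"))
  # partition is exhaustive and exclusive
  expect_false(anyNA(kc$label))
})

test_that("run_timecourse is deterministic end to end", {
  tmt <- generate_tmt(n_null = 40, n_late = 10, seed = 99)
  a <- run_timecourse(tmt)
  b <- run_timecourse(tmt)
  expect_identical(a$kinetics, b$kinetics)
  expect_identical(a$tests$`300s`$p_adj, b$tests$`300s`$p_adj)
})
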