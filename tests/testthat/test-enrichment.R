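test_that("count_target_residues counts by hand-checkable positions", {
  idr <- idr_set("P2", 1, 2, 5)
  ck <- count_target_residues("KAKYK", idr, "K")   # K at 1,3,5
  expect_equal(ck$n_in_idr, 1L)
  expect_equal(ck$n_total, 3L)
  cy <- count_target_residues("KAKYK", idr, "Y")   # Y at 4
  expect_equal(cy$n_in_idr, 0L)
  expect_equal(cy$n_total, 1L)
  ce <- count_target_residues("KAKYK", idr_set("P2", length = 5), "K")
  expect_equal(ce$n_in_idr, 0L)
  expect_error(count_target_residues("KAKYK", idr, character(0)),
               "empty residue set")
})

test_that("pooled_null_rate sums counts over the scope", {
  expect_equal(pooled_null_rate(data.frame(n_in_idr = c(2, 3),
                                           n_total = c(10, 10))), 0.25)
  expect_equal(pooled_null_rate(data.frame(n_in_idr = 0, n_total = 7)), 0)
  expect_equal(pooled_null_rate(data.frame(n_in_idr = 10, n_total = 10)), 1)
  expect_error(pooled_null_rate(data.frame(n_in_idr = 0, n_total = 0)),
               "no target residues")
})

test_that("binomial_test matches closed forms and binom.test", {
  expect_equal(binomial_test(10, 10, 0.5, "greater"), 2^-10)
  expect_equal(binomial_test(3, 10, 0.5), 0.34375)  # 2 * 176 / 1024
  # mode outcome: every outcome is included in the two-sided sum
  expect_equal(binomial_test(5, 10, 0.5), 1)
  # stats::binom.test as an independent oracle
  for (cfg in list(c(7, 20, 0.3), c(0, 15, 0.4), c(12, 12, 0.9),
                   c(33, 100, 0.25))) {
    expect_equal(binomial_test(cfg[1], cfg[2], cfg[3]),
                 stats::binom.test(cfg[1], cfg[2], cfg[3])$p.value,
                 tolerance = 1e-12)
    expect_equal(binomial_test(cfg[1], cfg[2], cfg[3], "greater"),
                 stats::binom.test(cfg[1], cfg[2], cfg[3],
                                   alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  # degenerate nulls refuse to produce a p-value
  expect_error(binomial_test(3, 10, 0), "p0")
  expect_error(binomial_test(3, 10, 1), "p0")
  # greater tail shrinks as k grows
  ps <- vapply(0:20, binomial_test, numeric(1), n = 20, p0 = 0.35,
               alternative = "greater")
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("study_enrichment assembles k, n, p0 from the biotinome", {
  prot <- tiny_proteome()
  idr <- tiny_idrsets()
  reg <- tiny_registry()
  # K study: P1 pos 2 (in [2,3]), P2 pos 5 (outside [1,2]), P2 pos 1 (in)
  sites <- validate_site_table(
    make_sites("SK", c("P1", "P2", "P2"), c(2, 5, 1), "K"), prot, reg)
  res <- study_enrichment(sites, prot, idr, reg)
  expect_equal(res$k, 2L)
  expect_equal(res$n, 3L)
  # biotinome = {P1, P2}; K in IDRs: P1 K2,K3 both in [2,3] -> 2 of 2;
  # P2 K1 in [1,2], K3/K5 out -> 1 of 3; p0 = 3/5
  expect_equal(res$p0, 3 / 5)
  expect_equal(res$fold, (2 / 3) / (3 / 5))
  expect_equal(res$p_value, binomial_test(2, 3, 3 / 5))
  expect_equal(res$table$rate, c(3 / 5, 2 / 3))
  # whole-proteome pooling adds P3 (K at 1:3, IDR [3,5] -> 1 of 3)
  resp <- study_enrichment(sites, prot, idr, reg, pool = "proteome")
  expect_equal(resp$p0, 4 / 8)
  expect_error(study_enrichment(sites, prot, idr, reg, study = "SY"),
               "empty biotinome")
  expect_error(study_enrichment(sites, prot, idr,
                                default_study_registry(), study = "SK"),
               "not in registry")
})

test_that("subset_enrichment restricts the scope by protein name", {
  prot <- tiny_proteome()
  idr <- tiny_idrsets()
  reg <- tiny_registry()
  sites <- validate_site_table(
    make_sites("SK", c("P1", "P2", "P3"), c(2, 1, 1), "K"), prot, reg)
  ribo <- subset_enrichment(sites, prot, idr, reg,
                            ribosomal_predicates$cytosolic_ribosomal,
                            scope_label = "cyto_ribo")
  expect_equal(ribo$n, 1L)            # only P1 is cytosolic-ribosomal
  expect_equal(ribo$scope, "SK:cyto_ribo")
  mito <- subset_enrichment(sites, prot, idr, reg,
                            ribosomal_predicates$mitochondrial_ribosomal)
  expect_equal(mito$n, 1L)            # P2
  all_ribo <- subset_enrichment(sites, prot, idr, reg, "ribosomal")
  expect_equal(all_ribo$n, 2L)        # P1 + P2: mito subset is contained
  expect_gte(all_ribo$n, mito$n)
  expect_error(subset_enrichment(sites, prot, idr, reg, "kinase"),
               "zero proteins")
})

test_that("biotin counts bin into 0..4 and 5+", {
  expect_equal(as.character(bin_biotin_counts(c(1, 2, 7))),
               c("1", "2", "5+"))
  expect_equal(levels(bin_biotin_counts(0)),
               c("0", "1", "2", "3", "4", "5+"))
  expect_error(bin_biotin_counts(-1))
})

test_that("biotin/disorder association computes Pearson r and bin medians", {
  # counts exactly proportional to fractions -> r = 1
  s <- data.frame(accession = paste0("P", 1:6),
                  biotin_count = 1:6,
                  disorder_fraction = (1:6) / 10,
                  binned_count = bin_biotin_counts(1:6))
  a <- biotin_disorder_association(s)
  expect_equal(a$r, 1)
  expect_lt(a$p_value, 1e-6)
  expect_equal(a$bins$median_fraction[a$bins$bin == "5+"],
               median(c(0.5, 0.6)))
  expect_equal(a$bins$n[a$bins$bin == "0"], 0L)
  s0 <- s; s0$disorder_fraction <- 0.3
  expect_error(biotin_disorder_association(s0), "zero variance")
  expect_error(biotin_disorder_association(s[1:2, ]), "at least 3")
})

test_that("protein_biotin_summary counts unique sites per protein", {
  prot <- tiny_proteome()
  idr <- tiny_idrsets()
  sites <- validate_site_table(
    make_sites("SK", c("P1", "P2", "P2", "P3"), c(2, 1, 3, 1), "K"), prot)
  s <- protein_biotin_summary(sites, prot, idr)
  expect_equal(s$biotin_count[match(c("P1", "P2", "P3"), s$accession)],
               c(1L, 2L, 1L))
  expect_equal(s$disorder_fraction[s$accession == "P2"], 2 / 5)
})
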