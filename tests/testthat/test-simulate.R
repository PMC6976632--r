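test_that("generators are pure functions of (config, seed)", {
  a <- generate_proteome(n_proteins = 30, seed = 42)
  b <- generate_proteome(n_proteins = 30, seed = 42)
  expect_identical(a, b)
  c <- generate_proteome(n_proteins = 30, seed = 43)
  expect_false(identical(a$proteome$sequence, c$proteome$sequence))

  idr <- call_idrs(a$tracks, caller = "VSL2b")
  s1 <- plant_sites(a$proteome, idr, "K", 100, 2, seed = 7)
  s2 <- plant_sites(a$proteome, idr, "K", 100, 2, seed = 7)
  expect_identical(s1, s2)
  expect_identical(generate_tmt(seed = 5), generate_tmt(seed = 5))
  g1 <- generate_go(a$proteome$accession, seed = 5)
  expect_identical(g1, generate_go(a$proteome$accession, seed = 5))
  # child seeds differ between components and stay below 2^31
  seeds <- vapply(c("proteome", "tmt", "go"), child_seed,
                  integer(1), seed = 42)
  expect_equal(length(unique(seeds)), 3L)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("disorder target fraction is honoured, including both extremes", {
  g0 <- generate_proteome(n_proteins = 10, disorder_fraction = 0,
                          seed = 1)
  expect_true(all(vapply(g0$tracks, function(t) all(t$VSL2b == 0),
                         logical(1))))
  g1 <- generate_proteome(n_proteins = 10, disorder_fraction = 1,
                          seed = 1)
  expect_true(all(vapply(g1$tracks, function(t) all(t$VSL2b == 1),
                         logical(1))))
  gq <- generate_proteome(n_proteins = 50, disorder_fraction = 0.3,
                          fraction_concentration = Inf, seed = 2)
  fr <- vapply(names(gq$tracks), function(a)
    mean(gq$tracks[[a]]$VSL2b), numeric(1))
  # constant-fraction mode: round(q * L) per protein, q +- rounding only
  expect_true(all(abs(fr - 0.3) < 0.01))
  # default mode: per-protein fractions vary around q with mean on target
  gh <- generate_proteome(n_proteins = 400, disorder_fraction = 0.3,
                          seed = 2)
  frh <- vapply(names(gh$tracks), function(a)
    mean(gh$tracks[[a]]$VSL2b), numeric(1))
  expect_gt(sd(frh), 0.05)
  expect_lt(abs(mean(frh) - 0.3), 0.03)
  expect_true(any(frh < 0.10) && any(frh > 0.30))  # all F/P/U classes occur
})

test_that("pseudo-predictors reduce to the truth when flip noise is zero", {
  g <- generate_proteome(n_proteins = 15, n_pseudo_predictors = 3,
                         flip_rate = 0, seed = 3)
  for (a in names(g$tracks)[1:5]) {
    tr <- g$tracks[[a]]
    for (p in names(tr)[-1]) expect_equal(tr[[p]], tr$VSL2b)
    cons <- combine_consensus(lapply(names(tr), function(p)
      binarize_track(tr[[p]], a, p)), 0.75)
    truth <- binarize_track(tr$VSL2b, a, "VSL2b")
    expect_equal(cons$start, truth$start)
    expect_equal(cons$end, truth$end)
  }
})

test_that("site planting respects residue chemistry and the rho limits", {
  g <- generate_proteome(n_proteins = 60, length_mean = 300, seed = 4)
  idr <- call_idrs(g$tracks, caller = "VSL2b")
  sK <- plant_sites(g$proteome, idr, "K", 200, 1, seed = 4)
  expect_true(all(sK$residue == "K"))
  expect_true(all(sK$modification == "biotin"))
  # rho = 1: in-IDR fraction near the residue-level q_r
  ctr <- do.call(rbind, lapply(g$proteome$accession, function(a)
    as.data.frame(count_target_residues(g$proteome[a, "sequence"],
                                        idr[[a]], "K"))))
  qr <- pooled_null_rate(ctr)
  frac <- mean(mapply(function(a, p) in_idr(idr[[a]], p),
                      sK$accession, sK$position))
  expect_lt(abs(frac - qr), 4 * sqrt(qr * (1 - qr) / nrow(sK)))
  # rho enormous: every site lands inside an IDR
  sHot <- plant_sites(g$proteome, idr, "K", 100, 1e9, seed = 5)
  expect_true(all(mapply(function(a, p) in_idr(idr[[a]], p),
                         sHot$accession, sHot$position)))
  expect_error(plant_sites(g$proteome, idr, "B", 10, 1, seed = 1),
               "no eligible residues")
})

test_that("clean TMT matrices pass the filter unchanged", {
  tmt <- generate_tmt(n_null = 30, n_late = 10, missing_rate = 0,
                      contamination = 0, seed = 6)
  flt <- filter_peptides(tmt)
  expect_equal(nrow(flt), 40L)
  expect_equal(flt$peptide_id, tmt$peptide_id)
  # flags and missingness appear at the configured rates
  tmt2 <- generate_tmt(n_null = 400, n_late = 0, missing_rate = 0.1,
                       contamination = 0.1, seed = 7)
  expect_gt(sum(is.na(as.matrix(tmt2[attr(tmt2, "channels")]))), 200)
  expect_gt(sum(!tmt2$is_biotinylated), 15)
})

test_that("a planted GO category is visibly over-represented", {
  world <- generate_go(sprintf("P%03d", 1:500), n_terms = 10,
                       category_size = 30, planted_odds = 5, seed = 8)
  planted <- unique(world$annotations$accession[
    world$annotations$term == world$planted_term])
  rate_in <- mean(planted %in% world$biotinome)
  rate_bg <- mean(setdiff(sprintf("P%03d", 1:500), planted) %in%
                  world$biotinome)
  expect_gt(rate_in, rate_bg)
  expect_error(generate_go(sprintf("P%d", 1:10), category_size = 20,
                           seed = 1),
               "larger than the proteome")
})
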