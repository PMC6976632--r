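# Synthetic-data generators emulating every input the pipeline consumes:
# proteomes with block-structured IDRs and realistic K/Y composition,
# biotin/PTM sites planted with a configurable IDR enrichment factor rho,
# TMT time-course matrices with early/late kinetics, and GO annotations
# with an abundance bias. Every generator is a pure function of
# (config, seed).

#' Default amino-acid composition for synthetic proteomes
#'
#' Lysine at 6\% and tyrosine at 3\% (their approximate natural
#' abundances -- the two labelling targets are the frequencies that
#' matter for power); the remaining 18 letters share the rest uniformly.
#' @return named numeric vector over the 20-letter alphabet, summing to 1.
#' @export
aa_composition <- function() {
  comp <- stats::setNames(rep((1 - 0.06 - 0.03) / 18, 20), AA_ALPHABET)
  comp[["K"]] <- 0.06
  comp[["Y"]] <- 0.03
  comp
}

#' Derive a child seed from a global seed
#'
#' Deterministic expansion of one global seed into per-component seeds so
#' components can be regenerated independently: a polynomial hash of the
#' component label is folded into the seed modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param what component label.
#' @return integer child seed in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, what) {
  h <- 0
  for (ch in utf8ToInt(what)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) + 31 * h) %% 2147483646 + 1)
}

# place `total` disordered residues in `nb` blocks uniformly without
# overlap on a protein of length L; returns a logical mask
place_idr_blocks <- function(L, total, nb) {
  if (total <= 0L) return(logical(L))
  if (total >= L) return(rep(TRUE, L))
  nb <- max(1L, min(nb, total))
  # split the disordered budget into nb positive parts
  if (nb > 1L) {
    cuts <- sort(sample.int(total - 1L, nb - 1L))
    lens <- diff(c(0L, cuts, total))
  } else lens <- total
  # distribute the ordered residues into nb + 1 gaps (ends may be 0)
  free <- L - total
  gaps <- if (free > 0L)
    tabulate(sample.int(nb + 1L, free, replace = TRUE), nbins = nb + 1L)
  else rep(0L, nb + 1L)
  mask <- logical(L)
  pos <- 0L
  for (i in seq_len(nb)) {
    pos <- pos + gaps[i]
    mask[(pos + 1L):(pos + lens[i])] <- TRUE
    pos <- pos + lens[i]
  }
  mask
}

#' Generate a synthetic proteome with block-structured IDRs
#'
#' Sequences are drawn i.i.d. from the residue composition. Each protein
#' draws its own disorder fraction from a Beta distribution with mean
#' \code{disorder_fraction} (so the proteome spans folded to unfolded
#' proteins while the pooled fraction stays on target), then receives
#' that many disordered residues placed in Poisson-many uniform blocks.
#' With \code{fraction_concentration = Inf} every protein has exactly
#' the target fraction, pinning the pooled fraction up to rounding. The noiseless
#' "truth" track is labelled \code{VSL2b}; optional pseudo-predictors are
#' derived from it by independent per-residue flips (the second is
#' labelled \code{IUPred-L}, further ones \code{pred3}, ...), emulating
#' disagreeing callers for union/consensus analyses.
#'
#' @param n_proteins number of proteins.
#' @param length_mean,length_dispersion negative-binomial residue-count
#'   parameters (a minimum length of 50 is enforced).
#' @param composition residue frequencies, see [aa_composition()].
#' @param disorder_fraction target proteome-wide fraction q of residues
#'   in IDRs.
#' @param fraction_concentration concentration of the Beta distribution
#'   from which each protein's own disorder fraction is drawn (mean q):
#'   real proteomes span fully folded to fully disordered, which is what
#'   populates the F/P/U classes. \code{Inf} gives every protein exactly
#'   fraction q.
#' @param blocks_mean expected number of IDR blocks per protein.
#' @param n_pseudo_predictors number of noisy pseudo-predictors beyond
#'   the truth track.
#' @param flip_rate per-residue flip probability for pseudo-predictors.
#' @param frac_ribosomal,frac_mito_ribosomal fractions of proteins named
#'   as (mitochondrial) ribosomal proteins, for name-predicate analyses.
#' @param seed integer seed (mandatory).
#' @return list with \code{proteome} and dense binary \code{tracks}.
#' @export
generate_proteome <- function(n_proteins = 200, length_mean = 400,
                              length_dispersion = 3,
                              composition = aa_composition(),
                              disorder_fraction = 0.3,
                              fraction_concentration = 8,
                              blocks_mean = 2,
                              n_pseudo_predictors = 1, flip_rate = 0.05,
                              frac_ribosomal = 0.08,
                              frac_mito_ribosomal = 0.04, seed) {
  stopifnot(!missing(seed), n_proteins >= 1,
            disorder_fraction >= 0, disorder_fraction <= 1,
            flip_rate >= 0, flip_rate <= 1)
  stopifnot(abs(sum(composition) - 1) < 1e-8)
  set.seed(child_seed(seed, "proteome"))
  lens <- pmax(50L, stats::rnbinom(n_proteins, mu = length_mean,
                                   size = length_dispersion))
  acc <- sprintf("SYN%04d", seq_len(n_proteins))
  seqs <- vapply(lens, function(L)
    paste(sample(names(composition), L, replace = TRUE,
                 prob = composition), collapse = ""), character(1))
  kind <- sample(c("ribo", "mito", "other"), n_proteins, replace = TRUE,
                 prob = c(frac_ribosomal, frac_mito_ribosomal,
                          1 - frac_ribosomal - frac_mito_ribosomal))
  descr <- ifelse(kind == "ribo",
                  sprintf("60S ribosomal protein L%d", seq_len(n_proteins)),
           ifelse(kind == "mito",
                  sprintf("39S mitochondrial ribosomal protein L%d",
                          seq_len(n_proteins)),
                  sprintf("hypothetical protein %d", seq_len(n_proteins))))
  prot <- proteome(acc, seqs, descr)

  pred_labels <- c("VSL2b",
                   if (n_pseudo_predictors >= 1L) "IUPred-L",
                   if (n_pseudo_predictors >= 2L)
                     sprintf("pred%d", seq(3L, n_pseudo_predictors + 1L)))
  q <- disorder_fraction
  frac <- if (is.finite(fraction_concentration) && q > 0 && q < 1) {
    stats::rbeta(n_proteins, fraction_concentration * q,
                 fraction_concentration * (1 - q))
  } else rep(q, n_proteins)
  tracks <- lapply(seq_len(n_proteins), function(i) {
    L <- lens[[i]]
    total <- as.integer(round(frac[[i]] * L))
    nb <- if (total > 0L) max(1L, stats::rpois(1L, blocks_mean)) else 0L
    truth <- place_idr_blocks(L, total, nb)
    tr <- list(as.numeric(truth))
    for (j in seq_len(n_pseudo_predictors)) {
      flip <- stats::runif(L) < flip_rate
      tr[[j + 1L]] <- as.numeric(xor(truth, flip))
    }
    stats::setNames(tr, pred_labels)
  })
  names(tracks) <- acc
  list(proteome = prot, tracks = tracks)
}

#' Plant modification sites with an IDR enrichment factor
#'
#' Each site independently picks one eligible-residue position in the
#' proteome with sampling weight \code{rho} inside IDRs and 1 outside,
#' with replacement; duplicates are then collapsed (real studies report
#' unique sites), so the achieved unique site count may be below
#' \code{n_sites}. The expected in-IDR site fraction is
#' \code{rho q_r / (rho q_r + 1 - q_r)} where \code{q_r} is the fraction
#' of eligible residues inside IDRs.
#'
#' @param proteome a \code{proteome}.
#' @param idrsets named list of \code{idr_set} defining "inside an IDR".
#' @param residues eligible residue letters (e.g. \code{"K"}).
#' @param n_sites number of planting draws.
#' @param rho IDR enrichment factor (>= 0; 1 is the null).
#' @param study_id study label for the site table.
#' @param modification modification type label.
#' @param seed integer seed.
#' @return a validated \code{site_table} of unique sites.
#' @export
plant_sites <- function(proteome, idrsets, residues = "K",
                        n_sites = 1000, rho = 1, study_id = "synth",
                        modification = "biotin", seed) {
  stopifnot(!missing(seed), rho >= 0, n_sites >= 1)
  set.seed(child_seed(seed, paste0("sites:", study_id, ":", modification)))
  pat <- sprintf("[%s]", paste(residues, collapse = ""))
  hits <- gregexpr(pat, proteome$sequence)
  n_hits <- vapply(hits, function(h) sum(h > 0L), integer(1))
  if (sum(n_hits) == 0L) stop("no eligible residues in the proteome")
  acc <- rep(proteome$accession, n_hits)
  pos <- unlist(lapply(hits, function(h) as.integer(h[h > 0L])),
                use.names = FALSE)
  inside <- unlist(lapply(which(n_hits > 0L), function(j)
    in_idr(idrsets[[proteome$accession[[j]]]],
           as.integer(hits[[j]]))), use.names = FALSE)
  w <- ifelse(inside, rho, 1)
  if (all(w == 0)) stop("all sampling weights are zero")
  idx <- sample.int(length(pos), n_sites, replace = TRUE, prob = w)
  sites <- data.frame(study_id = study_id,
                      accession = acc[idx],
                      position = pos[idx],
                      residue = substr(proteome$sequence[
                        match(acc[idx], proteome$accession)],
                        pos[idx], pos[idx]),
                      modification = modification)
  validate_site_table(sites, proteome, strict = TRUE)
}

#' Generate a synthetic TMT time-course matrix
#'
#' Log2 intensities are baseline + condition effect + Normal(0, sd)
#' noise. "Late" peptides receive \code{+effect} at both 120 s and 300 s
#' (biotin keeps accumulating on slowly-labelled sites); null peptides
#' are flat. A configurable fraction of cells is set missing and a
#' configurable fraction of peptides is flagged non-biotinylated /
#' non-ribosomal contamination. The ground truth is recorded in the
#' \code{truth_late} column.
#'
#' @param n_null,n_late numbers of flat and late peptides.
#' @param effect log2 intensity increase of late peptides.
#' @param sd per-cell noise standard deviation (log2 scale).
#' @param baseline mean log2 intensity at 10 s.
#' @param missing_rate per-cell missingness probability.
#' @param contamination probability that a peptide is flagged
#'   non-biotinylated (and, independently, non-ribosomal).
#' @param seed integer seed.
#' @return a \code{tmt_matrix}.
#' @export
generate_tmt <- function(n_null = 100, n_late = 25, effect = 0.75,
                         sd = 0.5, baseline = 10, missing_rate = 0.05,
                         contamination = 0.05, seed) {
  stopifnot(!missing(seed), n_null >= 0, n_late >= 0, n_null + n_late >= 2,
            sd > 0, missing_rate >= 0, missing_rate < 1)
  set.seed(child_seed(seed, "tmt"))
  n <- n_null + n_late
  late <- rep(c(FALSE, TRUE), c(n_null, n_late))
  ch <- c(paste0("10s_", 1:3), paste0("120s_", 1:3), paste0("300s_", 1:3),
          "carrier_1")
  eff <- outer(late, c(0, 0, 0, rep(1, 6), 0)) * effect
  m <- baseline + eff + matrix(stats::rnorm(n * 10, 0, sd), n, 10)
  m[, 10] <- baseline + 4  # 1 h carrier: heavily labelled reference
  inten <- 2^m
  if (missing_rate > 0)
    inten[matrix(stats::runif(n * 10) < missing_rate, n, 10)] <- NA
  d <- data.frame(peptide_id = sprintf("pep%04d", seq_len(n)),
                  accession = sprintf("RP%02d", (seq_len(n) %% 20) + 1L),
                  site = sample(30:200, n, replace = TRUE),
                  is_biotinylated = stats::runif(n) >= contamination,
                  is_ribosomal = stats::runif(n) >= contamination,
                  truth_late = late)
  d[ch] <- as.data.frame(inten)
  as_tmt_matrix(d)
}

#' Generate GO annotations with an abundance bias
#'
#' Per-protein bias factors (expression) are log-normal. Biotinome
#' membership is logistic in log bias with slope \code{bias_strength};
#' one planted category multiplies the membership odds of its members by
#' \code{planted_odds}. Categories sample their members weighted by
#' \code{bias^category_bias}, so with \code{category_bias > 0} category
#' membership correlates with abundance -- the situation that fools an
#' uncorrected Fisher test and that the Wallenius correction exists for.
#'
#' @param accessions protein accessions to annotate.
#' @param n_terms number of categories.
#' @param category_size members per category.
#' @param planted_odds odds multiplier of the planted category (term
#'   \code{GO_planted}); 1 means no planted effect.
#' @param bias_strength logistic slope of membership on log bias.
#' @param category_bias exponent tying category sampling to the bias.
#' @param membership_intercept logistic intercept (baseline logit).
#' @param seed integer seed.
#' @return list with \code{annotations} (accession, term), named
#'   \code{bias} vector, \code{biotinome} accessions and
#'   \code{planted_term}.
#' @export
generate_go <- function(accessions, n_terms = 50, category_size = 25,
                        planted_odds = 1, bias_strength = 1.5,
                        category_bias = 1, membership_intercept = -1,
                        seed) {
  stopifnot(!missing(seed), n_terms >= 1)
  n <- length(accessions)
  if (category_size > n) stop("planted category larger than the proteome")
  set.seed(child_seed(seed, "go"))
  bias <- stats::setNames(stats::rlnorm(n, 0, 1), accessions)
  wcat <- bias^category_bias
  terms <- c("GO_planted", sprintf("GO_null%03d", seq_len(n_terms - 1L)))
  ann <- do.call(rbind, lapply(terms, function(tm)
    data.frame(accession = sample(accessions, category_size,
                                  prob = wcat),
               term = tm)))
  eta <- membership_intercept + bias_strength * log(bias)
  if (planted_odds != 1) {
    planted <- unique(ann$accession[ann$term == "GO_planted"])
    eta[accessions %in% planted] <- eta[accessions %in% planted] +
      log(planted_odds)
  }
  member <- stats::runif(n) < stats::plogis(eta)
  list(annotations = ann, bias = bias,
       biotinome = accessions[member], planted_term = "GO_planted")
}
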