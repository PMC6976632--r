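# Observed vs expected modification within IDRs. The null rate p0 is the
# fraction of modifiable residues (the study chemistry's target residues)
# that fall inside predicted IDRs, pooled over the scope; a "success" is a
# modification inside an IDR, trials are the unique observed sites.

#' Count target residues inside and outside IDRs
#'
#' @param sequence amino-acid sequence of one protein.
#' @param idr the protein's \code{idr_set}.
#' @param residues non-empty set of amino-acid letters that the chemistry
#'   can modify (e.g. \code{"K"}, \code{"Y"}, or \code{c("S","T","Y")}).
#' @return list with \code{n_in_idr} and \code{n_total}.
#' @export
count_target_residues <- function(sequence, idr, residues) {
  if (length(residues) == 0L) stop("empty residue set")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pos <- which(chars %in% residues)
  list(n_in_idr = if (length(pos)) sum(in_idr(idr, pos)) else 0L,
       n_total = length(pos))
}

#' Pooled null success rate over a scope of proteins
#'
#' @param counts data frame (or list of lists) with columns
#'   \code{n_in_idr} and \code{n_total}, one row per protein in scope.
#' @return p0 = sum(n_in_idr) / sum(n_total). A p0 of exactly 0 or 1 marks
#'   an untestable scope; downstream tests refuse it.
#' @export
pooled_null_rate <- function(counts) {
  if (is.data.frame(counts)) {
    tot <- sum(counts$n_total); inn <- sum(counts$n_in_idr)
  } else {
    tot <- sum(vapply(counts, `[[`, numeric(1), "n_total"))
    inn <- sum(vapply(counts, `[[`, numeric(1), "n_in_idr"))
  }
  if (tot == 0) stop("no target residues in scope")
  inn / tot
}

# vectorized residue counting over a set of proteins (one gregexpr call
# over all sequences; no per-protein frames)
residue_idr_counts <- function(proteome, idrsets, residues, accessions) {
  i <- match(accessions, proteome$accession)
  if (anyNA(i)) stop("unknown accession ", accessions[is.na(i)][[1L]])
  pat <- sprintf("[%s]", paste(residues, collapse = ""))
  hits <- gregexpr(pat, proteome$sequence[i])
  n_total <- vapply(hits, function(h) sum(h > 0L), integer(1))
  n_in <- vapply(seq_along(accessions), function(j) {
    if (n_total[[j]] == 0L) return(0L)
    sum(in_idr(idrsets[[accessions[[j]]]], as.integer(hits[[j]])))
  }, integer(1))
  data.frame(accession = accessions, n_in_idr = n_in, n_total = n_total)
}

log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact binomial test by pmf summation
#'
#' Exact tail computation in log space (no normal approximation). The
#' two-sided p-value is the sum of probabilities of all outcomes no more
#' likely than the observed one (the conventional exact "small-p" method,
#' with a 1 + 1e-7 relative tolerance on pmf ties).
#'
#' @param k observed successes.
#' @param n trials (>= 1).
#' @param p0 null success probability, strictly inside (0, 1).
#' @param alternative \code{"two.sided"} or \code{"greater"}.
#' @return the p-value.
#' @export
binomial_test <- function(k, n, p0, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 1, k >= 0, k <= n)
  if (!(p0 > 0 && p0 < 1))
    stop("p0 must lie strictly inside (0,1); degenerate null is untestable")
  lp <- stats::dbinom(0:n, n, p0, log = TRUE)
  p <- if (alternative == "greater") {
    exp(log_sum_exp(lp[(k:n) + 1L]))
  } else {
    sel <- lp <= lp[[k + 1L]] + log1p(1e-7)
    exp(log_sum_exp(lp[sel]))
  }
  min(1, p)
}

# shared enrichment machinery: sites already restricted to one
# modification scope; residues = the modifiable alphabet for the null.
idr_enrichment_core <- function(sites, proteome, idrsets, residues,
                                scope = "study",
                                pool = c("biotinome", "proteome"),
                                alternative = c("two.sided", "greater")) {
  pool <- match.arg(pool)
  alternative <- match.arg(alternative)
  if (nrow(sites) == 0L) stop("no sites in scope '", scope, "'")
  no_idr <- setdiff(unique(sites$accession), names(idrsets))
  if (length(no_idr)) {
    warning(sprintf("dropping %d site(s) on %d protein(s) without disorder predictions",
                    sum(sites$accession %in% no_idr), length(no_idr)),
            call. = FALSE)
    sites <- sites[!sites$accession %in% no_idr, , drop = FALSE]
    if (nrow(sites) == 0L) stop("no sites with disorder predictions in scope")
  }
  pool_acc <- if (pool == "biotinome") unique(sites$accession)
              else intersect(proteome$accession, names(idrsets))
  counts <- residue_idr_counts(proteome, idrsets, residues, pool_acc)
  p0 <- pooled_null_rate(counts)
  n <- nrow(sites)
  by_acc <- split(sites$position, sites$accession)
  k <- sum(vapply(names(by_acc), function(acc)
    sum(in_idr(idrsets[[acc]], by_acc[[acc]])), numeric(1)))
  untestable <- p0 <= 0 || p0 >= 1
  res <- list(scope = scope,
              caller = idrsets[[pool_acc[[1L]]]]$caller,
              residues = residues,
              k = as.integer(k), n = as.integer(n), p0 = p0,
              fold = if (p0 > 0) (k / n) / p0 else NA_real_,
              p_value = if (untestable) NA_real_
                        else binomial_test(k, n, p0, alternative),
              alternative = alternative, pool = pool,
              untestable = untestable,
              n_proteins = length(pool_acc),
              table = data.frame(what = c("expected", "observed"),
                                 rate = c(p0, k / n)))
  class(res) <- "enrichment_result"
  res
}

#' Significance stars for a p-value
#'
#' Cosmetic annotation used on the expected/observed bars: \code{"***"}
#' for p < 0.0005 and \code{"****"} for p values indistinguishable from 0
#' at double precision.
#' @param p p-value.
#' @return character.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-300, "****",
                              ifelse(p < 5e-4, "***", "")))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("IDR enrichment [%s], caller %s, null over %s (%d proteins)\n",
              x$scope, x$caller, x$pool, x$n_proteins))
  cat(sprintf("  sites in IDRs: %d / %d (observed rate %.4f)\n",
              x$k, x$n, x$k / x$n))
  cat(sprintf("  expected rate p0 = %.4f (residues %s in IDRs / total)\n",
              x$p0, paste(x$residues, collapse = "")))
  if (x$untestable) {
    cat("  scope untestable: degenerate null rate\n")
  } else {
    cat(sprintf("  fold = %.3f, %s p = %.3g %s\n", x$fold, x$alternative,
                x$p_value, significance_stars(x$p_value)))
  }
  invisible(x)
}

#' IDR enrichment of biotinylation sites for one study
#'
#' The Fig.-3b-style statistic: trials are the study's unique biotin
#' sites, successes those inside predicted IDRs, and the null rate p0 is
#' the pooled fraction of the study chemistry's target residues (K or Y)
#' inside IDRs over the study's biotinome (proteins with at least one
#' detected site; \code{pool = "proteome"} pools over all proteins with
#' predictions instead).
#'
#' @param sites a validated \code{site_table}.
#' @param proteome a \code{proteome}.
#' @param idrsets named list of \code{idr_set} (see [call_idrs()]).
#' @param registry a \code{study_registry} supplying the target residue.
#' @param study study_id to analyse; may be omitted when the table holds a
#'   single study.
#' @param pool scope of the null-rate pooling.
#' @param alternative test sidedness (enrichment direction is carried by
#'   \code{fold}).
#' @return an \code{enrichment_result}; \code{$table} holds the tidy
#'   expected/observed rates for plotting.
#' @export
study_enrichment <- function(sites, proteome, idrsets, registry,
                             study = NULL,
                             pool = c("biotinome", "proteome"),
                             alternative = c("two.sided", "greater")) {
  sites <- sites[sites$modification == "biotin", , drop = FALSE]
  if (is.null(study)) {
    study <- unique(sites$study_id)
    if (length(study) != 1L)
      stop("site table holds several studies; pass `study`")
  }
  if (!study %in% registry$study_id)
    stop("study '", study, "' not in registry")
  sites <- sites[sites$study_id == study, , drop = FALSE]
  if (nrow(sites) == 0L) stop("empty biotinome for study ", study)
  target <- registry$target_residue[match(study, registry$study_id)]
  idr_enrichment_core(sites, proteome, idrsets, target, scope = study,
                      pool = match.arg(pool),
                      alternative = match.arg(alternative))
}

#' Ribosomal-protein name predicates
#'
#' Predicates (regular expressions on the protein description) selecting
#' cytosolic vs mitochondrial ribosomal proteins by name, as used for the
#' ribosome-focused subset enrichment.
#' @export
ribosomal_predicates <- list(
  cytosolic_ribosomal = function(description)
    grepl("ribosomal", description, ignore.case = TRUE) &
      !grepl("mitochondrial", description, ignore.case = TRUE),
  mitochondrial_ribosomal = function(description)
    grepl("mitochondrial ribosomal", description, ignore.case = TRUE))

#' IDR enrichment restricted to a named protein subset
#'
#' Identical computation to [study_enrichment()] restricted to proteins
#' selected by name (e.g. ribosomal proteins).
#'
#' @inheritParams study_enrichment
#' @param name_predicate either a function of the description vector
#'   returning a logical, or a regular expression matched against the
#'   description; see [ribosomal_predicates] for defaults.
#' @param scope_label label to carry in the result.
#' @export
subset_enrichment <- function(sites, proteome, idrsets, registry,
                              name_predicate, study = NULL,
                              scope_label = "subset",
                              pool = c("biotinome", "proteome"),
                              alternative = c("two.sided", "greater")) {
  sel <- if (is.function(name_predicate)) name_predicate(proteome$description)
         else grepl(name_predicate, proteome$description, ignore.case = TRUE)
  if (!any(sel)) stop("name predicate selects zero proteins")
  sub_prot <- proteome[sel, , drop = FALSE]
  class(sub_prot) <- class(proteome)
  sites <- sites[sites$modification == "biotin" &
                 sites$accession %in% sub_prot$accession, , drop = FALSE]
  if (is.null(study)) {
    study <- unique(sites$study_id)
    if (length(study) != 1L)
      stop("site table holds several studies; pass `study`")
  }
  sites <- sites[sites$study_id == study, , drop = FALSE]
  if (nrow(sites) == 0L) stop("no biotin sites in subset for study ", study)
  target <- registry$target_residue[match(study, registry$study_id)]
  idr_enrichment_core(sites, sub_prot,
                      idrsets[intersect(names(idrsets), sub_prot$accession)],
                      target, scope = paste(study, scope_label, sep = ":"),
                      pool = match.arg(pool),
                      alternative = match.arg(alternative))
}

#' Bin per-protein biotin counts into 0..4, 5+
#'
#' Proteins with five or more sites are collapsed into the \code{"5+"}
#' bin (there are few of them, and the pooled bin shows the trend).
#' @param counts integer vector of per-protein site counts.
#' @return factor with levels \code{0,1,2,3,4,5+}.
#' @export
bin_biotin_counts <- function(counts) {
  stopifnot(all(counts >= 0))
  factor(ifelse(counts >= 5, "5+", as.character(counts)),
         levels = c("0", "1", "2", "3", "4", "5+"))
}

#' Per-protein biotin counts and disorder fractions
#'
#' @inheritParams study_enrichment
#' @return data frame \code{accession}, \code{biotin_count} (unique
#'   sites), \code{disorder_fraction}, \code{binned_count}, one row per
#'   biotinome protein with disorder predictions.
#' @export
protein_biotin_summary <- function(sites, proteome, idrsets, study = NULL) {
  sites <- sites[sites$modification == "biotin", , drop = FALSE]
  if (!is.null(study))
    sites <- sites[sites$study_id == study, , drop = FALSE]
  sites <- sites[sites$accession %in% names(idrsets), , drop = FALSE]
  if (nrow(sites) == 0L) stop("no biotin sites in scope")
  cnt <- table(sites$accession)
  acc <- names(cnt)
  frac <- vapply(acc, function(a) disorder_fraction(idrsets[[a]]),
                 numeric(1))
  data.frame(accession = acc, biotin_count = as.integer(cnt),
             disorder_fraction = frac,
             binned_count = bin_biotin_counts(as.integer(cnt)),
             row.names = NULL)
}

#' Association between biotinylation frequency and disorder
#'
#' Pearson correlation between the per-protein number of unique biotin
#' sites (unbinned) and the predicted disorder fraction, with the
#' two-sided p-value from the t transform, plus the violin-plot-style
#' table of disorder-fraction distributions grouped by binned counts.
#'
#' @param summaries as returned by [protein_biotin_summary()].
#' @return a \code{biotin_disorder_association}: list with \code{r},
#'   \code{p_value}, \code{n}, per-bin summary \code{bins} and the long
#'   table \code{data}.
#' @export
biotin_disorder_association <- function(summaries) {
  stopifnot(all(c("biotin_count", "disorder_fraction") %in%
                names(summaries)))
  if (nrow(summaries) < 3L)
    stop("need at least 3 proteins")
  if (stats::sd(summaries$biotin_count) == 0 ||
      stats::sd(summaries$disorder_fraction) == 0)
    stop("zero variance in counts or disorder fractions")
  ct <- stats::cor.test(summaries$biotin_count,
                        summaries$disorder_fraction,
                        method = "pearson")
  bins <- do.call(rbind, lapply(
    split(summaries, summaries$binned_count, drop = FALSE),
    function(d) data.frame(n = nrow(d),
                           median_fraction = if (nrow(d)) {
                             stats::median(d$disorder_fraction)
                           } else NA_real_)))
  bins <- data.frame(bin = rownames(bins), bins, row.names = NULL)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(summaries), bins = bins, data = summaries),
            class = "biotin_disorder_association")
}

#' @export
print.biotin_disorder_association <- function(x, ...) {
  cat(sprintf("Biotin count vs disorder fraction over %d proteins: Pearson r = %.3f, p = %.3g\n",
              x$n, x$r, x$p_value))
  print(x$bins)
  invisible(x)
}

#' Export an enrichment result (or a list of them) as TSV
#' @param results an \code{enrichment_result} or list thereof.
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(x)
    data.frame(scope = x$scope, k = x$k, n = x$n, p0 = x$p0,
               fold = x$fold, p_value = x$p_value,
               alternative = x$alternative,
               stars = significance_stars(x$p_value))))
  write_tsv(df, path)
}
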