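# Endogenous PTMs reuse the biotin enrichment machinery with
# residue-type-specific backgrounds: phosphorylation can land on S/T/Y,
# the lysine-directed PTMs (ubiquitination, acetylation, sumoylation) on K.

PTM_BACKGROUNDS <- list(phospho = c("S", "T", "Y"),
                        ubiquitination = "K",
                        acetylation = "K",
                        sumoylation = "K")

#' Eligible residues for a PTM type
#' @param ptm_type one of \code{phospho}, \code{ubiquitination},
#'   \code{acetylation}, \code{sumoylation}.
#' @return character vector of eligible amino-acid letters.
#' @export
ptm_background <- function(ptm_type) {
  bg <- PTM_BACKGROUNDS[[ptm_type]]
  if (is.null(bg))
    stop("unsupported PTM type '", ptm_type, "'; supported: ",
         paste(names(PTM_BACKGROUNDS), collapse = ", "))
  bg
}

#' IDR enrichment of PTM sites
#'
#' Same null construction and exact binomial test as
#' [study_enrichment()], with the PTM type's eligible residues replacing
#' the labelling chemistry's target residue. Sites on residues outside
#' the eligible set are dropped with a warning (\code{strict = TRUE}
#' aborts).
#'
#' @inheritParams study_enrichment
#' @param ptm_type PTM type (see [ptm_background()]); \code{"biotin"} is
#'   accepted when \code{residues} is supplied explicitly, which makes
#'   the machinery equivalence with [study_enrichment()] testable.
#' @param residues override of the eligible residue set.
#' @param strict abort on ineligible residues instead of dropping.
#' @return an \code{enrichment_result}.
#' @export
ptm_idr_enrichment <- function(sites, proteome, idrsets, ptm_type,
                               residues = NULL, strict = FALSE,
                               pool = c("biotinome", "proteome"),
                               alternative = c("two.sided", "greater")) {
  if (is.null(residues)) residues <- ptm_background(ptm_type)
  sites <- sites[sites$modification == ptm_type, , drop = FALSE]
  if (nrow(sites) == 0L) stop("no sites of type '", ptm_type, "'")
  ok <- sites$residue %in% residues
  if (any(!ok)) {
    if (strict)
      stop(sprintf("%d %s site(s) on residues outside {%s}", sum(!ok),
                   ptm_type, paste(residues, collapse = ",")))
    warning(sprintf("dropping %d %s site(s) on ineligible residues",
                    sum(!ok), ptm_type), call. = FALSE)
    sites <- sites[ok, , drop = FALSE]
    if (nrow(sites) == 0L) stop("no eligible sites of type '", ptm_type, "'")
  }
  idr_enrichment_core(sites, proteome, idrsets, residues,
                      scope = ptm_type, pool = match.arg(pool),
                      alternative = match.arg(alternative))
}

#' Compare mean per-protein PTM burden between two protein sets
#'
#' Standard two-sample t-test for means of per-protein PTM counts, e.g.
#' the biotinome against a reference proteome (both samples supplied
#' explicitly).
#'
#' @param biotinome_counts per-protein PTM counts in the biotinome.
#' @param proteome_counts per-protein PTM counts in the reference set.
#' @param welch Welch test (default) or pooled-variance.
#' @return a \code{group_comparison} list: group means, mean difference,
#'   t statistic, degrees of freedom and p-value.
#' @export
biotinome_vs_proteome_ptm <- function(biotinome_counts, proteome_counts,
                                      welch = TRUE) {
  if (length(biotinome_counts) < 2L || length(proteome_counts) < 2L)
    stop("both samples need n >= 2")
  if (stats::sd(biotinome_counts) == 0 && stats::sd(proteome_counts) == 0)
    stop("degenerate variance in both samples")
  tt <- stats::t.test(biotinome_counts, proteome_counts,
                      var.equal = !welch)
  structure(list(mean_biotinome = mean(biotinome_counts),
                 mean_proteome = mean(proteome_counts),
                 mean_diff = mean(biotinome_counts) - mean(proteome_counts),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample %s t-test: means %.3f vs %.3f (diff %.3f), t = %.3f, df = %.1f, p = %.3g\n",
              if (x$welch) "Welch" else "pooled", x$mean_biotinome,
              x$mean_proteome, x$mean_diff, x$statistic, x$df, x$p_value))
  invisible(x)
}
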