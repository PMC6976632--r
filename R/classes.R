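# Folded / Partially Folded / Unfolded protein classes by predicted
# disorder fraction, and biotin-count comparisons across the classes.

#' Classify proteins by disorder fraction
#'
#' Folded (F) below 10\% disorder, Partially Folded (P) between 10 and
#' 30\% inclusive, Unfolded (U) above 30\%. The printed ranges "<10%",
#' "10-30%", ">30%" leave the two boundaries ambiguous; both are assigned
#' to P so each stated range is honoured literally.
#'
#' @param fraction numeric vector of disorder fractions in [0, 1].
#' @return factor with levels \code{F}, \code{P}, \code{U}.
#' @export
classify_protein <- function(fraction) {
  if (any(fraction < 0 | fraction > 1 | is.na(fraction)))
    stop("disorder fraction must lie in [0,1]")
  factor(ifelse(fraction < 0.10, "F",
                ifelse(fraction <= 0.30, "P", "U")),
         levels = c("F", "P", "U"))
}

#' Log2-transform biotin counts with a pseudo-count
#'
#' \code{log2(count + pseudo)}. With the default pseudo-count of 0.5,
#' zero counts map strictly below the zero line, separating unmodified
#' proteins visually from single-site ones.
#'
#' @param counts non-negative integer counts.
#' @param pseudo positive pseudo-count, default 0.5.
#' @export
log2_counts <- function(counts, pseudo = 0.5) {
  if (pseudo <= 0) stop("pseudo-count must be > 0")
  stopifnot(all(counts >= 0))
  log2(counts + pseudo)
}

#' Compare log2 biotin counts across structural classes
#'
#' Pairwise two-sample t-tests between the classes (F-P, U-P, U-F; Welch
#' by default), a one-way ANOVA across all classes, and Tukey's Honestly
#' Significant Differences post-hoc test (studentized-range family-wise
#' control with per-pair confidence intervals, via
#' \code{stats::TukeyHSD}).
#'
#' @param values_by_class named list mapping class labels (e.g. F, P, U)
#'   to numeric vectors of log2 counts.
#' @param welch use Welch (unequal-variance) pairwise t-tests; set
#'   \code{FALSE} for pooled-variance tests.
#' @param conf_level Tukey confidence level.
#' @return a \code{class_comparison}: list with \code{pairwise},
#'   \code{anova} and \code{tukey} components.
#' @export
compare_classes <- function(values_by_class, welch = TRUE,
                            conf_level = 0.95) {
  stopifnot(is.list(values_by_class), length(values_by_class) >= 2L)
  labs <- names(values_by_class)
  sizes <- vapply(values_by_class, length, integer(1))
  usable <- labs[sizes >= 2L]
  if (length(usable) < 2L)
    stop("need at least two classes with >= 2 observations")
  if (length(usable) < length(labs))
    warning("skipping class(es) with < 2 observations: ",
            paste(setdiff(labs, usable), collapse = ", "), call. = FALSE)

  pairs <- utils::combn(usable, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    x <- values_by_class[[b]]; y <- values_by_class[[a]]
    row <- tryCatch({
      tt <- stats::t.test(x, y, var.equal = !welch)
      data.frame(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
    }, error = function(e) {
      # degenerate (constant) data: a zero difference is certain, a
      # non-zero one infinitely significant
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      data.frame(statistic = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                 df = NA_real_, p_value = if (eq) 1 else 0)
    })
    cbind(data.frame(pair = paste(b, a, sep = "-"),
                     mean_diff = mean(x) - mean(y)), row)
  }))

  values <- unlist(values_by_class[usable], use.names = FALSE)
  group <- factor(rep(usable, sizes[usable]), levels = usable)
  if (stats::var(values) == 0) {
    anova <- list(F = 0, df1 = length(usable) - 1L,
                  df2 = length(values) - length(usable), p_value = 1)
    tukey <- data.frame(pair = pairwise$pair, diff = 0, lwr = 0, upr = 0,
                        p_adj = 1)
  } else {
    fit <- stats::aov(values ~ group)
    an <- summary(fit)[[1L]]
    anova <- list(F = an[["F value"]][[1L]],
                  df1 = an[["Df"]][[1L]], df2 = an[["Df"]][[2L]],
                  p_value = an[["Pr(>F)"]][[1L]])
    tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(list(pairwise = pairwise, anova = anova, tukey = tukey,
                 welch = welch,
                 sizes = stats::setNames(as.integer(sizes[usable]), usable)),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("Class comparison (%s t-tests), n = %s\n",
              if (x$welch) "Welch" else "pooled",
              paste(names(x$sizes), x$sizes, sep = ":", collapse = ", ")))
  print(x$pairwise, row.names = FALSE)
  cat(sprintf("ANOVA: F(%d, %d) = %.4g, p = %.3g\n", x$anova$df1,
              x$anova$df2, x$anova$F, x$anova$p_value))
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Structural-class analysis of in-IDR biotin counts for one study
#'
#' Classifies every biotinome protein as F/P/U from its disorder
#' fraction, counts its unique biotin sites inside IDRs, log2-transforms
#' the counts with a pseudo-count, and compares the classes.
#'
#' @inheritParams study_enrichment
#' @param pseudo pseudo-count for the log2 transform.
#' @param in_idr_only count only sites inside IDRs (the bean-plot
#'   quantity); set \code{FALSE} to count all sites.
#' @param welch use Welch pairwise t-tests.
#' @return list with per-protein \code{table} (accession, caller,
#'   fraction, class, biotin_count, log2_count) and the
#'   \code{class_comparison} in \code{$comparison}.
#' @export
biotin_class_analysis <- function(sites, proteome, idrsets, study = NULL,
                                  pseudo = 0.5, in_idr_only = TRUE,
                                  welch = TRUE) {
  sites <- sites[sites$modification == "biotin", , drop = FALSE]
  if (!is.null(study))
    sites <- sites[sites$study_id == study, , drop = FALSE]
  sites <- sites[sites$accession %in% names(idrsets), , drop = FALSE]
  if (nrow(sites) == 0L) stop("no biotin sites in scope")
  acc <- unique(sites$accession)
  counts <- vapply(acc, function(a) {
    p <- sites$position[sites$accession == a]
    if (in_idr_only) sum(in_idr(idrsets[[a]], p)) else length(p)
  }, integer(1))
  frac <- vapply(acc, function(a) disorder_fraction(idrsets[[a]]),
                 numeric(1))
  tab <- data.frame(accession = acc,
                    caller = vapply(idrsets[acc], `[[`, character(1),
                                    "caller"),
                    fraction = frac, class = classify_protein(frac),
                    biotin_count = counts,
                    log2_count = log2_counts(counts, pseudo),
                    row.names = NULL)
  cmp <- compare_classes(split(tab$log2_count, tab$class), welch = welch)
  list(table = tab, comparison = cmp)
}
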