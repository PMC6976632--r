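# 70S biotin-painting time course: peptide-level TMT reporter
# intensities at 10 s / 120 s / 300 s in triplicate plus a 1 h carrier
# channel. Deliberately NOT median-normalised by default: the fraction of
# biotinylated peptides genuinely differs between the early and late
# channels, and equalizing medians would erase that signal.

TMT_CONDITIONS <- c("10s", "120s", "300s")

#' Read a TMT peptide-intensity matrix
#'
#' TSV with metadata columns \code{peptide_id}, \code{accession},
#' \code{site}, \code{is_biotinylated}, \code{is_ribosomal} and channel
#' columns named \code{<condition>_<replicate>} (e.g. \code{10s_1} ...
#' \code{300s_3}, \code{carrier_1}).
#'
#' @param path input TSV.
#' @return a \code{tmt_matrix} data frame.
#' @export
read_tmt <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  as_tmt_matrix(d)
}

#' Validate a TMT matrix data frame
#' @param d data frame in the layout described in [read_tmt()].
#' @return a \code{tmt_matrix}.
#' @export
as_tmt_matrix <- function(d) {
  need <- c("peptide_id", "accession", "site", "is_biotinylated",
            "is_ribosomal")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("TMT matrix missing column(s): ",
                         paste(miss, collapse = ", "))
  ch <- grep("^[A-Za-z0-9]+_[0-9]+$", names(d), value = TRUE)
  conds <- unique(sub("_[0-9]+$", "", ch))
  for (cond in TMT_CONDITIONS)
    if (sum(startsWith(ch, paste0(cond, "_"))) < 2L)
      stop("need replicate channels for condition ", cond)
  for (cc in ch) {
    if (any(!is.na(d[[cc]]) & d[[cc]] <= 0))
      stop("reporter intensities must be positive (channel ", cc, ")")
  }
  d$is_biotinylated <- as.logical(d$is_biotinylated)
  d$is_ribosomal <- as.logical(d$is_ribosomal)
  attr(d, "channels") <- ch
  class(d) <- c("tmt_matrix", "data.frame")
  d
}

channel_cols <- function(tmt, condition) {
  grep(sprintf("^%s_[0-9]+$", condition), names(tmt), value = TRUE)
}

#' Filter a TMT matrix for the time-course test
#'
#' Removes peptides with any missing value in a required (non-carrier)
#' channel, non-biotinylated peptides and non-ribosomal peptides, and
#' drops the carrier channels (the 1 h timepoint is a carrier reference,
#' excluded from statistics). No median normalization is applied unless
#' \code{normalize = TRUE}.
#'
#' @param tmt a \code{tmt_matrix}.
#' @param normalize equalize per-channel medians (off by default, and
#'   deliberately so; see the package vignette).
#' @return the filtered \code{tmt_matrix}; per-reason removal counts in
#'   \code{attr(, "filter_report")}.
#' @export
filter_peptides <- function(tmt, normalize = FALSE) {
  stopifnot(inherits(tmt, "tmt_matrix"))
  req <- unlist(lapply(TMT_CONDITIONS, channel_cols, tmt = tmt))
  carrier <- setdiff(attr(tmt, "channels"), req)
  missing_any <- rowSums(is.na(as.matrix(tmt[req]))) > 0L
  reason <- rep(NA_character_, nrow(tmt))
  reason[!tmt$is_ribosomal] <- "non_ribosomal"
  reason[!tmt$is_biotinylated] <- "non_biotinylated"
  reason[missing_any] <- "missing_value"   # highest precedence
  report <- c(input = nrow(tmt),
              missing_value = sum(reason == "missing_value", na.rm = TRUE),
              non_biotinylated = sum(reason == "non_biotinylated",
                                     na.rm = TRUE),
              non_ribosomal = sum(reason == "non_ribosomal", na.rm = TRUE))
  keep <- is.na(reason)
  report <- c(report, retained = sum(keep))
  if (!any(keep))
    stop("no peptides survive filtering (",
         paste(names(report), report, sep = "=", collapse = ", "), ")")
  out <- tmt[keep, setdiff(names(tmt), carrier), drop = FALSE]
  if (normalize) {
    med <- vapply(out[req], stats::median, numeric(1))
    target <- exp(mean(log(med)))
    for (cc in req) out[[cc]] <- out[[cc]] * target / med[[cc]]
  }
  rownames(out) <- NULL
  attr(out, "channels") <- req
  attr(out, "filter_report") <- report
  class(out) <- c("tmt_matrix", "data.frame")
  out
}

#' Empirical-Bayes moderated t-test of a time-course contrast
#'
#' Per peptide: the mean log2 reporter-intensity difference between the
#' contrast condition and the 10 s reference, with the residual variance
#' shrunk toward an empirical-Bayes prior (d0, s0^2) estimated from the
#' ensemble of per-peptide variances by moment matching on log variances
#' (\code{limma::squeezeVar}); the moderated t uses the posterior
#' variance \code{(d0 s0^2 + dg s2) / (d0 + dg)} and d0 + dg degrees of
#' freedom, with Benjamini-Hochberg adjustment across peptides.
#'
#' @param tmt a filtered \code{tmt_matrix}.
#' @param contrast \code{"120s"} or \code{"300s"} (always against 10 s).
#' @param d0 prior degrees of freedom; \code{NULL} (default) estimates
#'   them empirically. \code{d0 = 0} reproduces the ordinary two-sample
#'   t-test; \code{d0 = Inf} shrinks every variance fully to s0^2.
#' @param s0_sq prior variance; \code{NULL} estimates it empirically
#'   (required only when a finite non-zero or infinite \code{d0} is
#'   forced).
#' @param log2 test on the log2 scale (default; the variance model
#'   assumes multiplicative reporter noise). \code{FALSE} is a
#'   linear-scale sensitivity mode.
#' @return a \code{moderated_tests} data frame: \code{peptide_id},
#'   \code{logFC}, \code{t_mod}, \code{df}, \code{p}, \code{p_adj}.
#' @export
moderated_test <- function(tmt, contrast = c("120s", "300s"), d0 = NULL,
                           s0_sq = NULL, log2 = TRUE) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(tmt, "tmt_matrix"))
  if (nrow(tmt) < 2L) stop("need at least 2 peptides")
  a_cols <- channel_cols(tmt, "10s")
  b_cols <- channel_cols(tmt, contrast)
  if (length(a_cols) < 2L || length(b_cols) < 2L)
    stop("need >= 2 replicates per condition")
  a <- as.matrix(tmt[a_cols]); b <- as.matrix(tmt[b_cols])
  if (anyNA(a) || anyNA(b)) stop("missing values present; run filter_peptides()")
  if (log2) { a <- log2(a); b <- log2(b) }
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  diff <- mb - ma
  dg <- na + nb - 2L
  s2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / dg

  if (is.null(d0)) {
    sq <- limma::squeezeVar(s2, df = dg)
    d0 <- sq$df.prior; s0_sq <- sq$var.prior; s2_post <- sq$var.post
  } else {
    if (d0 > 0 && is.null(s0_sq))
      s0_sq <- limma::squeezeVar(s2, df = dg)$var.prior
    s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
               else if (d0 == 0) s2
               else (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- diff / se
  # total df is capped at the pooled residual df of the ensemble (as in
  # limma): beyond that the prior cannot add information
  df <- min(d0 + dg, nrow(tmt) * dg)
  p <- 2 * stats::pt(-abs(t_mod), df = df)
  out <- data.frame(peptide_id = tmt$peptide_id, logFC = diff,
                    t_mod = t_mod, df = rep_len(df, length(t_mod)),
                    p = p, p_adj = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  attr(out, "contrast") <- paste0(contrast, "-10s")
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("moderated_tests", "data.frame")
  out
}

#' Classify peptides as early or late biotinylation events
#'
#' A peptide is a late biotinylation event iff some contrast shows a
#' significant increase over 10 s: adjusted p strictly below
#' \code{alpha} AND a positive log fold change. Everything else is
#' early. The partition is exhaustive and exclusive.
#'
#' @param ... one or more \code{moderated_tests} results (one per
#'   contrast) over the same peptides.
#' @param alpha significance threshold on the adjusted p-value (strict
#'   inequality).
#' @return data frame \code{peptide_id}, \code{label} (early/late),
#'   \code{triggered_by} (comma-joined contrasts, "" for early).
#' @export
classify_kinetics <- function(..., alpha = 0.05) {
  tests <- list(...)
  if (length(tests) == 1L && is.list(tests[[1L]]) &&
      !inherits(tests[[1L]], "data.frame"))
    tests <- tests[[1L]]
  stopifnot(length(tests) >= 1L)
  ids <- tests[[1L]]$peptide_id
  trig <- matrix(FALSE, length(ids), length(tests))
  for (j in seq_along(tests)) {
    tj <- tests[[j]]
    stopifnot(identical(tj$peptide_id, ids))
    trig[, j] <- tj$p_adj < alpha & tj$logFC > 0
  }
  labels <- vapply(seq_along(tests), function(j)
    attr(tests[[j]], "contrast") %||% paste0("contrast", j), character(1))
  late <- rowSums(trig) > 0L
  data.frame(peptide_id = ids,
             label = factor(ifelse(late, "late", "early"),
                            levels = c("early", "late")),
             triggered_by = apply(trig, 1L, function(z)
               paste(labels[z], collapse = ",")),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-shot time-course analysis
#'
#' Filter, test both contrasts (120 s and 300 s vs 10 s) and classify
#' peptides as early or late.
#'
#' @inheritParams filter_peptides
#' @inheritParams classify_kinetics
#' @param ... passed to [moderated_test()].
#' @return list with \code{filtered}, \code{tests} (per contrast) and
#'   \code{kinetics}.
#' @export
run_timecourse <- function(tmt, alpha = 0.05, normalize = FALSE, ...) {
  flt <- filter_peptides(tmt, normalize = normalize)
  tests <- lapply(c("120s", "300s"), function(ct)
    moderated_test(flt, contrast = ct, ...))
  names(tests) <- c("120s", "300s")
  list(filtered = flt, tests = tests,
       kinetics = classify_kinetics(tests, alpha = alpha))
}
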