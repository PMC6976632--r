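# Bias-corrected category (GO) enrichment. Protein detection in a
# proximity-labelling experiment depends on abundance; a category whose
# members are abundant looks spuriously enriched under Fisher's exact
# test. Following the goseq idea, a monotone probability weighting
# function (PWF) of biotinome membership against a per-protein bias
# factor (expression) supplies odds for the Wallenius noncentral
# hypergeometric test.

#' Fit a probability weighting function by isotonic regression
#'
#' Monotone non-decreasing regression of set membership on the bias
#' factor (weighted pool-adjacent-violators on the distinct bias values,
#' so tied bias values share one pooled probability). Fitted
#' probabilities are floored at a small epsilon to keep weights strictly
#' positive.
#'
#' @param membership logical (or 0/1) vector: is the protein in the set?
#' @param bias positive per-protein bias factor (e.g. expression).
#' @param eps positive floor for the fitted probabilities.
#' @return a \code{pwf}: list with per-protein \code{weights} (aligned
#'   with the input) and the fitted step function \code{knots}.
#' @export
fit_pwf <- function(membership, bias, eps = 1e-6) {
  membership <- as.numeric(membership)
  stopifnot(length(membership) == length(bias),
            all(membership %in% c(0, 1)))
  if (length(bias) < 10L) stop("need at least 10 proteins to fit a PWF")
  if (any(bias <= 0)) stop("bias factors must be positive")
  ub <- sort(unique(bias))
  if (length(ub) == 1L)
    message("constant bias factor: uniform weights (central hypergeometric)")
  y <- vapply(split(membership, factor(bias, levels = ub)), mean,
              numeric(1))
  w <- as.numeric(table(factor(bias, levels = ub)))
  fit <- pava(y, w)
  fitted <- pmax(fit, eps)
  weights <- fitted[match(bias, ub)]
  structure(list(weights = weights,
                 knots = data.frame(bias = ub, fitted = fitted)),
            class = "pwf")
}

# weighted pool-adjacent-violators: monotone non-decreasing fit
pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-15) {
      nw <- wt[i] + wt[i + 1L]
      nv <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) / nw
      val[i] <- nv; wt[i] <- nw
      idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx <- idx[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  out <- numeric(n)
  for (j in seq_along(val)) out[idx[[j]]] <- val[j]
  out
}

#' @export
print.pwf <- function(x, ...) {
  cat(sprintf("PWF over %d proteins: %d distinct bias values, fitted range [%.4g, %.4g]\n",
              length(x$weights), nrow(x$knots), min(x$knots$fitted),
              max(x$knots$fitted)))
  invisible(x)
}

# Wallenius noncentral hypergeometric pmf over 0..n white draws, by the
# exact sequential-draw recursion: after j draws with i white drawn, the
# next draw is white with probability odds*(m1-i) / (odds*(m1-i) + m2-(j-i)).
wallenius_pmf_recursion <- function(m1, m2, n, odds) {
  p <- 1
  for (j in seq_len(n) - 1L) {
    i <- 0:j
    wrem <- pmax(m1 - i, 0L)
    brem <- pmax(m2 - (j - i), 0L)
    denom <- odds * wrem + brem
    pw <- ifelse(denom > 0, odds * wrem / denom, 0)
    pnew <- numeric(j + 2L)
    pnew[i + 2L] <- pnew[i + 2L] + p * pw
    pnew[i + 1L] <- pnew[i + 1L] + p * (1 - pw)
    p <- pnew
  }
  p
}

# Single Wallenius pmf value by the integral representation
#   f(k) = C(m1,k) C(m2,n-k) D int_0^1 (1-u^odds)^k (1-u)^(n-k) u^(D-1) du
# with D the total weight of the undrawn items (the substitution t = u^D
# of Fog's form, which keeps the integrand polynomially behaved). The
# integral is split at the peak of its dominant factor and evaluated on a
# log scale to survive large populations.
wallenius_pmf_integral <- function(k, m1, m2, n, odds) {
  if (k < max(0L, n - m2) || k > min(n, m1)) return(0)
  D <- odds * (m1 - k) + (m2 - (n - k))
  if (D <= 0) { # all items drawn; point mass
    return(as.numeric(k == m1 && (n - k) == m2))
  }
  lg <- function(u) {
    out <- rep(-Inf, length(u))
    inside <- u > 0 & u < 1
    ui <- u[inside]
    out[inside] <- k * log1p(-ui^odds) + (n - k) * log1p(-ui) +
      (D - 1) * log(ui)
    out
  }
  opt <- stats::optimize(lg, c(0, 1), maximum = TRUE, tol = 1e-10)
  u_peak <- min(max(opt$maximum, 1e-12), 1 - 1e-12)
  lmax <- opt$objective
  f <- function(u) exp(lg(u) - lmax)
  int <- stats::integrate(f, 0, u_peak, rel.tol = 1e-10,
                          subdivisions = 1000L)$value +
         stats::integrate(f, u_peak, 1, rel.tol = 1e-10,
                          subdivisions = 1000L)$value
  exp(lchoose(m1, k) + lchoose(m2, n - k) + log(D) + lmax) * int
}

#' Wallenius noncentral hypergeometric over-representation tail
#'
#' P(X >= category_in) when \code{sample_size} items are drawn without
#' replacement from a population of \code{population} items of which
#' \code{category_size} are in the category, each category item having
#' sampling weight \code{odds} relative to non-category items. Computed
#' by the exact sequential-draw recursion for populations up to 2000 and
#' by numerical integration of Fog's integral representation above that
#' (the two agree to ~1e-9 on overlapping ranges).
#'
#' @param category_in observed in-sample category count.
#' @param category_size category size in the population.
#' @param sample_size number of draws.
#' @param population population size.
#' @param odds positive weight ratio category : non-category.
#' @param method computation method; \code{"auto"} picks by population.
#' @return the upper-tail p-value.
#' @export
wallenius_p <- function(category_in, category_size, sample_size,
                        population, odds = 1,
                        method = c("auto", "recursion", "integral")) {
  method <- match.arg(method)
  k <- as.integer(category_in); m1 <- as.integer(category_size)
  n <- as.integer(sample_size); N <- as.integer(population)
  m2 <- N - m1
  if (m1 < 0 || m2 < 0 || n < 0 || n > N || k < 0 || k > min(n, m1) ||
      (n - k) > m2)
    stop("impossible contingency margins")
  stopifnot(odds > 0)
  if (k <= max(0L, n - m2)) return(1)
  if (method == "auto") method <- if (N <= 2000L) "recursion" else "integral"
  if (method == "recursion") {
    pmf <- wallenius_pmf_recursion(m1, m2, n, odds)
    min(1, sum(pmf[(k:n) + 1L]))
  } else {
    ks <- k:min(n, m1)
    min(1, sum(vapply(ks, wallenius_pmf_integral, numeric(1),
                      m1 = m1, m2 = m2, n = n, odds = odds)))
  }
}

#' Bias-corrected GO category enrichment
#'
#' Tests every category of at least \code{min_category} annotated
#' proteins for over-representation in the biotinome. With
#' \code{correct_bias = TRUE} a PWF is fitted to the bias factor and the
#' Wallenius odds for each category are the mean fitted weight of its
#' members over the mean fitted weight of non-members; with
#' \code{correct_bias = FALSE} odds are 1 and the test reduces to the
#' central hypergeometric (Fisher) tail. Unannotated proteins are
#' excluded from the population. Benjamini-Hochberg adjustment across
#' tested categories.
#'
#' @param annotations data frame with columns \code{accession},
#'   \code{term}.
#' @param biotinome character vector of member accessions.
#' @param bias named positive numeric vector of per-protein bias factors
#'   (names are accessions), or a vector aligned with \code{universe}.
#' @param universe population accessions; defaults to all annotated
#'   proteins.
#' @param min_category smallest category size tested.
#' @param correct_bias apply the PWF/Wallenius correction.
#' @return a \code{go_results} data frame: \code{term}, \code{k},
#'   \code{category_size}, \code{odds}, \code{fold}, \code{p},
#'   \code{p_adj}, sorted by p.
#' @export
go_test <- function(annotations, biotinome, bias, universe = NULL,
                    min_category = 3L, correct_bias = TRUE) {
  stopifnot(all(c("accession", "term") %in% names(annotations)))
  if (length(biotinome) == 0L) stop("empty biotinome")
  if (is.null(universe)) universe <- unique(annotations$accession)
  annotated <- intersect(universe, unique(annotations$accession))
  population <- annotated
  N <- length(population)
  if (N == 0L) stop("no annotated proteins in the universe")
  member <- population %in% biotinome
  n <- sum(member)
  if (n == 0L) stop("biotinome does not intersect the annotated universe")

  if (correct_bias) {
    if (!is.null(names(bias))) {
      if (!all(population %in% names(bias)))
        stop("bias factors missing for some population proteins")
      bias <- bias[population]
    } else {
      stopifnot(length(bias) == length(universe))
      bias <- bias[match(population, universe)]
    }
    w <- fit_pwf(member, as.numeric(bias))$weights
  } else {
    w <- rep(1, N)
  }

  ann <- annotations[annotations$accession %in% population, , drop = FALSE]
  terms <- split(ann$accession, ann$term)
  terms <- lapply(terms, unique)
  terms <- terms[vapply(terms, length, integer(1)) >= min_category]
  if (length(terms) == 0L)
    stop("no category reaches min_category = ", min_category)

  rows <- lapply(names(terms), function(tm) {
    in_cat <- population %in% terms[[tm]]
    m1 <- sum(in_cat)
    if (m1 == N) return(NULL)  # category spanning the population: untestable
    k <- sum(in_cat & member)
    odds <- mean(w[in_cat]) / mean(w[!in_cat])
    data.frame(term = tm, k = k, category_size = m1,
               sample_size = n, population = N, odds = odds,
               fold = (k / n) / (m1 / N),
               p = wallenius_p(k, m1, n, N, odds))
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, -res$fold), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "correct_bias") <- correct_bias
  class(res) <- c("go_results", "data.frame")
  res
}
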