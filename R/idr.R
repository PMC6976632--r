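# IDR interval sets: sorted, non-overlapping, non-adjacent 1-based
# inclusive intervals on one protein. No minimum-length filter is ever
# applied -- an IDR may be a single residue.

#' Construct an IDR interval set
#'
#' Intervals are normalized on construction: sorted by start, overlapping
#' and adjacent intervals merged.
#'
#' @param accession protein accession.
#' @param start,end integer vectors of 1-based inclusive interval bounds.
#' @param length protein length in residues.
#' @param caller label of the disorder caller that produced the set.
#' @return an \code{idr_set}.
#' @export
idr_set <- function(accession, start = integer(), end = integer(),
                    length, caller = "unknown") {
  stopifnot(length(start) == length(end), length >= 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start))
    stop("intervals must satisfy 1 <= start <= end")
  if (any(end > length))
    stop("interval end ", max(end), " beyond protein length ", length)
  iv <- normalize_intervals(start, end)
  structure(list(accession = accession, start = iv$start, end = iv$end,
                 length = as.integer(length), caller = caller),
            class = "idr_set")
}

# merge sorted overlapping/adjacent intervals
normalize_intervals <- function(start, end) {
  if (length(start) == 0L)
    return(list(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ns <- start[1L]; ne <- end[1L]
  os <- integer(); oe <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ne + 1L) {
      ne <- max(ne, end[i])
    } else {
      os <- c(os, ns); oe <- c(oe, ne)
      ns <- start[i]; ne <- end[i]
    }
  }
  list(start = c(os, ns), end = c(oe, ne))
}

#' @export
print.idr_set <- function(x, ...) {
  cat(sprintf("IDR set for %s (caller %s, length %d): %d interval(s), %.1f%% disordered\n",
              x$accession, x$caller, x$length, length(x$start),
              100 * disorder_fraction(x)))
  if (length(x$start))
    cat(paste0("  [", x$start, ", ", x$end, "]", collapse = " "), "\n")
  invisible(x)
}

#' Binarize a per-residue disorder track into an IDR set
#'
#' Residue i is called disordered iff \code{values[i] >= threshold};
#' maximal runs of disordered residues become intervals. No minimum IDR
#' length is imposed (length-1 IDRs are legitimate calls: sensitivity is
#' preferred over specificity).
#'
#' @param values dense numeric per-residue track in [0,1] (binary tracks
#'   are a special case).
#' @param accession protein accession.
#' @param caller caller label to record.
#' @param threshold disorder-probability cutoff, default 0.5.
#' @return an \code{idr_set}.
#' @export
binarize_track <- function(values, accession = "protein",
                           caller = "track", threshold = 0.5) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            threshold >= 0, threshold <= 1)
  if (anyNA(values)) stop("track contains missing values")
  mask <- values >= threshold
  iv <- mask_to_intervals(mask)
  idr_set(accession, iv$start, iv$end, length(values), caller)
}

mask_to_intervals <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], end = ends[keep])
}

#' Expand an IDR set to a per-residue logical mask
#' @param idr an \code{idr_set}.
#' @return logical vector of length \code{idr$length}.
#' @export
idr_mask <- function(idr) {
  m <- logical(idr$length)
  for (i in seq_along(idr$start)) m[idr$start[i]:idr$end[i]] <- TRUE
  m
}

#' Residue-level union of two IDR sets
#'
#' A residue is in the union iff either caller marks it disordered
#' (an IDR accepted if called by one or both predictors).
#'
#' @param a,b \code{idr_set}s for the same protein.
#' @return an \code{idr_set} labelled \code{"<a>_<b>"}.
#' @export
combine_union <- function(a, b) {
  stopifnot(inherits(a, "idr_set"), inherits(b, "idr_set"))
  if (a$accession != b$accession)
    stop("accession mismatch: ", a$accession, " vs ", b$accession)
  if (a$length != b$length)
    stop("protein length mismatch for ", a$accession)
  idr_set(a$accession, c(a$start, b$start), c(a$end, b$end), a$length,
          paste(a$caller, b$caller, sep = "_"))
}

#' Quorum consensus of several IDR sets
#'
#' A residue is consensus-disordered iff at least a fraction
#' \code{quorum} of the supplied callers mark it disordered (inclusive
#' comparison, so 75\% of nine callers means >= 7 of 9). The denominator is
#' the number of callers supplied for this protein.
#'
#' @param idrs list of \code{idr_set}s for one protein.
#' @param quorum required fraction of callers in (0, 1]; \code{quorum = 1}
#'   is the residue-level intersection.
#' @return an \code{idr_set} labelled \code{"consensus<percent>"}.
#' @export
combine_consensus <- function(idrs, quorum = 0.75) {
  if (length(idrs) == 0L) stop("consensus requires at least one predictor")
  stopifnot(quorum > 0, quorum <= 1)
  acc <- unique(vapply(idrs, `[[`, character(1), "accession"))
  len <- unique(vapply(idrs, `[[`, integer(1), "length"))
  if (length(acc) != 1L || length(len) != 1L)
    stop("consensus inputs must describe one protein")
  counts <- Reduce(`+`, lapply(idrs, function(x) as.integer(idr_mask(x))))
  mask <- counts / length(idrs) >= quorum
  iv <- mask_to_intervals(mask)
  idr_set(acc, iv$start, iv$end, len,
          sprintf("consensus%d", as.integer(round(quorum * 100))))
}

#' Fraction of a protein covered by IDRs
#' @param idr an \code{idr_set}.
#' @return real in [0, 1]: covered residues / protein length.
#' @export
disorder_fraction <- function(idr) {
  stopifnot(inherits(idr, "idr_set"))
  if (length(idr$start) == 0L) return(0)
  sum(idr$end - idr$start + 1L) / idr$length
}

#' Is a residue position inside an IDR?
#'
#' Vectorized membership lookup by binary search over the sorted interval
#' starts; interval ends are inclusive.
#'
#' @param idr an \code{idr_set}.
#' @param position integer vector of 1-based residue positions.
#' @return logical vector.
#' @export
in_idr <- function(idr, position) {
  stopifnot(inherits(idr, "idr_set"))
  position <- as.integer(position)
  if (length(position) == 0L) return(logical())
  if (any(position < 1L | position > idr$length))
    stop("position out of range 1..", idr$length)
  if (length(idr$start) == 0L) return(rep(FALSE, length(position)))
  i <- findInterval(position, idr$start)
  i > 0L & position <= idr$end[pmax(i, 1L)]
}

#' Call IDR sets for a whole proteome
#'
#' Applies one caller-selection policy to the disorder tracks of every
#' protein that has predictions: a single named predictor, the residue
#' union of a pair of predictors, or the quorum consensus over all
#' available predictors.
#'
#' @param tracks as returned by [read_disorder_tracks()].
#' @param caller a predictor label present in the tracks, \code{"union"},
#'   or \code{"consensus"}.
#' @param predictors for \code{caller = "union"}: the two predictor labels
#'   to combine (default the first two of each protein).
#' @param quorum consensus quorum fraction.
#' @param threshold binarization threshold for score tracks.
#' @return named list of \code{idr_set}, one per protein with tracks.
#' @export
call_idrs <- function(tracks, caller = "union", predictors = NULL,
                      quorum = 0.75, threshold = 0.5) {
  out <- lapply(names(tracks), function(acc) {
    tr <- tracks[[acc]]
    sets <- lapply(names(tr), function(p)
      binarize_track(tr[[p]], acc, p, threshold))
    names(sets) <- names(tr)
    if (caller == "consensus") {
      combine_consensus(sets, quorum)
    } else if (caller == "union") {
      pr <- if (is.null(predictors)) names(sets)[1:2] else predictors
      if (anyNA(pr) || !all(pr %in% names(sets)))
        stop("union predictors not available for ", acc)
      combine_union(sets[[pr[[1L]]]], sets[[pr[[2L]]]])
    } else {
      if (!caller %in% names(sets))
        stop("no track for caller '", caller, "' on ", acc)
      sets[[caller]]
    }
  })
  names(out) <- names(tracks)
  out
}

#' Export IDR sets as a TSV interval table
#' @param idrsets named list of \code{idr_set}.
#' @param path output path.
#' @export
write_idr_sets <- function(idrsets, path) {
  rows <- lapply(idrsets, function(x) {
    if (length(x$start) == 0L) return(NULL)
    data.frame(accession = x$accession, caller = x$caller,
               start = x$start, end = x$end)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Disorder fractions for a set of proteins
#' @param idrsets named list of \code{idr_set}.
#' @return data frame \code{accession}, \code{caller}, \code{fraction}.
#' @export
disorder_fractions <- function(idrsets) {
  data.frame(accession = vapply(idrsets, `[[`, character(1), "accession"),
             caller = vapply(idrsets, `[[`, character(1), "caller"),
             fraction = vapply(idrsets, disorder_fraction, numeric(1)),
             row.names = NULL)
}
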