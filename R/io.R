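# 20-letter amino-acid alphabet; all coordinates in this package are 1-based
# and intervals inclusive on both ends (UniProt/PDB convention).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

SITE_MODIFICATIONS <- c("biotin", "phospho", "ubiquitination",
                        "acetylation", "sumoylation")

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a proteome table. The accession is the first
#' whitespace-delimited token of each header; with
#' \code{uniprot_accession = TRUE} the second pipe-delimited field of
#' UniProt-style headers (\code{sp|ACC|NAME desc}) is used instead.
#'
#' @param path path to a FASTA file.
#' @param uniprot_accession extract the accession from UniProt-style
#'   pipe-delimited headers.
#' @return a \code{proteome} data frame with columns \code{accession},
#'   \code{description}, \code{sequence} (upper case) and \code{length}.
#' @export
read_fasta <- function(path, uniprot_accession = FALSE) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  first_tok <- sub("\\s.*$", "", headers)
  accession <- first_tok
  if (uniprot_accession) {
    has_pipe <- grepl("\\|", first_tok)
    accession[has_pipe] <-
      vapply(strsplit(first_tok[has_pipe], "|", fixed = TRUE),
             function(x) if (length(x) >= 2L) x[[2L]] else x[[1L]],
             character(1))
  }
  description <- sub("^\\S+\\s*", "", headers)
  sequence <- toupper(as.character(aa))
  proteome(accession, sequence, description)
}

#' Construct a proteome table
#'
#' @param accession character vector of unique protein accessions.
#' @param sequence upper-case amino-acid sequences.
#' @param description optional free-text descriptions (protein names).
#' @return a \code{proteome} data frame.
#' @export
proteome <- function(accession, sequence, description = "") {
  stopifnot(length(accession) == length(sequence))
  sequence <- toupper(sequence)
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0L)
    stop("duplicate accession ", dup[[1L]])
  if (any(!nzchar(sequence))) stop("empty sequence for accession ",
                                   accession[!nzchar(sequence)][[1L]])
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                 sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[[1L]]
    stop(sprintf("non-amino-acid character '%s' at position %d of %s",
                 substr(sequence[[i]], bad[[i]], bad[[i]]), bad[[i]],
                 accession[[i]]))
  }
  out <- data.frame(accession = accession,
                    description = rep_len(description, length(accession)),
                    sequence = sequence,
                    length = nchar(sequence),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$accession
  class(out) <- c("proteome", "data.frame")
  out
}

#' Write a proteome to FASTA
#' @param prot a \code{proteome}.
#' @param path output path.
#' @export
write_fasta <- function(prot, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(prot$sequence, ifelse(
    nzchar(prot$description),
    paste(prot$accession, prot$description), prot$accession)))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' The default proximity-labelling study registry
#'
#' The four re-analysed in vivo biotinylation studies and the residue each
#' chemistry targets: APEX2 biotin-phenol labels tyrosines, BirA and
#' NHS-biotin acylate lysines.
#'
#' @return a \code{study_registry} data frame with columns \code{study_id},
#'   \code{target_residue}, \code{chemistry} and
#'   \code{activated_biotin_conc_uM} (upper bound where the source reports
#'   an inequality).
#' @export
default_study_registry <- function() {
  load_study_registry(data.frame(
    study_id = c("BioSITe", "Ab-APEX", "DiDBiT", "SpotBioID"),
    target_residue = c("Y", "Y", "K", "K"),
    chemistry = c("APEX2", "APEX2", "NHS-Biotin", "BirA"),
    activated_biotin_conc_uM = c(50, 500, 1000, 50),
    stringsAsFactors = FALSE))
}

#' Validate and load a study registry
#'
#' @param config a data frame with columns \code{study_id},
#'   \code{target_residue} and \code{chemistry} (and optionally
#'   \code{activated_biotin_conc_uM}), or \code{NULL} for the built-in
#'   default registry.
#' @return a validated \code{study_registry}.
#' @export
load_study_registry <- function(config = NULL) {
  if (is.null(config)) return(default_study_registry())
  config <- as.data.frame(config, stringsAsFactors = FALSE)
  need <- c("study_id", "target_residue", "chemistry")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("registry missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"activated_biotin_conc_uM" %in% names(config))
    config$activated_biotin_conc_uM <- NA_real_
  bad <- setdiff(config$target_residue, c("K", "Y"))
  if (length(bad)) stop("target_residue must be K or Y, got: ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(config$study_id))
    stop("duplicate study_id in registry")
  rownames(config) <- config$study_id
  class(config) <- c("study_registry", "data.frame")
  config
}

#' Validate a table of modification sites
#'
#' Core validation used by [read_site_table()]: checks each record against
#' the proteome coordinate frame, drops (or, with \code{strict = TRUE},
#' aborts on) records whose residue letter disagrees with the sequence or
#' whose accession is unknown, and deduplicates on
#' (study_id, accession, position, modification) -- unique sites are the
#' unit every downstream count uses.
#'
#' @param sites data frame with columns \code{study_id}, \code{accession},
#'   \code{position}, \code{residue}, \code{modification}.
#' @param proteome a \code{proteome}.
#' @param registry optional \code{study_registry}; when given, biotin sites
#'   whose residue is not the study's target residue are also dropped.
#' @param strict abort instead of dropping invalid records.
#' @return a \code{site_table} data frame; the per-reason drop counts are in
#'   \code{attr(, "validation")}.
#' @export
validate_site_table <- function(sites, proteome, registry = NULL,
                                strict = FALSE) {
  need <- c("study_id", "accession", "position", "residue", "modification")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  sites <- as.data.frame(sites)[need]
  pos_num <- suppressWarnings(as.numeric(sites$position))
  bad <- which(is.na(pos_num) | pos_num < 1 | pos_num != floor(pos_num))
  if (length(bad))
    stop(sprintf("invalid position '%s' at line %d",
                 as.character(sites$position[bad[[1L]]]), bad[[1L]] + 1L))
  sites$position <- as.integer(pos_num)
  bad_mod <- setdiff(unique(sites$modification), SITE_MODIFICATIONS)
  if (length(bad_mod))
    stop("unknown modification type(s): ", paste(bad_mod, collapse = ", "),
         "; supported: ", paste(SITE_MODIFICATIONS, collapse = ", "))

  report <- c(input = nrow(sites), unknown_accession = 0L,
              position_out_of_range = 0L, residue_mismatch = 0L,
              target_residue_mismatch = 0L, duplicate = 0L, retained = 0L)
  drop_or_stop <- function(keep, reason, sites) {
    n <- sum(!keep)
    if (n > 0L) {
      if (strict)
        stop(sprintf("%d site(s) failed validation (%s), e.g. %s:%d",
                     n, reason, sites$accession[!keep][[1L]],
                     sites$position[!keep][[1L]]))
      warning(sprintf("dropping %d site(s): %s", n, reason), call. = FALSE)
    }
    n
  }

  known <- sites$accession %in% proteome$accession
  report[["unknown_accession"]] <- drop_or_stop(known, "unknown accession",
                                                sites)
  sites <- sites[known, , drop = FALSE]

  plen <- proteome$length[match(sites$accession, proteome$accession)]
  inrange <- sites$position <= plen
  report[["position_out_of_range"]] <-
    drop_or_stop(inrange, "position out of range", sites)
  sites <- sites[inrange, , drop = FALSE]

  seqs <- proteome$sequence[match(sites$accession, proteome$accession)]
  actual <- substr(seqs, sites$position, sites$position)
  okres <- actual == sites$residue
  report[["residue_mismatch"]] <- drop_or_stop(okres, "residue mismatch",
                                               sites)
  sites <- sites[okres, , drop = FALSE]

  if (!is.null(registry)) {
    is_biotin <- sites$modification == "biotin"
    target <- registry$target_residue[match(sites$study_id,
                                            registry$study_id)]
    ok <- !is_biotin | (!is.na(target) & sites$residue == target)
    report[["target_residue_mismatch"]] <-
      drop_or_stop(ok, "biotin site not on the study's target residue",
                   sites)
    sites <- sites[ok, , drop = FALSE]
  }

  dup <- duplicated(sites[c("study_id", "accession", "position",
                            "modification")])
  report[["duplicate"]] <- sum(dup)
  sites <- sites[!dup, , drop = FALSE]

  report[["retained"]] <- nrow(sites)
  rownames(sites) <- NULL
  attr(sites, "validation") <- report
  class(sites) <- c("site_table", "data.frame")
  sites
}

#' Read a modification site table
#'
#' Reads a tab-separated site table (columns \code{study_id},
#' \code{accession}, \code{position}, \code{residue}, \code{modification})
#' and validates it against the proteome via [validate_site_table()].
#'
#' @inheritParams validate_site_table
#' @param path path to a TSV file.
#' @return a validated \code{site_table}.
#' @export
read_site_table <- function(path, proteome, registry = NULL,
                            strict = FALSE) {
  stopifnot(file.exists(path))
  sites <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE,
                             colClasses = "character")
  validate_site_table(sites, proteome, registry, strict)
}

#' Write a site table
#' @param sites a \code{site_table}.
#' @param path output path.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("study_id", "accession", "position", "residue", "modification")
  utils::write.table(as.data.frame(sites)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue disorder prediction tracks
#'
#' Two dialects are supported. \code{"tsv"}: dense per-residue rows with
#' columns \code{accession}, \code{predictor}, \code{position},
#' \code{value} (scores in [0,1] or binary calls); every residue 1..length
#' must be present. \code{"d2p2-json"}: a JSON object
#' \code{{accession: {predictor: [[start, end], ...], "length": L}}} with
#' 1-based inclusive disorder intervals, expanded here to dense binary
#' tracks (residues outside any interval are 0).
#'
#' @param path input file.
#' @param proteome a \code{proteome} providing protein lengths.
#' @param dialect \code{"tsv"} or \code{"d2p2-json"}.
#' @return a named list (accession) of named lists (predictor) of numeric
#'   per-residue vectors.
#' @export
read_disorder_tracks <- function(path, proteome,
                                 dialect = c("tsv", "d2p2-json")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("accession", "predictor", "position", "value")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("track table missing column(s): ",
                           paste(miss, collapse = ", "))
    out <- list()
    for (acc in unique(d$accession)) {
      L <- protein_length(proteome, acc)
      da <- d[d$accession == acc, , drop = FALSE]
      out[[acc]] <- lapply(split(da, da$predictor), function(dp) {
        if (any(dp$position > L))
          stop(sprintf("position %d beyond length %d of %s",
                       max(dp$position), L, acc))
        v <- rep(NA_real_, L)
        v[dp$position] <- dp$value
        if (anyNA(v))
          stop(sprintf("track for %s/%s: missing residue %d", acc,
                       dp$predictor[[1L]], which(is.na(v))[[1L]]))
        if (any(v < 0 | v > 1))
          stop("disorder values must lie in [0,1]")
        v
      })
    }
    out
  } else {
    j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- list()
    for (acc in names(j)) {
      entry <- j[[acc]]
      L <- if (!is.null(entry[["length"]])) as.integer(entry[["length"]])
           else protein_length(proteome, acc)
      preds <- setdiff(names(entry), "length")
      out[[acc]] <- lapply(stats::setNames(preds, preds), function(p) {
        v <- numeric(L)
        for (iv in entry[[p]]) {
          s <- as.integer(iv[[1L]]); e <- as.integer(iv[[2L]])
          if (e > L || s < 1L || s > e)
            stop(sprintf("interval [%d,%d] invalid for %s (length %d)",
                         s, e, acc, L))
          v[s:e] <- 1
        }
        v
      })
    }
    out
  }
}

#' Write disorder tracks in the dense TSV dialect
#' @param tracks as returned by [read_disorder_tracks()].
#' @param path output path.
#' @export
write_disorder_tracks <- function(tracks, path) {
  rows <- lapply(names(tracks), function(acc) {
    do.call(rbind, lapply(names(tracks[[acc]]), function(p) {
      v <- tracks[[acc]][[p]]
      data.frame(accession = acc, predictor = p,
                 position = seq_along(v), value = v)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

protein_length <- function(proteome, acc) {
  i <- match(acc, proteome$accession)
  if (is.na(i)) stop("unknown accession ", acc)
  proteome$length[[i]]
}

protein_sequence <- function(proteome, acc) {
  i <- match(acc, proteome$accession)
  if (is.na(i)) stop("unknown accession ", acc)
  proteome$sequence[[i]]
}
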