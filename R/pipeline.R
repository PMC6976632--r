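# Pipeline orchestration: simulate inputs to disk, run all analysis
# stages in dependency order, write fixed-format TSV reports plus a
# manifest. All tables use a fixed column order and 6-significant-digit
# float formatting so reruns diff cleanly.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a full set of synthetic pipeline inputs to a directory
#'
#' Generates a proteome (FASTA), disorder tracks (dense TSV), biotin
#' sites for every registry study plus phospho/ubiquitination PTM sites
#' (site TSV), a TMT time-course matrix (TSV), GO annotations and bias
#' factors (TSVs), and a manifest recording the configuration and seed.
#' All stochastic components derive child seeds from the one global
#' seed, so reruns are byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer global seed.
#' @param n_proteins,disorder_fraction,rho,n_sites proteome / planting
#'   parameters (see [generate_proteome()] and [plant_sites()]).
#' @param n_ptm_sites planting draws per PTM type.
#' @param registry study registry to emulate; default the four-study
#'   registry of [default_study_registry()].
#' @param tmt,go named lists of overrides for [generate_tmt()] and
#'   [generate_go()].
#' @param ... further arguments to [generate_proteome()].
#' @return invisibly, the named list of file paths.
#' @export
simulate_inputs <- function(dir, seed, n_proteins = 200,
                            disorder_fraction = 0.3, rho = 3,
                            n_sites = 1000, n_ptm_sites = 500,
                            registry = default_study_registry(),
                            tmt = list(), go = list(), ...) {
  stopifnot(!missing(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_proteome(n_proteins = n_proteins,
                           disorder_fraction = disorder_fraction,
                           seed = seed, ...)
  idr_truth <- call_idrs(gen$tracks, caller = "VSL2b")
  site_tabs <- lapply(registry$study_id, function(st)
    plant_sites(gen$proteome, idr_truth,
                residues = registry$target_residue[
                  match(st, registry$study_id)],
                n_sites = n_sites, rho = rho, study_id = st, seed = seed))
  ptm_tabs <- lapply(c("phospho", "ubiquitination"), function(pt)
    plant_sites(gen$proteome, idr_truth, residues = ptm_background(pt),
                n_sites = n_ptm_sites, rho = rho, study_id = "PTMdb",
                modification = pt, seed = seed))
  sites <- do.call(rbind, c(lapply(site_tabs, as.data.frame),
                            lapply(ptm_tabs, as.data.frame)))
  tmt_mat <- do.call(generate_tmt, c(list(seed = seed), tmt))
  go_set <- do.call(generate_go,
                    c(list(accessions = gen$proteome$accession,
                           seed = seed), go))

  paths <- list(fasta = file.path(dir, "proteome.fasta"),
                tracks = file.path(dir, "tracks.tsv"),
                sites = file.path(dir, "sites.tsv"),
                tmt = file.path(dir, "tmt.tsv"),
                go_annotations = file.path(dir, "go_annotations.tsv"),
                go_bias = file.path(dir, "go_bias.tsv"),
                biotinome = file.path(dir, "go_biotinome.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_fasta(gen$proteome, paths$fasta)
  write_disorder_tracks(gen$tracks, paths$tracks)
  utils::write.table(sites, paths$sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(tmt_mat), paths$tmt, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(go_set$annotations, paths$go_annotations,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(accession = names(go_set$bias),
                                bias = go_set$bias),
                     paths$go_bias, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(accession = go_set$biotinome),
                     paths$biotinome, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(generator = "biotinpaint::simulate_inputs",
                            version = pkg_version(), seed = seed,
                            n_proteins = n_proteins,
                            disorder_fraction = disorder_fraction,
                            rho = rho, n_sites = n_sites,
                            n_ptm_sites = n_ptm_sites),
                       paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

pkg_version <- function() {
  as.character(utils::packageVersion("biotinpaint"))
}

#' Read a key-value run configuration file
#'
#' Lines of \code{key: value} or \code{key = value}; \code{#} starts a
#' comment. Values are coerced to numeric or logical where possible.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- m[[2L]]; val <- trimws(m[[3L]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (toupper(val) %in% c("TRUE", "FALSE"))
                    as.logical(toupper(val))
                  else val
  }
  out
}

#' Run the full biotin-painting analysis pipeline
#'
#' Stages run in dependency order: input reading and validation, IDR
#' calling, then biotin enrichment, disorder association, structural
#' classes, PTM enrichment, GO enrichment and the TMT time course. Every
#' referenced input file must exist before any computation starts. Each
#' report is a fixed-format TSV in \code{out_dir}; a manifest records
#' options, seed and package version.
#'
#' @param config named list (or path to a file readable by
#'   [read_run_config()]) with entries: \code{fasta}, \code{sites},
#'   \code{tracks} (+ optional \code{tracks_dialect}), optional
#'   \code{tmt}, \code{go_annotations}, \code{go_bias},
#'   \code{go_biotinome}; \code{out_dir}; options \code{caller}
#'   (predictor label, \code{"union"} or \code{"consensus"}),
#'   \code{quorum}, \code{threshold}, \code{alternative}, \code{pool},
#'   \code{pseudo_count}, \code{alpha}, \code{analyses} (character
#'   vector), \code{seed}.
#' @return invisibly, a list of all stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(caller = "VSL2b", quorum = 0.75, threshold = 0.5,
         alternative = "two.sided", pool = "biotinome",
         pseudo_count = 0.5, alpha = 0.05, tracks_dialect = "tsv",
         analyses = c("enrichment", "association", "classes", "ptm",
                      "go", "timecourse"),
         seed = 1L), config)
  if (is.character(cfg$analyses) && length(cfg$analyses) == 1L)
    cfg$analyses <- strsplit(cfg$analyses, "[,;]\\s*")[[1L]]
  for (key in c("fasta", "sites", "tracks", "out_dir"))
    if (is.null(cfg[[key]])) stop("config is missing '", key, "'")
  inputs <- unlist(cfg[intersect(names(cfg),
                                 c("fasta", "sites", "tracks", "tmt",
                                   "go_annotations", "go_bias",
                                   "go_biotinome"))])
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  # run fn per study; a study with degenerate data (e.g. a single
  # structural class) is skipped with a warning rather than aborting
  per_study <- function(studies, fn) {
    res <- lapply(studies, function(st)
      tryCatch(fn(st), error = function(e) {
        warning("study ", st, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }))
    names(res) <- studies
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res) == 0L) {
      warning("stage produced no result for any study; skipped",
              call. = FALSE)
      return(NULL)
    }
    res
  }
  results <- list()
  registry <- stage("io", load_study_registry(cfg$registry))
  prot <- stage("io", read_fasta(cfg$fasta))
  tracks <- stage("io", read_disorder_tracks(cfg$tracks, prot,
                                             dialect = cfg$tracks_dialect))
  sites <- stage("io", read_site_table(cfg$sites, prot, registry))
  idrsets <- stage("idr", call_idrs(tracks, caller = cfg$caller,
                                    quorum = cfg$quorum,
                                    threshold = cfg$threshold))
  stage("idr", write_idr_sets(idrsets, file.path(cfg$out_dir, "idr.tsv")))
  stage("idr", write_tsv(disorder_fractions(idrsets),
                         file.path(cfg$out_dir, "disorder_fractions.tsv")))

  studies <- intersect(registry$study_id,
                       unique(sites$study_id[sites$modification == "biotin"]))
  if ("enrichment" %in% cfg$analyses && length(studies)) {
    results$enrichment <- stage("enrichment", {
      res <- lapply(studies, function(st)
        study_enrichment(sites, prot, idrsets, registry, study = st,
                         pool = cfg$pool, alternative = cfg$alternative))
      names(res) <- studies
      write_enrichment(res, file.path(cfg$out_dir, "enrichment.tsv"))
      bars <- do.call(rbind, lapply(studies, function(st)
        cbind(study = st, res[[st]]$table)))
      write_tsv(bars, file.path(cfg$out_dir, "enrichment_bars.tsv"))
      res
    })
  }
  if ("association" %in% cfg$analyses && length(studies)) {
    results$association <- stage("association", {
      res <- per_study(studies, function(st) biotin_disorder_association(
        protein_biotin_summary(sites, prot, idrsets, study = st)))
      if (!is.null(res)) {
        assoc <- do.call(rbind, lapply(names(res), function(st)
          data.frame(study = st, r = res[[st]]$r,
                     p_value = res[[st]]$p_value, n = res[[st]]$n)))
        write_tsv(assoc, file.path(cfg$out_dir, "association.tsv"))
        bins <- do.call(rbind, lapply(names(res), function(st)
          cbind(study = st, res[[st]]$bins)))
        write_tsv(bins, file.path(cfg$out_dir, "association_bins.tsv"))
      }
      res
    })
  }
  if ("classes" %in% cfg$analyses && length(studies)) {
    results$classes <- stage("classes", {
      res <- per_study(studies, function(st)
        biotin_class_analysis(sites, prot, idrsets, study = st,
                              pseudo = cfg$pseudo_count))
      if (!is.null(res)) {
        write_tsv(do.call(rbind, lapply(names(res), function(st)
          cbind(study = st, res[[st]]$table))),
          file.path(cfg$out_dir, "classes.tsv"))
        write_tsv(do.call(rbind, lapply(names(res), function(st)
          cbind(study = st, res[[st]]$comparison$tukey))),
          file.path(cfg$out_dir, "class_tukey.tsv"))
        write_tsv(do.call(rbind, lapply(names(res), function(st)
          cbind(study = st, res[[st]]$comparison$pairwise))),
          file.path(cfg$out_dir, "class_pairwise.tsv"))
      }
      res
    })
  }
  ptm_types <- intersect(names(PTM_BACKGROUNDS),
                         unique(sites$modification))
  if ("ptm" %in% cfg$analyses && length(ptm_types)) {
    results$ptm <- stage("ptm", {
      res <- lapply(ptm_types, function(pt)
        ptm_idr_enrichment(sites, prot, idrsets, pt, pool = cfg$pool,
                           alternative = cfg$alternative))
      names(res) <- ptm_types
      write_enrichment(res, file.path(cfg$out_dir, "ptm_enrichment.tsv"))
      res
    })
  }
  if ("go" %in% cfg$analyses && !is.null(cfg$go_annotations)) {
    results$go <- stage("go", {
      ann <- utils::read.delim(cfg$go_annotations,
                               stringsAsFactors = FALSE)
      bias_df <- utils::read.delim(cfg$go_bias, stringsAsFactors = FALSE)
      bias <- stats::setNames(bias_df$bias, bias_df$accession)
      biotinome <- if (!is.null(cfg$go_biotinome))
        utils::read.delim(cfg$go_biotinome,
                          stringsAsFactors = FALSE)$accession
      else unique(sites$accession[sites$modification == "biotin"])
      res <- go_test(ann, biotinome, bias)
      write_tsv(as.data.frame(res), file.path(cfg$out_dir, "go.tsv"))
      res
    })
  }
  if ("timecourse" %in% cfg$analyses && !is.null(cfg$tmt)) {
    results$timecourse <- stage("timecourse", {
      tmt <- read_tmt(cfg$tmt)
      res <- run_timecourse(tmt, alpha = cfg$alpha)
      for (ct in names(res$tests))
        write_tsv(as.data.frame(res$tests[[ct]]),
                  file.path(cfg$out_dir, sprintf("timecourse_%s.tsv", ct)))
      write_tsv(res$kinetics, file.path(cfg$out_dir, "kinetics.tsv"))
      res
    })
  }
  manifest <- list(package = "biotinpaint", version = pkg_version(),
                   caller = cfg$caller, quorum = cfg$quorum,
                   threshold = cfg$threshold,
                   alternative = cfg$alternative, pool = cfg$pool,
                   pseudo_count = cfg$pseudo_count, alpha = cfg$alpha,
                   seed = cfg$seed, analyses = cfg$analyses,
                   inputs = as.list(inputs),
                   site_validation = as.list(attr(sites, "validation")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
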