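#' @name pipeline
#' @title Pipeline stage runners
#' @description
#' File-level orchestration of the analysis stages. Each runner reads the
#' standard input formats, applies one stage with the thresholds of a
#' [rivit_config()], writes deterministic TSV outputs into `out_dir` and
#' records a run manifest (configuration snapshot, input checksums,
#' package version). Given identical inputs and configuration the outputs
#' are byte-identical; the manifest identifier, derived from the
#' configuration and input checksums, is stamped into every output TSV as
#' a leading comment.
NULL

run_manifest <- function(config, inputs, out_dir) {
  sums <- if (length(inputs) > 0) tools::md5sum(unlist(inputs)) else
    character(0)
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  run_id <- substr(unname(tools::md5sum(cfg_file)), 1, 8)
  if (length(sums) > 0) {
    id_file <- tempfile()
    writeLines(c(run_id, paste(names(sums), unname(sums))), id_file)
    run_id <- substr(unname(tools::md5sum(id_file)), 1, 8)
    unlink(id_file)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mf <- file.path(out_dir, "manifest.tsv")
  df <- rbind(
    data.frame(key = "run_id", value = run_id),
    data.frame(key = "package_version",
               value = as.character(utils::packageVersion("rivitseq"))),
    data.frame(key = "timestamp", value = format(Sys.time(), tz = "UTC")),
    data.frame(key = paste0("config.", names(config)),
               value = vapply(config, function(v) format(v), character(1))),
    if (length(sums) > 0)
      data.frame(key = paste0("md5.", basename(names(sums))),
                 value = unname(sums)) else NULL)
  utils::write.table(df, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  run_id
}

#' @rdname pipeline
#' @param config a [rivit_config()].
#' @param out_dir output directory.
#' @param seed overrides `config$rng_seed` when non-`NULL`.
#' @return `run_simulate` writes the full synthetic fixture set and
#'   returns the written paths invisibly.
#' @export
run_simulate <- function(config = rivit_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  sim <- simulate_rivit(seed = config$rng_seed)
  run_manifest(config, list(), out_dir)
  paths <- write_simulation(sim, out_dir)
  invisible(paths)
}

#' @rdname pipeline
#' @param track_paths named character vector of 5'-end track TSVs, names
#'   are sample identifiers matching the design.
#' @param design_path track design TSV.
#' @param annotation_path GFF3 annotation (spike-in rows flagged by
#'   `ercc_prefix`).
#' @param ercc_prefix spike-in identifier prefix.
#' @return `run_call_tss` writes `tss_calls.tsv`, `norm_factors.tsv` and
#'   `dependent_tss.bed`, returning the `tss_calls` object invisibly.
#' @export
run_call_tss <- function(config = rivit_config(), track_paths, design_path,
                         annotation_path, out_dir,
                         ercc_prefix = "ERCC-") {
  design <- read_sample_design(design_path)
  genes <- read_gene_annotation(annotation_path, ercc_prefix)
  ercc_ids <- genes$gene_id[genes$is_ercc]
  tracks <- lapply(track_paths, read_five_prime_track)
  names(tracks) <- names(track_paths)
  sig <- treatment_samples(design)
  ctl <- control_samples(design)
  missing <- setdiff(c(sig, ctl), names(tracks))
  if (length(missing) > 0)
    stop("design ", design_path, " names sample(s) without tracks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  calls <- call_tss_map(tracks[sig], tracks[ctl], ercc_ids, config)
  run_id <- run_manifest(config, c(track_paths, design_path,
                                   annotation_path), out_dir)
  write_results(as.data.frame(calls),
                file.path(out_dir, "tss_calls.tsv"),
                sort_by = c("contig", "strand", "position"),
                run_id = run_id)
  write_normalization_factors(attr(calls, "factors"),
                              length(attr(calls, "control_transcripts")),
                              file.path(out_dir, "norm_factors.tsv"))
  write_tss_bed(calls, file.path(out_dir, "dependent_tss.bed"))
  invisible(calls)
}

#' @rdname pipeline
#' @param counts_path fragment-count matrix TSV (spike-in rows included).
#' @return `run_de` writes `de_results.tsv` and returns the `de_results`
#'   invisibly.
#' @export
run_de <- function(config = rivit_config(), counts_path, design_path,
                   out_dir, ercc_prefix = "ERCC-") {
  counts <- read_count_matrix(counts_path)
  design <- read_sample_design(design_path)
  ercc_ids <- rownames(counts)[startsWith(rownames(counts), ercc_prefix)]
  res <- de_analysis(counts, design, ercc_ids, config)
  run_id <- run_manifest(config, c(counts_path, design_path), out_dir)
  write_results(as.data.frame(res), file.path(out_dir, "de_results.tsv"),
                sort_by = "gene_id", run_id = run_id)
  invisible(res)
}

#' @rdname pipeline
#' @param tss_path `tss_calls.tsv` from `run_call_tss`.
#' @param de_path `de_results.tsv` from `run_de`.
#' @param sigma_id label of the sigma factor under study.
#' @return `run_integrate` writes `targets.tsv` and `regulon_summary.tsv`
#'   and returns the target table invisibly.
#' @export
run_integrate <- function(config = rivit_config(), tss_path, de_path,
                          annotation_path, out_dir, sigma_id = "sigma",
                          ercc_prefix = "ERCC-") {
  genes <- read_gene_annotation(annotation_path, ercc_prefix)
  tss <- utils::read.delim(tss_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  de <- utils::read.delim(de_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  targets <- integrate_targets(genes, de, tss, config, sigma_id)
  run_id <- run_manifest(config, c(tss_path, de_path, annotation_path),
                         out_dir)
  write_results(targets, file.path(out_dir, "targets.tsv"),
                sort_by = c("sigma_id", "gene_id"), run_id = run_id)
  write_results(summarize_regulon(targets),
                file.path(out_dir, "regulon_summary.tsv"),
                sort_by = "sigma_id", run_id = run_id)
  invisible(targets)
}

#' @rdname pipeline
#' @param genome_path genome FASTA.
#' @return `run_motif_windows` writes `promoter_windows.fasta` for the
#'   sigma-dependent TSSs and returns the `DNAStringSet` invisibly.
#' @export
run_motif_windows <- function(config = rivit_config(), tss_path,
                              genome_path, out_dir) {
  tss <- utils::read.delim(tss_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if ("sigma_dependent" %in% names(tss))
    tss <- tss[tss$sigma_dependent, , drop = FALSE]
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  win <- extract_promoter_windows(tss, genome, config$promoter_window_nt)
  run_manifest(config, c(tss_path, genome_path), out_dir)
  Biostrings::writeXStringSet(win,
                              file.path(out_dir, "promoter_windows.fasta"))
  invisible(win)
}

#' @rdname pipeline
#' @param motif_path MEME XML or motif TSV.
#' @return `run_filter_motifs` writes `motifs_retained.tsv` and returns
#'   the [filter_motifs()] result invisibly.
#' @export
run_filter_motifs <- function(config = rivit_config(), motif_path,
                              out_dir) {
  rec <- read_motif_records(motif_path)
  res <- filter_motifs(rec, config$motif_min_width, config$motif_max_width,
                       config$motif_min_sites, config$motif_max_evalue)
  run_id <- run_manifest(config, motif_path, out_dir)
  write_results(res$retained, file.path(out_dir, "motifs_retained.tsv"),
                sort_by = NULL, run_id = run_id)
  invisible(res)
}

#' @rdname pipeline
#' @param target_paths character vector of `targets.tsv` files (one or
#'   more sigma factors).
#' @param prior_path optional TSV of prior sigma -> gene edges.
#' @return `run_network` writes SIF, GraphML and the shared-regulon and
#'   shared-TSS matrices, returning the `regulon_network` invisibly.
#' @param tss_paths optional named character vector of per-sigma
#'   `tss_calls.tsv` files for the shared-TSS matrix.
#' @export
run_network <- function(config = rivit_config(), target_paths, out_dir,
                        prior_path = NULL, tss_paths = NULL) {
  targets <- lapply(target_paths, utils::read.delim, comment.char = "#",
                    stringsAsFactors = FALSE)
  prior <- if (is.null(prior_path)) NULL else
    utils::read.delim(prior_path, comment.char = "#",
                      stringsAsFactors = FALSE)
  net <- build_network(targets, prior)
  run_id <- run_manifest(config, c(target_paths, prior_path, tss_paths),
                         out_dir)
  write_network_files(net$edges, file.path(out_dir, "network.sif"),
                      file.path(out_dir, "network.graphml"))
  write_matrix_tsv(shared_regulon_matrix(net),
                   file.path(out_dir, "shared_regulons.tsv"))
  if (!is.null(tss_paths)) {
    sets <- lapply(tss_paths, function(p) {
      t <- utils::read.delim(p, comment.char = "#",
                             stringsAsFactors = FALSE)
      if ("sigma_dependent" %in% names(t))
        t <- t[t$sigma_dependent, , drop = FALSE]
      t
    })
    write_matrix_tsv(shared_tss_matrix(sets, config$shared_tss_tolerance_nt),
                     file.path(out_dir, "shared_tss.tsv"))
  }
  invisible(net)
}

#' @rdname pipeline
#' @details `run_all` simulates the default synthetic experiment, then
#'   runs TSS calling, differential transcription, target integration,
#'   promoter-window extraction and network construction on the written
#'   files, exactly as the individual runners would.
#' @return `run_all` returns (invisibly) a list with the simulation
#'   paths, TSS calls, DE table, targets and network.
#' @export
run_all <- function(config = rivit_config(), out_dir, seed = NULL,
                    sigma_id = "sigma") {
  sim_dir <- file.path(out_dir, "sim")
  paths <- run_simulate(config, sim_dir, seed)
  track_paths <- unlist(paths[startsWith(names(paths), "track_")])
  names(track_paths) <- sub("^track_", "", names(track_paths))
  calls <- run_call_tss(config, track_paths, paths$design,
                        paths$annotation, file.path(out_dir, "tss"))
  de <- run_de(config, paths$counts, paths$count_design,
               file.path(out_dir, "de"))
  targets <- run_integrate(config, file.path(out_dir, "tss",
                                             "tss_calls.tsv"),
                           file.path(out_dir, "de", "de_results.tsv"),
                           paths$annotation,
                           file.path(out_dir, "targets"), sigma_id)
  run_motif_windows(config, file.path(out_dir, "tss", "tss_calls.tsv"),
                    paths$genome, file.path(out_dir, "motifs"))
  net <- run_network(config,
                     file.path(out_dir, "targets", "targets.tsv"),
                     file.path(out_dir, "network"))
  invisible(list(paths = paths, tss_calls = calls, de = de,
                 targets = targets, network = net))
}
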