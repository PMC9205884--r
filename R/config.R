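#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated record.
#' Defaults reproduce the published analysis settings: 5'-ends within 100 bp
#' are clustered, subclusters require a positional standard deviation below
#' 10, TSSs need a normalized read count of at least 4 in every sigma-factor
#' replicate, dependence requires the 2nd-lowest sigma replicate to be at
#' least 4x every control replicate, spike-in controls need 10 first-nucleotide
#' reads in all replicates, differential transcription uses fold change >= 2
#' at BH-adjusted P < 0.01, direct targets need a TSS within 300 nt upstream
#' of the initiation codon, operon extension reaches 50 nt downstream, and
#' motif filtering keeps 22-35 nt motifs present in >= 10 sequences with
#' E < 1e-5.
#'
#' @param cluster_window_nt maximum gap (nt) between 5'-end positions joined
#'   into one cluster.
#' @param subcluster_sd positional standard deviation bound; runs of cluster
#'   members with SD strictly below this form one subcluster.
#' @param min_norm_count minimum normalized read count required in every
#'   sigma-sample replicate for a TSS to enter dependence testing.
#' @param dependence_ratio required ratio of the 2nd-lowest sigma-replicate
#'   normalized count to the largest control-replicate count.
#' @param min_ercc_first_nt_reads minimum first-nucleotide read count a
#'   spike-in transcript must reach in every replicate to serve as a
#'   normalization control.
#' @param fc_threshold fold-change threshold (inclusive) for upregulation.
#' @param padj_threshold BH-adjusted P threshold (strict) for upregulation.
#' @param upstream_window_nt maximum distance (nt) from a TSS to the
#'   initiation codon for a direct target.
#' @param operon_gap_nt maximum downstream gap (nt) for operon extension.
#' @param motif_min_width,motif_max_width motif width bounds (nt, inclusive).
#' @param motif_min_sites minimum number of contributing sequences.
#' @param motif_max_evalue E-value bound (strict) for motif retention.
#' @param promoter_window_nt promoter window length extracted upstream of and
#'   including the TSS.
#' @param shared_tss_tolerance_nt positional tolerance (nt) when matching
#'   TSSs of two sigma factors.
#' @param rng_seed integer seed used by the simulation helpers.
#' @return An object of class `rivit_config`: a validated named list.
#' @examples
#' cfg <- rivit_config()
#' cfg$cluster_window_nt
#' @export
rivit_config <- function(cluster_window_nt = 100L,
                         subcluster_sd = 10,
                         min_norm_count = 4,
                         dependence_ratio = 4,
                         min_ercc_first_nt_reads = 10L,
                         fc_threshold = 2,
                         padj_threshold = 0.01,
                         upstream_window_nt = 300L,
                         operon_gap_nt = 50L,
                         motif_min_width = 22L,
                         motif_max_width = 35L,
                         motif_min_sites = 10L,
                         motif_max_evalue = 1e-5,
                         promoter_window_nt = 50L,
                         shared_tss_tolerance_nt = 2L,
                         rng_seed = 101L) {
  cfg <- list(
    cluster_window_nt = as.integer(cluster_window_nt),
    subcluster_sd = as.numeric(subcluster_sd),
    min_norm_count = as.numeric(min_norm_count),
    dependence_ratio = as.numeric(dependence_ratio),
    min_ercc_first_nt_reads = as.integer(min_ercc_first_nt_reads),
    fc_threshold = as.numeric(fc_threshold),
    padj_threshold = as.numeric(padj_threshold),
    upstream_window_nt = as.integer(upstream_window_nt),
    operon_gap_nt = as.integer(operon_gap_nt),
    motif_min_width = as.integer(motif_min_width),
    motif_max_width = as.integer(motif_max_width),
    motif_min_sites = as.integer(motif_min_sites),
    motif_max_evalue = as.numeric(motif_max_evalue),
    promoter_window_nt = as.integer(promoter_window_nt),
    shared_tss_tolerance_nt = as.integer(shared_tss_tolerance_nt),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "rivit_config"
  cfg
}

validate_config <- function(cfg) {
  positive <- c("cluster_window_nt", "subcluster_sd", "min_norm_count",
                "dependence_ratio", "min_ercc_first_nt_reads", "fc_threshold",
                "padj_threshold", "upstream_window_nt", "operon_gap_nt",
                "motif_min_width", "motif_max_width", "motif_min_sites",
                "motif_max_evalue", "promoter_window_nt")
  for (nm in positive) {
    v <- cfg[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("config field '", nm, "' must be a single positive value",
           call. = FALSE)
  }
  if (cfg$shared_tss_tolerance_nt < 0)
    stop("config field 'shared_tss_tolerance_nt' must be >= 0", call. = FALSE)
  if (cfg$motif_min_width > cfg$motif_max_width)
    stop("motif_min_width must be <= motif_max_width", call. = FALSE)
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' The on-disk format is a flat key-value (YAML) map whose keys mirror the
#' [rivit_config()] arguments. Unknown keys are an error so typos cannot
#' silently fall back to defaults.
#'
#' @param path file path.
#' @param config for `write_config`, a `rivit_config` object.
#' @return `read_config` returns a `rivit_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(rivit_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(rivit_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "rivit_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.rivit_config <- function(x, ...) {
  cat("RIViT pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
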