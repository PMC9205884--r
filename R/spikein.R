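#' First-nucleotide spike-in counts across replicates
#'
#' Collects, for each ERCC control transcript, the 5'-end read count at its
#' first nucleotide (position 1 of the spike-in contig, plus strand) in every
#' replicate track.
#'
#' @param tracks named list of [five_prime_track()] objects, one per
#'   replicate of every sample under comparison.
#' @param ercc_ids character vector of spike-in contig identifiers.
#' @return numeric matrix, transcripts x replicates.
#' @export
first_nt_counts <- function(tracks, ercc_ids) {
  stopifnot(length(tracks) > 0)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, function(t) attr(t, "sample_id"),
                            character(1))
  m <- vapply(tracks, function(tr) {
    hit <- tr$contig %in% ercc_ids & tr$strand == "+" & tr$position == 1L
    cnt <- stats::setNames(rep(0, length(ercc_ids)), ercc_ids)
    cnt[tr$contig[hit]] <- tr$count[hit]
    cnt
  }, numeric(length(ercc_ids)))
  matrix(m, nrow = length(ercc_ids),
         dimnames = list(ercc_ids, names(tracks)))
}

#' Select spike-in normalization controls
#'
#' A spike-in transcript qualifies as a normalization control only when its
#' first-nucleotide read count reaches `min_first_nt_reads` in all
#' replicates of all samples under comparison.
#'
#' @inheritParams first_nt_counts
#' @param min_first_nt_reads minimum first-nucleotide count (default 10).
#' @return character vector of qualifying transcript identifiers.
#' @export
select_control_transcripts <- function(tracks, ercc_ids,
                                       min_first_nt_reads = 10) {
  m <- first_nt_counts(tracks, ercc_ids)
  ok <- apply(m, 1, function(x) all(x >= min_first_nt_reads))
  sel <- rownames(m)[ok]
  if (length(sel) == 0)
    stop("no spike-in transcript has >= ", min_first_nt_reads,
         " first-nucleotide reads in every replicate; normalization is ",
         "impossible at this threshold - consider lowering ",
         "min_ercc_first_nt_reads", call. = FALSE)
  sel
}

#' Spike-in normalization factors
#'
#' For each control transcript the read count relative to the maximum across
#' samples is computed; a sample's normalization factor is the mean of these
#' relative counts over all control transcripts, so every factor lies in
#' (0, 1] and the best-covered sample(s) approach 1.
#'
#' @param counts numeric matrix, control transcripts x samples, of
#'   first-nucleotide read counts for the selected controls.
#' @return named numeric vector of per-sample factors in (0, 1].
#' @export
compute_normalization_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1) stop("need >= 1 control transcript", call. = FALSE)
  mx <- apply(counts, 1, max)
  if (any(mx <= 0))
    stop("control transcript with zero counts in every sample: ",
         paste(rownames(counts)[mx <= 0], collapse = ", "), call. = FALSE)
  rel <- counts / mx
  f <- colMeans(rel)
  stopifnot(all(f > 0), all(f <= 1 + 1e-12))
  pmin(f, 1)
}

#' Normalize read counts by a sample's factor
#'
#' Normalized counts are raw counts divided by the sample's normalization
#' factor; since factors lie in (0, 1], normalization never decreases a
#' count. Values stay real-valued (no rounding).
#'
#' @param raw raw count(s).
#' @param factor normalization factor(s) in (0, 1].
#' @return numeric normalized count(s).
#' @export
normalize_counts <- function(raw, factor) {
  if (any(factor <= 0)) stop("normalization factor must be > 0", call. = FALSE)
  raw / factor
}

#' Spike-in-anchored size factors for a count matrix
#'
#' Median-of-ratios size factors computed on the ERCC spike-in rows only:
#' each spike-in row is divided by its geometric mean across samples, the
#' per-sample median of these ratios is taken, and the factors are rescaled
#' to geometric mean 1. Rows containing a zero are excluded (their geometric
#' mean is degenerate); at least two usable spike-in rows are required.
#'
#' @param counts count matrix including spike-in rows.
#' @param ercc_ids row identifiers of the spike-in transcripts.
#' @return named numeric vector of per-sample size factors, geometric
#'   mean 1.
#' @export
compute_size_factors <- function(counts, ercc_ids) {
  m <- counts[rownames(counts) %in% ercc_ids, , drop = FALSE]
  if (nrow(m) < 2)
    stop("need >= 2 spike-in rows to compute size factors", call. = FALSE)
  usable <- rowSums(m == 0) == 0
  if (sum(usable) < 2)
    stop("fewer than 2 spike-in rows are zero-free; size factors are ",
         "undefined", call. = FALSE)
  m <- m[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  ratios <- m / geo
  sf <- apply(ratios, 2, stats::median)
  sf / exp(mean(log(sf)))
}

#' Export normalization factors
#'
#' @param factors named numeric vector from
#'   [compute_normalization_factors()].
#' @param n_controls number of control transcripts the factors are based
#'   on.
#' @param path output TSV.
#' @export
write_normalization_factors <- function(factors, n_controls, path) {
  write_results(
    data.frame(sample_id = names(factors), factor = unname(factors),
               n_control_transcripts = n_controls,
               stringsAsFactors = FALSE),
    path, sort_by = "sample_id")
}
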