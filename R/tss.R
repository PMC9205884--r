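#' Cluster 5'-end positions by proximity
#'
#' Single-linkage gap clustering: consecutive sorted positions whose gap is
#' at most `window` nucleotides belong to the same cluster, and clusters are
#' maximal. Every input position appears in exactly one cluster.
#'
#' @param positions integer vector of 1-based positions (one contig and
#'   strand).
#' @param window maximum gap joining two neighbours (inclusive).
#' @return list of sorted integer vectors, one per cluster, ordered by
#'   first position.
#' @export
cluster_positions <- function(positions, window) {
  if (length(positions) == 0) return(list())
  if (anyDuplicated(positions))
    stop("duplicate positions passed to cluster_positions", call. = FALSE)
  p <- sort(as.integer(positions))
  grp <- cumsum(c(1L, as.integer(diff(p) > window)))
  unname(split(p, grp))
}

# population standard deviation (divide by n)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Split a position cluster into subclusters
#'
#' Greedy scan in transcription direction (5' to 3': left to right on the
#' plus strand, right to left on the minus strand): the current run is
#' extended with the next member as long as the population standard
#' deviation of the run's positions stays strictly below `sd_threshold`;
#' otherwise a new subcluster starts. Scanning in transcription direction
#' makes the partition strand-symmetric. Singletons have SD 0 and always
#' qualify.
#'
#' @param positions integer vector of cluster member positions.
#' @param sd_threshold positional SD bound (strict).
#' @param strand `"+"` or `"-"`; sets the scan direction.
#' @return list of sorted integer vectors partitioning the input, ordered
#'   by first position.
#' @export
subcluster <- function(positions, sd_threshold, strand = "+") {
  p <- sort(as.integer(positions))
  if (length(p) == 0) return(list())
  if (strand == "-") p <- rev(p)
  out <- list()
  run <- p[1]
  for (x in p[-1]) {
    if (pop_sd(c(run, x)) < sd_threshold) {
      run <- c(run, x)
    } else {
      out[[length(out) + 1L]] <- sort(run)
      run <- x
    }
  }
  out[[length(out) + 1L]] <- sort(run)
  out[order(vapply(out, min, numeric(1)))]
}

#' Call a TSS from a subcluster
#'
#' The TSS is the member position with the largest read count summed across
#' the sigma-sample replicates; ties go to the most upstream member in
#' transcription direction (smallest coordinate on `+`, largest on `-`).
#' The TSS read count in each replicate is the sum over all subcluster
#' members, so no reads are lost.
#'
#' @param members integer vector of subcluster member positions.
#' @param counts numeric matrix members x replicates of raw 5'-end counts
#'   in the sigma-sample replicates (rows follow `members`).
#' @param strand `"+"` or `"-"`.
#' @return list with `position` (integer) and `counts` (named numeric, per
#'   replicate sums).
#' @export
call_tss <- function(members, counts, strand = "+") {
  members <- as.integer(members)
  counts <- matrix(as.numeric(counts), nrow = length(members),
                   dimnames = dimnames(counts))
  stopifnot(length(members) >= 1, nrow(counts) == length(members))
  pooled <- rowSums(counts)
  best <- which(pooled == max(pooled))
  pos <- if (strand == "+") members[best[which.min(members[best])]]
         else members[best[which.max(members[best])]]
  list(position = pos, counts = colSums(counts))
}

#' Minimum-abundance filter for TSS calls
#'
#' A TSS fails when its normalized read count is strictly below
#' `min_norm_count` in at least one sigma-sample replicate; failed calls
#' are excluded from dependence testing.
#'
#' @param norm_counts numeric matrix calls x sigma replicates of
#'   normalized counts.
#' @param min_norm_count threshold (default 4).
#' @return logical vector, `TRUE` where the call passes.
#' @export
filter_min_count <- function(norm_counts, min_norm_count = 4) {
  norm_counts <- as.matrix(norm_counts)
  apply(norm_counts, 1, function(x) all(x >= min_norm_count))
}

#' Sigma-factor dependence of a TSS
#'
#' Two criteria, both required: (i) the normalized read count in every
#' sigma-sample replicate exceeds the count in every no-sigma control
#' replicate; (ii) the 2nd-lowest sigma-replicate normalized count is at
#' least `ratio` times the largest control-replicate count.
#'
#' @param sigma_norm normalized counts in the sigma-sample replicates
#'   (length >= 2).
#' @param control_norm normalized counts in the control replicates.
#' @param ratio dependence ratio (default 4).
#' @return `TRUE` or `FALSE`.
#' @export
determine_dependence <- function(sigma_norm, control_norm, ratio = 4) {
  if (length(sigma_norm) < 2)
    stop("dependence criterion (ii) needs >= 2 sigma-sample replicates",
         call. = FALSE)
  ctrl_max <- if (length(control_norm) == 0) 0 else max(control_norm)
  crit_i <- min(sigma_norm) > ctrl_max
  crit_ii <- sort(sigma_norm)[2] >= ratio * ctrl_max
  crit_i && crit_ii
}

# raw counts at given positions in one track (0 where absent)
track_counts_at <- function(track, contig, strand, positions) {
  hit <- track$contig == contig & track$strand == strand &
    track$position %in% positions
  cnt <- stats::setNames(rep(0, length(positions)), positions)
  cnt[as.character(track$position[hit])] <- track$count[hit]
  unname(cnt)
}

#' Call TSSs and decide sigma-factor dependence genome-wide
#'
#' Full 5'-end workflow for one sigma-factor versus no-sigma comparison:
#' spike-in controls are selected jointly over all replicates of both
#' conditions and per-sample normalization factors computed; 5'-end
#' positions of the sigma-sample replicates (pooled) are clustered within
#' `cluster_window_nt` per contig and strand, subclustered at
#' `subcluster_sd`, and one TSS is called per subcluster; calls are
#' filtered at `min_norm_count` and the dependence criteria applied to the
#' passing calls. Spike-in contigs never yield TSS calls.
#'
#' @param sigma_tracks named list of [five_prime_track()] replicates of the
#'   sigma-factor sample.
#' @param control_tracks named list of replicates of the no-sigma control.
#' @param ercc_ids spike-in contig identifiers.
#' @param config a [rivit_config()].
#' @return object of class `tss_calls`: a data frame with one row per TSS
#'   call (contig, strand, position, n_members, per-replicate raw and
#'   normalized counts, `passes_min_count`, `sigma_dependent`) plus
#'   attributes `factors` (normalization factors), `control_transcripts`
#'   and `members` (list of member positions per call).
#' @export
call_tss_map <- function(sigma_tracks, control_tracks, ercc_ids,
                         config = rivit_config()) {
  stopifnot(length(sigma_tracks) >= 2)
  if (is.null(names(sigma_tracks)))
    names(sigma_tracks) <- vapply(sigma_tracks, attr, character(1),
                                  "sample_id")
  if (is.null(names(control_tracks)))
    names(control_tracks) <- vapply(control_tracks, attr, character(1),
                                    "sample_id")
  all_tracks <- c(sigma_tracks, control_tracks)
  ctrl_tx <- select_control_transcripts(all_tracks, ercc_ids,
                                        config$min_ercc_first_nt_reads)
  fnc <- first_nt_counts(all_tracks, ercc_ids)
  factors <- compute_normalization_factors(fnc[ctrl_tx, , drop = FALSE])

  sig_names <- names(sigma_tracks)
  ctl_names <- names(control_tracks)

  # sigma-sample replicates define which positions exist
  pooled <- do.call(rbind, lapply(sigma_tracks, function(t)
    as.data.frame(t)[, c("contig", "strand", "position")]))
  pooled <- pooled[!pooled$contig %in% ercc_ids, , drop = FALSE]
  pooled <- unique(pooled)

  rows <- list()
  members_list <- list()
  if (nrow(pooled) > 0) {
    key <- interaction(pooled$contig, pooled$strand, drop = TRUE)
    for (grp in split(pooled, key)) {
      contig <- grp$contig[1]; strand <- grp$strand[1]
      clusters <- cluster_positions(grp$position, config$cluster_window_nt)
      for (cl in clusters) {
        for (sub in subcluster(cl, config$subcluster_sd, strand)) {
          sig_mat <- vapply(sigma_tracks, track_counts_at,
                            numeric(length(sub)),
                            contig = contig, strand = strand, positions = sub)
          sig_mat <- matrix(sig_mat, nrow = length(sub),
                            dimnames = list(NULL, sig_names))
          call <- call_tss(sub, sig_mat, strand)
          ctl_cnt <- vapply(control_tracks, function(tr)
            sum(track_counts_at(tr, contig, strand, sub)), numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            contig = contig, strand = strand, position = call$position,
            n_members = length(sub),
            rbind(c(call$counts, ctl_cnt)),
            stringsAsFactors = FALSE, check.names = FALSE)
          members_list[[length(members_list) + 1L]] <- sub
        }
      }
    }
  }
  if (length(rows) == 0) {
    res <- data.frame(contig = character(), strand = character(),
                      position = integer(), n_members = integer())
    for (s in c(sig_names, ctl_names)) res[[paste0("raw_", s)]] <- numeric()
    for (s in c(sig_names, ctl_names)) res[[paste0("norm_", s)]] <- numeric()
    res$passes_min_count <- logical()
    res$sigma_dependent <- logical()
  } else {
    res <- do.call(rbind, rows)
    raw_cols <- c(sig_names, ctl_names)
    names(res)[5:(4 + length(raw_cols))] <- paste0("raw_", raw_cols)
    for (s in raw_cols)
      res[[paste0("norm_", s)]] <-
        normalize_counts(res[[paste0("raw_", s)]], factors[[s]])
    norm_sig <- as.matrix(res[, paste0("norm_", sig_names), drop = FALSE])
    norm_ctl <- as.matrix(res[, paste0("norm_", ctl_names), drop = FALSE])
    res$passes_min_count <- filter_min_count(norm_sig, config$min_norm_count)
    res$sigma_dependent <- res$passes_min_count &
      vapply(seq_len(nrow(res)), function(i)
        determine_dependence(norm_sig[i, ], norm_ctl[i, ],
                             config$dependence_ratio), logical(1))
    ord <- order(res$contig, res$strand, res$position)
    res <- res[ord, , drop = FALSE]
    members_list <- members_list[ord]
    rownames(res) <- NULL
  }
  attr(res, "factors") <- factors
  attr(res, "control_transcripts") <- ctrl_tx
  attr(res, "members") <- members_list
  attr(res, "sigma_samples") <- sig_names
  attr(res, "control_samples") <- ctl_names
  class(res) <- c("tss_calls", "data.frame")
  res
}

#' @export
print.tss_calls <- function(x, ...) {
  cat("TSS calls:", nrow(x), "subcluster(s);",
      sum(x$passes_min_count), "pass the abundance filter;",
      sum(x$sigma_dependent), "sigma-dependent\n")
  cat("normalization factors:",
      paste(sprintf("%s=%.3f", names(attr(x, "factors")),
                    attr(x, "factors")), collapse = ", "), "\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Export sigma-dependent TSSs as BED6
#'
#' Coordinates are converted to BED's 0-based half-open convention at this
#' boundary only; the score column carries the pooled raw sigma-sample
#' count.
#'
#' @param calls a `tss_calls` object.
#' @param path output BED file.
#' @export
write_tss_bed <- function(calls, path) {
  dep <- calls[calls$sigma_dependent, , drop = FALSE]
  sig <- paste0("raw_", attr(calls, "sigma_samples"))
  score <- if (nrow(dep) == 0) numeric(0) else
    rowSums(as.data.frame(dep)[, sig, drop = FALSE])
  bed <- data.frame(chrom = dep$contig, start = dep$position - 1L,
                    end = dep$position,
                    name = paste0(dep$contig, ":", dep$strand, ":",
                                  dep$position),
                    score = score, strand = dep$strand)
  utils::write.table(bed[order(bed$chrom, bed$start), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
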