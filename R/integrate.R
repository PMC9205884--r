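#' Assign direct sigma-factor targets
#'
#' A gene is a direct target when it is upregulated and at least one
#' sigma-dependent TSS lies on the same contig and strand within
#' `upstream_window_nt` of its initiation codon. The distance is measured
#' in transcription direction from the TSS to the first nucleotide of the
#' initiation codon; distance 0 (leaderless transcript, TSS at the codon)
#' qualifies, as does the inclusive upper bound. TSSs falling inside
#' another gene's coding span are still accepted but flagged.
#'
#' @param genes a [gene_set()] (spike-in rows ignored).
#' @param upregulated character vector of upregulated gene identifiers.
#' @param tss data frame of sigma-dependent TSSs with columns `contig`,
#'   `strand`, `position` (e.g. the dependent rows of a `tss_calls`).
#' @param upstream_window_nt window size (default 300).
#' @param sigma_id label recorded on every assignment.
#' @return data frame with columns `sigma_id`, `gene_id`, `evidence`
#'   (`"direct"`), `tss_ids`, `tss_position`, `distance`,
#'   `tss_within_gene`.
#' @export
assign_direct_targets <- function(genes, upregulated, tss,
                                  upstream_window_nt = 300,
                                  sigma_id = "sigma") {
  genes <- genes[!genes$is_ercc, , drop = FALSE]
  cand <- genes[genes$gene_id %in% upregulated, , drop = FALSE]
  out <- list()
  if (nrow(cand) > 0 && nrow(tss) > 0) {
    left <- gene_left(genes); right <- gene_right(genes)
    for (i in seq_len(nrow(cand))) {
      g <- cand[i, ]
      dir <- if (g$strand == "+") 1L else -1L
      same <- tss$contig == g$contig & tss$strand == g$strand
      d <- (g$start - tss$position) * dir
      hit <- same & d >= 0 & d <= upstream_window_nt
      if (!any(hit)) next
      hpos <- tss$position[hit]
      hd <- d[hit]
      ord <- order(hd)
      hpos <- hpos[ord]; hd <- hd[ord]
      inside <- vapply(hpos, function(p) any(
        genes$contig == g$contig & genes$gene_id != g$gene_id &
          left <= p & p <= right), logical(1))
      out[[length(out) + 1L]] <- data.frame(
        sigma_id = sigma_id, gene_id = g$gene_id, evidence = "direct",
        tss_ids = paste(paste0(g$contig, ":", g$strand, ":", hpos),
                        collapse = ","),
        tss_position = hpos[1], distance = hd[1],
        tss_within_gene = any(inside), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) == 0) data.frame(
    sigma_id = character(), gene_id = character(), evidence = character(),
    tss_ids = character(), tss_position = integer(), distance = integer(),
    tss_within_gene = logical(), stringsAsFactors = FALSE)
  else do.call(rbind, out)
  res[order(res$gene_id), , drop = FALSE]
}

#' Extend targets through operons
#'
#' Iterates to a fixed point: any upregulated gene that is not yet a target
#' and whose initiation codon lies at most `operon_gap_nt` nucleotides
#' downstream (in transcription direction) of the 3' end of an existing
#' target on the same contig and strand becomes an operon-extended target.
#' The gap is `(start of downstream gene) - (3' end of upstream target) - 1`
#' measured in transcription direction; overlapping genes (negative gap)
#' qualify. The result is independent of gene input order.
#'
#' @param targets data frame from [assign_direct_targets()].
#' @param upregulated character vector of upregulated gene identifiers.
#' @param genes a [gene_set()].
#' @param operon_gap_nt maximum positive gap (default 50).
#' @return the target table augmented with `evidence = "operon"` rows
#'   (their `parent_gene` column names the upstream target supporting
#'   them; direct rows carry `NA`).
#' @export
extend_operons <- function(targets, upregulated, genes, operon_gap_nt = 50) {
  genes <- genes[!genes$is_ercc, , drop = FALSE]
  if (!"parent_gene" %in% names(targets))
    targets$parent_gene <- rep(NA_character_, nrow(targets))
  sigma_id <- if (nrow(targets) > 0) targets$sigma_id[1] else "sigma"
  repeat {
    members <- targets$gene_id
    cand <- genes[genes$gene_id %in% setdiff(upregulated, members), ,
                  drop = FALSE]
    if (nrow(cand) == 0 || length(members) == 0) break
    added <- FALSE
    for (i in seq_len(nrow(cand))) {
      g <- cand[i, ]
      dir <- if (g$strand == "+") 1L else -1L
      up <- genes[genes$gene_id %in% members &
                    genes$contig == g$contig & genes$strand == g$strand, ,
                  drop = FALSE]
      if (nrow(up) == 0) next
      gaps <- (g$start - up$end) * dir - 1L
      # negative gaps (overlapping genes) qualify, but the candidate must
      # start downstream of the parent's own start
      hit <- gaps <= operon_gap_nt & ((g$start - up$start) * dir > 0)
      if (any(hit)) {
        j <- which(hit)[which.min(gaps[hit])]
        targets <- rbind(targets, data.frame(
          sigma_id = sigma_id, gene_id = g$gene_id, evidence = "operon",
          tss_ids = NA_character_, tss_position = NA_integer_,
          distance = NA_integer_, tss_within_gene = NA,
          parent_gene = up$gene_id[j], stringsAsFactors = FALSE))
        added <- TRUE
      }
    }
    if (!added) break
  }
  targets <- targets[order(targets$gene_id), , drop = FALSE]
  rownames(targets) <- NULL
  targets
}

#' Summarize regulon sizes
#'
#' @param targets one target table or a list of them (e.g. full-length and
#'   truncated sigma-factor variants as separate `sigma_id`s).
#' @return data frame `sigma_id`, `n_direct`, `n_operon`, `n_total`,
#'   sorted by `sigma_id`.
#' @export
summarize_regulon <- function(targets) {
  if (is.data.frame(targets)) targets <- list(targets)
  tab <- do.call(rbind, lapply(targets, function(t)
    as.data.frame(t)[, c("sigma_id", "gene_id", "evidence")]))
  if (is.null(tab) || nrow(tab) == 0)
    return(data.frame(sigma_id = character(), n_direct = integer(),
                      n_operon = integer(), n_total = integer()))
  agg <- lapply(split(tab, tab$sigma_id), function(d) data.frame(
    sigma_id = d$sigma_id[1],
    n_direct = sum(d$evidence == "direct"),
    n_operon = sum(d$evidence == "operon"),
    n_total = nrow(d), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$sigma_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate differential transcription and TSS calls into a regulon
#'
#' Applies the two target criteria: direct targets (upregulated gene with
#' a sigma-dependent TSS within the upstream window) and operon-extended
#' targets (upregulated gene immediately downstream of a target), yielding
#' the sigma factor's regulon.
#'
#' @param genes a [gene_set()].
#' @param de a `de_results` data frame (or any frame with `gene_id` and
#'   `upregulated`).
#' @param tss_calls a `tss_calls` data frame; only `sigma_dependent` rows
#'   are used.
#' @param config a [rivit_config()].
#' @param sigma_id label for this sigma factor.
#' @return target table as from [extend_operons()].
#' @export
integrate_targets <- function(genes, de, tss_calls,
                              config = rivit_config(),
                              sigma_id = "sigma") {
  upreg <- de$gene_id[de$upregulated]
  dep <- as.data.frame(tss_calls)
  if ("sigma_dependent" %in% names(dep))
    dep <- dep[dep$sigma_dependent, , drop = FALSE]
  direct <- assign_direct_targets(genes, upreg, dep,
                                  config$upstream_window_nt, sigma_id)
  extend_operons(direct, upreg, genes, config$operon_gap_nt)
}
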