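#' Extract promoter windows around sigma-dependent TSSs
#'
#' For each TSS the window of `window_nt` nucleotides ending at (and
#' including) the TSS is extracted in transcription direction:
#' `[TSS - window_nt + 1, TSS]` on the plus strand and the reverse
#' complement of `[TSS, TSS + window_nt - 1]` on the minus strand. The
#' default of 50 nt comfortably spans the -35 element, the 18-19 nt spacer
#' and the -10 element of sigma-factor promoters. TSSs closer than the
#' window to a contig edge are skipped with a warning.
#'
#' @param tss data frame with columns `contig`, `strand`, `position`.
#' @param genome a [Biostrings::DNAStringSet] keyed by contig.
#' @param window_nt window length (default 50).
#' @return a `DNAStringSet` named `contig:strand:position`.
#' @export
extract_promoter_windows <- function(tss, genome, window_nt = 50) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  seqs <- character(0)
  ids <- character(0)
  for (i in seq_len(nrow(tss))) {
    contig <- tss$contig[i]; strand <- tss$strand[i]
    pos <- tss$position[i]
    if (!contig %in% names(genome)) {
      warning("TSS contig not in genome: ", contig, call. = FALSE)
      next
    }
    len <- Biostrings::width(genome[contig])
    if (strand == "+") {
      from <- pos - window_nt + 1L; to <- pos
    } else {
      from <- pos; to <- pos + window_nt - 1L
    }
    if (from < 1L || to > len) {
      warning("TSS at ", contig, ":", strand, ":", pos,
              " is within ", window_nt, " nt of the contig edge; skipped",
              call. = FALSE)
      next
    }
    s <- Biostrings::subseq(genome[[contig]], from, to)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s))
    ids <- c(ids, paste0(contig, ":", strand, ":", pos))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Motif records from motif-discovery output
#'
#' Reads either MEME XML output or a minimal TSV (`motif_id`, `width`,
#' `n_sites`, `e_value`). Motif discovery itself is external; this package
#' only prepares its input and filters its output.
#'
#' @param path MEME XML or TSV file.
#' @return data frame with columns `motif_id`, `width`, `n_sites`,
#'   `e_value`.
#' @export
read_motif_records <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (grepl("<", first, fixed = TRUE)) read_meme_xml(path)
  else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    need <- c("motif_id", "width", "n_sites", "e_value")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop("motif TSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    df[, need]
  }
}

read_meme_xml <- function(path) {
  doc <- xml2::read_xml(path)
  motifs <- xml2::xml_find_all(doc, ".//motif")
  if (length(motifs) == 0)
    return(data.frame(motif_id = character(), width = integer(),
                      n_sites = integer(), e_value = numeric()))
  data.frame(
    motif_id = xml2::xml_attr(motifs, "id"),
    width = as.integer(xml2::xml_attr(motifs, "width")),
    n_sites = as.integer(xml2::xml_attr(motifs, "sites")),
    e_value = as.numeric(xml2::xml_attr(motifs, "e_value")),
    stringsAsFactors = FALSE)
}

#' Validate a position weight matrix
#'
#' @param pwm 4 x width numeric matrix (rows A, C, G, T); every column
#'   must sum to 1 within `tol`.
#' @param tol column-sum tolerance.
#' @return `pwm`, invisibly, or an error.
#' @export
validate_pwm <- function(pwm, tol = 1e-6) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4, ncol(pwm) >= 1)
  sums <- colSums(pwm)
  if (any(abs(sums - 1) > tol))
    stop("PWM column(s) do not sum to 1: ",
         paste(which(abs(sums - 1) > tol), collapse = ", "), call. = FALSE)
  invisible(pwm)
}

#' Filter motif-discovery records
#'
#' Retains motifs of `min_width` to `max_width` nucleotides (inclusive)
#' present in at least `min_sites` sequences with an E-value strictly below
#' `max_evalue`; the retained motif with the smallest E-value is the
#' consensus. Retained motifs with E-value below 1e-8 are additionally
#' annotated as high-confidence (a reporting tier, not a filter).
#'
#' @param records data frame from [read_motif_records()].
#' @param min_width,max_width width bounds (defaults 22 and 35).
#' @param min_sites minimum site count (default 10).
#' @param max_evalue E-value bound (default 1e-5).
#' @return list with `retained` (data frame plus `high_confidence`
#'   column) and `consensus` (one-row data frame, or `NULL` when nothing
#'   is retained).
#' @export
filter_motifs <- function(records, min_width = 22, max_width = 35,
                          min_sites = 10, max_evalue = 1e-5) {
  keep <- records$width >= min_width & records$width <= max_width &
    records$n_sites >= min_sites & records$e_value < max_evalue
  retained <- records[keep, , drop = FALSE]
  retained <- retained[order(retained$e_value, retained$motif_id), ,
                       drop = FALSE]
  rownames(retained) <- NULL
  retained$high_confidence <- retained$e_value < 1e-8
  consensus <- if (nrow(retained) == 0) NULL else retained[1, , drop = FALSE]
  list(retained = retained, consensus = consensus)
}
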