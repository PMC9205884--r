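#' Gene set container
#'
#' A `gene_set` is a data frame with one row per gene and columns
#' `gene_id`, `contig`, `strand` (`+`/`-`), `start`, `end`, `is_ercc`.
#' Coordinates are 1-based, fully closed, and strand-normalized: `start` is
#' always the first nucleotide of the initiation codon in transcription
#' direction and `end` the last coding nucleotide, so `start > end` on the
#' minus strand.
#'
#' @param df data frame with the columns above (`is_ercc` optional,
#'   defaults to `FALSE`).
#' @return the validated data frame with class `gene_set` prepended.
#' @export
gene_set <- function(df) {
  need <- c("gene_id", "contig", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("gene_set: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$is_ercc)) df$is_ercc <- FALSE
  df$gene_id <- as.character(df$gene_id)
  df$contig <- as.character(df$contig)
  df$strand <- as.character(df$strand)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$is_ercc <- as.logical(df$is_ercc)
  if (anyDuplicated(df$gene_id))
    stop("gene_set: duplicate gene_id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("gene_set: strand must be '+' or '-'", call. = FALSE)
  if (any(pmin(df$start, df$end) < 1L))
    stop("gene_set: coordinates must be >= 1", call. = FALSE)
  bad <- (df$strand == "+" & df$start > df$end) |
         (df$strand == "-" & df$start < df$end)
  if (any(bad))
    stop("gene_set: start must precede end in transcription direction for: ",
         paste(df$gene_id[bad], collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("gene_set", "data.frame")
  df
}

# leftmost / rightmost chromosomal coordinate regardless of strand
gene_left <- function(g) pmin(g$start, g$end)
gene_right <- function(g) pmax(g$start, g$end)

#' Read gene models from a GFF3 annotation
#'
#' Parses `gene` (or, where absent, `CDS`) features and normalizes their
#' coordinates so that `start` is the first nucleotide of the initiation
#' codon in transcription direction. Features whose identifier begins with
#' `ercc_prefix` are flagged as spike-in controls.
#'
#' @param path GFF3 file.
#' @param ercc_prefix identifier prefix marking ERCC spike-in entries.
#' @return a [gene_set()].
#' @export
read_gene_annotation <- function(path, ercc_prefix = "ERCC-") {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 in ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  feat <- as.data.frame(gr, stringsAsFactors = FALSE)
  type <- as.character(feat$type)
  keep <- if (any(type == "gene")) type == "gene" else type == "CDS"
  if (!any(keep))
    stop("no gene or CDS features found in ", path, call. = FALSE)
  feat <- feat[keep, , drop = FALSE]
  pick_id <- function(i) {
    for (field in c("ID", "locus_tag", "gene_id", "Name")) {
      v <- feat[[field]]
      if (!is.null(v) && !is.na(v[i]) && nzchar(as.character(v[i])))
        return(as.character(v[i]))
    }
    NA_character_
  }
  ids <- vapply(seq_len(nrow(feat)), pick_id, character(1))
  if (anyNA(ids))
    stop("feature(s) without ID/locus_tag in ", path, call. = FALSE)
  strand <- as.character(feat$strand)
  if (any(strand == "*"))
    stop("unstranded gene feature(s) in ", path, call. = FALSE)
  left <- feat$start
  right <- feat$end
  gene_set(data.frame(
    gene_id = ids,
    contig = as.character(feat$seqnames),
    strand = strand,
    start = ifelse(strand == "+", left, right),
    end = ifelse(strand == "+", right, left),
    is_ercc = startsWith(ids, ercc_prefix),
    stringsAsFactors = FALSE
  ))
}

#' 5'-end read-count track
#'
#' Sparse per-position counts of aligned read 5'-ends for one replicate:
#' a data frame with columns `contig`, `strand`, `position` (1-based) and
#' `count`, zero-count rows dropped. ERCC spike-in transcripts are carried
#' as extra contigs so one track holds genome and spike-in counts.
#'
#' @param df data frame with the columns above.
#' @param sample_id replicate identifier stored as an attribute.
#' @return the validated data frame with class `five_prime_track`.
#' @export
five_prime_track <- function(df, sample_id = NA_character_) {
  need <- c("contig", "strand", "position", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("five_prime_track: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, need, drop = FALSE]
  df$contig <- as.character(df$contig)
  df$strand <- as.character(df$strand)
  df$position <- as.integer(df$position)
  df$count <- as.numeric(df$count)
  if (!all(df$strand %in% c("+", "-")))
    stop("five_prime_track: strand must be '+' or '-'", call. = FALSE)
  if (any(df$position < 1L))
    stop("five_prime_track: positions must be >= 1", call. = FALSE)
  if (any(df$count < 0))
    stop("five_prime_track: negative count(s)", call. = FALSE)
  if (any(df$count != round(df$count)))
    stop("five_prime_track: non-integer count(s)", call. = FALSE)
  key <- paste(df$contig, df$strand, df$position)
  if (anyDuplicated(key))
    stop("five_prime_track: duplicate position(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
         call. = FALSE)
  df <- df[df$count > 0, , drop = FALSE]
  df <- df[order(df$contig, df$strand, df$position), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- as.character(sample_id)
  class(df) <- c("five_prime_track", "data.frame")
  df
}

#' Read a 5'-end count track
#'
#' Two dialects are supported. The tabular dialect is a 4-column TSV
#' (`contig`, `strand`, `position`, `count`) with 1-based positions, an
#' optional header row. The bedGraph dialect (0-based, half-open intervals)
#' is expanded to per-base 1-based counts; because bedGraph is unstranded,
#' the strand is supplied by the caller. Duplicate positions (including
#' overlapping bedGraph intervals) are an error, never summed.
#'
#' @param path input file.
#' @param sample_id replicate identifier.
#' @param format `"auto"` sniffs bedGraph by column count/content.
#' @param strand strand assigned to bedGraph records.
#' @return a [five_prime_track()].
#' @export
read_five_prime_track <- function(path, sample_id = basename(path),
                                  format = c("auto", "tsv", "bedgraph"),
                                  strand = "+") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(five_prime_track(
      data.frame(contig = character(), strand = character(),
                 position = integer(), count = numeric()), sample_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (format == "auto") {
    # the tabular dialect has strand symbols in column 2; bedGraph has
    # numeric interval starts there
    second <- vapply(fields, function(f) f[2], character(1))
    format <- if (any(second %in% c("+", "-"))) "tsv" else "bedgraph"
  }
  bad_len <- which(lengths(fields) != 4L)
  if (length(bad_len) > 0)
    stop("line ", bad_len[1], " of ", path, " does not have 4 columns",
         call. = FALSE)
  m <- do.call(rbind, fields)
  if (format == "tsv") {
    # drop a header row if present
    if (is.na(suppressWarnings(as.numeric(m[1, 3])))) m <- m[-1, , drop = FALSE]
    if (nrow(m) == 0)
      return(five_prime_track(
        data.frame(contig = character(), strand = character(),
                   position = integer(), count = numeric()), sample_id))
    df <- data.frame(contig = m[, 1], strand = m[, 2],
                     position = suppressWarnings(as.numeric(m[, 3])),
                     count = suppressWarnings(as.numeric(m[, 4])),
                     stringsAsFactors = FALSE)
    if (anyNA(df$position) || anyNA(df$count))
      stop("non-numeric position/count in ", path, call. = FALSE)
  } else {
    start0 <- suppressWarnings(as.numeric(m[, 2]))
    end0 <- suppressWarnings(as.numeric(m[, 3]))
    value <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(start0) || anyNA(end0) || anyNA(value))
      stop("non-numeric bedGraph coordinates in ", path, call. = FALSE)
    if (any(end0 <= start0))
      stop("empty/inverted bedGraph interval in ", path, call. = FALSE)
    n <- end0 - start0
    df <- data.frame(
      contig = rep(m[, 1], n),
      strand = strand,
      position = unlist(Map(function(s, e) (s + 1):e, start0, end0)),
      count = rep(value, n),
      stringsAsFactors = FALSE)
  }
  five_prime_track(df, sample_id)
}

#' @rdname read_five_prime_track
#' @param track a [five_prime_track()] to write (tabular dialect).
#' @export
write_five_prime_track <- function(track, path) {
  stopifnot(inherits(track, "five_prime_track"))
  df <- as.data.frame(track)
  df <- df[order(df$contig, df$strand, df$position), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write a fragment-count matrix
#'
#' TSV with a header row of sample identifiers and a first column of gene
#' identifiers (ERCC spike-in rows included). All cells must be non-negative
#' integers; missing or non-integer cells are an error.
#'
#' @param path file path.
#' @return `read_count_matrix` returns an integer matrix with gene
#'   identifiers as row names and sample identifiers as column names.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs >= 1 sample column", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s) in ", path, call. = FALSE)
  if (!is.numeric(m) || anyNA(m))
    stop("missing or non-numeric cell(s) in ", path, call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers in ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_count_matrix
#' @param m integer count matrix with row and column names.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Sample design
#'
#' Maps replicate identifiers to condition labels, with exactly one
#' condition designated the no-sigma-factor control.
#'
#' @param sample_id character vector of replicate identifiers.
#' @param condition condition label per replicate.
#' @param control the condition that is the no-sigma control.
#' @return data frame of class `sample_design` with attribute `control`.
#' @export
sample_design <- function(sample_id, condition, control) {
  sample_id <- as.character(sample_id)
  condition <- as.character(condition)
  stopifnot(length(sample_id) == length(condition))
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id(s) in design", call. = FALSE)
  if (!control %in% condition)
    stop("control condition '", control, "' absent from design", call. = FALSE)
  tab <- table(condition)
  if (any(tab < 2))
    stop("every condition needs >= 2 replicates; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  df <- data.frame(sample_id = sample_id, condition = condition,
                   stringsAsFactors = FALSE)
  attr(df, "control") <- as.character(control)
  class(df) <- c("sample_design", "data.frame")
  df
}

#' @rdname sample_design
#' @param path TSV with columns `sample_id`, `condition`, `is_control`.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "condition", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("design file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ctrl <- unique(df$condition[as.logical(df$is_control)])
  if (length(ctrl) != 1)
    stop("design file ", path, " must mark exactly one control condition",
         call. = FALSE)
  sample_design(df$sample_id, df$condition, ctrl)
}

#' @rdname sample_design
#' @param design a `sample_design` to write.
#' @export
write_sample_design <- function(design, path) {
  stopifnot(inherits(design, "sample_design"))
  df <- as.data.frame(design)
  df$is_control <- df$condition == attr(design, "control")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

control_samples <- function(design) {
  design$sample_id[design$condition == attr(design, "control")]
}
treatment_samples <- function(design, condition = NULL) {
  if (is.null(condition)) {
    conds <- setdiff(unique(design$condition), attr(design, "control"))
    if (length(conds) != 1)
      stop("design has ", length(conds), " non-control conditions; ",
           "specify one", call. = FALSE)
    condition <- conds
  }
  design$sample_id[design$condition == condition]
}

#' Write a result table deterministically
#'
#' Rows are sorted by the given key columns so identical analyses produce
#' byte-identical files. An optional run identifier is recorded as a
#' leading `#` comment line, which all readers in this package skip.
#'
#' @param df result data frame.
#' @param path output TSV.
#' @param sort_by columns to sort by (defaults to all columns, left to
#'   right).
#' @param run_id optional manifest/run identifier.
#' @export
write_results <- function(df, path, sort_by = names(df), run_id = NULL) {
  df <- as.data.frame(df)
  if (nrow(df) > 0 && length(sort_by) > 0)
    df <- df[do.call(order, df[sort_by]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(run_id)) writeLines(paste0("# run_id=", run_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export a regulatory network
#'
#' Writes a sigma-to-gene edge table as SIF (`source\tinteraction\ttarget`)
#' and GraphML.
#'
#' @param edges data frame with columns `sigma_id`, `gene_id` and
#'   optionally `provenance`.
#' @param sif_path,graphml_path output paths (either may be `NULL` to
#'   skip).
#' @export
write_network_files <- function(edges, sif_path = NULL, graphml_path = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("sigma_id", "gene_id") %in% names(edges)))
  edges <- edges[order(edges$sigma_id, edges$gene_id), , drop = FALSE]
  if (!is.null(sif_path)) {
    writeLines(paste(edges$sigma_id, "transcribes", edges$gene_id,
                     sep = "\t"), sif_path)
  }
  if (!is.null(graphml_path)) {
    attrs <- edges[, setdiff(names(edges), c("sigma_id", "gene_id")),
                   drop = FALSE]
    g <- igraph::graph_from_data_frame(
      cbind(edges[, c("sigma_id", "gene_id")], attrs), directed = TRUE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(NULL)
}
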