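#' Build the sigma-to-gene regulatory network
#'
#' Takes one or more target tables (and optionally a prior edge table, e.g.
#' previously known regulon members) and builds a directed network of
#' deduplicated sigma -> gene edges with provenance.
#'
#' @param targets a target table or list of target tables (columns
#'   `sigma_id`, `gene_id`).
#' @param prior optional data frame of prior edges (`sigma_id`,
#'   `gene_id`).
#' @return object of class `regulon_network`: list with `nodes` (data
#'   frame `id`, `type`) and `edges` (data frame `sigma_id`, `gene_id`,
#'   `provenance` in `{"rivit", "prior", "rivit,prior"}`).
#' @export
build_network <- function(targets, prior = NULL) {
  if (is.data.frame(targets)) targets <- list(targets)
  riv <- unique(do.call(rbind, lapply(targets, function(t)
    as.data.frame(t)[, c("sigma_id", "gene_id")])))
  if (is.null(riv)) riv <- data.frame(sigma_id = character(),
                                      gene_id = character())
  pri <- if (is.null(prior) || nrow(prior) == 0)
    data.frame(sigma_id = character(), gene_id = character())
  else unique(as.data.frame(prior)[, c("sigma_id", "gene_id")])
  rk <- paste(riv$sigma_id, riv$gene_id, sep = "\r")
  pk <- paste(pri$sigma_id, pri$gene_id, sep = "\r")
  all_k <- union(rk, pk)
  split_k <- strsplit(all_k, "\r", fixed = TRUE)
  edges <- data.frame(
    sigma_id = vapply(split_k, `[`, character(1), 1),
    gene_id = vapply(split_k, `[`, character(1), 2),
    provenance = paste0(ifelse(all_k %in% rk, "rivit", ""),
                        ifelse(all_k %in% rk & all_k %in% pk, ",", ""),
                        ifelse(all_k %in% pk, "prior", "")),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$sigma_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(id = sort(unique(edges$sigma_id)), type = "sigma_factor",
               stringsAsFactors = FALSE),
    data.frame(id = sort(setdiff(unique(edges$gene_id),
                                 unique(edges$sigma_id))),
               type = "gene", stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges), class = "regulon_network")
}

#' @export
print.regulon_network <- function(x, ...) {
  cat("Regulon network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "sigma_factor"), "sigma factors ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Shared-regulon crosstalk matrix
#'
#' Entry (a, b) is the number of genes in both sigma factors' regulons;
#' the diagonal holds regulon sizes.
#'
#' @param network a `regulon_network` (or a target table / list accepted
#'   by [build_network()]).
#' @return symmetric integer matrix, sigma factors as row/column names.
#' @export
shared_regulon_matrix <- function(network) {
  if (!inherits(network, "regulon_network")) network <- build_network(network)
  regs <- split(network$edges$gene_id, network$edges$sigma_id)
  sig <- sort(names(regs))
  m <- matrix(0L, length(sig), length(sig), dimnames = list(sig, sig))
  for (a in sig) for (b in sig)
    m[a, b] <- length(intersect(regs[[a]], regs[[b]]))
  m
}

# symmetric one-to-one matching of two sorted position vectors within tol
match_positions <- function(a, b, tol) {
  a <- sort(a); b <- sort(b)
  i <- 1L; j <- 1L; n <- 0L
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tol) { n <- n + 1L; i <- i + 1L; j <- j + 1L }
    else if (d < 0) i <- i + 1L
    else j <- j + 1L
  }
  n
}

#' Shared-TSS crosstalk matrix
#'
#' Entry (a, b) counts TSSs of sigma factor a matched one-to-one to TSSs
#' of sigma factor b on the same contig and strand within
#' `tolerance_nt`. Matching walks both sorted position lists in ascending
#' order and pairs the nearest unmatched positions, so the count is
#' symmetric by construction; tolerance 0 gives exact-position
#' intersection counts. The diagonal holds each sigma factor's TSS count.
#'
#' @param tss_sets named list (one element per sigma factor) of data
#'   frames with columns `contig`, `strand`, `position`.
#' @param tolerance_nt positional tolerance (default 2).
#' @return symmetric integer matrix.
#' @export
shared_tss_matrix <- function(tss_sets, tolerance_nt = 2) {
  sig <- names(tss_sets)
  stopifnot(!is.null(sig), all(nzchar(sig)))
  m <- matrix(0L, length(sig), length(sig), dimnames = list(sig, sig))
  for (a in sig) for (b in sig) {
    ta <- as.data.frame(tss_sets[[a]]); tb <- as.data.frame(tss_sets[[b]])
    if (a == b) { m[a, b] <- nrow(ta); next }
    total <- 0L
    keys <- unique(rbind(ta[, c("contig", "strand")],
                         tb[, c("contig", "strand")]))
    for (k in seq_len(nrow(keys))) {
      pa <- ta$position[ta$contig == keys$contig[k] &
                          ta$strand == keys$strand[k]]
      pb <- tb$position[tb$contig == keys$contig[k] &
                          tb$strand == keys$strand[k]]
      total <- total + match_positions(pa, pb, tolerance_nt)
    }
    m[a, b] <- total
  }
  m
}

#' Write a crosstalk matrix as TSV
#'
#' @param m matrix with sigma identifiers as dimnames.
#' @param path output TSV.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sigma_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
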