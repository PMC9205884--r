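# small in-code fixtures shared across test files

make_track <- function(contig, strand, position, count,
                       sample_id = "s1") {
  five_prime_track(data.frame(contig = contig, strand = strand,
                              position = position, count = count,
                              stringsAsFactors = FALSE), sample_id)
}

# a pair of replicate tracks holding ERCC first-nucleotide counts only
ercc_tracks <- function(counts) {
  # counts: matrix transcripts x samples
  lapply(seq_len(ncol(counts)), function(j)
    make_track(rownames(counts), "+", 1L, counts[, j],
               colnames(counts)[j])) |>
    stats::setNames(colnames(counts))
}

# exhaustive single-linkage oracle: two positions share a cluster iff they
# are connected by a chain of pairwise gaps <= window; connectivity is the
# transitive closure of the full pairwise adjacency matrix
cluster_oracle <- function(positions, window) {
  p <- sort(positions)
  n <- length(p)
  if (n == 0) return(list())
  adj <- abs(outer(p, p, "-")) <= window
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- apply(reach, 1, function(r) min(which(r)))
  out <- unname(lapply(split(p, comp), sort))
  out[order(vapply(out, min, numeric(1)))]
}

pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# hand Benjamini-Hochberg: p_(i) * m / i, cumulative minimum from the top
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

default_design <- function(n = 2) {
  sample_design(c(paste0("sigma_", 1:n), paste0("none_", 1:n)),
                rep(c("sigma", "no_sigma"), each = n),
                control = "no_sigma")
}

# four replicate tracks (2 sigma + 2 control) with random genome positions
# and fixed ERCC first-nucleotide counts
make_sim_tracks <- function(seed, n_pos = 30, len = 5000) {
  set.seed(seed)
  mk <- function(id, strand_pool = c("+", "-")) {
    pos <- sample(len, n_pos)
    make_track("chr", sample(strand_pool, n_pos, replace = TRUE),
               pos, sample(0:50, n_pos, replace = TRUE), id)
  }
  ercc <- rbind("ERCC-A" = c(50, 60, 55, 40), "ERCC-B" = c(30, 20, 25, 35))
  colnames(ercc) <- c("sig1", "sig2", "ctl1", "ctl2")
  tr <- list(sig1 = mk("sig1"), sig2 = mk("sig2"),
             ctl1 = mk("ctl1"), ctl2 = mk("ctl2"))
  for (s in names(tr)) {
    add <- make_track(rownames(ercc), "+", 1L, ercc[, s], s)
    tr[[s]] <- five_prime_track(rbind(as.data.frame(tr[[s]]),
                                      as.data.frame(add)), s)
  }
  tr
}
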