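test_that("genome simulation is deterministic and strand-normalized", {
  g1 <- simulate_genome(n_genes = 10, contig_length = 20000, seed = 71,
                        operon_pairs = 2)
  g2 <- simulate_genome(n_genes = 10, contig_length = 20000, seed = 71,
                        operon_pairs = 2)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
  neg <- g1$genes[g1$genes$strand == "-", ]
  expect_true(all(neg$start > neg$end))  # initiation codon at rightmost
  pos <- g1$genes[g1$genes$strand == "+", ]
  expect_true(all(pos$start < pos$end))
  expect_equal(nrow(g1$operon_pairs), 2L)
  # operon pair members are co-oriented and adjacent
  for (k in seq_len(nrow(g1$operon_pairs))) {
    p <- g1$genes[g1$genes$gene_id == g1$operon_pairs$parent[k], ]
    c_ <- g1$genes[g1$genes$gene_id == g1$operon_pairs$child[k], ]
    expect_equal(p$strand, c_$strand)
    dir <- if (p$strand == "+") 1L else -1L
    gap <- (c_$start - p$end) * dir - 1L
    expect_true(gap >= 0 && gap <= 50)
  }
})

test_that("a zero-gene genome has sequence but no features", {
  g <- simulate_genome(n_genes = 0, contig_length = 5000, seed = 73)
  expect_equal(nrow(g$genes), 0L)
  expect_equal(Biostrings::width(g$genome)[[1]], 5000L)
})

test_that("fragment ends match a naive motif-scan oracle", {
  g <- simulate_genome(n_genes = 0, contig_length = 30000, seed = 79)
  ends <- simulate_fragment_ends(g$genome)
  seq <- as.character(g$genome[[1]])
  naive <- sort(unique(unlist(lapply(
    c("GAATTC", "AAGCTT", "GGATCC", "CTCGAG"),
    function(m) {
      hits <- gregexpr(m, seq, fixed = TRUE)[[1]]
      hits[hits > 0]
    }))))
  # all four recognition sites are palindromic, so both strands coincide
  expect_equal(ends$position, naive)
  none <- simulate_fragment_ends(
    Biostrings::DNAStringSet(c(x = "AAAAAAAAAA")))
  expect_equal(nrow(none), 0L)
  planted <- simulate_fragment_ends(
    Biostrings::DNAStringSet(c(x = "AAAGAATTCAAA")))
  expect_equal(planted$position, 4L)
})

small_truth <- function(seed = 83) {
  sim <- simulate_rivit(n_genes = 20, contig_length = 40000, seed = seed,
                        n_planted_tss = 6, regulon_size = 5,
                        n_operon_pairs = 1)
  sim$truth
}

test_that("5'-end track simulation is seed-deterministic", {
  truth <- small_truth()
  t1 <- simulate_five_prime_tracks(truth, seed = 85)
  t2 <- simulate_five_prime_tracks(truth, seed = 85)
  for (s in names(t1$tracks))
    expect_identical(as.data.frame(t1$tracks[[s]]),
                     as.data.frame(t2$tracks[[s]]))
  t3 <- simulate_five_prime_tracks(truth, seed = 86)
  expect_false(identical(as.data.frame(t1$tracks[[1]]),
                         as.data.frame(t3$tracks[[1]])))
})

test_that("silencing every signal source yields empty tracks", {
  truth <- small_truth()
  truth$planted_tss <- truth$planted_tss[0, ]
  tr <- simulate_five_prime_tracks(truth, background_positions = 0,
                                   background_mean = 0, end_boost = 0,
                                   ercc_count_scale = 0, seed = 87)
  for (t in tr$tracks) expect_equal(nrow(t), 0L)
})

test_that("planted TSS counts realize their NB mean", {
  truth <- small_truth()
  # pin library efficiency so realized totals estimate the raw mean
  tr <- simulate_five_prime_tracks(truth, n_replicates = 25, seed = 89,
                                   efficiency_range = c(1, 1))
  sig <- tr$tracks[startsWith(names(tr$tracks), "sigma_")]
  pl <- truth$planted_tss
  totals <- unlist(lapply(sig, function(t) vapply(
    seq_len(nrow(pl)), function(i)
      sum(t$count[t$contig == pl$contig[i] & t$strand == pl$strand[i] &
                    abs(t$position - pl$position[i]) <= 1]) -
      # subtract expected background contribution: none planted there
      0, numeric(1))))
  n <- length(totals)
  se <- stats::sd(totals) / sqrt(n)
  expect_lt(abs(mean(totals) - 100), 4 * se + 2)
})

test_that("count matrices plant fold changes but leave spike-ins alone", {
  truth <- small_truth()
  cm <- simulate_count_matrix(truth, n_replicates = 20, seed = 91,
                              efficiency_range = c(1, 1))
  m <- cm$counts
  sig <- cm$design$sample_id[cm$design$condition == "sigma"]
  ctl <- cm$design$sample_id[cm$design$condition == "no_sigma"]
  reg <- truth$regulon$gene_id
  ratio <- rowMeans(m[reg, sig, drop = FALSE]) /
    rowMeans(m[reg, ctl, drop = FALSE])
  expect_true(all(abs(log2(ratio) - 2) < 0.5))
  high_ercc <- truth$ercc$id[truth$ercc$abundance > 50]
  er <- rowMeans(m[high_ercc, sig, drop = FALSE]) /
    rowMeans(m[high_ercc, ctl, drop = FALSE])
  expect_true(all(abs(log2(er)) < 0.5))
  cm2 <- simulate_count_matrix(truth, n_replicates = 20, seed = 91,
                               efficiency_range = c(1, 1))
  expect_identical(cm$counts, cm2$counts)
})

test_that("full simulations are reproducible and internally consistent", {
  s1 <- simulate_rivit(n_genes = 20, contig_length = 40000, seed = 93,
                       n_planted_tss = 6, regulon_size = 5,
                       n_operon_pairs = 1)
  s2 <- simulate_rivit(n_genes = 20, contig_length = 40000, seed = 93,
                       n_planted_tss = 6, regulon_size = 5,
                       n_operon_pairs = 1)
  expect_identical(s1$counts, s2$counts)
  expect_identical(as.data.frame(s1$truth$planted_tss),
                   as.data.frame(s2$truth$planted_tss))
  # every direct-regulon TSS lies within the upstream window of its gene
  pl <- s1$truth$planted_tss
  direct <- pl[!is.na(pl$target_gene), ]
  for (i in seq_len(nrow(direct))) {
    g <- s1$genes[s1$genes$gene_id == direct$target_gene[i], ]
    dir <- if (g$strand == "+") 1L else -1L
    d <- (g$start - direct$position[i]) * dir
    expect_true(d >= 0 && d <= 300)
  }
})

test_that("simulations round trip through the on-disk formats", {
  sim <- simulate_rivit(n_genes = 20, contig_length = 40000, seed = 95,
                        n_planted_tss = 6, regulon_size = 5,
                        n_operon_pairs = 1)
  dir <- tempfile()
  paths <- write_simulation(sim, dir)
  genes <- read_gene_annotation(paths$annotation)
  expect_equal(as.data.frame(genes)[order(genes$gene_id), ],
               as.data.frame(sim$genes)[order(sim$genes$gene_id), ],
               ignore_attr = TRUE)
  tr <- read_five_prime_track(paths$track_sigma_1, "sigma_1")
  expect_equal(as.data.frame(tr), as.data.frame(sim$tracks$sigma_1))
  expect_identical(read_count_matrix(paths$counts),
                   sim$counts[order(rownames(sim$counts)), ])
  genome <- Biostrings::readDNAStringSet(paths$genome)
  expect_equal(sort(names(genome)), sort(names(sim$genome)))
})
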