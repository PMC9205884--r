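test_that("gap clustering groups positions within the window, inclusively", {
  expect_equal(cluster_positions(c(100, 150, 400), 100),
               list(c(100L, 150L), 400L))
  expect_equal(cluster_positions(42, 100), list(42L))
  # chained gaps of exactly the window size stay in one cluster
  expect_equal(cluster_positions(c(1, 101, 201), 100),
               list(c(1L, 101L, 201L)))
  expect_equal(cluster_positions(integer(0), 100), list())
})

test_that("gap clustering matches the exhaustive single-linkage oracle", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(1:50, 1)
    pos <- sample(1:2000, n)
    win <- sample(c(5, 20, 100), 1)
    expect_equal(cluster_positions(pos, win), cluster_oracle(pos, win))
  }
})

test_that("subclustering keeps runs below the positional SD bound", {
  expect_equal(subcluster(c(100, 103, 105), 10), list(c(100L, 103L, 105L)))
  expect_lt(pop_sd_oracle(c(100, 103, 105)), 10)
  expect_equal(subcluster(77, 10), list(77L))
  # SD of {100, 150} is 25, so the pair splits into singletons
  expect_equal(pop_sd_oracle(c(100, 150)), 25)
  expect_equal(subcluster(c(100, 150), 10), list(100L, 150L))
})

test_that("subcluster partitions are valid and maximal on random clusters", {
  set.seed(17)
  for (rep in 1:30) {
    pos <- sort(sample(1:300, sample(2:30, 1)))
    subs <- subcluster(pos, 10)
    expect_equal(sort(unlist(subs)), pos)            # partition
    for (s in subs) expect_lt(pop_sd_oracle(s), 10)  # every run qualifies
    # greedy maximality: the next member could not have joined its
    # predecessor run
    if (length(subs) > 1)
      for (k in 2:length(subs))
        expect_gte(pop_sd_oracle(c(subs[[k - 1]], subs[[k]][1])), 10)
  }
})

test_that("the TSS is the argmax member and carries the summed counts", {
  cnt <- matrix(c(10, 2, 1), 3, 1, dimnames = list(NULL, "r1"))
  call <- call_tss(c(100, 103, 105), cnt, "+")
  expect_equal(call$position, 100L)
  expect_equal(unname(call$counts), 13)
  single <- call_tss(42, matrix(7, 1, 1, dimnames = list(NULL, "r1")), "+")
  expect_equal(single$position, 42L)
  expect_equal(unname(single$counts), 7)
})

test_that("argmax ties resolve to the most upstream position per strand", {
  cnt <- matrix(c(5, 5), 2, 1)
  expect_equal(call_tss(c(100, 110), cnt, "+")$position, 100L)
  expect_equal(call_tss(c(100, 110), cnt, "-")$position, 110L)
})

test_that("the abundance filter drops calls below threshold in any sigma replicate", {
  nm <- rbind(c(8.0, 3.9), c(4.0, 4.0), c(0, 0), c(12, 44))
  got <- filter_min_count(nm, 4)
  expect_equal(unname(got), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("dependence requires both criteria on normalized counts", {
  # criterion (i): every sigma replicate above every control replicate
  # criterion (ii): 2nd-lowest sigma >= ratio x max control
  expect_true(determine_dependence(c(8, 10, 12), c(1, 2), 4))
  expect_true(determine_dependence(c(5, 10, 12), c(1, 2), 4))
  expect_false(determine_dependence(c(5, 7, 12), c(1, 2), 4))   # 7 < 8
  expect_false(determine_dependence(c(2, 10, 12), c(1, 3), 4))  # (i) fails
  expect_true(determine_dependence(c(4, 4), c(0, 0), 4))
  expect_error(determine_dependence(5, c(1, 2), 4), ">= 2")
})


test_that("TSS calling conserves every clustered 5'-end read", {
  for (seed in c(23, 29, 31)) {
    tr <- make_sim_tracks(seed)
    calls <- call_tss_map(tr[c("sig1", "sig2")], tr[c("ctl1", "ctl2")],
                          c("ERCC-A", "ERCC-B"))
    for (s in c("sig1", "sig2")) {
      genome_rows <- !tr[[s]]$contig %in% c("ERCC-A", "ERCC-B")
      expect_equal(sum(calls[[paste0("raw_", s)]]),
                   sum(tr[[s]]$count[genome_rows]))
    }
  }
})

test_that("tightening thresholds never enlarges the dependent TSS set", {
  tr <- make_sim_tracks(37)
  dep_set <- function(min_count, ratio) {
    cfg <- rivit_config(min_norm_count = min_count,
                        dependence_ratio = ratio,
                        min_ercc_first_nt_reads = 10)
    calls <- call_tss_map(tr[c("sig1", "sig2")], tr[c("ctl1", "ctl2")],
                          c("ERCC-A", "ERCC-B"), cfg)
    with(calls[calls$sigma_dependent, ],
         paste(contig, strand, position))
  }
  base <- dep_set(4, 4)
  expect_true(all(dep_set(8, 4) %in% base))
  expect_true(all(dep_set(4, 8) %in% base))
})

test_that("mirrored coordinates and strands yield mirrored TSS calls", {
  tr <- make_sim_tracks(41)
  L <- 6001L
  flip <- function(t) {
    df <- as.data.frame(t)
    genome <- !df$contig %in% c("ERCC-A", "ERCC-B")
    df$position[genome] <- L - df$position[genome]
    df$strand[genome] <- ifelse(df$strand[genome] == "+", "-", "+")
    five_prime_track(df, attr(t, "sample_id"))
  }
  fwd <- call_tss_map(tr[c("sig1", "sig2")], tr[c("ctl1", "ctl2")],
                      c("ERCC-A", "ERCC-B"))
  rev <- call_tss_map(lapply(tr[c("sig1", "sig2")], flip),
                      lapply(tr[c("ctl1", "ctl2")], flip),
                      c("ERCC-A", "ERCC-B"))
  key <- function(x) sort(paste(x$contig,
                                ifelse(x$strand == "+", "-", "+"),
                                L - x$position, x$sigma_dependent))
  expect_equal(key(rev), sort(paste(fwd$contig, fwd$strand, fwd$position,
                                    fwd$sigma_dependent)))
})
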