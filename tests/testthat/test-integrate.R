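# two-contig layout exercising both strands
demo_genes <- function() {
  gene_set(data.frame(
    gene_id = c("gA", "gB", "gC", "gM"),
    contig = c("chr", "chr", "chr", "chr"),
    strand = c("+", "+", "+", "-"),
    start = c(1000L, 2050L, 2480L, 5000L),
    end = c(2000L, 2400L, 2900L, 4200L),
    stringsAsFactors = FALSE))
}

tss_at <- function(position, strand = "+", contig = "chr")
  data.frame(contig = contig, strand = strand, position = position,
             stringsAsFactors = FALSE)

test_that("direct targets need an upstream TSS within the window, inclusive", {
  g <- demo_genes()
  expect_equal(assign_direct_targets(g, "gA", tss_at(999), 300)$gene_id,
               "gA")                                   # d = 1
  expect_equal(assign_direct_targets(g, "gA", tss_at(700), 300)$gene_id,
               "gA")                                   # d = 300, inclusive
  expect_equal(nrow(assign_direct_targets(g, "gA", tss_at(699), 300)),
               0L)                                     # d = 301
  expect_equal(assign_direct_targets(g, "gA", tss_at(1000), 300)$distance,
               0L)                                     # leaderless
  expect_equal(nrow(assign_direct_targets(g, "gA", tss_at(1001), 300)),
               0L)                                     # downstream of codon
  # minus strand: upstream means larger coordinates
  expect_equal(assign_direct_targets(g, "gM", tss_at(5100, "-"),
                                     300)$gene_id, "gM")
  expect_equal(nrow(assign_direct_targets(g, "gM", tss_at(4900, "-"), 300)),
               0L)
  # strand and upregulation are both required
  expect_equal(nrow(assign_direct_targets(g, "gA", tss_at(999, "-"), 300)),
               0L)
  expect_equal(nrow(assign_direct_targets(g, character(0), tss_at(999),
                                          300)), 0L)
})

test_that("operon extension obeys the inclusive 50 nt gap", {
  g <- demo_genes()  # gA ends 2000; gB starts 2050 -> gap 49
  direct <- assign_direct_targets(g, c("gA", "gB"), tss_at(999), 300)
  ext <- extend_operons(direct, c("gA", "gB"), g, 50)
  expect_setequal(ext$gene_id, c("gA", "gB"))
  expect_equal(ext$evidence[ext$gene_id == "gB"], "operon")
  # move gB to gap 51 -> no extension
  g2 <- g; g2$start[g2$gene_id == "gB"] <- 2052L
  ext2 <- extend_operons(assign_direct_targets(g2, c("gA", "gB"),
                                               tss_at(999), 300),
                         c("gA", "gB"), g2, 50)
  expect_equal(ext2$gene_id, "gA")
})

test_that("operon chains close to a fixed point with parent links", {
  g <- demo_genes()  # gB -> gC gap = 2480 - 2400 - 1 = 79? use 30 nt
  g$start[g$gene_id == "gC"] <- 2431L
  g$end[g$gene_id == "gC"] <- 2900L
  up <- c("gA", "gB", "gC")
  ext <- extend_operons(assign_direct_targets(g, up, tss_at(999), 300),
                        up, g, 50)
  expect_setequal(ext$gene_id, up)
  expect_equal(sum(ext$evidence == "operon"), 2)
  # every operon target chains back to a direct target
  parent_of <- stats::setNames(ext$parent_gene, ext$gene_id)
  for (gid in ext$gene_id[ext$evidence == "operon"]) {
    cur <- gid
    for (step in 1:10) {
      cur <- parent_of[[cur]]
      if (ext$evidence[ext$gene_id == cur] == "direct") break
    }
    expect_equal(ext$evidence[ext$gene_id == cur], "direct")
  }
})

test_that("assignments are independent of gene input order", {
  g <- demo_genes()
  g$start[g$gene_id == "gC"] <- 2431L
  up <- c("gA", "gB", "gC", "gM")
  tss <- rbind(tss_at(999), tss_at(5100, "-"))
  ref <- extend_operons(assign_direct_targets(g, up, tss, 300), up, g, 50)
  for (rep in 1:5) {
    perm <- g[sample(nrow(g)), ]
    class(perm) <- class(g)
    got <- extend_operons(assign_direct_targets(perm, sample(up), tss, 300),
                          sample(up), perm, 50)
    expect_equal(got[order(got$gene_id), ], ref[order(ref$gene_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("enlarging windows never shrinks the target set", {
  g <- demo_genes()
  up <- c("gA", "gB", "gC", "gM")
  tss <- rbind(tss_at(720), tss_at(5250, "-"))
  base <- extend_operons(assign_direct_targets(g, up, tss, 300), up, g, 50)
  for (w in c(300, 400, 600)) for (gap in c(50, 80)) {
    bigger <- extend_operons(assign_direct_targets(g, up, tss, w),
                             up, g, gap)
    expect_true(all(base$gene_id %in% bigger$gene_id))
  }
})

test_that("TSSs inside another gene still qualify but are flagged", {
  g <- gene_set(data.frame(
    gene_id = c("up", "dn"), contig = "chr", strand = "+",
    start = c(100L, 1100L), end = c(1050L, 2000L)))
  # TSS at 1000 sits inside 'up' (100..1050) and 100 nt upstream of 'dn'
  res <- assign_direct_targets(g, "dn", tss_at(1000), 300)
  expect_equal(res$gene_id, "dn")
  expect_true(res$tss_within_gene)
})

test_that("regulon summaries count evidence classes per sigma factor", {
  g <- demo_genes()
  up <- c("gA", "gB")
  t1 <- extend_operons(assign_direct_targets(g, up, tss_at(999), 300,
                                             sigma_id = "sigR"),
                       up, g, 50)
  s <- summarize_regulon(t1)
  expect_equal(s$sigma_id, "sigR")
  expect_equal(s$n_direct, 1L)
  expect_equal(s$n_operon, 1L)
  expect_equal(s$n_total, 2L)
})
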