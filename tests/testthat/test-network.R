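tgt <- function(sigma, genes)
  data.frame(sigma_id = sigma, gene_id = genes, stringsAsFactors = FALSE)

test_that("networks deduplicate edges and track provenance", {
  net <- build_network(tgt("sigR", c("g1", "g2")))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sum(net$nodes$type == "sigma_factor"), 1L)
  expect_equal(sum(net$nodes$type == "gene"), 2L)
  both <- build_network(tgt("sigR", "g1"), prior = tgt("sigR", "g1"))
  expect_equal(nrow(both$edges), 1L)
  expect_equal(both$edges$provenance, "rivit,prior")
  shared <- build_network(list(tgt("sigR", "g1"), tgt("sigH", "g1")))
  expect_equal(sum(shared$edges$gene_id == "g1"), 2L)
})

test_that("shared-regulon matrices count pairwise intersections", {
  m <- shared_regulon_matrix(list(tgt("a", c("g1", "g2", "g3")),
                                  tgt("b", c("g2", "g3", "g4"))))
  expect_equal(m["a", "b"], 2L)
  expect_equal(m["a", "a"], 3L)
  expect_equal(m, t(m))
  dis <- shared_regulon_matrix(list(tgt("a", "g1"), tgt("b", "g2")))
  expect_equal(dis["a", "b"], 0L)
  same <- shared_regulon_matrix(list(tgt("a", c("x", "y")),
                                     tgt("b", c("x", "y"))))
  expect_true(all(same == 2L))
})

tss_set <- function(position, strand = "+", contig = "chr")
  data.frame(contig = contig, strand = strand, position = position,
             stringsAsFactors = FALSE)

test_that("shared-TSS matrices match positions within the tolerance", {
  m2 <- shared_tss_matrix(list(a = tss_set(100), b = tss_set(102)), 2)
  expect_equal(m2["a", "b"], 1L)
  m1 <- shared_tss_matrix(list(a = tss_set(100), b = tss_set(102)), 1)
  expect_equal(m1["a", "b"], 0L)
  ident <- shared_tss_matrix(list(a = tss_set(c(10, 50, 90)),
                                  b = tss_set(c(10, 50, 90))), 2)
  expect_true(all(ident == 3L))
  opp <- shared_tss_matrix(list(a = tss_set(100, "+"),
                                b = tss_set(100, "-")), 2)
  expect_equal(opp["a", "b"], 0L)
})

test_that("tolerance zero reduces to exact intersection; matching is one-to-one", {
  set.seed(67)
  for (rep in 1:10) {
    a <- tss_set(sample(1:200, 20))
    b <- tss_set(sample(1:200, 20))
    m0 <- shared_tss_matrix(list(a = a, b = b), 0)
    expect_equal(m0["a", "b"],
                 length(intersect(a$position, b$position)))
    mt <- shared_tss_matrix(list(a = a, b = b), 3)
    expect_equal(mt, t(mt))
    # one-to-one: shared count cannot exceed either set size
    expect_lte(mt["a", "b"], min(mt["a", "a"], mt["b", "b"]))
  }
  # dense case: three a-positions cannot all match one b-position
  dense <- shared_tss_matrix(list(a = tss_set(c(99, 100, 101)),
                                  b = tss_set(100)), 2)
  expect_equal(dense["a", "b"], 1L)
})

test_that("network files export as SIF and GraphML", {
  net <- build_network(list(tgt("sigR", c("g1", "g2")), tgt("sigH", "g1")))
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  write_network_files(net$edges, sif, gml)
  lines <- readLines(sif)
  expect_equal(length(lines), 3L)
  expect_true(all(grepl("\ttranscribes\t", lines)))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 4L)
  expect_equal(igraph::gsize(g), 3L)
})
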