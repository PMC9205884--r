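demo_genome <- function() {
  set.seed(61)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  Biostrings::DNAStringSet(c(chr = s))
}

test_that("promoter windows end at the TSS in transcription direction", {
  genome <- demo_genome()
  chr <- as.character(genome[["chr"]])
  w <- extract_promoter_windows(
    data.frame(contig = "chr", strand = "+", position = 100), genome, 50)
  expect_equal(as.character(w[[1]]), substr(chr, 51, 100))
  expect_equal(names(w), "chr:+:100")
  wm <- extract_promoter_windows(
    data.frame(contig = "chr", strand = "-", position = 100), genome, 50)
  expect_equal(as.character(wm[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr, 100, 149)))))
})

test_that("TSSs too close to the contig edge are skipped with a warning", {
  genome <- demo_genome()
  expect_warning(
    w <- extract_promoter_windows(
      data.frame(contig = "chr", strand = "+", position = 10), genome, 50),
    "edge")
  expect_equal(length(w), 0L)
  expect_warning(
    extract_promoter_windows(
      data.frame(contig = "chr", strand = "-", position = 290), genome, 50),
    "edge")
})

test_that("strand flip returns reverse-complemented windows", {
  genome <- demo_genome()
  fwd <- extract_promoter_windows(
    data.frame(contig = "chr", strand = "+", position = 150), genome, 40)
  # the mirrored TSS of a plus-strand window [111,150] is the minus-strand
  # TSS at 111 with window [111,150]
  rev <- extract_promoter_windows(
    data.frame(contig = "chr", strand = "-", position = 111), genome, 40)
  expect_equal(as.character(rev[[1]]),
               as.character(Biostrings::reverseComplement(fwd[[1]])))
})

motif_records <- function() {
  data.frame(
    motif_id = c("m_narrow", "m_ok", "m_best", "m_rare", "m_weak"),
    width = c(21L, 22L, 30L, 28L, 25L),
    n_sites = c(15L, 10L, 40L, 5L, 30L),
    e_value = c(1e-9, 1e-6, 1e-9, 1e-12, 1e-4))
}

test_that("motif filtering applies width, site and E-value rules", {
  res <- filter_motifs(motif_records(), 22, 35, 10, 1e-5)
  expect_setequal(res$retained$motif_id, c("m_ok", "m_best"))
  # width 21 rejected despite excellent E; 5 sites rejected; E 1e-4 rejected
  expect_false(any(c("m_narrow", "m_rare", "m_weak") %in%
                     res$retained$motif_id))
  expect_equal(res$consensus$motif_id, "m_best")  # smallest E value
  expect_true(res$retained$high_confidence[
    res$retained$motif_id == "m_best"])
  expect_false(res$retained$high_confidence[
    res$retained$motif_id == "m_ok"])
})

test_that("motif filtering is idempotent and handles empty retention", {
  res <- filter_motifs(motif_records(), 22, 35, 10, 1e-5)
  again <- filter_motifs(res$retained[, names(motif_records())],
                         22, 35, 10, 1e-5)
  expect_equal(again$retained$motif_id, res$retained$motif_id)
  none <- filter_motifs(motif_records(), 22, 35, 10, 1e-20)
  expect_equal(nrow(none$retained), 0L)
  expect_null(none$consensus)
})

test_that("motif records parse from MEME XML and TSV", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<MEME>",
    '  <motifs>',
    '    <motif id="motif_1" width="28" sites="12" e_value="3.1e-07"/>',
    '    <motif id="motif_2" width="18" sites="40" e_value="2.0e-02"/>',
    "  </motifs>",
    "</MEME>"), xml)
  rec <- read_motif_records(xml)
  expect_equal(rec$motif_id, c("motif_1", "motif_2"))
  expect_equal(rec$width, c(28L, 18L))
  expect_equal(rec$e_value, c(3.1e-7, 2e-2))
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(motif_records(), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_motif_records(tsv)$motif_id, motif_records()$motif_id)
})

test_that("position weight matrices must have unit column sums", {
  pwm <- matrix(0.25, 4, 10)
  expect_silent(validate_pwm(pwm))
  pwm[1, 3] <- 0.5
  expect_error(validate_pwm(pwm), "sum to 1")
})
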