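# evaluate code under a temporary RNG seed, restoring caller RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Simulate a bacterial genome with annotated genes
#'
#' Generates a random single-contig genome and places non-overlapping
#' genes on both strands, separated by wide intergenic gaps except for a
#' requested number of co-oriented adjacent gene pairs with short
#' (operon-like) gaps. Deterministic under `seed`.
#'
#' @param n_genes number of genes to place (operon-pair members count).
#' @param contig_length contig length (nt).
#' @param seed integer RNG seed.
#' @param operon_pairs number of co-oriented adjacent pairs with a short
#'   gap (each pair consumes two of `n_genes`).
#' @param gene_length_range min/max gene length (nt).
#' @param intergenic_range min/max gap between independent gene units.
#' @param operon_gap_range min/max gap inside an operon pair (nt).
#' @param contig_name contig identifier.
#' @return list with `genome` (a `DNAStringSet`), `genes` (a
#'   [gene_set()]) and `operon_pairs` (data frame `parent`, `child`:
#'   upstream and downstream member in transcription direction).
#' @export
simulate_genome <- function(n_genes = 60, contig_length = 100000L,
                            seed = 101L, operon_pairs = 0L,
                            gene_length_range = c(300L, 900L),
                            intergenic_range = c(400L, 800L),
                            operon_gap_range = c(20L, 40L),
                            contig_name = "chr") {
  stopifnot(operon_pairs * 2 <= n_genes)
  with_seed(seed, {
    seqchr <- paste(sample(c("A", "C", "G", "T"), contig_length,
                           replace = TRUE), collapse = "")
    genes <- list()
    pairs <- list()
    pos <- 500L
    n_placed <- 0L
    pair_left <- operon_pairs
    rint <- function(rng) sample(seq(rng[1], rng[2]), 1)
    while (n_placed < n_genes) {
      is_pair <- pair_left > 0 && (n_genes - n_placed) >= 2
      len1 <- rint(gene_length_range)
      unit_len <- len1 +
        if (is_pair) rint(operon_gap_range) + rint(gene_length_range) else 0L
      if (pos + unit_len + 500L > contig_length) break
      strand <- sample(c("+", "-"), 1)
      id1 <- sprintf("gene_%03d", n_placed + 1L)
      l1 <- pos; r1 <- pos + len1 - 1L
      genes[[id1]] <- data.frame(
        gene_id = id1, contig = contig_name, strand = strand,
        start = if (strand == "+") l1 else r1,
        end = if (strand == "+") r1 else l1, stringsAsFactors = FALSE)
      pos <- r1 + 1L
      n_placed <- n_placed + 1L
      if (is_pair) {
        gap <- rint(operon_gap_range)
        len2 <- rint(gene_length_range)
        id2 <- sprintf("gene_%03d", n_placed + 1L)
        l2 <- pos + gap; r2 <- l2 + len2 - 1L
        genes[[id2]] <- data.frame(
          gene_id = id2, contig = contig_name, strand = strand,
          start = if (strand == "+") l2 else r2,
          end = if (strand == "+") r2 else l2, stringsAsFactors = FALSE)
        # transcription direction decides which member is upstream
        pairs[[length(pairs) + 1L]] <- if (strand == "+")
          data.frame(parent = id1, child = id2, stringsAsFactors = FALSE)
        else data.frame(parent = id2, child = id1, stringsAsFactors = FALSE)
        pos <- r2 + 1L
        n_placed <- n_placed + 1L
        pair_left <- pair_left - 1L
      }
      pos <- pos + rint(intergenic_range)
    }
    if (n_placed < n_genes)
      stop("contig_length too small for ", n_genes, " genes", call. = FALSE)
    genome <- Biostrings::DNAStringSet(stats::setNames(seqchr, contig_name))
    gdf <- if (length(genes) == 0)
      data.frame(gene_id = character(), contig = character(),
                 strand = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    else do.call(rbind, genes)
    gdf$is_ercc <- logical(nrow(gdf))
    list(genome = genome, genes = gene_set(gdf),
         operon_pairs = if (length(pairs) == 0)
           data.frame(parent = character(), child = character())
         else do.call(rbind, pairs))
  })
}

#' Locate restriction-site fragment ends
#'
#' Finds every occurrence of the recognition motifs (defaults: EcoRI,
#' HindIII, BamHI, XhoI sites) on both strands of the genome. These
#' positions model the ends of the digested template fragments, where the
#' RNA polymerase core enzyme initiates transcription non-specifically.
#'
#' @param genome a `DNAStringSet`.
#' @param motifs character vector of recognition sequences.
#' @return data frame `contig`, `position` (1-based motif start),
#'   deduplicated and sorted.
#' @export
simulate_fragment_ends <- function(genome,
                                   motifs = c("GAATTC", "AAGCTT",
                                              "GGATCC", "CTCGAG")) {
  out <- list()
  for (contig in names(genome)) {
    subj <- genome[[contig]]
    pos <- integer(0)
    for (m in motifs) {
      for (pat in unique(c(m, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(m)))))) {
        hits <- Biostrings::matchPattern(pat, subj)
        pos <- c(pos, BiocGenerics::start(hits))
      }
    }
    if (length(pos) > 0)
      out[[contig]] <- data.frame(contig = contig,
                                  position = sort(unique(pos)),
                                  stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(contig = character(), position = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# draw NB counts; dispersion 0 degenerates to Poisson
rnb <- function(n, mu, dispersion) {
  if (n == 0) return(integer(0))
  if (all(mu == 0)) return(rep(0L, n))
  as.integer(if (dispersion <= 0) stats::rpois(n, mu)
             else stats::rnbinom(n, mu = mu, size = 1 / dispersion))
}

#' Simulate 5'-end tracks for a sigma-factor experiment
#'
#' Control replicates contain negative-binomial background counts at a
#' fixed set of random positions plus boosted counts on both strands at
#' restriction-fragment ends (non-specific initiation by the core enzyme).
#' Sigma-sample replicates add NB counts at the planted TSSs, spread over
#' the position and its two neighbours (+-1 nt jitter). Spike-in contigs
#' receive first-nucleotide counts proportional to their true abundance
#' times a per-sample library efficiency drawn uniformly from
#' `efficiency_range`; the same efficiency scales every count of that
#' replicate, which is what the spike-in normalization factors recover.
#'
#' @param truth a `rivit_truth` list as built by [simulate_rivit()]
#'   (fields used: `contig_lengths`, `planted_tss`, `fragment_ends`,
#'   `ercc`).
#' @param background_positions number of random background positions per
#'   strand.
#' @param background_mean NB mean of a background position.
#' @param end_boost NB mean at a fragment end (per strand).
#' @param nb_dispersion NB dispersion of all track counts.
#' @param n_replicates replicates per condition.
#' @param seed integer RNG seed.
#' @param ercc_count_scale expected first-nucleotide reads per abundance
#'   unit.
#' @param efficiency_range range of per-sample library efficiencies.
#' @param jitter_prob probability mass placed on TSS-1, TSS, TSS+1.
#' @return list with `tracks` (named list of [five_prime_track()]),
#'   `design` (a [sample_design()], control condition `"no_sigma"`) and
#'   `efficiency` (named vector).
#' @export
simulate_five_prime_tracks <- function(truth,
                                       background_positions = 150L,
                                       background_mean = 3,
                                       end_boost = 30,
                                       nb_dispersion = 0.1,
                                       n_replicates = 2L,
                                       seed = 102L,
                                       ercc_count_scale = 2,
                                       efficiency_range = c(0.5, 1),
                                       jitter_prob = c(0.15, 0.7, 0.15)) {
  with_seed(seed, {
    samples <- c(paste0("sigma_", seq_len(n_replicates)),
                 paste0("none_", seq_len(n_replicates)))
    cond <- rep(c("sigma", "no_sigma"), each = n_replicates)
    eff <- stats::setNames(
      stats::runif(length(samples), efficiency_range[1],
                   efficiency_range[2]), samples)
    planted <- truth$planted_tss
    # fixed background position set shared by all replicates
    bg <- list()
    for (contig in names(truth$contig_lengths)) {
      len <- truth$contig_lengths[[contig]]
      for (strand in c("+", "-")) {
        cand <- sample.int(len, background_positions)
        near_tss <- planted$contig == contig & planted$strand == strand
        if (any(near_tss))
          cand <- cand[vapply(cand, function(p)
            all(abs(p - planted$position[near_tss]) > 2), logical(1))]
        if (length(cand) == 0) next
        bg[[paste(contig, strand)]] <- data.frame(
          contig = contig, strand = strand, position = cand,
          mean = background_mean, stringsAsFactors = FALSE)
      }
    }
    ends <- truth$fragment_ends
    end_sites <- if (nrow(ends) > 0) rbind(
      data.frame(contig = ends$contig, strand = "+",
                 position = ends$position, mean = end_boost),
      data.frame(contig = ends$contig, strand = "-",
                 position = ends$position, mean = end_boost))
    else NULL
    base_sites <- rbind(do.call(rbind, bg), end_sites)
    ercc_sites <- data.frame(contig = truth$ercc$id, strand = "+",
                             position = 1L,
                             mean = truth$ercc$abundance * ercc_count_scale,
                             stringsAsFactors = FALSE)
    tracks <- list()
    for (si in seq_along(samples)) {
      s <- samples[si]
      sites <- rbind(base_sites, ercc_sites)
      cnt <- rnb(nrow(sites), sites$mean * eff[[s]], nb_dispersion)
      df <- data.frame(contig = sites$contig, strand = sites$strand,
                       position = sites$position, count = cnt,
                       stringsAsFactors = FALSE)
      if (cond[si] == "sigma" && nrow(planted) > 0) {
        tot <- rnb(nrow(planted), planted$mean * eff[[s]], nb_dispersion)
        for (k in seq_len(nrow(planted))) {
          if (tot[k] == 0) next
          spread <- stats::rmultinom(1, tot[k], jitter_prob)[, 1]
          df <- rbind(df, data.frame(
            contig = planted$contig[k], strand = planted$strand[k],
            position = planted$position[k] + (-1L:1L), count = spread,
            stringsAsFactors = FALSE))
        }
      }
      df <- df[df$count > 0, , drop = FALSE]
      agg <- if (nrow(df) == 0) df else
        stats::aggregate(count ~ contig + strand + position, df, sum)
      tracks[[s]] <- five_prime_track(agg, s)
    }
    list(tracks = tracks,
         design = sample_design(samples, cond, control = "no_sigma"),
         efficiency = eff)
  })
}

#' Simulate a whole-transcriptome fragment-count matrix
#'
#' NB-distributed per-gene fragment counts for the sigma and control
#' conditions. Planted regulon genes have their base mean multiplied by
#' the planted fold change in the sigma condition only; spike-in rows
#' scale with a fresh per-sample library efficiency and are unaffected by
#' condition.
#'
#' @inheritParams simulate_five_prime_tracks
#' @param base_mean_range log-uniform range of per-gene base means.
#' @param nb_dispersion NB dispersion of the counts.
#' @param ercc_count_scale expected fragments per abundance unit.
#' @return list with `counts` (integer matrix, genes + spike-ins x
#'   samples), `design` and `base_means`.
#' @export
simulate_count_matrix <- function(truth,
                                  base_mean_range = c(20, 500),
                                  nb_dispersion = 0.05,
                                  n_replicates = 2L,
                                  seed = 103L,
                                  ercc_count_scale = 4,
                                  efficiency_range = c(0.5, 1)) {
  with_seed(seed, {
    samples <- c(paste0("sigma_", seq_len(n_replicates)),
                 paste0("none_", seq_len(n_replicates)))
    cond <- rep(c("sigma", "no_sigma"), each = n_replicates)
    eff <- stats::setNames(
      stats::runif(length(samples), efficiency_range[1],
                   efficiency_range[2]), samples)
    gids <- truth$genes$gene_id[!truth$genes$is_ercc]
    base <- stats::setNames(
      exp(stats::runif(length(gids), log(base_mean_range[1]),
                       log(base_mean_range[2]))), gids)
    fc <- stats::setNames(rep(1, length(gids)), gids)
    if (nrow(truth$regulon) > 0)
      fc[truth$regulon$gene_id] <- truth$regulon$fold_change
    m <- matrix(0L, length(gids) + nrow(truth$ercc), length(samples),
                dimnames = list(c(gids, truth$ercc$id), samples))
    for (si in seq_along(samples)) {
      s <- samples[si]
      mu_gene <- base * (if (cond[si] == "sigma") fc else 1) * eff[[s]]
      mu_ercc <- truth$ercc$abundance * ercc_count_scale * eff[[s]]
      m[, s] <- rnb(nrow(m), c(mu_gene, mu_ercc), nb_dispersion)
    }
    list(counts = m,
         design = sample_design(samples, cond, control = "no_sigma"),
         base_means = base, efficiency = eff)
  })
}

#' Simulate a complete sigma-factor experiment with known truth
#'
#' Builds a genome with operon-like gene pairs, plants a regulon
#' (direct-target genes with sigma-dependent TSSs within the upstream
#' window of their initiation codons, plus operon-extended downstream
#' genes with no TSS of their own) and extra intergenic TSSs, places
#' non-specific background at restriction-fragment ends, emulates 92
#' spike-in transcripts with log-spaced abundances spanning the 1-150
#' range, and draws 5'-end tracks and a fragment-count matrix.
#'
#' Planted TSS positions are rejection-sampled away from fragment ends
#' (> 5 nt), from other planted TSSs on the same strand (> 105 nt, so
#' each yields its own cluster) and - for the extra intergenic TSSs -
#' from the upstream window of every gene, so the expected target set is
#' exactly the planted regulon.
#'
#' @param n_genes,contig_length,seed passed to [simulate_genome()].
#' @param n_planted_tss total planted sigma-dependent TSSs (>= number of
#'   direct-target genes).
#' @param regulon_size planted regulon size, operon children included.
#' @param n_operon_pairs operon pairs inside the regulon.
#' @param fold_change expression fold change of regulon genes.
#' @param tss_mean NB mean 5'-end count at a planted TSS per replicate.
#' @param n_replicates replicates per condition.
#' @param tss_distance_range distance range (nt) of planted TSSs upstream
#'   of their gene's initiation codon.
#' @param ... passed on to [simulate_five_prime_tracks()].
#' @return object of class `rivit_sim`: list with `genome`, `genes`
#'   (spike-in rows included), `tracks`, `design`, `counts`,
#'   `count_design`, `ercc_ids` and `truth` (class `rivit_truth`:
#'   `planted_tss`, `regulon`, `fragment_ends`, `ercc`,
#'   `contig_lengths`, `seed`).
#' @export
simulate_rivit <- function(n_genes = 60, contig_length = 100000L,
                           seed = 101L,
                           n_planted_tss = 20L,
                           regulon_size = 15L,
                           n_operon_pairs = 3L,
                           fold_change = 4,
                           tss_mean = 100,
                           n_replicates = 2L,
                           tss_distance_range = c(20L, 250L),
                           ...) {
  stopifnot(regulon_size >= 2 * n_operon_pairs,
            n_planted_tss >= regulon_size - n_operon_pairs)
  sub_seeds <- with_seed(seed, sample.int(2^31 - 2, 4))
  gen <- simulate_genome(n_genes, contig_length, seed = sub_seeds[1],
                         operon_pairs = n_operon_pairs)
  ends <- simulate_fragment_ends(gen$genome)
  ercc <- data.frame(
    id = sprintf("ERCC-%05d", seq_len(92)),
    abundance = 10^seq(log10(1), log10(150), length.out = 92),
    stringsAsFactors = FALSE)

  with_seed(sub_seeds[2], {
    genes <- gen$genes
    pairs <- gen$operon_pairs
    children <- pairs$child
    parents <- pairs$parent
    n_direct <- regulon_size - length(children)
    singles <- setdiff(genes$gene_id, c(children, parents))
    direct_ids <- c(parents,
                    sample(singles, n_direct - length(parents)))
    regulon <- rbind(
      data.frame(gene_id = direct_ids, fold_change = fold_change,
                 evidence_expected = "direct", parent = NA_character_,
                 stringsAsFactors = FALSE),
      if (length(children) > 0)
        data.frame(gene_id = children, fold_change = fold_change,
                   evidence_expected = "operon", parent = parents,
                   stringsAsFactors = FALSE))

    end_pos <- ends$position
    placed <- data.frame(contig = character(), strand = character(),
                         position = integer(), target_gene = character(),
                         stringsAsFactors = FALSE)
    ok_position <- function(p, strand) {
      if (length(end_pos) > 0 && any(abs(p - end_pos) <= 5)) return(FALSE)
      same <- placed$strand == strand
      if (any(same) && any(abs(p - placed$position[same]) <= 105))
        return(FALSE)
      TRUE
    }
    for (gid in direct_ids) {
      g <- genes[genes$gene_id == gid, ]
      dir <- if (g$strand == "+") 1L else -1L
      for (try in 1:200) {
        d <- sample(seq(tss_distance_range[1], tss_distance_range[2]), 1)
        p <- g$start - d * dir
        if (p > 60 && ok_position(p, g$strand)) break
        p <- NA_integer_
      }
      if (is.na(p)) stop("could not place TSS for ", gid, call. = FALSE)
      placed <- rbind(placed, data.frame(
        contig = g$contig, strand = g$strand, position = p,
        target_gene = gid, stringsAsFactors = FALSE))
    }
    n_extra <- n_planted_tss - nrow(placed)
    contig <- names(gen$genome)[1]
    len <- Biostrings::width(gen$genome)[1]
    upstream_clear <- function(p, strand) {
      same <- genes$strand == strand
      d <- (genes$start[same] - p) * (if (strand == "+") 1L else -1L)
      all(d < 0 | d > 320)
    }
    for (k in seq_len(n_extra)) {
      for (try in 1:500) {
        strand <- sample(c("+", "-"), 1)
        p <- sample.int(len - 120, 1) + 60L
        if (ok_position(p, strand) && upstream_clear(p, strand)) break
        p <- NA_integer_
      }
      if (is.na(p)) stop("could not place intergenic TSS", call. = FALSE)
      placed <- rbind(placed, data.frame(
        contig = contig, strand = strand, position = p,
        target_gene = NA_character_, stringsAsFactors = FALSE))
    }
    placed$mean <- tss_mean

    # spike-in contigs are materialized so FASTA round-trips stay coherent
    ercc_seqs <- Biostrings::DNAStringSet(vapply(ercc$id, function(i)
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
            collapse = ""), character(1)))
    names(ercc_seqs) <- ercc$id
    genome <- c(gen$genome, ercc_seqs)
    ercc_genes <- gene_set(data.frame(
      gene_id = ercc$id, contig = ercc$id, strand = "+",
      start = 1L, end = 150L, is_ercc = TRUE, stringsAsFactors = FALSE))
    all_genes <- gene_set(rbind(as.data.frame(genes),
                                as.data.frame(ercc_genes)))

    truth <- structure(list(
      planted_tss = placed, regulon = regulon, fragment_ends = ends,
      ercc = ercc, genes = all_genes,
      contig_lengths = stats::setNames(
        as.list(Biostrings::width(gen$genome)), names(gen$genome)),
      operon_pairs = pairs, seed = seed), class = "rivit_truth")

    tr <- simulate_five_prime_tracks(truth, n_replicates = n_replicates,
                                     seed = sub_seeds[3], ...)
    cm <- simulate_count_matrix(truth, n_replicates = n_replicates,
                                seed = sub_seeds[4])
    structure(list(genome = genome, genes = all_genes,
                   tracks = tr$tracks, design = tr$design,
                   counts = cm$counts, count_design = cm$design,
                   ercc_ids = ercc$id, truth = truth),
              class = "rivit_sim")
  })
}

#' @export
print.rivit_sim <- function(x, ...) {
  cat("RIViT simulation:", sum(!x$genes$is_ercc), "genes,",
      nrow(x$truth$planted_tss), "planted TSSs,",
      nrow(x$truth$regulon), "regulon genes (",
      sum(x$truth$regulon$evidence_expected == "operon"),
      "operon-extended ),", nrow(x$truth$fragment_ends),
      "fragment ends\n")
  invisible(x)
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Emits FASTA, GFF3, per-replicate 5'-end track TSVs, the fragment-count
#' matrix, both design files and the truth manifest.
#'
#' @param sim a `rivit_sim`.
#' @param dir output directory (created if needed).
#' @return named list of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$genome <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  paths$annotation <- file.path(dir, "annotation.gff3")
  write_gff3(sim$genes, paths$annotation)
  for (s in names(sim$tracks)) {
    p <- file.path(dir, paste0("track_", s, ".tsv"))
    write_five_prime_track(sim$tracks[[s]], p)
    paths[[paste0("track_", s)]] <- p
  }
  paths$counts <- file.path(dir, "counts.tsv")
  write_count_matrix(sim$counts, paths$counts)
  paths$design <- file.path(dir, "design_tracks.tsv")
  write_sample_design(sim$design, paths$design)
  paths$count_design <- file.path(dir, "design_counts.tsv")
  write_sample_design(sim$count_design, paths$count_design)
  paths$truth_tss <- file.path(dir, "truth_planted_tss.tsv")
  write_results(sim$truth$planted_tss, paths$truth_tss,
                sort_by = c("contig", "strand", "position"))
  paths$truth_regulon <- file.path(dir, "truth_regulon.tsv")
  write_results(sim$truth$regulon, paths$truth_regulon,
                sort_by = "gene_id")
  invisible(paths)
}

# minimal GFF3 emitter for gene models (read back via rtracklayer)
write_gff3 <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  g <- as.data.frame(genes)
  lines <- c("##gff-version 3",
             sprintf("%s\trivitseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$contig, gene_left(g), gene_right(g), g$strand,
                     g$gene_id))
  writeLines(lines, path)
  invisible(path)
}
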