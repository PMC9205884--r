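#' Moment-based negative-binomial dispersion estimates
#'
#' Genewise dispersions are estimated by the method of moments on
#' size-factor-normalized counts, pooled across the two conditions
#' (within-condition variances only, so true expression differences do not
#' inflate the estimate), and shrunk toward a common dispersion estimated
#' from all genes jointly. The common value is the ratio estimator
#' `sum(s2 - m) / sum(m^2)` over genes with mean >= 1, which is stable at
#' small replicate numbers where individual genewise estimates are noisy.
#' Shrinkage weights are the genewise residual degrees of freedom against a
#' prior weight `prior_df`; the result is floored at `floor`.
#'
#' @param counts integer count matrix (genes x samples), spike-in rows
#'   already excluded.
#' @param size_factors named per-sample size factors.
#' @param design a [sample_design()].
#' @param prior_df prior weight of the common dispersion (default 10).
#' @param floor lower bound on the final dispersion (default 0.01).
#' @return list with `dispersion` (named per-gene vector), `common`
#'   (scalar) and `genewise` (raw moment estimates).
#' @export
estimate_dispersions <- function(counts, size_factors, design,
                                 prior_df = 10, floor = 0.01) {
  y <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  ctrl <- control_samples(design)
  trt <- treatment_samples(design)
  yA <- y[, trt, drop = FALSE]; yB <- y[, ctrl, drop = FALSE]
  mA <- rowMeans(yA); mB <- rowMeans(yB)
  vA <- apply(yA, 1, stats::var); vB <- apply(yB, 1, stats::var)
  s2 <- (vA + vB) / 2
  m <- (mA + mB) / 2
  keep <- m >= 1
  common <- if (any(keep))
    max(sum(s2[keep] - m[keep]) / sum(m[keep]^2), 0) else floor
  gw <- rowMeans(cbind((vA - mA) / mA^2, (vB - mB) / mB^2), na.rm = TRUE)
  gw[!is.finite(gw)] <- 0
  gw <- pmax(gw, 0)
  dfg <- (length(trt) - 1) + (length(ctrl) - 1)
  disp <- pmax((dfg * gw + prior_df * common) / (dfg + prior_df), floor)
  names(disp) <- rownames(counts)
  list(dispersion = disp, common = common, genewise = gw)
}

#' Negative-binomial Wald test for one gene
#'
#' Condition means are computed from size-factor-normalized counts; the
#' log2 fold change uses a pseudocount of 0.5 so genes expressed in only
#' one condition stay defined. The Wald statistic is the log2 fold change
#' over its delta-method standard error under an NB variance
#' `mu + dispersion * mu^2`, referred to the standard normal.
#'
#' @param k integer counts for one gene, named by sample.
#' @param size_factors named per-sample size factors.
#' @param design a [sample_design()].
#' @param dispersion NB dispersion for this gene (shared across
#'   conditions). When `NULL`, a genewise moment estimate floored at 0.01
#'   is used; for matrix-wide analyses pass the shrunk estimate from
#'   [estimate_dispersions()] via [de_analysis()].
#' @param pseudocount added to both condition means before the ratio.
#' @return list with `log2fc`, `p_value`, `base_mean`, `dispersion` and
#'   `testable` (`FALSE` for all-zero genes, where `log2fc` and `p_value`
#'   are `NA`).
#' @export
nb_test <- function(k, size_factors, design, dispersion = NULL,
                    pseudocount = 0.5) {
  sf <- size_factors[design$sample_id]
  k <- k[design$sample_id]
  if (all(k == 0))
    return(list(log2fc = NA_real_, p_value = NA_real_, base_mean = 0,
                dispersion = NA_real_, testable = FALSE))
  y <- k / sf
  ctrl <- design$condition == attr(design, "control")
  trt <- !ctrl
  if (sum(trt) < 2 || sum(ctrl) < 2)
    stop("nb_test needs >= 2 replicates per condition", call. = FALSE)
  mA <- mean(y[trt]); mB <- mean(y[ctrl])
  if (is.null(dispersion)) {
    vA <- stats::var(y[trt]); vB <- stats::var(y[ctrl])
    gw <- mean(c((vA - mA) / mA^2, (vB - mB) / mB^2), na.rm = TRUE)
    dispersion <- max(gw, 0.01, na.rm = TRUE)
  }
  l2fc <- log2((mA + pseudocount) / (mB + pseudocount))
  # sampling variance on the normalized scale: keeps results invariant to
  # rescaling a sample together with its size factor
  vmA <- (mA + dispersion * mA^2) / sum(trt)
  vmB <- (mB + dispersion * mB^2) / sum(ctrl)
  se <- sqrt(vmA / ((mA + pseudocount)^2 * log(2)^2) +
             vmB / ((mB + pseudocount)^2 * log(2)^2))
  z <- l2fc / se
  list(log2fc = l2fc, p_value = 2 * stats::pnorm(-abs(z)),
       base_mean = mean(y), dispersion = dispersion, testable = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, applied to the
#' testable genes of one sigma-versus-control contrast.
#'
#' @param p numeric p-values (`NA` allowed and preserved).
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p) stats::p.adjust(p, method = "BH")

#' Flag significantly overexpressed genes
#'
#' A gene is upregulated when its fold change is at least `fc_threshold`
#' (inclusive) and its adjusted P value is below `padj_threshold` (strict);
#' genes with undefined statistics are never flagged.
#'
#' @param results data frame with columns `log2fc` and `padj`.
#' @param fc_threshold fold-change cut-off (default 2).
#' @param padj_threshold adjusted-P cut-off (default 0.01).
#' @return the data frame with a logical `upregulated` column set.
#' @export
call_upregulated <- function(results, fc_threshold = 2,
                             padj_threshold = 0.01) {
  fc <- 2^results$log2fc
  results$upregulated <- !is.na(fc) & !is.na(results$padj) &
    fc >= fc_threshold & results$padj < padj_threshold
  results
}

#' Differential transcription analysis, sigma versus no-sigma control
#'
#' Runs the negative-binomial Wald test on every non-spike-in gene of a
#' fragment-count matrix, with spike-in-anchored size factors, shrunk
#' moment dispersions, BH adjustment across testable genes, and
#' upregulation calls at the configured thresholds. Spike-in rows are the
#' normalization anchor and are excluded from testing and adjustment.
#'
#' @param counts count matrix including spike-in rows.
#' @param design a [sample_design()].
#' @param ercc_ids spike-in row identifiers.
#' @param config a [rivit_config()].
#' @param size_factors optional named per-sample factors; computed from the
#'   spike-in rows via [compute_size_factors()] when `NULL`.
#' @return data frame of class `de_results`: `gene_id`, `base_mean`,
#'   `log2fc`, `p_value`, `padj`, `upregulated`, `testable`, with the size
#'   factors and the dispersion fit as attributes.
#' @export
de_analysis <- function(counts, design, ercc_ids, config = rivit_config(),
                        size_factors = NULL) {
  stopifnot(all(design$sample_id %in% colnames(counts)))
  if (is.null(size_factors))
    size_factors <- compute_size_factors(counts, ercc_ids)
  genes <- counts[!rownames(counts) %in% ercc_ids, design$sample_id,
                  drop = FALSE]
  fit <- estimate_dispersions(genes, size_factors, design)
  res <- lapply(rownames(genes), function(g)
    nb_test(genes[g, ], size_factors, design,
            dispersion = fit$dispersion[[g]]))
  out <- data.frame(
    gene_id = rownames(genes),
    base_mean = vapply(res, `[[`, numeric(1), "base_mean"),
    log2fc = vapply(res, `[[`, numeric(1), "log2fc"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    testable = vapply(res, `[[`, logical(1), "testable"),
    stringsAsFactors = FALSE
  )
  out$padj <- NA_real_
  out$padj[out$testable] <- adjust_pvalues(out$p_value[out$testable])
  out <- call_upregulated(out, config$fc_threshold, config$padj_threshold)
  out <- out[, c("gene_id", "base_mean", "log2fc", "p_value", "padj",
                 "upregulated", "testable")]
  attr(out, "size_factors") <- size_factors
  attr(out, "dispersion_fit") <- fit[c("common")]
  class(out) <- c("de_results", "data.frame")
  out
}

#' @export
print.de_results <- function(x, ...) {
  cat("Differential transcription:", nrow(x), "genes;",
      sum(x$testable), "testable;", sum(x$upregulated), "upregulated\n")
  cat("common dispersion:",
      format(attr(x, "dispersion_fit")$common, digits = 3), "\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
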