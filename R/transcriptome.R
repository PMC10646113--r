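#' Filter genes by a minimum-count rule
#'
#' Keeps a gene when its count strictly exceeds `threshold` in at least one
#' sample (`by = "sample"`, the default reading of "exceeding N counts in at
#' least one timepoint" for a one-sample-per-timepoint design) or when the
#' replicate-mean of some timepoint exceeds it (`by = "timepoint_mean"`).
#'
#' @param counts integer matrix, genes x samples.
#' @param samples sample sheet with `sample_id`, `time_h` (needed for
#'   `timepoint_mean`).
#' @param threshold count threshold (strict >).
#' @param by filtering convention.
#' @return filtered count matrix.
#' @export
filter_min_counts <- function(counts, samples = NULL, threshold = 50,
                              by = c("sample", "timepoint_mean")) {
  by <- match.arg(by)
  if (by == "sample") {
    keep <- apply(counts, 1, max) > threshold
  } else {
    if (is.null(samples)) stop("samples sheet required for timepoint_mean")
    tp <- samples$time_h[match(colnames(counts), samples$sample_id)]
    means <- t(apply(counts, 1, function(x) tapply(x, tp, mean)))
    keep <- apply(means, 1, max) > threshold
  }
  if (!any(keep))
    stop("no gene passes the filter; consider lowering threshold (",
         threshold, ")")
  counts[keep, , drop = FALSE]
}

#' Library-size normalisation to log2 counts-per-million
#'
#' @param counts integer matrix, genes x samples, nonzero column sums.
#' @return matrix of log2(CPM + 1) values.
#' @export
normalize_counts <- function(counts) {
  ls <- colSums(counts)
  if (any(ls <= 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[ls <= 0], collapse = ", "))
  log2(t(t(counts) / ls) * 1e6 + 1)
}

#' Detect rhythmic genes with two reporting tiers
#'
#' Per gene, the zero-amplitude cosinor F test on the sample times (the
#' permutation variant when `n_perm > 0`), followed by Benjamini-Hochberg
#' adjustment across genes. Tier 1 collects genes with raw p < `alpha`,
#' tier 2 those with BH q < `alpha` (tier 2 is a subset of tier 1).
#'
#' @param norm normalised matrix (genes x samples), e.g. from
#'   [normalize_counts()].
#' @param time_h per-sample times (hours); at least 8 distinct timepoints
#'   spanning 2 cycles are expected for the 48-h design.
#' @param period_h test period.
#' @param n_perm permutations per gene (0 = parametric F test only, the
#'   default estimator).
#' @param seed permutation seed.
#' @param alpha tier threshold.
#' @return `gene_rhythm_stats` data.frame: `gene_id`, `p_raw`, `q_bh`,
#'   `amplitude_log2`, `acrophase_h`, `mesor_log2`, `tier1`, `tier2`.
#' @export
detect_rhythmic_genes <- function(norm, time_h, period_h = 24, n_perm = 0,
                                  seed = 1L, alpha = 0.05) {
  if (length(unique(time_h)) < 8)
    stop("rhythmic-gene detection needs at least 8 timepoints")
  if (length(time_h) != ncol(norm))
    stop("time_h must have one entry per sample")
  Y <- t(norm)
  st <- .cosinor_F_matrix(time_h, Y, period_h)
  n <- length(time_h)
  p <- stats::pf(st$F, 2, n - 3, lower.tail = FALSE)
  if (n_perm > 0) {
    exceed <- rep(0L, ncol(Y))
    .with_seed(seed, {
      for (b in seq_len(n_perm)) {
        Fb <- .cosinor_F_matrix(sample(time_h), Y, period_h)$F
        exceed <- exceed + (Fb >= st$F)
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(norm), p_raw = as.numeric(p),
                    q_bh = as.numeric(q),
                    amplitude_log2 = as.numeric(st$amplitude),
                    acrophase_h = as.numeric(st$acrophase_h),
                    mesor_log2 = as.numeric(st$mesor),
                    stringsAsFactors = FALSE)
  out$tier1 <- out$p_raw < alpha
  out$tier2 <- out$q_bh < alpha
  class(out) <- c("gene_rhythm_stats", "data.frame")
  out
}

#' Differential response between two sample groups
#'
#' Per-gene Welch two-sample t test on normalised log2 values, BH-adjusted,
#' with direction calls at the stated thresholds (the study's T0-vs-T4
#' design: `log2fc` is group B minus group A, so "up" means higher after the
#' stimulus).
#'
#' @param norm normalised matrix (genes x samples).
#' @param group_a,group_b column names (or indices) of the two groups; at
#'   least 2 replicates each.
#' @param fc_cut absolute log2 fold-change cutoff.
#' @param alpha BH q cutoff.
#' @return `differential_response_table` data.frame: `gene_id`, `log2fc`,
#'   `p_raw`, `q_bh`, `direction` in {up, down, ns}; attribute `summary`
#'   holds the up/down counts.
#' @export
differential_response <- function(norm, group_a, group_b, fc_cut = 1,
                                  alpha = 0.05) {
  A <- norm[, group_a, drop = FALSE]
  B <- norm[, group_b, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2)
    stop("each group needs at least 2 replicates for a variance estimate")
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  na <- ncol(A); nb <- ncol(B)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1   # zero-variance, zero-difference genes
  q <- stats::p.adjust(p, method = "BH")
  l2fc <- mb - ma
  direction <- rep("ns", nrow(norm))
  direction[q < alpha & l2fc >= fc_cut] <- "up"
  direction[q < alpha & l2fc <= -fc_cut] <- "down"
  out <- data.frame(gene_id = rownames(norm), log2fc = l2fc, p_raw = p,
                    q_bh = q, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- c(up = sum(direction == "up"),
                            down = sum(direction == "down"))
  class(out) <- c("differential_response_table", "data.frame")
  out
}

#' Project query samples onto a circadian reference time course
#'
#' Genes are z-scored across the reference timepoints; query samples are
#' z-scored with the reference per-gene mean and SD; each query is assigned
#' the reference timepoint whose z-vector it correlates with best
#' (Pearson).
#'
#' @param query matrix (genes x query samples).
#' @param reference matrix (genes x reference timepoints) covering a full
#'   cycle.
#' @param ref_time_h times of the reference columns (hours).
#' @param genes gene set used for the projection (default: all shared
#'   genes); fewer than 10 shared genes is an error.
#' @return `phase_projection` data.frame: `query_sample_id`,
#'   `assigned_time_h`, `max_correlation`; attribute `correlation_profile`
#'   is the full query x timepoint correlation matrix.
#' @export
project_sample_phase <- function(query, reference, ref_time_h,
                                 genes = NULL) {
  if (is.null(genes))
    genes <- intersect(rownames(query), rownames(reference))
  genes <- intersect(intersect(genes, rownames(query)), rownames(reference))
  R <- reference[genes, , drop = FALSE]
  mu <- rowMeans(R)
  sd <- apply(R, 1, stats::sd)
  usable <- sd > 0
  genes <- genes[usable]
  if (length(genes) < 10)
    stop("fewer than 10 shared informative genes; projection unstable")
  Rz <- (R[genes, ] - mu[usable]) / sd[usable]
  Qz <- (query[genes, , drop = FALSE] - mu[usable]) / sd[usable]
  cors <- stats::cor(Qz, Rz)   # query x reference timepoints
  colnames(cors) <- ref_time_h
  idx <- apply(cors, 1, which.max)
  out <- data.frame(query_sample_id = colnames(query),
                    assigned_time_h = ref_time_h[idx],
                    max_correlation = cors[cbind(seq_len(nrow(cors)), idx)],
                    stringsAsFactors = FALSE)
  attr(out, "correlation_profile") <- cors
  class(out) <- c("phase_projection", "data.frame")
  out
}

#' Write a rhythmic count experiment as plain-text tables
#'
#' Writes `counts.tsv` (rows = gene IDs, columns = sample IDs),
#' `samples.tsv` (`sample_id`, `time_h`, `replicate`) and `truth.tsv`.
#'
#' @param exp a `rhythmic_count_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(gene_id = rownames(exp$counts), exp$counts,
                                check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(exp$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(exp$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a rhythmic count experiment written by [write_count_experiment()]
#' @param dir directory holding `counts.tsv`, `samples.tsv` and optionally
#'   `truth.tsv`.
#' @return `rhythmic_count_experiment` (truth `NULL` when absent).
#' @export
read_count_experiment <- function(dir) {
  cf <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cf[, -1, drop = FALSE])
  rownames(counts) <- cf[[1]]
  storage.mode(counts) <- "integer"
  samples <- utils::read.delim(file.path(dir, "samples.tsv"))
  tf <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tf)) utils::read.delim(tf) else NULL
  structure(list(counts = counts, samples = samples, truth = truth),
            class = "rhythmic_count_experiment")
}
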