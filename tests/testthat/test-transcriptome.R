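test_that("minimum-count filter applies the strict 'exceeding' rule", {
  counts <- rbind(all50 = rep(50L, 4), one51 = c(51L, 0L, 0L, 0L),
                  zero = rep(0L, 4))
  colnames(counts) <- paste0("s", 1:4)
  kept <- filter_min_counts(counts)
  expect_identical(rownames(kept), "one51")
  expect_error(filter_min_counts(counts["zero", , drop = FALSE]),
               "threshold")
  # replicate-mean convention
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        time_h = c(0, 0, 4, 4))
  counts2 <- rbind(a = c(80L, 30L, 0L, 0L), b = c(60L, 40L, 0L, 0L))
  colnames(counts2) <- samples$sample_id
  kept2 <- filter_min_counts(counts2, samples, by = "timepoint_mean")
  expect_identical(rownames(kept2), "a")   # mean 55 > 50; mean 50 is not
})

test_that("CPM normalisation cancels library size and maps zero to zero", {
  c1 <- matrix(rpois(40, 50), 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  c2 <- c1
  c2[, 2] <- c1[, 2] * 2
  n1 <- normalize_counts(c1)
  n2 <- normalize_counts(c2)
  expect_equal(n1[, 2], n2[, 2], tolerance = 1e-12)
  cz <- c1; cz[1, 1] <- 0L
  expect_equal(normalize_counts(cz)[1, 1], 0)
  cz[, 1] <- 0L
  expect_error(normalize_counts(cz), "library size")
  # library-size factors removed: CV of constant-truth genes shrinks
  exp <- simulate_count_timeseries(g_genes = 300, frac_rhythmic = 0,
                                   frac_responsive = 0,
                                   lib_size_range = c(0.5, 2), seed = 6)
  raw_cv <- apply(exp$counts, 1, function(x) sd(x) / mean(x))
  cpm <- t(t(exp$counts) / colSums(exp$counts)) * 1e6
  norm_cv <- apply(cpm, 1, function(x) sd(x) / mean(x))
  expect_lt(median(norm_cv), median(raw_cv))
})

test_that("BH adjustment matches the brute-force step-up oracle exactly", {
  set.seed(99)
  for (i in 1:25) {
    m <- sample(3:20, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)
    expect_equal(stats::p.adjust(p, method = "BH"), bh_stepup_oracle(p),
                 tolerance = 1e-15)
  }
})

test_that("rhythmic-gene tiers are nested and recover planted rhythms", {
  exp <- simulate_count_timeseries(g_genes = 600, frac_rhythmic = 0.2,
                                   n_reps = 2, nb_dispersion = 0.1,
                                   seed = 8)
  filt <- filter_min_counts(exp$counts, exp$samples)
  norm <- normalize_counts(filt)
  rh <- detect_rhythmic_genes(norm, exp$samples$time_h)
  expect_true(all(rh$gene_id[rh$tier2] %in% rh$gene_id[rh$tier1]))
  expect_true(all(rh$q_bh >= rh$p_raw - 1e-15))
  truth <- exp$truth[match(rh$gene_id, exp$truth$gene_id), ]
  sens <- mean(rh$tier2[truth$rhythmic])
  expect_gte(sens, 0.8)
  # acrophase of confidently detected rhythmic genes matches the truth
  hit <- rh$tier2 & truth$rhythmic & rh$amplitude_log2 > 0.5
  dphi <- abs(wrap_phase_h(rh$acrophase_h[hit] - truth$acrophase_h[hit]))
  expect_lt(median(dphi), 1.5)
  expect_error(detect_rhythmic_genes(norm[, 1:6],
                                     exp$samples$time_h[1:6]),
               "timepoints")
})

test_that("permutation and parametric tiers agree on a small matrix", {
  exp <- simulate_count_timeseries(g_genes = 60, frac_rhythmic = 0.3,
                                   n_reps = 2, seed = 15)
  norm <- normalize_counts(filter_min_counts(exp$counts, exp$samples))
  par <- detect_rhythmic_genes(norm, exp$samples$time_h)
  per <- detect_rhythmic_genes(norm, exp$samples$time_h, n_perm = 500,
                               seed = 2)
  expect_gt(mean(par$tier1 == per$tier1), 0.9)
  per2 <- detect_rhythmic_genes(norm, exp$samples$time_h, n_perm = 500,
                                seed = 2)
  expect_identical(per$p_raw, per2$p_raw)
})

test_that("differential response calls planted fold changes and is antisymmetric", {
  exp <- simulate_count_timeseries(g_genes = 800, frac_rhythmic = 0.2,
                                   n_reps = 4, nb_dispersion = 0.1,
                                   true_log2fc = 2, seed = 5)
  norm <- normalize_counts(filter_min_counts(exp$counts, exp$samples))
  tt <- exp$samples$time_h
  A <- exp$samples$sample_id[tt == 0]
  B <- exp$samples$sample_id[tt == 4]
  de <- differential_response(norm, A, B)
  truth <- exp$truth[match(de$gene_id, exp$truth$gene_id), ]
  resp <- truth$responsive_T4
  expect_gte(sum(de$direction[resp] == "up"), 10)
  # up-calls are essentially all planted responders (high precision)
  expect_gte(mean(resp[de$direction == "up"]), 0.8)
  expect_gt(mean(de$log2fc[resp]), 1.4)

  flip <- differential_response(norm, B, A)
  expect_equal(de$log2fc, -flip$log2fc, tolerance = 1e-12)

  same <- differential_response(norm, A, A)
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$direction == "ns"))

  expect_error(differential_response(norm, A[1], B), "2 replicates")
})

test_that("phase projection assigns query samples to matching reference times", {
  exp <- simulate_count_timeseries(g_genes = 400, frac_rhythmic = 0.5,
                                   frac_responsive = 0, n_reps = 2,
                                   nb_dispersion = 0.05, seed = 4)
  norm <- normalize_counts(exp$counts)
  tt <- exp$samples$time_h
  ref_times <- sort(unique(tt))
  ref <- sapply(ref_times, function(x)
    rowMeans(norm[, tt == x, drop = FALSE]))
  rownames(ref) <- rownames(norm)
  genes <- exp$truth$gene_id[exp$truth$rhythmic]

  # self-projection of the ZT8 column
  q8 <- ref[, ref_times == 8, drop = FALSE]
  colnames(q8) <- "q8"
  pr <- project_sample_phase(q8, ref, ref_times, genes)
  expect_equal(pr$assigned_time_h, 8)

  # average of ZT12 and ZT16 lands on one of them
  qm <- (ref[, ref_times == 12] + ref[, ref_times == 16]) / 2
  qm <- matrix(qm, ncol = 1, dimnames = list(rownames(ref), "mix"))
  pr <- project_sample_phase(qm, ref, ref_times, genes)
  expect_true(pr$assigned_time_h %in% c(12, 16))

  # fresh sample generated at circadian time 14 projects within one step
  q14 <- simulate_count_timeseries(g_genes = 400, frac_rhythmic = 0.5,
                                   frac_responsive = 0, n_reps = 2,
                                   times = 14, nb_dispersion = 0.05,
                                   seed = 4)
  nq <- normalize_counts(q14$counts)[, 1, drop = FALSE]
  pr <- project_sample_phase(nq, ref, ref_times, genes)
  expect_lte(min(abs(c(pr$assigned_time_h - 14,
                       pr$assigned_time_h - 14 + 24,
                       pr$assigned_time_h - 14 - 24))), 4)

  expect_error(project_sample_phase(q8[1:5, , drop = FALSE], ref,
                                    ref_times), "10 shared")
})

test_that("count experiment tables round-trip through TSV", {
  exp <- simulate_count_timeseries(g_genes = 30, seed = 3)
  dir <- tempfile()
  write_count_experiment(exp, dir)
  back <- read_count_experiment(dir)
  expect_equal(back$counts, exp$counts)
  expect_equal(back$samples$time_h, exp$samples$time_h)
  expect_equal(back$truth$rhythmic, exp$truth$rhythmic)
})
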