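test_that("replicate aggregation averages non-sentinel Cq values", {
  m <- cq_measurement("gBlock", "with_blocker", c(30.0, 30.4, 30.2))
  expect_equal(as.numeric(aggregate_replicates(m)), 30.2)
  expect_equal(attr(aggregate_replicates(m), "n_dropped"), 0)

  single <- cq_measurement("gBlock", "no_blocker", 28.0)
  expect_equal(as.numeric(aggregate_replicates(single)), 28.0)

  mixed <- cq_measurement("sample_FF", "with_blocker", c(33.1, 45, 45),
                          sentinel_flags = c(FALSE, TRUE, TRUE))
  expect_equal(as.numeric(aggregate_replicates(mixed)), 33.1)
  expect_equal(attr(aggregate_replicates(mixed), "n_dropped"), 2)

  dead <- cq_measurement("sample_FF", "with_blocker", c(45, 45),
                         sentinel_flags = c(TRUE, TRUE))
  expect_error(aggregate_replicates(dead), "no amplification")
})

test_that("delta-Cq subtracts the no-blocker reference", {
  expect_equal(delta_cq(30, 25), 5)
  expect_equal(delta_cq(25, 25), 0)
  expect_equal(delta_cq(24, 25), -1)  # allowed, flagged downstream
  expect_error(delta_cq(45, 25), "with_blocker")
  expect_error(delta_cq(30, 45), "no_blocker")
  expect_error(delta_cq(NaN, 25), "finite")
})

test_that("VAF estimation inverts the doubling model", {
  expect_equal(estimate_vaf(3, 3), 100)           # pure-variant sample
  expect_equal(estimate_vaf(4, 3), 50)            # one doubling
  expect_equal(estimate_vaf(3 + 6.6439, 3), 1.0, tolerance = 1e-4)
  expect_warning(v <- estimate_vaf(2.8, 3), "clamped")
  expect_equal(v, 100)
  expect_error(estimate_vaf(1, 3), "positive control")

  # strictly decreasing in dcq_sample, increasing in dcq_gblock
  s <- seq(3, 10, by = 0.5)
  expect_true(all(diff(estimate_vaf(s, 3)) < 0))
  g <- seq(1, 3, by = 0.25)
  expect_true(all(diff(estimate_vaf(10, g)) > 0))
})

test_that("the as-typeset closed form diverges where the exponent form is exact", {
  # at dcq_sample == dcq_gblock the literal form divides by zero while a
  # pure-variant sample must read 100%
  expect_equal(estimate_vaf(3, 3, literal = FALSE), 100)
  expect_identical(estimate_vaf(3, 3, literal = TRUE), Inf)
  # below the calibrator the literal form goes negative
  expect_lt(estimate_vaf(2.6, 3, literal = TRUE), 0)
  # the two readings coincide nowhere except asymptotically
  expect_false(isTRUE(all.equal(estimate_vaf(5, 3, literal = TRUE),
                                estimate_vaf(5, 3))))
})

test_that("noise-free qPCR round-trips through the VAF estimator", {
  for (vaf in c(0.005, 0.01, 0.05, 0.5, 1.0)) {
    est <- noise_free_estimate(vaf)
    expect_equal(est, 100 * vaf, tolerance = 1e-6)
  }
})

test_that("mean-first and per-replicate delta-Cq orderings nearly agree", {
  cfg <- sim_config(cq_noise_sd = 0.15)
  v <- truth_row(vaf_ff = 0.02)
  m <- simulate_qpcr(v, default_assay(), "sample_FF", cfg, seed = 8)
  mean_first <- mean(m$with_blocker$replicate_cqs) -
    mean(m$no_blocker$replicate_cqs)
  per_rep <- mean(m$with_blocker$replicate_cqs -
                    m$no_blocker$replicate_cqs)
  expect_equal(mean_first, per_rep, tolerance = 1e-9)
})

test_that("three-outcome classification follows the Sanger allele", {
  cand <- list(ref = "G", alt = "A")
  ok <- list(validated = TRUE)
  expect_equal(
    classify_confirmation(cand, sanger_call("A", "G"), ok)$status,
    "confirmed")
  expect_equal(
    classify_confirmation(cand, sanger_call("G", "G"), ok)$status,
    "absent")
  # neither-matching allele needs >= 3 concordant replicates
  expect_equal(
    classify_confirmation(cand, sanger_call("GA", "G", 3), ok)$status,
    "misidentified")
  held <- classify_confirmation(cand, sanger_call("GA", "G", 2), ok)
  expect_equal(held$status, "failed_qc")
  expect_equal(held$reason, "pending_replicates")
  expect_equal(
    classify_confirmation(cand, sanger_call("A", "G"),
                          list(validated = FALSE))$status,
    "failed_qc")
})

test_that("noise-free cohort confirmation recovers the planted truth", {
  cfg <- tiny_config(cq_noise_sd = 0, per_base_error_rate = 0,
                     n_true_variants = 30, n_ff_only = 10,
                     n_artifact_variants = 15, n_misidentified = 3,
                     seed = 21L)
  truth <- simulate_truth_set(cfg)
  ffpe <- simulate_wes_calls(truth, "FFPE", cfg)

  # add planted false positives: FF-only variants "called" in FFPE
  key_t <- variant_key(truth$chrom, truth$pos, truth$ref,
                       truth$reported_alt)
  ff_only <- truth[truth$true_vaf_ffpe == 0 & !truth$is_artifact, ]
  fp <- tibble::tibble(
    chrom = ff_only$chrom, pos = ff_only$pos, ref = ff_only$ref,
    alt = ff_only$reported_alt, alt_reads = 4L, depth = 200L, vaf = 2,
    gene = ff_only$gene, category = ff_only$category, sample = "FFPE"
  )
  cand <- dplyr::bind_rows(ffpe, fp)

  inp <- simulate_confirmation_inputs(truth, cand, cfg)
  res <- confirm_candidates(cand, inp$measurements, inp$sanger_calls,
                            inp$assays)

  key_r <- variant_key(res$chrom, res$pos, res$ref, res$alt)
  ti <- match(key_r, key_t)
  expect_false(anyNA(ti))
  truly_present <- truth$true_vaf_ffpe[ti] > 0
  mis <- truth$reported_alt[ti] != truth$true_alt[ti]
  expect_true(all(res$status[truly_present & !mis] == "confirmed"))
  expect_true(all(res$status[mis & truly_present] == "misidentified"))
  expect_true(all(res$status[!truly_present] == "absent"))
  # conservation: the four outcomes partition the candidates
  expect_equal(sum(table(res$status)), nrow(cand))
  # VAF estimates exist exactly for confirmed results
  expect_true(all(is.na(res$estimated_vaf) != (res$status == "confirmed")))
  # and recover truth to high relative accuracy at zero noise
  conf <- res$status == "confirmed"
  expect_equal(res$estimated_vaf[conf],
               100 * truth$true_vaf_ffpe[ti][conf], tolerance = 1e-6)
})

test_that("degenerate confirmation inputs are reported, never dropped", {
  cand <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "G", alt = "A",
                         vaf = 2, sample = "FF", gene = "CG001",
                         category = "other")
  key <- variant_key("chr1", 1L, "G", "A")
  sang <- tibble::tibble(key = key, called_allele = "A",
                         n_replicate_reads = 1L)
  meas <- tibble::tibble(key = character(), template = character(),
                         condition = character(), cq = double(),
                         is_sentinel = logical())

  # empty candidate set
  expect_equal(nrow(confirm_candidates(cand[0, ], meas, sang,
                                       tibble::tibble(key = character(),
                                                      validated = logical()))),
               0)
  # unvalidated assay
  res <- confirm_candidates(cand, meas, sang,
                            tibble::tibble(key = key, validated = FALSE))
  expect_equal(res$status, "failed_qc")
  expect_equal(res$reason, "unvalidated_assay")
  # missing measurements
  res2 <- confirm_candidates(cand, meas, sang,
                             tibble::tibble(key = key, validated = TRUE))
  expect_equal(res2$status, "failed_qc")
  expect_equal(res2$reason, "missing_measurements")

  # all-sentinel with-blocker Cq + reference Sanger trace => absent
  full <- dplyr::bind_rows(
    tibble::tibble(key = key, template = "sample_FF",
                   condition = "with_blocker", cq = c(45, 45),
                   is_sentinel = TRUE),
    tibble::tibble(key = key, template = "sample_FF",
                   condition = "no_blocker", cq = c(25, 25),
                   is_sentinel = FALSE),
    tibble::tibble(key = key, template = "gBlock",
                   condition = "with_blocker", cq = c(28, 28),
                   is_sentinel = FALSE),
    tibble::tibble(key = key, template = "gBlock",
                   condition = "no_blocker", cq = c(25, 25),
                   is_sentinel = FALSE)
  )
  ref_trace <- tibble::tibble(key = key, called_allele = "G",
                              n_replicate_reads = 1L)
  res3 <- confirm_candidates(cand, full, ref_trace,
                             tibble::tibble(key = key, validated = TRUE))
  expect_equal(res3$status, "absent")
})
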