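test_that("stratified summaries count outcomes and round rates half-up", {
  res <- dplyr::bind_rows(
    make_results(61, 33, 0, sample = "FF"),
    make_results(48, 79, 5, sample = "FFPE")
  )
  by_sample <- summarize_confirmations(res, "sample")
  ff <- by_sample[by_sample$stratum == "FF", ]
  expect_equal(ff$n_tested, 94)
  expect_equal(ff$disconfirmed_rate, 35)
  expect_equal(by_sample$disconfirmed_rate[by_sample$stratum == "FFPE"], 64)

  overall <- summarize_confirmations(res)
  expect_equal(overall$n_tested, 226)
  expect_equal(overall$disconfirmed_rate, 52)

  # single confirmed result: nothing disconfirmed
  expect_equal(summarize_confirmations(make_results(1))$disconfirmed_rate, 0)
  # per-stratum conservation
  expect_true(all(by_sample$n_confirmed + by_sample$n_absent +
                    by_sample$n_misidentified == by_sample$n_tested))
  expect_error(summarize_confirmations(res[0, ]), "no confirmation results")
})

test_that("failed_qc rows leave denominators and are reported aside", {
  res <- make_results(3, 1, 0, n_failed = 2, sample = "FF")
  s <- summarize_confirmations(res)
  expect_equal(s$n_tested, 4)
  expect_equal(attr(s, "n_failed_qc"), 2)
})

test_that("any grouping partitions the tested total (partition property)", {
  cfg <- tiny_config(seed = 31L)
  res <- make_results(40, 25, 3,
                      sample = c("FF", "FFPE"),
                      category = c("nonsynonymous", "intron", "synonymous"),
                      cancer_related = c(TRUE, FALSE),
                      alteration = c("C>T/G>A", "indel", "A>C/T>G"))
  total <- summarize_confirmations(res)$n_tested
  overall_rate <- summarize_confirmations(res)$disconfirmed_fraction
  for (g in c("sample", "category", "cancer_related", "alteration")) {
    tab <- summarize_confirmations(res, g)
    expect_equal(sum(tab$n_tested), total)
    # overall disconfirmed rate is invariant to grouping choice
    expect_equal(sum(tab$n_absent + tab$n_misidentified) / sum(tab$n_tested),
                 overall_rate)
  }
})

test_that("VAF brackets and the 3% split stratify by WES VAF", {
  res <- dplyr::bind_rows(
    make_results(20, 0, 0, vaf = 4),           # all > 3% confirmed
    make_results(15, 15, 0, vaf = 1.5)         # half of <= 3% absent
  )
  out <- breakdown_by_vaf(res)
  split <- out$split
  expect_equal(split$disconfirmed_rate[split$stratum == ">3%"], 0)
  expect_equal(split$disconfirmed_rate[split$stratum == "<=3%"], 50)

  # one bracket covering the whole band reproduces the overall summary
  one <- breakdown_by_vaf(res, bracket_edges = c(0.5, 5))$brackets
  expect_equal(one$n_tested, 50)
  expect_equal(one$disconfirmed_fraction,
               summarize_confirmations(res)$disconfirmed_fraction)
  # empty bracket: zero tested, undefined rate
  empty <- breakdown_by_vaf(res, bracket_edges = c(0.5, 1, 5))$brackets
  expect_equal(empty$n_tested[1], 0)
  expect_true(is.na(empty$disconfirmed_rate[1]))
  expect_error(breakdown_by_vaf(res, bracket_edges = c(3, 2)),
               "strictly increasing")
})

test_that("category breakdown recovers planted per-category rates", {
  res <- dplyr::bind_rows(
    make_results(10, 0, 0, category = "nonsynonymous"),
    make_results(5, 5, 0, category = "intron")
  )
  out <- breakdown_by_category(res)
  expect_equal(out$disconfirmed_rate[out$stratum == "nonsynonymous"], 0)
  expect_equal(out$disconfirmed_rate[out$stratum == "intron"], 50)
  # single-category set yields one stratum
  expect_equal(nrow(breakdown_by_category(
    make_results(4, 2, 0, category = "nonsynonymous"))), 1)
  # unknown labels fall back to "other" with a warning
  expect_warning(
    out2 <- breakdown_by_category(make_results(2, 0, 0, category = "weird")),
    "other")
  expect_equal(out2$stratum, "other")
})

test_that("alteration breakdown reports class shares of tested and confirmed", {
  # planted FFPE-like spectrum: 79/132 tested and 44/48 confirmed are
  # deamination-class changes
  res <- dplyr::bind_rows(
    make_results(44, 35, 0, alteration = "C>T/G>A"),
    make_results(4, 49, 0, alteration = "A>C/T>G")
  )
  out <- breakdown_by_alteration(res)
  deam <- out[out$stratum == "C>T/G>A", ]
  expect_equal(sum(out$n_tested), 132)
  expect_equal(sum(out$n_confirmed), 48)
  expect_equal(deam$share_of_tested, 60)
  expect_equal(deam$share_of_confirmed, 92)

  # classes derived from ref/alt when not precomputed
  res2 <- make_results(3, 0, 0, ref = "G", alt = "A")
  out2 <- breakdown_by_alteration(res2)
  expect_equal(out2$stratum, "C>T/G>A")
  expect_equal(out2$share_of_tested, 100)
  # no confirmed variants: confirmed share undefined
  out3 <- breakdown_by_alteration(make_results(0, 5, 0,
                                               alteration = "indel"))
  expect_true(all(is.na(out3$share_of_confirmed)))
})

test_that("false-negative analysis counts BDA-positive FF-only variants", {
  ff <- tibble::tibble(chrom = "chr1", pos = 1:60, ref = "G", alt = "A",
                       vaf = 2)
  ffpe <- tibble::tibble(chrom = "chr1", pos = 61:80, ref = "G", alt = "A",
                         vaf = 2)
  # 50 FF-only variants tested on the FFPE template, 11 truly present
  conf <- tibble::tibble(chrom = "chr1", pos = 1:50, ref = "G", alt = "A",
                         status = rep(c("confirmed", "absent"), c(11, 39)))
  out <- false_negative_analysis(ff, ffpe, conf)
  expect_equal(out$n_tested, 50)
  expect_equal(out$n_false_negative, 11)
  expect_equal(out$n_true_negative, 39)

  # all tested variants truly absent
  conf0 <- dplyr::mutate(conf, status = "absent")
  expect_equal(false_negative_analysis(ff, ffpe, conf0)$n_false_negative, 0)
  # empty test set
  z <- false_negative_analysis(ff, ffpe, conf[0, ])
  expect_equal(z$n_tested, 0)
  expect_equal(z$n_false_negative, 0)
  # a confirmation for a variant already called in FFPE is out of scope
  bad <- tibble::tibble(chrom = "chr1", pos = 61L, ref = "G", alt = "A",
                        status = "confirmed")
  expect_error(false_negative_analysis(ff, ffpe, bad), "FFPE call set")
})
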