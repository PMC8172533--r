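QPCR_TEMPLATES <- c("sample_FF", "sample_FFPE", "gBlock", "gDNA_negative")

#' Construct a replicate Cq measurement
#'
#' One qPCR reaction condition (with or without blocker) on one template,
#' run in replicate. Replicates that never crossed threshold are recorded
#' at the no-amplification sentinel Cq (`max_cycles`) and flagged.
#'
#' @param template one of `"sample_FF"`, `"sample_FFPE"`, `"gBlock"`,
#'   `"gDNA_negative"`.
#' @param condition `"with_blocker"` or `"no_blocker"`.
#' @param replicate_cqs numeric Cq values, each in (0, `max_cycles`].
#' @param sentinel_flags logical, same length; TRUE marks no amplification.
#' @param max_cycles protocol length, default 45.
#' @return a `cq_measurement` list.
#' @export
cq_measurement <- function(template, condition, replicate_cqs,
                           sentinel_flags = rep(FALSE, length(replicate_cqs)),
                           max_cycles = 45) {
  template <- match.arg(template, QPCR_TEMPLATES)
  condition <- match.arg(condition, c("with_blocker", "no_blocker"))
  if (length(replicate_cqs) < 1) {
    stop("`replicate_cqs` must be non-empty", call. = FALSE)
  }
  if (any(replicate_cqs <= 0 | replicate_cqs > max_cycles)) {
    stop("replicate Cq values must lie in (0, max_cycles]", call. = FALSE)
  }
  if (length(sentinel_flags) != length(replicate_cqs)) {
    stop("`sentinel_flags` must match `replicate_cqs` in length",
         call. = FALSE)
  }
  structure(
    list(template = template, condition = condition,
         replicate_cqs = replicate_cqs,
         sentinel_flags = as.logical(sentinel_flags),
         max_cycles = max_cycles),
    class = "cq_measurement"
  )
}

#' Simulate with/without-blocker qPCR for one variant on one template
#'
#' The Cq model assumes copy-matched template inputs and perfect doubling of
#' the variant allele in the with-blocker reaction: the no-blocker Cq sits
#' at `base_cq`, and the with-blocker Cq is delayed by the assay's blocker
#' overhead plus one cycle per halving of the variant fraction
#' (`-log2(VAF)`). Consequently the noise-free model satisfies
#' `dCq_sample - dCq_gBlock = -log2(true VAF)` exactly, which is what the
#' downstream VAF estimator inverts. A 0% VAF template (the gDNA negative
#' control, or a variant truly absent from the tested sample) never crosses
#' threshold with blocker and is recorded at the sentinel Cq. Independent
#' Gaussian noise of sd `cq_noise_sd` is added per replicate.
#'
#' @param variant one row of a [simulate_truth_set()] table (or any list
#'   with `true_vaf_ff` / `true_vaf_ffpe`).
#' @param assay a [bda_assay()].
#' @param template one of `"sample_FF"`, `"sample_FFPE"`, `"gBlock"`,
#'   `"gDNA_negative"`.
#' @param config a [sim_config()] object.
#' @param seed optional integer; when supplied the draw is independently
#'   reproducible, otherwise the current RNG stream is used (so a seeded
#'   cohort loop stays deterministic as a whole).
#' @return list with elements `with_blocker` and `no_blocker`, each a
#'   [cq_measurement()].
#' @export
#' @examples
#' cfg <- sim_config(cq_noise_sd = 0, seed = 1)
#' v <- list(true_vaf_ff = 0.01, true_vaf_ffpe = 0.01)
#' m <- simulate_qpcr(v, bda_assay("chr1", 1, "G", "A"), "sample_FF", cfg)
#' mean(m$with_blocker$replicate_cqs) - mean(m$no_blocker$replicate_cqs)
simulate_qpcr <- function(variant, assay, template, config, seed = NULL) {
  template <- match.arg(template, QPCR_TEMPLATES)
  validate_sim_config(config)
  vaf <- switch(template,
    sample_FF = variant$true_vaf_ff,
    sample_FFPE = variant$true_vaf_ffpe,
    gBlock = 1,
    gDNA_negative = 0
  )
  draw <- function() {
    k <- config$replicates
    noise <- function() rnorm(k, 0, config$cq_noise_sd)
    nb_cq <- pmin(config$base_cq + noise(), config$max_cycles)
    if (vaf <= 0) {
      wb <- cq_measurement(template, "with_blocker",
                           rep(config$max_cycles, k),
                           rep(TRUE, k), config$max_cycles)
    } else {
      mu <- config$base_cq + assay$blocker_overhead_cycles - log2(vaf)
      wb_cq <- mu + noise()
      sent <- wb_cq >= config$max_cycles
      wb_cq[sent] <- config$max_cycles
      wb <- cq_measurement(template, "with_blocker", wb_cq, sent,
                           config$max_cycles)
    }
    list(
      with_blocker = wb,
      no_blocker = cq_measurement(template, "no_blocker", nb_cq,
                                  rep(FALSE, k), config$max_cycles)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
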