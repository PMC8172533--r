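#' Simulate WES variant calls from a truth set
#'
#' Draws a locus depth from an overdispersed (negative-binomial) depth
#' distribution with the sample's configured mean, samples variant-allele
#' reads binomially at the locus's true VAF, adds background error reads at
#' `per_base_error_rate`, and emits a call whenever alt reads reach
#' `min_alt_reads`. Calls are labelled with the truth's *reported* allele,
#' so planted misidentifications propagate into the call set. WES VAF is
#' reported in percent (100 * alt_reads / depth).
#'
#' @param truth tibble from [simulate_truth_set()]; must be non-empty.
#' @param sample `"FF"` or `"FFPE"`.
#' @param config a [sim_config()] object.
#' @param depth optional fixed depth (scalar or per-locus vector) overriding
#'   the depth distribution, for controlled experiments.
#' @return tibble of variant calls: `chrom`, `pos`, `ref`, `alt`,
#'   `alt_reads`, `depth`, `vaf` (percent), `gene`, `category`, `sample`.
#'   Deterministic given `config$seed`.
#' @export
#' @examples
#' cfg <- sim_config(n_true_variants = 30, n_ff_only = 0,
#'                   n_artifact_variants = 0, n_misidentified = 0, seed = 2)
#' calls <- simulate_wes_calls(simulate_truth_set(cfg), "FF", cfg)
#' head(calls)
simulate_wes_calls <- function(truth, sample = c("FF", "FFPE"), config,
                               depth = NULL) {
  if (!is.data.frame(truth) || nrow(truth) == 0) {
    stop("`truth` must be a non-empty truth-set table", call. = FALSE)
  }
  sample <- match.arg(sample)
  validate_sim_config(config)

  n <- nrow(truth)
  true_vaf <- if (sample == "FF") truth$true_vaf_ff else truth$true_vaf_ffpe
  depth_mean <- if (sample == "FF") config$depth_mean_ff else
    config$depth_mean_ffpe

  withr::with_seed(config$seed + match(sample, c("FF", "FFPE")), {
    dp <- if (is.null(depth)) {
      rnbinom(n, mu = depth_mean, size = config$depth_dispersion)
    } else {
      rep_len(as.integer(depth), n)
    }
    true_reads <- rbinom(n, dp, true_vaf)
    err_reads <- rbinom(n, dp - true_reads, config$per_base_error_rate)
    alt_reads <- true_reads + err_reads
  })

  keep <- dp > 0 & alt_reads >= config$min_alt_reads
  kept_alt <- alt_reads[keep]
  kept_dp <- dp[keep]
  tibble::tibble(
    chrom = truth$chrom[keep], pos = truth$pos[keep],
    ref = truth$ref[keep], alt = truth$reported_alt[keep],
    alt_reads = kept_alt, depth = kept_dp,
    vaf = 100 * kept_alt / kept_dp,
    gene = truth$gene[keep], category = truth$category[keep],
    sample = sample
  )
}
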