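#' Simulation configuration for the synthetic mirrored FF/FFPE cohort
#'
#' Collects every tunable of the synthetic-data generator and validates it.
#' Defaults describe a mirrored pair of samples from one tumor: a
#' fresh-frozen (FF) exome and its formalin-fixed paraffin-embedded (FFPE)
#' counterpart, the latter carrying extra low-level cytosine-deamination
#' artifacts (C:G>T:A) and a lower effective sequencing depth.
#'
#' @param n_true_variants number of true somatic variants shared by both
#'   samples (true VAF drawn log-uniformly over `vaf_range` in each).
#' @param n_ff_only number of true variants present in FF only
#'   (`true_vaf_ffpe = 0`); these feed the false-negative analysis.
#' @param n_artifact_variants number of FFPE-only damage artifacts
#'   (`true_vaf_ff = 0`).
#' @param n_misidentified number of shared variants whose simulated caller
#'   reports a wrong allele (an adjacent-insertion truth reported as a
#'   substitution); must not exceed `n_true_variants`.
#' @param vaf_range two fractions; true VAFs are log-uniform over this
#'   interval. Default `c(0.005, 0.05)`, the 0.5--5% band in which putative
#'   low-level calls are examined.
#' @param vaf_scale_ffpe multiplicative FF-to-FFPE true-VAF scaling for
#'   shared variants (the FF/FFPE relationship is not observable upstream,
#'   so it is exposed rather than asserted; default 1).
#' @param depth_mean_ff,depth_mean_ffpe mean WES depth at variant loci
#'   (reads). Defaults 824 and 243.
#' @param depth_dispersion negative-binomial size parameter for locus depth
#'   (smaller = more overdispersed). Default 4.
#' @param per_base_error_rate probability a sequenced base is a specific
#'   wrong base (background error reads). Default 1e-4.
#' @param deamination_excess probability an artifact variant belongs to the
#'   C:G>T:A deamination class (remainder spread over other substitution
#'   classes). Default 0.8.
#' @param min_alt_reads minimum alt reads for the simulated caller to emit
#'   a call. Default 3; set 4 to mimic the stricter FF behaviour.
#' @param cancer_gene_frac fraction of loci assigned to the cancer-related
#'   gene pool. Default 0.03.
#' @param base_cq no-blocker quantification cycle of a standard template
#'   input (all templates are copy-matched). Default 25 cycles.
#' @param cq_noise_sd per-replicate Gaussian Cq noise, cycles. Default 0.15.
#' @param replicates qPCR replicates per reaction (>= 2). Default 3.
#' @param max_cycles cycling protocol length; Cq values at this sentinel
#'   mean "no amplification". Default 45.
#' @param dominant_threshold post-enrichment allele fraction above which a
#'   Sanger trace calls the variant base, in (0, 0.5]. Default 0.2.
#' @param seed integer seed; every generator consuming the config is
#'   deterministic given it.
#'
#' @return a `bda_sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_true_variants = 50, n_artifact_variants = 10, seed = 7)
#' cfg$depth_mean_ffpe
sim_config <- function(n_true_variants = 1700,
                       n_ff_only = 300,
                       n_artifact_variants = 6500,
                       n_misidentified = 5,
                       vaf_range = c(0.005, 0.05),
                       vaf_scale_ffpe = 1,
                       depth_mean_ff = 824,
                       depth_mean_ffpe = 243,
                       depth_dispersion = 4,
                       per_base_error_rate = 1e-4,
                       deamination_excess = 0.8,
                       min_alt_reads = 3,
                       cancer_gene_frac = 0.03,
                       base_cq = 25,
                       cq_noise_sd = 0.15,
                       replicates = 3,
                       max_cycles = 45,
                       dominant_threshold = 0.2,
                       seed = 1L) {
  cfg <- list(
    n_true_variants = n_true_variants, n_ff_only = n_ff_only,
    n_artifact_variants = n_artifact_variants,
    n_misidentified = n_misidentified,
    vaf_range = vaf_range, vaf_scale_ffpe = vaf_scale_ffpe,
    depth_mean_ff = depth_mean_ff, depth_mean_ffpe = depth_mean_ffpe,
    depth_dispersion = depth_dispersion,
    per_base_error_rate = per_base_error_rate,
    deamination_excess = deamination_excess,
    min_alt_reads = min_alt_reads, cancer_gene_frac = cancer_gene_frac,
    base_cq = base_cq, cq_noise_sd = cq_noise_sd,
    replicates = replicates, max_cycles = max_cycles,
    dominant_threshold = dominant_threshold, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "bda_sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != trunc(v)) {
      stop("invalid config: `", field, "` must be a single count >= 0",
           call. = FALSE)
    }
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop("invalid config: `", field, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  for (f in c("n_true_variants", "n_ff_only", "n_artifact_variants",
              "n_misidentified", "min_alt_reads", "replicates",
              "max_cycles")) chk_count(f)
  for (f in c("per_base_error_rate", "deamination_excess", "vaf_range",
              "cancer_gene_frac")) chk_prob(f)
  if (cfg$replicates < 2) {
    stop("invalid config: `replicates` must be >= 2 (reactions are run in ",
         "duplicate or triplicate)", call. = FALSE)
  }
  if (cfg$n_misidentified > cfg$n_true_variants) {
    stop("invalid config: `n_misidentified` exceeds `n_true_variants`",
         call. = FALSE)
  }
  if (length(cfg$vaf_range) != 2 || diff(cfg$vaf_range) < 0 ||
      cfg$vaf_range[1] <= 0) {
    stop("invalid config: `vaf_range` must be increasing and positive",
         call. = FALSE)
  }
  if (cfg$cq_noise_sd < 0) {
    stop("invalid config: `cq_noise_sd` must be >= 0", call. = FALSE)
  }
  if (cfg$dominant_threshold <= 0 || cfg$dominant_threshold > 0.5) {
    stop("invalid config: `dominant_threshold` must be in (0, 0.5]",
         call. = FALSE)
  }
  if (cfg$depth_mean_ff <= 0 || cfg$depth_mean_ffpe <= 0 ||
      cfg$depth_dispersion <= 0) {
    stop("invalid config: depth parameters must be positive", call. = FALSE)
  }
  invisible(cfg)
}
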