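#' Quantitative accuracy of delta-Cq VAF estimation under replicate noise
#'
#' Simulates a panel of independent assays, each targeting a variant with a
#' true VAF drawn log-uniformly over `config$vaf_range`: triplicate (or as
#' configured) with-blocker and no-blocker Cq values are generated for the
#' sample and for its gBlock calibrator with Gaussian replicate noise,
#' replicates are averaged, both delta-Cq values formed, and the VAF
#' estimated. The per-assay fold deviation is
#' `max(estimate/truth, truth/estimate)`; its median across assays is the
#' headline accuracy figure (BDA delta-Cq estimates are expected to sit
#' within 1.5-fold of an orthogonal ddPCR measurement).
#'
#' @param n_assays number of simulated assays.
#' @param config a [sim_config()]; `cq_noise_sd`, `replicates` and
#'   `vaf_range` drive the simulation, `seed` makes it reproducible.
#' @param assay a [bda_assay()] shared by all targets.
#' @return tibble with `true_vaf` (percent), `estimated_vaf` (percent) and
#'   `fold_deviation`.
#' @export
#' @examples
#' sim <- vaf_accuracy_simulation(50, sim_config(seed = 42))
#' median(sim$fold_deviation)
vaf_accuracy_simulation <- function(n_assays, config,
                                    assay = bda_assay("chr1", 1L, "G", "A")) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    true_vaf <- rloguni(n_assays, config$vaf_range[1], config$vaf_range[2])
    est <- vapply(true_vaf, function(f) {
      v <- list(true_vaf_ff = f, true_vaf_ffpe = f)
      m <- simulate_qpcr(v, assay, "sample_FF", config)
      g <- simulate_qpcr(v, assay, "gBlock", config)
      dcq_s <- delta_cq(aggregate_replicates(m$with_blocker),
                        aggregate_replicates(m$no_blocker),
                        config$max_cycles)
      dcq_g <- delta_cq(aggregate_replicates(g$with_blocker),
                        aggregate_replicates(g$no_blocker),
                        config$max_cycles)
      estimate_vaf(dcq_s, dcq_g, tolerance = 3 * config$cq_noise_sd + 1e-9)
    }, double(1))
    true_pct <- 100 * true_vaf
    tibble::tibble(
      true_vaf = true_pct, estimated_vaf = est,
      fold_deviation = pmax(est / true_pct, true_pct / est)
    )
  })
}
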