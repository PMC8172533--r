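# Small-scale simulation config used across tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_true_variants = 40, n_ff_only = 5, n_artifact_variants = 20,
    n_misidentified = 2, seed = 11L
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Build a confirmation-results tibble from per-status counts, with
# optional stratification columns recycled across rows.
make_results <- function(n_confirmed = 0, n_absent = 0,
                         n_misidentified = 0, n_failed = 0, ...) {
  status <- rep(c("confirmed", "absent", "misidentified", "failed_qc"),
                c(n_confirmed, n_absent, n_misidentified, n_failed))
  out <- tibble::tibble(status = status)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- rep_len(extra[[nm]], nrow(out))
  out
}

# Truth row helper for single-variant simulator calls
truth_row <- function(ref = "G", true_alt = "A", reported_alt = true_alt,
                      vaf_ff = 0.01, vaf_ffpe = vaf_ff) {
  list(chrom = "chr1", pos = 1000L, ref = ref, true_alt = true_alt,
       reported_alt = reported_alt, true_vaf_ff = vaf_ff,
       true_vaf_ffpe = vaf_ffpe, gene = "CG001",
       category = "nonsynonymous", is_artifact = FALSE)
}

default_assay <- function(...) {
  bda_assay("chr1", 1000L, "G", "A", ...)
}

# Deterministic noise-free ΔCq pipeline for one true VAF
noise_free_estimate <- function(true_vaf, cfg = sim_config(cq_noise_sd = 0),
                                assay = default_assay()) {
  v <- truth_row(vaf_ff = true_vaf)
  m_s <- simulate_qpcr(v, assay, "sample_FF", cfg, seed = 1)
  m_g <- simulate_qpcr(v, assay, "gBlock", cfg, seed = 2)
  dcq_s <- delta_cq(aggregate_replicates(m_s$with_blocker),
                    aggregate_replicates(m_s$no_blocker))
  dcq_g <- delta_cq(aggregate_replicates(m_g$with_blocker),
                    aggregate_replicates(m_g$no_blocker))
  estimate_vaf(dcq_s, dcq_g)
}
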