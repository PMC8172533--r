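BASES <- c("A", "C", "G", "T")

CATEGORIES <- c("nonsynonymous", "frameshift", "synonymous", "intron",
                "regulatory", "other")

# category mix loosely matching an FFPE-heavy somatic call set
CATEGORY_WEIGHTS <- c(nonsynonymous = 0.25, frameshift = 0.05,
                      synonymous = 0.20, intron = 0.30,
                      regulatory = 0.10, other = 0.10)

# log-uniform draw over [lo, hi]
rloguni <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# random single-base substitution alts for given refs
random_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
         USE.NAMES = FALSE)
}

#' Generate the ground-truth variant set for a mirrored FF/FFPE tumor pair
#'
#' Produces three kinds of loci: shared true somatic variants (present in
#' both samples), FF-only true variants, and FFPE-only damage artifacts
#' whose substitution class is C>T or G>A with probability
#' `deamination_excess` (cytosine deamination during fixation). A configured
#' number of shared variants are planted as "misidentified": the truth is a
#' single-base insertion but the simulated caller reports a substitution of
#' the same base, so the reported allele differs from the true one.
#'
#' @param config a [sim_config()] object.
#' @return a tibble with one row per truth variant: `chrom`, `pos`, `ref`,
#'   `true_alt`, `reported_alt`, `true_vaf_ff`, `true_vaf_ffpe`, `gene`,
#'   `category`, `is_artifact`. Deterministic given `config$seed`.
#' @export
#' @examples
#' truth <- simulate_truth_set(sim_config(n_true_variants = 20,
#'   n_ff_only = 0, n_artifact_variants = 5, n_misidentified = 2, seed = 3))
#' table(truth$is_artifact)
simulate_truth_set <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n_shared <- config$n_true_variants
    n_ffonly <- config$n_ff_only
    n_art <- config$n_artifact_variants
    n <- n_shared + n_ffonly + n_art
    if (n == 0) {
      return(tibble::tibble(
        chrom = character(), pos = integer(), ref = character(),
        true_alt = character(), reported_alt = character(),
        true_vaf_ff = double(), true_vaf_ffpe = double(),
        gene = character(), category = character(), is_artifact = logical()
      ))
    }

    chrom <- paste0("chr", sample(c(1:22, "X"), n, replace = TRUE))
    pos <- integer(n)
    for (cn in unique(chrom)) {   # unique positions within a chromosome
      idx <- which(chrom == cn)
      pos[idx] <- sample.int(5e7L, length(idx)) + 10000L
    }
    ref <- sample(BASES, n, replace = TRUE)
    alt <- random_alt(ref)

    n_cancer_genes <- max(1L, ceiling(n * config$cancer_gene_frac / 10))
    cancer_pool <- sprintf("CG%03d", seq_len(max(n_cancer_genes, 25L)))
    other_pool <- sprintf("OG%04d", seq_len(max(ceiling(n / 8), 50L)))
    in_cancer <- runif(n) < config$cancer_gene_frac
    gene <- ifelse(in_cancer,
                   sample(cancer_pool, n, replace = TRUE),
                   sample(other_pool, n, replace = TRUE))
    category <- sample(CATEGORIES, n, replace = TRUE,
                       prob = CATEGORY_WEIGHTS)
    is_artifact <- rep(c(FALSE, FALSE, TRUE), c(n_shared, n_ffonly, n_art))
    ff_only <- rep(c(FALSE, TRUE, FALSE), c(n_shared, n_ffonly, n_art))

    vaf <- rloguni(n, config$vaf_range[1], config$vaf_range[2])
    true_vaf_ff <- ifelse(is_artifact, 0, vaf)
    true_vaf_ffpe <- ifelse(
      is_artifact, vaf,
      ifelse(ff_only, 0, pmin(1, vaf * config$vaf_scale_ffpe))
    )

    # bias artifact substitution classes toward C:G>T:A deamination
    if (n_art > 0) {
      art <- which(is_artifact)
      deam <- runif(n_art) < config$deamination_excess
      ref[art[deam]] <- sample(c("C", "G"), sum(deam), replace = TRUE)
      alt[art[deam]] <- ifelse(ref[art[deam]] == "C", "T", "A")
      redo <- art[!deam]
      # keep non-deamination artifacts out of the C>T/G>A class
      ct_ga <- (ref[redo] == "C" & alt[redo] == "T") |
        (ref[redo] == "G" & alt[redo] == "A")
      while (any(ct_ga)) {
        alt[redo[ct_ga]] <- random_alt(ref[redo[ct_ga]])
        ct_ga <- (ref[redo] == "C" & alt[redo] == "T") |
          (ref[redo] == "G" & alt[redo] == "A")
      }
    }

    reported_alt <- alt
    # plant misidentifications: truth is an anchored 1-bp insertion, the
    # caller reports the inserted base as a substitution at the anchor
    if (config$n_misidentified > 0) {
      mis <- sample(seq_len(n_shared), config$n_misidentified)
      ins_base <- random_alt(ref[mis])
      alt[mis] <- paste0(ref[mis], ins_base)
      reported_alt[mis] <- ins_base
    }

    out <- tibble::tibble(
      chrom = chrom, pos = pos, ref = ref, true_alt = alt,
      reported_alt = reported_alt,
      true_vaf_ff = true_vaf_ff, true_vaf_ffpe = true_vaf_ffpe,
      gene = gene, category = category, is_artifact = is_artifact
    )
    dplyr::arrange(out, chrom_rank(.data$chrom), .data$pos)
  })
}
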