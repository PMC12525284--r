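#' Default growth-trait models
#'
#' Eight growth traits: birth weight, body weights at 90/180/240 days, and
#' average daily gains over the intervals 0-90, 90-180, 180-240 and 0-240
#' days. Variance components are stated per trait (units kg resp. kg/day);
#' heritabilities are typical moderate values for ovine growth traits
#' (0.20-0.35).
#'
#' @param n_qtl causal SNPs per trait.
#' @return Named list of [trait_model] objects.
#' @export
default_traits <- function(n_qtl = 300L) {
  spec <- list(
    #            mu     sigma2_p  h2
    BW          = c(4.2,   0.60, 0.30),
    W90         = c(26.0, 16.00, 0.30),
    W180        = c(42.0, 30.00, 0.35),
    W240        = c(55.0, 42.00, 0.35),
    ADG_0_90    = c(0.24, 0.0016, 0.25),
    ADG_90_180  = c(0.18, 0.0020, 0.25),
    ADG_180_240 = c(0.21, 0.0025, 0.20),
    ADG_0_240   = c(0.21, 0.0012, 0.30)
  )
  out <- lapply(names(spec), function(nm) {
    v <- spec[[nm]]
    trait_model(name = nm, mu = v[1], sigma2_a = v[3] * v[2],
                sigma2_e = (1 - v[3]) * v[2], n_qtl = n_qtl)
  })
  names(out) <- names(spec)
  out
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults are the study
#' conditions of the simulated cohort: a 5,000-SNP panel on 5 chromosomes,
#' 200 phenotyped reference animals, 40 embryo/lamb pairs, biopsy arms at
#' 1/5/10/20/30 cells, and the 10-cell arm feeding imputation and GBLUP.
#'
#' @param seed master integer seed; every stage derives its own stream
#'   from it.
#' @param n_snps,n_chr marker panel dimensions.
#' @param n_ref reference (phenotyped) individuals.
#' @param n_pairs embryo/lamb pairs.
#' @param maf_low,maf_high founder site-frequency bounds.
#' @param switch_prob per-adjacent-marker recombination switch probability.
#' @param arms biopsy cell-number arms.
#' @param q_capture_fail,eps_error WGA noise parameters (see
#'   [wga_noise_model]).
#' @param lamb_eps,lamb_missing error and missingness of the lamb blood
#'   genotyping channel.
#' @param qc a [qc_thresholds].
#' @param hmm an [hmm_params].
#' @param gblup_cells which arm feeds imputation and the GEBV comparison.
#' @param traits list of [trait_model]s.
#' @param with_imputation run the imputation stage and the imputed GEBV
#'   comparison.
#' @return A list of class `egs_config`.
#' @export
egs_config <- function(seed = 1L,
                       n_snps = 5000L, n_chr = 5L,
                       n_ref = 200L, n_pairs = 40L,
                       maf_low = 0.05, maf_high = 0.5,
                       switch_prob = 0.001,
                       arms = c(1L, 5L, 10L, 20L, 30L),
                       q_capture_fail = 0.72, eps_error = 0.003,
                       lamb_eps = 0.002, lamb_missing = 0.01,
                       qc = qc_thresholds(),
                       hmm = hmm_params(),
                       gblup_cells = 10L,
                       traits = default_traits(),
                       with_imputation = TRUE) {
  stopifnot(gblup_cells %in% arms, length(traits) >= 1L)
  structure(as.list(environment()), class = "egs_config")
}

# deterministic per-stage seed derived from the master seed; kept well
# below .Machine$integer.max for small master seeds
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}
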