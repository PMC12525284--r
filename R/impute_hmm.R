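#' HMM imputation parameters
#'
#' @param switch_rate per-adjacent-marker haplotype switch probability, in
#'   `(0, 0.5]`.
#' @param emit_error per-site per-allele emission error, in `(0, 0.5)`.
#' @param posterior_call_min minimum genotype posterior required to emit
#'   (or change) a call, in `(1/3, 1]`.
#' @param top_k number of panel haplotypes pre-selected by identity-by-state
#'   similarity to the target before building the diploid state space; the
#'   result is identical to the full panel whenever `top_k >= H`.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(switch_rate = 0.01, emit_error = 0.01,
                       posterior_call_min = 0.9, top_k = 20L) {
  if (!(switch_rate > 0 && switch_rate <= 0.5)) stop("switch_rate must be in (0, 0.5]")
  if (!(emit_error > 0 && emit_error < 0.5)) stop("emit_error must be in (0, 0.5)")
  if (!(posterior_call_min > 1 / 3 && posterior_call_min <= 1)) {
    stop("posterior_call_min must be in (1/3, 1]")
  }
  stopifnot(top_k >= 2L)
  structure(list(switch_rate = switch_rate, emit_error = emit_error,
                 posterior_call_min = posterior_call_min,
                 top_k = as.integer(top_k)), class = "hmm_params")
}

# IBS-style similarity of each panel haplotype to an observed genotype
# vector: hom sites score allele agreement, het sites are uninformative
# (constant 0.5). Used only for top-K haplotype pre-selection.
hap_ibs_scores <- function(observed, haps) {
  called <- !is.na(observed)
  if (!any(called)) return(rep(0, nrow(haps)))
  g <- observed[called]
  h <- haps[, called, drop = FALSE]
  hom0 <- g == 0L
  hom2 <- g == 2L
  score <- numeric(nrow(haps))
  if (any(hom0)) score <- score + rowSums(h[, hom0, drop = FALSE] == 0L)
  if (any(hom2)) score <- score + rowSums(h[, hom2, drop = FALSE] == 1L)
  score <- score + 0.5 * sum(g == 1L)
  score / length(g)
}

#' Impute one sample against a phased reference panel
#'
#' Diploid Li-Stephens HMM: the hidden state is an ordered pair of panel
#' haplotypes, each copy switching independently between markers with
#' probability `switch_rate`; the genotype implied by the pair is compared
#' to the observed call through a per-allele error channel (`emit_error`);
#' missing sites emit uniformly. Forward-backward posteriors over genotypes
#' \{0, 1, 2\} are computed with per-site normalization. The output call at
#' a site is the posterior argmax where the posterior reaches
#' `posterior_call_min`; below the threshold an existing call is kept
#' unchanged and a missing site stays missing, so calls are only ever added
#' or corrected, never dropped.
#'
#' Panels larger than `top_k` haplotypes are first reduced to the `top_k`
#' most IBS-similar haplotypes (deterministic ties by panel order).
#'
#' @param observed genotype vector over the panel's marker map (NA =
#'   missing).
#' @param panel a [hap_panel] with at least 2 haplotypes.
#' @param params an [hmm_params].
#' @return List with `imputed` (genotype vector), `posterior` (3 x S matrix
#'   of genotype posteriors) and `haps_used` (row indices of the panel
#'   haplotypes in the state space).
#' @export
impute_sample <- function(observed, panel, params = hmm_params()) {
  stopifnot(inherits(panel, "hap_panel"), inherits(params, "hmm_params"))
  s <- ncol(panel$haps)
  if (length(observed) != s) stop("observed vector does not match the panel's marker map")
  if (nrow(panel$haps) < 2L) stop("panel must contain at least 2 haplotypes")
  haps <- panel$haps
  haps_used <- seq_len(nrow(haps))
  if (nrow(haps) > params$top_k) {
    sc <- hap_ibs_scores(observed, haps)
    haps_used <- order(sc, decreasing = TRUE)[seq_len(params$top_k)]
    haps_used <- sort(haps_used)
    haps <- haps[haps_used, , drop = FALSE]
  }
  obs <- as.integer(observed)
  post <- hmm_genotype_posterior_cpp(haps, obs, params$switch_rate,
                                     params$emit_error)
  best <- max.col(t(post), ties.method = "first") - 1L
  pmax_post <- apply(post, 2L, max)
  confident <- pmax_post >= params$posterior_call_min
  imputed <- obs
  imputed[confident] <- best[confident]
  # below threshold: keep the original call (never drop a call)
  list(imputed = imputed, posterior = post, haps_used = haps_used)
}

#' Impute every sample of a genotype matrix
#'
#' Restricts to the intersection of the matrix and panel marker maps
#' (matched by SNP id), then runs [impute_sample] per sample.
#'
#' @param gm a [geno_matrix].
#' @param panel a [hap_panel].
#' @param params an [hmm_params].
#' @return A [geno_matrix] of post-imputation calls on the shared map, with
#'   the per-sample mean maximum posterior attached as attribute
#'   `mean_max_posterior`.
#' @export
impute_matrix <- function(gm, panel, params = hmm_params()) {
  shared <- intersect(gm$map$snp_id, panel$map$snp_id)
  if (length(shared) == 0L) stop("marker maps share no SNPs")
  gm <- subset_geno(gm, snps = match(shared, gm$map$snp_id))
  keep <- match(shared, panel$map$snp_id)
  pmap <- panel$map[keep, , drop = FALSE]
  class(pmap) <- c("marker_map", "data.frame")
  panel <- hap_panel(panel$haps[, keep, drop = FALSE], pmap,
                     individuals = panel$individuals)
  out <- gm$calls
  conf <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    res <- impute_sample(gm$calls[i, ], panel, params)
    out[i, ] <- res$imputed
    conf[i] <- mean(apply(res$posterior, 2L, max))
  }
  g <- geno_matrix(out, gm$map)
  attr(g, "mean_max_posterior") <- stats::setNames(conf, rownames(out))
  g
}
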