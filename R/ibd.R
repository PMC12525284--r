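#' Method-of-moments IBD estimate for a sample pair
#'
#' PLINK-style estimator: identity-by-state counts (IBS0/1/2 over jointly
#' called SNPs) are combined with their allele-frequency expectations under
#' each identity-by-descent state to solve for P(IBD=0), P(IBD=1), P(IBD=2).
#' Expectations use exact without-replacement allele-count products (the
#' finite-sample correction), with allele counts taken as `2 * n_called`
#' individuals from the cohort the frequencies were estimated on. Negative
#' solutions are truncated to `[0, 1]` and renormalized;
#' `pi_hat = P(IBD=2) + P(IBD=1) / 2`.
#'
#' SNPs that are monomorphic, frequency-undefined, or estimated from fewer
#' than two individuals are excluded. Pairs with fewer than `min_joint`
#' usable SNPs are flagged `low_confidence`.
#'
#' @param gm a [geno_matrix] containing both samples.
#' @param id_a,id_b sample ids.
#' @param freqs [allele_frequencies] of the cohort (typically the reference
#'   population), aligned to `gm`'s marker map.
#' @param min_joint minimum usable SNP count before flagging.
#' @return An object of class `ibd_estimate`: `p_ibd0`, `p_ibd1`, `p_ibd2`,
#'   `pi_hat`, `n_snps`, `low_confidence`.
#' @export
moment_ibd <- function(gm, id_a, id_b, freqs = allele_frequencies(gm),
                       min_joint = 200L) {
  calls <- gm$calls
  if (!all(c(id_a, id_b) %in% rownames(calls))) stop("sample id not in matrix")
  idx <- match(gm$map$snp_id, freqs$snp_id)
  if (anyNA(idx)) stop("frequencies do not cover the marker map")
  p <- freqs$p_alt[idx]
  nc <- freqs$n_called[idx]
  ga <- calls[id_a, ]
  gb <- calls[id_b, ]
  use <- !is.na(ga) & !is.na(gb) & !is.na(p) & p > 0 & p < 1 & nc >= 2L
  if (!any(use)) stop("no usable SNPs for IBD estimation")
  ga <- ga[use]; gb <- gb[use]; p <- p[use]; t_all <- 2 * nc[use]

  ibs <- 2L - abs(ga - gb)
  n_ibs <- tabulate(ibs + 1L, nbins = 3L)  # counts of IBS0, IBS1, IBS2

  x <- p * t_all          # alt allele count
  y <- t_all - x          # ref allele count
  d4 <- t_all * (t_all - 1) * (t_all - 2) * (t_all - 3)
  d3 <- t_all * (t_all - 1) * (t_all - 2)
  # expectations of IBS class probabilities given IBD state, summed over SNPs
  e00 <- sum(2 * x * (x - 1) * y * (y - 1) / d4)
  e10 <- sum((4 * x * (x - 1) * (x - 2) * y + 4 * x * y * (y - 1) * (y - 2)) / d4)
  e20 <- sum((x * (x - 1) * (x - 2) * (x - 3) + y * (y - 1) * (y - 2) * (y - 3) +
                4 * x * (x - 1) * y * (y - 1)) / d4)
  e11 <- sum((2 * x * (x - 1) * y + 2 * x * y * (y - 1)) / d3)
  e21 <- sum((x * (x - 1) * (x - 2) + y * (y - 1) * (y - 2) +
                x * (x - 1) * y + x * y * (y - 1)) / d3)
  s <- length(ga)

  z0 <- n_ibs[1] / e00
  z1 <- (n_ibs[2] - z0 * e10) / e11
  z2 <- (n_ibs[3] - z0 * e20 - z1 * e21) / s
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  if (sum(z) == 0) z <- c(1, 0, 0) else z <- z / sum(z)
  structure(list(p_ibd0 = z[1], p_ibd1 = z[2], p_ibd2 = z[3],
                 pi_hat = z[3] + z[2] / 2,
                 n_snps = s,
                 low_confidence = s < min_joint),
            class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("IBD: Z0 %.3f  Z1 %.3f  Z2 %.3f  pi_hat %.3f  (%d SNPs%s)\n",
              x$p_ibd0, x$p_ibd1, x$p_ibd2, x$pi_hat, x$n_snps,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}
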