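#' QC thresholds (PLINK-style)
#'
#' Thresholds mirror the PLINK flags they are named after: `maf_min`
#' (`--maf`, SNPs with minor allele frequency below it removed; ties kept),
#' `hwe_p_min` (`--hwe`, SNPs with exact-test p-value below it removed),
#' `mind_max` (`--mind`, samples with missing fraction above it removed),
#' `geno_max` (`--geno`, SNPs with missing fraction above it removed).
#'
#' @param maf_min,hwe_p_min,mind_max,geno_max values in `[0, 1]`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_p_min = 1e-5,
                          mind_max = 0.1, geno_max = 0.1) {
  v <- c(maf_min, hwe_p_min, mind_max, geno_max)
  if (any(v < 0 | v > 1)) stop("all thresholds must be in [0, 1]")
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 mind_max = mind_max, geno_max = geno_max),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (two-sided,
#' Wigginton-style, no mid-p). An asymptotic chi-square alternative is
#' available via `method = "chisq"`.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts, not all
#'   zero.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt, method = c("exact", "chisq")) {
  method <- match.arg(method)
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(cnt < 0) || anyNA(cnt)) stop("genotype counts must be non-negative")
  n <- sum(cnt)
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2 * n_hom_ref + n_het
  n_b <- 2 * n_hom_alt + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  if (method == "chisq") {
    p <- n_a / (2 * n)
    expct <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((cnt - expct)^2 / pmax(expct, .Machine$double.eps))
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | allele counts), up to a constant
  logp <- h_log_prob(hets, n, rare)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed het count inconsistent with allele counts")
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# unnormalized log conditional probability of h heterozygotes given
# N genotypes and a rare-allele count R:
#   P(h) = 2^h N! R! (2N-R)! / ( ((R-h)/2)! h! ((2N-R-h)/2)! (2N)! )
h_log_prob <- function(h, n, rare) {
  common <- 2 * n - rare
  h * log(2) - lfactorial((rare - h) / 2) - lfactorial(h) -
    lfactorial((common - h) / 2)
}

#' Apply marker and sample QC
#'
#' Filters applied in the fixed order sample missingness (`mind`) ->
#' SNP missingness (`geno`) -> MAF -> HWE, with the statistics for each
#' later filter recomputed on the data surviving the earlier ones (PLINK's
#' documented order). The MAF filter keeps SNPs at the threshold
#' (`>=` semantics) and removes SNPs whose frequency is undefined
#' (all-missing) when `maf_min > 0`. HWE genotype counts can be restricted
#' to a subset of samples (e.g. the phenotyped reference cohort) via
#' `hwe_samples`, so WGA-noisy biopsy genotypes do not distort the test;
#' SNP removal still applies to the whole matrix.
#'
#' The operation is idempotent: a second pass at the same thresholds
#' removes nothing. An empty surviving matrix is flagged in the report, not
#' an error.
#'
#' @param gm a [geno_matrix].
#' @param thr a [qc_thresholds].
#' @param hwe_samples optional character vector of sample ids for the HWE
#'   counts; default all samples.
#' @return List with `gm` (filtered [geno_matrix]) and `report` (class
#'   `qc_report`): per-step removal counts and surviving dimensions.
#' @export
apply_qc <- function(gm, thr, hwe_samples = NULL) {
  stopifnot(inherits(thr, "qc_thresholds"))
  dims_in <- dim(gm$calls)
  steps <- data.frame(step = c("mind", "geno", "maf", "hwe"),
                      axis = c("sample", "snp", "snp", "snp"),
                      removed = 0L, stringsAsFactors = FALSE)

  # 1. sample missingness
  miss_s <- 1 - call_rates(gm)$per_sample
  keep_s <- miss_s <= thr$mind_max
  steps$removed[1] <- sum(!keep_s)
  gm <- subset_geno(gm, samples = which(keep_s))

  if (nrow(gm$calls) > 0L) {
    # 2. SNP missingness
    miss_m <- 1 - call_rates(gm)$per_snp
    keep_m <- miss_m <= thr$geno_max
    steps$removed[2] <- sum(!keep_m)
    gm <- subset_geno(gm, snps = which(keep_m))

    # 3. MAF
    if (ncol(gm$calls) > 0L) {
      p <- allele_frequencies(gm)$p_alt
      maf <- pmin(p, 1 - p)
      keep_m <- if (thr$maf_min > 0) !is.na(maf) & maf >= thr$maf_min else rep(TRUE, length(maf))
      steps$removed[3] <- sum(!keep_m)
      gm <- subset_geno(gm, snps = which(keep_m))
    }

    # 4. HWE
    if (ncol(gm$calls) > 0L) {
      sub <- gm$calls
      if (!is.null(hwe_samples)) {
        sub <- sub[rownames(sub) %in% hwe_samples, , drop = FALSE]
      }
      pvals <- apply(sub, 2L, function(col) {
        cnt <- tabulate(col + 1L, nbins = 3L)
        if (sum(cnt) == 0L) return(1)
        hwe_exact_test(cnt[1], cnt[2], cnt[3])
      })
      keep_m <- pvals >= thr$hwe_p_min
      steps$removed[4] <- sum(!keep_m)
      gm <- subset_geno(gm, snps = which(keep_m))
    }
  }

  report <- structure(list(steps = steps,
                           dims_in = dims_in,
                           dims_out = dim(gm$calls),
                           empty = any(dim(gm$calls) == 0L),
                           thresholds = thr),
                      class = "qc_report")
  list(gm = gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$dims_in[1], "samples x", x$dims_in[2], "SNPs ->",
      x$dims_out[1], "x", x$dims_out[2], "\n")
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %-5s removed %d %s(s)\n", x$steps$step[i],
                x$steps$removed[i], x$steps$axis[i]))
  }
  if (x$empty) cat("  WARNING: QC left an empty matrix\n")
  invisible(x)
}
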