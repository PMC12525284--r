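#' Genotype matrix
#'
#' Samples x SNPs matrix of alt-allele dosages in \{0, 1, 2\}; missing calls
#' are `NA`. This is the container every pipeline stage shares; the alt-dosage
#' coding makes the VanRaden centering `g - 2 p_i` direct.
#'
#' @param calls integer matrix, samples in rows, SNPs in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param map [marker_map] with one row per column of `calls`.
#' @param samples sample ids; defaults to `rownames(calls)`.
#' @return An object of class `geno_matrix` with elements `calls` (named
#'   integer matrix) and `map`.
#' @export
geno_matrix <- function(calls, map, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    if (nrow(calls) == 0L) samples <- character(0) else stop("sample ids are required")
  }
  samples <- as.character(samples)
  if (length(samples) != nrow(calls)) stop("sample ids do not match rows")
  if (anyDuplicated(samples)) stop("duplicated sample ids")
  if (ncol(calls) != nrow(map)) stop("calls and marker map disagree on SNP count")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be in {0, 1, 2, NA}")
  }
  dimnames(calls) <- list(samples, map$snp_id)
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs;",
      sprintf("call rate %.4f\n", mean(!is.na(x$calls))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix].
#' @param samples,snps sample ids / SNP ids (or logical or integer indices)
#'   to retain; `NULL` keeps all.
#' @return A [geno_matrix].
#' @export
subset_geno <- function(gm, samples = NULL, snps = NULL) {
  calls <- gm$calls
  map <- gm$map
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, map$snp_id)
    calls <- calls[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    class(map) <- c("marker_map", "data.frame")
  }
  geno_matrix(calls, map)
}

#' Phased haplotype panel
#'
#' 2N x S binary matrix of alt-allele indicators: two rows (maternal and
#' paternal copies) per individual, aligned to a [marker_map]. Serves as the
#' imputation reference; no missing entries are allowed.
#'
#' @param haps binary matrix with an even number of rows.
#' @param map [marker_map].
#' @param individuals individual ids, one per row pair; defaults to ids
#'   recovered from rownames of the form `<id>.1` / `<id>.2`.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haps, map, individuals = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (anyNA(haps)) stop("haplotype panel contains missing entries")
  if (!all(haps %in% c(0L, 1L))) stop("haplotypes must be binary")
  if (nrow(haps) %% 2L != 0L) stop("haplotype count must be even")
  if (ncol(haps) != nrow(map)) stop("haplotypes and marker map disagree on SNP count")
  n_ind <- nrow(haps) / 2L
  if (is.null(individuals)) {
    if (!is.null(rownames(haps))) {
      individuals <- unique(sub("\\.[12]$", "", rownames(haps)))
      if (length(individuals) != n_ind) stop("cannot recover individual ids from rownames")
    } else {
      individuals <- sprintf("ind%04d", seq_len(n_ind))
    }
  }
  individuals <- as.character(individuals)
  if (length(individuals) != n_ind) stop("one individual id per haplotype pair required")
  if (anyDuplicated(individuals)) stop("duplicated individual ids")
  rownames(haps) <- paste(rep(individuals, each = 2L), rep(1:2, n_ind), sep = ".")
  colnames(haps) <- map$snp_id
  structure(list(haps = haps, map = map, individuals = individuals),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("hap_panel:", nrow(x$haps), "haplotypes (", length(x$individuals),
      "individuals ) x", ncol(x$haps), "SNPs\n")
  invisible(x)
}

#' Collapse a haplotype panel to unphased genotypes
#'
#' @param panel a [hap_panel].
#' @return A [geno_matrix] of alt-allele dosages.
#' @export
panel_to_genotypes <- function(panel) {
  h <- panel$haps
  odd <- seq(1L, nrow(h), by = 2L)
  calls <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  rownames(calls) <- panel$individuals
  geno_matrix(calls, panel$map)
}

#' Per-SNP alt-allele frequencies
#'
#' Frequencies are computed over non-missing calls only:
#' `p_i = alt count / (2 * n called)`. SNPs with no calls get `NA` and an
#' `n_called` of 0 so downstream consumers can exclude them.
#'
#' @param gm a [geno_matrix].
#' @return `data.frame` with columns `snp_id`, `p_alt`, `n_called`.
#' @export
allele_frequencies <- function(gm) {
  calls <- gm$calls
  n_called <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_called > 0L, alt / (2 * n_called), NA_real_)
  data.frame(snp_id = gm$map$snp_id, p_alt = unname(p),
             n_called = unname(n_called), stringsAsFactors = FALSE)
}

#' Per-sample and per-SNP call rates
#'
#' @param gm a [geno_matrix].
#' @return List with named numeric vectors `per_sample` and `per_snp`, each
#'   the fraction of non-missing calls along that axis.
#' @export
call_rates <- function(gm) {
  called <- !is.na(gm$calls)
  list(per_sample = rowMeans(called), per_snp = colMeans(called))
}
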