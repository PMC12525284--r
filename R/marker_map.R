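#' Marker map for a SNP panel
#'
#' A marker map describes the panel of biallelic SNPs every genotype object
#' in the pipeline is aligned to: one row per SNP with a unique id, a
#' chromosome label, a 1-based physical position and the REF/ALT alleles.
#' Positions must be strictly increasing within each chromosome.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome chromosome label per SNP.
#' @param position 1-based physical position (bp), integer-valued.
#' @param allele_ref,allele_alt single-character REF and ALT alleles.
#'
#' @return A `data.frame` of class `marker_map`.
#' @export
marker_map <- function(snp_id, chromosome, position, allele_ref, allele_alt) {
  mm <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = as.character(chromosome),
    position = as.integer(position),
    allele_ref = as.character(allele_ref),
    allele_alt = as.character(allele_alt),
    stringsAsFactors = FALSE
  )
  validate_marker_map(mm)
  class(mm) <- c("marker_map", "data.frame")
  mm
}

validate_marker_map <- function(mm) {
  if (nrow(mm) == 0L) stop("marker map is empty")
  if (anyDuplicated(mm$snp_id)) stop("marker map: snp ids are not unique")
  if (anyNA(mm$position)) stop("marker map: missing positions")
  for (chr in unique(mm$chromosome)) {
    pos <- mm$position[mm$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("marker map: positions not strictly increasing on chromosome ", chr)
    }
  }
  if (any(nchar(mm$allele_ref) != 1L) || any(nchar(mm$allele_alt) != 1L)) {
    stop("marker map: alleles must be single characters")
  }
  if (any(mm$allele_ref == mm$allele_alt)) {
    stop("marker map: ref and alt alleles identical at some SNPs")
  }
  invisible(mm)
}

#' Build an evenly spaced synthetic marker map
#'
#' Stand-in for a 50K-style ovine SNP array at desk scale: `n_snps` biallelic
#' markers spread over `n_chr` chromosomes at fixed spacing.
#'
#' @param n_snps total number of SNPs.
#' @param n_chr number of chromosomes to spread them over.
#' @param spacing distance in bp between adjacent SNPs.
#' @return A [marker_map].
#' @export
make_marker_map <- function(n_snps = 5000, n_chr = 5, spacing = 50000L) {
  stopifnot(n_snps >= 1, n_chr >= 1, n_snps >= n_chr)
  per_chr <- rep(n_snps %/% n_chr, n_chr)
  extra <- n_snps %% n_chr
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  chrom <- rep(as.character(seq_len(n_chr)), per_chr)
  position <- unlist(lapply(per_chr, function(k) spacing * seq_len(k)),
                     use.names = FALSE)
  idx <- seq_len(n_snps)
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                  byrow = TRUE)
  pick <- ((idx - 1L) %% nrow(pairs)) + 1L
  marker_map(
    snp_id = sprintf("snp%05d", idx),
    chromosome = chrom,
    position = position,
    allele_ref = pairs[pick, 1],
    allele_alt = pairs[pick, 2]
  )
}
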