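#' Write genotypes or a phased panel to VCF
#'
#' Emits a minimal deterministic VCF v4.2 with a GT-only FORMAT column.
#' Unphased genotype matrices use `/` separators (`./.` for missing); phased
#' haplotype panels use `|` and carry no missing entries. Output is plain
#' text and byte-stable across runs for identical inputs.
#'
#' @param x a [geno_matrix] or [hap_panel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) UseMethod("write_vcf")

vcf_fixed_cols <- function(map) {
  paste(map$chromosome, map$position, map$snp_id, map$allele_ref,
        map$allele_alt, ".", ".", ".", "GT", sep = "\t")
}

vcf_header <- function(sample_ids) {
  c("##fileformat=VCFv4.2",
    "##source=embryogs",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

#' @export
write_vcf.geno_matrix <- function(x, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  g <- t(x$calls)                                   # SNPs x samples
  gt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gt[ok] <- gt_code[g[ok] + 1L]
  body <- paste(vcf_fixed_cols(x$map),
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(rownames(x$calls)), body), path)
  invisible(path)
}

#' @export
write_vcf.hap_panel <- function(x, path) {
  h <- x$haps
  odd <- seq(1L, nrow(h), by = 2L)
  a <- t(h[odd, , drop = FALSE])                    # SNPs x individuals
  b <- t(h[odd + 1L, , drop = FALSE])
  gt <- matrix(paste(a, b, sep = "|"), nrow(a), ncol(a))
  body <- paste(vcf_fixed_cols(x$map),
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(x$individuals), body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix or phased haplotype panel
#'
#' Only biallelic records are accepted; multi-allelic records are skipped
#' with a warning carrying the skip count (also attached as attribute
#' `n_multiallelic`). With `as = "auto"` the file is returned as a phased
#' [hap_panel] when every genotype is `|`-separated and non-missing, and as
#' an unphased [geno_matrix] otherwise; `as = "panel"` enforces the phased
#' contract and fails on any `/` separator or missing allele.
#'
#' @param path VCF file path.
#' @param as one of `"auto"`, `"genotypes"`, `"panel"`.
#' @return A [geno_matrix] or [hap_panel].
#' @export
read_vcf <- function(path, as = c("auto", "genotypes", "panel")) {
  as <- match.arg(as)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  if (anyDuplicated(colnames(v@gt)[-1])) stop("duplicated sample ids in ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) |
    nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  n_multi <- sum(multi)
  if (n_multi > 0L) {
    warning("skipped ", n_multi, " non-biallelic record(s) in ", path)
  }
  if (all(multi)) stop("no biallelic records left in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")        # SNPs x samples
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  map <- marker_map(fix$ID, fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)

  phased <- !grepl("/", gt, fixed = TRUE) & !is.na(gt) &
    !grepl("\\.", gt)
  all_phased <- all(phased)
  if (as == "panel" && !all_phased) {
    stop("file is not a fully phased panel (unphased or missing genotypes found)")
  }
  want_panel <- as == "panel" || (as == "auto" && all_phased)

  a1 <- substr(gt, 1L, 1L)
  a3 <- substr(gt, 3L, 3L)
  if (want_panel) {
    h1 <- matrix(as.integer(a1), nrow(gt), ncol(gt))
    h2 <- matrix(as.integer(a3), nrow(gt), ncol(gt))
    n_ind <- ncol(gt)
    haps <- matrix(0L, 2L * n_ind, nrow(gt))
    haps[seq(1L, 2L * n_ind, by = 2L), ] <- t(h1)
    haps[seq(2L, 2L * n_ind, by = 2L), ] <- t(h2)
    out <- hap_panel(haps, map, individuals = colnames(gt))
  } else {
    d1 <- suppressWarnings(as.integer(a1))
    d2 <- suppressWarnings(as.integer(a3))
    calls <- t(matrix(d1 + d2, nrow(gt), ncol(gt)))
    rownames(calls) <- colnames(gt)
    out <- geno_matrix(calls, map)
  }
  attr(out, "n_multiallelic") <- n_multi
  out
}
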