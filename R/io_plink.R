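#' Write a genotype matrix as PLINK text .ped/.map
#'
#' One line per sample in the .ped (family id = individual id, unknown
#' parents/sex, phenotype -9) with two allele letters per SNP; missing calls
#' become `0 0`. The .map carries chromosome, SNP id, a zero genetic
#' position, and the physical position.
#'
#' @param gm a [geno_matrix].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_plink_text <- function(gm, prefix) {
  map <- gm$map
  n_snp <- nrow(map)
  calls <- gm$calls
  a1 <- matrix("0", nrow(calls), n_snp)
  a2 <- a1
  ref <- matrix(map$allele_ref, nrow(calls), n_snp, byrow = TRUE)
  alt <- matrix(map$allele_alt, nrow(calls), n_snp, byrow = TRUE)
  ok <- !is.na(calls)
  a1[ok] <- ifelse(calls[ok] >= 1L, alt[ok], ref[ok])
  a2[ok] <- ifelse(calls[ok] == 2L, alt[ok], ref[ok])
  inter <- matrix("", nrow(calls), 2L * n_snp)
  inter[, seq(1L, 2L * n_snp, by = 2L)] <- a1
  inter[, seq(2L, 2L * n_snp, by = 2L)] <- a2
  ids <- rownames(calls)
  ped <- paste(ids, ids, 0L, 0L, 0L, -9L,
               apply(inter, 1L, paste, collapse = " "))
  writeLines(ped, paste0(prefix, ".ped"))
  map_lines <- paste(map$chromosome, map$snp_id, 0L, map$position, sep = "\t")
  writeLines(map_lines, paste0(prefix, ".map"))
  invisible(prefix)
}

#' Read PLINK text .ped/.map into a genotype matrix
#'
#' Allele letters are mapped to alt-allele dosages against REF/ALT. The .map
#' format does not carry alleles, so either pass the original [marker_map]
#' (`alleles`) or let the reader infer per-SNP alleles from the data (the
#' minor observed allele becomes ALT; ties broken alphabetically). `0 0`
#' becomes missing; allele order within a genotype is immaterial. A letter
#' matching neither REF nor ALT at its SNP is an error.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param alleles optional [marker_map] supplying REF/ALT per SNP (matched by
#'   SNP id).
#' @return A [geno_matrix].
#' @export
read_plink_text <- function(ped_path, map_path, alleles = NULL) {
  mp <- read.table(map_path, header = FALSE, colClasses = "character",
                   col.names = c("chromosome", "snp_id", "cm", "position"))
  n_snp <- nrow(mp)
  ped <- read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped) != 6L + 2L * n_snp) {
    stop(".ped and .map disagree on SNP count")
  }
  ids <- ped[[2L]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_snp, by = 2L), drop = FALSE]
  if (any(xor(a1 == "0", a2 == "0"))) {
    stop("half-missing genotype (single '0' allele) in .ped")
  }
  if (!is.null(alleles)) {
    idx <- match(mp$snp_id, alleles$snp_id)
    if (anyNA(idx)) stop("SNP ids in .map not found in supplied marker map")
    ref <- alleles$allele_ref[idx]
    alt <- alleles$allele_alt[idx]
  } else {
    ref <- alt <- character(n_snp)
    for (j in seq_len(n_snp)) {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[obs != "0"]
      lev <- sort(unique(obs))
      if (length(lev) > 2L) stop("more than two alleles at SNP ", mp$snp_id[j])
      if (length(lev) == 0L) lev <- c("A", "B")
      if (length(lev) == 1L) lev <- c(lev, if (lev == "A") "B" else "A")
      cnt <- c(sum(obs == lev[1]), sum(obs == lev[2]))
      # minor allele is ALT; alphabetical tie-break keeps it deterministic
      if (cnt[2] < cnt[1] || (cnt[1] == cnt[2])) {
        ref[j] <- lev[1]; alt[j] <- lev[2]
      } else {
        ref[j] <- lev[2]; alt[j] <- lev[1]
      }
    }
  }
  refm <- matrix(ref, nrow(al), n_snp, byrow = TRUE)
  altm <- matrix(alt, nrow(al), n_snp, byrow = TRUE)
  score <- function(a) {
    out <- matrix(NA_integer_, nrow(al), n_snp)
    out[a == refm] <- 0L
    out[a == altm] <- 1L
    bad <- a != "0" & is.na(out)
    if (any(bad)) {
      k <- which(bad, arr.ind = TRUE)[1L, ]
      stop("allele '", a[bad][1L], "' at SNP ", mp$snp_id[k[2L]],
           " matches neither REF nor ALT")
    }
    out
  }
  calls <- score(a1) + score(a2)
  rownames(calls) <- ids
  map <- marker_map(mp$snp_id, mp$chromosome, as.integer(mp$position), ref, alt)
  geno_matrix(calls, map)
}
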