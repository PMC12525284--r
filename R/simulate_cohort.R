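#' Simulate founder haplotypes
#'
#' Draws `2 * n_founders` binary haplotypes over a marker map. Each site
#' gets an alt-allele frequency drawn uniformly on `[maf_low, maf_high]`,
#' and alleles are sampled independently across sites and haplotypes.
#' Founder linkage disequilibrium is deliberately absent: the haplotype
#' sharing that imputation exploits arises downstream from pedigree
#' co-inheritance, not from founder LD.
#'
#' @param n_founders number of founder individuals.
#' @param map a [marker_map].
#' @param maf_low,maf_high bounds of the per-site frequency distribution,
#'   `0 <= maf_low <= maf_high <= 0.5` (`maf_low = maf_high` pins every
#'   site to one frequency).
#' @param seed integer seed; the draw is deterministic given it.
#' @return A [hap_panel]; the drawn per-site frequencies are attached as
#'   attribute `site_freq`.
#' @export
simulate_founder_haplotypes <- function(n_founders, map, maf_low = 0.05,
                                        maf_high = 0.5, seed = 1L) {
  validate_marker_map(map)
  if (!(maf_low >= 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 <= maf_low <= maf_high <= 0.5")
  }
  stopifnot(n_founders >= 1)
  s <- nrow(map)
  h <- 2L * n_founders
  set.seed(seed)
  freq <- runif(s, maf_low, maf_high)
  haps <- matrix(rbinom(h * s, 1L, rep(freq, each = h)), nrow = h)
  out <- hap_panel(haps, map, individuals = sprintf("ref%04d", seq_len(n_founders)))
  attr(out, "site_freq") <- freq
  out
}

#' Drop offspring through a pedigree with recombination
#'
#' Each offspring receives one recombinant gamete from a randomly chosen
#' sire (male founder) and one from a dam (female founder). A gamete is
#' built per chromosome as a Markov walk over the parent's two haplotypes:
#' a fair start, then a switch between the parental haplotypes with
#' probability `switch_prob` at each adjacent marker. Founders are assigned
#' alternating sexes; at least one of each is required.
#'
#' Each offspring is a prospective embryo/lamb pair: the embryo and the lamb
#' born from it share this one true genotype and differ only in how it is
#' later observed (biopsy/WGA channel versus blood channel).
#'
#' @param founders founder [hap_panel].
#' @param n_offspring number of offspring to generate.
#' @param switch_prob per-adjacent-marker haplotype switch probability in
#'   `[0, 0.5]`.
#' @param seed integer seed.
#' @param ids optional offspring ids (default `pair01`, `pair02`, ...).
#' @return List with `panel` (offspring [hap_panel], haplotype 1 paternal,
#'   haplotype 2 maternal) and `pedigree` (data.frame `id`, `sire`, `dam`,
#'   `generation`; founders have `NA` parents).
#' @export
drop_pedigree <- function(founders, n_offspring, switch_prob = 0.001,
                          seed = 1L, ids = NULL) {
  stopifnot(n_offspring >= 1)
  if (switch_prob < 0 || switch_prob > 0.5) stop("switch_prob must be in [0, 0.5]")
  f_ids <- founders$individuals
  n_f <- length(f_ids)
  sex <- rep_len(c("M", "F"), n_f)
  males <- which(sex == "M")
  females <- which(sex == "F")
  if (length(males) < 1L || length(females) < 1L) {
    stop("need at least one male and one female founder")
  }
  if (is.null(ids)) ids <- sprintf("pair%02d", seq_len(n_offspring))
  map <- founders$map
  chr_idx <- split(seq_len(nrow(map)), map$chromosome)
  # preserve map order of chromosomes
  chr_idx <- chr_idx[unique(map$chromosome)]
  set.seed(seed)
  gamete <- function(parent_row1, parent_row2) {
    g <- integer(nrow(map))
    for (idx in chr_idx) {
      k <- length(idx)
      start <- rbinom(1L, 1L, 0.5)
      if (k > 1L) {
        switches <- rbinom(k - 1L, 1L, switch_prob)
        state <- (start + cumsum(c(0L, switches))) %% 2L
      } else {
        state <- start
      }
      g[idx] <- ifelse(state == 0L, parent_row1[idx], parent_row2[idx])
    }
    g
  }
  haps <- matrix(0L, 2L * n_offspring, nrow(map))
  sires <- character(n_offspring)
  dams <- character(n_offspring)
  for (o in seq_len(n_offspring)) {
    si <- males[sample.int(length(males), 1L)]
    di <- females[sample.int(length(females), 1L)]
    sires[o] <- f_ids[si]
    dams[o] <- f_ids[di]
    haps[2L * o - 1L, ] <- gamete(founders$haps[2L * si - 1L, ],
                                  founders$haps[2L * si, ])
    haps[2L * o, ] <- gamete(founders$haps[2L * di - 1L, ],
                             founders$haps[2L * di, ])
  }
  panel <- hap_panel(haps, map, individuals = ids)
  pedigree <- rbind(
    data.frame(id = f_ids, sire = NA_character_, dam = NA_character_,
               generation = 0L, stringsAsFactors = FALSE),
    data.frame(id = ids, sire = sires, dam = dams, generation = 1L,
               stringsAsFactors = FALSE)
  )
  list(panel = panel, pedigree = pedigree)
}

#' Trait model (variance components and genetic architecture)
#'
#' @param name trait label.
#' @param mu trait mean (the model's single fixed effect), trait units.
#' @param sigma2_a additive genetic variance.
#' @param sigma2_e residual variance.
#' @param n_qtl number of causal SNPs.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(name, mu = 0, sigma2_a = 0.3, sigma2_e = 0.7,
                        n_qtl = 300L) {
  stopifnot(sigma2_a >= 0, sigma2_e >= 0, n_qtl >= 1)
  structure(list(name = name, mu = mu, sigma2_a = sigma2_a,
                 sigma2_e = sigma2_e, n_qtl = as.integer(n_qtl)),
            class = "trait_model")
}

#' Heritability of a trait model
#' @param model a [trait_model].
#' @return `sigma2_a / (sigma2_a + sigma2_e)`.
#' @export
heritability <- function(model) {
  model$sigma2_a / (model$sigma2_a + model$sigma2_e)
}

#' Simulate a polygenic trait: y = mu + a + e
#'
#' `n_qtl` causal SNPs get standard-normal effects; breeding values are the
#' centered genotype score scaled so that the realized variance of `a`
#' across all individuals equals `sigma2_a` exactly. Phenotypes
#' `y = mu + a + e` with `e ~ N(0, sigma2_e)` are produced for the
#' designated reference cohort only; true breeding values are returned for
#' everyone.
#'
#' @param gm complete (no missing) truth [geno_matrix].
#' @param model a [trait_model].
#' @param phenotyped_ids ids receiving a phenotype record; default all.
#' @param seed integer seed.
#' @return List with `true_bv` (named vector over all individuals) and
#'   `phenotypes` (data.frame `id`, `value`).
#' @export
simulate_traits <- function(gm, model, phenotyped_ids = rownames(gm$calls),
                            seed = 1L) {
  calls <- gm$calls
  if (anyNA(calls)) stop("truth genotypes must be complete")
  if (model$n_qtl > ncol(calls)) stop("n_qtl exceeds SNP count")
  set.seed(seed)
  qtl <- sample.int(ncol(calls), model$n_qtl)
  beta <- rnorm(model$n_qtl)
  x <- calls[, qtl, drop = FALSE]
  x <- sweep(x, 2L, colMeans(x))
  a_raw <- drop(x %*% beta)
  if (model$sigma2_a == 0) {
    a <- rep(0, nrow(calls))
  } else {
    v <- var(a_raw)
    if (v <= 0) stop("causal SNPs carry no variance; cannot scale to sigma2_a")
    a <- a_raw * sqrt(model$sigma2_a / v)
  }
  names(a) <- rownames(calls)
  stopifnot(all(phenotyped_ids %in% rownames(calls)))
  e <- rnorm(length(phenotyped_ids), 0, sqrt(model$sigma2_e))
  phen <- data.frame(id = phenotyped_ids,
                     value = model$mu + a[phenotyped_ids] + e,
                     stringsAsFactors = FALSE)
  rownames(phen) <- NULL
  list(true_bv = a, phenotypes = phen)
}
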