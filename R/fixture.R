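# Cohort assembly shared by run_pipeline() and emit_fixture().

# Lamb "blood" genotyping channel: essentially clean observation of the
# true genotype with a small uniform missing rate and residual call error.
observe_blood <- function(truth, eps, miss_rate, seed) {
  g <- truth$calls
  set.seed(seed)
  n <- length(g)
  obs <- g
  if (miss_rate > 0) obs[rbinom(n, 1L, miss_rate) == 1L] <- NA_integer_
  if (eps > 0) {
    called <- which(!is.na(obs))
    flip <- called[rbinom(length(called), 1L, eps) == 1L]
    if (length(flip)) {
      obs[flip] <- (obs[flip] + sample(c(1L, 2L), length(flip), replace = TRUE)) %% 3L
    }
  }
  geno_matrix(obs, truth$map)
}

#' Simulate the full study cohort
#'
#' Builds everything the pipeline consumes, with known ground truth:
#' founder reference cohort, embryo/lamb pair offspring (one true genotype
#' per pair, observed through two channels), polygenic traits with
#' phenotypes on the reference cohort, biopsy genotypes per cell-number
#' arm, the lamb blood genotypes, and the phased reference panel (true
#' haplotypes of the cohort plus the offspring, mirroring a self-cohort
#' sequencing panel).
#'
#' @param cfg an [egs_config].
#' @return List with elements `map`, `founders`, `pedigree`, `truth_ref`,
#'   `truth_pairs`, `truth_all`, `panel`, `phenotypes` (wide data.frame),
#'   `true_bv` (individuals x traits matrix), `biopsy` (named list of
#'   [geno_matrix] per arm, embryo ids), `lambs` ([geno_matrix], lamb ids),
#'   `pairs` (data.frame `pair`, `embryo`, `lamb`).
#' @export
simulate_cohort_data <- function(cfg = egs_config()) {
  stopifnot(inherits(cfg, "egs_config"))
  map <- make_marker_map(cfg$n_snps, cfg$n_chr)
  founders <- simulate_founder_haplotypes(cfg$n_ref, map, cfg$maf_low,
                                          cfg$maf_high,
                                          seed = stage_seed(cfg$seed, 1L))
  drop <- drop_pedigree(founders, cfg$n_pairs, cfg$switch_prob,
                        seed = stage_seed(cfg$seed, 2L))
  truth_ref <- panel_to_genotypes(founders)
  truth_pairs <- panel_to_genotypes(drop$panel)
  truth_all <- geno_matrix(rbind(truth_ref$calls, truth_pairs$calls), map)

  true_bv <- matrix(NA_real_, nrow(truth_all$calls), length(cfg$traits),
                    dimnames = list(rownames(truth_all$calls), names(cfg$traits)))
  phen <- data.frame(id = founders$individuals, stringsAsFactors = FALSE)
  for (k in seq_along(cfg$traits)) {
    tr <- simulate_traits(truth_all, cfg$traits[[k]],
                          phenotyped_ids = founders$individuals,
                          seed = stage_seed(cfg$seed, 10L + k))
    true_bv[, k] <- tr$true_bv
    phen[[cfg$traits[[k]]$name]] <- tr$phenotypes$value
  }

  pair_ids <- drop$panel$individuals
  pairs <- data.frame(pair = pair_ids,
                      embryo = sub("^pair", "embryo", pair_ids),
                      lamb = sub("^pair", "lamb", pair_ids),
                      stringsAsFactors = FALSE)

  biopsy <- list()
  for (j in seq_along(cfg$arms)) {
    arm <- cfg$arms[j]
    noise <- wga_noise_model(arm, cfg$q_capture_fail, cfg$eps_error)
    obs <- apply_wga_noise(truth_pairs, noise,
                           seed = stage_seed(cfg$seed, 30L + j))
    rownames(obs$calls) <- pairs$embryo
    biopsy[[sprintf("cells%02d", arm)]] <- obs
  }
  lambs <- observe_blood(truth_pairs, cfg$lamb_eps, cfg$lamb_missing,
                         seed = stage_seed(cfg$seed, 50L))
  rownames(lambs$calls) <- pairs$lamb

  panel <- hap_panel(rbind(founders$haps, drop$panel$haps), map,
                     individuals = c(founders$individuals, pair_ids))

  list(map = map, founders = founders, pedigree = drop$pedigree,
       truth_ref = truth_ref, truth_pairs = truth_pairs,
       truth_all = truth_all, panel = panel, phenotypes = phen,
       true_bv = true_bv, biopsy = biopsy, lambs = lambs, pairs = pairs)
}

#' Write the simulated cohort to disk as a fixture file set
#'
#' Emits a truth VCF, one biopsy VCF per cell-number arm, the lamb blood
#' VCF, the phased reference-panel VCF, phenotype and pedigree TSVs, and a
#' YAML manifest carrying the scalar configuration and an md5 checksum per
#' file. Output is byte-identical across runs at a fixed seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param config an [egs_config]; its `seed` is overridden by `seed`.
#' @return Invisibly, the manifest as a list.
#' @export
emit_fixture <- function(out_dir, seed = 1L, config = egs_config()) {
  config$seed <- seed
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  sim <- simulate_cohort_data(config)
  files <- character(0)
  wf <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, stats::setNames(path, name))
    path
  }
  wf("truth.vcf", function(p) write_vcf(sim$truth_all, p))
  for (nm in names(sim$biopsy)) {
    local({
      gm <- sim$biopsy[[nm]]
      wf(paste0("biopsy_", nm, ".vcf"), function(p) write_vcf(gm, p))
    })
  }
  wf("lambs.vcf", function(p) write_vcf(sim$lambs, p))
  wf("panel.vcf", function(p) write_vcf(sim$panel, p))
  wf("phenotypes.tsv", function(p) {
    write.table(sim$phenotypes, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  wf("pedigree.tsv", function(p) {
    write.table(sim$pedigree, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  checks <- tools::md5sum(unname(files))
  names(checks) <- names(files)
  manifest <- list(
    seed = as.integer(seed),
    n_snps = config$n_snps, n_chr = config$n_chr,
    n_ref = config$n_ref, n_pairs = config$n_pairs,
    arms = as.integer(config$arms),
    q_capture_fail = config$q_capture_fail,
    eps_error = config$eps_error,
    pair_id_convention = "embryoNN <-> lambNN share truth pairNN",
    md5 = as.list(checks)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
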