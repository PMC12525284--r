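test_that("founder haplotype simulation honours shape, frequency bounds and determinism", {
  map3 <- make_marker_map(3, 1)
  p <- simulate_founder_haplotypes(2, map3, 0.5, 0.5, seed = 1)
  expect_equal(dim(p$haps), c(4L, 3L))
  expect_true(all(p$haps %in% 0:1))

  p0 <- simulate_founder_haplotypes(5, map3, 0, 0, seed = 1)
  expect_true(all(p0$haps == 0L))

  p1 <- simulate_founder_haplotypes(10, map3, 0.1, 0.4, seed = 42)
  p2 <- simulate_founder_haplotypes(10, map3, 0.1, 0.4, seed = 42)
  expect_identical(p1$haps, p2$haps)

  expect_error(simulate_founder_haplotypes(2, map3, 0.4, 0.1), "maf")
  expect_error(simulate_founder_haplotypes(2, map3, 0.05, 0.7), "maf")
})

test_that("realized founder allele frequencies track their drawn site frequencies", {
  map <- make_marker_map(1000, 2)
  p <- simulate_founder_haplotypes(200, map, 0.05, 0.5, seed = 9)
  freq_drawn <- attr(p, "site_freq")
  counts <- colSums(p$haps)
  n <- nrow(p$haps)
  lo <- qbinom(0.005, n, freq_drawn)
  hi <- qbinom(0.995, n, freq_drawn)
  inside <- mean(counts >= lo & counts <= hi)
  expect_gte(inside, 0.95)
})

test_that("pedigree drop is Mendelian-consistent and recombination-free gametes copy a parental haplotype", {
  map <- make_marker_map(400, 2)
  founders <- simulate_founder_haplotypes(20, map, 0.1, 0.5, seed = 3)
  drop <- drop_pedigree(founders, 10, switch_prob = 0, seed = 5)
  ped <- drop$pedigree[drop$pedigree$generation == 1L, ]
  chrs <- split(seq_len(nrow(map)), map$chromosome)
  for (i in seq_len(nrow(ped))) {
    pat <- drop$panel$haps[2L * i - 1L, ]
    mat <- drop$panel$haps[2L * i, ]
    si <- match(ped$sire[i], founders$individuals)
    di <- match(ped$dam[i], founders$individuals)
    # zero switch probability: each chromosome of a gamete copies one
    # parental haplotype exactly (chromosomes segregate independently)
    for (idx in chrs) {
      expect_true(identical(pat[idx], founders$haps[2L * si - 1L, idx]) ||
                    identical(pat[idx], founders$haps[2L * si, idx]))
      expect_true(identical(mat[idx], founders$haps[2L * di - 1L, idx]) ||
                    identical(mat[idx], founders$haps[2L * di, idx]))
    }
  }

  # with recombination: offspring genotypes stay in the Mendelian set
  drop2 <- drop_pedigree(founders, 10, switch_prob = 0.02, seed = 6)
  kid_g <- panel_to_genotypes(drop2$panel)$calls
  f_g <- panel_to_genotypes(founders)$calls
  ped2 <- drop2$pedigree[drop2$pedigree$generation == 1L, ]
  for (i in seq_len(nrow(ped2))) {
    gs <- f_g[ped2$sire[i], ]
    gd <- f_g[ped2$dam[i], ]
    # allele from sire must be producible by the sire, likewise dam
    pat <- drop2$panel$haps[2L * i - 1L, ]
    mat <- drop2$panel$haps[2L * i, ]
    expect_true(all(ifelse(pat == 1L, gs >= 1L, gs <= 1L)))
    expect_true(all(ifelse(mat == 1L, gd >= 1L, gd <= 1L)))
  }

  expect_error(drop_pedigree(founders, 2, switch_prob = 0.9), "switch_prob")
})

test_that("transmitted gametes sample both parental haplotypes evenly", {
  map <- make_marker_map(5000, 5)
  founders <- simulate_founder_haplotypes(30, map, 0.05, 0.5, seed = 11)
  drop <- drop_pedigree(founders, 40, switch_prob = 0.01, seed = 12)
  ped <- drop$pedigree[drop$pedigree$generation == 1L, ]
  share <- numeric(0)
  for (i in seq_len(nrow(ped))) {
    si <- match(ped$sire[i], founders$individuals)
    pat <- drop$panel$haps[2L * i - 1L, ]
    h1 <- founders$haps[2L * si - 1L, ]
    h2 <- founders$haps[2L * si, ]
    informative <- h1 != h2
    share <- c(share, mean(pat[informative] == h1[informative]))
  }
  expect_lt(abs(mean(share) - 0.5), 0.05)
})

test_that("trait simulation obeys its noise-free limits and variance scaling", {
  map <- make_marker_map(300, 1)
  founders <- simulate_founder_haplotypes(100, map, 0.1, 0.5, seed = 2)
  gm <- panel_to_genotypes(founders)

  m0 <- trait_model("t", mu = 10, sigma2_a = 1, sigma2_e = 0, n_qtl = 50)
  tr <- simulate_traits(gm, m0, seed = 4)
  expect_equal(tr$phenotypes$value - 10,
               unname(tr$true_bv[tr$phenotypes$id]), tolerance = 1e-12)

  ma <- trait_model("t", mu = 0, sigma2_a = 0, sigma2_e = 1, n_qtl = 50)
  tra <- simulate_traits(gm, ma, seed = 4)
  expect_true(all(tra$true_bv == 0))

  big <- simulate_founder_haplotypes(500, make_marker_map(1000, 1), 0.1, 0.5, seed = 7)
  mb <- trait_model("t", mu = 0, sigma2_a = 2.5, sigma2_e = 1, n_qtl = 500)
  trb <- simulate_traits(panel_to_genotypes(big), mb, seed = 8)
  expect_lt(abs(var(trb$true_bv) / 2.5 - 1), 0.15)

  expect_error(simulate_traits(gm, trait_model("t", n_qtl = 10000)), "n_qtl")
})

test_that("WGA noise matches its closed forms and is pure allelic dropout at eps = 0", {
  map <- make_marker_map(20000, 1)
  het <- geno_matrix(matrix(1L, 1, 20000), map, "x")

  # q = 0: noiseless channel
  clean <- apply_wga_noise(het, wga_noise_model(5, 0, 0), seed = 1)
  expect_identical(clean$calls, het$calls)

  # q = 0.5, 1 cell, het site: P(missing) = 1/4, P(hom | called) = 2/3
  obs <- apply_wga_noise(het, wga_noise_model(1, 0.5, 0), seed = 2)
  expect_lt(abs(mean(is.na(obs$calls)) - 0.25), 0.02)
  called <- obs$calls[!is.na(obs$calls)]
  expect_lt(abs(mean(called != 1L) - 2 / 3), 0.02)
  # eps = 0: every wrong call is a homozygote at a true het
  expect_true(all(called %in% c(0L, 1L, 2L)))
  wrong <- called[called != 1L]
  expect_true(all(wrong %in% c(0L, 2L)))

  # q = 0.5, 30 cells: expected call rate above 0.999
  expect_gt(expected_call_rate(wga_noise_model(30, 0.5, 0)), 0.999)
  obs30 <- apply_wga_noise(het, wga_noise_model(30, 0.5, 0), seed = 3)
  expect_gt(mean(!is.na(obs30$calls)), 0.999)
})

test_that("dropout errors at eps = 0 are strictly het-to-hom on mixed genotypes", {
  gm <- rand_gm(30, 400, miss_rate = 0, seed = 13)
  obs <- apply_wga_noise(gm, wga_noise_model(2, 0.5, 0), seed = 14)
  disagree <- !is.na(obs$calls) & obs$calls != gm$calls
  expect_true(all(gm$calls[disagree] == 1L))
  expect_true(all(obs$calls[disagree] %in% c(0L, 2L)))
})

test_that("call rate rises and mismatch falls with biopsy cell number", {
  gm <- rand_gm(20, 800, miss_rate = 0, seed = 21)
  for (seed in 1:3) {
    cr <- mm <- numeric(0)
    for (cells in c(1, 5, 10, 20, 30)) {
      obs <- apply_wga_noise(gm, wga_noise_model(cells, 0.72, 0.003),
                             seed = seed)
      called <- !is.na(obs$calls)
      cr <- c(cr, mean(called))
      mm <- c(mm, mean(obs$calls[called] != gm$calls[called]))
    }
    expect_true(all(diff(cr) >= -1e-12))
    expect_true(all(diff(mm) <= 1e-3))
  }
})

test_that("stochastic generators are bit-reproducible given seed and parameters", {
  gm <- rand_gm(10, 200, miss_rate = 0, seed = 31)
  a <- apply_wga_noise(gm, wga_noise_model(3, 0.6, 0.01), seed = 99)
  b <- apply_wga_noise(gm, wga_noise_model(3, 0.6, 0.01), seed = 99)
  expect_identical(a$calls, b$calls)
  f1 <- simulate_founder_haplotypes(5, make_marker_map(50, 1), seed = 7)
  f2 <- simulate_founder_haplotypes(5, make_marker_map(50, 1), seed = 7)
  expect_identical(f1$haps, f2$haps)
})

test_that("fixture emission is deterministic and round-trips through the readers", {
  cfg <- egs_config(seed = 2, n_snps = 200, n_chr = 2, n_ref = 16,
                    n_pairs = 4, arms = c(1L, 5L, 30L), gblup_cells = 5L,
                    traits = default_traits(n_qtl = 50L))
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  m1 <- emit_fixture(d1, seed = 2, config = cfg)
  m2 <- emit_fixture(d2, seed = 2, config = cfg)
  expect_identical(unname(unlist(m1$md5)), unname(unlist(m2$md5)))

  truth <- read_vcf(file.path(d1, "truth.vcf"))
  expect_s3_class(truth, "geno_matrix")
  expect_equal(dim(truth$calls), c(20L, 200L))
  panel <- read_vcf(file.path(d1, "panel.vcf"), as = "panel")
  expect_s3_class(panel, "hap_panel")
  expect_equal(nrow(panel$haps), 40L)
  phen <- read.table(file.path(d1, "phenotypes.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(phen), 16L)
  expect_equal(ncol(phen), 9L)  # id + eight traits

  # biopsy arms: mean call rate monotone non-decreasing in cell number
  crs <- sapply(c("01", "05", "30"), function(a) {
    gm <- read_vcf(file.path(d1, sprintf("biopsy_cells%s.vcf", a)))
    mean(!is.na(gm$calls))
  })
  expect_true(all(diff(crs) >= -1e-12))
})
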