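test_that("VanRaden G matches hand arithmetic and exact centering", {
  gm <- geno_matrix(matrix(c(0L, 2L, 2L, 0L), 2, 2, byrow = TRUE),
                    make_marker_map(2, 1), c("a", "b"))
  fr <- data.frame(snp_id = gm$map$snp_id, p_alt = c(0.5, 0.5),
                   n_called = c(2L, 2L))
  g <- build_G(gm, fr)
  expect_equal(unname(g$G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  expect_equal(g$denominator, 1)

  # an individual sitting exactly at 2p everywhere has a zero row
  gm2 <- geno_matrix(rbind(c(1L, 1L, 1L), c(0L, 2L, 0L)),
                     make_marker_map(3, 1), c("centered", "other"))
  fr2 <- data.frame(snp_id = gm2$map$snp_id, p_alt = rep(0.5, 3),
                    n_called = rep(2L, 3))
  g2 <- build_G(gm2, fr2)
  expect_equal(unname(g2$G["centered", ]), c(0, 0), tolerance = 1e-12)
})

test_that("G is invariant to swapping the REF/ALT labels at any SNP", {
  gm <- rand_gm(15, 120, miss_rate = 0, seed = 26)
  fr <- allele_frequencies(gm)
  g1 <- build_G(gm, fr)$G
  # swap labels at a third of the SNPs: g -> 2 - g, p -> 1 - p
  swap <- seq(1, 120, by = 3)
  calls2 <- gm$calls
  calls2[, swap] <- 2L - calls2[, swap]
  fr2 <- fr
  fr2$p_alt[swap] <- 1 - fr2$p_alt[swap]
  g2 <- build_G(geno_matrix(calls2, gm$map), fr2)$G
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("G on unrelated individuals has unit diagonal and null off-diagonal on average", {
  founders <- simulate_founder_haplotypes(200, make_marker_map(2000, 2),
                                          0.05, 0.5, seed = 27)
  gm <- panel_to_genotypes(founders)
  g <- build_G(gm)$G
  expect_lt(abs(mean(diag(g)) - 1), 0.05)
  expect_lt(abs(mean(g[upper.tri(g)])), 0.02)
})

test_that("missing genotypes are centered to zero and monomorphic SNPs dropped", {
  calls <- rbind(c(0L, NA, 2L), c(2L, 1L, 2L))
  gm <- geno_matrix(calls, make_marker_map(3, 1), c("a", "b"))
  fr <- data.frame(snp_id = gm$map$snp_id, p_alt = c(0.5, 0.25, 1),
                   n_called = c(2L, 1L, 2L))
  g <- build_G(gm, fr)
  expect_equal(length(g$snps_used), 2L)  # the fixed SNP is excluded
  expect_equal(g$n_missing_set, 1L)
  expect_error(build_G(gm, transform(fr, p_alt = c(0, 1, 1))), "usable")
})

test_that("mixed-model solutions match the direct GLS oracle", {
  set.seed(28)
  for (rep_i in 1:10) {
    n <- sample(5:30, 1)
    l <- matrix(rnorm(n * n), n)
    g_mat <- tcrossprod(l) / n + diag(0.5, n)
    ids <- sprintf("i%02d", seq_len(n))
    dimnames(g_mat) <- list(ids, ids)
    grm <- structure(list(G = g_mat, ids = ids, denominator = 1,
                          snps_used = character(0), n_missing_set = 0L),
                     class = "grm")
    n_ph <- sample(3:n, 1)
    ph_ids <- sample(ids, n_ph)
    y <- rnorm(n_ph, 5)
    model <- trait_model("t", sigma2_a = runif(1, 0.2, 2),
                         sigma2_e = runif(1, 0.2, 2))
    fit <- fit_gblup(grm, data.frame(id = ph_ids, value = y), model)
    z <- matrix(0, n_ph, n)
    z[cbind(seq_len(n_ph), match(ph_ids, ids))] <- 1
    oracle <- gls_oracle(fit$G_used, y, z, model$sigma2_a, model$sigma2_e)
    expect_equal(fit$b_hat, oracle$b, tolerance = 1e-8)
    expect_equal(unname(fit$gebv), oracle$a, tolerance = 1e-8)
  }
})

test_that("identity-G balanced data reduces to the ridge closed form", {
  n <- 10
  ids <- sprintf("i%02d", 1:n)
  g_mat <- diag(n); dimnames(g_mat) <- list(ids, ids)
  grm <- structure(list(G = g_mat, ids = ids, denominator = 1,
                        snps_used = character(0), n_missing_set = 0L),
                   class = "grm")
  set.seed(29)
  y <- rnorm(n, 3)
  model <- trait_model("t", sigma2_a = 0.5, sigma2_e = 1)
  fit <- fit_gblup(grm, data.frame(id = ids, value = y), model)
  delta <- fit$regularization$delta
  lambda_eff <- fit$lambda / (1 + delta)
  expect_equal(fit$b_hat, mean(y), tolerance = 1e-10)
  expect_equal(unname(fit$gebv), (y - mean(y)) / (1 + lambda_eff),
               tolerance = 1e-10)
})

test_that("infinite shrinkage drives breeding values to zero and the mean to the average", {
  grm <- build_G(rand_gm(12, 300, 0, seed = 30))
  set.seed(31)
  y <- rnorm(12, 7)
  phen <- data.frame(id = grm$ids, value = y)
  model <- trait_model("t", sigma2_a = 1e-8, sigma2_e = 1)
  fit <- fit_gblup(grm, phen, model)
  expect_lt(max(abs(fit$gebv)), 1e-4)
  expect_equal(fit$b_hat, mean(y), tolerance = 1e-4)
})

test_that("reliability limits are exact and clamping is counted", {
  model <- trait_model("t", sigma2_a = 0.4, sigma2_e = 0.6)
  fake <- list(pev = c(a = 0, b = 0.4, c = 0.6))
  rel <- reliability(fake, model)
  expect_equal(as.vector(rel), c(1, 0, 0))
  expect_equal(attr(rel, "n_clamped"), 1L)
  expect_error(reliability(fake, trait_model("t", sigma2_a = 0)), "sigma2_a")
})

test_that("an individual unlinked to all phenotyped animals has near-zero reliability", {
  founders <- simulate_founder_haplotypes(80, make_marker_map(2000, 2),
                                          0.05, 0.5, seed = 32)
  gm <- panel_to_genotypes(founders)
  model <- trait_model("t", sigma2_a = 0.5, sigma2_e = 0.5, n_qtl = 200)
  tr <- simulate_traits(gm, model, seed = 33)
  grm <- build_G(gm)
  # phenotype everyone except the last (unrelated) individual
  phen <- tr$phenotypes[1:79, ]
  fit <- fit_gblup(grm, phen, model)
  expect_lt(fit$reliability[80], 0.05)
  # phenotyped individuals carry real information
  expect_gt(mean(fit$reliability[1:79]), 0.3)
})

test_that("embryo and lamb GEBVs coincide when both channels carry identical genotypes", {
  founders <- simulate_founder_haplotypes(60, make_marker_map(1000, 2),
                                          0.05, 0.5, seed = 34)
  drop <- drop_pedigree(founders, 8, 0.005, seed = 35)
  ref <- panel_to_genotypes(founders)
  off <- panel_to_genotypes(drop$panel)
  freqs <- allele_frequencies(ref)
  model <- trait_model("t", sigma2_a = 0.5, sigma2_e = 0.5, n_qtl = 100)
  all_g <- geno_matrix(rbind(ref$calls, off$calls), ref$map)
  tr <- simulate_traits(all_g, model, phenotyped_ids = founders$individuals,
                        seed = 36)
  phen <- tr$phenotypes

  embryo_calls <- off$calls
  rownames(embryo_calls) <- sub("pair", "embryo", rownames(off$calls))
  lamb_calls <- off$calls
  rownames(lamb_calls) <- sub("pair", "lamb", rownames(off$calls))
  grm_e <- build_G(geno_matrix(rbind(ref$calls, embryo_calls), ref$map), freqs)
  grm_l <- build_G(geno_matrix(rbind(ref$calls, lamb_calls), ref$map), freqs)
  fit_e <- fit_gblup(grm_e, phen, model)
  fit_l <- fit_gblup(grm_l, phen, model)
  pairs <- data.frame(embryo = rownames(embryo_calls),
                      lamb = rownames(lamb_calls))
  cmp <- compare_gebv(fit_e, fit_l, pairs)
  expect_equal(cmp$fit$slope, 1, tolerance = 1e-6)
  expect_equal(cmp$fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(max(abs(cmp$table$residual)), 1e-6)

  # degenerate regressor errors out
  fit_const <- fit_l
  fit_const$gebv[] <- 1
  expect_error(compare_gebv(fit_e, fit_const, pairs), "constant x")
  expect_error(compare_gebv(fit_e, fit_l,
                            data.frame(embryo = "nope", lamb = pairs$lamb[1])),
               "unresolvable")
})

test_that("GEBV accuracy on phenotyped animals is positive at moderate heritability", {
  founders <- simulate_founder_haplotypes(150, make_marker_map(1500, 2),
                                          0.05, 0.5, seed = 37)
  gm <- panel_to_genotypes(founders)
  model <- trait_model("t", sigma2_a = 0.5, sigma2_e = 0.5, n_qtl = 200)
  tr <- simulate_traits(gm, model, seed = 38)
  fit <- fit_gblup(build_G(gm), tr$phenotypes, model)
  expect_gt(cor(tr$true_bv, fit$gebv[names(tr$true_bv)]), 0.5)
})
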