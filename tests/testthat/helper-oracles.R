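# Independent oracles and small fixture builders used across the suite.

# Random genotype matrix with controllable missingness.
rand_gm <- function(n = 20, s = 50, miss_rate = 0.1, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * s, replace = TRUE), n, s)
  if (miss_rate > 0) calls[runif(n * s) < miss_rate] <- NA_integer_
  geno_matrix(calls, make_marker_map(s, 2),
              samples = sprintf("s%03d", seq_len(n)))
}

# Brute-force path enumeration for the diploid copying HMM: sums the joint
# probability of every hidden-state path explicitly (chunked over the
# first-site state), with no forward-backward recursion. Returns the 3 x S
# genotype posterior.
oracle_genotype_posterior <- function(haps, obs, r, e) {
  k <- nrow(haps); s <- ncol(haps); kk <- k * k
  t1 <- matrix(r / k, k, k) + diag(1 - r, k)
  tp <- matrix(0, kk, kk)
  for (a in seq_len(kk)) {
    ka <- (a - 1) %% k + 1; la <- (a - 1) %/% k + 1
    for (b in seq_len(kk)) {
      kb <- (b - 1) %% k + 1; lb <- (b - 1) %/% k + 1
      tp[a, b] <- t1[ka, kb] * t1[la, lb]
    }
  }
  emit <- rbind(
    c((1 - e)^2, e * (1 - e), e^2),
    c(2 * e * (1 - e), (1 - e)^2 + e^2, 2 * e * (1 - e)),
    c(e^2, e * (1 - e), (1 - e)^2)
  ) # rows: observed 0/1/2; cols: true genotype 0/1/2
  em <- matrix(1, kk, s)
  for (t in seq_len(s)) {
    if (!is.na(obs[t])) {
      for (a in seq_len(kk)) {
        ka <- (a - 1) %% k + 1; la <- (a - 1) %/% k + 1
        g <- haps[ka, t] + haps[la, t]
        em[a, t] <- emit[obs[t] + 1, g + 1]
      }
    }
  }
  post_state <- matrix(0, kk, s)
  n_rest <- kk^(s - 1)
  idx <- as.numeric(0:(n_rest - 1))
  rest <- matrix(0L, n_rest, max(s - 1, 0))
  for (t in seq_len(s - 1)) {
    rest[, t] <- as.integer((idx %/% kk^(t - 1)) %% kk) + 1L
  }
  for (a1 in seq_len(kk)) {
    w <- rep(em[a1, 1] / kk, n_rest)
    prev <- rep(a1, n_rest)
    for (t in seq_len(s - 1)) {
      cur <- rest[, t]
      w <- w * tp[cbind(prev, cur)] * em[cbind(cur, t + 1)]
      prev <- cur
    }
    post_state[a1, 1] <- post_state[a1, 1] + sum(w)
    for (t in seq_len(s - 1)) {
      acc <- rowsum(w, rest[, t])
      post_state[as.integer(rownames(acc)), t + 1] <-
        post_state[as.integer(rownames(acc)), t + 1] + acc[, 1]
    }
  }
  post_state <- sweep(post_state, 2, colSums(post_state), "/")
  post <- matrix(0, 3, s)
  for (t in seq_len(s)) {
    for (a in seq_len(kk)) {
      ka <- (a - 1) %% k + 1; la <- (a - 1) %/% k + 1
      g <- haps[ka, t] + haps[la, t]
      post[g + 1, t] <- post[g + 1, t] + post_state[a, t]
    }
  }
  post
}

# Direct generalized-least-squares oracle for the animal model
# y = 1 b + Z a + e: BLUE/BLUP through V = Z G Z' s2a + I s2e inversion.
gls_oracle <- function(g_used, y, z, sigma2_a, sigma2_e) {
  v <- z %*% g_used %*% t(z) * sigma2_a + diag(sigma2_e, length(y))
  vi <- solve(v)
  one <- rep(1, length(y))
  b <- drop(solve(t(one) %*% vi %*% one, t(one) %*% vi %*% y))
  a <- unname(drop(sigma2_a * g_used %*% t(z) %*% vi %*% (y - one * b)))
  list(b = unname(b), a = a)
}

# Hardy-Weinberg exact p-value by full enumeration with absolute
# probabilities (factorial formula including the normalizing constant).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - rare - hets) / 2) + hets * log(2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  probs <- exp(logp)
  stopifnot(abs(sum(probs) - 1) < 1e-8)  # the enumeration is exhaustive
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Independent single-pass recount of the sequential QC filters, written as
# plain loops over the raw matrix.
qc_recount_oracle <- function(calls, maf_min, hwe_min, mind_max, geno_max,
                              hwe_rows = seq_len(nrow(calls))) {
  removed <- c(mind = 0L, geno = 0L, maf = 0L, hwe = 0L)
  keep_r <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (mean(is.na(calls[i, ])) > mind_max) keep_r[i] <- FALSE
  }
  removed["mind"] <- sum(!keep_r)
  m <- calls[keep_r, , drop = FALSE]
  hwe_rows <- intersect(hwe_rows, which(keep_r))
  hwe_sub <- calls[hwe_rows, , drop = FALSE]
  keep_c <- rep(TRUE, ncol(m))
  for (j in seq_len(ncol(m))) {
    if (mean(is.na(m[, j])) > geno_max) keep_c[j] <- FALSE
  }
  removed["geno"] <- sum(!keep_c)
  for (j in which(keep_c)) {
    col <- m[, j]
    nc <- sum(!is.na(col))
    if (nc == 0) { if (maf_min > 0) { keep_c[j] <- FALSE; removed["maf"] <- removed["maf"] + 1L }; next }
    p <- sum(col, na.rm = TRUE) / (2 * nc)
    if (min(p, 1 - p) < maf_min) { keep_c[j] <- FALSE; removed["maf"] <- removed["maf"] + 1L }
  }
  for (j in which(keep_c)) {
    col <- hwe_sub[, j]
    cnt <- c(sum(col == 0, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
             sum(col == 2, na.rm = TRUE))
    pv <- if (sum(cnt) == 0) 1 else hwe_oracle(cnt[1], cnt[2], cnt[3])
    if (pv < hwe_min) { keep_c[j] <- FALSE; removed["hwe"] <- removed["hwe"] + 1L }
  }
  list(removed = removed, dims_out = c(sum(keep_r), sum(keep_c)))
}
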