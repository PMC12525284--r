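#' Whole-genome-amplification noise model for biopsy genotypes
#'
#' Observation model for a chip genotype derived from an `n_cells`
#' trophectoderm biopsy after WGA. Each of the two allele copies at a site
#' is captured independently by each cell with per-cell failure probability
#' `q_capture_fail`; a copy is observed iff at least one cell captures it
#' (miss probability `q_capture_fail^n_cells`). If neither copy is observed
#' the call is missing; if exactly one copy of a heterozygote is observed
#' the call collapses to the corresponding homozygote (allelic dropout).
#' Finally, any called genotype is replaced by a uniformly different call
#' with probability `eps_error` (residual chip/clustering error).
#'
#' @param n_cells biopsy cell count, integer >= 1.
#' @param q_capture_fail per-cell per-allele-copy capture failure
#'   probability in `[0, 1]`.
#' @param eps_error residual error probability per called genotype in
#'   `[0, 1]`.
#' @return An object of class `wga_noise_model`.
#' @export
wga_noise_model <- function(n_cells = 10L, q_capture_fail = 0.72,
                            eps_error = 0.003) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L) stop("n_cells must be an integer >= 1")
  if (q_capture_fail < 0 || q_capture_fail > 1) stop("q_capture_fail must be in [0, 1]")
  if (eps_error < 0 || eps_error > 1) stop("eps_error must be in [0, 1]")
  structure(list(n_cells = n_cells, q_capture_fail = q_capture_fail,
                 eps_error = eps_error), class = "wga_noise_model")
}

#' Corrupt truth genotypes through the WGA biopsy channel
#'
#' Applies the [wga_noise_model] observation process to a complete truth
#' genotype matrix. In the `eps_error = 0` limit every wrong call is an
#' allelic dropout, i.e. strictly a heterozygote called as a homozygote.
#'
#' @param truth complete [geno_matrix] of true genotypes.
#' @param noise a [wga_noise_model].
#' @param seed integer seed; output is deterministic given it.
#' @return A [geno_matrix] of observed biopsy calls (with `NA` for missing).
#' @export
apply_wga_noise <- function(truth, noise, seed = 1L) {
  stopifnot(inherits(noise, "wga_noise_model"))
  g <- truth$calls
  if (anyNA(g)) stop("truth genotypes must be complete")
  n <- length(g)
  m <- noise$q_capture_fail^noise$n_cells  # per-copy miss probability
  set.seed(seed)
  # copy 1 carries allele 0 of a het; copy 2 allele 1 (symmetric under iid miss)
  miss1 <- matrix(rbinom(n, 1L, m) == 1L, nrow(g))
  miss2 <- matrix(rbinom(n, 1L, m) == 1L, nrow(g))
  allele1 <- ifelse(g == 2L, 1L, 0L)
  allele2 <- ifelse(g >= 1L, 1L, 0L)
  obs <- matrix(NA_integer_, nrow(g), ncol(g))
  both <- !miss1 & !miss2
  only1 <- !miss1 & miss2
  only2 <- miss1 & !miss2
  obs[both] <- g[both]
  obs[only1] <- 2L * allele1[only1]
  obs[only2] <- 2L * allele2[only2]
  if (noise$eps_error > 0) {
    called <- which(!is.na(obs))
    flip <- called[rbinom(length(called), 1L, noise$eps_error) == 1L]
    if (length(flip)) {
      shift <- sample(c(1L, 2L), length(flip), replace = TRUE)
      obs[flip] <- (obs[flip] + shift) %% 3L
    }
  }
  rownames(obs) <- rownames(g)
  geno_matrix(obs, truth$map)
}

#' Expected call rate of the WGA channel
#'
#' Closed form under the per-copy capture model: a call is made unless both
#' copies are missed, so the expected call rate is
#' `1 - (q^n_cells)^2`, independent of the true genotype.
#'
#' @param noise a [wga_noise_model].
#' @return Expected per-site call probability.
#' @export
expected_call_rate <- function(noise) {
  1 - noise$q_capture_fail^(2L * noise$n_cells)
}
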