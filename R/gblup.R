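#' VanRaden genomic relationship matrix
#'
#' `G = M M' / sum(2 p_i (1 - p_i))` with `M` the genotype matrix centered
#' by `2 p_i` (method 1). SNPs with undefined or monomorphic frequency are
#' excluded; missing genotypes are set to `2 p_i` (zero after centering)
#' and counted. Frequencies default to those of `gm` itself, but in the
#' pipeline they come from the phenotyped reference cohort so embryo and
#' lamb matrices are centered identically. G is invariant to which allele
#' is labeled ALT at any SNP (centering symmetry), so using the alt-allele
#' frequency rather than the strict minor-allele frequency is immaterial.
#'
#' @param gm a [geno_matrix].
#' @param freqs optional [allele_frequencies] for centering (matched by SNP
#'   id); default computed from `gm`.
#' @return An object of class `grm`: `G` (named N x N matrix), `ids`,
#'   `denominator`, `snps_used`, `n_missing_set`.
#' @export
build_G <- function(gm, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(gm)
  idx <- match(gm$map$snp_id, freqs$snp_id)
  if (anyNA(idx)) stop("frequencies do not cover the marker map")
  p <- freqs$p_alt[idx]
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("no usable SNPs (all monomorphic or frequency-undefined)")
  p <- p[use]
  m <- gm$calls[, use, drop = FALSE]
  n_missing <- sum(is.na(m))
  m <- sweep(m, 2L, 2 * p)
  m[is.na(gm$calls[, use, drop = FALSE])] <- 0
  denom <- sum(2 * p * (1 - p))
  g <- tcrossprod(m) / denom
  structure(list(G = g, ids = rownames(gm$calls), denominator = denom,
                 snps_used = gm$map$snp_id[use], n_missing_set = n_missing),
            class = "grm")
}

# Regularize a relationship matrix for inversion: ridge delta on the
# diagonal, and if the system is still near-singular blend toward the
# identity with weight w. Returns the matrix actually used plus what was
# done, so downstream consumers (and oracle tests) see the effective prior.
regularize_G <- function(g, delta = 1e-6, blend_w = 0.01) {
  n <- nrow(g)
  greg <- g + diag(delta, n)
  blended <- FALSE
  ok <- tryCatch({ chol(greg); TRUE }, error = function(e) FALSE)
  if (!ok || rcond(greg) < 1e-12) {
    greg <- (1 - blend_w) * g + blend_w * diag(n) + diag(delta, n)
    blended <- TRUE
  }
  list(G = greg, delta = delta, blended = blended, blend_w = blend_w)
}

#' Fit GBLUP through the mixed-model equations
#'
#' Solves `y = 1 b + Z a + e` with `a ~ N(0, G sigma2_a)` and
#' `e ~ N(0, I sigma2_e)` for the fixed mean and the genomic breeding
#' values of every individual in `G` (phenotyped or not), via the
#' mixed-model equations with `lambda = sigma2_e / sigma2_a`:
#' the coefficient matrix is `[[1'1, 1'Z], [Z'1, Z'Z + lambda G^-1]]`.
#' Variance components are inputs, not estimated. `G` is ridge-regularized
#' (`+1e-6 I`) before inversion and blended toward the identity with weight
#' 0.01 if still ill-conditioned; the regularized matrix is kept on the fit
#' object. PEV per individual is the corresponding diagonal element of the
#' inverse coefficient matrix times `sigma2_e`.
#'
#' @param grm a [build_G] result (or any `grm`).
#' @param phenotypes data.frame with columns `id`, `value`; every id must
#'   be present in the relationship matrix.
#' @param model a [trait_model] supplying `sigma2_a > 0`, `sigma2_e > 0`.
#' @return An object of class `gblup_fit`: `b_hat`, `gebv` (named vector
#'   over all individuals), `pev`, `reliability`, `lambda`, `trait`,
#'   `G_used`, `regularization`.
#' @export
fit_gblup <- function(grm, phenotypes, model) {
  stopifnot(inherits(grm, "grm"), inherits(model, "trait_model"))
  if (model$sigma2_a <= 0 || model$sigma2_e <= 0) {
    stop("sigma2_a and sigma2_e must be positive")
  }
  ids <- grm$ids
  if (!all(phenotypes$id %in% ids)) stop("phenotyped id missing from G")
  n_ind <- length(ids)
  n_rec <- nrow(phenotypes)
  y <- phenotypes$value
  zi <- match(phenotypes$id, ids)
  z <- matrix(0, n_rec, n_ind)
  z[cbind(seq_len(n_rec), zi)] <- 1
  lambda <- model$sigma2_e / model$sigma2_a
  reg <- regularize_G(grm$G)
  ginv <- chol2inv(chol(reg$G))
  ztz <- crossprod(z)
  cmat <- rbind(
    cbind(n_rec, t(colSums(z))),
    cbind(colSums(z), ztz + lambda * ginv)
  )
  rhs <- c(sum(y), drop(crossprod(z, y)))
  cinv <- solve(cmat)
  sol <- unname(drop(cinv %*% rhs))
  gebv <- sol[-1]
  names(gebv) <- ids
  pev <- diag(cinv)[-1] * model$sigma2_e
  names(pev) <- ids
  fit <- structure(list(b_hat = sol[1], gebv = gebv, pev = pev,
                        lambda = lambda, trait = model$name, model = model,
                        ids = ids, G_used = reg$G,
                        regularization = reg[c("delta", "blended", "blend_w")]),
                   class = "gblup_fit")
  fit$reliability <- reliability(fit, model)
  fit
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit '%s': %d individuals, b_hat %.4f, lambda %.3f, mean reliability %.3f\n",
              x$trait, length(x$gebv), x$b_hat, x$lambda, mean(x$reliability)))
  invisible(x)
}

#' Reliability from prediction error variance
#'
#' `reliability = 1 - PEV / sigma2_a`, clamped to `[0, 1]`; the number of
#' clamped individuals is attached as attribute `n_clamped`.
#'
#' @param fit a [gblup_fit] (anything with a `pev` element).
#' @param model a [trait_model] with `sigma2_a > 0`.
#' @return Named numeric vector of reliabilities.
#' @export
reliability <- function(fit, model) {
  if (model$sigma2_a <= 0) stop("sigma2_a must be positive")
  raw <- 1 - fit$pev / model$sigma2_a
  clamped <- pmin(pmax(raw, 0), 1)
  attr(clamped, "n_clamped") <- sum(raw != clamped)
  clamped
}

#' Compare embryo and lamb GEBVs over matched pairs
#'
#' Ordinary least squares of embryo GEBVs (y) on lamb GEBVs (x) for one
#' trait, with the residual table used for the regression-residual
#' composite display.
#'
#' @param fit_embryo,fit_lamb [gblup_fit] objects for the same trait.
#' @param pairs data.frame with columns `embryo`, `lamb` giving the matched
#'   ids (embryo ids resolvable in `fit_embryo`, lamb ids in `fit_lamb`).
#' @return List with `fit` (a [linear_fit]) and `table` (per-pair GEBVs and
#'   residuals).
#' @export
compare_gebv <- function(fit_embryo, fit_lamb, pairs) {
  if (!identical(fit_embryo$trait, fit_lamb$trait)) {
    stop("fits are for different traits")
  }
  if (!all(pairs$embryo %in% names(fit_embryo$gebv)) ||
      !all(pairs$lamb %in% names(fit_lamb$gebv))) {
    stop("unresolvable pair member")
  }
  x <- unname(fit_embryo$gebv[pairs$embryo])
  y_lamb <- unname(fit_lamb$gebv[pairs$lamb])
  fit <- linear_fit(y_lamb, x)  # embryo on lamb
  tab <- data.frame(embryo = pairs$embryo, lamb = pairs$lamb,
                    gebv_lamb = y_lamb, gebv_embryo = x,
                    residual = fit$residuals, stringsAsFactors = FALSE)
  list(fit = fit, table = tab)
}
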