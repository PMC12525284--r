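#' Genotype concordance between two samples
#'
#' Computed over sites called in both samples. Any call inequality is one
#' mismatch (a het/hom disagreement gets no partial credit), so
#' `consistency_rate + mismatch_rate = 1` by construction. Sites missing in
#' either member are excluded from the denominator.
#'
#' @param ga,gb genotype vectors over the same marker map (values
#'   \{0, 1, 2, NA\}).
#' @param id_a,id_b labels for the two samples.
#' @return An object of class `concordance_pair`: counts, rates, and a
#'   per-SNP `match` track (`TRUE`/`FALSE` where both called, `NA`
#'   elsewhere).
#' @export
pair_concordance <- function(ga, gb, id_a = "a", id_b = "b") {
  if (length(ga) != length(gb)) stop("genotype vectors differ in length")
  if (length(ga) == 0L) stop("empty genotype vectors")
  joint <- !is.na(ga) & !is.na(gb)
  if (!any(joint)) stop("no jointly called sites: concordance undefined")
  match_track <- rep(NA, length(ga))
  match_track[joint] <- ga[joint] == gb[joint]
  n_both <- sum(joint)
  n_match <- sum(match_track[joint])
  structure(list(id_a = id_a, id_b = id_b,
                 n_both_called = n_both, n_match = n_match,
                 consistency_rate = n_match / n_both,
                 mismatch_rate = 1 - n_match / n_both,
                 match = match_track),
            class = "concordance_pair")
}

#' Per-SNP concordance across pairs
#'
#' @param pairs list of [pair_concordance] results over one shared marker
#'   map.
#' @param snp_ids optional SNP ids for the rows of the output.
#' @return `data.frame` with per SNP the number of informative pairs and the
#'   fraction of them matching (`NaN` where no pair is informative).
#' @export
per_snp_concordance <- function(pairs, snp_ids = NULL) {
  stopifnot(length(pairs) >= 1L)
  tracks <- vapply(pairs, function(p) p$match, pairs[[1]]$match)
  tracks <- matrix(tracks, ncol = length(pairs))
  n_informative <- rowSums(!is.na(tracks))
  n_match <- rowSums(tracks, na.rm = TRUE)
  data.frame(snp_id = if (is.null(snp_ids)) seq_len(nrow(tracks)) else snp_ids,
             n_informative = n_informative,
             frac_match = n_match / n_informative,
             stringsAsFactors = FALSE)
}

#' Ordinary least squares fit with intercept
#'
#' Thin wrapper around `stats::lm` returning the quantities the pipeline
#' reports: slope, intercept, R-squared and residuals in input order. A
#' constant response gives slope 0 and R-squared 0 (SST = 0 is treated as
#' a perfectly explained null model, reported as 0).
#'
#' @param x,y numeric vectors, equal length >= 3; `x` must vary.
#' @return An object of class `linear_fit`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (sd(x) == 0) stop("constant x: regression undefined")
  fit <- lm(y ~ x)
  res <- unname(stats::residuals(fit))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(res^2) / sst
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 residuals = res,
                 fitted = unname(stats::fitted(fit))),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: y = %.4f + %.4f x, R^2 = %.4f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, length(x$residuals)))
  invisible(x)
}
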