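## Significance tests for effect contrasts.

## Every effect in the decomposition is a linear contrast over genotypes
## (and, for interaction components, over genotype-by-environment cells).
## Tests are based on the unshrunken genotype / cell means with the plot
## residual variance of the joint ANOVA, so they are invariant to BLUP
## shrinkage: the t statistic equals that of the corresponding
## least-squares contrast.  Main-effect contrast c over genotype means has
## variance sum(c^2) * sigma2e / (H*K); the deviation-coded environment
## component of the same contrast has variance
## sum(c^2) * (H-1)/H * sigma2e / K.
.contrastStats <- function(fit, cvec) {
  H <- fit@nEnv; K <- fit@nBlocks
  empty <- list(
    se = NA_real_, p = NA_real_, stars = NA_character_,
    envSE = rep(NA_real_, H), envP = rep(NA_real_, H),
    envStars = rep(NA_character_, H))
  if (!is.finite(fit@sigma2e) || fit@dfe <= 0) return(empty)
  c0 <- stats::setNames(numeric(length(fit@gMean)), names(fit@gMean))
  bad <- setdiff(names(cvec), names(c0))
  if (length(bad)) stop("contrast names not in the fit: ", paste(bad, collapse = ", "))
  c0[names(cvec)] <- cvec
  ss <- sum(c0^2)
  se <- sqrt(ss * fit@sigma2e / (H * K))
  tval <- sum(c0 * fit@gMean) / se
  p <- 2 * stats::pt(-abs(tval), fit@dfe)
  dev <- fit@cellMean - rowMeans(fit@cellMean)
  envT <- drop(crossprod(c0, dev))
  envSE <- rep(sqrt(ss * (H - 1) / H * fit@sigma2e / K), H)
  envP <- 2 * stats::pt(-abs(envT / envSE), fit@dfe)
  if (se == 0) { p <- NA_real_; envP[] <- NA_real_ }
  list(se = se, p = p, stars = .starsForP(p),
       envSE = envSE, envP = envP, envStars = .starsForP(envP))
}

#' Degree of dominance
#'
#' The ratio d/a of the dominance to the additive effect of one locus, in
#' the substitution-line convention (heterozygote and homozygote deviations
#' from the recipient).  |d/a| > 1 is labelled super-dominant.
#'
#' @param a additive effect, days.
#' @param d dominance effect, days.
#' @return list with `ratio` and `category` (`"super-dominant"`,
#'   `"complete dominance"`, `"partial dominance"`, `"no dominance"`, or
#'   `"dominance only"` when `a` is 0 and the ratio undefined).
#' @examples
#' dominanceDegree(a = 4, d = 8)  # ratio 2, super-dominant
#' @export
dominanceDegree <- function(a, d) {
  if (is.na(a) || a == 0)
    return(list(ratio = NA_real_, category = "dominance only"))
  r <- d / a
  category <- if (abs(r) > 1) "super-dominant"
  else if (abs(r) == 1) "complete dominance"
  else if (r == 0) "no dominance"
  else "partial dominance"
  list(ratio = r, category = category)
}
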