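## BLUP prediction of genotypic and genotype-by-environment effects.

#' BLUP of genotypic, interaction and block effects
#'
#' Solves Henderson's mixed-model equations for
#' \eqn{y = X\beta + Z_G u_G + Z_{GE} u_{GE} + Z_B u_B + e} with
#' \eqn{\beta = (\mu, E)} fixed and variance ratios
#' \eqn{\lambda_i = \sigma^2_e / \sigma^2_i} taken from `vc`.  Predictions
#' shrink toward zero; components estimated as zero yield identically zero
#' predictions.  After solving, the usual sum-to-zero identification is
#' applied: `G` is centred, `GE` is double-centred and `B` centred within
#' environment, the absorbed means being folded into `mu`, `G` and the
#' environment effects (contrasts between materials are unaffected).  When
#' the residual variance is zero the equations reduce to least squares and
#' the exact balanced decomposition of cell means is returned (no
#' shrinkage).
#'
#' The returned fit also carries the unshrunken genotype and cell means and
#' the residual variance of the joint ANOVA, which downstream significance
#' tests of effect contrasts are based on.
#'
#' @param plots plot records (see [fitAnova()]).
#' @param vc a [VarianceComponents]; default is MINQUE(1) on the same data.
#' @return a [MixedModelFit].
#' @export
predictBlup <- function(plots, vc = NULL) {
  if (is.null(vc)) vc <- estimateVarianceMinque(plots)
  L <- .plotLayout(plots)
  s <- varComp(vc)
  an <- fitAnova(plots)
  msErr <- an$ms[an$source == "error"]
  dfErr <- an$df[an$source == "error"]
  sigma2e <- if (length(msErr)) msErr else NA_real_
  dfe <- if (length(dfErr)) dfErr else 0
  envs <- L$environments; mats <- L$materials
  H <- L$H; J <- L$J; K <- L$K
  blockDev <- L$blockMean - L$envMean[L$envOfBlock]

  if (s[["e"]] <= 1e-10 * max(1, sum(s))) {
    ## zero residual variance: no shrinkage; exact balanced decomposition
    mu <- L$grand
    E <- L$envMean - L$grand
    G <- L$gMean - L$grand
    GE <- sweep(sweep(L$cellMean, 2L, L$envMean), 1L, L$gMean) + L$grand
    B <- blockDev
  } else if (all(s[c("G", "GE", "B")] == 0)) {
    warning("all random variance components are zero; predictions are 0")
    mu <- L$grand
    E <- L$envMean - L$grand
    G <- stats::setNames(numeric(J), mats)
    GE <- matrix(0, J, H, dimnames = list(mats, envs))
    B <- stats::setNames(numeric(H * K), levels(L$blk))
  } else {
    D <- .designMatrices(L)
    active <- names(which(s[c("G", "GE", "B")] > 0))
    Zs <- list(G = D$ZG, GE = D$ZGE, B = D$ZB)[active]
    W <- do.call(cbind, c(list(D$X), Zs))
    p <- ncol(D$X)
    sizes <- vapply(Zs, ncol, integer(1))
    C <- crossprod(W)
    lam <- rep(c(0, s[["e"]] / s[active]), times = c(p, sizes))
    diag(C) <- diag(C) + lam
    sol <- drop(solve(C, crossprod(W, L$y)))
    beta <- sol[seq_len(p)]
    rest <- sol[-seq_len(p)]
    splitIdx <- rep(names(sizes), times = sizes)
    mu <- beta[1L]
    E <- stats::setNames(c(0, beta[-1L]), envs)
    G <- if ("G" %in% active)
      stats::setNames(rest[splitIdx == "G"], mats)
    else stats::setNames(numeric(J), mats)
    GE <- matrix(0, J, H, dimnames = list(mats, envs))
    if ("GE" %in% active) {
      uge <- rest[splitIdx == "GE"]
      ## model.matrix(~0 + mat:env) orders materials fastest within environment
      GE <- matrix(uge, J, H, dimnames = list(mats, envs))
    }
    B <- if ("B" %in% active)
      stats::setNames(rest[splitIdx == "B"], levels(L$blk))
    else stats::setNames(numeric(H * K), levels(L$blk))
    ## identification: double-centre GE, centre B within env, centre G.
    ## GE row means are folded into G only when G is itself in the model,
    ## so a zero genotypic component keeps its all-zero predictions.
    r <- if ("G" %in% active) rowMeans(GE) else rep(0, J)
    cm <- colMeans(GE); m <- mean(cm)
    GE <- GE - outer(r, rep(1, H)) - outer(rep(1, J), cm) + m
    G <- G + r
    E <- E + cm
    mu <- mu - m
    bm <- tapply(B, L$envOfBlock, mean)
    B <- B - bm[L$envOfBlock]
    E <- E + bm
    g0 <- mean(G); G <- G - g0; mu <- mu + g0
    e0 <- mean(E); E <- E - e0; mu <- mu + e0
  }
  new("MixedModelFit", mu = unname(mu), envEffects = stats::setNames(as.numeric(E), envs),
      G = stats::setNames(as.numeric(G), mats), GE = GE,
      B = stats::setNames(as.numeric(B), levels(L$blk)), vc = vc,
      gMean = stats::setNames(as.numeric(L$gMean), mats),
      cellMean = L$cellMean, sigma2e = as.numeric(sigma2e), dfe = as.numeric(dfe),
      nEnv = H, nBlocks = K, anova = an)
}

#' @describeIn predictBlup genotypic BLUPs as a named vector
#' @param fit a [MixedModelFit].
#' @export
genotypicBlup <- function(fit) fit@G

#' @describeIn predictBlup genotype-by-environment BLUPs (materials x envs)
#' @export
interactionBlup <- function(fit) fit@GE

setMethod("show", "MixedModelFit", function(object) {
  cat("MixedModelFit:", length(object@G), "materials x",
      object@nEnv, "environments x", object@nBlocks, "blocks\n")
  cat("  mu =", round(object@mu, 2), "d;  env effects:",
      paste(sprintf("%s=%+.2f", names(object@envEffects), object@envEffects),
            collapse = ", "), "\n")
  cat("  variance components (", object@vc@method, "): ",
      paste(sprintf("%s=%.3f", names(varComp(object)), varComp(object)),
            collapse = ", "), "\n", sep = "")
  cat("  residual MS =", round(object@sigma2e, 4), "on", object@dfe, "df\n")
})
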