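## Variance-component estimation: MINQUE(1) and the ANOVA/EMS method.

.designMatrices <- function(L) {
  ZG <- stats::model.matrix(~ 0 + L$mat)
  ZGE <- stats::model.matrix(~ 0 + L$mat:L$env)
  ZB <- stats::model.matrix(~ 0 + L$blk)
  X <- stats::model.matrix(~ L$env)
  list(X = X, ZG = ZG, ZGE = ZGE, ZB = ZB)
}

#' MINQUE(1) variance components
#'
#' Minimum-norm quadratic unbiased estimation of the variance components of
#' \eqn{y = \mu + E + G + GE + B + e} (environments fixed; genotypes,
#' genotype-by-environment and blocks-within-environment random), with all
#' prior values set to 1.  Solves the MINQUE normal equations
#' \eqn{tr(Q V_i Q V_j)\,\theta_j = y' Q V_i Q y} with
#' \eqn{V_0 = \sum_i \theta_i^{(0)} V_i} built from the priors and
#' \eqn{Q = V_0^{-1} - V_0^{-1} X (X' V_0^{-1} X)^{-1} X' V_0^{-1}}.
#' By default a single pass is performed (priors are not updated);
#' `iterations > 1` re-solves with the previous estimates as priors.
#' Negative solutions are truncated to zero with a warning, since downstream
#' BLUP requires nonnegative variance ratios; the untruncated solutions are
#' kept in the `raw` slot.
#'
#' @param plots plot records (see [fitAnova()]).
#' @param priors named numeric prior values `c(G=, GE=, B=, e=)`, all
#'   strictly positive.
#' @param iterations number of MINQUE passes (1 = classical MINQUE(1)).
#' @return a [VarianceComponents] with `method = "MINQUE1"`.
#' @export
estimateVarianceMinque <- function(plots, priors = c(G = 1, GE = 1, B = 1, e = 1),
                                   iterations = 1L) {
  if (any(priors <= 0)) stop("prior values must be strictly positive")
  L <- .plotLayout(plots)
  D <- .designMatrices(L)
  y <- L$y
  comp <- c("G", "GE", "B", "e")
  U <- list(G = D$ZG, GE = D$ZGE, B = D$ZB)
  th <- priors[comp]
  for (it in seq_len(max(1L, iterations))) {
    V0 <- th[["e"]] * diag(L$N)
    for (k in names(U)) V0 <- V0 + th[[k]] * tcrossprod(U[[k]])
    Vinv <- chol2inv(chol(V0))
    VX <- Vinv %*% D$X
    Q <- Vinv - VX %*% solve(crossprod(D$X, VX), t(VX))
    QU <- lapply(U, function(u) Q %*% u)
    S <- matrix(0, 4L, 4L, dimnames = list(comp, comp))
    q <- stats::setNames(numeric(4L), comp)
    Qy <- Q %*% y
    for (i in 1:3) {
      for (j in i:3) {
        S[i, j] <- S[j, i] <- sum(crossprod(U[[j]], QU[[i]])^2)
      }
      S[i, 4L] <- S[4L, i] <- sum(QU[[i]]^2)
      q[i] <- sum(crossprod(U[[i]], Qy)^2)
    }
    S[4L, 4L] <- sum(Q^2)
    q[4L] <- sum(Qy^2)
    if (rcond(S) < 1e-12) {
      ev <- eigen(S, symmetric = TRUE)
      near <- comp[abs(ev$vectors[, 4L]) > 0.3]
      stop("MINQUE coefficient matrix is singular; confounded components: ",
           paste(near, collapse = ", "))
    }
    raw <- stats::setNames(drop(solve(S, q)), comp)
    th <- pmax(raw, 1e-10)
  }
  .makeVC(raw, "MINQUE1")
}

.makeVC <- function(raw, method) {
  trunc <- raw < 0
  if (any(trunc))
    warning("negative variance component(s) truncated to zero: ",
            paste(names(raw)[trunc], collapse = ", "))
  new("VarianceComponents", sigma2 = pmax(raw, 0), raw = raw,
      method = method, truncated = trunc)
}

#' ANOVA / expected-mean-square variance components
#'
#' Method-of-moments estimates from the equivalence of observed and expected
#' mean squares of the balanced joint ANOVA:
#' \eqn{\hat\sigma^2_e = MS_e}, \eqn{\hat\sigma^2_{GE} = (MS_{GE}-MS_e)/K},
#' \eqn{\hat\sigma^2_G = (MS_G - MS_{GE})/(HK)},
#' \eqn{\hat\sigma^2_B = (MS_B - MS_e)/J}.  On balanced designs this agrees
#' with MINQUE for any choice of priors.
#'
#' @inheritParams estimateVarianceMinque
#' @return a [VarianceComponents] with `method = "ANOVA-EMS"`.
#' @export
estimateVarianceAnova <- function(plots) {
  an <- fitAnova(plots)
  ms <- stats::setNames(an$ms, an$source)
  lay <- attr(an, "layout")
  need <- c("genotypes", "genotype:environment", "blocks", "error")
  if (!all(need %in% names(ms)))
    stop("ANOVA-EMS estimation needs all of: ", paste(need, collapse = ", "))
  raw <- c(
    G = (ms[["genotypes"]] - ms[["genotype:environment"]]) / (lay$H * lay$K),
    GE = (ms[["genotype:environment"]] - ms[["error"]]) / lay$K,
    B = (ms[["blocks"]] - ms[["error"]]) / lay$J,
    e = ms[["error"]])
  .makeVC(raw, "ANOVA-EMS")
}

#' @rdname varComp
#' @export
setMethod("varComp", "VarianceComponents", function(object) object@sigma2)

#' @rdname varComp
#' @export
setMethod("varComp", "MixedModelFit", function(object) object@vc@sigma2)

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", object@method, ")\n", sep = "")
  print(round(object@sigma2, 4))
  if (any(object@truncated))
    cat("  truncated to zero:", paste(names(object@truncated)[object@truncated],
                                      collapse = ", "), "\n")
})

#' Heritability on the plot basis
#'
#' General heritability is the genotypic share of phenotypic variance
#' (expressed in all environments), peculiar heritability the genotype-by-
#' environment share (expressed only in particular environments).  The
#' default phenotypic denominator is the plot-level variance
#' \eqn{\sigma^2_G + \sigma^2_{GE} + \sigma^2_B + \sigma^2_e}; with
#' `basis = "mean"` the interaction, block and residual components are
#' divided by the numbers of environments and plots entering an entry mean
#' (requires `layout`).
#'
#' @param vc a [VarianceComponents] (or [MixedModelFit]).
#' @param basis `"plot"` (default) or `"mean"` (entry-mean basis).
#' @param layout list with `H` (environments) and `K` (blocks), as attached
#'   to [fitAnova()] output; needed for `basis = "mean"`.
#' @return named numeric `c(general=, peculiar=)`, fractions in [0, 1].
#' @export
heritability <- function(vc, basis = c("plot", "mean"), layout = NULL) {
  basis <- match.arg(basis)
  s <- varComp(vc)
  if (any(!is.finite(s))) stop("variance components must be finite")
  sp <- if (basis == "plot") sum(s) else {
    if (is.null(layout)) stop("'layout' with H and K is required for basis='mean'")
    s[["G"]] + s[["GE"]] / layout$H + (s[["B"]] + s[["e"]]) / (layout$H * layout$K)
  }
  if (sp <= 0) stop("phenotypic variance is zero; heritability undefined")
  c(general = unname(s[["G"]] / sp), peculiar = unname(s[["GE"]] / sp))
}
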