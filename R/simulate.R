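## Synthetic plot-level data with the exact structure the estimators assume.

#' Simulate a multi-environment randomized-block pyramiding trial
#'
#' Generates one plot-mean heading date per (environment, block, material)
#' cell under
#' \eqn{y_{hjk} = \mu + E_h + G_j + GE_{hj} + B_{k/h} + e_{hjk}}
#' with fixed environment shifts, genotypic values and interactions derived
#' from the truth model ([genotypicValue()], [interactionValue()]),
#' Gaussian block effects \eqn{B \sim N(0, blockSd^2)} and Gaussian plot
#' residuals \eqn{e \sim N(0, residSd^2)}.  Within-plot plant-to-plant
#' variation is not modelled: the observation is already the plot mean.
#' Identical seeds give byte-identical output.
#'
#' @param truth a [TruthModel].
#' @param materials a [MaterialCatalog].
#' @param blocksPerEnv number of complete blocks per environment.
#' @param seed optional integer seed.
#' @return data.frame with columns `env`, `block`, `material`, `hd` (days).
#'   The companion ground truth is available as `truthEffects(truth, materials)`.
#' @examples
#' tm <- hdTruthPreset()
#' plots <- simulateExperiment(tm, enumerateMaterials(), seed = 1)
#' nrow(plots)  # 3 envs x 3 blocks x 65 materials = 585
#' @export
simulateExperiment <- function(truth, materials, blocksPerEnv = 3L, seed = NULL) {
  if (!is(materials, "MaterialCatalog")) stop("'materials' must be a MaterialCatalog")
  if (!nrow(materialStates(materials))) stop("empty materials list")
  if (blocksPerEnv < 1L) stop("'blocksPerEnv' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  envs <- names(truth@envEffects)
  mats <- materialNames(materials)
  H <- length(envs); K <- as.integer(blocksPerEnv); J <- length(mats)
  G <- genotypicValue(materials, truth)
  GE <- interactionValue(materials, truth)
  B <- matrix(stats::rnorm(H * K, 0, truth@blockSd), H, K,
              dimnames = list(envs, sprintf("b%d", seq_len(K))))
  eps <- stats::rnorm(H * K * J, 0, truth@residSd)
  out <- data.frame(
    env = rep(envs, each = K * J),
    block = rep(rep(sprintf("b%d", seq_len(K)), each = J), times = H),
    material = rep(mats, times = H * K),
    stringsAsFactors = FALSE)
  out$hd <- truth@mu + truth@envEffects[out$env] + G[out$material] +
    GE[cbind(out$material, out$env)] + B[cbind(out$env, out$block)] +
    eps
  rownames(out) <- NULL
  out$hd <- unname(out$hd)
  out
}

#' Simulate plot data directly from variance components
#'
#' Draws every random term of the mixed model from its distribution:
#' \eqn{G_j \sim N(0,\sigma^2_G)}, \eqn{GE_{hj} \sim N(0,\sigma^2_{GE})},
#' \eqn{B_{k/h} \sim N(0,\sigma^2_B)}, \eqn{e \sim N(0,\sigma^2_e)}.
#' This is the generating model under which the variance-component
#' estimators are evaluated (Monte-Carlo recovery studies); for trait-level
#' simulation with explicit genetic effects use [simulateExperiment()].
#'
#' @param sigma2 named numeric `c(G=, GE=, B=, e=)`, days^2.
#' @param nMaterials number of genotypes.
#' @param environments environment labels (or a count).
#' @param blocksPerEnv blocks per environment.
#' @param mu grand mean, days.
#' @param envEffects optional named fixed environment shifts.
#' @param seed optional integer seed.
#' @return data.frame with columns `env`, `block`, `material`, `hd`.
#' @export
simulateVarianceModel <- function(sigma2 = c(G = 25, GE = 4, B = 1, e = 4),
                                  nMaterials = 13L,
                                  environments = c("e1", "e2", "e3"),
                                  blocksPerEnv = 3L, mu = 80,
                                  envEffects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(environments) && length(environments) == 1L)
    environments <- sprintf("e%d", seq_len(environments))
  H <- length(environments); K <- as.integer(blocksPerEnv)
  J <- as.integer(nMaterials)
  if (is.null(envEffects)) envEffects <- stats::setNames(numeric(H), environments)
  mats <- sprintf("m%02d", seq_len(J))
  G <- stats::rnorm(J, 0, sqrt(sigma2[["G"]]))
  GE <- matrix(stats::rnorm(H * J, 0, sqrt(sigma2[["GE"]])), J, H,
               dimnames = list(mats, environments))
  B <- matrix(stats::rnorm(H * K, 0, sqrt(sigma2[["B"]])), H, K,
              dimnames = list(environments, sprintf("b%d", seq_len(K))))
  eps <- stats::rnorm(H * K * J, 0, sqrt(sigma2[["e"]]))
  out <- data.frame(
    env = rep(environments, each = K * J),
    block = rep(rep(sprintf("b%d", seq_len(K)), each = J), times = H),
    material = rep(mats, times = H * K),
    stringsAsFactors = FALSE)
  out$hd <- mu + envEffects[out$env] + G[match(out$material, mats)] +
    GE[cbind(out$material, out$env)] +
    B[cbind(out$env, out$block)] + eps
  out$hd <- unname(out$hd)
  out
}
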