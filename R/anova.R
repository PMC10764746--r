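## Joint ANOVA of the multi-environment randomized-block trial.

## Validates the balanced layout and precomputes the cell means every
## downstream estimator uses.
.plotLayout <- function(plots) {
  need <- c("env", "block", "material", "hd")
  if (!all(need %in% names(plots)))
    stop("plot table must have columns ", paste(need, collapse = ", "))
  if (!nrow(plots)) stop("empty plot table")
  env <- factor(plots$env, levels = unique(plots$env))
  mat <- factor(plots$material, levels = unique(plots$material))
  blk <- factor(paste(plots$env, plots$block, sep = ":"),
                levels = unique(paste(plots$env, plots$block, sep = ":")))
  counts <- table(blk, mat)
  if (any(counts != 1L))
    stop("unbalanced layout: every (environment, block) must contain every ",
         "material exactly once")
  kPerEnv <- table(sub(":.*$", "", levels(blk)))
  if (length(unique(kPerEnv)) != 1L)
    stop("unbalanced layout: environments have differing block counts")
  H <- nlevels(env); J <- nlevels(mat); K <- as.integer(kPerEnv[[1L]])
  y <- plots$hd
  envOfBlock <- factor(sub(":.*$", "", levels(blk)), levels = levels(env))
  list(
    env = env, mat = mat, blk = blk, y = y,
    H = H, J = J, K = K, N = length(y),
    environments = levels(env), materials = levels(mat),
    grand = mean(y),
    envMean = tapply(y, env, mean),
    gMean = tapply(y, mat, mean),
    blockMean = tapply(y, blk, mean),
    envOfBlock = envOfBlock,
    cellMean = tapply(y, list(mat, env), mean))
}

#' Joint analysis of variance with expected mean squares
#'
#' Two-factor ANOVA of plot-mean heading date with genotypes crossed with
#' environments and complete blocks nested in environments.  Sources are
#' environments (fixed), blocks-within-environments, genotypes, genotype x
#' environment, and the residual.  Expected mean squares follow the model
#' with G, GE and B random: genotypes are tested against the G x E mean
#' square, G x E and blocks against the residual, and environments against
#' the Satterthwaite combination MS(B) + MS(GE) - MS(error).
#'
#' @param plots data.frame of plot records (`env`, `block`, `material`, `hd`),
#'   one plot per (environment, block, material) cell.
#' @return data.frame with columns `source`, `df`, `ss`, `ms`, `Fvalue`,
#'   `pvalue`; sources with zero degrees of freedom are omitted.  The EMS
#'   coefficient matrix (columns `e`, `B`, `GE`, `G`, in plot-variance units)
#'   is attached as `attr(, "ems")` and the layout as `attr(, "layout")`.
#' @export
fitAnova <- function(plots) {
  L <- .plotLayout(plots)
  H <- L$H; J <- L$J; K <- L$K
  ssE <- J * K * sum((L$envMean - L$grand)^2)
  ssB <- J * sum((L$blockMean - L$envMean[L$envOfBlock])^2)
  ssG <- H * K * sum((L$gMean - L$grand)^2)
  dev <- sweep(sweep(L$cellMean, 2L, L$envMean), 1L, L$gMean) + L$grand
  ssGE <- K * sum(dev^2)
  ssT <- sum((L$y - L$grand)^2)
  ssErr <- max(0, ssT - ssE - ssB - ssG - ssGE)
  df <- c(environments = H - 1L, blocks = H * (K - 1L), genotypes = J - 1L,
          `genotype:environment` = (H - 1L) * (J - 1L),
          error = H * (K - 1L) * (J - 1L))
  ss <- c(ssE, ssB, ssG, ssGE, ssErr)
  keep <- df > 0L
  ms <- ifelse(keep, ss / df, NA_real_)
  names(ms) <- names(df)
  Fv <- p <- stats::setNames(rep(NA_real_, 5L), names(df))
  safeF <- function(num, den, df1, df2) {
    if (is.na(num) || is.na(den) || den <= 0 || df2 <= 0) return(c(NA, NA))
    f <- num / den
    c(f, stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  r <- safeF(ms["genotypes"], ms["genotype:environment"],
             df["genotypes"], df["genotype:environment"])
  Fv["genotypes"] <- r[1]; p["genotypes"] <- r[2]
  r <- safeF(ms["genotype:environment"], ms["error"],
             df["genotype:environment"], df["error"])
  Fv["genotype:environment"] <- r[1]; p["genotype:environment"] <- r[2]
  r <- safeF(ms["blocks"], ms["error"], df["blocks"], df["error"])
  Fv["blocks"] <- r[1]; p["blocks"] <- r[2]
  ## quasi-F for the fixed environments term under the random model
  if (all(keep[c("blocks", "genotype:environment", "error")])) {
    den <- ms["blocks"] + ms["genotype:environment"] - ms["error"]
    if (!is.na(den) && den > 0) {
      df2 <- den^2 / (ms["blocks"]^2 / df["blocks"] +
                      ms["genotype:environment"]^2 / df["genotype:environment"] +
                      ms["error"]^2 / df["error"])
      Fv["environments"] <- ms["environments"] / den
      p["environments"] <- stats::pf(Fv["environments"], df["environments"],
                                     df2, lower.tail = FALSE)
    }
  }
  out <- data.frame(source = names(df), df = as.integer(df), ss = ss, ms = ms,
                    Fvalue = Fv, pvalue = p, stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  ems <- rbind(
    environments = c(e = 1, B = J, GE = K, G = 0),
    blocks = c(1, J, 0, 0),
    genotypes = c(1, 0, K, H * K),
    `genotype:environment` = c(1, 0, K, 0),
    error = c(1, 0, 0, 0))[keep, , drop = FALSE]
  attr(out, "ems") <- ems
  attr(out, "layout") <- L[c("H", "J", "K", "N", "environments", "materials")]
  out
}
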