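## Promote/inhibit network between loci from background-dependent effects.

#' Effect of a focal locus-state in a genetic background
#'
#' The conditional effect of a focal single-locus substitution (`"L-1"` or
#' `"L-2"`) in the background of another material is
#' \eqn{g(\mathrm{background+focal}) - g(\mathrm{background})}; its change
#' from the focal's solo effect (`delta`) is, algebraically, the sum of the
#' epistasis terms linking the focal to the background loci (for an order-1
#' background, exactly the dual epistasis of the pair).
#'
#' @param et an [EffectTable] with single and pyramiding rows.
#' @param focal a locus-state token such as `"Hd3a-2"`.
#' @param background a material identifier (order >= 1) not involving the
#'   focal locus.
#' @return one-row data.frame with `baseline` (solo effect),
#'   `effectInBackground`, `delta`, `se`, `p`, `stars` and `available`.
#' @export
effectInBackground <- function(et, focal, background) {
  loci <- et@loci
  fst <- drop(parseMaterialId(focal, loci))
  bst <- drop(parseMaterialId(background, loci))
  if (sum(fst != 0) != 1L) stop("'focal' must be a single locus-state token")
  if (any(fst != 0 & bst != 0))
    stop("focal locus already substituted in the background material")
  comb <- materialId(fst + bst, reference = et@reference)
  fl <- names(fst)[fst != 0]
  baseline <- .singleEffectOf(et, fl, fst[fst != 0])$value
  gOf <- function(id) {
    k <- sum(parseMaterialId(id, loci) != 0)
    if (k == 1L) {
      s <- drop(parseMaterialId(id, loci))
      .singleEffectOf(et, names(s)[s != 0], s[s != 0])$value
    } else .etValue(et, "pyramiding", id)
  }
  gBg <- gOf(background); gComb <- gOf(comb)
  eff <- gComb - gBg
  delta <- eff - baseline
  se <- p <- NA_real_; stars <- NA_character_
  if (!is.null(et@fit)) {
    cvec <- stats::setNames(c(1, -1, -1, 1),
                            c(comb, background, materialId(fst), et@reference))
    cs <- tryCatch(.contrastStats(et@fit, cvec), error = function(e) NULL)
    if (!is.null(cs)) { se <- cs$se; p <- cs$p; stars <- cs$stars }
  }
  data.frame(focal = focal, background = background, combined = comb,
             baseline = baseline, effectInBackground = eff, delta = delta,
             se = se, p = p, stars = stars,
             available = !is.na(delta), stringsAsFactors = FALSE)
}

#' Pairwise promote/inhibit network between loci
#'
#' For every ordered pair of loci (source = background, target = focal) the
#' four dual-epistasis entries over focal state x background state are the
#' evidence for whether the source changes the target's effect.  A piece of
#' evidence counts as a change when it is significant (p-value if
#' available, else printed stars) and at least `deltaThreshold` days in
#' magnitude; its direction is *promoting* when it pushes the focal effect
#' further in the direction of the focal's own solo effect and *inhibiting*
#' when it pulls the effect back toward zero (or past it).  An edge is
#' called only when a strict majority (more than half) of the evidence
#' shows a change — a single deviating state combination, as for Hd1 with
#' Ehd1 in the reference study, leaves the pair independent, and one
#' additional borderline contrast cannot create an edge; the summary relation is
#' the majority direction of the changed evidence, with ties reported as
#' ambiguous.  Heterozygous and homozygous focal states are also classified
#' separately, since they can respond in opposite directions.
#'
#' @param et an [EffectTable] containing single and dual-epistasis rows.
#' @param alpha significance level for evidence.
#' @param deltaThreshold minimum absolute change (days) to count as
#'   evidence of regulation.
#' @return data.frame of edges with columns `source`, `target`, `relation`
#'   (`"promotes"`, `"inhibits"`, `"independent"`, `"ambiguous"`),
#'   `detail` (per focal state), and evidence counts; the full evidence
#'   table is attached as `attr(, "evidence")`.
#' @export
buildNetwork <- function(et, alpha = 0.05, deltaThreshold = 1) {
  loci <- et@loci
  dual <- et@effects[et@effects$kind == "dualEpistasis", , drop = FALSE]
  dualEnvP <- et@envP[et@effects$kind == "dualEpistasis", , drop = FALSE]
  rownames(dual) <- dual$id
  evidence <- list(); edges <- list()
  majority <- function(dirs) {
    nP <- sum(dirs == "promotes", na.rm = TRUE)
    nI <- sum(dirs == "inhibits", na.rm = TRUE)
    if (nP + nI == 0) "independent"
    else if (nP > nI) "promotes" else if (nI > nP) "inhibits" else "ambiguous"
  }
  for (src in loci) for (tgt in setdiff(loci, src)) {
    ev <- list()
    for (f in 1:2) for (b in 1:2) {
      st <- stats::setNames(integer(length(loci)), loci)
      st[tgt] <- f; st[src] <- b
      pid <- materialId(st)
      delta <- if (pid %in% dual$id) dual[pid, "value"] else NA_real_
      pv <- if (pid %in% dual$id) dual[pid, "p"] else NA_real_
      strs <- if (pid %in% dual$id) dual[pid, "stars"] else NA_character_
      sig <- if (!is.na(pv)) pv <= alpha
             else !is.na(strs) && strs %in% c("*", "**") &&
                  (alpha >= 0.05 || strs == "**")
      baseline <- .singleEffectOf(et, tgt, f)$value
      refSign <- if (is.na(baseline) || baseline == 0) sign(delta) else sign(baseline)
      changed <- isTRUE(sig) && !is.na(delta) && abs(delta) >= deltaThreshold
      dir <- if (changed) { if (refSign * delta > 0) "promotes" else "inhibits" }
             else NA_character_
      ev[[length(ev) + 1L]] <- data.frame(
        source = src, target = tgt, focalState = paste0(tgt, "-", f),
        backgroundState = paste0(src, "-", b), pair = pid,
        baseline = baseline, delta = delta, significant = isTRUE(sig),
        changed = changed, direction = dir, stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, ev)
    evidence[[length(evidence) + 1L]] <- ev
    nChanged <- sum(ev$changed)
    relation <- if (nChanged <= nrow(ev) / 2) "independent" else majority(ev$direction)
    detail <- vapply(paste0(tgt, "-", 1:2), function(fs) {
      sub <- ev[ev$focalState == fs, ]
      if (!sum(sub$changed)) "independent" else majority(sub$direction)
    }, character(1))
    edges[[length(edges) + 1L]] <- data.frame(
      source = src, target = tgt, relation = relation,
      detail = paste(sprintf("%s:%s", names(detail), detail), collapse = "; "),
      nEvidence = nrow(ev), nChanged = nChanged,
      nPromote = sum(ev$direction == "promotes", na.rm = TRUE),
      nInhibit = sum(ev$direction == "inhibits", na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edges)
  attr(out, "evidence") <- do.call(rbind, evidence)
  out
}
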