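## Bliss independence: expected combination effects and synergy
## classification over dose grids.

#' Bliss-expected combination effect
#'
#' \code{Yab = Ya + Yb - Ya Yb}: the null combination effect of two drugs
#' acting independently, for fractional effects in [0, 1]. Commutative,
#' with fixed points at 0 and 1, and \code{Yab >= max(Ya, Yb)}.
#'
#' @param Ya,Yb fractional single-agent effects in [0, 1] (vectorized).
#' @return Bliss-expected fractional effect.
#' @examples
#' blissExpected(0.5, 0.5)  # 0.75
#' @export
blissExpected <- function(Ya, Yb) {
  if (any(!is.finite(c(Ya, Yb))) || any(c(Ya, Yb) < 0) ||
      any(c(Ya, Yb) > 1))
    stop("effects must lie in [0, 1]", call. = FALSE)
  Ya + Yb - Ya * Yb
}

#' Classify a dose-combination surface against Bliss independence
#'
#' Evaluates \code{effect_fn} over the full dose grid, computes the Bliss
#' expectation from the single-agent rows, and marks each dose pair
#' synergistic when the model effect exceeds the Bliss expectation by more
#' than \code{tol}, antagonistic when it falls short by more than
#' \code{tol}, additive otherwise. For in vivo use the conventional effect
#' scale is fractional TGI/100 clipped to [0, 1].
#'
#' @param doses_a,doses_b dose vectors; a zero dose is prepended when
#'   missing (single-agent effects anchor the Bliss expectation).
#' @param effect_fn function(dose_a, dose_b) -> fractional effect in
#'   [0, 1]; non-finite values mark the cell "undefined".
#' @param tol additive tolerance band (default 0.01).
#' @return a \code{\linkS4class{SynergySurface}} over the supplied doses.
#' @export
classifySurface <- function(doses_a, doses_b, effect_fn, tol = 0.01) {
  .assertNonNeg(doses_a, "doses_a"); .assertNonNeg(doses_b, "doses_b")
  ga <- if (0 %in% doses_a) doses_a else c(0, doses_a)
  gb <- if (0 %in% doses_b) doses_b else c(0, doses_b)
  eff <- matrix(NA_real_, length(ga), length(gb),
                dimnames = list(ga, gb))
  for (i in seq_along(ga))
    for (j in seq_along(gb))
      eff[i, j] <- effect_fn(ga[i], gb[j])
  effC <- pmin(pmax(eff, 0), 1)
  ya <- effC[, 1]   # drug A alone (B = 0)
  yb <- effC[1, ]   # drug B alone (A = 0)
  bliss <- outer(ya, yb, function(a, b) a + b - a * b)
  cls <- matrix("additive", length(ga), length(gb))
  cls[which(effC > bliss + tol)] <- "synergistic"
  cls[which(effC < bliss - tol)] <- "antagonistic"
  cls[which(!is.finite(eff))] <- "undefined"
  keep_a <- ga %in% doses_a
  keep_b <- gb %in% doses_b
  new("SynergySurface", doses_a = ga[keep_a], doses_b = gb[keep_b],
      model_effect = effC[keep_a, keep_b, drop = FALSE],
      bliss_effect = bliss[keep_a, keep_b, drop = FALSE],
      classification = cls[keep_a, keep_b, drop = FALSE])
}

#' Write a synergy surface as delimited matrix files
#'
#' Emits model-effect, Bliss-effect and classification matrices plus a
#' summary table comparing model-predicted and Bliss-predicted effects.
#'
#' @param surface a \code{SynergySurface}.
#' @param prefix file path prefix.
#' @export
writeSurface <- function(surface, prefix) {
  wt <- function(m, f) utils::write.table(
    m, paste0(prefix, "_", f, ".tsv"), sep = "\t", quote = FALSE,
    col.names = NA)
  wt(surface@model_effect, "model")
  wt(surface@bliss_effect, "bliss")
  wt(surface@classification, "class")
  summary <- data.frame(
    dose_a = rep(surface@doses_a, times = length(surface@doses_b)),
    dose_b = rep(surface@doses_b, each = length(surface@doses_a)),
    model = as.vector(surface@model_effect),
    bliss = as.vector(surface@bliss_effect),
    class = as.vector(surface@classification))
  utils::write.table(summary, paste0(prefix, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
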