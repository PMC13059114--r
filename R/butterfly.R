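## Butterfly-plot projection of per-cell lineage-state signature scores and
## the cell-cycle score (CCS).

#' Butterfly coordinates from lineage-state scores
#'
#' Projects per-cell signature scores onto the two-dimensional butterfly
#' plot. For each cell,
#' `D = max(opc, npc) - max(ac, mes)` separates progenitor-like (D > 0)
#' from differentiated-like (D < 0) states; the X coordinate is
#' `log2((opc - npc) + 1)` when D > 0 and `log2((ac - mes) + 1)` when
#' D < 0; the Y coordinate uses the signed form
#' `sign(D) * log2(|D| + 1)`, which extends the printed `log2(D + 1)`
#' symmetrically to negative D (where the unsigned form is undefined for
#' D <= -1). D = 0 maps to the origin.
#'
#' @param scores data.frame with numeric columns `opc`, `npc`, `ac`, `mes`
#'   (and optionally `cell_id`, carried through).
#' @return data.frame with columns D, X, Y (plus cell_id when present).
#' @export
butterflyCoords <- function(scores) {
    need <- c("opc", "npc", "ac", "mes")
    miss <- setdiff(need, names(scores))
    if (length(miss)) configError("scores lack column '%s'", miss[1])
    if (!all(vapply(scores[need], function(x) all(is.finite(x)), TRUE)))
        inputError("all scores must be finite")
    D <- pmax(scores$opc, scores$npc) - pmax(scores$ac, scores$mes)
    X <- numeric(length(D)); Y <- numeric(length(D))
    pos <- D > 0; neg <- D < 0
    argPos <- (scores$opc - scores$npc) + 1
    argNeg <- (scores$ac - scores$mes) + 1
    if (any(pos & argPos <= 0))
        metricError("log2 argument <= 0 for (opc - npc) + 1 in a D > 0 cell")
    if (any(neg & argNeg <= 0))
        metricError("log2 argument <= 0 for (ac - mes) + 1 in a D < 0 cell")
    X[pos] <- log2(argPos[pos])
    X[neg] <- log2(argNeg[neg])
    Y <- sign(D) * log2(abs(D) + 1)
    out <- data.frame(D = D, X = X, Y = Y)
    if ("cell_id" %in% names(scores)) out <- cbind(cell_id = scores$cell_id, out)
    out
}

#' Cell-cycle score
#'
#' CCS = G1/S score + G2/M score, a per-cell proxy for proliferative
#' activity.
#'
#' @param g1s,g2m numeric signature scores (vectorised).
#' @return numeric CCS.
#' @export
cellCycleScore <- function(g1s, g2m) g1s + g2m
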