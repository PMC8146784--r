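#' Diagnostic plots for an evaluation report
#'
#' Cosmetic helpers: ROC curves of all members (and the ensemble) from
#' the pooled test scores, and boxplots of the per-iteration CCRs.
#'
#' @param report an \code{"evaluationReport"} from
#'   \code{\link{runRepeatedEvaluation}}.
#' @param main plot title.
#' @return Invisibly, \code{NULL}; called for the plot side effect.
#' @export
plotRocCurves <- function(report, main = "ROC (pooled test scores)") {
    keep <- !vapply(report$roc, is.null, logical(1))
    rocs <- report$roc[keep]
    graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                   xlab = "False positive rate",
                   ylab = "True positive rate", main = main)
    cols <- seq_along(rocs) + 1L
    for (i in seq_along(rocs)) {
        graphics::lines(rocs[[i]]$points$fpr, rocs[[i]]$points$tpr,
                        col = cols[i])
    }
    graphics::legend("bottomright", bty = "n",
                     legend = sprintf("%s (AUC %.3f)", names(rocs),
                                      vapply(rocs, `[[`, numeric(1), "auc")),
                     col = cols, lty = 1)
    invisible(NULL)
}

#' @rdname plotRocCurves
#' @export
plotCcrBoxplots <- function(report, main = "Per-iteration CCR") {
    graphics::boxplot(report$iterationCCR, ylab = "CCR (%)", main = main)
    invisible(NULL)
}
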