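# Confusion-count metrics and ROC. The murmur class is the positive
# class throughout: sensitivity is murmur recall, specificity is normal
# recall, PPV/NPV are the precisions of murmur and normal calls.

#' Confusion counts from labels and predictions
#'
#' @param truth character vector of true labels (`"murmur"`/`"normal"`).
#' @param predicted character vector of predicted labels.
#' @return named list with integers `Tp`, `Tn`, `Fp`, `Fn` (murmur =
#'   positive).
#' @export
confusionCounts <- function(truth, predicted) {
    stopifnot(length(truth) == length(predicted),
              all(truth %in% PCG_LABELS), all(predicted %in% PCG_LABELS))
    list(Tp = sum(truth == "murmur" & predicted == "murmur"),
         Tn = sum(truth == "normal" & predicted == "normal"),
         Fp = sum(truth == "normal" & predicted == "murmur"),
         Fn = sum(truth == "murmur" & predicted == "normal"))
}

#' Accuracy, sensitivity, specificity, PPV and NPV from confusion counts
#'
#' Implements the standard identities
#' `accuracy = (Tp + Tn) / (Tp + Tn + Fp + Fn)`,
#' `sensitivity = Tp / (Tp + Fn)`, `specificity = Tn / (Fp + Tn)`,
#' `PPV = Tp / (Tp + Fp)`, `NPV = Tn / (Fn + Tn)`, reported as
#' percentages. A metric whose denominator is zero is reported as `NA`
#' (absent), not 0.
#'
#' @param counts list with `Tp`, `Tn`, `Fp`, `Fn` (see
#'   [confusionCounts()]).
#' @return named numeric vector of the five percentages.
#' @export
metricReport <- function(counts) {
    with(counts, {
        total <- Tp + Tn + Fp + Fn
        pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
        c(accuracy = pct(Tp + Tn, total),
          sensitivity = pct(Tp, Tp + Fn),
          specificity = pct(Tn, Fp + Tn),
          ppv = pct(Tp, Tp + Fp),
          npv = pct(Tn, Fn + Tn))
    })
}

#' ROC curve by threshold sweep and trapezoid AUC
#'
#' Sweeps a decision threshold over the unique murmur-posterior scores
#' and returns one (FPR, TPR) point per threshold plus the trapezoid
#' area under the curve. Ties receive the conventional half-credit
#' through the trapezoid rule.
#'
#' @param truth true labels (`"murmur"` positive).
#' @param scores murmur posterior per clip.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`,
#'   decreasing threshold) and `auc`.
#' @export
rocCurve <- function(truth, scores) {
    stopifnot(length(truth) == length(scores))
    pos <- truth == "murmur"
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0 || nNeg == 0)
        stop("ROC needs both classes present")
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    tpr <- vapply(thr, function(t) sum(scores >= t & pos) / nPos,
                  numeric(1))
    fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nNeg,
                  numeric(1))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
         auc = auc)
}

#' Evaluate a trained model on a test set
#'
#' Predicts each clip (class = argmax of the posterior; murmur
#' posterior = ROC score), assembles confusion counts, the five metrics,
#' the ROC curve, and a per-site metric breakdown obtained by filtering
#' the test set by auscultation site. A site lacking either class gets
#' `NA` for the metrics that are undefined there and no AUC.
#'
#' @param weights trained weights.
#' @param features list of feature matrices for the test clips.
#' @param labels true labels.
#' @param sites optional auscultation site per clip; enables the
#'   per-site breakdown.
#' @return list with `counts`, `metrics`, `roc`, `auc`, `scores`,
#'   `predicted`, and (when `sites` is given) `perSite` (data.frame,
#'   one row per site).
#' @export
evaluateModel <- function(weights, features, labels, sites = NULL) {
    if (!length(features)) stop("empty test set")
    stopifnot(length(features) == length(labels))
    scores <- predictScores(features, weights)
    predicted <- ifelse(scores >= 0.5, "murmur", "normal")
    counts <- confusionCounts(labels, predicted)
    metrics <- metricReport(counts)
    roc <- if (length(unique(labels)) == 2L) rocCurve(labels, scores)
           else NULL
    out <- list(counts = counts, metrics = metrics,
                roc = roc$points, auc = roc$auc,
                scores = scores, predicted = predicted)
    if (!is.null(sites)) {
        stopifnot(length(sites) == length(labels))
        perSite <- lapply(unique(sites), function(s) {
            sel <- sites == s
            m <- metricReport(confusionCounts(labels[sel],
                                              predicted[sel]))
            data.frame(site = s, n = sum(sel), t(m))
        })
        out$perSite <- do.call(rbind, perSite)
    }
    out
}
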