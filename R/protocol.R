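# End-to-end evaluation protocols over a cohort: the 70/30
# subject-exclusive split task and subject-exclusive K-fold
# cross-validation, with one metric row per architecture or fold and,
# for K-fold, an arithmetic mean row.

cohortFeatures <- function(clips, config) {
    clipFeatures(clips, config)
}

#' Run an evaluation protocol over a cohort
#'
#' For `protocol = "split"`: one subject-exclusive 70/30 split, each
#' architecture trained on the training side and evaluated on the test
#' side (one table row per architecture). For `protocol = "kfold"`:
#' K subject-exclusive folds; each fold is held out once while the
#' others train, giving one row per fold plus an `average` row holding
#' the arithmetic mean of the fold percentages.
#'
#' @param clips list of [PCGClip-class].
#' @param manifest matching manifest data.frame.
#' @param configs named list of [ModelConfig-class] (names label table
#'   rows); K-fold uses the first config only.
#' @param protocol `"split"` or `"kfold"`.
#' @param trainFraction split protocol's target train fraction.
#' @param K number of folds.
#' @param seed master seed; sub-seeds for splitting and each training
#'   run are derived from it deterministically.
#' @param epochs,batchSize,lr,validationFraction training
#'   hyperparameters passed to [trainModel()].
#' @return list with `table` (data.frame of percentage metrics and AUC)
#'   and `details` (per-row evaluation objects).
#' @export
runProtocol <- function(clips, manifest, configs,
                        protocol = c("split", "kfold"),
                        trainFraction = 0.7, K = 4L, seed = 1L,
                        epochs = 20L, batchSize = 8L, lr = 1e-3,
                        validationFraction = 0) {
    protocol <- match.arg(protocol)
    checkManifestClips(manifest, clips)
    if (is(configs, "ModelConfig"))
        configs <- stats::setNames(list(configs), configs@architecture)

    trainEval <- function(config, trainIdx, testIdx, runSeed) {
        feTr <- cohortFeatures(clips[trainIdx], config)
        feTe <- cohortFeatures(clips[testIdx], config)
        fit <- trainModel(feTr, manifest$label[trainIdx], config,
                          epochs = epochs, batchSize = batchSize,
                          lr = lr, seed = runSeed,
                          validationFraction = validationFraction)
        ev <- evaluateModel(fit$weights, feTe, manifest$label[testIdx],
                            sites = manifest$site[testIdx])
        ev$weights <- fit$weights
        ev$log <- fit$log
        ev
    }

    rows <- list(); details <- list()
    if (protocol == "split") {
        plan <- splitTrainTest(manifest, trainFraction, seed = seed)
        trainIdx <- which(manifest$subject_id %in% plan$trainSubjects)
        testIdx <- which(manifest$subject_id %in% plan$testSubjects)
        for (i in seq_along(configs)) {
            ev <- trainEval(configs[[i]], trainIdx, testIdx,
                            runSeed = seed + 1000L * i)
            rows[[i]] <- data.frame(row = names(configs)[i],
                                    t(ev$metrics), auc = ev$auc)
            details[[names(configs)[i]]] <- ev
        }
        details$plan <- plan
    } else {
        folds <- kfoldSplit(manifest, K = K, seed = seed)
        config <- configs[[1]]
        for (k in seq_along(folds)) {
            testIdx <- which(manifest$subject_id %in% folds[[k]])
            trainIdx <- setdiff(seq_len(nrow(manifest)), testIdx)
            ev <- trainEval(config, trainIdx, testIdx,
                            runSeed = seed + 1000L * k)
            rows[[k]] <- data.frame(row = sprintf("fold%d", k),
                                    t(ev$metrics), auc = ev$auc)
            details[[sprintf("fold%d", k)]] <- ev
        }
        tab <- do.call(rbind, rows)
        avg <- data.frame(row = "average",
                          t(colMeans(tab[, -1], na.rm = TRUE)))
        rows[[length(rows) + 1L]] <- avg
        details$folds <- folds
    }
    list(table = do.call(rbind, rows), details = details)
}

checkManifestClips <- function(manifest, clips) {
    if (length(clips) != nrow(manifest))
        stop("manifest rows (", nrow(manifest),
             ") and clips (", length(clips), ") differ in number")
    invisible(TRUE)
}

#' Write a protocol metric table as TSV
#'
#' Percentages are printed to one decimal place, mirroring the layout
#' of published per-model / per-fold / per-site tables.
#'
#' @param table data.frame from [runProtocol()] or a per-site table.
#' @param path output TSV path.
#' @export
writeMetricTable <- function(table, path) {
    num <- vapply(table, is.numeric, logical(1))
    digits <- ifelse(names(table) == "auc", 3L, 1L)
    table[num] <- Map(function(x, d) round(x, d), table[num],
                      digits[num])
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
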