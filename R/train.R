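# Training: Adam on the cross-entropy, gradient accumulation over
# mini-batches, optional early stopping on a validation carve-out.

# Walk the parallel weight/gradient trees, applying f(tensor, grad, key)
# and rebuilding the weight tree. Non-numeric bookkeeping entries
# (config, dims, kernel metadata) are passed through untouched.
walkTensors <- function(weights, grads, f, prefix = "") {
    tensorNames <- list(conv = c("W", "b"), lstm = c("Wx", "Wh", "b"),
                        dense = c("W", "b"), out = c("W", "b"),
                        tap = c("W_c", "W_r", "u", "b_global", "W_l",
                                "b_l", "v", "W_g"))
    for (part in names(tensorNames)) {
        wp <- weights[[part]]
        gp <- grads[[part]]
        if (is.null(wp) || is.null(gp)) next
        if (part %in% c("out", "tap")) {
            for (nm in tensorNames[[part]])
                weights[[part]][[nm]] <- f(wp[[nm]], gp[[nm]],
                                           paste0(part, ".", nm))
        } else {
            for (i in seq_along(wp))
                for (nm in tensorNames[[part]])
                    weights[[part]][[i]][[nm]] <-
                        f(wp[[i]][[nm]], gp[[i]][[nm]],
                          paste0(part, i, ".", nm))
        }
    }
    weights
}

zeroLike <- function(weights) {
    walkTensors(weights, weights, function(w, g, k) w * 0)
}

addGrads <- function(acc, grads, scale = 1) {
    walkTensors(acc, grads, function(a, g, k) a + scale * g)
}

#' Train a classifier on featurized clips
#'
#' Minimizes the softmax cross-entropy with Adam. Gradients are averaged
#' over mini-batches of clips (clips are processed at natural length; no
#' padding is needed because gradients are accumulated per clip). With
#' `validationFraction > 0` a subject-agnostic carve-out of the training
#' clips monitors the loss and training stops early when it has not
#' improved for `patience` epochs.
#'
#' @param features list of `N x inputDim` matrices (standardized
#'   spectrogram frames, see [clipFeatures()]).
#' @param labels character vector, `"murmur"`/`"normal"`, one per clip.
#' @param config a [ModelConfig-class].
#' @param epochs maximum training epochs.
#' @param batchSize clips per Adam step.
#' @param lr Adam learning rate.
#' @param seed seed controlling initialization and shuffling.
#' @param validationFraction fraction of clips carved out for early
#'   stopping (0 disables).
#' @param patience early-stopping patience in epochs.
#' @param verbose print per-epoch losses.
#' @return list with `weights` and `log` (data.frame of per-epoch mean
#'   training loss and, when enabled, validation loss).
#' @export
trainModel <- function(features, labels, config, epochs = 50L,
                       batchSize = 8L, lr = 1e-3, seed = 1L,
                       validationFraction = 0.1, patience = 5L,
                       verbose = FALSE) {
    stopifnot(length(features) == length(labels))
    if (!length(features)) stop("empty training set")
    stopifnot(all(labels %in% PCG_LABELS))
    if (length(unique(labels)) < 2L)
        stop("training set must contain both classes")
    classIdx <- ifelse(labels == "murmur", 2L, 1L)

    set.seed(seed)
    weights <- initWeights(config, inputDim = ncol(features[[1]]),
                           seed = seed)
    n <- length(features)
    valIdx <- integer(0)
    if (validationFraction > 0 && n >= 10L) {
        nVal <- max(2L, round(validationFraction * n))
        valIdx <- sample.int(n, nVal)
    }
    trIdx <- setdiff(seq_len(n), valIdx)

    m1 <- zeroLike(weights)
    m2 <- zeroLike(weights)
    beta1 <- 0.9; beta2 <- 0.999; epsAdam <- 1e-8
    step <- 0L
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      valLoss = numeric(0))
    bestVal <- Inf; bestWeights <- weights; bad <- 0L

    for (ep in seq_len(epochs)) {
        ord <- sample(trIdx)
        losses <- numeric(length(ord))
        bi <- 0L
        acc <- NULL
        flush <- function(k) {
            step <<- step + 1L
            sc <- 1 / k
            m1 <<- walkTensors(m1, acc, function(m, g, key)
                beta1 * m + (1 - beta1) * g * sc)
            m2 <<- walkTensors(m2, acc, function(m, g, key)
                beta2 * m + (1 - beta2) * (g * sc)^2)
            c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
            upd <- walkTensors(m1, m2, function(a, b, key)
                lr * (a / c1) / (sqrt(b / c2) + epsAdam))
            weights <<- addGrads(weights, upd, scale = -1)
        }
        for (j in seq_along(ord)) {
            i <- ord[j]
            lg <- lossAndGradients(features[[i]], classIdx[i], weights)
            losses[j] <- lg$loss
            acc <- if (bi == 0L) lg$grads else addGrads(acc, lg$grads)
            bi <- bi + 1L
            if (bi == batchSize) { flush(bi); bi <- 0L }
        }
        if (bi > 0L) flush(bi)

        vl <- NA_real_
        if (length(valIdx)) {
            vl <- mean(vapply(valIdx, function(i)
                -log(max(modelForwardCached(features[[i]],
                         weights)$o[classIdx[i]], 1e-12)), numeric(1)))
            if (vl < bestVal - 1e-6) {
                bestVal <- vl; bestWeights <- weights; bad <- 0L
            } else bad <- bad + 1L
        }
        log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                     valLoss = vl))
        if (verbose)
            message(sprintf("epoch %d: loss %.4f val %.4f", ep,
                            mean(losses), vl))
        if (length(valIdx) && bad >= patience) break
    }
    if (length(valIdx)) weights <- bestWeights
    list(weights = weights, log = log)
}

#' Featurize a list of clips for training or evaluation
#'
#' STFT log-power frames, standardized per recording when the model
#' config requests it.
#'
#' @param clips list of [PCGClip-class].
#' @param config a [ModelConfig-class] (controls standardization).
#' @param frameLength,frameShift STFT framing in samples.
#' @return list of `N x (frameLength/2 + 1)` matrices.
#' @export
clipFeatures <- function(clips, config, frameLength = 512L,
                         frameShift = 256L) {
    lapply(clips, function(cl) {
        sp <- stftLogpower(cl, frameLength, frameShift)
        if (config@standardize) sp <- standardizeFrames(sp)
        sp@frames
    })
}

#' Murmur posterior scores for a list of feature matrices
#'
#' @param features list of feature matrices.
#' @param weights trained weights.
#' @return numeric vector of murmur-class posteriors in \[0, 1\].
#' @export
predictScores <- function(features, weights) {
    vapply(features, function(X)
        modelForwardCached(X, weights)$o[2], numeric(1))
}

#' Save / load a weight checkpoint
#'
#' The checkpoint is a single RDS archive of every named tensor; a JSON
#' sidecar (`<path>.json`) records the architecture and feature settings
#' so a checkpoint is self-describing.
#'
#' @param weights trained weights.
#' @param path checkpoint path.
#' @param featureSettings list of featurization settings to record.
#' @export
saveCheckpoint <- function(weights, path, featureSettings = list()) {
    saveRDS(weights, path)
    cfg <- weights$config
    meta <- list(
        architecture = cfg@architecture,
        convSpec = cfg@convSpec, rnnSpec = cfg@rnnSpec,
        denseSpec = cfg@denseSpec, standardize = cfg@standardize,
        dims = weights$dims, features = featureSettings,
        package_version = as.character(utils::packageVersion("tapcrnn")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
    if (!file.exists(path))
        stop("no such checkpoint: ", path)
    readRDS(path)
}
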