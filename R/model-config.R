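#' Construct a model configuration
#'
#' With only `architecture` given, returns the published architecture:
#' \describe{
#'   \item{cnn}{three conv layers — 32 filters 1x4, 32 filters 1x4,
#'     32 filters 4x4 — global average pooling over frames, then two
#'     512-wide dense layers.}
#'   \item{crnn}{two conv layers of 16 filters 1x4, two 256-wide LSTM
#'     layers, two 256-wide dense layers; classification from the last
#'     recurrent output h(N).}
#'   \item{tap_crnn}{the CRNN encoder plus the temporal attentive
#'     pooling block; classification from the concatenation of the
#'     attentive context and h(N).}
#' }
#' Kernel sizes are (time x frequency): a 1x4 kernel scans 4 adjacent
#' frequency bins within a frame, giving frequency-shift-invariant
#' features. Convolutions use same-padding and stride 1, so the
#' per-frame feature dimension is `257 * nFilters` of the last layer.
#'
#' @param architecture `"cnn"`, `"crnn"` or `"tap_crnn"`.
#' @param convSpec list of `(nFilters, kernelTime, kernelFreq)` triples.
#' @param rnnSpec integer vector of LSTM widths (empty for `"cnn"`).
#' @param denseSpec integer vector of dense hidden widths.
#' @param standardize apply per-recording feature standardization.
#' @return a [ModelConfig-class].
#' @export
modelConfig <- function(architecture = c("tap_crnn", "crnn", "cnn"),
                        convSpec = NULL, rnnSpec = NULL, denseSpec = NULL,
                        standardize = TRUE) {
    architecture <- match.arg(architecture)
    if (is.null(convSpec))
        convSpec <- switch(architecture,
            cnn = list(c(32L, 1L, 4L), c(32L, 1L, 4L), c(32L, 4L, 4L)),
            list(c(16L, 1L, 4L), c(16L, 1L, 4L)))
    convSpec <- lapply(convSpec, as.integer)
    if (is.null(rnnSpec))
        rnnSpec <- if (architecture == "cnn") integer(0) else c(256L, 256L)
    if (is.null(denseSpec))
        denseSpec <- if (architecture == "cnn") c(512L, 512L)
                     else c(256L, 256L)
    new("ModelConfig", architecture = architecture, convSpec = convSpec,
        rnnSpec = as.integer(rnnSpec), denseSpec = as.integer(denseSpec),
        nClasses = 2L, standardize = standardize)
}

glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model weights
#'
#' Glorot-uniform weight matrices, zero biases (LSTM forget-gate bias
#' 1). The TAP block's parameter shapes are asserted at construction:
#' `W_c` and `W_l` are `cnn_dim x cnn_dim`, `W_r` and `W_g` are
#' `rnn_dim x rnn_dim`, `u` and `b_global` have length
#' `cnn_dim + rnn_dim`, `v` and `b_l` length `cnn_dim`.
#'
#' @param config a [ModelConfig-class].
#' @param inputDim per-frame feature dimension (257 for the default
#'   512-sample frames).
#' @param seed integer seed for reproducible initialization.
#' @return a weight list; element `dims` records `inputDim`, `cnnDim`
#'   and `rnnDim`.
#' @export
initWeights <- function(config, inputDim = 257L, seed = 1L) {
    stopifnot(is(config, "ModelConfig"))
    validObject(config)
    set.seed(seed)
    inputDim <- as.integer(inputDim)

    conv <- list()
    cIn <- 1L
    for (l in config@convSpec) {
        nf <- l[1]; kt <- l[2]; kf <- l[3]
        conv[[length(conv) + 1L]] <- list(
            W = glorot(kt * kf * cIn, nf), b = numeric(nf),
            kt = kt, kf = kf, cIn = cIn, nf = nf)
        cIn <- nf
    }
    cnnDim <- inputDim * cIn

    lstm <- list()
    dIn <- cnnDim
    for (h in config@rnnSpec) {
        b <- numeric(4L * h)
        b[(h + 1L):(2L * h)] <- 1              # forget gate bias
        lstm[[length(lstm) + 1L]] <- list(
            Wx = glorot(dIn, 4L * h), Wh = glorot(h, 4L * h), b = b)
        dIn <- h
    }
    rnnDim <- if (length(config@rnnSpec)) dIn else 0L

    tap <- NULL
    if (config@architecture == "tap_crnn") {
        tap <- list(
            W_c = glorot(cnnDim, cnnDim),
            W_r = glorot(rnnDim, rnnDim),
            u = glorot(cnnDim + rnnDim, 1L)[, 1],
            b_global = numeric(cnnDim + rnnDim),
            W_l = glorot(cnnDim, cnnDim),
            b_l = numeric(cnnDim),
            v = glorot(cnnDim, 1L)[, 1],
            W_g = glorot(rnnDim, rnnDim))
        checkTapShapes(tap, cnnDim, rnnDim)
    }

    headIn <- switch(config@architecture,
        cnn = cnnDim, crnn = rnnDim, tap_crnn = cnnDim + rnnDim)
    dense <- list()
    dIn <- headIn
    for (w in config@denseSpec) {
        dense[[length(dense) + 1L]] <- list(W = glorot(dIn, w),
                                            b = numeric(w))
        dIn <- w
    }
    out <- list(W = glorot(dIn, config@nClasses),
                b = numeric(config@nClasses))

    list(conv = conv, lstm = lstm, tap = tap, dense = dense, out = out,
         config = config,
         dims = list(inputDim = inputDim, cnnDim = cnnDim,
                     rnnDim = rnnDim))
}

checkTapShapes <- function(tap, cnnDim, rnnDim) {
    stopifnot(
        identical(dim(tap$W_c), c(cnnDim, cnnDim)),
        identical(dim(tap$W_r), c(rnnDim, rnnDim)),
        length(tap$u) == cnnDim + rnnDim,
        length(tap$b_global) == cnnDim + rnnDim,
        identical(dim(tap$W_l), c(cnnDim, cnnDim)),
        length(tap$b_l) == cnnDim,
        length(tap$v) == cnnDim,
        identical(dim(tap$W_g), c(rnnDim, rnnDim)))
    invisible(TRUE)
}
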