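# Forward computations. Every operation keeps the caches needed by the
# analytic backward pass in model-backward.R; public wrappers expose the
# plain results.

sigmoid <- function(x) 1 / (1 + exp(-x))

# im2col index cache: same shapes recur for every clip of a cohort.
.idxCache <- new.env(parent = emptyenv())

convIm2colIdx <- function(N, K, C, kt, kf) {
    key <- paste(N, K, C, kt, kf, sep = "_")
    got <- .idxCache[[key]]
    if (!is.null(got)) return(got)
    Np <- N + kt - 1L
    Kp <- K + kf - 1L
    n <- rep(seq_len(N), times = K)
    k <- rep(seq_len(K), each = N)
    off <- expand.grid(it = 0:(kt - 1L), jf = 0:(kf - 1L),
                       c = 0:(C - 1L))
    idx <- matrix(0L, N * K, nrow(off))
    for (j in seq_len(nrow(off)))
        idx[, j] <- (n + off$it[j]) +
            Np * ((k + off$jf[j] - 1L) + Kp * off$c[j])
    res <- list(idx = idx, Np = Np, Kp = Kp,
                pt = (kt - 1L) %/% 2L, pf = (kf - 1L) %/% 2L)
    .idxCache[[key]] <- res
    res
}

convLayerForward <- function(A, layer) {
    d <- dim(A)                     # N x K x C
    N <- d[1]; K <- d[2]; C <- d[3]
    if (C != layer$cIn)
        stop("conv layer expects ", layer$cIn, " input channels, got ", C)
    ic <- convIm2colIdx(N, K, C, layer$kt, layer$kf)
    Ap <- array(0, c(ic$Np, ic$Kp, C))
    Ap[ic$pt + seq_len(N), ic$pf + seq_len(K), ] <- A
    P <- matrix(Ap[as.vector(ic$idx)], nrow(ic$idx), ncol(ic$idx))
    Z <- tanh(sweep(P %*% layer$W, 2, layer$b, "+"))
    out <- array(Z, c(N, K, layer$nf))
    list(out = out, P = P, Z = Z, ic = ic, dimIn = d)
}

#' Convolutional frame encoder
#'
#' Applies the configured stack of tanh convolutional layers
#' (same-padding, stride 1) to the spectrogram and flattens frequency
#' and channels per frame, giving the per-frame features
#' `Y = [y(1), ..., y(N)]` of dimension `cnn_dim = nBins * nFilters`.
#'
#' @param X numeric matrix `N x nBins` (a spectrogram's frames) or a
#'   [Spectrogram-class].
#' @param weights result of [initWeights()].
#' @return numeric matrix `N x cnn_dim`.
#' @export
convEncode <- function(X, weights) {
    if (is(X, "Spectrogram")) X <- X@frames
    convForward(X, weights$conv)$Y
}

convForward <- function(X, convLayers) {
    if (nrow(X) == 0) stop("empty input")
    A <- array(X, c(dim(X), 1L))
    caches <- vector("list", length(convLayers))
    for (i in seq_along(convLayers)) {
        caches[[i]] <- convLayerForward(A, convLayers[[i]])
        A <- caches[[i]]$out
    }
    d <- dim(A)
    list(Y = matrix(A, d[1], d[2] * d[3]), caches = caches,
         outDim = d)
}

lstmLayerForward <- function(Y, layer) {
    N <- nrow(Y)
    H <- nrow(layer$Wh)
    Xp <- Y %*% layer$Wx
    G <- matrix(0, N, 4L * H)        # post-activation gates i,f,o,g
    Cc <- matrix(0, N, H); Hh <- matrix(0, N, H); Tc <- matrix(0, N, H)
    h <- numeric(H); cc <- numeric(H)
    i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
    for (t in seq_len(N)) {
        a <- Xp[t, ] + as.vector(h %*% layer$Wh) + layer$b
        gi <- sigmoid(a[i1]); gf <- sigmoid(a[i2])
        go <- sigmoid(a[i3]); gg <- tanh(a[i4])
        cc <- gf * cc + gi * gg
        tc <- tanh(cc)
        h <- go * tc
        G[t, ] <- c(gi, gf, go, gg)
        Cc[t, ] <- cc; Tc[t, ] <- tc; Hh[t, ] <- h
    }
    list(H = Hh, G = G, Cc = Cc, Tc = Tc, Xin = Y)
}

#' Recurrent (LSTM) encoder
#'
#' Standard stacked LSTM over the per-frame convolutional features.
#'
#' @param Y numeric matrix `N x cnn_dim` from [convEncode()].
#' @param weights result of [initWeights()] (a crnn or tap_crnn model).
#' @return list with `H` (`N x rnn_dim` recurrent outputs) and `hN`
#'   (the output at the last time step, `H[N, ]`).
#' @export
recurrentEncode <- function(Y, weights) {
    if (!length(weights$lstm)) stop("model has no recurrent layers")
    fw <- lstmForward(Y, weights$lstm)
    list(H = fw$H, hN = fw$hN)
}

lstmForward <- function(Y, lstmLayers) {
    caches <- vector("list", length(lstmLayers))
    A <- Y
    for (i in seq_along(lstmLayers)) {
        caches[[i]] <- lstmLayerForward(A, lstmLayers[[i]])
        A <- caches[[i]]$H
    }
    list(H = A, hN = A[nrow(A), ], caches = caches)
}

softmaxVec <- function(e) {
    e <- e - max(e)
    x <- exp(e)
    x / sum(x)
}

#' Global attention weights (temporal attentive pooling, step 1)
#'
#' Builds the global attentive vector
#' `c(n) = [W_c y(n); W_r h(N)]` and returns
#' `alpha_global(n) = softmax_n(u' tanh(c(n) + b_global))`, a
#' distribution over the N frames of the clip (softmax taken across
#' frames; a per-frame softmax of a scalar would be identically 1).
#'
#' @param Y `N x cnn_dim` convolutional features.
#' @param hN final recurrent output (`rnn_dim` vector).
#' @param tap the TAP parameter list (`weights$tap`).
#' @return nonnegative length-N vector summing to 1.
#' @export
globalAttention <- function(Y, hN, tap) {
    tapGlobalForward(Y, hN, tap)$alpha
}

tapGlobalForward <- function(Y, hN, tap) {
    D <- ncol(Y)
    if (ncol(tap$W_c) != D)
        stop("W_c has ", ncol(tap$W_c), " columns but cnn features have ",
             D, " dimensions")
    if (ncol(tap$W_r) != length(hN))
        stop("W_r has ", ncol(tap$W_r), " columns but hN has length ",
             length(hN))
    uc <- tap$u[seq_len(D)]
    ur <- tap$u[-seq_len(D)]
    bc <- tap$b_global[seq_len(D)]
    br <- tap$b_global[-seq_len(D)]
    C1 <- Y %*% t(tap$W_c)
    T1 <- tanh(sweep(C1, 2, bc, "+"))
    r <- as.vector(tap$W_r %*% hN)
    t2 <- tanh(r + br)
    e <- as.vector(T1 %*% uc) + sum(ur * t2)
    alpha <- softmaxVec(e)
    list(alpha = alpha, T1 = T1, t2 = t2, uc = uc, ur = ur, r = r)
}

#' Local attention weights (temporal attentive pooling, step 2)
#'
#' Scales each frame feature by its global weight,
#' `z(n) = alpha_global(n) y(n)`, and returns
#' `beta_local(n) = softmax_n(v' tanh(W_l z(n) + b_l))`.
#'
#' @param Y `N x cnn_dim` convolutional features.
#' @param alphaGlobal output of [globalAttention()].
#' @param tap the TAP parameter list.
#' @return nonnegative length-N vector summing to 1.
#' @export
localAttention <- function(Y, alphaGlobal, tap) {
    tapLocalForward(Y, alphaGlobal, tap)$beta
}

tapLocalForward <- function(Y, alpha, tap) {
    if (ncol(tap$W_l) != ncol(Y))
        stop("W_l has ", ncol(tap$W_l), " columns but cnn features have ",
             ncol(Y), " dimensions")
    Z <- alpha * Y
    M <- tanh(sweep(Z %*% t(tap$W_l), 2, tap$b_l, "+"))
    s <- as.vector(M %*% tap$v)
    beta <- softmaxVec(s)
    list(beta = beta, Z = Z, M = M)
}

#' Attentive context vector
#'
#' `f_hat = (1/N) sum_n alpha_global(n) beta_local(n) y(n)`: the mean of
#' the doubly-weighted convolutional features.
#'
#' @param Y `N x cnn_dim` convolutional features.
#' @param alphaGlobal,betaLocal the two attention weight vectors.
#' @return numeric vector of length `cnn_dim`.
#' @export
attentiveContext <- function(Y, alphaGlobal, betaLocal) {
    stopifnot(length(alphaGlobal) == nrow(Y),
              length(betaLocal) == nrow(Y))
    as.vector(crossprod(Y, alphaGlobal * betaLocal)) / nrow(Y)
}

denseForward <- function(s, weights) {
    acts <- list()
    a <- s
    for (l in weights$dense) {
        a <- tanh(as.vector(a %*% l$W) + l$b)
        acts[[length(acts) + 1L]] <- a
    }
    logits <- as.vector(a %*% weights$out$W) + weights$out$b
    o <- softmaxVec(logits)
    list(o = o, acts = acts, sIn = s)
}

#' Dense classification head
#'
#' Concatenates the attentive context with the transformed last
#' recurrent output, `s = [f_hat; W_g h(N)]`, applies the tanh dense
#' layers and a final linear layer, and returns the softmax class
#' posterior (entry 1 = normal, entry 2 = murmur).
#'
#' @param fHat attentive context from [attentiveContext()].
#' @param hN final recurrent output.
#' @param weights result of [initWeights()] (tap_crnn).
#' @return posterior vector of length 2, nonnegative, summing to 1.
#' @export
classifyHead <- function(fHat, hN, weights) {
    s <- c(fHat, as.vector(weights$tap$W_g %*% hN))
    denseForward(s, weights)$o
}

#' Full forward pass of a classifier
#'
#' Runs the architecture selected in the weights' [ModelConfig-class]:
#' \itemize{
#'   \item `cnn`: conv stack, global average over frames, dense head.
#'   \item `crnn`: conv stack, LSTM stack, dense head on `h(N)`.
#'   \item `tap_crnn`: conv + LSTM, temporal attentive pooling, dense
#'     head on `[f_hat; W_g h(N)]`; additionally returns the attention
#'     trace with `epl(n) = alpha_global(n) * beta_local(n)`.
#' }
#'
#' @param X `N x inputDim` feature matrix or [Spectrogram-class]
#'   (standardized per the config if it is a `Spectrogram`).
#' @param weights result of [initWeights()].
#' @return list with `posterior` (length-2), and for tap_crnn `alpha`,
#'   `beta` and `epl` (length-N each).
#' @export
modelForward <- function(X, weights) {
    fw <- modelForwardCached(prepInput(X, weights$config), weights)
    out <- list(posterior = fw$o)
    if (!is.null(fw$alpha)) {
        out$alpha <- fw$alpha
        out$beta <- fw$beta
        out$epl <- fw$alpha * fw$beta
    }
    out
}

prepInput <- function(X, config) {
    if (is(X, "Spectrogram")) {
        if (config@standardize) X <- standardizeFrames(X)
        X <- X@frames
    }
    X
}

modelForwardCached <- function(X, weights) {
    arch <- weights$config@architecture
    cf <- convForward(X, weights$conv)
    Y <- cf$Y
    if (arch == "cnn") {
        pooled <- colMeans(Y)
        df <- denseForward(pooled, weights)
        return(list(o = df$o, conv = cf, dense = df, pooled = pooled))
    }
    lf <- lstmForward(Y, weights$lstm)
    hN <- lf$hN
    if (arch == "crnn") {
        df <- denseForward(hN, weights)
        return(list(o = df$o, conv = cf, lstm = lf, dense = df))
    }
    ga <- tapGlobalForward(Y, hN, weights$tap)
    la <- tapLocalForward(Y, ga$alpha, weights$tap)
    fHat <- attentiveContext(Y, ga$alpha, la$beta)
    s <- c(fHat, as.vector(weights$tap$W_g %*% hN))
    df <- denseForward(s, weights)
    list(o = df$o, conv = cf, lstm = lf, global = ga, local = la,
         fHat = fHat, dense = df, alpha = ga$alpha, beta = la$beta,
         Y = Y, hN = hN)
}
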