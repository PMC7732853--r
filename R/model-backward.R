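# Analytic gradients for every architecture. The layout of the returned
# gradient list mirrors the weight list so the optimizer can walk both
# in parallel. All gradients are verified against central finite
# differences in the test suite.

convLayerBackward <- function(dOut, cache, layer, wantInputGrad = TRUE) {
    d <- dim(dOut)
    N <- d[1]; K <- d[2]
    dZ <- matrix(dOut, N * K, layer$nf) * (1 - cache$Z^2)
    dW <- crossprod(cache$P, dZ)
    db <- colSums(dZ)
    dA <- NULL
    if (wantInputGrad) {
        dP <- dZ %*% t(layer$W)
        ic <- cache$ic
        dAp <- numeric(ic$Np * ic$Kp * layer$cIn)
        # for a fixed patch offset the map output -> padded cell is
        # injective, so a plain indexed add per column is exact
        for (j in seq_len(ncol(ic$idx))) {
            ii <- ic$idx[, j]
            dAp[ii] <- dAp[ii] + dP[, j]
        }
        dAp <- array(dAp, c(ic$Np, ic$Kp, layer$cIn))
        dA <- dAp[ic$pt + seq_len(cache$dimIn[1]),
                  ic$pf + seq_len(cache$dimIn[2]), , drop = FALSE]
    }
    list(dW = dW, db = db, dA = dA)
}

convBackward <- function(dY, convFw, convLayers) {
    d <- convFw$outDim
    dA <- array(dY, d)
    grads <- vector("list", length(convLayers))
    for (i in rev(seq_along(convLayers))) {
        g <- convLayerBackward(dA, convFw$caches[[i]], convLayers[[i]],
                               wantInputGrad = i > 1L)
        grads[[i]] <- list(W = g$dW, b = g$db)
        dA <- g$dA
    }
    grads
}

lstmLayerBackward <- function(dH, cache, layer) {
    N <- nrow(dH)
    H <- nrow(layer$Wh)
    i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
    dA <- matrix(0, N, 4L * H)
    dhNext <- numeric(H)
    dcNext <- numeric(H)
    for (t in N:1) {
        gi <- cache$G[t, i1]; gf <- cache$G[t, i2]
        go <- cache$G[t, i3]; gg <- cache$G[t, i4]
        tc <- cache$Tc[t, ]
        cPrev <- if (t > 1L) cache$Cc[t - 1L, ] else numeric(H)
        dh <- dH[t, ] + dhNext
        dgo <- dh * tc
        dc <- dcNext + dh * go * (1 - tc^2)
        dgi <- dc * gg
        dgg <- dc * gi
        dgf <- dc * cPrev
        dcNext <- dc * gf
        da <- c(dgi * gi * (1 - gi), dgf * gf * (1 - gf),
                dgo * go * (1 - go), dgg * (1 - gg^2))
        dA[t, ] <- da
        dhNext <- as.vector(layer$Wh %*% da)
    }
    Hprev <- rbind(numeric(H), cache$H[-N, , drop = FALSE])
    list(dWx = crossprod(cache$Xin, dA),
         dWh = crossprod(Hprev, dA),
         db = colSums(dA),
         dX = dA %*% t(layer$Wx))
}

lstmBackward <- function(dH, lstmFw, lstmLayers) {
    grads <- vector("list", length(lstmLayers))
    for (i in rev(seq_along(lstmLayers))) {
        g <- lstmLayerBackward(dH, lstmFw$caches[[i]], lstmLayers[[i]])
        grads[[i]] <- list(Wx = g$dWx, Wh = g$dWh, b = g$db)
        dH <- g$dX
    }
    list(grads = grads, dY = dH)
}

denseBackward <- function(dLogits, denseFw, weights) {
    nD <- length(weights$dense)
    aPrev <- if (nD) denseFw$acts[[nD]] else denseFw$sIn
    gOut <- list(W = outer(aPrev, dLogits), b = dLogits)
    da <- as.vector(weights$out$W %*% dLogits)
    gDense <- vector("list", nD)
    if (nD) for (i in nD:1) {
        a <- denseFw$acts[[i]]
        dz <- da * (1 - a^2)
        aPrev <- if (i > 1L) denseFw$acts[[i - 1L]] else denseFw$sIn
        gDense[[i]] <- list(W = outer(aPrev, dz), b = dz)
        da <- as.vector(weights$dense[[i]]$W %*% dz)
    }
    list(out = gOut, dense = gDense, dS = da)
}

# Backward through the TAP block (Eqs. of the attentive pooling).
# Inputs: dfHat (cnn_dim), the cached forward pieces; returns gradients
# for all TAP tensors except W_g plus dY and dhN contributions.
tapBackward <- function(dfHat, fw) {
    Y <- fw$Y
    N <- nrow(Y)
    ga <- fw$global
    la <- fw$local
    alpha <- ga$alpha
    beta <- la$beta

    w <- alpha * beta
    dw <- as.vector(Y %*% dfHat) / N
    dY <- (w / N) %o% dfHat

    dalpha <- beta * dw
    dbeta <- alpha * dw

    # beta = softmax(s), s = M v, M = tanh(Z W_l' + b_l), Z = alpha * Y
    ds <- beta * (dbeta - sum(beta * dbeta))
    dv <- as.vector(crossprod(la$M, ds))
    dM <- ds %o% fw$tapv
    dL <- dM * (1 - la$M^2)
    dW_l <- crossprod(dL, la$Z)
    db_l <- colSums(dL)
    dZ <- dL %*% fw$tapW_l
    dalpha <- dalpha + rowSums(dZ * Y)
    dY <- dY + alpha * dZ

    # alpha = softmax(e), e = T1 uc + const(ur, t2)
    de <- alpha * (dalpha - sum(alpha * dalpha))
    duc <- as.vector(crossprod(ga$T1, de))
    dT1 <- de %o% ga$uc
    dC1 <- dT1 * (1 - ga$T1^2)
    dW_c <- crossprod(dC1, Y)
    dbc <- colSums(dC1)
    dY <- dY + dC1 %*% fw$tapW_c

    # recurrent half of c(n): identical for every n, so only the total
    # softmax mass sum(de) (analytically zero) reaches it
    deTot <- sum(de)
    dur <- deTot * ga$t2
    dt2 <- deTot * ga$ur
    dr <- dt2 * (1 - ga$t2^2)
    dW_r <- dr %o% fw$hN
    dbr <- dr
    dhN <- as.vector(crossprod(fw$tapW_r, dr))

    list(W_c = dW_c, W_r = dW_r, u = c(duc, dur),
         b_global = c(dbc, dbr), W_l = dW_l, b_l = db_l, v = dv,
         dY = dY, dhN = dhN)
}

#' Loss and gradients for one clip
#'
#' Cross-entropy loss of the softmax posterior against the clip label
#' and its analytic gradient with respect to every weight tensor.
#'
#' @param X `N x inputDim` feature matrix (already standardized).
#' @param classIndex 1 (normal) or 2 (murmur).
#' @param weights result of [initWeights()].
#' @return list with `loss`, `posterior`, and `grads` mirroring the
#'   weight list layout.
#' @export
lossAndGradients <- function(X, classIndex, weights) {
    fw <- modelForwardCached(X, weights)
    # stash tap tensors the backward needs without re-closing over weights
    if (weights$config@architecture == "tap_crnn") {
        fw$tapv <- weights$tap$v
        fw$tapW_l <- weights$tap$W_l
        fw$tapW_c <- weights$tap$W_c
        fw$tapW_r <- weights$tap$W_r
    }
    o <- fw$o
    loss <- -log(max(o[classIndex], 1e-12))
    dLogits <- o
    dLogits[classIndex] <- dLogits[classIndex] - 1

    db <- denseBackward(dLogits, fw$dense, weights)
    arch <- weights$config@architecture
    grads <- list(conv = NULL, lstm = list(), tap = NULL,
                  dense = db$dense, out = db$out)

    if (arch == "cnn") {
        N <- nrow(X)
        dY <- matrix(rep(db$dS / N, each = N), N)
        grads$conv <- convBackward(dY, fw$conv, weights$conv)
        return(list(loss = loss, posterior = o, grads = grads))
    }

    if (arch == "crnn") {
        dhN <- db$dS
        dY <- NULL
        tapG <- NULL
    } else {
        D <- length(fw$fHat)
        dfHat <- db$dS[seq_len(D)]
        dq <- db$dS[-seq_len(D)]
        tapG <- tapBackward(dfHat, fw)
        tapG$W_g <- dq %o% fw$hN
        dhN <- tapG$dhN + as.vector(crossprod(weights$tap$W_g, dq))
        dY <- tapG$dY
    }

    N <- nrow(fw$lstm$H)
    dH <- matrix(0, N, ncol(fw$lstm$H))
    dH[N, ] <- dhN
    lb <- lstmBackward(dH, fw$lstm, weights$lstm)
    grads$lstm <- lb$grads
    dYtot <- if (is.null(dY)) lb$dY else dY + lb$dY
    grads$conv <- convBackward(dYtot, fw$conv, weights$conv)
    if (!is.null(tapG)) {
        tapG$dY <- NULL; tapG$dhN <- NULL
        grads$tap <- tapG[c("W_c", "W_r", "u", "b_global", "W_l", "b_l",
                            "v", "W_g")]
    }
    list(loss = loss, posterior = o, grads = grads)
}
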