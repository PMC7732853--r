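# Classifier architectures and the temporal attentive pooling block:
# shape contracts, softmax normalization, degenerate cases, loop-oracle
# equivalence, permutation sensitivity.

test_that("attention weights match the per-frame loop oracle on 50
           random small instances", {
    for (s in 1:50) {
        inst <- randomTapInstance(s)
        alpha <- globalAttention(inst$Y, inst$hN, inst$tap)
        beta <- localAttention(inst$Y, alpha, inst$tap)
        fhat <- attentiveContext(inst$Y, alpha, beta)
        orc <- oracleTap(inst$Y, inst$hN, inst$tap)
        expect_equal(alpha, orc$alpha, tolerance = 1e-9)
        expect_equal(beta, orc$beta, tolerance = 1e-9)
        expect_equal(fhat, orc$fhat, tolerance = 1e-9)
        expect_equal(sum(alpha), 1, tolerance = 1e-12)
        expect_equal(sum(beta), 1, tolerance = 1e-12)
        expect_true(all(alpha >= 0) && all(beta >= 0))
    }
})

test_that("a single frame degenerates to alpha = beta = EPL = 1", {
    inst <- randomTapInstance(99)
    Y1 <- inst$Y[1, , drop = FALSE]
    alpha <- globalAttention(Y1, inst$hN, inst$tap)
    expect_equal(alpha, 1)
    beta <- localAttention(Y1, alpha, inst$tap)
    expect_equal(beta, 1)
    expect_equal(attentiveContext(Y1, alpha, beta), Y1[1, ])
})

test_that("hand-set two-frame instance matches a direct tanh/softmax
           computation", {
    Y <- rbind(c(0.3, -0.2), c(-0.1, 0.5))
    hN <- c(0.2, -0.4)
    tap <- list(W_c = diag(2), W_r = diag(2), u = rep(1, 4),
                b_global = rep(0, 4), W_l = diag(2), b_l = c(0, 0),
                v = c(1, 1), W_g = diag(2))
    e <- c(sum(tanh(c(Y[1, ], hN))), sum(tanh(c(Y[2, ], hN))))
    expected <- exp(e) / sum(exp(e))
    expect_equal(globalAttention(Y, hN, tap), expected,
                 tolerance = 1e-12)
})

test_that("uniform alpha with identical frames gives uniform beta and
           the stated attentive-context identities", {
    y0 <- c(0.4, -0.3, 0.1)
    Y <- rbind(y0, y0)
    inst <- randomTapInstance(7, maxDim = 3L)
    tap <- inst$tap
    tap$W_l <- matrix(rnorm(9), 3, 3)
    tap$b_l <- rnorm(3)
    tap$v <- rnorm(3)
    beta <- localAttention(Y, c(0.5, 0.5), tap)
    expect_equal(beta, c(0.5, 0.5), tolerance = 1e-12)
    expect_equal(attentiveContext(Y, c(0.5, 0.5), c(0.5, 0.5)),
                 0.25 * y0, tolerance = 1e-12)
    expect_equal(attentiveContext(Y, c(1, 0), c(1, 0)), y0 / 2,
                 tolerance = 1e-12)
})

test_that("conv encoder preserves frame count and flattens to
           nBins * nFilters (published CRNN spec gives 4112)", {
    cfg <- modelConfig("crnn")       # 2 x 16 filters, 1x4
    w <- initWeights(cfg, inputDim = 257L, seed = 1)
    X <- matrix(rnorm(3 * 257), 3, 257)
    Y <- convEncode(X, w)
    expect_equal(dim(Y), c(3L, 4112L))
    expect_equal(dim(convEncode(X[1, , drop = FALSE], w)), c(1L, 4112L))
    # zero input with zero biases propagates zeros through tanh
    expect_equal(convEncode(matrix(0, 2, 257), w),
                 matrix(0, 2, 4112))
})

test_that("recurrent encoder has the published width and is
           deterministic", {
    cfg <- modelConfig("crnn")
    w <- initWeights(cfg, inputDim = 257L, seed = 1)
    Y <- convEncode(matrix(rnorm(2 * 257), 2, 257), w)
    r1 <- recurrentEncode(Y, w)
    r2 <- recurrentEncode(Y, w)
    expect_length(r1$hN, 256L)
    expect_identical(r1$H, r2$H)
    expect_equal(r1$hN, r1$H[nrow(r1$H), ])
    expect_equal(recurrentEncode(Y[1, , drop = FALSE], w)$hN,
                 recurrentEncode(Y[1, , drop = FALSE], w)$H[1, ])
})

test_that("posteriors are distributions; all-zero weights give
           (0.5, 0.5)", {
    cfg <- tinyTapConfig()
    w <- initWeights(cfg, inputDim = 6L, seed = 2)
    X <- matrix(rnorm(4 * 6), 4, 6)
    o <- modelForward(X, w)$posterior
    expect_equal(sum(o), 1, tolerance = 1e-12)
    expect_true(all(o >= 0))
    wz <- w
    wz$out$W[] <- 0; wz$out$b[] <- 0
    expect_equal(modelForward(X, wz)$posterior, c(0.5, 0.5),
                 tolerance = 1e-12)
})

test_that("tap_crnn forward returns the EPL trace with the softmax
           normalizations", {
    cfg <- tinyTapConfig()
    w <- initWeights(cfg, inputDim = 6L, seed = 3)
    X <- matrix(rnorm(7 * 6), 7, 6)
    fw <- modelForward(X, w)
    expect_equal(fw$epl, fw$alpha * fw$beta)
    expect_equal(sum(fw$alpha), 1, tolerance = 1e-9)
    expect_equal(sum(fw$beta), 1, tolerance = 1e-9)
    expect_true(all(fw$epl >= 0) && sum(fw$epl) <= 1 + 1e-12)
    # single-frame clip: EPL = [1]
    fw1 <- modelForward(X[1, , drop = FALSE], w)
    expect_equal(fw1$epl, 1)
})

test_that("with a zeroed attentive context and identity W_g, tap_crnn
           reduces to the crnn with shared weights", {
    crnnCfg <- tinyCrnnConfig()
    tapCfg <- tinyTapConfig()
    wc <- initWeights(crnnCfg, inputDim = 6L, seed = 4)
    wt <- initWeights(tapCfg, inputDim = 6L, seed = 5)
    wt$conv <- wc$conv
    wt$lstm <- wc$lstm
    wt$tap$W_g <- diag(4)
    D <- wt$dims$cnnDim
    # dense head: zero block for f_hat, crnn weights for W_g h(N)
    wt$dense[[1]]$W <- rbind(matrix(0, D, 4), wc$dense[[1]]$W)
    wt$dense[[1]]$b <- wc$dense[[1]]$b
    wt$out <- wc$out
    X <- matrix(rnorm(5 * 6), 5, 6)
    expect_equal(modelForward(X, wt)$posterior,
                 modelForward(X, wc)$posterior, tolerance = 1e-12)
})

test_that("permuting frames changes hN (order-aware recurrence)", {
    cfg <- tinyCrnnConfig()
    w <- initWeights(cfg, inputDim = 6L, seed = 6)
    set.seed(8)
    X <- matrix(rnorm(6 * 6), 6, 6)
    Y <- convEncode(X, w)
    h1 <- recurrentEncode(Y, w)$hN
    h2 <- recurrentEncode(Y[c(3, 1, 6, 2, 5, 4), ], w)$hN
    expect_gt(max(abs(h1 - h2)), 1e-6)
})

test_that("shape mismatches raise errors naming the offending matrix", {
    inst <- randomTapInstance(12)
    bad <- inst$tap
    bad$W_c <- matrix(0, inst$D + 1, inst$D + 1)
    expect_error(globalAttention(inst$Y, inst$hN, bad), "W_c")
    bad2 <- inst$tap
    bad2$W_l <- matrix(0, inst$D + 1, inst$D + 1)
    alpha <- rep(1 / inst$N, inst$N)
    expect_error(localAttention(inst$Y, alpha, bad2), "W_l")
})
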