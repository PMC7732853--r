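# Independent oracles. These re-derive expected values by the most
# direct route available (explicit per-frame loops, naive DFT
# summation, FFT band masking, exhaustive pair enumeration) and never
# call the package's implementation path.

# Per-frame loop implementation of the attentive pooling equations.
oracleTap <- function(Y, hN, tap) {
    N <- nrow(Y)
    D <- ncol(Y)
    e <- numeric(N)
    for (n in seq_len(N)) {
        cn <- c(as.vector(tap$W_c %*% Y[n, ]),
                as.vector(tap$W_r %*% hN))
        e[n] <- sum(tap$u * tanh(cn + tap$b_global))
    }
    a <- exp(e - max(e)); alpha <- a / sum(a)
    s <- numeric(N)
    for (n in seq_len(N)) {
        zn <- alpha[n] * Y[n, ]
        s[n] <- sum(tap$v * tanh(as.vector(tap$W_l %*% zn) + tap$b_l))
    }
    b <- exp(s - max(s)); beta <- b / sum(b)
    fhat <- numeric(D)
    for (n in seq_len(N))
        fhat <- fhat + alpha[n] * beta[n] * Y[n, ]
    list(alpha = alpha, beta = beta, fhat = fhat / N)
}

# Naive O(L^2) DFT of one windowed frame; returns log-power of the
# first L/2 + 1 bins.
oracleDftLogpower <- function(frame, logFloor = 1e-10) {
    L <- length(frame)
    nk <- L %/% 2 + 1
    out <- numeric(nk)
    for (k in seq_len(nk)) {
        ang <- -2 * pi * (k - 1) * (0:(L - 1)) / L
        re <- sum(frame * cos(ang))
        im <- sum(frame * sin(ang))
        out[k] <- log(max(re^2 + im^2, logFloor))
    }
    out
}

# Windowed-periodogram band power of one contiguous sample stretch
# (independent of the Butterworth filter used by the synthesizer).
oracleBandPower <- function(xw, rate, band) {
    L <- length(xw)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)
    sp <- stats::fft(xw * w)
    f <- (seq_len(L) - 1) * rate / L
    keep <- f >= band[1] & f <= band[2]
    sum(Mod(sp[keep])^2) / L
}

# Murmur-band energy contrast: log ratio of mean in-band power in
# mid-systole to mean in-band power in mid-diastole. The first 80 ms
# after S1/S2 onsets and a 15 ms pre-onset margin are excluded so the
# broadband heart-sound transients do not leak into either window.
oracleContrast <- function(clip, band = c(100, 600)) {
    x <- samples(clip)
    rate <- sampleRate(clip)
    iv <- systolicIntervals(clip)
    win <- function(t0, t1) {
        i0 <- max(1L, round(t0 * rate) + 1L)
        i1 <- min(length(x), round(t1 * rate))
        if (i1 - i0 > 32L) x[i0:i1] else NULL
    }
    eIn <- 0; nIn <- 0; eOut <- 0; nOut <- 0
    for (k in seq_len(nrow(iv))) {
        xs <- win(iv[k, 1] + 0.08, iv[k, 2] - 0.015)
        if (!is.null(xs)) {
            eIn <- eIn + oracleBandPower(xs, rate, band)
            nIn <- nIn + length(xs)
        }
        if (k < nrow(iv)) {
            xd <- win(iv[k, 2] + 0.08, iv[k + 1, 1] - 0.015)
            if (!is.null(xd)) {
                eOut <- eOut + oracleBandPower(xd, rate, band)
                nOut <- nOut + length(xd)
            }
        }
    }
    log((eIn / nIn) / (eOut / nOut))
}

# Exhaustive pairwise ranking probability with half-credit ties.
oracleRankScore <- function(epl, mask) {
    num <- 0; den <- 0
    for (i in which(mask == 1L)) for (j in which(mask == 0L)) {
        den <- den + 1
        if (epl[i] > epl[j]) num <- num + 1
        else if (epl[i] == epl[j]) num <- num + 0.5
    }
    num / den
}

# Brute-force confusion recount.
oracleCounts <- function(truth, predicted) {
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
        if (truth[i] == "murmur") {
            if (predicted[i] == "murmur") tp <- tp + 1 else fn <- fn + 1
        } else {
            if (predicted[i] == "normal") tn <- tn + 1 else fp <- fp + 1
        }
    }
    list(Tp = tp, Tn = tn, Fp = fp, Fn = fn)
}

# Central finite-difference gradient of the clip loss w.r.t. one tensor.
numericGrad <- function(X, classIndex, weights, get, set, eps = 1e-5) {
    th <- get(weights)
    g <- th
    for (i in seq_along(th)) {
        tp <- th; tp[i] <- th[i] + eps
        tm <- th; tm[i] <- th[i] - eps
        g[i] <- (lossAndGradients(X, classIndex, set(weights, tp))$loss -
                 lossAndGradients(X, classIndex, set(weights, tm))$loss) /
                (2 * eps)
    }
    g
}

relErr <- function(a, b) {
    na <- sqrt(sum(as.vector(a)^2))
    nb <- sqrt(sum(as.vector(b)^2))
    if (nb < 1e-10 && na < 1e-10) return(0)
    sqrt(sum((as.vector(a) - as.vector(b))^2)) / max(nb, 1e-8)
}
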