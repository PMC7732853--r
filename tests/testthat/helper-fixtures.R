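# Shared fixtures: tiny model configurations and clip builders used
# across test files. Everything is generated in code; no binary data.

tinyTapConfig <- function() {
    modelConfig("tap_crnn", convSpec = list(c(2L, 1L, 3L)),
                rnnSpec = 4L, denseSpec = 4L, standardize = FALSE)
}

tinyCrnnConfig <- function() {
    modelConfig("crnn", convSpec = list(c(2L, 1L, 3L)),
                rnnSpec = 4L, denseSpec = 4L, standardize = FALSE)
}

tinyCnnConfig <- function() {
    modelConfig("cnn", convSpec = list(c(2L, 1L, 3L), c(2L, 2L, 2L)),
                denseSpec = 4L, standardize = FALSE)
}

# Desk-scale architectures for the synthetic end-to-end experiments:
# same layer structure as the published models, reduced widths so a
# training run fits a single CPU.
deskTapConfig <- function() {
    modelConfig("tap_crnn", convSpec = list(c(2L, 1L, 4L), c(2L, 1L, 4L)),
                rnnSpec = c(24L, 24L), denseSpec = c(24L, 24L))
}

deskCrnnConfig <- function() {
    modelConfig("crnn", convSpec = list(c(2L, 1L, 4L), c(2L, 1L, 4L)),
                rnnSpec = c(24L, 24L), denseSpec = c(24L, 24L))
}

deskCnnConfig <- function() {
    modelConfig("cnn",
                convSpec = list(c(2L, 1L, 4L), c(2L, 1L, 4L),
                                c(2L, 4L, 4L)),
                denseSpec = c(24L, 24L))
}

# A short synthetic clip for feature / EPL tests (2 s keeps STFT small).
shortClip <- function(label = "murmur", seed = 11, duration = 2,
                      snr = 10) {
    synthesizeClip(synthConfig(duration = duration, seed = seed,
                               murmurSnrDb = snr), label)
}

# Manifest without any clips, for split-protocol tests.
fakeManifest <- function(nMurmur, nNormal, clipsPerSubject = 10L) {
    subj <- c(sprintf("M%02d", seq_len(nMurmur)),
              sprintf("N%02d", seq_len(nNormal)))
    lab <- rep(c("murmur", "normal"), c(nMurmur, nNormal))
    data.frame(
        path = paste0(rep(subj, each = clipsPerSubject), "_",
                      seq_len(clipsPerSubject), ".wav"),
        subject_id = rep(subj, each = clipsPerSubject),
        site = rep_len(c("aortic", "pulmonic", "erb", "tricuspid",
                         "mitral"), nMurmur * clipsPerSubject +
                       nNormal * clipsPerSubject),
        label = rep(lab, each = clipsPerSubject),
        stringsAsFactors = FALSE)
}

randomTapInstance <- function(seed, maxN = 8L, maxDim = 4L) {
    set.seed(seed)
    N <- sample(2:maxN, 1)
    D <- sample(2:maxDim, 1)
    R <- sample(2:maxDim, 1)
    Y <- matrix(rnorm(N * D), N, D)
    hN <- rnorm(R)
    tap <- list(
        W_c = matrix(rnorm(D * D), D, D),
        W_r = matrix(rnorm(R * R), R, R),
        u = rnorm(D + R),
        b_global = rnorm(D + R),
        W_l = matrix(rnorm(D * D), D, D),
        b_l = rnorm(D),
        v = rnorm(D),
        W_g = matrix(rnorm(R * R), R, R))
    list(Y = Y, hN = hN, tap = tap, N = N, D = D, R = R)
}
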