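#' Short-time Fourier transform log-power features
#'
#' Converts a clip into the model's time-frequency input
#' `X = [x(1), ..., x(N)]`: frames of `frameLength` samples taken every
#' `frameShift` samples (tail samples that do not fill a frame are
#' dropped), each windowed and transformed, with entry
#' `(n, k) = log(max(|DFT_k|^2, logFloor))`. With the default 512/256
#' framing the feature dimension is `512/2 + 1 = 257`.
#'
#' @param clip a [PCGClip-class] (or a bare numeric waveform, in which
#'   case `rate` must be supplied).
#' @param frameLength analysis frame length in samples.
#' @param frameShift hop size in samples.
#' @param logFloor floor applied to the power before the natural log so
#'   every entry is finite.
#' @param window `"hann"` (default, periodic) or `"rect"`.
#' @param rate sampling rate when `clip` is a bare numeric vector.
#' @return a [Spectrogram-class] with
#'   `N = floor((nSamples - frameLength)/frameShift) + 1` rows.
#' @examples
#' clip <- synthesizeClip(synthConfig(seed = 1), "normal")
#' sp <- stftLogpower(clip)
#' dim(specFrames(sp))  # 155 x 257
#' @export
stftLogpower <- function(clip, frameLength = 512L, frameShift = 256L,
                         logFloor = 1e-10, window = c("hann", "rect"),
                         rate = NULL) {
    window <- match.arg(window)
    if (is(clip, "PCGClip")) {
        x <- clip@samples
        rate <- clip@rate
    } else {
        x <- as.numeric(clip)
        if (is.null(rate)) stop("rate must be given for a bare waveform")
    }
    frameLength <- as.integer(frameLength)
    frameShift <- as.integer(frameShift)
    if (length(x) < frameLength)
        stop("clip has ", length(x), " samples, shorter than one frame (",
             frameLength, ")")
    n <- (length(x) - frameLength) %/% frameShift + 1L
    w <- if (window == "hann")
        0.5 - 0.5 * cos(2 * pi * (0:(frameLength - 1L)) / frameLength)
    else rep(1, frameLength)
    starts <- (seq_len(n) - 1L) * frameShift
    fm <- matrix(x[rep(starts, each = frameLength) +
                   seq_len(frameLength)], frameLength, n) * w
    sp <- stats::mvfft(fm)[seq_len(frameLength %/% 2L + 1L), , drop = FALSE]
    pow <- Re(sp)^2 + Im(sp)^2
    frames <- t(log(pmax(pow, logFloor)))
    new("Spectrogram", frames = frames, frameLength = frameLength,
        frameShift = frameShift, rate = rate)
}

#' Per-recording feature standardization
#'
#' Subtracts the recording's global mean log-power and divides by a
#' fixed nominal scale of 4 (the typical spread of centered log-power
#' heart-sound spectra; a constant, so no recording statistic beyond
#' the mean enters the features). Raw log-power offsets destabilize
#' training, and the centering makes the model input invariant to
#' waveform amplitude scaling (a gain adds one constant to every
#' log-power entry). Two stronger normalizations are deliberately
#' avoided: per-bin centering would absorb a stationary murmur's band
#' elevation into the reference and spread class evidence over every
#' frame, and dividing by the recording's own standard deviation would
#' leak murmur power into the scale of all frames — either way the
#' temporal localization that the attention weights are meant to expose
#' would be destroyed.
#'
#' @param spec a [Spectrogram-class].
#' @return a [Spectrogram-class] with standardized frames.
#' @export
standardizeFrames <- function(spec) {
    f <- spec@frames
    spec@frames <- (f - mean(f)) / 4
    spec
}

#' Frame-level murmur mask from ground-truth systolic intervals
#'
#' Frame `n` is marked 1 iff its center time falls inside a
#' murmur-bearing systolic interval of the clip. For clips labeled
#' `"normal"` the recorded systolic intervals carry no murmur, so the
#' mask is all zero; an empty interval list likewise yields all zeros.
#'
#' @param clip a [PCGClip-class] with systolic annotations (synthetic).
#' @param spec the clip's [Spectrogram-class].
#' @return integer 0/1 vector of length `nFrames(spec)`.
#' @export
frameAnnotations <- function(clip, spec) {
    stopifnot(is(clip, "PCGClip"))
    if (clip@label == "murmur" && nrow(clip@systolicIntervals) == 0)
        stop("murmur clip carries no systolic annotations; ",
             "frame masks are only defined for annotated (synthetic) clips")
    centers <- frameTimes(spec)
    mask <- integer(length(centers))
    if (clip@label == "murmur" && nrow(clip@systolicIntervals)) {
        iv <- clip@systolicIntervals
        for (k in seq_len(nrow(iv)))
            mask[centers >= iv[k, 1] & centers <= iv[k, 2]] <- 1L
    }
    mask
}
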