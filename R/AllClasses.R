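#' @import methods
NULL

AUSC_SITES <- c("aortic", "pulmonic", "erb", "tricuspid", "mitral")
PCG_LABELS <- c("normal", "murmur")

#' PCGClip: a single labeled phonocardiogram recording
#'
#' Container for one mono heart-sound recording together with its subject
#' and auscultation-site metadata, the binary class label, and (for
#' synthetic clips) ground-truth systolic intervals in seconds.
#'
#' @slot samples numeric waveform, dimensionless amplitude in \[-1, 1\].
#' @slot rate sampling rate in Hz.
#' @slot subjectId opaque subject identifier.
#' @slot site one of `"aortic"`, `"pulmonic"`, `"erb"`, `"tricuspid"`,
#'   `"mitral"`.
#' @slot label `"murmur"` or `"normal"`.
#' @slot systolicIntervals two-column matrix `(start_s, end_s)` of
#'   S1-onset to S2-onset intervals, sorted and non-overlapping; a
#'   zero-row matrix when unknown (real recordings).
#' @export
setClass("PCGClip",
    representation(
        samples = "numeric",
        rate = "numeric",
        subjectId = "character",
        site = "character",
        label = "character",
        systolicIntervals = "matrix"
    ),
    prototype(
        samples = numeric(0), rate = 4000,
        subjectId = NA_character_, site = "aortic", label = "normal",
        systolicIntervals = matrix(numeric(0), 0, 2)
    )
)

setValidity("PCGClip", function(object) {
    msg <- character(0)
    s <- object@samples
    if (length(s) && (!all(is.finite(s)) || max(abs(s)) > 1 + 1e-9))
        msg <- c(msg, "samples must be finite and within [-1, 1]")
    if (length(object@rate) != 1L || object@rate <= 0)
        msg <- c(msg, "rate must be a single positive number")
    if (!object@site %in% AUSC_SITES)
        msg <- c(msg, paste0("site must be one of: ",
                             paste(AUSC_SITES, collapse = ", ")))
    if (!object@label %in% PCG_LABELS)
        msg <- c(msg, "label must be 'murmur' or 'normal'")
    iv <- object@systolicIntervals
    if (ncol(iv) != 2L) {
        msg <- c(msg, "systolicIntervals must have two columns")
    } else if (nrow(iv)) {
        dur <- length(s) / object@rate
        if (any(iv[, 1] >= iv[, 2]))
            msg <- c(msg, "systolic intervals must have start < end")
        if (is.unsorted(iv[, 1]) ||
            (nrow(iv) > 1L && any(iv[-nrow(iv), 2] > iv[-1L, 1] + 1e-12)))
            msg <- c(msg, "systolic intervals must be sorted and non-overlapping")
        if (any(iv[, 1] < -1e-12) || any(iv[, 2] > dur + 1e-9))
            msg <- c(msg, "systolic intervals must lie inside [0, duration]")
    }
    if (length(msg)) msg else TRUE
})

#' SynthConfig: parameters of the synthetic phonocardiogram generator
#'
#' @slot rate sampling rate in Hz.
#' @slot duration clip length in seconds.
#' @slot heartRateBpm heart rate in beats per minute.
#' @slot s1s2GapFraction fraction of the cardiac cycle between S1 onset
#'   and S2 onset (the systolic fraction).
#' @slot murmurBand numeric length-2, band edges in Hz of the murmur
#'   noise; must lie inside (0, rate/2).
#' @slot murmurSnrDb murmur level in dB relative to the broadband
#'   background noise floor (RMS within systole vs background RMS).
#' @slot backgroundNoiseDb background noise floor in dB relative to the
#'   RMS of the S1/S2 transient train (negative = quieter).
#' @slot seed integer seed controlling every random draw.
#' @export
setClass("SynthConfig",
    representation(
        rate = "numeric", duration = "numeric", heartRateBpm = "numeric",
        s1s2GapFraction = "numeric", murmurBand = "numeric",
        murmurSnrDb = "numeric", backgroundNoiseDb = "numeric",
        seed = "integer"
    ),
    prototype(
        rate = 4000, duration = 10, heartRateBpm = 80,
        s1s2GapFraction = 0.35, murmurBand = c(100, 600),
        murmurSnrDb = 10, backgroundNoiseDb = -30, seed = 1L
    )
)

setValidity("SynthConfig", function(object) {
    msg <- character(0)
    if (object@rate <= 0) msg <- c(msg, "rate must be positive")
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (object@heartRateBpm <= 0) msg <- c(msg, "heartRateBpm must be positive")
    if (object@s1s2GapFraction <= 0 || object@s1s2GapFraction >= 1)
        msg <- c(msg, "s1s2GapFraction must lie strictly between 0 and 1")
    b <- object@murmurBand
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1] || b[2] >= object@rate / 2)
        msg <- c(msg, "murmurBand must satisfy 0 < low < high < rate/2")
    if (length(msg)) msg else TRUE
})

#' Spectrogram: log-power STFT frames of one recording
#'
#' The model input `X = [x(1), ..., x(N)]`: one row per analysis frame,
#' one column per frequency bin (`frameLength/2 + 1` bins).
#'
#' @slot frames N x (frameLength/2 + 1) matrix of natural-log power.
#' @slot frameLength analysis frame length in samples.
#' @slot frameShift hop size in samples.
#' @slot rate sampling rate of the underlying waveform in Hz.
#' @export
setClass("Spectrogram",
    representation(
        frames = "matrix", frameLength = "integer",
        frameShift = "integer", rate = "numeric"
    )
)

setValidity("Spectrogram", function(object) {
    msg <- character(0)
    if (!all(is.finite(object@frames)))
        msg <- c(msg, "all spectrogram entries must be finite (log floor)")
    if (ncol(object@frames) != object@frameLength %/% 2L + 1L)
        msg <- c(msg, "frame dimension must equal frameLength/2 + 1")
    if (object@frameShift <= 0L || object@frameLength <= 0L)
        msg <- c(msg, "frameLength and frameShift must be positive")
    if (length(msg)) msg else TRUE
})

#' ModelConfig: architecture description of a classifier
#'
#' Presets follow the published architectures: the CNN baseline has three
#' convolutional layers (32 filters 1x4, 32 filters 1x4, 32 filters 4x4)
#' and two 512-wide dense layers; the CRNN has two convolutional layers
#' (16 filters, 1x4), two 256-wide LSTM layers and two 256-wide dense
#' layers; the TAP-CRNN adds the temporal attentive pooling block on top
#' of the CRNN encoder. Kernel sizes are (time x frequency). Hyperbolic
#' tangent activations throughout; softmax output.
#'
#' @slot architecture `"cnn"`, `"crnn"` or `"tap_crnn"`.
#' @slot convSpec list of integer triples `(nFilters, kernelTime,
#'   kernelFreq)`, one per convolutional layer.
#' @slot rnnSpec integer vector of LSTM hidden widths (empty for cnn).
#' @slot denseSpec integer vector of dense hidden widths.
#' @slot nClasses number of output classes (2).
#' @slot standardize logical; apply per-recording, per-bin
#'   mean/variance standardization to features before the encoder.
#' @export
setClass("ModelConfig",
    representation(
        architecture = "character", convSpec = "list",
        rnnSpec = "integer", denseSpec = "integer",
        nClasses = "integer", standardize = "logical"
    )
)

setValidity("ModelConfig", function(object) {
    msg <- character(0)
    if (!object@architecture %in% c("cnn", "crnn", "tap_crnn"))
        msg <- c(msg, "architecture must be cnn, crnn or tap_crnn")
    if (object@architecture == "cnn" && length(object@rnnSpec))
        msg <- c(msg, "cnn architecture must have an empty rnnSpec")
    if (object@architecture %in% c("crnn", "tap_crnn") && !length(object@rnnSpec))
        msg <- c(msg, "recurrent architectures need a nonempty rnnSpec")
    if (!length(object@convSpec))
        msg <- c(msg, "convSpec must list at least one layer")
    for (l in object@convSpec)
        if (length(l) != 3L || any(l < 1))
            msg <- c(msg, "each convSpec entry must be (nFilters, kt, kf), all >= 1")
    if (object@nClasses != 2L)
        msg <- c(msg, "only the two-class problem is supported")
    if (length(msg)) msg else TRUE
})

#' EPLTrace: per-frame event presence likelihood of one clip
#'
#' The raw per-frame product `alpha_global(n) * beta_local(n)` of the two
#' TAP attention weights, aligned to frame center times, optionally with
#' the ground-truth murmur mask of a synthetic clip.
#'
#' @slot timeS frame center times in seconds.
#' @slot epl nonnegative per-frame attention products.
#' @slot mask integer 0/1 ground-truth murmur mask, or length-0 when the
#'   clip carries no annotations.
#' @slot clipId identifier of the source clip.
#' @export
setClass("EPLTrace",
    representation(
        timeS = "numeric", epl = "numeric", mask = "integer",
        clipId = "character"
    )
)

setValidity("EPLTrace", function(object) {
    msg <- character(0)
    if (length(object@timeS) != length(object@epl))
        msg <- c(msg, "timeS and epl must have equal length")
    if (length(object@mask) &&
        length(object@mask) != length(object@epl))
        msg <- c(msg, "mask must be empty or match epl in length")
    if (any(object@epl < -1e-12))
        msg <- c(msg, "epl values must be nonnegative")
    if (length(msg)) msg else TRUE
})
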