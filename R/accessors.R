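#' @rdname accessors
#' @export
setMethod("samples", "PCGClip", function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("sampleRate", "PCGClip", function(object) object@rate)

#' @rdname accessors
#' @export
setMethod("sampleRate", "Spectrogram", function(object) object@rate)

#' @rdname accessors
#' @export
setMethod("clipDuration", "PCGClip",
          function(object) length(object@samples) / object@rate)

#' @rdname accessors
#' @export
setMethod("subjectId", "PCGClip", function(object) object@subjectId)

#' @rdname accessors
#' @export
setMethod("site", "PCGClip", function(object) object@site)

#' @rdname accessors
#' @export
setMethod("clipLabel", "PCGClip", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("systolicIntervals", "PCGClip",
          function(object) object@systolicIntervals)

#' @rdname accessors
#' @export
setMethod("specFrames", "Spectrogram", function(object) object@frames)

#' @rdname accessors
#' @export
setMethod("nFrames", "Spectrogram", function(object) nrow(object@frames))

#' Frame center times of a spectrogram
#'
#' Frame `n` (1-based) covers samples `(n-1)*shift + 1 ...
#' (n-1)*shift + frameLength`; its center time is
#' `((n-1)*shift + frameLength/2) / rate` seconds.
#'
#' @rdname accessors
#' @export
setMethod("frameTimes", "Spectrogram", function(object) {
    n <- nrow(object@frames)
    ((seq_len(n) - 1) * object@frameShift + object@frameLength / 2) /
        object@rate
})

#' @rdname accessors
#' @export
setMethod("frameTimes", "EPLTrace", function(object) object@timeS)

#' @rdname accessors
#' @export
setMethod("eplValues", "EPLTrace", function(object) object@epl)

#' @rdname accessors
#' @export
setMethod("eplMask", "EPLTrace", function(object) object@mask)

setMethod("show", "PCGClip", function(object) {
    cat(sprintf(
        "PCGClip: %s / %s / %s\n  %.3g s at %g Hz (%d samples), %d systolic interval(s)\n",
        object@subjectId, object@site, object@label,
        clipDuration(object), object@rate, length(object@samples),
        nrow(object@systolicIntervals)))
})

setMethod("show", "Spectrogram", function(object) {
    cat(sprintf(
        "Spectrogram: %d frames x %d bins (frame %d, shift %d, %g Hz)\n",
        nrow(object@frames), ncol(object@frames),
        object@frameLength, object@frameShift, object@rate))
})

setMethod("show", "ModelConfig", function(object) {
    conv <- vapply(object@convSpec, function(l)
        sprintf("%dx(%dx%d)", l[1], l[2], l[3]), character(1))
    cat(sprintf("ModelConfig: %s\n  conv: %s\n  rnn: %s\n  dense: %s -> %d classes\n",
        object@architecture, paste(conv, collapse = ", "),
        if (length(object@rnnSpec)) paste(object@rnnSpec, collapse = ", ") else "-",
        paste(object@denseSpec, collapse = ", "), object@nClasses))
})

setMethod("show", "EPLTrace", function(object) {
    cat(sprintf("EPLTrace: %s, %d frames, sum(EPL) = %.4f%s\n",
        object@clipId, length(object@epl), sum(object@epl),
        if (length(object@mask)) sprintf(", %d murmur frames",
                                         sum(object@mask)) else ""))
})

setMethod("show", "SynthConfig", function(object) {
    cat(sprintf(
        "SynthConfig: %g Hz, %g s, %g bpm, systole %.2f of cycle\n  murmur band %g-%g Hz at %g dB SNR, background %g dB, seed %d\n",
        object@rate, object@duration, object@heartRateBpm,
        object@s1s2GapFraction, object@murmurBand[1], object@murmurBand[2],
        object@murmurSnrDb, object@backgroundNoiseDb, object@seed))
})
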