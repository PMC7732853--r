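# Frame-level event presence likelihood (EPL): the per-frame product of
# the global and local attention weights of a TAP-CRNN. High EPL marks
# the frames on which the model concentrates its pooled evidence — for
# a murmur clip, the systolic regions.

#' Extract the EPL trace of a clip
#'
#' Runs the TAP-CRNN forward pass and returns the raw per-frame product
#' `alpha_global(n) * beta_local(n)` aligned to frame center times.
#' Because each factor is a distribution over frames, every EPL value
#' lies in \[0, 1\] and the values sum to at most 1. The EPL is reported
#' unnormalized; divide by its maximum for plotting if desired.
#'
#' @param weights trained tap_crnn weights.
#' @param clip a [PCGClip-class].
#' @param frameLength,frameShift STFT framing in samples.
#' @return an [EPLTrace-class]; the ground-truth murmur mask is
#'   attached when the clip carries systolic annotations.
#' @export
extractEpl <- function(weights, clip, frameLength = 512L,
                       frameShift = 256L) {
    if (weights$config@architecture != "tap_crnn")
        stop("EPL is undefined for architecture '",
             weights$config@architecture,
             "': only tap_crnn produces attention weights")
    sp <- stftLogpower(clip, frameLength, frameShift)
    fw <- modelForward(sp, weights)
    mask <- if (nrow(clip@systolicIntervals) > 0L)
        frameAnnotations(clip, sp) else integer(0)
    new("EPLTrace", timeS = frameTimes(sp), epl = fw$epl, mask = mask,
        clipId = paste(clip@subjectId, clip@site, sep = "_"))
}

#' Frame-level EPL localization score
#'
#' The probability that a randomly chosen murmur frame receives a
#' higher EPL than a randomly chosen non-murmur frame (a pairwise
#' ranking statistic; ties count one half), averaged over clips. 1
#' means perfect localization, 0.5 chance level. Traces whose mask is
#' all-zero or all-one carry no rankable pairs and are skipped with a
#' warning.
#'
#' @param traces list of [EPLTrace-class] with ground-truth masks.
#' @return scalar in \[0, 1\], or `NA` if no trace was scorable.
#' @export
eplLocalizationScore <- function(traces) {
    if (is(traces, "EPLTrace")) traces <- list(traces)
    perClip <- vapply(traces, function(tr) {
        m <- tr@mask
        if (!length(m))
            stop("trace ", tr@clipId, " has no ground-truth mask")
        if (all(m == 0L) || all(m == 1L)) {
            warning("trace ", tr@clipId,
                    " has a degenerate mask; skipped")
            return(NA_real_)
        }
        a <- tr@epl[m == 1L]
        b <- tr@epl[m == 0L]
        # P(murmur frame > other frame) + half credit for ties
        (sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))) /
            (length(a) * length(b))
    }, numeric(1))
    if (all(is.na(perClip))) return(NA_real_)
    mean(perClip, na.rm = TRUE)
}

#' Write / read an EPL trace as TSV
#'
#' Columns `time_s`, `epl` and (when a mask is present) `mask`. Values
#' round-trip at full double precision.
#'
#' @param trace an [EPLTrace-class].
#' @param path TSV path.
#' @export
writeEplTrace <- function(trace, path) {
    df <- data.frame(time_s = trace@timeS, epl = trace@epl)
    if (length(trace@mask)) df$mask <- trace@mask
    utils::write.table(format(df, digits = 17), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEplTrace
#' @export
readEplTrace <- function(path, clipId = basename(path)) {
    df <- utils::read.table(path, sep = "\t", header = TRUE)
    new("EPLTrace", timeS = as.numeric(df$time_s),
        epl = as.numeric(df$epl),
        mask = if ("mask" %in% names(df)) as.integer(df$mask)
               else integer(0),
        clipId = clipId)
}

#' Plot a spectrogram with its EPL curve
#'
#' Two-panel base-graphics figure: the clip's log-power spectrogram on
#' top, the EPL trace below, sharing the time axis.
#'
#' @param spec a [Spectrogram-class].
#' @param trace the matching [EPLTrace-class].
#' @export
plotEpl <- function(spec, trace) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op))
    t <- frameTimes(spec)
    f <- seq_len(ncol(spec@frames)) * spec@rate / (2 * ncol(spec@frames))
    graphics::image(t, f, spec@frames, col = grDevices::hcl.colors(64),
                    xlab = "", ylab = "frequency (Hz)")
    graphics::plot(trace@timeS, trace@epl, type = "h",
                   xlab = "time (s)", ylab = "EPL")
    if (length(trace@mask))
        graphics::points(trace@timeS[trace@mask == 1L],
                         rep(0, sum(trace@mask)), pch = "|",
                         col = "red")
    invisible(NULL)
}
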