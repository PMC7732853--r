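#' Construct a synthetic-generator configuration
#'
#' Defaults emulate a 10-second electronic-stethoscope recording at
#' 4000 Hz: heart sounds are low-frequency (< 1 kHz), and 4000 Hz keeps a
#' 512-sample analysis frame at 128 ms. The murmur of a ventricular
#' septal defect is modeled as band-limited noise (100-600 Hz) filling
#' the S1-to-S2 (systolic) interval of every cycle.
#'
#' @param rate sampling rate (Hz).
#' @param duration clip duration (s).
#' @param heartRateBpm heart rate (beats per minute).
#' @param s1s2GapFraction systolic fraction of the cycle (S1 onset to S2
#'   onset).
#' @param murmurBand length-2 band edges (Hz) of the murmur noise.
#' @param murmurSnrDb murmur RMS (within systole) relative to the
#'   background noise RMS, in dB.
#' @param backgroundNoiseDb background noise RMS relative to the S1/S2
#'   transient-train RMS, in dB.
#' @param seed integer seed.
#' @return a [SynthConfig-class] object.
#' @export
synthConfig <- function(rate = 4000, duration = 10, heartRateBpm = 80,
                        s1s2GapFraction = 0.35, murmurBand = c(100, 600),
                        murmurSnrDb = 10, backgroundNoiseDb = -30,
                        seed = 1L) {
    new("SynthConfig", rate = rate, duration = duration,
        heartRateBpm = heartRateBpm, s1s2GapFraction = s1s2GapFraction,
        murmurBand = as.numeric(murmurBand), murmurSnrDb = murmurSnrDb,
        backgroundNoiseDb = backgroundNoiseDb, seed = as.integer(seed))
}

# Exponentially decaying tone burst used for S1 and S2. freq in Hz, decay
# time constant tau in s, length dur in s.
toneBurst <- function(rate, dur, freq, tau) {
    t <- seq(0, dur, by = 1 / rate)
    sin(2 * pi * freq * t) * exp(-t / tau) * sin(pi * pmin(t / 0.005, 1) / 2)
}

# Short cosine on/off ramps so gated noise has no clicks.
gateEnvelope <- function(n, rampN) {
    env <- rep(1, n)
    r <- min(rampN, floor(n / 2))
    if (r > 0) {
        ramp <- (1 - cos(pi * seq_len(r) / r)) / 2
        env[seq_len(r)] <- ramp
        env[n + 1 - seq_len(r)] <- ramp
    }
    env
}

# Band-pass white noise to the murmur band (4th-order Butterworth,
# zero-phase).
bandNoise <- function(n, rate, band) {
    bf <- signal::butter(4, band / (rate / 2), type = "pass")
    x <- stats::rnorm(n + 2000)
    y <- signal::filtfilt(bf, x)
    y[1001:(1000 + n)]
}

#' Synthesize one phonocardiogram clip
#'
#' Builds a periodic train of S1/S2 transients (short exponentially
#' decaying 30-150 Hz tone bursts) at the configured heart rate, adds a
#' broadband background noise floor, and, for the murmur class, adds
#' band-limited noise gated to every S1-to-S2 interval at the configured
#' SNR. The realized S1-to-S2 intervals are recorded in the clip for both
#' classes (for normal clips they annotate systole without any injected
#' murmur). The waveform is peak-normalized to 0.9 and is bit-identical
#' for identical configuration and seed.
#'
#' @param config a [SynthConfig-class].
#' @param label `"murmur"` or `"normal"`.
#' @param subjectId,site metadata stored on the clip.
#' @param murmurGain extra multiplicative gain on the murmur amplitude
#'   (used for per-site loudness profiles).
#' @return a [PCGClip-class] with `systolicIntervals` filled in.
#' @examples
#' clip <- synthesizeClip(synthConfig(seed = 7), "murmur")
#' clip
#' @export
synthesizeClip <- function(config, label = c("murmur", "normal"),
                           subjectId = "synthetic", site = "tricuspid",
                           murmurGain = 1) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    label <- match.arg(label)
    rate <- config@rate
    nSamp <- round(config@duration * rate)

    set.seed(config@seed)
    period <- 60 / config@heartRateBpm
    # slight cycle-to-cycle jitter (2% sd) for realism
    nCycles <- ceiling(config@duration / period) + 1L
    cycleLen <- period * (1 + 0.02 * stats::rnorm(nCycles))
    s1Onsets <- cumsum(c(0.05, cycleLen[-nCycles]))
    s1Onsets <- s1Onsets[s1Onsets < config@duration]

    s1 <- toneBurst(rate, 0.06, 55, 0.012)
    s2 <- toneBurst(rate, 0.05, 75, 0.010)

    x <- numeric(nSamp)
    intervals <- NULL
    addBurst <- function(x, t0, burst, amp) {
        i0 <- round(t0 * rate) + 1L
        idx <- i0:min(i0 + length(burst) - 1L, nSamp)
        if (length(idx) > 0 && idx[1] <= nSamp)
            x[idx] <- x[idx] + amp * burst[seq_along(idx)]
        x
    }
    sysFrac <- config@s1s2GapFraction
    for (k in seq_along(s1Onsets)) {
        t1 <- s1Onsets[k]
        t2 <- t1 + sysFrac * (if (k < length(s1Onsets))
            s1Onsets[k + 1] - t1 else period)
        ampJit <- 1 + 0.05 * stats::rnorm(2)
        x <- addBurst(x, t1, s1, ampJit[1])
        if (t2 < config@duration) {
            x <- addBurst(x, t2, s2, 0.8 * ampJit[2])
            intervals <- rbind(intervals, c(t1, t2))
        }
    }
    if (is.null(intervals)) intervals <- matrix(numeric(0), 0, 2)

    heartRms <- sqrt(mean(x^2))
    bgRms <- heartRms * 10^(config@backgroundNoiseDb / 20)
    x <- x + bgRms * stats::rnorm(nSamp)

    if (label == "murmur" && nrow(intervals)) {
        mur <- bandNoise(nSamp, rate, config@murmurBand)
        gate <- numeric(nSamp)
        for (k in seq_len(nrow(intervals))) {
            i0 <- round(intervals[k, 1] * rate) + 1L
            i1 <- min(round(intervals[k, 2] * rate), nSamp)
            if (i1 > i0)
                gate[i0:i1] <- gateEnvelope(i1 - i0 + 1L, round(0.01 * rate))
        }
        mg <- mur * gate
        inSys <- gate > 0.5
        murRms <- sqrt(mean(mg[inSys]^2))
        target <- bgRms * 10^(config@murmurSnrDb / 20) * murmurGain
        x <- x + mg * (target / murRms)
    }

    x <- 0.9 * x / max(abs(x))
    new("PCGClip", samples = x, rate = rate, subjectId = subjectId,
        site = site, label = label, systolicIntervals = intervals)
}

# Per-site murmur loudness profile: a VSD murmur is loudest at the lower
# left sternal border (tricuspid area / Erb's point).
SITE_MURMUR_GAIN <- c(aortic = 0.7, pulmonic = 0.8, erb = 1.2,
                      tricuspid = 1.3, mitral = 0.8)

#' Synthesize a multi-subject cohort across all five auscultation sites
#'
#' Every subject contributes `clipsPerSubjectPerSite` clips at each of
#' the five standard auscultation sites. Per-subject physiology is
#' jittered from the base configuration (heart rate +/- 10 bpm, murmur
#' SNR +/- 3 dB, both held fixed within a subject so that
#' subject-exclusive splitting is meaningful); murmur loudness follows a
#' per-site gain profile peaking at the tricuspid area and Erb's point.
#' All randomness derives from `config@seed`.
#'
#' @param nMurmurSubjects,nNormalSubjects subject counts per class.
#' @param clipsPerSubjectPerSite recordings per subject per site.
#' @param config base [SynthConfig-class].
#' @return list with `clips` (list of [PCGClip-class]) and `manifest`
#'   (data.frame with columns `clip`, `subject_id`, `site`, `label`; the
#'   `clip` column indexes into `clips` and doubles as a unique path stem
#'   when the cohort is written to disk).
#' @export
synthesizeCohort <- function(nMurmurSubjects, nNormalSubjects,
                             clipsPerSubjectPerSite = 2L,
                             config = synthConfig()) {
    stopifnot(nMurmurSubjects >= 1, nNormalSubjects >= 1,
              clipsPerSubjectPerSite >= 1)
    set.seed(config@seed)
    nSub <- nMurmurSubjects + nNormalSubjects
    subjects <- data.frame(
        subject_id = sprintf("S%03d", seq_len(nSub)),
        label = rep(c("murmur", "normal"),
                    c(nMurmurSubjects, nNormalSubjects)),
        hr = config@heartRateBpm + stats::runif(nSub, -10, 10),
        snr = config@murmurSnrDb + stats::runif(nSub, -3, 3),
        stringsAsFactors = FALSE)
    clipSeeds <- sample.int(.Machine$integer.max,
                            nSub * 5L * clipsPerSubjectPerSite)

    clips <- vector("list", length(clipSeeds))
    rows <- vector("list", length(clipSeeds))
    i <- 0L
    for (s in seq_len(nSub)) {
        for (siteName in AUSC_SITES) {
            for (r in seq_len(clipsPerSubjectPerSite)) {
                i <- i + 1L
                cfg <- config
                cfg@heartRateBpm <- subjects$hr[s]
                cfg@murmurSnrDb <- subjects$snr[s]
                cfg@seed <- clipSeeds[i]
                clips[[i]] <- synthesizeClip(
                    cfg, subjects$label[s],
                    subjectId = subjects$subject_id[s], site = siteName,
                    murmurGain = SITE_MURMUR_GAIN[[siteName]])
                rows[[i]] <- data.frame(
                    clip = sprintf("%s_%s_%02d", subjects$subject_id[s],
                                   siteName, r),
                    subject_id = subjects$subject_id[s],
                    site = siteName, label = subjects$label[s],
                    stringsAsFactors = FALSE)
            }
        }
    }
    manifest <- do.call(rbind, rows)
    stopifnot(!anyDuplicated(manifest$clip))
    list(clips = clips, manifest = manifest)
}
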