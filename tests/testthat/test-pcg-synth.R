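# Synthetic phonocardiogram generator: determinism, annotation
# consistency, class contrast against an independent band-energy
# oracle, cohort bookkeeping, WAV round trips.

test_that("clip geometry and annotation invariants hold", {
    cfg <- synthConfig(rate = 4000, duration = 10, seed = 42)
    clip <- synthesizeClip(cfg, "murmur")
    expect_length(samples(clip), 40000L)
    expect_equal(clipDuration(clip), 10)
    expect_true(all(abs(samples(clip)) <= 1))
    expect_equal(max(abs(samples(clip))), 0.9, tolerance = 1e-12)
    iv <- systolicIntervals(clip)
    expect_gt(nrow(iv), 5)
    expect_true(all(iv[, 1] < iv[, 2]))
    expect_true(all(diff(iv[, 1]) > 0))
    expect_true(all(iv[-nrow(iv), 2] <= iv[-1, 1]))
    expect_true(all(iv >= 0 & iv <= 10))
    # normal clips carry the same style of annotations
    norm <- synthesizeClip(cfg, "normal")
    expect_gt(nrow(systolicIntervals(norm)), 5)
})

test_that("same config and seed give bit-identical waveforms", {
    cfg <- synthConfig(seed = 7)
    a <- synthesizeClip(cfg, "murmur")
    b <- synthesizeClip(cfg, "murmur")
    expect_identical(samples(a), samples(b))
    co1 <- synthesizeCohort(2, 2, 1, synthConfig(seed = 9))
    co2 <- synthesizeCohort(2, 2, 1, synthConfig(seed = 9))
    expect_identical(co1$manifest, co2$manifest)
    expect_identical(lapply(co1$clips, samples),
                     lapply(co2$clips, samples))
})

test_that("murmur clips show higher systolic band energy than normal
           clips (independent FFT band oracle)", {
    cfg <- synthConfig(seed = 33)
    mur <- synthesizeClip(cfg, "murmur")
    nor <- synthesizeClip(cfg, "normal")
    expect_gt(oracleContrast(mur), oracleContrast(nor))
})

test_that("band-energy contrast separates the classes with zero overlap
           at 10 dB murmur SNR over 100 seeded clips", {
    contrasts <- vapply(1:100, function(s) {
        lab <- if (s <= 50) "murmur" else "normal"
        oracleContrast(synthesizeClip(synthConfig(seed = 5000 + s),
                                      lab))
    }, numeric(1))
    expect_gt(min(contrasts[1:50]), max(contrasts[51:100]))
})

test_that("cohort bookkeeping: counts, subject set, manifest-clip
           bijection", {
    co <- synthesizeCohort(2, 2, 1, synthConfig(seed = 3))
    expect_length(co$clips, 20L)
    expect_equal(nrow(co$manifest), 20L)
    expect_equal(sum(co$manifest$label == "murmur"), 10L)
    expect_setequal(unique(co$manifest$subject_id),
                    sprintf("S%03d", 1:4))
    expect_false(anyDuplicated(co$manifest$clip) > 0)
    # every subject contributes at every site
    tab <- table(co$manifest$subject_id, co$manifest$site)
    expect_true(all(tab == 1))
    # arithmetic: 3 + 2 subjects, 2 clips/site -> 50 clips
    co2 <- synthesizeCohort(3, 2, 2, synthConfig(seed = 4,
                                                 duration = 1))
    expect_length(co2$clips, 50L)
})

test_that("per-subject physiology is fixed within a subject", {
    co <- synthesizeCohort(1, 1, 2, synthConfig(seed = 12,
                                                duration = 4))
    m <- co$manifest
    for (s in unique(m$subject_id)) {
        idx <- which(m$subject_id == s)
        gaps <- vapply(idx, function(i) {
            iv <- systolicIntervals(co$clips[[i]])
            mean(diff(iv[, 1]))
        }, numeric(1))
        # same subject -> same base heart rate (cycle jitter is small)
        expect_lt(max(gaps) - min(gaps), 0.05 * mean(gaps))
    }
})

test_that("WAV round trip preserves rate, length and samples to 16-bit
           quantization", {
    clip <- shortClip(seed = 21)
    path <- withr::local_tempfile(fileext = ".wav")
    writeClip(clip, path)
    back <- readClip(path, subjectId(clip), site(clip),
                     clipLabel(clip))
    expect_equal(sampleRate(back), sampleRate(clip))
    expect_length(samples(back), length(samples(clip)))
    expect_lt(max(abs(samples(back) - samples(clip))), 1 / 32767)
})

test_that("unreadable and malformed audio inputs give explicit errors", {
    expect_error(readClip(file.path(tempdir(), "nope.wav")),
                 "no such file")
    # hand-build a stereo WAV header: must be rejected, naming the path
    path <- withr::local_tempfile(fileext = ".wav")
    con <- file(path, "wb")
    writeChar("RIFF", con, eos = NULL)
    writeBin(36L, con, size = 4, endian = "little")
    writeChar("WAVEfmt ", con, eos = NULL)
    writeBin(16L, con, size = 4, endian = "little")
    writeBin(1L, con, size = 2, endian = "little")
    writeBin(2L, con, size = 2, endian = "little")   # 2 channels
    writeBin(4000L, con, size = 4, endian = "little")
    writeBin(16000L, con, size = 4, endian = "little")
    writeBin(4L, con, size = 2, endian = "little")
    writeBin(16L, con, size = 2, endian = "little")
    writeChar("data", con, eos = NULL)
    writeBin(0L, con, size = 4, endian = "little")
    close(con)
    expect_error(readClip(path), "multichannel")
    expect_error(readClip(path), basename(path), fixed = TRUE)
})

test_that("manifest and annotation sidecars round-trip", {
    co <- synthesizeCohort(2, 2, 1, synthConfig(seed = 5, duration = 1))
    mpath <- withr::local_tempfile(fileext = ".tsv")
    writeManifest(co$manifest, mpath)
    back <- readManifest(mpath)
    expect_equal(back$path, co$manifest$clip)
    expect_equal(back$label, co$manifest$label)
    apath <- withr::local_tempfile(fileext = ".tsv")
    writeAnnotations(co$clips[[1]], apath)
    expect_equal(readAnnotations(apath),
                 systolicIntervals(co$clips[[1]]),
                 ignore_attr = TRUE)
})

test_that("invalid generator configurations are rejected", {
    expect_error(synthConfig(murmurBand = c(100, 3000)), "murmurBand")
    expect_error(synthConfig(s1s2GapFraction = 1.2), "s1s2GapFraction")
    expect_error(synthConfig(heartRateBpm = -10), "heartRateBpm")
})
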