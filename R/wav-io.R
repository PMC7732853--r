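# Minimal canonical RIFF/WAVE PCM-16 mono reader and writer. Heart-sound
# recorders in this domain save plain 16-bit PCM; no installed R package
# provides WAV I/O, so the format is handled directly here.

#' Write a clip to a 16-bit PCM mono WAV file
#'
#' @param clip a [PCGClip-class].
#' @param path output file path; the directory must exist.
#' @return `path`, invisibly.
#' @export
writeClip <- function(clip, path) {
    stopifnot(is(clip, "PCGClip"))
    dir <- dirname(path)
    if (!dir.exists(dir))
        stop("directory does not exist: ", dir)
    pcm <- as.integer(round(pmax(-1, pmin(1, clip@samples)) * 32767))
    con <- file(path, "wb")
    on.exit(close(con))
    dataBytes <- 2L * length(pcm)
    writeChar("RIFF", con, eos = NULL)
    writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
    writeChar("WAVEfmt ", con, eos = NULL)
    writeBin(16L, con, size = 4, endian = "little")     # fmt chunk size
    writeBin(1L, con, size = 2, endian = "little")      # PCM
    writeBin(1L, con, size = 2, endian = "little")      # mono
    writeBin(as.integer(clip@rate), con, size = 4, endian = "little")
    writeBin(as.integer(clip@rate * 2), con, size = 4, endian = "little")
    writeBin(2L, con, size = 2, endian = "little")      # block align
    writeBin(16L, con, size = 2, endian = "little")     # bits/sample
    writeChar("data", con, eos = NULL)
    writeBin(dataBytes, con, size = 4, endian = "little")
    writeBin(pcm, con, size = 2, endian = "little")
    invisible(path)
}

#' Read a 16-bit PCM mono WAV file as a clip
#'
#' Metadata (subject, site, label) comes from the accompanying manifest
#' row, not from the audio file. Multichannel or non-PCM files are
#' rejected with an explicit error; real recordings carry no
#' ground-truth systolic intervals.
#'
#' @param path WAV file path.
#' @param subjectId,site,label metadata to attach (typically one
#'   manifest row).
#' @return a [PCGClip-class] with empty `systolicIntervals`.
#' @export
readClip <- function(path, subjectId = NA_character_, site = "aortic",
                     label = "normal") {
    if (!file.exists(path))
        stop("no such file: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    if (!identical(readChar(con, 4), "RIFF"))
        stop("not a RIFF/WAVE file: ", path)
    invisible(readBin(con, "integer", size = 4, endian = "little"))
    if (!identical(readChar(con, 4), "WAVE"))
        stop("not a RIFF/WAVE file: ", path)
    fmt <- NULL
    repeat {
        id <- readChar(con, 4)
        if (length(id) == 0 || nchar(id) < 4)
            stop("malformed WAV (missing data chunk): ", path)
        sz <- readBin(con, "integer", size = 4, endian = "little")
        if (id == "fmt ") {
            fmt <- list(
                audioFormat = readBin(con, "integer", size = 2,
                                      endian = "little"),
                nChannels = readBin(con, "integer", size = 2,
                                    endian = "little"),
                rate = readBin(con, "integer", size = 4, endian = "little"))
            invisible(readBin(con, "raw", n = sz - 8L))
        } else if (id == "data") {
            if (is.null(fmt))
                stop("malformed WAV (data before fmt): ", path)
            if (fmt$audioFormat != 1L)
                stop("unsupported encoding (not PCM) in ", path)
            if (fmt$nChannels != 1L)
                stop("multichannel input not supported (", fmt$nChannels,
                     " channels): ", path)
            pcm <- readBin(con, "integer", n = sz %/% 2L, size = 2,
                           signed = TRUE, endian = "little")
            return(new("PCGClip", samples = pcm / 32767,
                       rate = fmt$rate, subjectId = subjectId,
                       site = site, label = label))
        } else {
            invisible(readBin(con, "raw", n = sz))
        }
    }
}

#' Write / read a dataset manifest
#'
#' The manifest is a TSV with header `path  subject_id  site  label`,
#' one row per soundtrack. Paths must be unique; labels must be
#' `"murmur"` or `"normal"`.
#'
#' @param manifest data.frame with columns `path`, `subject_id`, `site`,
#'   `label` (a cohort manifest's `clip` column is accepted as `path`).
#' @param path TSV file path.
#' @return `readManifest` returns the validated data.frame.
#' @export
writeManifest <- function(manifest, path) {
    if ("clip" %in% names(manifest) && !"path" %in% names(manifest))
        names(manifest)[names(manifest) == "clip"] <- "path"
    checkManifest(manifest)
    utils::write.table(manifest[, c("path", "subject_id", "site", "label")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    if (!file.exists(path))
        stop("no such manifest: ", path)
    m <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    checkManifest(m)
    m
}

checkManifest <- function(m) {
    need <- c("path", "subject_id", "site", "label")
    miss <- setdiff(need, names(m))
    if (length(miss))
        stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(m$path))
        stop("manifest paths are not unique")
    if (!all(m$label %in% PCG_LABELS))
        stop("manifest labels must be 'murmur' or 'normal'")
    if (!all(m$site %in% AUSC_SITES))
        stop("manifest sites must be one of: ",
             paste(AUSC_SITES, collapse = ", "))
    invisible(TRUE)
}

#' Write / read a systolic-interval annotation sidecar
#'
#' TSV of `start_s  end_s`, one row per systolic interval of one clip.
#'
#' @param clip a [PCGClip-class] carrying `systolicIntervals`.
#' @param path TSV file path.
#' @export
writeAnnotations <- function(clip, path) {
    iv <- systolicIntervals(clip)
    utils::write.table(
        data.frame(start_s = iv[, 1], end_s = iv[, 2]),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
    a <- utils::read.table(path, sep = "\t", header = TRUE)
    as.matrix(a[, c("start_s", "end_s")])
}
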