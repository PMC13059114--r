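## Reading/writing image sequences and result tables.

#' Load an image sequence into a FrameStack
#'
#' Reads either a multi-page TIFF (page order t-major, then channel: pages
#' `t1c1, t1c2, ..., t2c1, ...`) or a directory of lexicographically ordered
#' per-frame images (PNG or TIFF; each file one timepoint, channels as image
#' planes). Integer imagery is preserved bit-exact.
#'
#' @param path path to a multi-page TIFF file or a directory of frames.
#' @param channelMap named vector mapping roles to 1-based channel indices;
#'   must cover `"red"` and `"green"` (`"brightfield"` optional).
#' @param pixelSizeUm microns per pixel.
#' @param frameIntervalMin minutes between frames.
#' @param nChannels number of channels per timepoint (multi-page TIFF only;
#'   defaults to the largest index in `channelMap`).
#' @return A [FrameStack-class].
#' @export
loadStack <- function(path, channelMap, pixelSizeUm = 1, frameIntervalMin = 60,
                      nChannels = NULL) {
    if (!all(c("red", "green") %in% names(channelMap)))
        configError("channelMap must name 'red' and 'green' channels")
    bad <- setdiff(names(channelMap), c("brightfield", "red", "green"))
    if (length(bad)) configError("unknown channel role '%s' in channelMap", bad[1])
    if (!file.exists(path)) inputError("no such file or directory: %s", path)

    if (dir.exists(path)) {
        files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                                 ignore.case = TRUE, full.names = TRUE))
        if (!length(files)) inputError("no PNG/TIFF frames found in %s", path)
        frames <- lapply(files, readFrameFile)
    } else {
        pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
        if (is.null(nChannels)) nChannels <- max(channelMap)
        if (length(pages) %% nChannels != 0)
            formatError("page count %d not divisible by %d channels",
                        length(pages), nChannels)
        nT <- length(pages) %/% nChannels
        frames <- lapply(seq_len(nT), function(t) {
            chans <- pages[((t - 1) * nChannels + 1):(t * nChannels)]
            dims <- unique(vapply(chans, function(m) paste(dim(m), collapse = "x"), ""))
            if (length(dims) != 1) formatError("inconsistent page dimensions at t=%d", t)
            arr <- array(0, c(nrow(chans[[1]]), ncol(chans[[1]]), nChannels))
            for (c in seq_len(nChannels)) arr[, , c] <- chans[[c]]
            arr
        })
    }
    dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
    if (length(unique(dims)) != 1)
        formatError("frames have inconsistent dimensions (%s)",
                    paste(unique(dims), collapse = " vs "))
    FrameStack(frames, channelMap, pixelSizeUm, frameIntervalMin)
}

readFrameFile <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
    } else {
        tiff::readTIFF(f, as.is = TRUE)
    }
    if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
    img
}

#' Write a FrameStack as a multi-page TIFF
#'
#' Pages are ordered t-major then channel, matching what [loadStack()]
#' expects. Data are written as 16-bit when all intensities are integers in
#' `[0, 65535]`, else as 32-bit float.
#'
#' @param stack a [FrameStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
    d <- dim(stack@data)
    pages <- list()
    isInt <- all(stack@data == round(stack@data)) &&
        max(stack@data) <= 65535 && min(stack@data) >= 0
    for (t in seq_len(d[4])) for (c in seq_len(d[3])) {
        m <- matrix(stack@data[, , c, t], d[1], d[2])
        pages[[length(pages) + 1]] <- if (isInt) m / 65535 else m
    }
    ok <- tryCatch({
        tiff::writeTIFF(pages, path,
                        bits.per.sample = if (isInt) 16L else 32L)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) ioError("cannot write TIFF %s: %s", path, conditionMessage(ok))
    invisible(path)
}

#' Maximum-intensity z-projection
#'
#' Collapses per-timepoint z-stacks to single planes by a per-channel
#' maximum-intensity projection, preserving the brightest fluorescent nuclei
#' regardless of focal plane.
#'
#' @param volume list over timepoints; each element a list over z of
#'   (height, width, channel) arrays, or a 4D array (h, w, channel, z).
#' @param channelMap,pixelSizeUm,frameIntervalMin as in [loadStack()].
#' @return A [FrameStack-class] of projected frames.
#' @export
projectZ <- function(volume, channelMap, pixelSizeUm = 1, frameIntervalMin = 60) {
    frames <- lapply(volume, function(v) {
        if (is.list(v)) {
            if (!length(v)) inputError("empty z dimension")
            out <- v[[1]]
            if (length(dim(out)) == 2) dim(out) <- c(dim(out), 1L)
            for (z in v[-1]) {
                if (length(dim(z)) == 2) dim(z) <- c(dim(z), 1L)
                out <- pmax(out, z)
            }
            out
        } else {
            if (length(dim(v)) != 4 || dim(v)[4] < 1)
                inputError("z-volume must be a (h, w, channel, z) array")
            apply(v, c(1, 2, 3), max)
        }
    })
    FrameStack(frames, channelMap, pixelSizeUm, frameIntervalMin)
}

#' Convert a multi-channel frame to grayscale
#'
#' Either picks a single channel or forms a weighted sum normalised by the
#' weight total, so output never exceeds the largest input channel value.
#'
#' @param frame (height, width, channel) array.
#' @param recipe either a single channel index (or role name resolved by the
#'   caller), or a numeric weight vector of length n_channels.
#' @return grayscale matrix.
#' @export
toGray <- function(frame, recipe) {
    if (length(dim(frame)) == 2) return(frame)
    nc <- dim(frame)[3]
    if (length(recipe) == 1) {
        ch <- as.integer(recipe)
        if (ch < 1 || ch > nc) configError("recipe names absent channel %d", ch)
        return(matrix(frame[, , ch], dim(frame)[1], dim(frame)[2]))
    }
    if (length(recipe) != nc)
        configError("weight recipe length %d != %d channels", length(recipe), nc)
    if (any(recipe < 0)) configError("recipe weights must be non-negative")
    s <- sum(recipe)
    if (s == 0) configError("recipe weights are all zero")
    out <- matrix(0, dim(frame)[1], dim(frame)[2])
    for (c in seq_len(nc)) if (recipe[c] > 0)
        out <- out + (recipe[c] / s) * frame[, , c]
    out
}

## full-precision CSV: numeric columns via %.17g so read-back is exact
formatFull <- function(df) {
    for (j in seq_along(df)) {
        if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
            df[[j]] <- sprintf("%.17g", df[[j]])
    }
    df
}

#' Write result tables as CSV
#'
#' Writes one CSV per result kind into `outDir`. Numeric values are written
#' with enough digits that re-reading reproduces them exactly.
#'
#' @param results named list of data.frames; conventional names are
#'   `transforms`, `detections`, `trajectories`, `metrics`, `summary`.
#' @param outDir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeTables <- function(results, outDir) {
    if (!dir.exists(outDir)) {
        ok <- tryCatch(dir.create(outDir, recursive = TRUE), warning = function(w) FALSE)
        if (isFALSE(ok) || !dir.exists(outDir)) ioError("cannot create %s", outDir)
    }
    paths <- character(0)
    for (nm in names(results)) {
        p <- file.path(outDir, paste0(nm, ".csv"))
        ok <- tryCatch({
            write.csv(formatFull(results[[nm]]), p, row.names = FALSE, quote = FALSE)
            TRUE
        }, error = function(e) e)
        if (!isTRUE(ok)) ioError("cannot write %s: %s", p, conditionMessage(ok))
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' Read back a table written by [writeTables()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readTable <- function(path) {
    if (!file.exists(path)) inputError("no such file: %s", path)
    read.csv(path, stringsAsFactors = FALSE)
}
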