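## Classed conditions so callers (and the CLI) can map failures to exit codes.

stError <- function(class, fmt, ...) {
    msg <- sprintf(fmt, ...)
    stop(structure(
        class = c(class, "spheroTrackError", "error", "condition"),
        list(message = msg, call = sys.call(-1))
    ))
}

configError       <- function(fmt, ...) stError("configError", fmt, ...)
inputError        <- function(fmt, ...) stError("inputError", fmt, ...)
formatError       <- function(fmt, ...) stError("formatError", fmt, ...)
segmentationError <- function(fmt, ...) stError("segmentationError", fmt, ...)
registrationError <- function(fmt, ...) stError("registrationError", fmt, ...)
metricError       <- function(fmt, ...) stError("metricError", fmt, ...)
ioError           <- function(fmt, ...) stError("ioError", fmt, ...)

#' Normalise an angle to (-180, 180] degrees
#'
#' @param theta angle(s) in degrees.
#' @return angle(s) wrapped into the half-open interval (-180, 180].
#' @keywords internal
wrapAngle <- function(theta) {
    out <- (theta + 180) %% 360 - 180
    out[out == -180] <- 180
    out
}

## Quadratic (parabolic) sub-sample peak refinement from three samples
## around a discrete extremum; returns offset in [-0.5, 0.5].
quadPeakOffset <- function(sm1, s0, sp1) {
    den <- sm1 - 2 * s0 + sp1
    if (!is.finite(den) || den == 0) return(0)
    off <- 0.5 * (sm1 - sp1) / den
    max(-0.5, min(0.5, off))
}
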