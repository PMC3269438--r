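## Spot-level quantification: pixel labels from responsibilities, and
## model-based background / foreground / corrected intensities.

#' Classify pixels from a fitted mixture
#'
#' Assigns each pixel to its maximum-responsibility component; exact ties go
#' to the lower-mean component.  Component 1 is background (\code{"BG"}),
#' component \code{K} (for \code{K >= 2}) is foreground (\code{"FG"}), and
#' the middle component of a three-component fit is \code{"INTERMEDIATE"}
#' (fuzzy spot edges, donut holes).  A \code{K = 1} fit labels every pixel
#' background.
#'
#' @param fit a \code{\linkS4class{MixtureFit}}.
#' @return character vector of labels, one per pixel.
#' @export
classifyPixels <- function(fit) {
  stopifnot(is(fit, "MixtureFit"))
  K <- nComponents(fit)
  lab_map <- switch(K, "BG", c("BG", "FG"), c("BG", "INTERMEDIATE", "FG"))
  comp <- max.col(fit@resp, ties.method = "first")
  lab_map[comp]
}

#' Quantify a spot from its selected mixture fit
#'
#' Produces the spot-level summary: background intensity is the smallest
#' fitted mean, foreground intensity the largest (for \code{K >= 2}), and
#' the background-corrected intensity their difference.  Under the censored
#' model the foreground mean is estimated beyond the saturation ceiling, so
#' \code{fg} (and \code{corrected}) may exceed \code{S}; the empirical
#' median/mean over FG-labeled pixels are also reported for comparison with
#' fixed-circle quantification, and these necessarily saturate at \code{S}.
#' A \code{K = 1} fit is a blank (or weak) spot: foreground and corrected
#' intensities are reported missing, not zero.
#'
#' @param mask the \code{\linkS4class{PixelMask}} the fit was selected on.
#' @param fit the \code{\linkS4class{MixtureFit}} returned by
#'   \code{\link{selectK}} (or \code{\link{fitMixture}}) for that mask.
#' @return a \code{\linkS4class{SpotQuantification}}.
#' @examples
#' set.seed(11)
#' y <- pmin(c(rnorm(400, 8000, 2000), rnorm(100, 70000, 6000)), 65535)
#' mask <- PixelMask(y)
#' q <- quantifySpot(mask, selectK(mask, censored = TRUE))
#' fgIntensity(q) > 65535   # dynamic range extended beyond saturation
#' @export
quantifySpot <- function(mask, fit) {
  stopifnot(is(mask, "PixelMask"), is(fit, "MixtureFit"))
  if (nrow(fit@resp) != length(mask@values))
    stop("fit and mask disagree on the number of pixels")
  K <- nComponents(fit)
  labels <- classifyPixels(fit)
  S <- mask@satThreshold
  flags <- fit@flags[fit@flags %in% c("degenerate_fg", "not_converged")]
  bg <- mixMeans(fit)[1]
  if (K >= 2L) {
    fg <- mixMeans(fit)[K]
    if ("degenerate_fg" %in% flags) fg <- S
    corrected <- fg - bg
  } else {
    fg <- NA_real_
    corrected <- NA_real_
    flags <- c("blank", flags)
  }
  fg_vals <- mask@values[labels == "FG"]
  new("SpotQuantification",
      spotId = mask@spotId, kSelected = as.integer(K),
      bg = bg, fg = fg, corrected = corrected, labels = labels,
      nFg = sum(labels == "FG"), nBg = sum(labels == "BG"),
      nIntermediate = sum(labels == "INTERMEDIATE"),
      nSaturated = sum(mask@values >= S),
      fgEmpiricalMedian = if (length(fg_vals)) stats::median(fg_vals)
                          else NA_real_,
      fgEmpiricalMean = if (length(fg_vals)) mean(fg_vals) else NA_real_,
      flags = flags)
}

#' @rdname applyCensoring
setMethod("applyCensoring", signature(x = "numeric"), function(x, S) {
  if (S <= 0) stop("censoring threshold must be positive")
  pmin(x, S)
})

#' @rdname applyCensoring
setMethod("applyCensoring", signature(x = "PixelMask"), function(x, S) {
  if (S <= 0) stop("censoring threshold must be positive")
  PixelMask(pmin(x@values, S), satThreshold = S, spotId = x@spotId,
            coords = if (nrow(x@coords)) x@coords else NULL)
})

#' Tabulate spot quantifications
#'
#' @param x a \code{\linkS4class{SpotQuantification}}.
#' @param row.names,optional,... passed through (unused).
#' @return one-row \code{data.frame} with the standard output schema:
#'   \code{spot_id, K, bg, fg, corrected, n_pixels, n_fg, n_intermediate,
#'   n_saturated, fg_empirical_median, flags}.
#' @export
as.data.frame.SpotQuantification <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(
    spot_id = x@spotId, K = x@kSelected, bg = x@bg, fg = x@fg,
    corrected = x@corrected, n_pixels = length(x@labels), n_fg = x@nFg,
    n_intermediate = x@nIntermediate, n_saturated = x@nSaturated,
    fg_empirical_median = x@fgEmpiricalMedian,
    flags = paste(x@flags, collapse = ","),
    stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "SpotQuantification",
          as.data.frame.SpotQuantification)
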