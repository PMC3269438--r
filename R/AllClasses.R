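#' @import methods
NULL

## Central S4 containers. Coordinates are 0-based (row, col); spot centers are
## given in (x, y) = (col, row) order, matching scanner conventions.

#' PixelMask: the pixels of one target mask
#'
#' A target mask is the hexagonal (or rectangular) cell around one spot
#' center, containing the spot and its local background.  A \code{PixelMask}
#' holds the pixel intensity values of one such cell, their optional image
#' coordinates, and the saturation threshold \code{S} at which values are
#' right-censored (pixels recorded exactly at \code{S} hit the scanner
#' ceiling; \code{S = Inf} marks genuinely uncensored data).
#'
#' @slot spotId character scalar identifier.
#' @slot values numeric vector of pixel intensities (ADU), all \code{<= S}.
#' @slot coords integer matrix with columns \code{row}, \code{col} (0-based)
#'   and one row per pixel, or a 0-row matrix when positions are unknown.
#' @slot satThreshold saturation threshold \code{S} in ADU (65535 for 16-bit
#'   scanners), or \code{Inf}.
#' @aliases PixelMask-class
#' @exportClass PixelMask
setClass("PixelMask",
  representation(
    spotId = "character",
    values = "numeric",
    coords = "matrix",
    satThreshold = "numeric"
  )
)

setValidity("PixelMask", function(object) {
  msg <- character(0)
  n <- length(object@values)
  if (n < 1L) msg <- c(msg, "mask must contain at least one pixel")
  if (length(object@spotId) != 1L) msg <- c(msg, "spotId must be a scalar")
  S <- object@satThreshold
  if (length(S) != 1L || is.na(S) || S <= 0)
    msg <- c(msg, "satThreshold must be a positive scalar (possibly Inf)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "pixel values must be finite")
  else if (length(S) == 1L && !is.na(S) && any(object@values > S))
    msg <- c(msg, "pixel values must not exceed the saturation threshold")
  if (nrow(object@coords) > 0L) {
    if (nrow(object@coords) != n)
      msg <- c(msg, "coords must have one row per pixel")
    if (ncol(object@coords) != 2L)
      msg <- c(msg, "coords must have two columns (row, col)")
    if (anyDuplicated(object@coords))
      msg <- c(msg, "pixel coordinates must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PixelMask
#'
#' @param values numeric vector of pixel intensities (ADU).
#' @param satThreshold saturation threshold \code{S} (default 65535, the
#'   16-bit ceiling); use \code{Inf} for uncensored data.
#' @param spotId spot identifier.
#' @param coords optional integer matrix of 0-based (row, col) positions.
#' @return a \code{\linkS4class{PixelMask}}.
#' @examples
#' m <- PixelMask(c(8000, 9000, 65535), spotId = "s1")
#' nSaturated(m)
#' @export
PixelMask <- function(values, satThreshold = 65535, spotId = "spot",
                      coords = NULL) {
  if (is.null(coords)) {
    coords <- matrix(integer(0), nrow = 0, ncol = 2,
                     dimnames = list(NULL, c("row", "col")))
  } else {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "integer"
    colnames(coords) <- c("row", "col")
  }
  new("PixelMask", spotId = as.character(spotId),
      values = as.numeric(values), coords = coords,
      satThreshold = as.numeric(satThreshold))
}

#' Parameters of a (possibly censored) Gaussian mixture
#'
#' Parameters of a \code{K}-component Gaussian mixture (\code{K <= 3}) whose
#' last component may be right-censored at the saturation threshold.
#' Components are ordered by increasing mean for identifiability; the
#' background is component 1 and the foreground is component \code{K}.
#'
#' @slot weights mixing weights, sum to 1.
#' @slot means component means (ADU), non-decreasing; the foreground mean may
#'   exceed the saturation threshold under the censored model.
#' @slot sds component standard deviations (ADU), positive.
#' @slot censoredLast logical; if \code{TRUE} the last component is a normal
#'   right-censored at \code{satThreshold}.
#' @slot satThreshold saturation threshold \code{S} (ADU).
#' @aliases MixtureParams-class
#' @exportClass MixtureParams
setClass("MixtureParams",
  representation(
    weights = "numeric",
    means = "numeric",
    sds = "numeric",
    censoredLast = "logical",
    satThreshold = "numeric"
  )
)

setValidity("MixtureParams", function(object) {
  msg <- character(0)
  K <- length(object@means)
  if (K < 1L || K > 3L) msg <- c(msg, "K must be 1, 2 or 3")
  if (length(object@weights) != K || length(object@sds) != K)
    msg <- c(msg, "weights, means and sds must have equal length")
  else {
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "mixing weights must sum to 1")
    if (any(object@weights < -1e-12 | object@weights > 1 + 1e-12))
      msg <- c(msg, "mixing weights must lie in [0, 1]")
    if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
    if (K > 1L && any(diff(object@means) < 0))
      msg <- c(msg, "means must be ordered increasingly")
  }
  if (length(object@censoredLast) != 1L)
    msg <- c(msg, "censoredLast must be a logical scalar")
  if (object@censoredLast && !is.finite(object@satThreshold))
    msg <- c(msg, "a censored last component requires a finite satThreshold")
  if (length(msg)) msg else TRUE
})

#' Construct MixtureParams
#'
#' @param weights,means,sds numeric vectors of equal length \code{K <= 3};
#'   means must be non-decreasing and weights sum to 1.
#' @param censoredLast is the last component right-censored at
#'   \code{satThreshold}?
#' @param satThreshold saturation threshold \code{S} (ADU).
#' @return a \code{\linkS4class{MixtureParams}}.
#' @examples
#' MixtureParams(c(0.8, 0.2), c(8000, 60000), c(2000, 6000),
#'               censoredLast = TRUE)
#' @export
MixtureParams <- function(weights, means, sds, censoredLast = FALSE,
                          satThreshold = 65535) {
  new("MixtureParams", weights = as.numeric(weights),
      means = as.numeric(means), sds = as.numeric(sds),
      censoredLast = isTRUE(censoredLast),
      satThreshold = as.numeric(satThreshold))
}

#' Result of an EM mixture fit
#'
#' @slot params fitted \code{\linkS4class{MixtureParams}}.
#' @slot resp n x K responsibility matrix; rows sum to 1.
#' @slot logLik attained observed-data log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @slot nIter number of EM iterations run.
#' @slot converged did the relative log-likelihood increase fall below the
#'   tolerance before \code{maxIter}?
#' @slot nParams number of free parameters, \code{3K - 1}.
#' @slot aic,bic information criteria, \code{-2 l + penalty}.
#' @slot flags character vector of condition flags (e.g.
#'   \code{"degenerate_fg"}, \code{"not_converged"}).
#' @slot spotId identifier of the fitted mask.
#' @slot selection list describing model selection when produced by
#'   \code{\link{selectK}} (criterion, per-K values, chosen K), else empty.
#' @aliases MixtureFit-class
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(
    params = "MixtureParams",
    resp = "matrix",
    logLik = "numeric",
    logLikTrace = "numeric",
    nIter = "integer",
    converged = "logical",
    nParams = "integer",
    aic = "numeric",
    bic = "numeric",
    flags = "character",
    spotId = "character",
    selection = "list"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character(0)
  K <- length(object@params@means)
  if (ncol(object@resp) != K)
    msg <- c(msg, "resp must have one column per component")
  else {
    rs <- rowSums(object@resp)
    if (any(abs(rs - 1) > 1e-8))
      msg <- c(msg, "responsibility rows must sum to 1")
    if (any(object@resp < -1e-12 | object@resp > 1 + 1e-12))
      msg <- c(msg, "responsibilities must lie in [0, 1]")
  }
  if (object@nParams != 3L * K - 1L)
    msg <- c(msg, "nParams must equal 3K - 1")
  if (length(msg)) msg else TRUE
})

#' Spot-level quantification
#'
#' Spot summary produced by \code{\link{quantifySpot}}: the background
#' intensity is the smallest fitted mean, the foreground intensity the
#' largest (model-based, so it may exceed the saturation threshold), and the
#' background-corrected intensity their difference.  Blank spots
#' (\code{K = 1}) carry \code{NA} foreground/corrected intensities.
#'
#' @slot spotId spot identifier.
#' @slot kSelected selected number of mixture components.
#' @slot bg background intensity (ADU).
#' @slot fg foreground intensity (ADU; \code{NA} for blank spots).
#' @slot corrected background-corrected intensity \code{fg - bg}.
#' @slot labels per-pixel labels in \code{"BG"}, \code{"INTERMEDIATE"},
#'   \code{"FG"}.
#' @slot nFg,nBg,nIntermediate,nSaturated pixel counts.
#' @slot fgEmpiricalMedian,fgEmpiricalMean empirical summaries over
#'   FG-labeled pixels (these saturate at \code{S}).
#' @slot flags condition flags (\code{"blank"}, \code{"degenerate_fg"},
#'   \code{"not_converged"}).
#' @aliases SpotQuantification-class
#' @exportClass SpotQuantification
setClass("SpotQuantification",
  representation(
    spotId = "character",
    kSelected = "integer",
    bg = "numeric",
    fg = "numeric",
    corrected = "numeric",
    labels = "character",
    nFg = "integer",
    nBg = "integer",
    nIntermediate = "integer",
    nSaturated = "integer",
    fgEmpiricalMedian = "numeric",
    fgEmpiricalMean = "numeric",
    flags = "character"
  )
)

setValidity("SpotQuantification", function(object) {
  msg <- character(0)
  n <- length(object@labels)
  if (object@nFg + object@nBg + object@nIntermediate != n)
    msg <- c(msg, "label counts must partition the pixels")
  if (!all(object@labels %in% c("BG", "INTERMEDIATE", "FG")))
    msg <- c(msg, "labels must be BG, INTERMEDIATE or FG")
  blank <- object@kSelected == 1L
  if (blank != ("blank" %in% object@flags))
    msg <- c(msg, "blank flag must coincide with K = 1")
  if (blank && !is.na(object@corrected))
    msg <- c(msg, "blank spots have no corrected intensity")
  if (length(msg)) msg else TRUE
})

#' Grid specification for target-mask construction
#'
#' @slot gridType \code{"hex"} (orange-crate packed arrays) or \code{"rect"}.
#' @slot centers numeric matrix with columns \code{x}, \code{y} (pixel units,
#'   0-based; x = column, y = row) and one row per spot.
#' @slot pitch nominal center-to-center spacing in pixels.
#' @slot imageShape integer (rows, cols) of the target image.
#' @slot spotIds character spot identifiers, one per center.
#' @aliases GridSpec-class
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    gridType = "character",
    centers = "matrix",
    pitch = "numeric",
    imageShape = "integer",
    spotIds = "character"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character(0)
  if (!object@gridType %in% c("hex", "rect"))
    msg <- c(msg, "gridType must be 'hex' or 'rect'")
  if (length(object@pitch) != 1L || !is.finite(object@pitch) ||
      object@pitch <= 0)
    msg <- c(msg, "pitch must be a positive scalar")
  if (nrow(object@centers) < 1L) msg <- c(msg, "need at least one center")
  if (ncol(object@centers) != 2L)
    msg <- c(msg, "centers must have two columns (x, y)")
  else {
    rows <- object@imageShape[1]; cols <- object@imageShape[2]
    if (any(object@centers[, 1] < 0 | object@centers[, 1] > cols - 1 |
            object@centers[, 2] < 0 | object@centers[, 2] > rows - 1))
      msg <- c(msg, "all centers must lie within the image bounds")
    if (anyDuplicated(object@centers))
      msg <- c(msg, "duplicate spot centers")
  }
  if (length(object@spotIds) != nrow(object@centers))
    msg <- c(msg, "need one spotId per center")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param centers matrix or data.frame with columns \code{x}, \code{y}
#'   (pixel units, 0-based).
#' @param pitch nominal center-to-center spacing in pixels.
#' @param imageShape integer (rows, cols).
#' @param gridType \code{"hex"} or \code{"rect"}.
#' @param spotIds optional spot identifiers (default \code{spot_1, ...}).
#' @return a \code{\linkS4class{GridSpec}}.
#' @export
GridSpec <- function(centers, pitch, imageShape, gridType = c("hex", "rect"),
                     spotIds = NULL) {
  gridType <- match.arg(gridType)
  centers <- as.matrix(centers)
  colnames(centers) <- c("x", "y")
  if (is.null(spotIds)) spotIds <- paste0("spot_", seq_len(nrow(centers)))
  new("GridSpec", gridType = gridType, centers = centers,
      pitch = as.numeric(pitch), imageShape = as.integer(imageShape),
      spotIds = as.character(spotIds))
}

#' Per-spot target masks over an image
#'
#' @slot spotIds spot identifiers.
#' @slot indices list of integer matrices, one per spot, with columns
#'   \code{row}, \code{col} (0-based pixel positions); masks are pairwise
#'   disjoint.
#' @slot clipped logical; was the cell clipped at an image border (edge
#'   spot)?
#' @slot imageShape integer (rows, cols).
#' @aliases TargetMaskSet-class
#' @exportClass TargetMaskSet
setClass("TargetMaskSet",
  representation(
    spotIds = "character",
    indices = "list",
    clipped = "logical",
    imageShape = "integer"
  )
)

setValidity("TargetMaskSet", function(object) {
  msg <- character(0)
  if (length(object@indices) != length(object@spotIds) ||
      length(object@clipped) != length(object@spotIds))
    msg <- c(msg, "indices, clipped and spotIds must be parallel")
  rows <- object@imageShape[1]; cols <- object@imageShape[2]
  all_lin <- unlist(lapply(object@indices, function(m) {
    if (nrow(m) == 0) return(integer(0))
    m[, 1] * cols + m[, 2]
  }))
  if (anyDuplicated(all_lin)) msg <- c(msg, "masks must be pairwise disjoint")
  for (m in object@indices) {
    if (nrow(m) > 0 && (any(m[, 1] < 0 | m[, 1] >= rows) ||
                        any(m[, 2] < 0 | m[, 2] >= cols))) {
      msg <- c(msg, "mask pixels must lie within the image")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulation scenario for the selection/bias study
#'
#' A generating censored Gaussian mixture mimicking immunosignaturing
#' arrays: the foreground (last) component sits so that a target fraction
#' \code{pSat} of its draws exceeds the saturation threshold.
#'
#' @slot kTrue true number of components (2 or 3).
#' @slot satThreshold saturation threshold \code{S} (default 65535).
#' @slot weights,means,sds generating mixture parameters (means increasing).
#' @slot pSat target foreground saturation fraction.
#' @slot nPixels pixels per simulated target mask.
#' @slot nTrials default number of simulation trials.
#' @aliases SimScenario-class
#' @exportClass SimScenario
setClass("SimScenario",
  representation(
    kTrue = "integer",
    satThreshold = "numeric",
    weights = "numeric",
    means = "numeric",
    sds = "numeric",
    pSat = "numeric",
    nPixels = "integer",
    nTrials = "integer"
  )
)

setValidity("SimScenario", function(object) {
  msg <- character(0)
  K <- object@kTrue
  if (!K %in% c(2L, 3L)) msg <- c(msg, "kTrue must be 2 or 3")
  if (length(object@means) != K || length(object@sds) != K ||
      length(object@weights) != K)
    msg <- c(msg, "parameter vectors must have length kTrue")
  else {
    if (any(diff(object@means) <= 0))
      msg <- c(msg, "means must be strictly increasing")
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must sum to 1")
    p <- stats::pnorm((object@satThreshold - object@means[K]) /
                        object@sds[K], lower.tail = FALSE)
    if (abs(p - object@pSat) > 1e-12)
      msg <- c(msg, "foreground mean inconsistent with pSat")
  }
  if (object@pSat <= 0 || object@pSat >= 1)
    msg <- c(msg, "pSat must lie in (0, 1)")
  if (object@nPixels < 1L) msg <- c(msg, "nPixels must be positive")
  if (length(msg)) msg else TRUE
})

#' Summary of a simulation experiment
#'
#' @slot scenario the generating \code{\linkS4class{SimScenario}}.
#' @slot methods methods run, subset of \code{GMM0} (regular mixture on
#'   uncensored data), \code{CGMM} (censored mixture on censored data),
#'   \code{GMM1} (regular mixture on censored data).
#' @slot nTrials number of simulated trials.
#' @slot selectionRate percent of trials selecting the true K, per method.
#' @slot relBias relative bias per parameter (rows) and method (columns),
#'   computed over correctly-selected trials only.
#' @slot relBiasSE Monte-Carlo standard error of each relative bias (same
#'   layout as \code{relBias}).
#' @slot nTrialsUsed per-method number of correctly-selected trials entering
#'   the bias summaries.
#' @slot nFailed per-method number of trials whose fit failed.
#' @aliases SimSummary-class
#' @exportClass SimSummary
setClass("SimSummary",
  representation(
    scenario = "SimScenario",
    methods = "character",
    nTrials = "integer",
    selectionRate = "numeric",
    relBias = "matrix",
    relBiasSE = "matrix",
    nTrialsUsed = "integer",
    nFailed = "integer"
  )
)
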