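#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; use these rather
#' than reaching into slots.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spotId", function(x) standardGeneric("spotId"))
#' @rdname accessors
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))
#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))
#' @rdname accessors
#' @export
setGeneric("satThreshold", function(x) standardGeneric("satThreshold"))
#' @rdname accessors
#' @export
setGeneric("nSaturated", function(x) standardGeneric("nSaturated"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("mixWeights", function(x) standardGeneric("mixWeights"))
#' @rdname accessors
#' @export
setGeneric("mixMeans", function(x) standardGeneric("mixMeans"))
#' @rdname accessors
#' @export
setGeneric("mixSds", function(x) standardGeneric("mixSds"))
#' @rdname accessors
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))
#' @rdname accessors
#' @export
setGeneric("mixParams", function(x) standardGeneric("mixParams"))
#' @rdname accessors
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))
#' @rdname accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))
#' @rdname accessors
#' @export
setGeneric("bgIntensity", function(x) standardGeneric("bgIntensity"))
#' @rdname accessors
#' @export
setGeneric("fgIntensity", function(x) standardGeneric("fgIntensity"))
#' @rdname accessors
#' @export
setGeneric("correctedIntensity",
           function(x) standardGeneric("correctedIntensity"))
#' @rdname accessors
#' @export
setGeneric("pixelLabels", function(x) standardGeneric("pixelLabels"))
#' @rdname accessors
#' @export
setGeneric("maskIndices", function(x) standardGeneric("maskIndices"))
#' @rdname accessors
#' @export
setGeneric("isClipped", function(x) standardGeneric("isClipped"))
#' @rdname accessors
#' @export
setGeneric("selectionRates", function(x) standardGeneric("selectionRates"))
#' @rdname accessors
#' @export
setGeneric("relativeBiases", function(x) standardGeneric("relativeBiases"))
#' @rdname accessors
#' @export
setGeneric("relativeBiasSE", function(x) standardGeneric("relativeBiasSE"))

#' Censor intensity values at an (artificial) saturation threshold
#'
#' Elementwise \code{min(value, S)}; used both by the simulation harness and
#' to generate artificially censored data sets from uncensored images.  The
#' operation is idempotent, and for a \code{\linkS4class{PixelMask}} the
#' saturation threshold of the result becomes \code{S}.
#'
#' @param x numeric vector of intensities or a \code{PixelMask}.
#' @param S censoring threshold (> 0).
#' @return object of the same kind as \code{x}, censored at \code{S}.
#' @examples
#' applyCensoring(c(500, 900, 1200), 1000)
#' @export
setGeneric("applyCensoring", function(x, S) standardGeneric("applyCensoring"))

## ---- accessor methods ----

#' @rdname accessors
setMethod("spotId", "PixelMask", function(x) x@spotId)
#' @rdname accessors
setMethod("spotId", "MixtureFit", function(x) x@spotId)
#' @rdname accessors
setMethod("spotId", "SpotQuantification", function(x) x@spotId)
#' @rdname accessors
setMethod("pixelValues", "PixelMask", function(x) x@values)
#' @rdname accessors
setMethod("pixelCoords", "PixelMask", function(x) x@coords)
#' @rdname accessors
setMethod("satThreshold", "PixelMask", function(x) x@satThreshold)
#' @rdname accessors
setMethod("satThreshold", "MixtureParams", function(x) x@satThreshold)
#' @rdname accessors
setMethod("satThreshold", "MixtureFit",
          function(x) x@params@satThreshold)
#' @rdname accessors
setMethod("nSaturated", "PixelMask",
          function(x) sum(x@values >= x@satThreshold))

#' @rdname accessors
setMethod("nComponents", "MixtureParams", function(x) length(x@means))
#' @rdname accessors
setMethod("nComponents", "MixtureFit", function(x) length(x@params@means))
#' @rdname accessors
setMethod("mixWeights", "MixtureParams", function(x) x@weights)
#' @rdname accessors
setMethod("mixWeights", "MixtureFit", function(x) x@params@weights)
#' @rdname accessors
setMethod("mixMeans", "MixtureParams", function(x) x@means)
#' @rdname accessors
setMethod("mixMeans", "MixtureFit", function(x) x@params@means)
#' @rdname accessors
setMethod("mixSds", "MixtureParams", function(x) x@sds)
#' @rdname accessors
setMethod("mixSds", "MixtureFit", function(x) x@params@sds)
#' @rdname accessors
setMethod("isCensored", "MixtureParams", function(x) x@censoredLast)
#' @rdname accessors
setMethod("isCensored", "MixtureFit", function(x) x@params@censoredLast)
#' @rdname accessors
setMethod("mixParams", "MixtureFit", function(x) x@params)
#' @rdname accessors
setMethod("responsibilities", "MixtureFit", function(x) x@resp)
#' @rdname accessors
setMethod("converged", "MixtureFit", function(x) x@converged)
#' @rdname accessors
setMethod("fitFlags", "MixtureFit", function(x) x@flags)
#' @rdname accessors
setMethod("fitFlags", "SpotQuantification", function(x) x@flags)

#' @rdname accessors
setMethod("selectedK", "SpotQuantification", function(x) x@kSelected)
#' @rdname accessors
setMethod("bgIntensity", "SpotQuantification", function(x) x@bg)
#' @rdname accessors
setMethod("fgIntensity", "SpotQuantification", function(x) x@fg)
#' @rdname accessors
setMethod("correctedIntensity", "SpotQuantification", function(x) x@corrected)
#' @rdname accessors
setMethod("pixelLabels", "SpotQuantification", function(x) x@labels)

#' @rdname accessors
setMethod("spotId", "TargetMaskSet", function(x) x@spotIds)
#' @rdname accessors
setMethod("maskIndices", "TargetMaskSet", function(x) x@indices)
#' @rdname accessors
setMethod("isClipped", "TargetMaskSet", function(x) x@clipped)

#' @rdname accessors
setMethod("selectionRates", "SimSummary", function(x) x@selectionRate)
#' @rdname accessors
setMethod("relativeBiases", "SimSummary", function(x) x@relBias)
#' @rdname accessors
setMethod("relativeBiasSE", "SimSummary", function(x) x@relBiasSE)

#' @param object object to display.
#' @rdname accessors
setMethod("show", "PixelMask", function(object) {
  cat("PixelMask '", object@spotId, "': ", length(object@values),
      " pixels, S = ", format(object@satThreshold),
      ", ", sum(object@values >= object@satThreshold), " saturated\n",
      sep = "")
})

setMethod("show", "MixtureParams", function(object) {
  K <- length(object@means)
  cat(K, "-component ", if (object@censoredLast) "censored " else "",
      "Gaussian mixture (S = ", format(object@satThreshold), ")\n", sep = "")
  print(round(rbind(weight = object@weights, mean = object@means,
                    sd = object@sds), 4))
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit: K = ", nComponents(object),
      if (isCensored(object)) " (censored last component)", "\n",
      "  logLik = ", format(object@logLik), ", BIC = ",
      format(object@bic), ", ", object@nIter, " iterations",
      if (!object@converged) " [not converged]", "\n", sep = "")
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
  show(object@params)
})

setMethod("show", "SpotQuantification", function(object) {
  cat("Spot '", object@spotId, "': K = ", object@kSelected,
      if ("blank" %in% object@flags) " (blank)", "\n",
      "  bg = ", format(round(object@bg, 1)),
      ", fg = ", format(round(object@fg, 1)),
      ", corrected = ", format(round(object@corrected, 1)), "\n",
      "  pixels: ", object@nBg, " BG / ", object@nIntermediate,
      " intermediate / ", object@nFg, " FG (", object@nSaturated,
      " saturated)\n", sep = "")
})

setMethod("show", "TargetMaskSet", function(object) {
  sizes <- vapply(object@indices, nrow, integer(1))
  cat("TargetMaskSet: ", length(object@indices), " masks on a ",
      object@imageShape[1], "x", object@imageShape[2], " image; ",
      sum(object@clipped), " clipped at edges; mask sizes ",
      min(sizes), "-", max(sizes), " pixels\n", sep = "")
})

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario: K = ", object@kTrue, ", target FG saturation ",
      100 * object@pSat, "%, ", object@nPixels, " pixels/mask, S = ",
      format(object@satThreshold), "\n", sep = "")
  print(round(rbind(weight = object@weights, mean = object@means,
                    sd = object@sds), 4))
})

setMethod("show", "SimSummary", function(object) {
  cat("SimSummary over", object@nTrials, "trials\n")
  cat("  correct-K selection rate (%):\n")
  print(round(object@selectionRate, 1))
  cat("  relative bias (correct-K trials only):\n")
  print(round(object@relBias, 4))
})
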