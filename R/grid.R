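## Target-mask construction from spot centers and pixel extraction from
## 16-bit grayscale TIFF images, plus the plain-text I/O surface (centers
## CSV / GenePix-style tables in, results TSV + JSON run manifest out).
##
## Conventions: pixels live at integer 0-based (row, col) positions; spot
## centers are supplied in (x, y) = (col, row) order, matching scanner
## output.  Cells are built by nearest-center assignment, which yields
## hexagonal cells on an orange-crate (hexagonally packed) lattice and
## rectangles on a rectangular lattice; pixels farther than `pitch` from
## every center stay unassigned so distant background cannot bleed into
## edge masks.

#' Build per-spot target masks from a grid of spot centers
#'
#' Assigns every image pixel to its nearest spot center (Euclidean
#' distance), leaving pixels farther than \code{pitch} from all centers
#' unassigned.  On a hexagonally packed center lattice this produces the
#' hexagonal target masks appropriate to orange-crate printed arrays; on a
#' rectangular lattice it produces rectangles.  Cells whose nominal extent
#' crosses an image border are clipped there and flagged.
#'
#' @param grid a \code{\linkS4class{GridSpec}}.
#' @return a \code{\linkS4class{TargetMaskSet}} with pairwise-disjoint
#'   masks.
#' @export
buildMasks <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  validObject(grid)
  rows <- grid@imageShape[1]; cols <- grid@imageShape[2]
  centers <- grid@centers
  ncen <- nrow(centers)
  pitch <- grid@pitch
  if (ncen > 1) {
    nn <- .nnDistance(centers)
    if (abs(stats::median(nn) - pitch) > 0.25 * pitch)
      warning("pitch (", pitch, ") differs from the median nearest-",
              "neighbor center distance (", round(stats::median(nn), 2),
              ") by more than 25%")
  }
  best <- matrix(Inf, rows, cols)
  idx <- matrix(0L, rows, cols)
  p2 <- pitch^2
  for (j in seq_len(ncen)) {
    cx <- centers[j, 1]; cy <- centers[j, 2]
    rr <- max(0, ceiling(cy - pitch)):min(rows - 1, floor(cy + pitch))
    cc <- max(0, ceiling(cx - pitch)):min(cols - 1, floor(cx + pitch))
    d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
    sub <- best[rr + 1, cc + 1, drop = FALSE]
    upd <- d2 < sub & d2 <= p2
    if (any(upd)) {
      sub[upd] <- d2[upd]
      best[rr + 1, cc + 1] <- sub
      isub <- idx[rr + 1, cc + 1, drop = FALSE]
      isub[upd] <- j
      idx[rr + 1, cc + 1] <- isub
    }
  }
  indices <- vector("list", ncen)
  assigned <- which(idx > 0L, arr.ind = TRUE)
  owner <- idx[assigned]
  for (j in seq_len(ncen)) {
    sel <- assigned[owner == j, , drop = FALSE]
    m <- cbind(row = sel[, 1] - 1L, col = sel[, 2] - 1L)
    storage.mode(m) <- "integer"
    indices[[j]] <- m
  }
  clipped <- centers[, 1] < pitch | centers[, 1] > cols - 1 - pitch |
             centers[, 2] < pitch | centers[, 2] > rows - 1 - pitch
  new("TargetMaskSet", spotIds = grid@spotIds, indices = indices,
      clipped = as.logical(clipped),
      imageShape = grid@imageShape)
}

.nnDistance <- function(centers) {
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Extract per-spot pixel values from an image
#'
#' Looks up each mask's pixel values in the image, clamps them to
#' \code{[0, S]} (so an \code{S} below the native 16-bit ceiling acts as an
#' artificial saturation threshold), and returns one
#' \code{\linkS4class{PixelMask}} per spot with coordinates preserved.
#' Empty masks are skipped with a warning.
#'
#' @param image numeric/integer matrix (rows x cols) of pixel intensities,
#'   as returned by \code{\link{readImage}}.
#' @param masks a \code{\linkS4class{TargetMaskSet}}.
#' @param S saturation threshold (default 65535).
#' @return named list of \code{\linkS4class{PixelMask}} objects.
#' @export
extractPixels <- function(image, masks, S = 65535) {
  stopifnot(is(masks, "TargetMaskSet"), is.matrix(image))
  if (any(dim(image) != masks@imageShape))
    stop("image dimensions do not match the mask set")
  out <- list()
  for (j in seq_along(masks@indices)) {
    m <- masks@indices[[j]]
    if (nrow(m) == 0) {
      warning("empty mask for spot ", masks@spotIds[j], "; skipped")
      next
    }
    vals <- image[cbind(m[, 1] + 1L, m[, 2] + 1L)]
    vals <- pmin(pmax(as.numeric(vals), 0), S)
    out[[masks@spotIds[j]]] <- PixelMask(vals, satThreshold = S,
                                         spotId = masks@spotIds[j],
                                         coords = m)
  }
  out
}

#' Read a 16-bit grayscale TIFF image
#'
#' @param path path to a single-channel 16-bit grayscale TIFF.
#' @return integer matrix (rows x cols) of raw pixel intensities in
#'   \code{[0, 65535]}.
#' @export
readImage <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) == 3L)
    stop("multi-channel TIFF images are not supported; supply one ",
         "grayscale channel per file")
  bits <- attr(img, "bits.per.sample")
  if (!is.null(bits) && bits != 16L)
    stop("expected a 16-bit image, got ", bits, " bits per sample")
  storage.mode(img) <- "integer"
  d <- dim(img)
  attributes(img) <- NULL
  dim(img) <- d
  img
}

#' Read spot centers into a GridSpec
#'
#' Accepts either a plain CSV with columns \code{spot_id}, \code{x},
#' \code{y} (pixel units, 0-based; an optional \code{block} column is
#' carried into the spot ids) or a GenePix-style results table (ATF/GPR)
#' whose \code{X}, \code{Y} center columns are in micrometres and are
#' converted with the \code{micronsPerPixel} scanner-resolution factor.
#'
#' @param path path to the centers file.
#' @param imageShape integer (rows, cols) of the image the centers refer
#'   to.
#' @param pitch nominal center-to-center spacing in pixels.
#' @param gridType \code{"hex"} or \code{"rect"}.
#' @param format \code{"auto"} (by extension), \code{"csv"} or
#'   \code{"gpr"}.
#' @param micronsPerPixel scanner resolution for GPR input (required for
#'   \code{format = "gpr"}; GPR files do not reliably carry it).
#' @return a \code{\linkS4class{GridSpec}} (centers are validated against
#'   the image bounds).
#' @export
readCenters <- function(path, imageShape, pitch,
                        gridType = c("hex", "rect"),
                        format = c("auto", "csv", "gpr"),
                        micronsPerPixel = NULL) {
  gridType <- match.arg(gridType)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gpr$", path, ignore.case = TRUE)) "gpr"
              else "csv"
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("spot_id", "x", "y")
    if (!all(need %in% names(tab)))
      stop("centers CSV must contain columns ",
           paste(need, collapse = ", "))
    ids <- as.character(tab$spot_id)
    if ("block" %in% names(tab)) ids <- paste(tab$block, ids, sep = ":")
    centers <- cbind(x = as.numeric(tab$x), y = as.numeric(tab$y))
  } else {
    if (is.null(micronsPerPixel))
      stop("micronsPerPixel must be supplied for GPR input (scanner ",
           "resolution metadata)")
    tab <- .readGpr(path)
    if (!all(c("X", "Y") %in% names(tab)))
      stop("GPR table must contain X and Y center columns")
    ids <- if (all(c("Block", "Column", "Row") %in% names(tab)))
      paste(tab$Block, tab$Row, tab$Column, sep = "-")
    else if ("ID" %in% names(tab)) as.character(tab$ID)
    else paste0("spot_", seq_len(nrow(tab)))
    centers <- cbind(x = as.numeric(tab$X) / micronsPerPixel,
                     y = as.numeric(tab$Y) / micronsPerPixel)
  }
  GridSpec(centers, pitch = pitch, imageShape = imageShape,
           gridType = gridType, spotIds = ids)
}

## minimal ATF/GPR reader: skip the optional-header block, keep the table
.readGpr <- function(path) {
  lines <- readLines(path, n = 200L)
  hdr <- grep("(^|\t)\"?Block\"?\t", lines)[1]
  if (is.na(hdr)) stop("could not locate the GPR column header line")
  utils::read.delim(path, skip = hdr - 1L, check.names = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write (and read back) spot quantification results
#'
#' \code{writeResults} emits the tab-separated spot table (schema:
#' \code{spot_id, K, bg, fg, corrected, n_pixels, n_fg, n_intermediate,
#' n_saturated, fg_empirical_median, flags}) plus an optional JSON run
#' manifest recording parameters, package version and seed.
#'
#' @param path output TSV path.
#' @param results list of \code{\linkS4class{SpotQuantification}} objects
#'   or an already-assembled \code{data.frame}.
#' @param manifest optional named list of run parameters written as JSON
#'   next to \code{path} (\code{<path>.manifest.json}) or at
#'   \code{manifestPath}.
#' @param manifestPath optional explicit manifest path.
#' @return invisibly, the written \code{data.frame}.
#' @export
writeResults <- function(path, results, manifest = NULL,
                         manifestPath = NULL) {
  tab <- if (is.data.frame(results)) results
  else do.call(rbind, lapply(results, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(manifest)) {
    manifest$package <- "censpot"
    manifest$version <- as.character(utils::packageVersion("censpot"))
    if (is.null(manifestPath))
      manifestPath <- paste0(path, ".manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(tab)
}

#' @rdname writeResults
#' @return \code{readResults}: the results \code{data.frame}.
#' @export
readResults <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(spot_id = "character",
                                   flags = "character"))
}

#' Segment and quantify every spot of a gridded image
#'
#' Convenience pipeline: build target masks from the grid, extract per-spot
#' pixels, run \code{\link{selectK}} on each mask and
#' \code{\link{quantifySpot}} on the winner.
#'
#' @param image matrix from \code{\link{readImage}}.
#' @param grid a \code{\linkS4class{GridSpec}}.
#' @param S saturation threshold (default 65535).
#' @param censored use the censored mixture (saturation-corrected)?
#' @param criterion,relThreshold passed to \code{\link{selectK}}.
#' @return \code{data.frame} with one row per spot (the
#'   \code{\link{writeResults}} schema).
#' @export
segmentImage <- function(image, grid, S = 65535, censored = TRUE,
                         criterion = "BIC", relThreshold = 0.001) {
  masks <- buildMasks(grid)
  pix <- extractPixels(image, masks, S = S)
  rows <- lapply(pix, function(mask) {
    fit <- selectK(mask, censored = censored, criterion = criterion,
                   relThreshold = relThreshold)
    as.data.frame(quantifySpot(mask, fit))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
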