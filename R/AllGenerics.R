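#' Accessors
#'
#' Small accessor family for the package's S4 containers; user code should
#' use these rather than reaching into slots.
#'
#' @param object,x one of the package's S4 objects.
#' @param ... unused.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesImages", function(object, ...) standardGeneric("seriesImages"))

#' @rdname accessors
#' @export
setMethod("seriesImages", "LongitudinalSeries", function(object, ...) object@images)

#' @rdname accessors
#' @export
setMethod("seriesImages", "Phantom", function(object, ...) object@images)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object, ...) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LongitudinalSeries", function(object, ...) object@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LevelSetTriple", function(object, ...) object@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "Phantom", function(object, ...) object@spec@voxelSpacing)

#' @rdname accessors
#' @export
setGeneric("phantomLabels", function(object, ...) standardGeneric("phantomLabels"))

#' @rdname accessors
#' @export
setMethod("phantomLabels", "Phantom", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setGeneric("phantomPriors", function(object, ...) standardGeneric("phantomPriors"))

#' @rdname accessors
#' @export
setMethod("phantomPriors", "Phantom", function(object, ...) object@priors)

#' @rdname accessors
#' @export
setGeneric("phantomSpecOf", function(object, ...) standardGeneric("phantomSpecOf"))

#' @rdname accessors
#' @export
setMethod("phantomSpecOf", "Phantom", function(object, ...) object@spec)

#' @rdname accessors
#' @export
setGeneric("groundTruthThicknessOf",
  function(object, ...) standardGeneric("groundTruthThicknessOf"))

#' @rdname accessors
#' @export
setMethod("groundTruthThicknessOf", "Phantom", function(object, ...) object@gtThickness)

#' @rdname accessors
#' @export
setGeneric("resultLabels", function(object, ...) standardGeneric("resultLabels"))

#' @rdname accessors
#' @export
setMethod("resultLabels", "SegmentationResult", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setGeneric("resultThickness", function(object, ...) standardGeneric("resultThickness"))

#' @rdname accessors
#' @export
setMethod("resultThickness", "SegmentationResult", function(object, ...) object@thickness)

#' @rdname accessors
#' @export
setGeneric("resultReport", function(object, ...) standardGeneric("resultReport"))

#' @rdname accessors
#' @export
setMethod("resultReport", "SegmentationResult", function(object, ...) object@report)

#' @rdname accessors
#' @export
setGeneric("thicknessValues", function(object, ...) standardGeneric("thicknessValues"))

#' @rdname accessors
#' @export
setMethod("thicknessValues", "ThicknessField", function(object, ...) object@thickness)

#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(object, ...) standardGeneric("surfacePoints"))

#' @rdname accessors
#' @export
setMethod("surfacePoints", "ThicknessField", function(object, ...) object@points)

#' @rdname accessors
#' @export
setGeneric("thicknessTable", function(object, ...) standardGeneric("thicknessTable"))

#' @rdname accessors
#' @export
setMethod("thicknessTable", "ThicknessField", function(object, ...) {
  pts <- object@points
  colnames(pts) <- paste0(c("x", "y", "z")[seq_len(ncol(pts))], "_mm")
  data.frame(pts, thickness_mm = object@thickness)
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "),
      "grid,", object@nTimepoints, "time points\n")
  cat("  spacing (mm):", paste(object@voxelSpacing, collapse = ", "), "\n")
  cat("  class means (CSF,GM,WM):", paste(object@baseMeans, collapse = ", "),
      " decline/step:", paste(object@perStepDecline, collapse = ", "), "\n")
  cat("  noise sigma:", object@noiseSigma, " PVE sigma (mm):", object@pveSigma, "\n")
  cat("  GM thickness (mm):", object@baselineThickness,
      " shrinkage rate:", object@shrinkageRate, "\n")
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom with", length(object@labels), "time points on a",
      paste(dim(object@labels[[1]]), collapse = " x "), "grid\n")
  cat("  shrinkage rate:", object@spec@shrinkageRate,
      " noise sigma:", object@spec@noiseSigma, "\n")
})

setMethod("show", "LongitudinalSeries", function(object) {
  cat("LongitudinalSeries:", length(object@images), "time points,",
      paste(dim(object@images[[1]]), collapse = " x "), "grid, spacing",
      paste(object@spacing, collapse = "x"), "mm\n")
})

setMethod("show", "LevelSetTriple", function(object) {
  cat("LevelSetTriple (t =", object@timeIndex, ") on a",
      paste(dim(object@phi1), collapse = " x "), "grid\n")
})

setMethod("show", "ThicknessField", function(object) {
  cat("ThicknessField:", nrow(object@points), "surface points, thickness",
      sprintf("%.2f-%.2f mm (mean %.2f)", min(object@thickness),
              max(object@thickness), mean(object@thickness)), "\n")
})

setMethod("show", "EvolutionParams", function(object) {
  cat("EvolutionParams: nu =", object@nu, " lambdaS =", object@lambdaS,
      " mu =", object@mu, " omega =", object@omega, "\n")
  cat("  thickness range [", object@dmin, ",", object@dmax, "] mm;",
      object@nOuter, "outer x", object@nInner, "inner iterations\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:", length(object@labels), "time points\n")
  if (!is.null(object@report$dice)) {
    cat("  Dice vs ground truth:\n")
    print(object@report$dice)
  }
})
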