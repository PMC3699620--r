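# Quantitative evaluation: Dice overlap, per-ROI mean thickness, and the
# temporal-variation statistic used to quantify longitudinal consistency.

#' Dice ratio
#'
#' \eqn{DR = 2|A \cap B| / (|A| + |B|)}, ranging from 0 (worst) to 1 (best
#' agreement). Two empty sets agree perfectly (1); exactly one empty set
#' gives 0.
#'
#' @param a,b logical volumes on the same grid.
#' @return overlap ratio in \[0, 1\].
#' @examples
#' dice(matrix(c(TRUE, TRUE, FALSE), 1), matrix(c(TRUE, FALSE, FALSE), 1))
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("volumes are on different grids")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(a & b) / (na + nb)
}

#' Mean cortical thickness per region of interest
#'
#' Averages the surface-point thickness over each ROI; a surface point is
#' assigned the ROI label of its nearest voxel centre. ROIs containing no
#' surface points are reported as \code{NA} (missing, not zero).
#'
#' @param thickness a [ThicknessField-class].
#' @param roiLabels integer ROI label volume on the image grid (0 = outside
#'   any ROI).
#' @param spacing voxel spacing in mm.
#' @return named numeric vector of per-ROI means, one entry per nonzero ROI
#'   label.
#' @export
roiMeanThickness <- function(thickness, roiLabels, spacing = 1) {
  stopifnot(is(thickness, "ThicknessField"))
  d <- dim(roiLabels)
  h <- .spacingFor(roiLabels, spacing)
  pts <- thickness@points
  idx <- matrix(0L, nrow(pts), length(d))
  for (a in seq_along(d))
    idx[, a] <- pmin(pmax(as.integer(round(pts[, a] / h[a] + 0.5)), 1L), d[a])
  lin <- idx[, 1]; mult <- 1
  for (a in seq_along(d)[-1]) {
    mult <- mult * d[a - 1]
    lin <- lin + (idx[, a] - 1L) * mult
  }
  ptRoi <- roiLabels[lin]
  rois <- sort(setdiff(unique(as.integer(roiLabels)), 0L))
  out <- vapply(rois, function(r) {
    sel <- ptRoi == r
    if (!any(sel)) NA_real_ else mean(thickness@thickness[sel])
  }, numeric(1))
  names(out) <- as.character(rois)
  out
}

#' Temporal variation of a per-time-point statistic
#'
#' Total variation \eqn{\sum_t |x_{t+1} - x_t|}: zero iff the series is
#' constant, and equal to the absolute range for any monotone series. Used
#' to quantify how "bumpy" a longitudinal thickness trajectory is.
#'
#' @param x numeric vector of per-time-point values (length >= 2).
#' @return a scalar.
#' @examples
#' temporalVariation(c(3.0, 3.4, 2.8)) # 1.0
#' @export
temporalVariation <- function(x) {
  if (length(x) < 2) stop("at least two time points are required")
  sum(abs(diff(x)))
}

#' Evaluate a segmentation result against ground truth
#'
#' @param result a [SegmentationResult-class].
#' @param gtLabels list of ground-truth label volumes.
#' @param roiLabels optional ROI label volume for per-ROI thickness.
#' @param spacing voxel spacing in mm.
#' @return list with \code{dice} (data frame), \code{meanThickness}
#'   (per-time-point mean outer-surface thickness), \code{temporalVariation}
#'   of the mean thickness, and per-ROI tables when ROIs are given.
#' @export
evaluateResult <- function(result, gtLabels, roiLabels = NULL, spacing = 1) {
  stopifnot(is(result, "SegmentationResult"))
  meanTh <- vapply(result@thickness, function(tf) mean(tf@thickness), 0)
  out <- list(dice = .diceTable(result@labels, gtLabels),
              meanThickness = meanTh,
              temporalVariation = temporalVariation(meanTh))
  if (!is.null(roiLabels)) {
    out$roiMeanThickness <- t(vapply(result@thickness, roiMeanThickness,
      numeric(length(setdiff(unique(as.integer(roiLabels)), 0L))),
      roiLabels = roiLabels, spacing = spacing))
    out$roiTemporalVariation <- apply(out$roiMeanThickness, 2,
                                      temporalVariation)
  }
  out
}
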