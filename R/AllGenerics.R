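#' @rdname painSurfaceIndex
#' @export
setGeneric("painSurfaceIndex", function(x) standardGeneric("painSurfaceIndex"))

#' @rdname predominantIntensity
#' @export
setGeneric("predominantIntensity",
           function(x) standardGeneric("predominantIntensity"))

#' @rdname colorCount
#' @export
setGeneric("colorCount", function(x) standardGeneric("colorCount"))

#' Accessors for avatar and summary objects
#'
#' `silhouetteMask()` returns the logical canvas mask; `viewMasks()` the
#' front/back halves as a named list; `pixelScale()` the cm^2-per-pixel
#' scale; `drawableArea()` the realised silhouette area in cm^2; `surfaces()`
#' the per-intensity surfaces of a [SurfaceSummary-class]; `totalSurface()`
#' its total.
#'
#' @param x an [Avatar-class] or [SurfaceSummary-class] object.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("silhouetteMask", function(x) standardGeneric("silhouetteMask"))

#' @rdname accessors
#' @export
setGeneric("viewMasks", function(x) standardGeneric("viewMasks"))

#' @rdname accessors
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' @rdname accessors
#' @export
setGeneric("drawableArea", function(x) standardGeneric("drawableArea"))

#' @rdname accessors
#' @export
setGeneric("surfaces", function(x) standardGeneric("surfaces"))

#' @rdname accessors
#' @export
setGeneric("totalSurface", function(x) standardGeneric("totalSurface"))

setMethod("silhouetteMask", "Avatar", function(x) x@mask)

setMethod("viewMasks", "Avatar", function(x) {
  list(front = x@mask[, seq_len(x@viewSplit), drop = FALSE],
       back = x@mask[, -seq_len(x@viewSplit), drop = FALSE])
})

setMethod("pixelScale", "Avatar", function(x) x@pixelScale)

setMethod("drawableArea", "Avatar", function(x) sum(x@mask) * x@pixelScale)

setMethod("surfaces", "SurfaceSummary", function(x) x@surfaces)

setMethod("totalSurface", "SurfaceSummary", function(x) x@total)

setMethod("show", "Avatar", function(object) {
  cat(sprintf("Avatar: %.0f cm, %.0f kg (BMI %.1f)\n", object@height,
              object@weight, object@weight / (object@height / 100)^2))
  cat(sprintf("  canvas %d x %d px at %.1f mm/px (%.3f cm^2/px)\n",
              nrow(object@mask), ncol(object@mask), object@resolution,
              object@pixelScale))
  cat(sprintf("  drawable area %.1f cm^2 (Du Bois target %.1f cm^2)\n",
              drawableArea(object), object@targetArea))
})

setMethod("show", "PainDrawing", function(object) {
  px <- vapply(object@intensityMasks, sum, 0)
  ty <- vapply(object@typologyMasks, sum, 0)
  cat("PainDrawing on", paste(dim(object@intensityMasks[[1]]), collapse = " x "),
      "grid\n")
  cat("  intensity px:", paste(sprintf("%s=%d", names(px), px), collapse = ", "),
      "\n")
  cat("  typology px: ", paste(sprintf("%s=%d", names(ty), ty), collapse = ", "),
      "\n")
})

setMethod("show", "SurfaceSummary", function(object) {
  cat(sprintf("SurfaceSummary: total %.2f cm^2, index %.2f, %d color(s)\n",
              object@total, object@index, object@colorCount))
  for (lv in names(object@surfaces))
    cat(sprintf("  %-12s %9.2f cm^2  (%5.1f%%)\n", lv, object@surfaces[lv],
                object@percentages[lv]))
  cat("  predominant:", ifelse(is.na(object@predominant), "none",
                               object@predominant), "\n")
})

setMethod("show", "TypologySummary", function(object) {
  cat(sprintf(
    "TypologySummary: neuropathic %.2f cm^2 (%.1f%%), mechanical %.2f cm^2 (%.1f%%), mixed %.2f cm^2\n",
    object@neuropathic, object@neuropathicPct, object@mechanical,
    object@mechanicalPct, object@mixed))
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig (synthetic cohort generator)\n")
  cat("  group probs (painless, low..very_severe):",
      paste(signif(object@groupProbs, 4), collapse = ", "), "\n")
  cat("  stratum NPRS means:", paste(object@groupNprsMean, collapse = ", "),
      " SDs:", paste(object@groupNprsSD, collapse = ", "), "\n")
  cat(sprintf("  total surface ~ lognormal(%.4f, %.4f); coupling %.4f\n",
              object@surfaceLogMean, object@surfaceLogSD, object@coupling))
})
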