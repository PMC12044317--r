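#' @import methods
NULL

## Canonical intensity ordering, least to most severe. Weights are the
## published scoring weights; display colors follow the charting interface.
.INTENSITY_LEVELS <- c("low", "moderate", "severe", "very_severe")
.INTENSITY_WEIGHTS <- c(low = 1, moderate = 2, severe = 3, very_severe = 4)
.INTENSITY_COLORS <- c(low = "light blue", moderate = "dark blue",
                       severe = "orange", very_severe = "red")

.TYPOLOGY_SUBLAYERS <- c(nociceptive = "mechanical", trigger = "mechanical",
                         burn = "neuropathic", tingling = "neuropathic",
                         allodynia = "neuropathic", hypoesthesia = "neuropathic")

#' Intensity levels and scoring weights
#'
#' The body chart offers four pain-intensity colors. Each carries an integer
#' scoring weight used by the pain surface index: 1 (low, light blue),
#' 2 (moderate, dark blue), 3 (severe, orange), 4 (very severe, red).
#'
#' @return `intensityLevels()` returns the four level names in increasing
#'   severity; `intensityWeights()` the named integer weights;
#'   `typologySublayers()` a named character vector mapping each of the six
#'   typology sublayers to its family (`"mechanical"` or `"neuropathic"`).
#' @examples
#' intensityLevels()
#' intensityWeights()
#' @export
intensityLevels <- function() .INTENSITY_LEVELS

#' @rdname intensityLevels
#' @export
intensityWeights <- function() .INTENSITY_WEIGHTS

#' @rdname intensityLevels
#' @export
typologySublayers <- function() .TYPOLOGY_SUBLAYERS

#' Avatar: an anthropometry-scaled two-view body silhouette
#'
#' An `Avatar` holds front and back body silhouettes on a single raster
#' canvas (front view on the left, back view on the right), together with
#' the physical scale of a pixel. The silhouette is scaled so that the total
#' drawable area across both views equals the patient's Du Bois body surface
#' area.
#'
#' @slot height numeric, standing height in cm.
#' @slot weight numeric, body mass in kg.
#' @slot resolution numeric, pixel edge length in mm.
#' @slot mask logical matrix, TRUE inside the silhouette (both views).
#' @slot viewSplit integer, last column of the front view; columns
#'   `1:viewSplit` are the front view, the rest the back view.
#' @slot pixelScale numeric, cm^2 per pixel (`resolution^2 / 100`).
#' @slot targetArea numeric, the Du Bois BSA in cm^2 the silhouette was
#'   scaled to.
#' @export
setClass("Avatar",
  representation(height = "numeric", weight = "numeric",
                 resolution = "numeric", mask = "matrix",
                 viewSplit = "integer", pixelScale = "numeric",
                 targetArea = "numeric"))

setValidity("Avatar", function(object) {
  msg <- character()
  if (object@pixelScale <= 0) msg <- c(msg, "pixelScale must be > 0")
  if (!is.logical(object@mask) || !any(object@mask))
    msg <- c(msg, "silhouette mask must be a nonempty logical matrix")
  fr <- object@mask[, seq_len(object@viewSplit), drop = FALSE]
  bk <- object@mask[, -seq_len(object@viewSplit), drop = FALSE]
  if (!any(fr) || !any(bk))
    msg <- c(msg, "both views must contain silhouette pixels")
  got <- sum(object@mask) * object@pixelScale
  if (abs(got - object@targetArea) > 0.01 * object@targetArea)
    msg <- c(msg, sprintf(
      "silhouette area %.1f cm^2 deviates from target BSA %.1f cm^2 by > 1%%",
      got, object@targetArea))
  if (length(msg)) msg else TRUE
})

#' PainDrawing: per-layer binary pain masks on an avatar grid
#'
#' Four intensity layers (one per color) and six typology sublayers
#' (nociceptive, trigger; burn, tingling, allodynia, hypoesthesia), each a
#' logical raster congruent with the avatar canvas. Intensity layers are
#' stored as drawn; [resolveIntensityLayers()] makes them disjoint with a
#' most-severe-wins rule. Mechanical and neuropathic typology families may
#' overlap; the overlap is mixed pain.
#'
#' @slot intensityMasks named list of 4 logical matrices
#'   (low/moderate/severe/very_severe).
#' @slot typologyMasks named list of 6 logical matrices, one per sublayer.
#' @export
setClass("PainDrawing",
  representation(intensityMasks = "list", typologyMasks = "list"))

setValidity("PainDrawing", function(object) {
  msg <- character()
  if (!identical(names(object@intensityMasks), .INTENSITY_LEVELS))
    msg <- c(msg, "intensityMasks must be named low/moderate/severe/very_severe")
  if (!identical(sort(names(object@typologyMasks)),
                 sort(names(.TYPOLOGY_SUBLAYERS))))
    msg <- c(msg, "typologyMasks must carry the six typology sublayers")
  dims <- unique(lapply(c(object@intensityMasks, object@typologyMasks), dim))
  if (length(dims) > 1L) msg <- c(msg, "all masks must share one grid")
  if (length(msg)) msg else TRUE
})

#' SurfaceSummary: per-intensity surfaces and patient-level indices
#'
#' @slot surfaces named numeric, cm^2 per intensity level.
#' @slot total numeric, total painted surface in cm^2.
#' @slot percentages named numeric, percentage of total per level (all 0
#'   when total is 0).
#' @slot index numeric, the weighted pain surface index in cm^2.
#' @slot colorCount integer, number of levels with positive surface.
#' @slot predominant character, level with the largest surface (ties to the
#'   more severe level), or `NA_character_` for a painless chart.
#' @export
setClass("SurfaceSummary",
  representation(surfaces = "numeric", total = "numeric",
                 percentages = "numeric", index = "numeric",
                 colorCount = "integer", predominant = "character"))

setValidity("SurfaceSummary", function(object) {
  msg <- character()
  if (!identical(names(object@surfaces), .INTENSITY_LEVELS))
    msg <- c(msg, "surfaces must be named low/moderate/severe/very_severe")
  if (any(object@surfaces < 0)) msg <- c(msg, "surfaces must be >= 0")
  if (abs(object@total - sum(object@surfaces)) >
      1e-8 * max(1, object@total))
    msg <- c(msg, "total must equal the sum of per-level surfaces")
  if (length(msg)) msg else TRUE
})

#' TypologySummary: neuropathic / mechanical / mixed decomposition
#'
#' Family surfaces use the exclusive convention: `neuropathic` is the union
#' of the four neuropathic sublayers minus any overlap with the mechanical
#' union, `mechanical` symmetrically, and `mixed` is the overlap itself, so
#' the three always sum to the area of the full typology union.
#'
#' @slot neuropathic,mechanical,mixed numeric surfaces in cm^2.
#' @slot neuropathicPct,mechanicalPct numeric, percent of the total painted
#'   surface (0 when nothing is painted).
#' @slot byIntensity numeric matrix (2 families x 4 intensity levels), each
#'   family's exclusive region crossed with the resolved intensity layers,
#'   in cm^2.
#' @export
setClass("TypologySummary",
  representation(neuropathic = "numeric", mechanical = "numeric",
                 mixed = "numeric", neuropathicPct = "numeric",
                 mechanicalPct = "numeric", byIntensity = "matrix"))

setValidity("TypologySummary", function(object) {
  vals <- c(object@neuropathic, object@mechanical, object@mixed)
  if (any(vals < 0)) return("typology surfaces must be >= 0")
  pct <- c(object@neuropathicPct, object@mechanicalPct)
  if (any(pct < 0 | pct > 100)) return("percentages must lie in [0, 100]")
  TRUE
})

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Calibration constants default to the published full-cohort tables; see
#' [cohortConfig()] for the meaning of each field and [generateCohort()] for
#' the generative model.
#'
#' @slot groupProbs numeric(5): painless plus the four predominant-intensity
#'   strata (low/moderate/severe/very_severe order), summing to 1.
#' @slot groupNprsMean,groupNprsSD numeric(4) per-stratum NPRS moments,
#'   stored in low..very_severe order.
#' @slot colorCountProbs numeric(5) over 0..4 colors.
#' @slot surfaceLogMean,surfaceLogSD numeric lognormal parameters of total
#'   surface.
#' @slot intensityShares numeric(4) mean share of total per level.
#' @slot shareConcentration numeric Dirichlet concentration for shares.
#' @slot typologyProps numeric(3) mean neuropathic/mechanical/mixed shares.
#' @slot typologyConcentration numeric Dirichlet concentration.
#' @slot coupling numeric Gaussian-copula correlation linking the NPRS and
#'   total-surface latents within stratum.
#' @slot painlessNprsMean,painlessNprsSD numeric NPRS moments of the
#'   painless stratum.
#' @export
setClass("CohortConfig",
  representation(groupProbs = "numeric", groupNprsMean = "numeric",
                 groupNprsSD = "numeric", colorCountProbs = "numeric",
                 surfaceLogMean = "numeric", surfaceLogSD = "numeric",
                 intensityShares = "numeric", shareConcentration = "numeric",
                 typologyProps = "numeric", typologyConcentration = "numeric",
                 coupling = "numeric", painlessNprsMean = "numeric",
                 painlessNprsSD = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@groupProbs) != 5L ||
      abs(sum(object@groupProbs) - 1) > 1e-8 || any(object@groupProbs < 0))
    msg <- c(msg, "groupProbs must be 5 nonnegative values summing to 1")
  if (length(object@colorCountProbs) != 5L ||
      abs(sum(object@colorCountProbs) - 1) > 1e-8 ||
      any(object@colorCountProbs < 0))
    msg <- c(msg, "colorCountProbs must be 5 nonnegative values summing to 1")
  if (length(object@groupNprsMean) != 4L || length(object@groupNprsSD) != 4L)
    msg <- c(msg, "group NPRS moments must have 4 entries")
  if (any(object@groupNprsSD <= 0)) msg <- c(msg, "group NPRS SDs must be > 0")
  if (length(object@intensityShares) != 4L ||
      abs(sum(object@intensityShares) - 1) > 1e-8)
    msg <- c(msg, "intensityShares must be 4 values summing to 1")
  if (length(object@typologyProps) != 3L ||
      abs(sum(object@typologyProps) - 1) > 1e-8)
    msg <- c(msg, "typologyProps must be 3 values summing to 1")
  if (abs(object@coupling) >= 1) msg <- c(msg, "coupling must lie in (-1, 1)")
  if (object@surfaceLogSD <= 0) msg <- c(msg, "surfaceLogSD must be > 0")
  if (length(msg)) msg else TRUE
})
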