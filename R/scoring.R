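.asSurfaceVector <- function(x) {
  if (length(x) != 4L) stop("need 4 per-intensity surfaces")
  if (!is.numeric(x) || anyNA(x)) stop("surfaces must be numeric and non-NA")
  if (any(x < 0)) stop("surfaces must be >= 0")
  if (is.null(names(x))) names(x) <- .INTENSITY_LEVELS
  x[.INTENSITY_LEVELS]
}

#' Summarise per-intensity surfaces into patient-level indices
#'
#' @param surfaces numeric(4), cm^2 per level, in low/moderate/severe/
#'   very_severe order (names optional).
#' @return a [SurfaceSummary-class] carrying the total, per-level
#'   percentages, weighted pain surface index, color count and predominant
#'   intensity.
#' @examples
#' s <- surfaceSummary(c(100, 50, 25, 10))
#' painSurfaceIndex(s)   # 315
#' @export
surfaceSummary <- function(surfaces) {
  s <- .asSurfaceVector(surfaces)
  total <- sum(s)
  pct <- if (total > 0) 100 * s / total else s * 0
  new("SurfaceSummary", surfaces = s, total = total, percentages = pct,
      index = .psi(s), colorCount = .colorCount(s),
      predominant = .predominant(s))
}

.psi <- function(s) sum(.INTENSITY_WEIGHTS * s)

.predominant <- function(s) {
  if (sum(s) == 0) return(NA_character_)
  ## ties break toward the more severe level: scan from severe end
  i <- 5L - which.max(rev(s))
  .INTENSITY_LEVELS[i]
}

.colorCount <- function(s) sum(s > 0)

#' Weighted pain surface index
#'
#' The pain surface index is the per-intensity surface weighted by the
#' intensity's integer weight and summed:
#' \eqn{PSI = 1\,S_{low} + 2\,S_{mod} + 3\,S_{sev} + 4\,S_{vsev}} (cm^2).
#' It lies between the total surface (all low) and four times the total
#' (all very severe).
#'
#' @param x a [SurfaceSummary-class] or a numeric(4) of per-level surfaces
#'   in low/moderate/severe/very_severe order.
#' @return the index in weighted cm^2.
#' @examples
#' painSurfaceIndex(c(100, 50, 25, 10))  # 315
#' @export
#' @rdname painSurfaceIndex
setMethod("painSurfaceIndex", "SurfaceSummary", function(x) x@index)

#' @rdname painSurfaceIndex
#' @export
setMethod("painSurfaceIndex", "numeric",
          function(x) .psi(.asSurfaceVector(x)))

#' Predominant intensity of a drawing
#'
#' The intensity level occupying the largest drawn surface. A painless
#' chart (total surface 0) has no predominant level and returns
#' `NA_character_`; ties are broken toward the more severe level.
#'
#' @param x a [SurfaceSummary-class] or numeric(4) of per-level surfaces.
#' @return one of `"low"`, `"moderate"`, `"severe"`, `"very_severe"`, or
#'   `NA_character_`.
#' @export
#' @rdname predominantIntensity
setMethod("predominantIntensity", "SurfaceSummary",
          function(x) x@predominant)

#' @rdname predominantIntensity
#' @export
setMethod("predominantIntensity", "numeric",
          function(x) .predominant(.asSurfaceVector(x)))

#' Number of intensity colors used
#'
#' @param x a [SurfaceSummary-class] or numeric(4) of per-level surfaces.
#' @return integer in 0..4: how many intensity levels carry a positive
#'   surface.
#' @export
#' @rdname colorCount
setMethod("colorCount", "SurfaceSummary", function(x) x@colorCount)

#' @rdname colorCount
#' @export
setMethod("colorCount", "numeric",
          function(x) .colorCount(.asSurfaceVector(x)))

#' Score a cohort table
#'
#' Recomputes the patient-level indices for every row of a cohort table
#' from its per-intensity surface columns, overwriting `index`,
#' `color_count` and `predominant`.
#'
#' @param cohort data.frame with columns `s_low`, `s_mod`, `s_sev`,
#'   `s_vsev` (cm^2).
#' @return the cohort with `total`, `index`, `color_count`, `predominant`
#'   (re)computed.
#' @export
scoreCohort <- function(cohort) {
  need <- c("s_low", "s_mod", "s_sev", "s_vsev")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  S <- as.matrix(cohort[, need])
  if (any(S < 0)) stop("surfaces must be >= 0")
  cohort$total <- rowSums(S)
  cohort$index <- as.vector(S %*% .INTENSITY_WEIGHTS)
  cohort$color_count <- as.integer(rowSums(S > 0))
  cohort$predominant <- apply(S, 1L, .predominant)
  cohort
}
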