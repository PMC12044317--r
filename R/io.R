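.ALL_LAYERS <- function() c(.INTENSITY_LEVELS, names(.TYPOLOGY_SUBLAYERS))

#' Read a pain drawing from its JSON interchange format
#'
#' The schema is a single JSON object:
#' \preformatted{
#' {"patient_id": "P001", "height_cm": 170, "weight_kg": 70,
#'  "resolution_mm": 2,
#'  "layers": [
#'    {"layer": "very_severe", "polygon": [[x, y], ...]},
#'    {"layer": "burn", "strokes": [[x, y], ...], "brush_mm": 10}
#'  ]}
#' }
#' Coordinates are avatar grid pixels (0-based, origin top-left). Layer
#' names are the four intensity levels or the six typology sublayers;
#' several entries may target the same layer (their union is taken).
#'
#' @param path JSON file path.
#' @param resolution fallback mm-per-pixel when the file does not carry
#'   `resolution_mm`.
#' @return list with `patient_id`, `avatar` ([Avatar-class]), `drawing`
#'   ([PainDrawing-class]) and the raw `spec`.
#' @export
readDrawingJSON <- function(path, resolution = 2) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("height_cm", "weight_kg"))
    if (is.null(spec[[f]]))
      stop("drawing JSON is missing required field '", f, "'")
  if (is.null(spec$layers)) stop("drawing JSON is missing required field 'layers'")
  res <- if (!is.null(spec$resolution_mm)) spec$resolution_mm else resolution
  avatar <- buildAvatar(as.numeric(spec$height_cm),
                        as.numeric(spec$weight_kg), res)
  strokesByLayer <- list()
  for (entry in spec$layers) {
    ly <- entry$layer
    if (is.null(ly) || !ly %in% .ALL_LAYERS())
      stop("unknown or missing layer name: ",
           if (is.null(ly)) "<missing>" else ly)
    toMat <- function(x) do.call(rbind, lapply(x, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    s <- if (!is.null(entry$polygon)) list(polygon = toMat(entry$polygon))
         else if (!is.null(entry$strokes))
           list(points = toMat(entry$strokes),
                brush_mm = if (is.null(entry$brush_mm)) 0
                           else as.numeric(entry$brush_mm))
         else stop("layer entry for '", ly, "' has neither polygon nor strokes")
    strokesByLayer[[ly]] <- c(strokesByLayer[[ly]], list(s))
  }
  masks <- lapply(strokesByLayer, rasterizeStrokes, avatar = avatar)
  im <- masks[intersect(names(masks), .INTENSITY_LEVELS)]
  tm <- masks[intersect(names(masks), names(.TYPOLOGY_SUBLAYERS))]
  list(patient_id = spec$patient_id, avatar = avatar,
       drawing = painDrawing(im, tm, avatar), spec = spec)
}

#' @rdname readDrawingJSON
#' @param spec a drawing specification list following the schema above.
#' @param path output file path.
#' @export
writeDrawingJSON <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export / import drawing layers as 8-bit PNG masks
#'
#' Each layer is written as `<prefix>_<layer>.png`, an 8-bit grayscale
#' image with 255 inside the layer and 0 outside. The round trip is
#' bit-exact.
#'
#' @param drawing a [PainDrawing-class].
#' @param dir output directory.
#' @param prefix filename prefix (e.g. the patient id).
#' @return `exportMasksPNG` the written paths (invisibly);
#'   `importMasksPNG` a [PainDrawing-class].
#' @export
exportMasksPNG <- function(drawing, dir, prefix = "drawing") {
  stopifnot(is(drawing, "PainDrawing"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  masks <- c(drawing@intensityMasks, drawing@typologyMasks)
  paths <- character(0)
  for (ly in names(masks)) {
    p <- file.path(dir, paste0(prefix, "_", ly, ".png"))
    png::writePNG(masks[[ly]] * 1, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname exportMasksPNG
#' @param avatar the [Avatar-class] defining the expected grid.
#' @export
importMasksPNG <- function(dir, prefix, avatar) {
  stopifnot(is(avatar, "Avatar"))
  readMask <- function(ly) {
    p <- file.path(dir, paste0(prefix, "_", ly, ".png"))
    if (!file.exists(p)) return(NULL)
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    .checkGrid(m, avatar)
    m > 0.5
  }
  im <- Filter(Negate(is.null),
               stats::setNames(lapply(.INTENSITY_LEVELS, readMask),
                               .INTENSITY_LEVELS))
  tm <- Filter(Negate(is.null),
               stats::setNames(lapply(names(.TYPOLOGY_SUBLAYERS), readMask),
                               names(.TYPOLOGY_SUBLAYERS)))
  painDrawing(im, tm, avatar)
}

#' Read and write cohort tables
#'
#' Cohort CSVs are UTF-8, comma-separated with a header row and "." as the
#' decimal mark; surfaces are written to 0.01 cm^2.
#'
#' @param cohort a cohort data.frame (see [generateCohort()]).
#' @param path CSV file path.
#' @return `readCohortCSV` the cohort data.frame; `writeCohortCSV` the path
#'   (invisibly).
#' @export
writeCohortCSV <- function(cohort, path) {
  num <- vapply(cohort, is.numeric, TRUE) & names(cohort) != "nprs"
  cohort[num] <- lapply(cohort[num], function(x) round(x, 2))
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("nprs", "s_low", "s_mod", "s_sev", "s_vsev")
  miss <- setdiff(need, names(co))
  if (length(miss))
    stop("cohort CSV is missing required columns: ",
         paste(miss, collapse = ", "))
  co
}

#' Run the discriminant-validity battery on a cohort
#'
#' Computes, for a cohort table: Pearson correlations (with Fisher-z
#' intervals) and average variance extracted between NPRS and the pain
#' surface index, the raw surface, each per-level surface and the typology
#' surfaces; the likelihood-ratio test of the NPRS-index correlation
#' against 1; the bootstrap variance-explained of the surface; the cubic
#' orthogonal-polynomial fits of log(index + 1) and log(surface + 1) on
#' NPRS; the color-usage distribution; and the Jonckheere-Terpstra trend of
#' NPRS over the predominant-intensity groups (painless charts excluded).
#'
#' @param cohort cohort data.frame with at least `nprs` and the per-level
#'   surface columns; `total`, `index`, `color_count`, `predominant` are
#'   recomputed via [scoreCohort()].
#' @param nBoot bootstrap replicates for the variance-explained interval.
#' @param seed seed for the bootstrap.
#' @param span LOESS span for the smoothed curves.
#' @return a list of results, one entry per battery component.
#' @export
validateCohort <- function(cohort, nBoot = 2000, seed = 1, span = 0.75) {
  cohort <- scoreCohort(cohort)
  set.seed(as.integer(seed))
  vars <- list(surface = cohort$total, index = cohort$index,
               low = cohort$s_low, moderate = cohort$s_mod,
               severe = cohort$s_sev, very_severe = cohort$s_vsev)
  if (!is.null(cohort$neuro_cm2)) vars$neuropathic <- cohort$neuro_cm2
  if (!is.null(cohort$mech_cm2)) vars$mechanical <- cohort$mech_cm2
  correlations <- lapply(vars, function(v)
    tryCatch(pearsonCI(cohort$nprs, v), error = function(e) NULL))
  aves <- lapply(vars, function(v)
    tryCatch(avgVarianceExtracted(cohort$nprs, v), error = function(e) NULL))
  lrt <- tryCatch(lrtCorrelation(cohort$nprs, cohort$index, rho0 = 1),
                  error = function(e) NULL)
  ve <- varianceExplained(cohort$nprs, cohort$total, nBoot = nBoot)
  cubic_index <- cubicLogFit(cohort$index, cohort$nprs)
  cubic_surface <- cubicLogFit(cohort$total, cohort$nprs)
  loess_index <- loessCurve(cohort$nprs, log(cohort$index + 1), span = span)
  colors <- colorUsageRates(cohort$color_count)
  grouped <- split(cohort$nprs, factor(cohort$predominant,
                                       levels = .INTENSITY_LEVELS))
  grouped <- Filter(length, grouped)
  trend <- if (length(grouped) >= 2L)
    jonckheereTest(grouped, alternative = "increasing") else NULL
  groups <- data.frame(
    level = names(grouped),
    n = vapply(grouped, length, 1L),
    mean_nprs = vapply(grouped, mean, 0),
    sd_nprs = vapply(grouped, stats::sd, 0), row.names = NULL)
  list(n = nrow(cohort), correlations = correlations, ave = aves,
       lrt_vs_one = lrt, variance_explained = ve,
       cubic_index = cubic_index, cubic_surface = cubic_surface,
       loess_index = loess_index, color_usage = colors,
       predominant_groups = groups, trend = trend)
}

## Descriptive mean (SD) block in the style of a cohort summary table.
.cohortDescriptives <- function(cohort) {
  cohort <- scoreCohort(cohort)
  painted <- cohort$total > 0
  pct <- function(col) ifelse(painted, 100 * cohort[[col]] / cohort$total, NA)
  ms <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  rows <- list(
    `NPRS` = ms(cohort$nprs),
    `Pain surface (cm2)` = ms(cohort$total),
    `Pain surface index` = ms(cohort$index),
    `Very severe surface (cm2)` = ms(cohort$s_vsev),
    `Very severe surface (%)` = ms(pct("s_vsev")),
    `Severe surface (cm2)` = ms(cohort$s_sev),
    `Severe surface (%)` = ms(pct("s_sev")),
    `Moderate surface (cm2)` = ms(cohort$s_mod),
    `Moderate surface (%)` = ms(pct("s_mod")),
    `Low surface (cm2)` = ms(cohort$s_low),
    `Low surface (%)` = ms(pct("s_low")))
  if (!is.null(cohort$neuro_cm2)) {
    rows$`Neuropathic surface (cm2)` <- ms(cohort$neuro_cm2)
    rows$`Neuropathic surface (%)` <- ms(pct("neuro_cm2"))
    rows$`Mechanical surface (cm2)` <- ms(cohort$mech_cm2)
    rows$`Mechanical surface (%)` <- ms(pct("mech_cm2"))
    rows$`Mixed surface (cm2)` <- ms(cohort$mixed_cm2)
  }
  rows
}

#' Write a cohort analysis report
#'
#' Produces a Markdown report and a machine-readable JSON twin holding the
#' descriptive summary table and the full discriminant-validity battery.
#' Output is deterministic for identical inputs and seed.
#'
#' @param cohort cohort data.frame (may be empty).
#' @param mdPath Markdown output path.
#' @param jsonPath JSON output path (optional, `NULL` to skip).
#' @inheritParams validateCohort
#' @return invisibly, `TRUE` if a full report was written and `FALSE` for
#'   an empty-cohort stub.
#' @export
writeReport <- function(cohort, mdPath, jsonPath = NULL, nBoot = 2000,
                        seed = 1, span = 0.75) {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    writeLines(c("# Body chart cohort report", "", "No patients."), mdPath)
    if (!is.null(jsonPath))
      jsonlite::write_json(list(n = 0, message = "no patients"), jsonPath,
                           auto_unbox = TRUE, digits = NA)
    return(invisible(FALSE))
  }
  cohort <- scoreCohort(cohort)
  desc <- .cohortDescriptives(cohort)
  res <- validateCohort(cohort, nBoot = nBoot, seed = seed, span = span)
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c("# Body chart cohort report", "",
             sprintf("Patients: %d", nrow(cohort)), "",
             "## Descriptive summary", "",
             "| Variable | Mean (SD) |", "| --- | --- |")
  for (nm in names(desc))
    lines <- c(lines, sprintf("| %s | %s (%s) |", nm, fmt(desc[[nm]]["mean"]),
                              fmt(desc[[nm]]["sd"])))
  lines <- c(lines, "", "## Color usage", "",
             sprintf("| %d colors | %s%% |", 0:4,
                     fmt(100 * res$color_usage$proportions, 1)),
             sprintf("| 2 or more | %s%% |",
                     fmt(100 * res$color_usage$multi_rate, 1)), "",
             "## Correlation with NPRS", "",
             "| Variable | r (95% CI) | p | AVE |", "| --- | --- | --- | --- |")
  for (nm in names(res$correlations)) {
    cr <- res$correlations[[nm]]
    if (is.null(cr)) next
    lines <- c(lines, sprintf("| %s | %s (%s to %s) | %.3g | %s |", nm,
                              fmt(cr$r, 3), fmt(cr$ci_low, 3),
                              fmt(cr$ci_high, 3), cr$p,
                              fmt(res$ave[[nm]]$ave, 5)))
  }
  if (!is.null(res$lrt_vs_one))
    lines <- c(lines, "",
               sprintf("LRT of r(NPRS, index) = 1: chi2(1) = %s, p = %.3g",
                       fmt(res$lrt_vs_one$chi2, 1), res$lrt_vs_one$p))
  lines <- c(lines, "",
             sprintf("Variance of surface explained by NPRS: R2 = %s%% (95%% CI %s%% to %s%%)",
                     fmt(100 * res$variance_explained$r2, 2),
                     fmt(100 * res$variance_explained$ci_low, 2),
                     fmt(100 * res$variance_explained$ci_high, 2)), "",
             "## Cubic fit of log(index + 1) on NPRS", "",
             "| Term | Estimate (95% CI) | p |", "| --- | --- | --- |")
  cf <- res$cubic_index
  for (nm in names(cf$coefficients))
    lines <- c(lines, sprintf("| %s | %s (%s to %s) | %.3g |", nm,
                              fmt(cf$coefficients[nm], 2), fmt(cf$ci[nm, 1], 2),
                              fmt(cf$ci[nm, 2], 2), cf$p[nm]))
  lines <- c(lines, "", sprintf("R2 = %s%%", fmt(100 * cf$r2, 1)),
             "", "## Predominant intensity groups", "",
             "| Level | n | Mean NPRS (SD) |", "| --- | --- | --- |")
  g <- res$predominant_groups
  for (i in seq_len(nrow(g)))
    lines <- c(lines, sprintf("| %s | %d | %s (%s) |", g$level[i], g$n[i],
                              fmt(g$mean_nprs[i], 1), fmt(g$sd_nprs[i], 1)))
  if (!is.null(res$trend))
    lines <- c(lines, "",
               sprintf("Jonckheere-Terpstra trend (increasing): JT = %s, z = %s, p = %.3g",
                       fmt(res$trend$jt, 0), fmt(res$trend$z, 2), res$trend$p))
  writeLines(lines, mdPath)
  if (!is.null(jsonPath)) {
    strip <- function(x) {
      if (inherits(x, "polyFitResult")) x$fit <- NULL
      if (is.list(x) && !is.data.frame(x)) lapply(x, strip) else x
    }
    jsonlite::write_json(
      list(n = nrow(cohort),
           descriptives = lapply(desc, as.list),
           battery = strip(unclass(res))),
      jsonPath, auto_unbox = TRUE, digits = 8, force = TRUE)
  }
  invisible(TRUE)
}
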