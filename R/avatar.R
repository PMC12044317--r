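## Scanline polygon fill on a pixel grid.
##
## Coordinates are continuous, origin at the top-left corner of pixel (1,1),
## x growing along columns and y along rows; pixel (r,c) covers the half-open
## box [ (c-1)*px, c*px ) x [ (r-1)*px, r*px ) and its centre sits at
## ((c-0.5)*px, (r-0.5)*px). A pixel is inside when its centre is inside the
## polygon (even-odd rule), with half-open edge handling so that abutting
## polygons tile without double counting.
.scanFill <- function(xs, ys, nr, nc, px = 1) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  keep <- ys != y2                      # horizontal edges never cross a centre
  x1 <- xs[keep]; y1 <- ys[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  ## rows whose centre (r - 0.5) * px lies in [ylo, yhi)
  rlo <- pmax(1L, as.integer(ceiling(ylo / px + 0.5)))
  rhi <- pmin(nr, as.integer(ceiling(yhi / px + 0.5)) - 1L)
  nrows <- pmax(0L, rhi - rlo + 1L)
  if (sum(nrows) == 0L) return(matrix(FALSE, nr, nc))
  edge <- rep.int(seq_along(x1), nrows)
  rowv <- sequence(nrows) + rep.int(rlo - 1L, nrows)
  yc <- (rowv - 0.5) * px
  xint <- x1[edge] + (yc - y1[edge]) * (x2[edge] - x1[edge]) /
    (y2[edge] - y1[edge])
  o <- order(rowv, xint)
  rowv <- rowv[o]; xint <- xint[o]
  ## even-odd: successive pairs of crossings bound filled spans
  cnt <- tabulate(rowv, nbins = nr)
  if (any(cnt %% 2L != 0L))             # numeric vertex graze; drop odd rows
    warning("odd crossing count in scanline fill; vertex grazing a row centre")
  first <- rep.int(cumsum(c(0L, cnt[-nr])), cnt)
  pos <- seq_along(rowv) - first        # 1,2,... within each row
  xl <- xint[pos %% 2L == 1L]; xr <- xint[pos %% 2L == 0L]
  rs <- rowv[pos %% 2L == 1L]
  clo <- pmax(1L, as.integer(ceiling(xl / px + 0.5)))
  chi <- pmin(nc, as.integer(ceiling(xr / px + 0.5)) - 1L)
  len <- pmax(0L, chi - clo + 1L)
  mask <- matrix(FALSE, nr, nc)
  if (sum(len) > 0L) {
    cc <- sequence(len) + rep.int(clo - 1L, len)
    rr <- rep.int(rs, len)
    mask[cbind(rr, cc)] <- TRUE
  }
  mask
}

## Procedural body-silhouette template: one simple polygon (head, trunk,
## arms, legs) of unit height, symmetric about x = 0, y pointing down.
## Absolute proportions do not matter; buildAvatar() rescales the width so
## the rasterised area matches the Du Bois target.
.silhouetteTemplate <- function() {
  th <- seq(-pi / 2, 0.62 * pi, length.out = 13)
  head <- cbind(0.062 * cos(th), 0.075 + 0.062 * sin(th))
  right <- rbind(
    head,
    c(0.030, 0.130), c(0.032, 0.152),           # neck
    c(0.095, 0.158), c(0.145, 0.172),           # shoulder
    c(0.163, 0.270), c(0.172, 0.380),           # outer arm
    c(0.178, 0.455), c(0.168, 0.492),           # hand
    c(0.140, 0.488), c(0.132, 0.400),           # inner arm
    c(0.124, 0.300), c(0.112, 0.205),           # armpit
    c(0.108, 0.320), c(0.098, 0.400),           # trunk
    c(0.112, 0.480), c(0.108, 0.600),           # hip / outer leg
    c(0.095, 0.750), c(0.085, 0.900),
    c(0.082, 0.955), c(0.092, 0.985),           # foot
    c(0.030, 0.985), c(0.028, 0.920),           # inner leg
    c(0.030, 0.800), c(0.034, 0.650),
    c(0.012, 0.560), c(0.000, 0.545))           # crotch
  left <- right[rev(seq_len(nrow(right) - 1L)[-1L]), , drop = FALSE]
  left[, 1] <- -left[, 1]
  rbind(right, left)
}

.shoelace <- function(xs, ys) {
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  abs(sum(xs * y2 - x2 * ys)) / 2
}

#' Du Bois body surface area
#'
#' The clinical-standard Du Bois & Du Bois formula,
#' \eqn{BSA = 0.007184 \, H^{0.725} \, W^{0.425}} with height in cm and
#' weight in kg, returned in cm^2.
#'
#' @param height standing height in cm.
#' @param weight body mass in kg.
#' @return body surface area in cm^2 (vectorised).
#' @examples
#' duBoisBSA(170, 70) / 1e4  # about 1.81 m^2
#' @export
duBoisBSA <- function(height, weight) {
  0.007184 * height^0.725 * weight^0.425 * 1e4
}

#' Build an anthropometry-scaled avatar
#'
#' Constructs the two-view drawable body chart for a patient. A procedural
#' body-silhouette polygon is scaled anisotropically — vertically to the
#' patient's height, horizontally so that the combined drawable area of the
#' front and back views equals the Du Bois body surface area (split equally
#' between the views) — then rasterised at the requested resolution.
#'
#' @param height standing height in cm, in \[100, 220\].
#' @param weight body mass in kg, in \[30, 200\].
#' @param resolution pixel edge length in mm, in \[1, 10\]; default 2 mm,
#'   i.e. 0.04 cm^2 per pixel.
#' @return an [Avatar-class] object. Its drawable area matches the Du Bois
#'   BSA within 1 percent.
#' @examples
#' av <- buildAvatar(170, 70)
#' drawableArea(av)      # ~ 18100 cm^2
#' @export
buildAvatar <- function(height, weight, resolution = 2) {
  if (!is.numeric(height) || length(height) != 1L || is.na(height) ||
      height < 100 || height > 220)
    stop("height must be a single value in [100, 220] cm, got: ",
         format(height))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 30 || weight > 200)
    stop("weight must be a single value in [30, 200] kg, got: ",
         format(weight))
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution < 1 || resolution > 10)
    stop("resolution must be a single value in [1, 10] mm per pixel")

  bsa <- duBoisBSA(height, weight)
  target_view <- bsa / 2
  tpl <- .silhouetteTemplate()
  unit_area <- .shoelace(tpl[, 1], tpl[, 2])
  ## anisotropic scaling: height -> H cm, width stretched to hit the area
  k <- target_view / (unit_area * height^2)
  px <- resolution / 10                  # cm per pixel edge
  margin <- 2 * px
  xs <- tpl[, 1] * height * k
  ys <- tpl[, 2] * height
  xs <- xs - min(xs) + margin
  ys <- ys - min(ys) + margin
  nr <- as.integer(ceiling((max(ys) + margin) / px))
  nc <- as.integer(ceiling((max(xs) + margin) / px))
  view <- .scanFill(xs, ys, nr, nc, px)
  new("Avatar", height = height, weight = weight, resolution = resolution,
      mask = cbind(view, view), viewSplit = nc,
      pixelScale = resolution^2 / 100, targetArea = bsa)
}

.checkGrid <- function(mask, avatar) {
  if (!identical(dim(mask), dim(avatar@mask)))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match avatar canvas ",
         paste(dim(avatar@mask), collapse = "x"))
  invisible(TRUE)
}

#' Rasterize drawn strokes onto an avatar canvas
#'
#' Converts a list of drawn shapes into a binary layer mask. Each element of
#' `strokes` is a list with either a `polygon` (n x 2 matrix of x, y
#' vertices, filled by the even-odd rule) or `points` (n x 2 polyline, n >= 1)
#' with a `brush_mm` radius, dilated to a capsule of that radius. Coordinates
#' are in avatar grid space: 0-based pixel units, origin at the top-left
#' corner, x along columns and y along rows. The result is intersected with
#' the silhouette, so strokes outside the body contribute nothing.
#'
#' @param strokes list of stroke descriptors (may be empty).
#' @param avatar an [Avatar-class].
#' @return logical matrix congruent with the avatar canvas.
#' @examples
#' av <- buildAvatar(170, 70)
#' sq <- list(list(polygon = cbind(c(300, 320, 320, 300), c(200, 200, 240, 240))))
#' sum(rasterizeStrokes(sq, av))  # 20 x 40 = 800 px if fully inside
#' @export
rasterizeStrokes <- function(strokes, avatar) {
  stopifnot(is(avatar, "Avatar"))
  nr <- nrow(avatar@mask); nc <- ncol(avatar@mask)
  out <- matrix(FALSE, nr, nc)
  for (s in strokes) {
    if (!is.null(s$polygon)) {
      p <- as.matrix(s$polygon)
      if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p))
        stop("malformed polygon: need a numeric n x 2 matrix with n >= 3")
      out <- out | .scanFill(p[, 1], p[, 2], nr, nc, px = 1)
    } else if (!is.null(s$points)) {
      p <- as.matrix(s$points)
      if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L || anyNA(p))
        stop("malformed polyline: need a numeric n x 2 matrix with n >= 1")
      r_px <- (if (is.null(s$brush_mm)) 0 else s$brush_mm) / avatar@resolution
      if (r_px < 0) stop("brush radius must be >= 0")
      out <- out | .dilatePolyline(p, r_px, nr, nc)
    } else {
      stop("each stroke needs a 'polygon' or a 'points' entry")
    }
  }
  out & avatar@mask
}

## Mark pixels whose centre lies within radius r (pixels) of the polyline.
.dilatePolyline <- function(p, r, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  segs <- if (nrow(p) == 1L) list(c(1L, 1L)) else
    lapply(seq_len(nrow(p) - 1L), function(i) c(i, i + 1L))
  for (sg in segs) {
    a <- p[sg[1], ]; b <- p[sg[2], ]
    rlo <- max(1L, floor(min(a[2], b[2]) - r + 0.5))
    rhi <- min(nr, ceiling(max(a[2], b[2]) + r + 0.5))
    clo <- max(1L, floor(min(a[1], b[1]) - r + 0.5))
    chi <- min(nc, ceiling(max(a[1], b[1]) + r + 0.5))
    if (rlo > rhi || clo > chi) next
    cx <- (clo:chi) - 0.5; cy <- (rlo:rhi) - 0.5
    X <- matrix(cx, length(cy), length(cx), byrow = TRUE)
    Y <- matrix(cy, length(cy), length(cx))
    d <- b - a; L2 <- sum(d^2)
    if (L2 == 0) {
      dist2 <- (X - a[1])^2 + (Y - a[2])^2
    } else {
      t <- pmin(1, pmax(0, ((X - a[1]) * d[1] + (Y - a[2]) * d[2]) / L2))
      dist2 <- (X - (a[1] + t * d[1]))^2 + (Y - (a[2] + t * d[2]))^2
    }
    sub <- dist2 <= r^2
    out[rlo:rhi, clo:chi] <- out[rlo:rhi, clo:chi] | sub
  }
  out
}

#' Resolve overlapping intensity layers
#'
#' Patients may paint the same pixel with several intensity colors. The
#' resolved layers are pairwise disjoint: each pixel is assigned to the most
#' severe intensity claiming it. The union of pixels is preserved and the
#' operation is idempotent.
#'
#' @param masks named list of 4 logical matrices
#'   (`low`, `moderate`, `severe`, `very_severe`), congruent grids.
#' @return named list of 4 disjoint logical matrices in the same order.
#' @export
resolveIntensityLayers <- function(masks) {
  stopifnot(identical(names(masks), .INTENSITY_LEVELS),
            length(unique(lapply(masks, dim))) == 1L)
  claimed <- masks$very_severe
  out <- list(very_severe = masks$very_severe)
  for (lv in c("severe", "moderate", "low")) {
    out[[lv]] <- masks[[lv]] & !claimed
    claimed <- claimed | masks[[lv]]
  }
  out[.INTENSITY_LEVELS]
}

#' Measure calibrated pain surfaces
#'
#' Resolves the drawing's intensity layers, confines them to the silhouette,
#' and converts pixel counts to cm^2 via the avatar's pixel scale. The
#' returned summary also carries the weighted pain surface index, color
#' count and predominant intensity (see [painSurfaceIndex()]).
#'
#' @param drawing a [PainDrawing-class] congruent with `avatar`.
#' @param avatar an [Avatar-class].
#' @return a [SurfaceSummary-class].
#' @export
measureSurfaces <- function(drawing, avatar) {
  stopifnot(is(drawing, "PainDrawing"), is(avatar, "Avatar"))
  .checkGrid(drawing@intensityMasks[[1]], avatar)
  res <- resolveIntensityLayers(drawing@intensityMasks)
  s <- vapply(res, function(m) sum(m & avatar@mask), 0) * avatar@pixelScale
  surfaceSummary(s)
}

#' Decompose the pain surface by typology
#'
#' The mechanical union (nociceptive + trigger sublayers) and the
#' neuropathic union (burn + tingling + allodynia + hypoesthesia) may
#' overlap; the overlap is mixed pain. The exclusive convention is used:
#' each family's surface excludes the mixed region, so
#' neuropathic + mechanical + mixed equals the area of the full typology
#' union. Family regions (exclusive) are also crossed with the resolved
#' intensity layers.
#'
#' @inheritParams measureSurfaces
#' @return a [TypologySummary-class]. Percentages are relative to the total
#'   painted (intensity) surface.
#' @export
measureTypology <- function(drawing, avatar) {
  stopifnot(is(drawing, "PainDrawing"), is(avatar, "Avatar"))
  .checkGrid(drawing@typologyMasks[[1]], avatar)
  fam <- .TYPOLOGY_SUBLAYERS
  unionOf <- function(nms) {
    m <- Reduce(`|`, drawing@typologyMasks[nms])
    m & avatar@mask
  }
  mech <- unionOf(names(fam)[fam == "mechanical"])
  neur <- unionOf(names(fam)[fam == "neuropathic"])
  mixed <- mech & neur
  mech_x <- mech & !mixed
  neur_x <- neur & !mixed
  ps <- avatar@pixelScale
  res <- resolveIntensityLayers(drawing@intensityMasks)
  byInt <- rbind(
    neuropathic = vapply(res, function(m) sum(m & neur_x), 0) * ps,
    mechanical = vapply(res, function(m) sum(m & mech_x), 0) * ps)
  total <- sum(vapply(res, function(m) sum(m & avatar@mask), 0)) * ps
  pct <- function(a) if (total > 0) 100 * a / total else 0
  new("TypologySummary",
      neuropathic = sum(neur_x) * ps, mechanical = sum(mech_x) * ps,
      mixed = sum(mixed) * ps,
      neuropathicPct = min(100, pct(sum(neur_x) * ps)),
      mechanicalPct = min(100, pct(sum(mech_x) * ps)),
      byIntensity = byInt)
}

#' Construct a PainDrawing from layer masks
#'
#' @param intensityMasks named list of logical matrices; missing levels are
#'   filled with empty masks.
#' @param typologyMasks named list of logical matrices; missing sublayers
#'   are filled with empty masks.
#' @param avatar the [Avatar-class] defining the grid.
#' @return a [PainDrawing-class].
#' @export
painDrawing <- function(intensityMasks = list(), typologyMasks = list(),
                        avatar) {
  stopifnot(is(avatar, "Avatar"))
  empty <- matrix(FALSE, nrow(avatar@mask), ncol(avatar@mask))
  im <- lapply(.INTENSITY_LEVELS, function(lv) {
    m <- intensityMasks[[lv]]
    if (is.null(m)) empty else { .checkGrid(m, avatar); m & avatar@mask }
  })
  names(im) <- .INTENSITY_LEVELS
  tm <- lapply(names(.TYPOLOGY_SUBLAYERS), function(lv) {
    m <- typologyMasks[[lv]]
    if (is.null(m)) empty else { .checkGrid(m, avatar); m & avatar@mask }
  })
  names(tm) <- names(.TYPOLOGY_SUBLAYERS)
  new("PainDrawing", intensityMasks = im, typologyMasks = tm)
}
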