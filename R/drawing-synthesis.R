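## Grow a connected blob of exactly `target` pixels inside `available`
## (logical matrix), by randomised frontier accretion from a random seed
## pixel. Starts additional blobs if a region gets boxed in. Returns the
## linear indices of the grown pixels, or errors if `available` runs out.
.growBlob <- function(available, target, nr) {
  if (target == 0L) return(integer(0))
  avail <- available
  region <- integer(target)
  ngot <- 0L
  frontier <- integer(0)
  neighbours <- function(i) {
    r <- (i - 1L) %% nr + 1L
    out <- c(if (r > 1L) i - 1L, if (r < nr) i + 1L, i - nr, i + nr)
    out[out >= 1L & out <= length(avail)]
  }
  while (ngot < target) {
    frontier <- unique(frontier[avail[frontier]])
    if (!length(frontier)) {                 # seed a (new) blob
      open <- which(avail)
      if (!length(open))
        stop("infeasible target area: silhouette exhausted while growing blob")
      frontier <- open[sample.int(length(open), 1L)]
    }
    pick <- frontier[sample.int(length(frontier), 1L)]
    ngot <- ngot + 1L
    region[ngot] <- pick
    avail[pick] <- FALSE
    nb <- neighbours(pick)
    frontier <- c(frontier[frontier != pick], nb[avail[nb]])
  }
  region
}

#' Synthesise a pain drawing matching a cohort record
#'
#' Places randomised connected blob regions on the avatar so that the
#' measured per-intensity and typology surfaces reproduce a synthetic
#' cohort record. Intensity regions are grown disjointly inside the
#' silhouette; typology regions (neuropathic-only, mechanical-only, mixed)
#' are grown inside the painted area, and the mixed region is included in
#' both family masks so that [measureTypology()] recovers the record's
#' decomposition.
#'
#' @param record one-row data.frame (or list) with `s_low`, `s_mod`,
#'   `s_sev`, `s_vsev`, `neuro_cm2`, `mech_cm2`, `mixed_cm2` in cm^2.
#' @param avatar an [Avatar-class]; the record's total surface must fit in
#'   the drawable area.
#' @param seed integer seed.
#' @return a [PainDrawing-class] whose measured surfaces match the record
#'   within the pixel quantisation (well under 2 percent for regions of a
#'   few cm^2 or more).
#' @export
generateDrawing <- function(record, avatar, seed = 1) {
  stopifnot(is(avatar, "Avatar"))
  set.seed(as.integer(seed))
  ps <- avatar@pixelScale
  nr <- nrow(avatar@mask)
  tgt <- vapply(c("s_low", "s_mod", "s_sev", "s_vsev"),
                function(k) as.numeric(record[[k]]), 0)
  if (anyNA(tgt) || any(tgt < 0)) stop("record has invalid surfaces")
  px <- as.integer(round(tgt / ps))
  if (sum(px) > sum(avatar@mask))
    stop(sprintf("infeasible target area: %.0f cm^2 exceeds drawable %.0f cm^2",
                 sum(tgt), drawableArea(avatar)))
  avail <- avatar@mask
  imasks <- list()
  for (k in 4:1) {                          # most severe first
    lv <- .INTENSITY_LEVELS[k]
    m <- matrix(FALSE, nr, ncol(avatar@mask))
    if (px[k] > 0L) {
      id <- .growBlob(avail, px[k], nr)
      m[id] <- TRUE
      avail[id] <- FALSE
    }
    imasks[[lv]] <- m
  }
  imasks <- imasks[.INTENSITY_LEVELS]

  painted <- Reduce(`|`, imasks)
  tpx <- as.integer(round(c(record[["neuro_cm2"]], record[["mech_cm2"]],
                            record[["mixed_cm2"]]) / ps))
  over <- sum(tpx) - sum(painted)
  if (over > 0L) {                          # rounding overshoot: trim largest
    i <- which.max(tpx)
    if (tpx[i] < over) stop("infeasible typology areas for painted surface")
    tpx[i] <- tpx[i] - over
  }
  tavail <- painted
  regions <- list()
  for (i in order(tpx, decreasing = TRUE)) {
    id <- if (tpx[i] > 0L) .growBlob(tavail, tpx[i], nr) else integer(0)
    tavail[id] <- FALSE
    regions[[i]] <- id
  }
  blank <- matrix(FALSE, nr, ncol(avatar@mask))
  neuroMask <- blank; neuroMask[c(regions[[1]], regions[[3]])] <- TRUE
  mechMask <- blank; mechMask[c(regions[[2]], regions[[3]])] <- TRUE
  ## attribute each family to one representative sublayer
  tmasks <- list(burn = neuroMask, nociceptive = mechMask)
  painDrawing(imasks, tmasks, avatar)
}
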