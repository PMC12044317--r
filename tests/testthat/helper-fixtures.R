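# Shared fixtures. A coarse avatar keeps the raster small for speed; the
# default 2 mm resolution is exercised where accuracy is under test.
coarseAvatar <- function(height = 170, weight = 70, resolution = 5) {
  buildAvatar(height, weight, resolution)
}

# a blank mask congruent with an avatar canvas
blankMask <- function(avatar) {
  matrix(FALSE, nrow(silhouetteMask(avatar)), ncol(silhouetteMask(avatar)))
}

# random per-intensity surface vector; prob. `tieProb` of duplicating one
# value to exercise tie handling, `zeroProb` of an all-zero summary
randomSurfaces <- function(tieProb = 0.3, zeroProb = 0.05) {
  if (runif(1) < zeroProb) return(c(0, 0, 0, 0))
  s <- round(rexp(4, 1 / 100), 1)
  if (runif(1) < tieProb) {
    ij <- sample.int(4, 2)
    s[ij[1]] <- s[ij[2]]
  }
  if (runif(1) < 0.3) s[sample.int(4, sample.int(3, 1))] <- 0
  s
}

# brute-force argmax-with-severity-ties oracle for the predominant level
predominantOracle <- function(s) {
  if (sum(s) == 0) return(NA_character_)
  lv <- intensityLevels()
  cand <- which(s == max(s))
  lv[max(cand)]
}

# independent Mann-Whitney U (ties as 1/2) for the two-group JT reduction
mannWhitneyU <- function(x1, x2) {
  d <- outer(x2, x1, "-")
  sum(d > 0) + 0.5 * sum(d == 0)
}
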