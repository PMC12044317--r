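## Stored calibration of the copula coupling (see calibrateCoupling);
## reproduces the published NPRS-index correlation r = 0.14 under the
## default configuration.
.DEFAULT_COUPLING <- 0.1088

## Lognormal parameters matching a target mean/SD (moment matching):
## sigma^2 = log(1 + (sd/mean)^2), mu = log(mean) - sigma^2 / 2.
.lognormalFromMoments <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Synthetic cohort generator configuration
#'
#' Defaults encode the full-cohort calibration of the generator: the
#' predominant-intensity strata (38.0 / 32.5 / 24.2 / 4.9 percent of
#' patients for very severe / severe / moderate / low, plus 0.5 percent
#' painless), per-stratum NPRS means 7.2 / 6.4 / 5.4 / 5.1 (SDs 1.8 / 1.8 /
#' 1.9 / 2.7), the color-count multinomial (0.5 / 33 / 34.2 / 24.3 / 8
#' percent for 0..4 colors), a lognormal total surface matching mean 668.2
#' and SD 837.6 cm^2, mean intensity shares 6.7 / 23.7 / 32.6 / 37.1
#' percent (low..very severe), and typology shares 56.2 percent neuropathic,
#' 28.0 percent mechanical, remainder mixed. `coupling` is the
#' Gaussian-copula correlation between the NPRS and total-surface latents
#' within a stratum; its default is the stored calibration that reproduces
#' the published NPRS-index correlation of 0.14 (see [calibrateCoupling()]).
#'
#' @param coupling within-stratum copula correlation, in (-1, 1).
#' @param surfaceMean,surfaceSD target moments of the total surface (cm^2).
#' @param groupProbs numeric(5): painless, then low..very_severe strata
#'   shares; renormalised to sum to 1.
#' @param groupNprsMean,groupNprsSD numeric(4), low..very_severe order.
#' @param colorCountProbs numeric(5) over 0..4 colors.
#' @param intensityShares numeric(4) mean per-level share of the total
#'   surface, low..very_severe; renormalised.
#' @param shareConcentration Dirichlet concentration of the per-patient
#'   intensity shares.
#' @param typologyProps numeric(3): mean neuropathic / mechanical / mixed
#'   shares of the total surface.
#' @param typologyConcentration Dirichlet concentration of the typology
#'   shares.
#' @param painlessNprsMean,painlessNprsSD NPRS moments of the painless
#'   stratum (patients reporting pain in the last 24 h but drawing none).
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(coupling = .DEFAULT_COUPLING,
                         surfaceMean = 668.2, surfaceSD = 837.6,
                         groupProbs = c(0.005, 0.049, 0.242, 0.325, 0.380),
                         groupNprsMean = c(5.1, 5.4, 6.4, 7.2),
                         groupNprsSD = c(2.7, 1.9, 1.8, 1.8),
                         colorCountProbs = c(0.005, 0.33, 0.342, 0.243, 0.08),
                         intensityShares = c(0.067, 0.237, 0.326, 0.371),
                         shareConcentration = 2.0,
                         typologyProps = c(0.562, 0.280, 0.158),
                         typologyConcentration = 0.4,
                         painlessNprsMean = 2, painlessNprsSD = 2) {
  ln <- .lognormalFromMoments(surfaceMean, surfaceSD)
  new("CohortConfig",
      groupProbs = groupProbs / sum(groupProbs),
      groupNprsMean = groupNprsMean, groupNprsSD = groupNprsSD,
      colorCountProbs = colorCountProbs / sum(colorCountProbs),
      surfaceLogMean = unname(ln["mu"]), surfaceLogSD = unname(ln["sigma"]),
      intensityShares = intensityShares / sum(intensityShares),
      shareConcentration = shareConcentration,
      typologyProps = typologyProps / sum(typologyProps),
      typologyConcentration = typologyConcentration,
      coupling = coupling,
      painlessNprsMean = painlessNprsMean, painlessNprsSD = painlessNprsSD)
}

## Quantile of a normal(mean, sd) truncated to [lo, hi], vectorised.
.qtruncnorm <- function(u, mean, sd, lo = 0, hi = 10) {
  pa <- stats::pnorm((lo - mean) / sd)
  pb <- stats::pnorm((hi - mean) / sd)
  stats::qnorm(pa + u * (pb - pa)) * sd + mean
}

#' Generate a synthetic cohort
#'
#' Draws `n` synthetic patients from a stratified generative model:
#' \enumerate{
#'   \item a predominant-intensity stratum (or painless) from `groupProbs`;
#'   \item an NPRS score from the stratum's normal, truncated to \[0, 10\]
#'     and rounded to an integer;
#'   \item a color count from `colorCountProbs` (painless charts use 0
#'     colors); the predominant level is always among the painted levels;
#'   \item a total surface from the moment-matched lognormal, linked to the
#'     NPRS latent through a Gaussian copula of strength `coupling`;
#'   \item per-level surface shares from a Dirichlet over the painted
#'     levels (mean = `intensityShares`), with the largest share forced
#'     onto the predominant level;
#'   \item neuropathic / mechanical / mixed shares of the total from a
#'     typology Dirichlet, crossed with the intensity shares.
#' }
#' The output is deterministic given `(n, config, seed)`.
#'
#' @param n number of patients, >= 1.
#' @param config a [CohortConfig-class]; default [cohortConfig()].
#' @param seed integer seed for all randomness.
#' @return data.frame with one row per patient: `patient_id`, `nprs`,
#'   `group` (drawn stratum), per-level surfaces `s_low`..`s_vsev`, `total`,
#'   `index`, `color_count`, `predominant`, `neuro_cm2`, `mech_cm2`,
#'   `mixed_cm2`, and family-by-intensity columns `neuro_low`..`mech_vsev`.
#' @examples
#' co <- generateCohort(200, seed = 1)
#' mean(co$nprs)
#' @export
generateCohort <- function(n, config = cohortConfig(), seed = 1) {
  stopifnot(is(config, "CohortConfig"))
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stop("invalid generator config: ", paste(v, collapse = "; "))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))

  lv <- .INTENSITY_LEVELS
  group <- sample.int(5L, n, replace = TRUE, prob = config@groupProbs) - 1L
  painless <- group == 0L

  gi <- pmax(group, 1L)                 # safe index; painless overwritten below
  m <- ifelse(painless, config@painlessNprsMean, config@groupNprsMean[gi])
  s <- ifelse(painless, config@painlessNprsSD, config@groupNprsSD[gi])
  z1 <- stats::rnorm(n)
  nprs <- as.integer(pmin(10, pmax(0, round(.qtruncnorm(stats::pnorm(z1),
                                                        m, s)))))

  ## Gaussian copula between the NPRS latent and the total-surface latent
  z2 <- config@coupling * z1 + sqrt(1 - config@coupling^2) * stats::rnorm(n)
  total <- stats::qlnorm(stats::pnorm(z2), config@surfaceLogMean,
                         config@surfaceLogSD)
  total[painless] <- 0

  pc <- config@colorCountProbs[2:5] / sum(config@colorCountProbs[2:5])
  cc <- integer(n)
  cc[!painless] <- sample.int(4L, sum(!painless), replace = TRUE, prob = pc)

  ## which levels are painted: the predominant level always, plus cc - 1
  ## others chosen by random ranking
  present <- matrix(FALSE, n, 4L)
  keys <- matrix(stats::runif(4L * n), n, 4L)
  for (i in which(!painless)) {
    g <- group[i]
    others <- setdiff(1:4, g)
    pick <- others[order(keys[i, others])][seq_len(cc[i] - 1L)]
    present[i, c(g, pick)] <- TRUE
  }

  ## Dirichlet shares over painted levels, mean matching intensityShares;
  ## the largest component is swapped onto the predominant level
  alpha <- matrix(rep(config@shareConcentration * config@intensityShares,
                      each = n), n, 4L)
  gm <- matrix(0, n, 4L)
  idx <- which(present)
  gm[idx] <- stats::rgamma(length(idx), shape = alpha[idx])
  ## zero gamma draws (tiny shapes) on painted levels get a floor so the
  ## level keeps a positive surface
  gm[idx][gm[idx] == 0] <- 1e-12
  shares <- gm / pmax(rowSums(gm), .Machine$double.xmin)
  shares[painless, ] <- 0
  amax <- max.col(shares, ties.method = "first")
  for (i in which(!painless)) {
    g <- group[i]
    if (amax[i] != g) {
      tmp <- shares[i, g]; shares[i, g] <- shares[i, amax[i]]
      shares[i, amax[i]] <- tmp
    }
  }
  S <- shares * total

  ## typology split of the total painted surface
  ta <- config@typologyConcentration * config@typologyProps
  tg <- cbind(stats::rgamma(n, ta[1]), stats::rgamma(n, ta[2]),
              stats::rgamma(n, ta[3]))
  tg[tg == 0] <- 1e-12
  tshare <- tg / rowSums(tg)
  tshare[painless, ] <- 0
  neuro <- tshare[, 1] * total
  mech <- tshare[, 2] * total
  mixed <- tshare[, 3] * total

  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    nprs = nprs,
    group = c("none", lv)[group + 1L],
    s_low = S[, 1], s_mod = S[, 2], s_sev = S[, 3], s_vsev = S[, 4],
    neuro_cm2 = neuro, mech_cm2 = mech, mixed_cm2 = mixed,
    stringsAsFactors = FALSE)
  fam <- cbind(neuro, mech)
  for (f in 1:2)
    for (k in 1:4)
      out[[paste0(c("neuro", "mech")[f], "_",
                  c("low", "mod", "sev", "vsev")[k])]] <- fam[, f] * shares[, k]
  scoreCohort(out)
}

#' Calibrate the copula coupling to a target correlation
#'
#' The generator has one free dependence parameter: the within-stratum
#' Gaussian-copula correlation between the NPRS latent and the
#' total-surface latent. This routine bisects on that parameter until the
#' Pearson correlation between NPRS and the pain surface index, simulated
#' at a large n with common random numbers, is within `tol` of `targetR`.
#'
#' @param targetR target Pearson correlation in (-1, 1).
#' @param config starting [CohortConfig-class].
#' @param tol tolerance on the simulated correlation (default 0.01).
#' @param seed seed used for every bisection evaluation (common random
#'   numbers make the simulated correlation monotone in the coupling).
#' @param n cohort size per evaluation (default 20000).
#' @param nSeeds number of seeds averaged per evaluation (default 1; a
#'   larger value reduces the Monte-Carlo error of the calibration).
#' @param maxIter bisection iteration cap.
#' @return the config with `coupling` calibrated; the bisection trace is
#'   attached as `attr(, "trace")` (a data.frame of coupling and simulated
#'   r values).
#' @export
calibrateCoupling <- function(targetR, config = cohortConfig(), tol = 0.01,
                              seed = 1, n = 20000, nSeeds = 1, maxIter = 40) {
  if (abs(targetR) >= 1) stop("targetR must lie in (-1, 1)")
  evalR <- function(cpl) {
    cfg <- config
    cfg@coupling <- cpl
    mean(vapply(seq_len(nSeeds), function(k) {
      co <- generateCohort(n, cfg, seed = seed + k - 1L)
      stats::cor(co$nprs, co$index)
    }, 0))
  }
  lo <- -0.995; hi <- 0.995
  rlo <- evalR(lo); rhi <- evalR(hi)
  if (targetR < rlo || targetR > rhi)
    stop(sprintf(
      "target r = %.3f unreachable: attainable range is [%.3f, %.3f]",
      targetR, rlo, rhi))
  trace <- data.frame(coupling = c(lo, hi), r = c(rlo, rhi))
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    rmid <- evalR(mid)
    trace <- rbind(trace, data.frame(coupling = mid, r = rmid))
    if (abs(rmid - targetR) < tol || (hi - lo) < 1e-4) break
    if (rmid < targetR) lo <- mid else hi <- mid
  }
  config@coupling <- mid
  attr(config, "trace") <- trace
  config
}
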