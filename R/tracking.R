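# Turning differential correlation maps into motion: lobe detection and
# pairing, subpixel displacement estimation, adaptive reference-frame
# choice, and chaining of relative displacements into trajectories that
# extend beyond the memory range.

# Rescale a zero-padded correlation map so the lag-dependent noise
# variance is uniform: the number of overlapping pixels at lag l is
# (n - |l_r|)(n - |l_c|), so noise-driven fluctuations shrink like
# sqrt(overlap) towards the map edges.  Detection statistics are computed
# on this whitened map.
.overlapWhiten <- function(map) {
  d <- dim(map@values)
  n <- map@center
  fr <- pmax(n[1] - abs(seq_len(d[1]) - n[1]), 1) / n[1]
  fc <- pmax(n[2] - abs(seq_len(d[2]) - n[2]), 1) / n[2]
  map@values / sqrt(outer(fr, fc))
}

#' Robust noise level of a correlation map
#'
#' 1.4826 times the median absolute deviation of the overlap-whitened map
#' values (the zero-padded correlation's noise variance scales with the
#' lag-dependent overlap area, which is equalized first), excluding a
#' central disk (the residual self-correlation region around zero lag).
#' The returned level refers to the whitened map, i.e. to the centre of
#' the lag grid.
#'
#' @param map A [CorrelationMap-class].
#' @param excludeRadiusPx Radius (px) of the central exclusion disk.
#' @return Noise level (map units at zero lag).
#' @export
mapNoiseLevel <- function(map, excludeRadiusPx = 4) {
  d <- dim(map@values)
  w <- .overlapWhiten(map)
  ix <- outer(rep(1, d[1]), seq_len(d[2]) - map@center[2])
  iy <- outer(seq_len(d[1]) - map@center[1], rep(1, d[2]))
  keep <- (ix^2 + iy^2) > excludeRadiusPx^2
  1.4826 * stats::mad(w[keep], center = 0, constant = 1)
}

# Default central exclusion radius: 3 speckle grains (in lag pixels).
.defaultExcludeRadius <- function(map, config) {
  if (is.null(config)) return(4)
  3 * expectedGrainDiameter(config) / map@pitch
}

# Local extrema of a map above a threshold: strict maxima (sign = +1) or
# minima (sign = -1) of `vals` over a (2w+1)^2 neighborhood, outside the
# exclusion disk.  Returns a data.frame of integer positions and values.
.localExtrema <- function(vals, thr, sign, center, excludeRadiusPx, w = 2L) {
  v <- vals * sign
  cand <- which(v > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  d <- dim(vals)
  r2 <- (cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2
  cand <- cand[r2 > excludeRadiusPx^2, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1L, r - w):min(d[1], r + w)
    cc <- max(1L, c - w):min(d[2], c + w)
    keep[i] <- v[r, c] >= max(v[rr, cc]) &&
      sum(v[rr, cc] == v[r, c]) == 1L
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(row = cand[, 1], col = cand[, 2],
             value = vals[cand])
}

# Subpixel (3-point parabolic, per axis) refinement of an extremum.
# Returns list(pos = c(row, col) fractional, refined = logical).
.refinePeak <- function(vals, r, c) {
  d <- dim(vals)
  if (r <= 1 || r >= d[1] || c <= 1 || c >= d[2])
    return(list(pos = c(r, c), refined = FALSE))
  dr <- .parabolicOffset(vals[r - 1, c], vals[r, c], vals[r + 1, c])
  dc <- .parabolicOffset(vals[r, c - 1], vals[r, c], vals[r, c + 1])
  if (is.na(dr) || is.na(dc)) return(list(pos = c(r, c), refined = FALSE))
  list(pos = c(r + dr, c + dc), refined = TRUE)
}

#' Extract paired motion lobes from a differential correlation map
#'
#' Finds local extrema exceeding \code{thresholdSigma} times the map's
#' robust noise, outside a central exclusion disk, and pairs each negative
#' lobe with its nearest positive lobe of comparable magnitude (amplitude
#' ratio within \[1/3, 3\]; intensity-conserving motion makes paired lobes
#' of comparable magnitude).  Lobe positions are refined to subpixel
#' accuracy by a 3-point parabolic fit per axis (falling back, flagged, to
#' the integer peak at the map border).  The vector from the positive to
#' the negative lobe of a pair is the detector-plane displacement of the
#' moving object between the two correlated frames.
#'
#' @param map A [CorrelationMap-class] of kind "differential".
#' @param thresholdSigma Detection threshold in robust-noise units.
#' @param maxFeatures Maximum number of pairs returned (strongest first).
#' @param config Optional [OpticalConfig-class], used to size the default
#'   exclusion disk (3 speckle grains).
#' @param excludeRadiusPx Central exclusion radius override (px).
#' @param maxPairDistPx Maximum lobe pairing distance (px).
#' @param ratioGate Allowed |positive/negative| amplitude ratio range.
#' @return List of [MotionFeature-class] (possibly empty).
#' @export
extractMotionFeatures <- function(map, thresholdSigma = 5, maxFeatures = 5L,
                                  config = NULL, excludeRadiusPx = NULL,
                                  maxPairDistPx = Inf,
                                  ratioGate = c(1 / 3, 3)) {
  det <- .detectLobes(map, thresholdSigma, config, excludeRadiusPx)
  pos <- det$pos; neg <- det$neg; noise <- det$noise
  if (is.null(pos) || nrow(pos) == 0 || nrow(neg) == 0) return(list())
  neg <- neg[order(neg$value), , drop = FALSE]   # most negative first
  usedPos <- logical(nrow(pos))
  feats <- list()
  for (i in seq_len(nrow(neg))) {
    dist2 <- (pos$row - neg$row[i])^2 + (pos$col - neg$col[i])^2
    ratio <- pos$value / abs(neg$value[i])
    ok <- !usedPos & ratio >= ratioGate[1] & ratio <= ratioGate[2] &
      dist2 <= maxPairDistPx^2
    if (!any(ok)) next
    j <- which(ok)[which.min(dist2[ok])]
    usedPos[j] <- TRUE
    rp <- .refinePeak(det$w, pos$row[j], pos$col[j])
    rn <- .refinePeak(-det$w, neg$row[i], neg$col[i])
    posLobe <- c((rp$pos[2] - map@center[2]) * map@pitch,
                 (rp$pos[1] - map@center[1]) * map@pitch)
    negLobe <- c((rn$pos[2] - map@center[2]) * map@pitch,
                 (rn$pos[1] - map@center[1]) * map@pitch)
    amp <- min(pos$value[j], abs(neg$value[i]))
    feats[[length(feats) + 1L]] <- methods::new("MotionFeature",
      posLobe = posLobe, negLobe = negLobe,
      posAmp = pos$value[j], negAmp = neg$value[i],
      displacementDet = negLobe - posLobe,
      snr = amp / noise, refined = rp$refined && rn$refined)
  }
  if (length(feats) == 0) return(feats)
  ord <- order(vapply(feats, function(f) f@snr, numeric(1)),
               decreasing = TRUE)
  feats[ord][seq_len(min(maxFeatures, length(feats)))]
}

#' Object-plane displacement of a motion feature
#'
#' Maps the detector-plane lobe separation back to the object plane via the
#' geometric scale factor L_o/L_s (including the pinhole-style axis
#' un-flip).  Only relative motion between the correlated frames is
#' observable; absolute position is not.
#'
#' @param feature A [MotionFeature-class].
#' @param config An [OpticalConfig-class].
#' @return Object-plane displacement (x, y) in mm.
#' @export
estimateDisplacement <- function(feature, config) {
  detectorToObjectShift(feature@displacementDet, config)
}

#' Rotation angle from a motion feature about a known pivot
#'
#' For a sub-object rotating about a pivot, the paired lobes sit at the old
#' and new object positions relative to a static background object; the
#' angle subtended at the pivot's lag is the rotation between the
#' correlated frames (invariant under the axis reversal of the imaging
#' geometry).
#'
#' @param feature A [MotionFeature-class].
#' @param pivotLag_mm Lag position (x, y) in mm of the rotation pivot
#'   relative to the reference static object, i.e.
#'   \code{objectToDetectorShift(pivot - reference, config)}.
#' @return Signed rotation angle in degrees (positive from +x towards +y).
#' @export
estimateRotationAngle <- function(feature, pivotLag_mm) {
  v0 <- feature@posLobe - pivotLag_mm
  v1 <- feature@negLobe - pivotLag_mm
  atan2(v0[1] * v1[2] - v0[2] * v1[1], sum(v0 * v1)) * 180 / pi
}

#' Choose the reference-frame lag maximizing motion visibility
#'
#' The cross-correlation may use any previous frame as reference; if the
#' object barely moved between the correlated frames the differential
#' signal is weak.  This evaluates the differential map of the current
#' frame against each candidate lag, forms the consensus of its lobe-pair
#' displacements (every static structure within the memory range of the
#' mover votes for the same displacement), and returns the lag whose
#' consensus cluster carries the largest total SNR -- or a no-motion flag
#' when every candidate's best feature stays below \code{minSnr}.
#'
#' @param history List of [SpeckleFrame-class] (time-ordered).
#' @param currentIndex Index of the current frame in `history`.
#' @param candidateLags Candidate reference lags (frames back).
#' @param minSnr Minimum SNR for motion to be declared.
#' @param thresholdSigma Lobe detection threshold (robust-noise units).
#' @param config Optional [OpticalConfig-class] (sizes the exclusion disk).
#' @param excludeRadiusPx Central exclusion radius override (px).
#' @param maxPairDistPx Maximum lobe pairing distance (px).
#' @param maxFeatures Lobe pairs returned for the chosen lag.
#' @param consensusTolPx Cluster tolerance (px) for consistent lobe pairs.
#' @param switchMargin A longer lag replaces a shorter one only if its
#'   consensus score exceeds the incumbent's by this factor: the shortest
#'   lag suffers the least decorrelation, so longer references are used
#'   only when they are clearly more visible.
#' @param window,normalize Correlation options.
#' @return List with elements \code{lag} (chosen lag or NA), \code{snr}
#'   (strongest consistent feature), \code{features} (of the chosen lag),
#'   \code{displacementDet} (consensus detector-plane displacement, mm),
#'   \code{nConsistent}, \code{noMotion}.
#' @export
chooseReferenceLag <- function(history, currentIndex,
                               candidateLags = c(1L, 2L, 5L), minSnr = 5,
                               window = "none", normalize = "coeff",
                               thresholdSigma = 5, config = NULL,
                               excludeRadiusPx = NULL, maxPairDistPx = Inf,
                               maxFeatures = 5L, consensusTolPx = 2,
                               switchMargin = 1.5) {
  if (length(history) == 0) stop("empty frame history", call. = FALSE)
  lags <- sort(candidateLags[candidateLags >= 1 &
                               candidateLags < currentIndex])
  if (length(lags) == 0)
    stop("no candidate lag lies within the history", call. = FALSE)
  none <- list(lag = NA_integer_, snr = 0, features = list(),
               displacementDet = c(0, 0), nConsistent = 0L, noMotion = TRUE)
  best <- none
  bestScore <- -Inf
  bestMap <- NULL
  for (lag in lags) {
    dm <- differentialCorrelation(history[[currentIndex]],
                                  history[[currentIndex - lag]],
                                  window = window, normalize = normalize)
    vote <- .displacementVote(dm, thresholdSigma = thresholdSigma,
                              config = config,
                              excludeRadiusPx = excludeRadiusPx,
                              maxPairDistPx = maxPairDistPx,
                              tolPx = consensusTolPx)
    if (is.null(vote)) next
    need <- if (best$noMotion || best$snr < minSnr) bestScore
            else switchMargin * bestScore
    if (vote$score > need) {
      bestScore <- vote$score
      bestMap <- dm
      best <- list(lag = as.integer(lag), snr = vote$snr, features = list(),
                   displacementDet = vote$displacement,
                   nConsistent = vote$n, noMotion = FALSE)
    }
  }
  if (best$snr < minSnr) {
    none$snr <- best$snr
    return(none)
  }
  best$features <- extractMotionFeatures(bestMap,
    thresholdSigma = thresholdSigma, maxFeatures = maxFeatures,
    config = config, excludeRadiusPx = excludeRadiusPx,
    maxPairDistPx = maxPairDistPx)
  best
}

# Detect thresholded positive and negative lobes of a differential map
# (shared by the pair extractor and the displacement vote).
.detectLobes <- function(map, thresholdSigma, config, excludeRadiusPx) {
  if (map@kind != "differential")
    stop("motion features are defined on differential maps, not '",
         map@kind, "'", call. = FALSE)
  if (is.null(excludeRadiusPx))
    excludeRadiusPx <- .defaultExcludeRadius(map, config)
  w <- .overlapWhiten(map)
  d <- dim(w)
  # restrict the search to lags within half a frame: beyond it fewer than
  # a quarter of the pixels overlap and the lag estimate is starved (the
  # whitened noise there is heavy-tailed, and no meaningful correlation
  # structure lives at such extreme lags)
  search <- 0.5 * min(map@center - 1L)
  ix <- outer(rep(1, d[1]), seq_len(d[2]) - map@center[2])
  iy <- outer(seq_len(d[1]) - map@center[1], rep(1, d[2]))
  r2 <- ix^2 + iy^2
  outside <- r2 > search^2
  w[outside] <- 0
  keep <- r2 > excludeRadiusPx^2 & !outside
  noise <- 1.4826 * stats::mad(w[keep], center = 0, constant = 1)
  if (!is.finite(noise) || noise == 0)
    return(list(pos = NULL, neg = NULL, noise = noise, w = w))
  thr <- thresholdSigma * noise
  list(pos = .localExtrema(w, thr, +1, map@center, excludeRadiusPx),
       neg = .localExtrema(w, thr, -1, map@center, excludeRadiusPx),
       noise = noise, w = w)
}

# Displacement of a mover from its self-pair: the differential's self
# term is B(lag - d) - B(lag) with B the (broad) object self-correlation
# blob, so the positive lobe's peak is pushed outward by the central
# well's flank.  The zero crossing between well and lobe, however, sits
# at exactly d/2 for any blob width: estimate the magnitude as twice the
# zero-crossing radius along the centre-to-lobe axis (direction from the
# refined lobe).  Returns the effective positive-lobe position (px,
# c(row, col) relative to centre) or NULL if no crossing exists.
.selfPairLobe <- function(w, ctr, lobeRow, lobeCol) {
  # direction from the subpixel-refined lobe: the well's radial push
  # hardly changes the bearing, while integer quantization would cost
  # several degrees at small radii
  rp <- .refinePeak(w, lobeRow, lobeCol)
  v <- rp$pos - ctr
  r <- sqrt(sum(v^2))
  if (r < 2) return(NULL)
  u <- v / r
  ts <- seq(0.25, r, by = 0.25)
  f <- .bilinear(w, ctr[1] + ts * u[1], ctr[2] + ts * u[2])
  pk <- w[lobeRow, lobeCol]
  # peak refinement is already unbiased when well and lobe are separated
  # (and in the empty gap between separated blobs the crossing location is
  # noise): only use the crossing when the well's flank genuinely reaches
  # the lobe, i.e. the deep-well region extends to about half the radius
  below <- which(f < -0.2 * pk)
  if (length(below) == 0) return(NULL)
  wEdge <- ts[max(below)]
  if (r > 2.2 * wEdge + 1) return(NULL)
  # first crossing that stays positive for at least one pixel (noise dips
  # near the lobe must not masquerade as the well edge)
  pos <- f > 0
  cross <- which(!pos[-length(pos)] & pos[-1])
  for (i in cross) {
    if (all(pos[(i + 1):min(i + 4, length(pos))])) {
      t0 <- ts[i] + 0.25 * (-f[i]) / (f[i + 1] - f[i])
      if (t0 > 0.2 * r && t0 < 0.8 * r) return(2 * t0 * u)
      break
    }
  }
  NULL
}

# Joint two-Gaussian fit of a +/- lobe pair along its axis.  At step
# sizes comparable to the lobe width the opposite-sign tails push the two
# peaks apart, biasing peak-based separation estimates outward; fitting
# blob(+) - blob(-) with a shared width removes that repulsion bias.  The
# perpendicular component comes from a parabolic offset at each lobe
# (the partner's gradient vanishes there).  Returns the displacement
# (negative minus positive position) in px as c(row, col), or NULL when
# the fit fails or wanders.
.pairFit <- function(w, posRC, negRC, maxSep = 8.5) {
  v <- c(negRC[1] - posRC[1], negRC[2] - posRC[2])
  dInt <- sqrt(sum(v^2))
  # beyond about an object-autocorrelation width the tails no longer
  # interact and the plain parabolic peak is the better (unbiased,
  # model-free) estimator
  if (dInt < 2 || dInt > maxSep) return(NULL)
  u <- v / dInt
  ts <- seq(-4, dInt + 4, by = 0.25)
  rr <- posRC[1] + ts * u[1]
  cc <- posRC[2] + ts * u[2]
  ok <- rr >= 1 & rr <= nrow(w) & cc >= 1 & cc <= ncol(w)
  ts <- ts[ok]
  if (length(ts) < 12) return(NULL)
  f <- .bilinear(w, posRC[1] + ts * u[1], posRC[2] + ts * u[2])
  df <- data.frame(ts = ts, f = f)
  fit <- tryCatch(suppressWarnings(stats::nls(
    f ~ a1 * exp(-(ts - m1)^2 / (2 * s^2)) -
        a2 * exp(-(ts - m2)^2 / (2 * s^2)),
    data = df,
    start = list(a1 = max(f), a2 = -min(f), m1 = 0, m2 = dInt, s = 2),
    control = stats::nls.control(maxiter = 100, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) return(NULL)
  cf <- stats::coef(fit)
  if (cf[["a1"]] <= 0 || cf[["a2"]] <= 0 || cf[["s"]] <= 0.5 ||
      cf[["s"]] > dInt + 4 || abs(cf[["m1"]]) > 1.5 ||
      abs(cf[["m2"]] - dInt) > 1.5) return(NULL)
  sep <- cf[["m2"]] - cf[["m1"]]
  up <- c(-u[2], u[1])
  perp <- function(rc) {
    fm <- .bilinear(w, rc[1] - up[1], rc[2] - up[2])
    f0 <- .bilinear(w, rc[1], rc[2])
    fp <- .bilinear(w, rc[1] + up[1], rc[2] + up[2])
    off <- .parabolicOffset(fm, f0, fp)
    if (is.na(off)) 0 else off
  }
  dPerp <- perp(negRC) - perp(posRC)   # note: both refined on w as-is
  sep * u + dPerp * up
}

# Displacement vote over all admissible (+,-) lobe combinations of a
# differential map.  Every static background structure within the memory
# range of the mover contributes one lobe pair at the *same* displacement
# (new minus old position), while accidental cross-pairings scatter, so
# the displacement supported by the heaviest cluster of pair votes is the
# mover's step.  Within the winning cluster each physical lobe is counted
# once.  Returns NULL when no lobes are found.
.displacementVote <- function(map, thresholdSigma = 5, config = NULL,
                              excludeRadiusPx = NULL, maxPairDistPx = Inf,
                              ratioGate = c(1 / 3, 3), tolPx = 2) {
  det <- .detectLobes(map, thresholdSigma, config, excludeRadiusPx)
  pos <- det$pos; neg <- det$neg
  if (is.null(pos) || nrow(pos) == 0) return(NULL)
  # the mover's own old-x-new correlation contributes a strong positive
  # lobe at minus the displacement whose negative partner is the residual
  # at zero lag (inside the exclusion disk): admit the centre as a
  # negative-lobe candidate so the self-pair votes for the true step
  ctrVal <- det$w[map@center[1], map@center[2]]
  isCtr <- logical(nrow(neg))
  if (ctrVal < -thresholdSigma * det$noise) {
    neg <- rbind(neg, data.frame(row = map@center[1], col = map@center[2],
                                 value = ctrVal))
    isCtr <- c(isCtr, TRUE)
  }
  if (nrow(neg) == 0) return(NULL)
  cand <- expand.grid(i = seq_len(nrow(pos)), j = seq_len(nrow(neg)))
  dr <- neg$row[cand$j] - pos$row[cand$i]
  dc <- neg$col[cand$j] - pos$col[cand$i]
  ratio <- pos$value[cand$i] / abs(neg$value[cand$j])
  # the centre residual collects every decorrelation term, so the
  # amplitude-comparability gate does not apply to self-pairs
  ok <- (dr^2 + dc^2) <= maxPairDistPx^2 &
    (isCtr[cand$j] | (ratio >= ratioGate[1] & ratio <= ratioGate[2]))
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  dr <- dr[ok]; dc <- dc[ok]
  amp <- pmin(pos$value[cand$i], abs(neg$value[cand$j]))
  # heaviest displacement cluster, each lobe counted at most once
  best <- NULL
  for (m in seq_along(dr)) {
    mem <- which((dr - dr[m])^2 + (dc - dc[m])^2 <= tolPx^2)
    usedP <- logical(nrow(pos)); usedN <- logical(nrow(neg))
    sel <- integer()
    for (mm in mem[order(amp[mem], decreasing = TRUE)]) {
      if (usedP[cand$i[mm]] || usedN[cand$j[mm]]) next
      usedP[cand$i[mm]] <- TRUE; usedN[cand$j[mm]] <- TRUE
      sel <- c(sel, mm)
    }
    sc <- sum(amp[sel])
    if (is.null(best) || sc > best$score) best <- list(score = sc, sel = sel)
  }
  sel <- best$sel
  w <- amp[sel]
  # subpixel refinement of the member lobes
  disp <- matrix(0, length(sel), 2)
  for (s in seq_along(sel)) {
    i <- cand$i[sel[s]]; j <- cand$j[sel[s]]
    est <- .pairFit(det$w, c(pos$row[i], pos$col[i]),
                    c(neg$row[j], neg$col[j]))
    if (!is.null(est)) {
      disp[s, ] <- c(est[2], est[1]) * map@pitch
      next
    }
    if (isCtr[j]) {
      e <- .selfPairLobe(det$w, map@center, pos$row[i], pos$col[i])
      if (!is.null(e)) {
        disp[s, ] <- -c(e[2], e[1]) * map@pitch
        next
      }
    }
    rp <- .refinePeak(det$w, pos$row[i], pos$col[i])
    rn <- .refinePeak(-det$w, neg$row[j], neg$col[j])
    disp[s, ] <- c(rn$pos[2] - rp$pos[2], rn$pos[1] - rp$pos[1]) * map@pitch
  }
  list(displacement = colSums(disp * w) / sum(w),
       snr = max(w) / det$noise, score = sum(w) / det$noise,
       n = length(sel))
}

#' Track a moving object across a speckle sequence
#'
#' Iterates over frames, choosing for each the reference lag that maximizes
#' the differential-lobe SNR, converting the strongest lobe pair to an
#' object-plane displacement, and chaining the relative displacements into
#' a cumulative trajectory.  Each step only requires the mover to stay
#' within the memory range of some static background structure between the
#' two correlated frames, so the accumulated track can extend far beyond
#' the memory range itself (mosaicing it).  Steps flagged no-motion
#' contribute zero displacement; steps whose correlation fails are marked
#' invalid without aborting the track.
#'
#' @param frameList List of [SpeckleFrame-class] (>= 2, time-ordered).
#' @param config An [OpticalConfig-class].
#' @param thresholdSigma Lobe detection threshold (robust-noise units).
#' @param candidateLags Candidate reference lags.
#' @param minSnr No-motion threshold on the best feature SNR.
#' @param window,normalize Correlation options.
#' @param excludeRadiusPx Central exclusion radius (px); default 3 grains.
#' @param maxPairDistPx Maximum lobe pairing distance (px); defaults to the
#'   detector-mapped memory range (a trackable step cannot exceed it).
#' @param maxFeatures Lobe pairs kept per step for the consensus estimate.
#' @param consensusTolPx Cluster tolerance (px) for the per-step consensus
#'   of feature displacements.
#' @return A [Trajectory-class]; its table has one row per frame after the
#'   first, with per-step and cumulative object-plane displacements (mm),
#'   the reference lag used, the step SNR and a validity flag.
#' @export
buildTrajectory <- function(frameList, config, thresholdSigma = 5,
                            candidateLags = c(1L, 2L, 5L), minSnr = 5,
                            window = "none", normalize = "coeff",
                            excludeRadiusPx = NULL, maxPairDistPx = NULL,
                            maxFeatures = 6L, consensusTolPx = 2) {
  n <- length(frameList)
  if (n < 2) stop("need at least two frames to track", call. = FALSE)
  if (is.null(maxPairDistPx))
    maxPairDistPx <- max(5, memoryRange(config) * config@L_s /
                           (config@L_o * config@detectorPitch))
  cum <- matrix(0, n, 2)
  refLag <- rep(NA_integer_, n)
  snr <- rep(NA_real_, n)
  valid <- rep(TRUE, n)
  for (t in 2:n) {
    res <- tryCatch(
      chooseReferenceLag(frameList, t, candidateLags, minSnr,
                         window = window, normalize = normalize,
                         thresholdSigma = thresholdSigma, config = config,
                         excludeRadiusPx = excludeRadiusPx,
                         maxPairDistPx = maxPairDistPx,
                         maxFeatures = maxFeatures,
                         consensusTolPx = consensusTolPx),
      error = function(e) e)
    if (inherits(res, "error")) {
      cum[t, ] <- cum[t - 1, ]
      valid[t] <- FALSE
      next
    }
    snr[t] <- if (is.finite(res$snr)) res$snr else NA_real_
    if (res$noMotion) {
      cum[t, ] <- cum[t - 1, ]
    } else {
      d <- detectorToObjectShift(res$displacementDet, config)
      refLag[t] <- res$lag
      cum[t, ] <- cum[t - res$lag, ] + d
    }
  }
  steps <- rbind(c(0, 0), diff(cum))
  tab <- data.frame(frame = seq_len(n) - 1L,
                    dx_mm = steps[, 1], dy_mm = steps[, 2],
                    cum_x_mm = cum[, 1], cum_y_mm = cum[, 2],
                    ref_lag = refLag, snr = snr, valid = valid)[-1, ]
  rownames(tab) <- NULL
  methods::new("Trajectory", table = tab, pitchObj = config@objectPitch)
}

setMethod("show", "MotionFeature", function(object) {
  cat(sprintf(paste0("MotionFeature: + (%.3g, %.3g) mm [%.3g]  ",
                     "- (%.3g, %.3g) mm [%.3g]\n  detector displacement ",
                     "(%.3g, %.3g) mm, snr %.1f%s\n"),
              object@posLobe[1], object@posLobe[2], object@posAmp,
              object@negLobe[1], object@negLobe[2], object@negAmp,
              object@displacementDet[1], object@displacementDet[2],
              object@snr, if (object@refined) "" else " (integer peak)"))
})

setMethod("show", "Trajectory", function(object) {
  tab <- object@table
  cat(sprintf("Trajectory: %d step(s), final cumulative (%.4g, %.4g) mm\n",
              nrow(tab), tab$cum_x_mm[nrow(tab)], tab$cum_y_mm[nrow(tab)]))
  cat(sprintf("  valid steps: %d/%d, median snr %.1f\n",
              sum(tab$valid), nrow(tab),
              stats::median(tab$snr, na.rm = TRUE)))
})
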