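# Synthetic hidden-plane scene generator: sprites, dot fields, multi-shape
# scenes and per-frame rigid motion with intensity-conserving resampling.

# ---- sprites -----------------------------------------------------------

# Anti-aliased rasterization of an indicator function f(x, y) -> {0,1}
# (coordinates in px relative to sprite centre) on an n x n sprite grid,
# supersampled ss x ss per pixel.
.rasterIndicator <- function(n, f, ss = 4L) {
  c0 <- floor(n / 2) + 1L
  sub <- (seq_len(ss) - 0.5) / ss - 0.5
  out <- matrix(0, n, n)
  for (oy in sub) for (ox in sub) {
    x <- outer(rep(1, n), seq_len(n) - c0 + ox)
    y <- outer(seq_len(n) - c0 + oy, rep(1, n))
    out <- out + f(x, y)
  }
  out / ss^2
}

#' Sprite generators
#'
#' Small nonnegative intensity patches used as hidden-scene sub-objects,
#' rasterized with 4x supersampling so edges are smooth at the object-plane
#' pitch.
#'
#' @param radius Disk radius in object-plane pixels.
#' @param size Overall size (tip-to-tip for the star, side for the square)
#'   in pixels.
#' @param nPoints Number of star points.
#' @param width,height Rectangle dimensions in pixels.
#' @param intensity Peak intensity (arbitrary units).
#' @return A numeric matrix.
#' @examples
#' sum(diskSprite(3) > 0)
#' @export
diskSprite <- function(radius, intensity = 1) {
  n <- 2L * ceiling(radius) + 3L
  intensity * .rasterIndicator(n, function(x, y) (x^2 + y^2 <= radius^2) + 0)
}

#' @rdname diskSprite
#' @export
starSprite <- function(size, nPoints = 5L, intensity = 1) {
  rOut <- size / 2
  rIn <- rOut * 0.45
  n <- 2L * ceiling(rOut) + 3L
  # star as union of nPoints kite triangles: inside if radius below the
  # piecewise-linear boundary r(phi) interpolating outer and inner vertices
  intensity * .rasterIndicator(n, function(x, y) {
    r <- sqrt(x^2 + y^2)
    phi <- atan2(y, x)
    # sector angle within one point, folded to [0, pi/nPoints]
    a <- (phi %% (2 * pi / nPoints))
    a <- pmin(a, 2 * pi / nPoints - a)
    # boundary radius: linear in angle between tip (a=0) and valley
    half <- pi / nPoints
    rb <- rOut + (rIn - rOut) * (a / half)
    (r <= rb) + 0
  })
}

#' @rdname diskSprite
#' @export
rectSprite <- function(width, height = width, intensity = 1) {
  n <- max(ceiling(width), ceiling(height)) + 3L
  intensity * .rasterIndicator(n, function(x, y)
    (abs(x) <= width / 2 & abs(y) <= height / 2) + 0)
}

#' @rdname diskSprite
#' @param innerRadius Inner radius of the ring in pixels.
#' @export
ringSprite <- function(radius, innerRadius = 0.6 * radius, intensity = 1) {
  n <- 2L * ceiling(radius) + 3L
  intensity * .rasterIndicator(n, function(x, y) {
    r2 <- x^2 + y^2
    (r2 <= radius^2 & r2 >= innerRadius^2) + 0
  })
}

.spriteByKind <- function(kind, size, intensity = 1) {
  switch(kind,
    disk = diskSprite(size / 2, intensity),
    star = starSprite(size, intensity = intensity),
    rect = ,
    square = rectSprite(size, intensity = intensity),
    ring = ringSprite(size / 2, intensity = intensity),
    stop("unknown sprite kind: ", kind, call. = FALSE))
}

#' Construct a sub-object
#'
#' @param sprite Nonnegative numeric matrix.
#' @param anchor Object-plane position (x, y) of the sprite centre, mm.
#' @param mobile Whether the sub-object may move.
#' @param label Display label.
#' @return A [SubObject-class].
#' @export
subObject <- function(sprite, anchor = c(0, 0), mobile = FALSE,
                      label = "object") {
  methods::new("SubObject", sprite = sprite, anchor = as.numeric(anchor),
               mobile = mobile, label = label)
}

# ---- rasterization of a (possibly transformed) sub-object --------------

# Rasterize `sub`'s sprite onto a dim[1] x dim[2] scene grid (pitch mm/px)
# after shifting by shift_mm, rotating by rot (degrees, about the sprite
# centre) and scaling by `scale`.  Bilinear sampling of the pristine sprite;
# the result is renormalized to the pristine sprite total so rigid motion
# conserves the radiated intensity.  Errors if the support leaves the grid.
.rasterSub <- function(sub, dim, pitch, shift_mm = c(0, 0), rot = 0,
                       scale = 1) {
  if (scale <= 0) stop("motion scale factor must be positive", call. = FALSE)
  spr <- sub@sprite
  ns <- base::dim(spr)
  sc0 <- floor(ns / 2) + 1L
  ctr <- sub@anchor + shift_mm                    # sprite centre, mm
  cx <- floor(dim[2] / 2) + 1L
  cy <- floor(dim[1] / 2) + 1L
  halfExt <- 0.5 * sqrt(sum(ns^2)) * scale * pitch + pitch
  # grid bounds check (support must stay inside the scene)
  if (ctr[1] - halfExt < (1 - cx) * pitch || ctr[1] + halfExt > (dim[2] - cx) * pitch ||
      ctr[2] - halfExt < (1 - cy) * pitch || ctr[2] + halfExt > (dim[1] - cy) * pitch)
    stop(sprintf("sub-object '%s' leaves the scene grid", sub@label),
         call. = FALSE)
  colRange <- max(1L, floor(cx + (ctr[1] - halfExt) / pitch)):
              min(dim[2], ceiling(cx + (ctr[1] + halfExt) / pitch))
  rowRange <- max(1L, floor(cy + (ctr[2] - halfExt) / pitch)):
              min(dim[1], ceiling(cy + (ctr[2] + halfExt) / pitch))
  xs <- (colRange - cx) * pitch - ctr[1]          # scene coords rel. centre
  ys <- (rowRange - cy) * pitch - ctr[2]
  th <- rot * pi / 180
  ct <- cos(th); st <- sin(th)
  X <- outer(rep(1, length(ys)), xs)
  Y <- outer(ys, rep(1, length(xs)))
  # inverse transform into pristine sprite pixel coordinates
  U <- ( ct * X + st * Y) / (scale * pitch) + sc0[2]
  V <- (-st * X + ct * Y) / (scale * pitch) + sc0[1]
  patch <- .bilinear(spr, V, U)
  tot <- sum(patch)
  target <- sum(spr)
  if (tot > 0) patch <- patch * (target / tot)
  out <- matrix(0, dim[1], dim[2])
  out[rowRange, colRange] <- patch
  out
}

# Bilinear interpolation of matrix m at (row, col) coordinate matrices;
# zero outside.
.bilinear <- function(m, R, C) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(R); c0 <- floor(C)
  fr <- R - r0; fc <- C - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v <- get(r0, c0) * (1 - fr) * (1 - fc) +
       get(r0 + 1, c0) * fr * (1 - fc) +
       get(r0, c0 + 1) * (1 - fr) * fc +
       get(r0 + 1, c0 + 1) * fr * fc
  dim(v) <- dim(R)
  v
}

# ---- scenes and sequences ----------------------------------------------

#' Build an object scene from sub-objects
#'
#' @param subObjects List of [SubObject-class].
#' @param dim Scene grid size (rows, cols) in pixels.
#' @param pitch Object-plane pitch (mm/px).
#' @return An [ObjectScene-class] whose intensity is the rasterized sum.
#' @export
objectScene <- function(subObjects, dim = c(128L, 128L), pitch) {
  if (length(subObjects) == 0) stop("scene needs at least one sub-object",
                                    call. = FALSE)
  dim <- as.integer(dim)
  layers <- lapply(subObjects, .rasterSub, dim = dim, pitch = pitch)
  methods::new("ObjectScene", intensity = Reduce(`+`, layers), pitch = pitch,
               subObjects = subObjects)
}

#' Build a static scene sequence
#'
#' All frames identical until [applyMotion()] is used; static sub-objects
#' are rasterized once and shared bit-identically across frames.
#'
#' @inheritParams objectScene
#' @param nFrames Number of frames.
#' @param frameInterval Time between frames (arbitrary units).
#' @return A [SceneSequence-class].
#' @export
sceneSequence <- function(subObjects, dim = c(128L, 128L), pitch,
                          nFrames = 1L, frameInterval = 1) {
  sc <- objectScene(subObjects, dim, pitch)
  methods::new("SceneSequence", frames = rep(list(sc), nFrames),
               frameInterval = frameInterval, motion = list())
}

#' Dot-field scene: many static dots plus one mobile star
#'
#' Emulates a tracking scene made of a large number of static disks at
#' seeded-random non-overlapping positions plus a single star-shaped
#' sub-object flagged mobile.  Deterministic given the seed.
#'
#' @param nDots Number of static dots (>= 0).
#' @param dotRadius Dot radius (object-plane px).
#' @param starSize Star tip-to-tip size (px).
#' @param dim Grid size (rows, cols).
#' @param pitch Object-plane pitch (mm/px).
#' @param seed Integer seed.
#' @param nFrames Number of (initially identical) frames.
#' @param starAnchor Star position (x, y) in mm; default grid centre.
#' @param margin Keep-out margin from the grid edge, px.
#' @param region Optional c(xmin, xmax, ymin, ymax) in mm restricting where
#'   dots are placed (e.g. a band around a planned trajectory).
#' @param minSepPx Minimum centre-to-centre dot separation (px); defaults
#'   to barely non-overlapping supports.  Larger values keep the
#'   differential lobes of distinct dots from crowding each other.
#' @param maxTries Placement retries per dot before giving up.
#' @return A [SceneSequence-class]; sub-object 1 is the star.
#' @examples
#' sq <- makeDotfieldScene(10, seed = 1, dim = c(96, 96), pitch = 0.0688)
#' length(sq@frames[[1]]@subObjects)  # 11
#' @export
makeDotfieldScene <- function(nDots = 50L, dotRadius = 1.5, starSize = 9,
                              dim = c(128L, 128L), pitch, seed,
                              nFrames = 1L, starAnchor = c(0, 0),
                              margin = 6, region = NULL, minSepPx = NULL,
                              maxTries = 500L) {
  dim <- as.integer(dim)
  star <- subObject(starSprite(starSize), anchor = starAnchor, mobile = TRUE,
                    label = "star")
  subs <- list(star)
  if (nDots > 0) {
    cx <- floor(dim[2] / 2) + 1L; cy <- floor(dim[1] / 2) + 1L
    lim <- c((1 + margin - cx) * pitch, (dim[2] - margin - cx) * pitch,
             (1 + margin - cy) * pitch, (dim[1] - margin - cy) * pitch)
    if (!is.null(region)) {
      lim <- c(max(lim[1], region[1]), min(lim[2], region[2]),
               max(lim[3], region[3]), min(lim[4], region[4]))
    }
    if (lim[1] >= lim[2] || lim[3] >= lim[4])
      stop("dot placement region is empty", call. = FALSE)
    if (is.null(minSepPx)) minSepPx <- 2 * dotRadius + 2
    minSep <- minSepPx * pitch
    starSep <- (starSize / 2 + dotRadius + 2) * pitch
    pos <- matrix(NA_real_, nDots, 2)
    .withSeed(.deriveSeed(seed, "scene-dots"), {
      for (i in seq_len(nDots)) {
        placed <- FALSE
        for (tr in seq_len(maxTries)) {
          p <- c(stats::runif(1, lim[1], lim[2]),
                 stats::runif(1, lim[3], lim[4]))
          okStar <- .vlen(p - starAnchor) >= starSep
          okDots <- i == 1 ||
            all(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                              matrix(p, i - 1, 2, byrow = TRUE))^2)) >= minSep)
          if (okStar && okDots) { pos[i, ] <- p; placed <- TRUE; break }
        }
        if (!placed)
          stop("dot placement failed: grid too crowded for ", nDots,
               " dots", call. = FALSE)
      }
    })
    dotSpr <- diskSprite(dotRadius)
    for (i in seq_len(nDots))
      subs[[i + 1L]] <- subObject(dotSpr, anchor = pos[i, ],
                                  label = sprintf("dot%02d", i))
  }
  sceneSequence(subs, dim, pitch, nFrames)
}

#' Multi-shape scene
#'
#' A scene of a few shapes, any subset of which can be flagged mobile
#' (e.g. three shapes of which one moves and rotates).
#'
#' @param shapes List of shape specs, each a list with elements
#'   \code{kind} ("disk", "star", "rect"/"square", "ring"), \code{size}
#'   (px), \code{anchor} (x, y) mm, and optionally \code{intensity},
#'   \code{mobile}, \code{label}.
#' @inheritParams objectScene
#' @param nFrames Number of frames.
#' @return A [SceneSequence-class].
#' @export
makeMultishapeScene <- function(shapes, dim = c(128L, 128L), pitch,
                                nFrames = 1L) {
  if (length(shapes) == 0) stop("at least one shape is required", call. = FALSE)
  subs <- lapply(seq_along(shapes), function(i) {
    sh <- shapes[[i]]
    subObject(.spriteByKind(sh$kind, sh$size,
                            if (is.null(sh$intensity)) 1 else sh$intensity),
              anchor = sh$anchor,
              mobile = isTRUE(sh$mobile),
              label = if (is.null(sh$label)) sprintf("%s%d", sh$kind, i)
                      else sh$label)
  })
  # overlap check at t0 (conservative circumscribed-circle test)
  n <- length(subs)
  if (n > 1) {
    rad <- vapply(subs, function(s) 0.5 * sqrt(sum(dim(s@sprite)^2)) * pitch,
                  numeric(1))
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      d <- .vlen(subs[[i]]@anchor - subs[[j]]@anchor)
      if (d < 0.7 * (rad[i] + rad[j]))
        stop(sprintf("shapes %d and %d overlap at t0", i, j), call. = FALSE)
    }
  }
  sceneSequence(subs, dim, pitch, nFrames)
}

#' Apply per-frame motion to one sub-object
#'
#' Re-rasterizes the indexed sub-object at every frame (translation,
#' rotation about the sprite centre, isotropic scaling) with
#' intensity-conserving bilinear resampling; all other sub-objects stay
#' bit-identical across frames.  Sub-pixel translations are allowed: each
#' frame is rasterized from the pristine sprite, never by shifting already
#' rasterized pixels.
#'
#' @param seq A [SceneSequence-class].
#' @param subIndex Index of the sub-object to move.
#' @param motion data.frame (or matrix) with one row per frame and columns
#'   \code{dx}, \code{dy} (mm), \code{rot} (degrees), \code{scale}.
#'   Missing columns default to no translation / rotation / scaling.
#' @return A new [SceneSequence-class]; the moved sub-object's per-frame
#'   anchor is updated so simulations retain the ground truth.
#' @export
applyMotion <- function(seq, subIndex, motion) {
  nf <- length(seq@frames)
  motion <- as.data.frame(motion)
  if (nrow(motion) != nf)
    stop("motion must have one row per frame (", nf, ")", call. = FALSE)
  for (col in c("dx", "dy")) if (is.null(motion[[col]])) motion[[col]] <- 0
  if (is.null(motion$rot)) motion$rot <- 0
  if (is.null(motion$scale)) motion$scale <- 1
  f1 <- seq@frames[[1]]
  dims <- dim(f1@intensity)
  subs <- f1@subObjects
  if (subIndex < 1 || subIndex > length(subs))
    stop("'subIndex' out of range", call. = FALSE)
  # motion records compose: repeated calls (e.g. two independent movers)
  # each keep their own per-frame transform, keyed by sub-object index
  rec <- seq@motion
  rec[[as.character(subIndex)]] <- motion
  moving <- as.integer(names(rec))
  staticIdx <- setdiff(seq_along(subs), moving)
  staticLayer <- if (length(staticIdx))
    Reduce(`+`, lapply(subs[staticIdx], .rasterSub, dim = dims,
                       pitch = f1@pitch))
  else matrix(0, dims[1], dims[2])
  framesOut <- vector("list", nf)
  for (t in seq_len(nf)) {
    subsT <- subs
    layer <- staticLayer
    for (mi in moving) {
      mt <- rec[[as.character(mi)]]
      sh <- c(mt$dx[t], mt$dy[t])
      layer <- layer + .rasterSub(subs[[mi]], dims, f1@pitch,
                                  shift_mm = sh, rot = mt$rot[t],
                                  scale = mt$scale[t])
      subsT[[mi]] <- subObject(subs[[mi]]@sprite, subs[[mi]]@anchor + sh,
                               mobile = TRUE, label = subs[[mi]]@label)
    }
    framesOut[[t]] <- methods::new("ObjectScene", intensity = layer,
                                   pitch = f1@pitch, subObjects = subsT)
  }
  methods::new("SceneSequence", frames = framesOut,
               frameInterval = seq@frameInterval, motion = rec)
}

#' Straight-line per-frame motion helper
#'
#' Convenience builder for [applyMotion()]: constant velocity
#' \code{step_mm} per frame starting at zero offset.
#'
#' @param nFrames Number of frames.
#' @param step_mm Per-frame translation (x, y) in mm.
#' @param rotStep Per-frame rotation increment (degrees).
#' @param scaleStep Per-frame multiplicative size change.
#' @return A motion data.frame.
#' @export
linearMotion <- function(nFrames, step_mm = c(0, 0), rotStep = 0,
                         scaleStep = 1) {
  t <- seq_len(nFrames) - 1
  data.frame(dx = t * step_mm[1], dy = t * step_mm[2], rot = t * rotStep,
             scale = scaleStep^t)
}

setMethod("show", "ObjectScene", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("ObjectScene %dx%d px (pitch %g mm), %d sub-object(s), total intensity %.4g\n",
              d[1], d[2], object@pitch, length(object@subObjects),
              sum(object@intensity)))
})

setMethod("show", "SceneSequence", function(object) {
  d <- dim(object@frames[[1]]@intensity)
  nm <- sum(vapply(object@frames[[1]]@subObjects, function(s) s@mobile,
                   logical(1)))
  cat(sprintf("SceneSequence: %d frame(s) of %dx%d px, %d sub-object(s) (%d mobile)\n",
              length(object@frames), d[1], d[2],
              length(object@frames[[1]]@subObjects), nm))
})

setMethod("show", "SubObject", function(object) {
  cat(sprintf("SubObject '%s' %s at (%.3g, %.3g) mm, %dx%d sprite, sum %.4g\n",
              object@label, if (object@mobile) "(mobile)" else "(static)",
              object@anchor[1], object@anchor[2],
              nrow(object@sprite), ncol(object@sprite), sum(object@sprite)))
})
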