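# Synthetic hidden-scene generator.

test_that("dot-field scenes are deterministic and non-overlapping", {
  p <- 0.0688
  a <- makeDotfieldScene(20, dim = c(128, 128), pitch = p, seed = 7)
  b <- makeDotfieldScene(20, dim = c(128, 128), pitch = p, seed = 7)
  expect_identical(intensity(a@frames[[1]]), intensity(b@frames[[1]]))
  subs <- a@frames[[1]]@subObjects
  expect_length(subs, 21)          # star + 20 dots
  expect_true(subs[[1]]@mobile)
  expect_true(all(!vapply(subs[-1], function(s) s@mobile, logical(1))))
  # brute-force pairwise support distance check (dots only)
  anchors <- t(vapply(subs[-1], function(s) s@anchor, numeric(2)))
  dmin <- min(dist(anchors))
  expect_gte(dmin, (2 * 1.5 + 2) * p - 1e-9)
  # zero dots -> only the star
  s0 <- makeDotfieldScene(0, dim = c(64, 64), pitch = p, seed = 1)
  expect_length(s0@frames[[1]]@subObjects, 1)
  # overcrowded placement fails loudly
  expect_error(makeDotfieldScene(500, dim = c(48, 48), pitch = p, seed = 1),
               "crowded")
})

test_that("multishape scenes validate their inputs", {
  p <- 0.0688
  sh <- list(list(kind = "star", size = 9, anchor = c(-1.5, 0), mobile = TRUE),
             list(kind = "disk", size = 4, anchor = c(1.2, 0.8)),
             list(kind = "rect", size = 5, anchor = c(0.2, -1.4)))
  sq <- makeMultishapeScene(sh, dim = c(96, 96), pitch = p)
  expect_length(sq@frames[[1]]@subObjects, 3)
  expect_equal(sum(vapply(sq@frames[[1]]@subObjects,
                          function(s) s@mobile, logical(1))), 1)
  expect_error(makeMultishapeScene(list(), dim = c(96, 96), pitch = p),
               "at least one")
  shBad <- sh
  shBad[[2]]$anchor <- c(-1.5, 0.05)
  expect_error(makeMultishapeScene(shBad, dim = c(96, 96), pitch = p),
               "overlap")
})

test_that("motion moves only the indexed sub-object, conserving intensity", {
  p <- 0.0688
  sq <- makeDotfieldScene(6, dim = c(96, 96), pitch = p, seed = 3,
                          nFrames = 4, region = c(-2, 2, -2, 2))
  # identity motion: all frames identical
  id <- applyMotion(sq, 1, data.frame(dx = 0, dy = 0)[rep(1, 4), ])
  for (t in 2:4)
    expect_identical(intensity(id@frames[[t]]), intensity(id@frames[[1]]))
  # translation: centroid advances 5 px/frame, statics bit-identical
  mv <- applyMotion(sq, 1, linearMotion(4, c(5 * p, 0)))
  staticMask <- intensity(sq@frames[[1]]) -
    speckletrack:::.rasterSub(sq@frames[[1]]@subObjects[[1]],
                              c(96L, 96L), p)
  cents <- sapply(1:4, function(t) {
    m <- intensity(mv@frames[[t]]) - staticMask
    xs <- (seq_len(96) - 49) * p
    sum(outer(rep(1, 96), xs) * m) / sum(m)
  })
  expect_equal(diff(cents), rep(5 * p, 3), tolerance = 0.1 * p)
  # per-frame total intensity conserved to 1 %
  tots <- vapply(mv@frames, function(f) sum(intensity(f)), numeric(1))
  expect_true(all(abs(tots / tots[1] - 1) < 0.01))
  # statics unchanged, bit for bit: the frame-to-frame difference is
  # exactly zero wherever the mover's support never reaches
  mobiles <- lapply(1:4, function(t) intensity(mv@frames[[t]]) - staticMask)
  untouched <- Reduce(`&`, lapply(mobiles, function(m) m == 0))
  expect_gt(sum(untouched & staticMask > 0), 0)
  for (t in 2:4) {
    dI <- intensity(mv@frames[[t]]) - intensity(mv@frames[[1]])
    expect_identical(unique(dI[untouched]), 0)
  }
  # sprite pushed off the grid errors
  expect_error(applyMotion(sq, 1, linearMotion(4, c(40 * p, 0))),
               "leaves the scene")
})

test_that("rotation and scaling resample the pristine sprite, conserving sum", {
  p <- 0.0688
  sq <- sceneSequence(list(subObject(starSprite(11), c(0, 0), mobile = TRUE)),
                      dim = c(64, 64), pitch = p, nFrames = 5)
  rot <- applyMotion(sq, 1, data.frame(dx = 0, dy = 0,
                                       rot = c(0, 45, 90, 135, 180),
                                       scale = 1))
  tots <- vapply(rot@frames, function(f) sum(intensity(f)), numeric(1))
  expect_true(all(abs(tots / tots[1] - 1) < 0.01))
  sc <- applyMotion(sq, 1, data.frame(dx = 0, dy = 0, rot = 0,
                                      scale = c(1, 1.2, 1.44, 0.8, 0.6)))
  tots2 <- vapply(sc@frames, function(f) sum(intensity(f)), numeric(1))
  expect_true(all(abs(tots2 / tots2[1] - 1) < 0.01))
  # scaled support really grows
  expect_gt(sum(intensity(sc@frames[[3]]) > 0),
            sum(intensity(sc@frames[[5]]) > 0))
})

test_that("sub-pixel translation shifts the rasterized centroid accordingly", {
  p <- 0.0688
  sq <- sceneSequence(list(subObject(diskSprite(3), c(0, 0), mobile = TRUE)),
                      dim = c(64, 64), pitch = p, nFrames = 3)
  mv <- applyMotion(sq, 1, data.frame(dx = c(0, 0.5, 1.25) * p, dy = 0))
  xs <- (seq_len(64) - 33) * p
  cents <- sapply(1:3, function(t) {
    m <- intensity(mv@frames[[t]])
    sum(outer(rep(1, 64), xs) * m) / sum(m)
  })
  expect_equal(cents - cents[1], c(0, 0.5, 1.25) * p, tolerance = 0.05 * p)
})
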