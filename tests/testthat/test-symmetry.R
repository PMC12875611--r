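test_that("axis placement handles vertical, horizontal and oblique segments", {
  img <- labelImage(matrix(1L, 120, 120), scaleUmPerPx = 4)

  ax <- placeAxis(img, c(10, 50), c(90, 50))
  expect_equal(ax@rotationDeg, 0)
  expect_equal(ax@mirrorRow, 50)
  expect_equal(ax@centerCol, 50)

  # horizontal dorsoventral segment: rotated end points share a column,
  # dorsal above ventral
  axH <- placeAxis(img, c(60, 10), c(60, 110))
  expect_equal(abs(axH@rotationDeg), 90)
  ctr <- c(60.5, 60.5)
  dp <- SectionSymmetry:::rotatePoint(c(60, 10), axH@rotationDeg, ctr)
  vp <- SectionSymmetry:::rotatePoint(c(60, 110), axH@rotationDeg, ctr)
  expect_equal(dp[2], vp[2], tolerance = 1e-9)
  expect_lt(dp[1], vp[1])

  # oblique: rotation is -atan2(dcol, drow), verified by the grid oracle
  axO <- placeAxis(img, c(10, 10), c(90, 30))
  expect_equal(axO@rotationDeg, -atan2(20, 80) * 180 / pi)
  dp <- SectionSymmetry:::rotatePoint(c(10, 10), axO@rotationDeg, ctr)
  vp <- SectionSymmetry:::rotatePoint(c(90, 30), axO@rotationDeg, ctr)
  expect_equal(dp[2], vp[2], tolerance = 1e-9)
  expect_lt(dp[1], vp[1])
  expect_equal(axO@mirrorRow, (dp[1] + vp[1]) / 2)

  expect_error(placeAxis(img, c(10, 10), c(10, 10)), "differ")
  expect_error(placeAxis(img, c(0, 10), c(90, 30)), "inside")
})

test_that("window extraction follows the 400 um and odd-extent rules", {
  lab <- generateLabelSection(testSpec(seed = 7))
  ends <- sectionEndpoints(lab)
  ax <- placeAxis(lab, ends$dorsal, ends$ventral)
  win <- extractWindow(lab, ax, windowSpec(80, widthUm = 400))
  expect_equal(ncol(win@dorsal), 100L)  # 400 um at 4 um/px
  # mirror-symmetric raster: the aligned halves are identical
  expect_identical(win@dorsal, win@ventral)

  # 5-row raster with an integer mirror row: the centre row joins no half
  small <- labelImage(matrix(rep(c(2L, 3L, 4L, 3L, 5L), 4), 5, 4),
                      scaleUmPerPx = 100)
  axS <- placeAxis(small, c(1, 2), c(5, 2))
  expect_equal(axS@mirrorRow, 3)
  winS <- extractWindow(small, axS, windowSpec(3, widthUm = 400))
  expect_identical(dim(winS@dorsal), c(2L, 4L))
  expect_identical(winS@dorsal, matrix(rep(c(2L, 3L), 4), 2, 4))
  expect_identical(winS@ventral, matrix(rep(c(5L, 3L), 4), 2, 4))

  expect_error(extractWindow(lab, ax, windowSpec(5)), "outside")
})

test_that("color masks apply the all-three-channels tolerance rule", {
  # pixels (110,105,95) and (111,100,100) against target color (100,100,100)
  half <- array(c(110, 111, 105, 100, 95, 100), c(2, 1, 3))
  expect_identical(classMask(half, c(100, 100, 100), tol = 10)[, 1],
                   c(TRUE, FALSE))
  expect_true(all(classMask(half, c(0, 0, 0), tol = 255)))
  expect_error(classMask(half, c(1, 1, 1), tol = 300), "0..255")

  # tol 0 on a palette-exact render equals the label equality mask
  lab <- generateLabelSection(testSpec(seed = 3))
  rgb <- labelImageToRGB(lab)
  for (cl in c(1L, 3L, 5L)) {
    expect_identical(classMask(pixels(rgb), paletteColor(defaultPalette(), cl),
                               tol = 0),
                     classMask(labels(lab), cl))
  }
})

test_that("the worked 2x4 toy window scores (1.0, 0.5, 0.5), combined 0.6", {
  # halves after splitting at the vertical axis and flipping one side;
  # classes: muscle = 3, cartilage = 2, epidermis = 5
  dorsal <- matrix(c(3L, 5L, 2L, 5L), 2, 2)
  ventral <- matrix(c(3L, 2L, 2L, 5L), 2, 2)
  res <- scoreWindow(makeLabelWindow(dorsal, ventral))
  expect_equal(unname(res@score["class_3"]), 1.0)
  expect_equal(unname(res@score["class_2"]), 0.5)
  expect_equal(unname(res@score["class_5"]), 0.5)
  expect_equal(res@combined, 0.6)
  expect_true(all(is.na(res@score[c("class_1", "class_4")])))

  oracle <- bruteSymmetryScores(dorsal, ventral)
  expect_equal(unname(res@score), unname(oracle$score))
  expect_equal(res@combined, oracle$combined)

  # the "sum" denominator halves every count's weight
  resSum <- scoreWindow(makeLabelWindow(dorsal, ventral),
                        denominator = "sum")
  expect_equal(unname(resSum@score["class_3"]), 0.5)
  expect_equal(resSum@combined, 3 / 8)
})

test_that("identity and disjoint windows score 1 and 0", {
  half <- matrix(sample(1:5, 24, replace = TRUE), 4, 6)
  res <- scoreWindow(makeLabelWindow(half, half))
  expect_true(all(res@score[!is.na(res@score)] == 1))
  expect_equal(res@combined, 1)

  dis <- scoreWindow(makeLabelWindow(matrix(3L, 3, 3), matrix(2L, 3, 3)))
  expect_equal(unname(dis@score["class_3"]), 0)
  expect_equal(unname(dis@score["class_2"]), 0)
  expect_equal(dis@combined, 0)
})

test_that("scores agree with the pixel-pair enumeration oracle on random windows", {
  set.seed(31)
  for (i in 1:300) {
    H <- sample(1:8, 1); W <- sample(1:8, 1)
    dorsal <- matrix(sample(1:5, H * W, replace = TRUE), H, W)
    ventral <- matrix(sample(1:5, H * W, replace = TRUE), H, W)
    res <- scoreWindow(makeLabelWindow(dorsal, ventral))
    oracle <- bruteSymmetryScores(dorsal, ventral)
    expect_equal(unname(res@matching), unname(oracle$matching))
    expect_equal(unname(res@total), unname(oracle$total))
    expect_equal(res@combined, oracle$combined)

    # half-swap symmetry
    swap <- scoreWindow(makeLabelWindow(ventral, dorsal))
    expect_equal(swap@score, res@score)
    expect_equal(swap@combined, res@combined)

    # range and mediant property
    ok <- !is.na(res@score)
    expect_true(all(res@score[ok] >= 0 & res@score[ok] <= 1))
    expect_true(all(res@matching <= res@total))
    if (any(ok)) {
      expect_gte(res@combined + 1e-12, min(res@score[ok]))
      expect_lte(res@combined - 1e-12, max(res@score[ok]))
    }
  }
})

test_that("relabeling classes permutes per-class scores, combined unchanged", {
  set.seed(5)
  dorsal <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  ventral <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  res <- scoreWindow(makeLabelWindow(dorsal, ventral))
  perm <- c(3L, 1L, 5L, 2L, 4L)  # class k -> perm[k]
  resP <- scoreWindow(makeLabelWindow(matrix(perm[dorsal], 6, 6),
                                      matrix(perm[ventral], 6, 6)))
  expect_equal(unname(resP@score[paste0("class_", perm)]),
               unname(res@score[paste0("class_", 1:5)]))
  expect_equal(resP@combined, res@combined)
})

test_that("angle refinement recovers an imposed tilt and honours its contract", {
  lab <- generateLabelSection(testSpec(seed = 7))
  ends <- sectionEndpoints(lab)
  ax <- placeAxis(lab, ends$dorsal, ends$ventral)
  win <- windowSpec(80)

  # symmetric section: the optimum is the identity
  ref0 <- refineAngle(lab, ax, win, searchDeg = 3, stepDeg = 0.5)
  expect_equal(ref0@rotationDeg, ax@rotationDeg)

  # search 0 returns the input unchanged
  expect_identical(refineAngle(lab, ax, win, searchDeg = 0), ax)

  # a section pre-rotated by +2 degrees is recovered at -2
  tilted <- SectionSymmetry:::rotateRaster(lab, 2)
  axT <- placeAxis(tilted, ends$dorsal, ends$ventral)
  refT <- refineAngle(tilted, axT, win, searchDeg = 5, stepDeg = 0.5)
  expect_equal(refT@rotationDeg - axT@rotationDeg, -2)

  # no epidermis in the window is a contract violation
  bare <- labelImage(matrix(4L, 60, 60), scaleUmPerPx = 4)
  axB <- placeAxis(bare, c(5, 30), c(55, 30))
  expect_error(refineAngle(bare, axB, windowSpec(30, widthUm = 80),
                           searchDeg = 2), "no epidermal contour")
})

test_that("scoreSample is consistent with single-window scoring", {
  lab <- generateLabelSection(testSpec(seed = 7))
  ends <- sectionEndpoints(lab)
  ax <- placeAxis(lab, ends$dorsal, ends$ventral)

  res <- scoreSample(lab, ax, seq(60, 104, by = 4), sampleId = "sym")
  expect_length(res, 12L)
  expect_true(all(sapply(res, function(r) r@combined) == 1))
  expect_true(all(sapply(res, function(r) r@sampleId) == "sym"))

  asym <- generateLabelSection(testSpec(asymmetry = 1, seed = 9))
  endsA <- sectionEndpoints(asym)
  axA <- placeAxis(asym, endsA$dorsal, endsA$ventral)
  resA <- scoreSample(asym, axA, c(70, 90))
  expect_false(resA[[1]]@combined == resA[[2]]@combined)
  for (i in 1:2) {
    direct <- scoreWindow(extractWindow(asym, axA,
                                        windowSpec(c(70, 90)[i])))
    expect_equal(resA[[i]]@score, direct@score)
    expect_equal(resA[[i]]@combined, direct@combined)
  }
  expect_error(scoreSample(asym, axA, numeric(0)), "at least one")
})

test_that("RGB-domain scoring with tolerance matches label-domain scoring", {
  lab <- generateLabelSection(testSpec(seed = 7))
  rgb <- labelImageToRGB(lab)
  ends <- sectionEndpoints(lab)
  ax <- placeAxis(lab, ends$dorsal, ends$ventral)
  winL <- extractWindow(lab, ax, windowSpec(80))
  winR <- extractWindow(rgb, ax, windowSpec(80))
  resL <- scoreWindow(winL)
  resR <- scoreWindow(winR, tol = 0)
  expect_equal(resR@score, resL@score)
  expect_equal(resR@combined, resL@combined)
})
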