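test_that("the default ROI set matches the template coordinates", {
  rois <- defaultRois()
  expect_equal(nrow(rois), 4L)
  projL <- rois[rois$side == "left" & rois$fiber == "projection", ]
  expect_equal(c(projL$x, projL$y, projL$z), c(116, 109, 99))
  expect_true(all(rois$y == 109))
  expect_true(all(rois$diameter == 5))
  # hemispheric reflection of the printed centers about the 182-voxel grid's
  # x mid-plane holds within one voxel
  projR <- rois[rois$side == "right" & rois$fiber == "projection", ]
  assocL <- rois[rois$fiber == "association" & rois$side == "left", ]
  assocR <- rois[rois$fiber == "association" & rois$side == "right", ]
  expect_lte(abs((181 - projL$x) - projR$x), 1)
  expect_lte(abs((181 - assocL$x) - assocR$x), 1)
  r1 <- defaultRois(oneBased = TRUE)
  expect_equal(r1$x, rois$x - 1L)
})

test_that("a 5 mm sphere on a 1 mm grid averages exactly 81 voxels", {
  # oracle: enumerate integer offsets with i^2+j^2+k^2 <= 2.5^2
  off <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  nOracle <- sum(rowSums(off^2) <= 2.5^2)
  expect_equal(nOracle, 81L)
  map <- array(0, c(11, 11, 11))
  roi <- data.frame(name = "r", x = 5, y = 5, z = 5, diameter = 5)
  map[alpsdti:::sphereVoxels(c(5, 5, 5), 5, dim(map))] <- 1
  expect_equal(sum(map), 81)
  expect_equal(roiMean(map, roi), 1)           # constant map -> the constant
  map2 <- array(seq_len(11^3), c(11, 11, 11))
  expect_equal(roiMean(map2, roi),
               mean(map2[alpsdti:::sphereVoxels(c(5, 5, 5), 5, dim(map2))]))
})

test_that("boundary-clipped spheres raise an error naming the ROI", {
  map <- array(0, c(11, 11, 11))
  corner <- data.frame(name = "corner_roi", x = 0, y = 0, z = 0, diameter = 5)
  expect_error(roiMean(map, corner), "corner_roi")
})

test_that("ALPS arithmetic follows the ratio formula", {
  spec <- smokePhantomSpec()
  dims <- spec$gridShape
  rois <- spec$rois
  iso <- mapsFromDiagonals(array(1e-3, dims), array(1e-3, dims),
                           array(1e-3, dims))
  expect_equal(alpsIndices(computeAlps(iso, rois)),
               c(left = 1, right = 1, mean = 1), tolerance = 1e-12)
  two <- mapsFromDiagonals(array(2e-3, dims), array(1e-3, dims),
                           array(1e-3, dims))
  expect_equal(alpsIndices(computeAlps(two, rois)),
               c(left = 2, right = 2, mean = 2), tolerance = 1e-12)
})

test_that("ALPS requires one ROI per side-fiber combination", {
  spec <- smokePhantomSpec()
  maps <- mapsFromDiagonals(array(1e-3, spec$gridShape),
                            array(1e-3, spec$gridShape),
                            array(1e-3, spec$gridShape))
  expect_error(computeAlps(maps, spec$rois[-2, ]), "right association|missing")
  dup <- spec$rois
  dup$fiber[2] <- "projection"
  expect_error(computeAlps(maps, dup), "missing")
})

test_that("non-positive denominators are refused with diagnostics", {
  spec <- smokePhantomSpec()
  dims <- spec$gridShape
  bad <- mapsFromDiagonals(array(1e-3, dims), array(0, dims), array(0, dims))
  expect_error(computeAlps(bad, spec$rois), "denominator")
})

test_that("ALPS is scale-invariant and the mean lies between the sides", {
  spec <- smokePhantomSpec()
  dims <- spec$gridShape
  set.seed(8)
  mk <- function(f) mapsFromDiagonals(array(f * runif(prod(dims), 0.5e-3, 1.5e-3), dims),
                                      array(f * runif(prod(dims), 0.5e-3, 1.5e-3), dims),
                                      array(f * runif(prod(dims), 0.5e-3, 1.5e-3), dims))
  set.seed(8); a <- computeAlps(mk(1), spec$rois)
  set.seed(8); b <- computeAlps(mk(3.7), spec$rois)
  expect_equal(alpsIndices(a), alpsIndices(b), tolerance = 1e-12)
  expect_gte(a@mean, min(a@left, a@right))
  expect_lte(a@mean, max(a@left, a@right))
})
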