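test_that("forward model matches closed-form attenuation", {
  sch <- makeScheme(c(0, 1000), 6, seed = 2)
  s <- simulateSignal(diag(rep(0.7e-3, 3)), sch, s0 = 100)
  expect_equal(s[bValues(sch) == 0], 100)           # b = 0 gives s0 exactly
  expect_equal(unique(round(s[bValues(sch) > 0], 8)),
               round(100 * exp(-0.7), 8), tolerance = 1e-4)
  # anisotropic: oracle is the direct quadratic form per measurement
  set.seed(5)
  D <- randomSPD()
  s2 <- simulateSignal(D, sch, s0 = 1)
  oracle <- vapply(seq_len(nMeasurements(sch)), function(i) {
    g <- bVectors(sch)[i, ]
    exp(-bValues(sch)[i] * drop(t(g) %*% D %*% g))
  }, numeric(1))
  oracle[bValues(sch) == 0] <- 1
  expect_equal(s2, oracle, tolerance = 1e-12)
})

test_that("forward model rejects invalid inputs", {
  sch <- makeScheme(c(0, 1000), 6, seed = 2)
  expect_error(simulateSignal(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3), sch),
               "symmetric")
  expect_error(simulateSignal(diag(c(-1e-3, 1e-3, 1e-3)), sch),
               "semidefinite")
  expect_error(new("AcquisitionScheme", bvals = c(0, -100),
                   bvecs = rbind(c(0, 0, 0), c(1, 0, 0))), "non-negative")
})

test_that("Rician noise has the analytic second moment and is seeded", {
  A <- 10; sigma <- 2
  x <- rep(A, 1e5)
  y <- addRicianNoise(x, sigma, seed = 3)
  expect_true(all(y >= 0))
  # E[Y^2] = A^2 + 2 sigma^2; tolerance 4 Monte-Carlo SEs
  expect_equal(mean(y^2), A^2 + 2 * sigma^2, tolerance = 0.6 / 108)
  expect_identical(y, addRicianNoise(x, sigma, seed = 3))
  expect_false(identical(y, addRicianNoise(x, sigma, seed = 4)))
  expect_identical(addRicianNoise(x, 0, seed = 3), x)   # sigma = 0 is identity
})

test_that("isotropic phantom has ground-truth ALPS of exactly 1", {
  spec <- smokePhantomSpec(isotropicD = 0.75e-3)
  ph <- buildSubjectPhantom(spec, NULL, smallScheme(), subjectSeed = 1,
                            noise = FALSE)
  expect_equal(unname(ph$groundTruth$alps), c(1, 1, 1), tolerance = 1e-12)
})

test_that("noise-free phantoms round-trip the full pipeline exactly", {
  spec <- smokePhantomSpec()
  ph <- buildSubjectPhantom(spec, groupPreset("HC"), smallScheme(),
                            subjectSeed = 11, noise = FALSE)
  maps <- eigenMaps(fitTensor(selectShells(ph$dwi, 1000)))
  alps <- computeAlps(maps, spec$rois)
  expect_equal(alps@left, unname(ph$groundTruth$alps["left"]),
               tolerance = 1e-9)
  expect_equal(alps@right, unname(ph$groundTruth$alps["right"]),
               tolerance = 1e-9)
})

test_that("stored ground truth equals the ALPS formula on the painted field", {
  spec <- smokePhantomSpec()
  ph <- buildSubjectPhantom(spec, groupPreset("DMMCI"), smallScheme(),
                            subjectSeed = 21, noise = FALSE, imaging = FALSE)
  mapsTrue <- eigenMaps(ph$trueField)
  alps <- computeAlps(mapsTrue, spec$rois)
  expect_equal(alps@left, unname(ph$groundTruth$alps["left"]),
               tolerance = 1e-12)
  expect_equal(alps@mean, unname(ph$groundTruth$alps["mean"]),
               tolerance = 1e-12)
})

test_that("x-mirroring a phantom's maps swaps left and right ALPS exactly", {
  spec <- smokePhantomSpec()
  ph <- buildSubjectPhantom(spec, groupPreset("HC"), smallScheme(),
                            subjectSeed = 31, noise = FALSE, imaging = FALSE)
  maps <- eigenMaps(ph$trueField)
  a <- computeAlps(maps, spec$rois)
  m <- computeAlps(mirrorMaps(maps), mirrorRois(spec$rois, gridDim(maps)[1]))
  expect_identical(m@left, a@right)
  expect_identical(m@right, a@left)
  expect_identical(m@mean, a@mean)
})

test_that("overlapping phantom structures are rejected", {
  spec <- smokePhantomSpec()
  spec$rois$x <- c(19L, 21L, 13L, 7L)   # spheres 2 voxels apart overlap
  expect_error(alpsdti:::specStructureIndex(spec), "overlap")
})

test_that("ALPS is invariant under global rescaling of all diffusivities", {
  spec1 <- smokePhantomSpec()
  spec2 <- spec1
  for (nm in names(spec2$roiTensors))
    spec2$roiTensors[[nm]] <- spec2$roiTensors[[nm]] * 2
  for (nm in names(spec2$hippoTensors))
    spec2$hippoTensors[[nm]] <- spec2$hippoTensors[[nm]] * 2
  spec2$backgroundTensor <- spec2$backgroundTensor * 2
  sch <- smallScheme()
  a1 <- computeAlps(eigenMaps(buildSubjectPhantom(spec1, NULL, sch, 1,
                                                  imaging = FALSE)$trueField),
                    spec1$rois)
  a2 <- computeAlps(eigenMaps(buildSubjectPhantom(spec2, NULL, sch, 1,
                                                  imaging = FALSE)$trueField),
                    spec2$rois)
  expect_equal(alpsIndices(a1), alpsIndices(a2), tolerance = 1e-12)
})

test_that("cohort generation is reproducible and respects group sizes", {
  spec <- smokePhantomSpec()
  sch <- smallScheme()
  c1 <- generateCohort(studyPresets(), studySizes(), spec, sch, seed = 7,
                       keepImaging = FALSE, imaging = FALSE)
  expect_equal(nrow(c1$covariates), 113L)
  expect_equal(as.vector(table(c1$covariates$group)[c("HC", "DMNC", "DMMCI")]),
               c(37L, 37L, 39L))
  expect_false(anyDuplicated(c1$covariates$subject_id) > 0)
  c2 <- generateCohort(studyPresets(), studySizes(), spec, sch, seed = 7,
                       keepImaging = FALSE, imaging = FALSE)
  expect_identical(c1$covariates, c2$covariates)
  # HC is missing duration by design; diabetic groups always have it
  expect_true(all(is.na(c1$covariates$duration[c1$covariates$group == "HC"])))
  expect_true(all(!is.na(c1$covariates$duration[c1$covariates$group != "HC"])))
})

test_that("a single-group cohort equals the matching subset of the full cohort", {
  spec <- smokePhantomSpec()
  sch <- smallScheme()
  full <- generateCohort(studyPresets(), c(HC = 5L, DMNC = 5L, DMMCI = 5L),
                         spec, sch, seed = 42, keepImaging = FALSE,
                         imaging = FALSE)$covariates
  hcOnly <- generateCohort(studyPresets()["HC"], c(HC = 5L), spec, sch,
                           seed = 42, keepImaging = FALSE,
                           imaging = FALSE)$covariates
  expect_identical(hcOnly, full[full$group == "HC", ])
})

test_that("group ALPS means are ordered as calibrated, across seeds", {
  spec <- smokePhantomSpec()
  sch <- smallScheme()
  sizes <- c(HC = 200L, DMNC = 200L, DMMCI = 200L)
  ok <- vapply(1:20, function(s) {
    cv <- generateCohort(studyPresets(), sizes, spec, sch, seed = s,
                         keepImaging = FALSE, imaging = FALSE)$covariates
    m <- tapply(cv$truth_alps_mean, cv$group, mean)
    m[["DMMCI"]] < m[["HC"]]
  }, logical(1))
  expect_true(all(ok))
})

test_that("drawn covariates track the group presets", {
  cv <- alpsdti:::drawCovariates(groupPreset("DMMCI"), 4000, seed = 5)
  expect_equal(median(cv$HbA1c), 7.4, tolerance = 0.05)
  expect_equal(mean(cv$gender == "male"), 19 / 39, tolerance = 0.03)
  expect_true(all(cv$MoCA >= 17 & cv$MoCA <= 25))  # MCI screening window
  cvHC <- alpsdti:::drawCovariates(groupPreset("HC"), 4000, seed = 5)
  expect_true(all(cvHC$MoCA >= 26))
  expect_true(all(cvHC$education >= 6))
  expect_equal(mean(cvHC$SBP), 124.22, tolerance = 1)
})
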