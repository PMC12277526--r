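test_that("shell selection keeps b0 and the sub-cutoff shells, aligned", {
  spec <- smokePhantomSpec(isotropicD = 0.75e-3)
  sch <- makeScheme(c(0, 300, 350, 650, 950, 1000, 1350, 1650, 1700, 2000,
                      2700, 3000), 12, seed = 1)
  ph <- buildSubjectPhantom(spec, NULL, sch, subjectSeed = 1, noise = FALSE)
  low <- selectShells(ph$dwi, 1000)                 # strict: b < 1000
  expect_setequal(unique(bValues(low)), c(0, 300, 350, 650, 950))
  expect_equal(nMeasurements(low), 1L + 4L * 12L)   # counting oracle
  inc <- selectShells(ph$dwi, 1000, inclusive = TRUE)
  expect_setequal(unique(bValues(inc)), c(0, 300, 350, 650, 950, 1000))
  expect_equal(nMeasurements(inc), 1L + 5L * 12L)
  all <- selectShells(ph$dwi, Inf)                  # identity
  expect_identical(signalMatrix(all), signalMatrix(ph$dwi))
  # scheme and signal stay aligned: kept columns match kept b-values
  keep <- bValues(ph$dwi) < 1000
  expect_identical(signalMatrix(low), signalMatrix(ph$dwi)[, keep])
  expect_error(selectShells(ph$dwi, 200), "fewer than 6")
})

test_that("noiseless fits recover any SPD tensor to numerical precision", {
  sch <- smallScheme(12)
  # isotropic: diagonal recovered, off-diagonals vanish
  iso <- fitTensor(singleVoxelDataset(diag(rep(0.7e-3, 3)), sch))
  expect_equal(unname(iso@D[1, 1:3]), rep(0.7e-3, 3), tolerance = 1e-12)
  expect_lt(max(abs(iso@D[1, 4:6])), 1e-12)
  # random SPD tensors against the independent pseudoinverse oracle
  set.seed(99)
  for (i in 1:5) {
    D <- randomSPD()
    ds <- singleVoxelDataset(D, sch)
    fit <- fitTensor(ds)
    Dhat <- matrix(c(fit@D[1, 1], fit@D[1, 4], fit@D[1, 5],
                     fit@D[1, 4], fit@D[1, 2], fit@D[1, 6],
                     fit@D[1, 5], fit@D[1, 6], fit@D[1, 3]), 3, 3)
    expect_equal(Dhat, D, tolerance = 1e-10)
    Doracle <- oracleTensorFit(signalMatrix(ds)[1, ], bValues(sch),
                               bVectors(sch))
    expect_equal(Dhat, Doracle, tolerance = 1e-10)
  }
})

test_that("under-determined designs and bad voxels are rejected or flagged", {
  sch5 <- new("AcquisitionScheme",
              bvals = c(0, rep(1000, 5)),
              bvecs = rbind(c(0, 0, 0),
                            bVectors(makeScheme(c(0, 1000), 6))[2:6, ]))
  D <- diag(rep(1e-3, 3))
  expect_error(fitTensor(singleVoxelDataset(D, sch5)), "6 distinct")
  # a voxel with a zero signal is flagged and excluded, not fitted
  sch <- smallScheme(12)
  mask <- array(TRUE, c(2, 1, 1))
  sig <- rbind(simulateSignal(D, sch, 100), simulateSignal(D, sch, 100))
  sig[2, 3] <- 0
  ds <- new("DWIDataset", signal = sig, mask = mask, scheme = sch,
            voxelSize = 1)
  fit <- fitTensor(ds)
  expect_false(fit@flags[1])
  expect_true(fit@flags[2])
  expect_equal(unname(fit@D[2, ]), rep(0, 6))
})

test_that("multiple b0 volumes are averaged before fitting", {
  schA <- makeScheme(c(0, 0, 1000), 12, seed = 4)
  schB <- makeScheme(c(0, 1000), 12, seed = 4)
  D <- diag(c(1.5e-3, 0.5e-3, 0.5e-3))
  fitA <- fitTensor(singleVoxelDataset(D, schA))
  fitB <- fitTensor(singleVoxelDataset(D, schB))
  expect_equal(fitA@D, fitB@D, tolerance = 1e-12)
})

test_that("eigen maps satisfy the FA/MD/AD/RD identities", {
  sch <- smallScheme(12)
  # isotropic voxel
  maps <- eigenMaps(fitTensor(singleVoxelDataset(diag(rep(0.7e-3, 3)), sch)))
  expect_equal(maps@fa[1], 0, tolerance = 1e-9)
  expect_equal(maps@md[1], 0.7e-3, tolerance = 1e-12)
  expect_equal(maps@ad[1], 0.7e-3, tolerance = 1e-12)
  expect_equal(maps@rd[1], 0.7e-3, tolerance = 1e-12)
  # prolate tensor: FA from direct evaluation of the formula
  ev <- c(1.7e-3, 0.2e-3, 0.2e-3)
  maps2 <- eigenMaps(fitTensor(singleVoxelDataset(diag(ev), sch)))
  lb <- mean(ev)
  faOracle <- sqrt(1.5) * sqrt(sum((ev - lb)^2)) / sqrt(sum(ev^2))
  expect_equal(maps2@fa[1], faOracle, tolerance = 1e-9)
  expect_equal(faOracle, 0.8703883, tolerance = 1e-6)
  expect_equal(maps2@ad[1], 1.7e-3, tolerance = 1e-12)
  expect_equal(maps2@rd[1], 0.2e-3, tolerance = 1e-12)
  # MD two independent ways: diagonal mean vs eigenvalue mean
  expect_equal(mean(c(maps2@dxx[1], maps2@dyy[1], maps2@dzz[1])),
               mean(maps2@evals[1, ]), tolerance = 1e-15)
})

test_that("degenerate voxels get FA = 0 and a flag", {
  field <- new("TensorField", D = matrix(0, 1, 6),
               mask = array(TRUE, c(1, 1, 1)), flags = FALSE,
               residualNorm = 0, voxelSize = 1)
  maps <- eigenMaps(field)
  expect_equal(maps@fa[1], 0)
  expect_true(maps@flags[1])
  # negative eigenvalue: clamped to zero and flagged
  fieldNeg <- new("TensorField", D = cbind(-1e-4, 1e-3, 1e-3, 0, 0, 0),
                  mask = array(TRUE, c(1, 1, 1)), flags = FALSE,
                  residualNorm = 0, voxelSize = 1)
  mneg <- eigenMaps(fieldNeg)
  expect_true(mneg@flags[1])
  expect_true(all(mneg@evals[1, ] >= 0))
})

test_that("rotating tensors and gradients together preserves the invariants", {
  sch <- smallScheme(15)
  set.seed(12)
  for (i in 1:3) {
    D <- randomSPD()
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    Drot <- Q %*% D %*% t(Q)
    m1 <- eigenMaps(fitTensor(singleVoxelDataset(D, sch)))
    m2 <- eigenMaps(fitTensor(singleVoxelDataset(Drot, sch)))
    for (nm in c("fa", "md", "ad", "rd"))
      expect_equal(scalarMap(m2, nm)[1], scalarMap(m1, nm)[1],
                   tolerance = 1e-9)
  }
})
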