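# Shared fixtures: small schemes, single-voxel datasets, map builders and a
# lazily cached full-pipeline cohort for the end-to-end checks.

smallScheme <- function(n = 12, shells = c(0, 300, 650, 950), seed = 101) {
  makeScheme(shells, n, seed = seed)
}

# one-voxel dataset carrying the forward-model signal of a single tensor
singleVoxelDataset <- function(tensor, scheme, s0 = 1000) {
  mask <- array(TRUE, c(1L, 1L, 1L))
  sig <- matrix(simulateSignal(tensor, scheme, s0), nrow = 1)
  new("DWIDataset", signal = sig, mask = mask, scheme = scheme, voxelSize = 1)
}

# DiffusivityMaps with prescribed diagonal maps (for ALPS arithmetic tests)
mapsFromDiagonals <- function(dxx, dyy, dzz, voxelSize = 1) {
  dims <- dim(dxx)
  z <- array(0, dims)
  ev <- matrix(0, prod(dims), 3)
  new("DiffusivityMaps", dxx = dxx, dyy = dyy, dzz = dzz,
      fa = z, md = (dxx + dyy + dzz) / 3, ad = z, rd = z, evals = ev,
      flags = rep(FALSE, prod(dims)), mask = array(TRUE, dims),
      voxelSize = voxelSize)
}

# independent log-linear pseudoinverse tensor fit (test oracle; never the
# package's code path)
oracleTensorFit <- function(signal, bvals, bvecs) {
  gx <- bvecs[, 1]; gy <- bvecs[, 2]; gz <- bvecs[, 3]
  X <- cbind(1, -bvals * gx^2, -bvals * gy^2, -bvals * gz^2,
             -2 * bvals * gx * gy, -2 * bvals * gx * gz, -2 * bvals * gy * gz)
  beta <- qr.solve(X, log(signal))
  matrix(c(beta[2], beta[5], beta[6],
           beta[5], beta[3], beta[7],
           beta[6], beta[7], beta[4]), 3, 3)
}

# textbook Benjamini-Hochberg step-up (test oracle)
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

randomSPD <- function(scale = 1e-3) {
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  Q %*% diag(runif(3, 0.1, 2) * scale) %*% t(Q)
}

# cohort table with measured-column names filled from ground truth (for
# statistics-layer tests that do not need the imaging chain)
truthAsMeasured <- function(cv) {
  cv$alps_left <- cv$truth_alps_left
  cv$alps_right <- cv$truth_alps_right
  cv$alps_mean <- cv$truth_alps_mean
  for (m in c("fa", "md", "ad", "rd")) for (s in c("left", "right"))
    cv[[paste0("hippo_", m, "_", s)]] <- cv[[paste0("truth_hippo_", m, "_", s)]]
  cv
}

# full-pipeline 113-subject cohort at seed 42 (reduced grid, SNR 20, the
# emulated 12-shell/99-direction protocol); computed once per session
.acceptanceCache <- new.env(parent = emptyenv())
acceptanceCohort <- function() {
  if (is.null(.acceptanceCache$cohort)) {
    spec <- reducedPhantomSpec(snr = 20)
    scheme <- makeScheme(c(0, 300, 350, 650, 950, 1000, 1350, 1650, 1700,
                           2000, 2700, 3000), 99,
                         seed = alpsdti:::deriveSeed(42, "scheme"))
    atlas <- syntheticHippocampusAtlas(spec)
    coh <- generateCohort(studyPresets(), studySizes(), spec, scheme,
                          seed = 42, keepImaging = FALSE,
                          analyze = function(ph)
                            analyzeSubject(ph$dwi, spec$rois, atlas))
    .acceptanceCache$cohort <- coh$covariates
  }
  .acceptanceCache$cohort
}
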