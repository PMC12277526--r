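# Shell selection, weighted-linear-least-squares tensor fitting and derived
# scalar maps.

#' Restrict a dataset to low-b shells
#'
#' Retains b = 0 measurements and every measurement with b below (strictly,
#' or up to when \code{inclusive}) the cutoff. The default strict cutoff
#' follows the convention of extracting "b values below 1000"; set
#' \code{inclusive = TRUE} to keep the cutoff shell itself.
#'
#' @param dataset a [DWIDataset-class].
#' @param bMax shell cutoff (s/mm^2); \code{Inf} is the identity.
#' @param inclusive keep measurements with b == bMax as well.
#' @return a [DWIDataset-class] with scheme and signal kept aligned.
#' @export
selectShells <- function(dataset, bMax = 1000, inclusive = FALSE) {
  stopifnot(is(dataset, "DWIDataset"))
  b <- dataset@scheme@bvals
  keep <- b == 0 | (if (inclusive) b <= bMax else b < bMax)
  if (!any(b[keep] == 0))
    stop("shell selection left no b = 0 measurement")
  dirs <- unique(round(dataset@scheme@bvecs[keep & b > 0, , drop = FALSE], 9))
  if (nrow(dirs) < 6)
    stop("shell selection left fewer than 6 gradient directions; ",
         "the tensor would be under-determined")
  new("DWIDataset",
      signal = dataset@signal[, keep, drop = FALSE],
      mask = dataset@mask,
      scheme = new("AcquisitionScheme", bvals = b[keep],
                   bvecs = dataset@scheme@bvecs[keep, , drop = FALSE]),
      voxelSize = dataset@voxelSize)
}

# Design matrix of the log-linear tensor model:
# log S = log s0 - b (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
#                     + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
tensorDesign <- function(bvals, bvecs) {
  gx <- bvecs[, 1]; gy <- bvecs[, 2]; gz <- bvecs[, 3]
  cbind(1, -bvals * gx^2, -bvals * gy^2, -bvals * gz^2,
        -2 * bvals * gx * gy, -2 * bvals * gx * gz, -2 * bvals * gy * gz)
}

#' Fit per-voxel diffusion tensors
#'
#' Weighted linear least squares on log-signals: an ordinary least-squares
#' pass provides predicted signals, whose squares serve as weights for one
#' refinement iteration (the standard WLLS compromise between the speed of
#' log-linear fitting and the accuracy of nonlinear estimators). Multiple
#' b = 0 volumes are averaged into one before fitting. Voxels containing
#' non-positive signals are flagged and excluded; on noise-free data the fit
#' is exact.
#'
#' @param dataset a [DWIDataset-class] (typically after [selectShells()]).
#' @return a [TensorField-class].
#' @export
fitTensor <- function(dataset) {
  stopifnot(is(dataset, "DWIDataset"))
  b <- dataset@scheme@bvals
  g <- dataset@scheme@bvecs
  if (!any(b == 0)) stop("dataset lacks a b = 0 measurement")
  dirs <- unique(round(g[b > 0, , drop = FALSE], 9))
  if (nrow(dirs) < 6)
    stop("fewer than 6 distinct non-zero-b directions: design under-determined")

  # average b0 volumes into one
  b0 <- which(b == 0)
  dw <- which(b > 0)
  sig <- cbind(rowMeans(dataset@signal[, b0, drop = FALSE]),
               dataset@signal[, dw, drop = FALSE])
  X <- tensorDesign(c(0, b[dw]), rbind(c(0, 0, 0), g[dw, , drop = FALSE]))
  if (qr(X)$rank < 7) stop("gradient design is rank-deficient")

  nvox <- prod(dim(dataset@mask))
  maskIdx <- which(as.vector(dataset@mask))
  bad <- rowSums(sig <= 0) > 0          # voxels unusable in the log domain
  ok <- which(!bad)
  D <- matrix(0, nvox, 6,
              dimnames = list(NULL, c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")))
  flags <- rep(FALSE, nvox)
  flags[maskIdx[bad]] <- TRUE
  resid <- numeric(nvox)
  if (length(ok)) {
    Y <- t(log(sig[ok, , drop = FALSE]))          # n_meas x n_ok
    K <- solve(crossprod(X), t(X))                # OLS projector
    beta <- K %*% Y                               # 7 x n_ok
    # one WLLS refinement with weights = squared predicted signals
    W <- exp(2 * (X %*% beta))                    # n_meas x n_ok
    pairIdx <- which(upper.tri(matrix(0, 7, 7), diag = TRUE), arr.ind = TRUE)
    P <- X[, pairIdx[, 1]] * X[, pairIdx[, 2]]    # n_meas x 28
    A <- crossprod(P, W)                          # 28 x n_ok
    Bt <- crossprod(X, W * Y)                     # 7 x n_ok
    M <- matrix(0, 7, 7)
    for (v in seq_along(ok)) {
      M[cbind(pairIdx[, 1], pairIdx[, 2])] <- A[, v]
      M[cbind(pairIdx[, 2], pairIdx[, 1])] <- A[, v]
      beta[, v] <- solve(M, Bt[, v])
    }
    res <- Y - X %*% beta
    resid[maskIdx[ok]] <- sqrt(colSums(res^2))
    D[maskIdx[ok], ] <- t(beta[2:7, , drop = FALSE])
  }
  new("TensorField", D = D, mask = dataset@mask, flags = flags,
      residualNorm = resid, voxelSize = dataset@voxelSize)
}

#' Derive scalar diffusivity maps from a tensor field
#'
#' Per voxel: symmetric eigendecomposition with eigenvalues sorted
#' descending; FA = sqrt(3/2) * ||lambda - mean||/||lambda||; MD is the
#' eigenvalue mean (identically trace/3); AD the largest eigenvalue; RD the
#' mean of the two smaller ones. Negative eigenvalues are clamped to zero
#' before map computation and the voxel flagged; an all-zero tensor gets
#' FA = 0 and a flag.
#'
#' @param field a [TensorField-class].
#' @return a [DiffusivityMaps-class].
#' @export
eigenMaps <- function(field) {
  stopifnot(is(field, "TensorField"))
  dims <- dim(field@mask)
  nvox <- prod(dims)
  idx <- which(as.vector(field@mask) & !field@flags)
  ev <- matrix(0, nvox, 3)
  flags <- field@flags
  if (length(idx)) {
    Dm <- field@D[idx, , drop = FALSE]
    vals <- matrix(0, length(idx), 3)
    M <- matrix(0, 3, 3)
    for (v in seq_along(idx)) {
      M[1, 1] <- Dm[v, 1]; M[2, 2] <- Dm[v, 2]; M[3, 3] <- Dm[v, 3]
      M[1, 2] <- M[2, 1] <- Dm[v, 4]
      M[1, 3] <- M[3, 1] <- Dm[v, 5]
      M[2, 3] <- M[3, 2] <- Dm[v, 6]
      vals[v, ] <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    }
    neg <- vals < 0
    if (any(neg)) {
      flags[idx[rowSums(neg) > 0]] <- TRUE
      vals[neg] <- 0
    }
    ev[idx, ] <- vals
  }
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  lb <- (l1 + l2 + l3) / 3
  den <- sqrt(l1^2 + l2^2 + l3^2)
  zero <- den == 0
  flags[as.vector(field@mask) & !field@flags & zero] <- TRUE   # degenerate voxels
  fa <- ifelse(zero, 0,
               sqrt(1.5) * sqrt((l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2) /
                 ifelse(zero, 1, den))
  arr <- function(x) array(x, dims)
  new("DiffusivityMaps",
      dxx = arr(field@D[, 1]), dyy = arr(field@D[, 2]), dzz = arr(field@D[, 3]),
      fa = arr(fa), md = arr(lb), ad = arr(l1), rd = arr((l2 + l3) / 2),
      evals = ev, flags = flags, mask = field@mask, voxelSize = field@voxelSize)
}
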