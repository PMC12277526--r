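# Acquisition-scheme construction: deterministic quasi-uniform direction sets.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that library code never
#' perturbs user-level random streams.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.finite(seed)) stop("seed must be a finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic, well-spread 32-bit seed derived from a base seed and labels.
deriveSeed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) else as.numeric(x)
  })))
  h <- 0
  for (p in parts) h <- (h * 1103515245 + p * 7919 + 12345) %% 2147483647
  as.integer(h)
}

# Spherical Fibonacci lattice: n quasi-uniform points on S^2.
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Uniform random rotation matrix (quaternion method).
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a multi-shell acquisition scheme
#'
#' Directions are a spherical Fibonacci lattice (quasi-uniform) rotated by a
#' seed-determined random rotation, shared across shells; each zero entry in
#' `shells` contributes one b = 0 measurement.
#'
#' @param shells numeric vector of b-values (s/mm^2), non-negative; zeros give
#'   b0 measurements.
#' @param nDirections number of gradient directions per non-zero shell (>= 6,
#'   or the tensor is under-determined).
#' @param seed integer controlling the lattice rotation; the same seed always
#'   yields the same scheme.
#' @return an [AcquisitionScheme-class] object.
#' @examples
#' makeScheme(c(0, 1000), nDirections = 6)
#' @export
makeScheme <- function(shells, nDirections = 99L, seed = 0L) {
  if (!length(shells) || any(shells < 0))
    stop("shells must be a non-empty vector of non-negative b-values")
  if (nDirections < 6)
    stop("nDirections must be >= 6: fewer directions under-determine the tensor")
  dirs <- fibonacciSphere(as.integer(nDirections))
  rot <- withSeed(seed, randomRotation())
  dirs <- dirs %*% t(rot)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  bvals <- numeric(0)
  bvecs <- matrix(numeric(0), 0, 3)
  for (b in shells) {
    if (b == 0) {
      bvals <- c(bvals, 0)
      bvecs <- rbind(bvecs, c(0, 0, 0))
    } else {
      bvals <- c(bvals, rep(b, nrow(dirs)))
      bvecs <- rbind(bvecs, dirs)
    }
  }
  new("AcquisitionScheme", bvals = bvals, bvecs = bvecs)
}

#' The acquisition scheme of the emulated protocol
#'
#' Twelve b-values (0, 300, 350, 650, 950, 1000, 1350, 1650, 1700, 2000, 2700,
#' 3000 s/mm^2) with 99 gradient directions per non-zero shell.
#'
#' @param nDirections directions per shell (default 99).
#' @param seed lattice-rotation seed.
#' @export
paperScheme <- function(nDirections = 99L, seed = 0L) {
  makeScheme(c(0, 300, 350, 650, 950, 1000, 1350, 1650, 1700, 2000, 2700, 3000),
             nDirections = nDirections, seed = seed)
}
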