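#' @useDynLib contourprop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd t.test ks.test optim dnorm
#' @importFrom utils write.csv head packageVersion
#' @importFrom tools md5sum
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never disturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic child seed
#'
#' Hierarchical seed derivation (e.g. cohort seed to patient seed to fraction
#' seed) via a multiplicative congruential mix; results stay strictly below
#' 2^31 - 1 so they are always valid R integer seeds.
#'
#' @param seed parent seed.
#' @param ... integer indices of the child stream.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 1000003 + 12345) %% 2147483647
  as.integer(s)
}

# Contract a 3D coefficient array with one matrix per axis:
# out[i,j,k] = sum_{a,b,c} Bx[i,a] By[j,b] Bz[k,c] coef[a,b,c].
tensor3_contract <- function(coef, Bx, By, Bz) {
  d <- dim(coef)
  t1 <- Bx %*% matrix(coef, nrow = d[1])            # (nx, d2*d3)
  t1 <- array(t1, c(nrow(Bx), d[2], d[3]))
  t2 <- By %*% matrix(aperm(t1, c(2, 1, 3)), nrow = d[2])
  t2 <- array(t2, c(nrow(By), nrow(Bx), d[3]))
  t3 <- Bz %*% matrix(aperm(t2, c(3, 2, 1)), nrow = d[3])
  aperm(array(t3, c(nrow(Bz), nrow(Bx), nrow(By))), c(2, 3, 1))
}

# Cubic B-spline kernel (support |t| < 2, partition of unity on a uniform grid).
bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Basis matrix mapping n_ctrl control coefficients to n_vox dense samples.
# Control points are spaced so the outermost pair sits one knot outside the
# volume; rows sum to one, hence |dense| <= max |coefficient|.
bspline_basis_matrix <- function(n_vox, n_ctrl) {
  if (n_ctrl < 4) stop("need at least 4 control points per axis")
  h <- (n_vox - 1) / (n_ctrl - 3)
  x <- 0:(n_vox - 1)
  cgrid <- ((1:n_ctrl) - 2) * h
  outer(x, cgrid, function(xx, cc) bspline3((xx - cc) / h))
}

# Truncated, renormalized Gaussian smoothing matrix along one axis
# (sigma in voxels; sigma 0 -> identity).
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  B <- outer(0:(n - 1), 0:(n - 1), function(i, j) {
    d <- i - j
    ifelse(abs(d) <= ceiling(3 * sigma), exp(-d^2 / (2 * sigma^2)), 0)
  })
  B / rowSums(B)
}

gauss_smooth3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  tensor3_contract(vol, gauss_matrix(d[1], sigma), gauss_matrix(d[2], sigma),
                   gauss_matrix(d[3], sigma))
}

# Zero-mean / unit-sd intensity normalization used before network input.
normalize_volume <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

# Smooth random scalar field (cubic B-spline interpolated uniform control
# offsets), used for background texture and smooth perturbations.
smooth_noise3 <- function(d, n_ctrl, amplitude, seed) {
  nc <- pmax(4L, rep(as.integer(n_ctrl), length.out = 3))
  B <- lapply(1:3, function(a) bspline_basis_matrix(d[a], nc[a]))
  coefs <- with_seed(seed, array(runif(prod(nc), -amplitude, amplitude), nc))
  tensor3_contract(coefs, B[[1]], B[[2]], B[[3]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_same_grid <- function(da, db, what = "inputs") {
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
}
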