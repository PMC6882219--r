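# small shared helpers

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 1-D Gaussian convolution matrix (zero-padded edges), kernel normalized
conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  k <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-k:k, sd = sigma)
  kern <- kern / sum(kern)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - k):(j + k)
    ok <- idx >= 1 & idx <= n
    m[idx[ok], j] <- kern[ok]
  }
  t(m)
}

# separable 3-D Gaussian smoothing of an array, sigma per axis in voxels
gauss_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    m <- conv_matrix(d[ax], sigma_vox[ax])
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    a <- array(m %*% matrix(a, d[ax]), d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

# rotation matrix about a coordinate axis (1=x, 2=y, 3=z), degrees
rot_axis <- function(axis, deg) {
  th <- deg * pi / 180
  r <- diag(3)
  ax <- setdiff(1:3, axis)
  r[ax[1], ax[1]] <- cos(th); r[ax[2], ax[2]] <- cos(th)
  r[ax[1], ax[2]] <- -sin(th); r[ax[2], ax[1]] <- sin(th)
  if (axis == 2) { # keep a proper right-handed rotation for the middle axis
    r[ax[1], ax[2]] <- sin(th); r[ax[2], ax[1]] <- -sin(th)
  }
  r
}

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# linear voxel index (1-based) from an n x 3 matrix of 0-based integer indices
voxel_linear_index <- function(shape, ijk) {
  ijk <- rbind3(ijk)
  1L + ijk[, 1] + shape[1] * (ijk[, 2] + shape[2] * ijk[, 3])
}

# count strict sign changes in a sequence; values within tol of zero (and
# NAs) are treated as zero and skipped, so centroid noise does not register
count_sign_changes <- function(x, tol = 0) {
  s <- sign(x)
  s[!is.na(x) & abs(x) <= tol] <- 0
  s <- s[!is.na(s) & s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}
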