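# Lazily built shared fixtures; generation is deterministic, so caching a
# single instance per case keeps the suite fast without coupling tests.
.fixtures <- new.env(parent = emptyenv())

fix_model <- function(kind = "normal", seed = 1L) {
  key <- paste(kind, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_heart(synthetic_heart_spec(kind, seed = seed))
  .fixtures[[key]]
}

fix_raster <- function(kind = "normal", spacing = c(0.4, 0.4, 0.4)) {
  key <- paste("ras", kind, paste(spacing, collapse = "_"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- rasterize(fix_model(kind), spacing = spacing, margin = 2)
  .fixtures[[key]]
}

random_unit_dirs <- function(n) {
  d <- matrix(stats::rnorm(n * 3), n, 3)
  d / sqrt(rowSums(d^2))
}

random_rigid_pose <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  pose(R, stats::runif(3, -20, 20))
}

expect_same_crossings <- function(fast, brute, tol = 1e-9) {
  expect_equal(nrow(fast), nrow(brute))
  if (nrow(brute)) {
    expect_lt(max(abs(fast$distance - brute$distance)), tol)
    expect_identical(fast$structure, brute$structure)
    expect_identical(fast$entering, brute$entering)
  }
}

# pixel data only, attribute-free
px <- function(img) {
  x <- unclass(img)
  attributes(x) <- list(dim = dim(x))
  x
}
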