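test_that("sinuosity is the perimeter-to-width ratio with a floor of 1", {
  expect_equal(compute_sinuosity(12, 5)$sinuosity, 2.4)
  # fully webbed limit: outline equals the width
  expect_equal(compute_sinuosity(7, 7)$sinuosity, 1)
  expect_equal(
    compute_sinuosity(c(12, 7), c(5, 7))$sinuosity,
    c(2.4, 1)
  )
  expect_error(compute_sinuosity(-1, 2), "positive")
  expect_error(compute_sinuosity(3, 0), "positive")
  expect_error(compute_sinuosity(4, 5), "below 1")
})

test_that("centroid size matches its closed form and is homogeneous", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  config <- rbind(sq, matrix(0.5, 5L, 2L)) # 5 extra landmarks at the centroid
  expect_equal(centroid_size(config), sqrt(2))
  set.seed(11)
  for (i in 1:5) {
    m <- rand_config()
    expect_equal(centroid_size(3 * m), 3 * centroid_size(m))
    # brute-force double loop over landmarks
    cent <- colMeans(m)
    brute <- sqrt(sum(apply(m, 1L, function(r) sum((r - cent)^2))))
    expect_equal(centroid_size(m), brute, tolerance = 1e-12)
  }
  expect_error(centroid_size(matrix(1, 9L, 2L)), "zero-size")
})

test_that("GPA aligns exact copies perfectly", {
  set.seed(21)
  base <- rand_config()
  arr <- array(0, c(9L, 2L, 6L))
  for (i in 1:6) arr[, , i] <- rand_similarity(base)
  g <- gpa(arr)
  expect_true(g$converged)
  d <- dist(g$tangent_coords)
  expect_lt(max(d), 1e-10)
  expect_lt(procrustes_distance(g$consensus, base), 1e-10)
})

test_that("GPA pairwise solution matches the two-form closed form", {
  set.seed(22)
  for (i in 1:5) {
    a <- rand_config()
    b <- rand_config()
    g <- gpa(array(c(a, b), c(9L, 2L, 2L)))
    d_gpa <- sqrt(sum((g$aligned[, , 1L] - g$aligned[, , 2L])^2))
    expect_equal(d_gpa, opa_distance_oracle(a, b), tolerance = 1e-6)
  }
})

test_that("pairwise distances agree with vegan's symmetric Procrustes", {
  library(vegan)
  set.seed(28)
  for (i in 1:5) {
    a <- rand_config()
    th <- runif(1, 0, 2 * pi)
    r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    b <- a %*% r + matrix(rnorm(18, sd = 0.05), 9L)
    d <- procrustes_distance(a, b) # partial: unit sizes, rotation only
    # vegan also rescales optimally (full-Procrustes distance); with
    # s = cos(rho) the two are related by full^2 = 1 - (1 - partial^2/2)^2
    v <- vegan::procrustes(a, b, symmetric = TRUE)
    expect_equal(v$ss, 1 - (1 - d^2 / 2)^2, tolerance = 1e-10)
  }
})

test_that("GPA output is invariant to similarity transforms of the input", {
  set.seed(23)
  arr <- array(rnorm(9 * 2 * 5), c(9L, 2L, 5L))
  g1 <- gpa(arr)
  arr2 <- arr
  for (i in 1:5) arr2[, , i] <- rand_similarity(arr[, , i])
  g2 <- gpa(arr2)
  expect_lt(max(abs(g1$tangent_coords - g2$tangent_coords)), 1e-8)
  expect_lt(max(abs(g1$consensus - g2$consensus)), 1e-8)
})

test_that("GPA bookkeeping: centring, sizes, consensus, convergence flag", {
  set.seed(24)
  arr <- array(rnorm(9 * 2 * 7), c(9L, 2L, 7L))
  g <- gpa(arr)
  # aligned configurations are centred at the origin with unit size
  expect_lt(max(abs(apply(g$aligned, 3L, colMeans))), 1e-12)
  expect_equal(
    unname(apply(g$aligned, 3L, function(m) sqrt(sum(m^2)))),
    rep(1, 7),
    tolerance = 1e-12
  )
  # raw centroid sizes are retained
  expect_equal(unname(g$centroid_sizes), apply(arr, 3L, centroid_size))
  # consensus of the aligned configurations equals the consensus field
  expect_lt(
    max(abs(center_scale_oracle(apply(g$aligned, c(1, 2), mean)) - g$consensus)),
    1e-7
  )
  # an exhausted iteration budget flags, it does not throw
  g_stuck <- gpa(arr, max_iter = 1L)
  expect_false(g_stuck$converged)
  expect_error(
    gpa(list(rand_config(9L), rand_config(8L))),
    "mismatched landmark"
  )
})

test_that("GPA alignment is optimal against random alternative rotations", {
  set.seed(25)
  arr <- array(rnorm(9 * 2 * 5), c(9L, 2L, 5L))
  g <- gpa(arr)
  cons_ss <- function(x) {
    cons <- apply(x, c(1, 2), mean)
    sum(apply(x, 3L, function(m) sum((m - cons)^2)))
  }
  ours <- cons_ss(g$aligned)
  for (b in 1:1000) {
    x <- g$aligned
    for (i in 1:5) {
      th <- rnorm(1, sd = 0.2)
      r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      x[, , i] <- x[, , i] %*% r
    }
    expect_gte(cons_ss(x), ours - 1e-12)
  }
})

test_that("tangent distances track Procrustes distances to first order", {
  set.seed(26)
  base <- center_scale_oracle(rand_config())
  arr <- array(0, c(9L, 2L, 8L))
  for (i in 1:8) arr[, , i] <- base + matrix(rnorm(18, sd = 0.008), 9L)
  g <- gpa(arr)
  td <- as.matrix(dist(g$tangent_coords))
  for (i in 1:7) {
    for (j in (i + 1):8) {
      pd <- procrustes_distance(arr[, , i], arr[, , j])
      expect_lt(abs(td[i, j] - pd) / pd, 0.01)
    }
  }
})

test_that("thin-plate splines interpolate, and bending vanishes iff affine", {
  set.seed(27)
  ref <- rand_config()
  # identity deformation
  grid_id <- tps_grid(ref, ref, exaggeration = 3)
  expect_equal(grid_id$warped, grid_id$grid, tolerance = 1e-9)
  expect_equal(grid_id$bending_energy, 0, tolerance = 1e-12)
  # affine target: zero bending energy, straight grid lines
  aff <- ref %*% matrix(c(1.1, 0.2, -0.3, 0.8), 2L) + 2
  w_aff <- tps_warp(ref, aff)
  expect_lt(w_aff$bending_energy, 1e-10)
  g_aff <- tps_grid(ref, aff)
  row1 <- g_aff$warped[seq_len(g_aff$nx), ]
  fit <- lm(row1[, 2L] ~ row1[, 1L])
  expect_lt(max(abs(residuals(fit))), 1e-8)
  # interpolation property with exaggeration
  tgt <- rand_config()
  for (ex in c(1, 2)) {
    w <- tps_warp(ref, tgt, exaggeration = ex)
    expect_equal(
      w$warp(ref),
      ref + ex * (tgt - ref),
      tolerance = 1e-9, ignore_attr = TRUE
    )
    expect_gte(w$bending_energy, 0)
  }
  # collinear reference is a stated failure mode
  col_ref <- cbind(1:9, 2 * (1:9) + 1)
  expect_error(tps_warp(col_ref, rand_config()), "collinear")
})
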