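make_table <- function(species, size, sinuosity) {
  data.frame(
    specimen_id = sprintf("s%03d", seq_along(size)),
    species_id = species,
    foot_length = size,
    foot_width = 0.5 * size,
    perimeter = sinuosity * 0.5 * size,
    sinuosity = sinuosity,
    foot_area = 1,
    body_weight = 1
  )
}

test_that("species regressions match the normal-equations oracle", {
  set.seed(31)
  species <- rep(c("a", "b", "c"), each = 12L)
  size <- runif(36, 4, 20)
  sinu <- 3 - 0.02 * size + rnorm(36, sd = 0.2)
  reg <- fit_species_regressions(make_table(species, size, sinu))
  for (sp in c("a", "b", "c")) {
    idx <- species == sp
    o <- ols_oracle(size[idx], sinu[idx])
    r <- reg[reg$species_id == sp, ]
    expect_equal(r$beta1, unname(o$beta1), tolerance = 1e-9)
    expect_equal(r$se_beta, unname(o$se), tolerance = 1e-9)
    expect_equal(r$t_stat, unname(o$t), tolerance = 1e-9)
    expect_equal(r$p_value, unname(o$p), tolerance = 1e-9)
    expect_equal(r$t_stat, r$beta1 / r$se_beta, tolerance = 1e-9)
  }
})

test_that("noise-free allometry is recovered exactly, and tiny species drop", {
  size <- seq(4, 20, length.out = 10L)
  tab <- make_table(rep("a", 10L), size, 3.2 - 0.035 * size)
  tab2 <- rbind(tab, make_table(rep("tiny", 2L), c(5, 6), c(2.5, 2.5)))
  expect_warning(reg <- fit_species_regressions(tab2), "tiny")
  expect_equal(reg$beta1, -0.035, tolerance = 1e-12)
  expect_equal(reg$p_value, 0)
})

test_that("trajectory coding follows the significance rule strictly", {
  reg <- data.frame(
    species_id = c("ambrosii_like", "sarrabusensis_like", "boundary", "flat"),
    beta1 = c(0.0001995, -0.05263, -0.02, 0),
    se_beta = NA,
    t_stat = NA,
    p_value = c(0.976, 0.0199, 0.05, NaN),
    n = 30L
  )
  coded <- code_trajectories(reg, alpha_level = 0.05)
  expect_equal(unname(coded["ambrosii_like"]), "isometric")
  expect_equal(unname(coded["sarrabusensis_like"]), "allometric")
  # p exactly at the threshold codes isometric (strict inequality)
  expect_equal(unname(coded["boundary"]), "isometric")
  # undefined p (zero-variance fit) codes isometric
  expect_equal(unname(coded["flat"]), "isometric")
})

test_that("sequential ANCOVA matches the nested-model oracle", {
  set.seed(32)
  species <- rep(c("a", "b", "c"), each = 15L)
  size <- runif(45, 4, 20)
  sinu <- 2.5 + 0.3 * (species == "b") - 0.02 * size +
    0.015 * size * (species == "c") + rnorm(45, sd = 0.15)
  tab <- make_table(species, size, sinu)
  a <- ancova_webbing(tab)
  o <- ancova_oracle(species, size, sinu)
  expect_equal(a$SS[1:3], unname(o$SS), tolerance = 1e-8)
  expect_equal(a$df[1:3], o$df)
  expect_equal(a$F[1:3], unname(o$F), tolerance = 1e-8)
  expect_equal(a$P[1:3], unname(o$P), tolerance = 1e-8)
  expect_equal(a$SS[4L], o$ss_resid, tolerance = 1e-8)
  # MS = SS/df and the sequential SS sum to the total SS
  expect_equal(a$MS, a$SS / a$df, tolerance = 1e-12)
  expect_equal(sum(a$SS), o$ss_total, tolerance = 1e-8)
})

test_that("a null design yields zero species and interaction SS", {
  size <- rep(seq(4, 20, length.out = 12L), 3L) # same sizes in every species
  species <- rep(c("a", "b", "c"), each = 12L)
  sinu <- 3 - 0.03 * size
  a <- ancova_webbing(make_table(species, size, sinu))
  expect_equal(a$SS[1L], 0, tolerance = 1e-12)
  expect_equal(a$SS[3L], 0, tolerance = 1e-12)
  expect_gt(a$SS[2L], 0)
})

test_that("a rank-deficient design is rejected with the offending term", {
  species <- rep(c("a", "b"), each = 5L)
  size <- rep(7, 10L) # no size variation: size collinear with intercept
  expect_error(
    ancova_webbing(make_table(species, size, rnorm(10, 2.5))),
    "collinear"
  )
})

test_that("MANCOVA Pillai traces match the cross-product-matrix oracle", {
  set.seed(33)
  species <- rep(c("a", "b", "c"), each = 14L)
  size <- runif(42, 4, 20)
  y <- cbind(
    0.1 * size + rnorm(42, sd = 0.3),
    -0.05 * size * (species == "b") + rnorm(42, sd = 0.3),
    rnorm(42, sd = 0.3)
  )
  m <- mancova_shape(y, species, size = size)
  o <- pillai_oracle(species, size, y)
  for (i in 1:3) {
    expect_equal(m$pillai_trace[i], o[[i]]$pillai, tolerance = 1e-8)
    expect_equal(m$approx_F[i], o[[i]]$F, tolerance = 1e-8)
    expect_equal(m$df_num[i], o[[i]]$df1)
    expect_equal(m$df_den[i], o[[i]]$df2)
  }
})

test_that("one-dimensional MANCOVA reproduces the ANCOVA exactly", {
  set.seed(34)
  species <- rep(c("a", "b", "c"), each = 12L)
  size <- runif(36, 4, 20)
  sinu <- 2.5 - 0.02 * size + 0.02 * size * (species == "c") +
    rnorm(36, sd = 0.2)
  a <- ancova_webbing(make_table(species, size, sinu))
  m <- mancova_shape(matrix(sinu, ncol = 1L), species, size = size)
  expect_equal(m$approx_F, a$F[1:3], tolerance = 1e-10)
  # Pillai for a single response is SS_effect / (SS_effect + SS_error)
  expect_equal(
    m$pillai_trace,
    a$SS[1:3] / (a$SS[1:3] + a$SS[4L]),
    tolerance = 1e-10
  )
})

test_that("MANCOVA detects species-specific shape allometry on the fixture", {
  hits <- 0L
  for (s in 1:10) {
    ds <- generate_dataset(hydromantes_params(), seed = 4000 + s)
    g <- gpa(ds$landmarks)
    m <- mancova_shape(g, ds$specimens$species_id)
    a <- ancova_webbing(ds$specimens)
    if (m$P[3L] < 0.05 && a$P[3L] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("regression scores are exact projections onto the allometry axis", {
  set.seed(35)
  v <- webbing_shape_vector()
  lcs <- runif(30, 1.4, 3)
  # noise-free single-axis construction: scores must be perfectly
  # collinear with log centroid size
  y <- outer(lcs, 0.05 * v)
  scores <- regression_scores(y, size = exp(lcs))
  expect_equal(abs(cor(scores, lcs)), 1, tolerance = 1e-12)
  # with noise, the scores equal an explicit least-squares projection
  yn <- y + matrix(rnorm(length(y), sd = 0.01), nrow(y))
  scores_n <- regression_scores(yn, size = exp(lcs))
  yc <- sweep(yn, 2L, colMeans(yn))
  xc <- lcs - mean(lcs)
  b <- qr.solve(cbind(xc), yc)[1L, ]
  expect_equal(
    unname(scores_n),
    unname(as.numeric(yc %*% b / sqrt(sum(b^2)))),
    tolerance = 1e-9
  )
  expect_error(
    regression_scores(matrix(0, 30, 4), size = exp(lcs)),
    "isometric"
  )
})

test_that("regression scores inherit the GPA invariance", {
  ds <- generate_dataset(hydromantes_params(), seed = 77)
  g1 <- gpa(ds$landmarks)
  arr <- landmark_mm(ds$landmarks)
  set.seed(36)
  for (i in seq_len(dim(arr)[3L])) arr[, , i] <- rand_similarity(arr[, , i])
  g2 <- gpa(arr)
  s1 <- regression_scores(g1)
  s2 <- regression_scores(g2, size = g1$centroid_sizes)
  expect_lt(max(abs(s1 - s2)), 1e-8)
})

test_that("trajectory endpoints equal the linear predictor at the extremes", {
  set.seed(37)
  species <- rep(c("a", "b"), each = 10L)
  size <- c(runif(10, 4, 12), runif(10, 6, 20))
  y <- cbind(2 + 0.1 * size + rnorm(20, sd = 0.1), rnorm(20))
  tm <- predict_trajectories(y, species, size)
  for (m in tm) {
    idx <- species == m$species_id
    # per-coordinate univariate regressions assembled into a vector
    for (j in 1:2) {
      cf <- coef(lm(y[idx, j] ~ size[idx]))
      expect_equal(m$predicted_juvenile[j], unname(cf[1L] + cf[2L] * min(size[idx])),
        tolerance = 1e-9
      )
      expect_equal(m$predicted_adult[j], unname(cf[1L] + cf[2L] * max(size[idx])),
        tolerance = 1e-9
      )
    }
  }
  # zero slope: juvenile and adult predictions coincide
  flat <- predict_trajectories(rep(2.5, 20), species, size)
  for (m in flat) expect_equal(m$predicted_juvenile, m$predicted_adult)
})

test_that("the power law is recovered exactly and transforms equivariantly", {
  set.seed(38)
  w <- exp(runif(30, log(0.5), log(10)))
  a <- 0.14 * w^0.75
  fit <- fit_power_law(a, w)
  expect_equal(fit$alpha, 0.75, tolerance = 1e-10)
  expect_equal(fit$b, 0.14, tolerance = 1e-10)
  # scale equivariance: areas times c -> b times c, alpha unchanged
  fit_c <- fit_power_law(100 * a, w)
  expect_equal(fit_c$alpha, fit$alpha, tolerance = 1e-10)
  expect_equal(fit_c$b, 100 * fit$b, tolerance = 1e-8)
  # degenerate design: one repeated point
  expect_error(fit_power_law(rep(2, 5), rep(3, 5)), "not identifiable")
  # missing and non-positive rows are excluded with a warning
  expect_warning(
    fit2 <- fit_power_law(c(a, -1, NA), c(w, 2, 2)),
    "excluding 2"
  )
  expect_equal(fit2$n, 30L)
  expect_equal(fit2$alpha, fit$alpha)
})

test_that("growth-parameter comparison ranks by distance, order-invariantly", {
  fit <- list(alpha = 0.75, b = 0.14)
  refs <- data.frame(
    label = c("Y", "X"),
    alpha = c(1.2, 0.75),
    b = c(0.5, 0.14)
  )
  cmp <- compare_growth_parameters(fit, refs)
  expect_equal(cmp$label[1L], "X")
  expect_equal(cmp$distance[1L], 0)
  cmp_rev <- compare_growth_parameters(fit, refs[2:1, ])
  expect_equal(cmp$label, cmp_rev$label)
  expect_equal(cmp$distance, cmp_rev$distance)
})
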