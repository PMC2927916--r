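# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written from first principles (normal
# equations, explicit cross-product matrices, brute-force enumeration) so
# it does not share code paths with the package implementation.

rand_config <- function(p = 9L) matrix(rnorm(2L * p), p, 2L)

# apply a random similarity transform (proper rotation, translation, scale)
rand_similarity <- function(m, max_shift = 10) {
  th <- runif(1, 0, 2 * pi)
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  u <- exp(runif(1, log(0.5), log(2)))
  sweep(m %*% r * u, 2L, runif(2L, -max_shift, max_shift), "+")
}

center_scale_oracle <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

# closed-form two-configuration (ordinary) Procrustes distance:
# centre, scale to unit centroid size, best proper rotation via SVD
opa_distance_oracle <- function(a, b) {
  cs <- function(m) {
    m <- sweep(m, 2L, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- cs(a)
  b <- cs(b)
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, d)) %*% t(s$v)
  sqrt(sum((a - b %*% rot)^2))
}

# OLS slope inference from the normal equations
ols_oracle <- function(x, y) {
  x_mat <- cbind(1, x)
  xtx_inv <- solve(crossprod(x_mat))
  beta <- xtx_inv %*% crossprod(x_mat, y)
  rss <- sum((y - x_mat %*% beta)^2)
  se <- sqrt(rss / (length(y) - 2) * xtx_inv[2L, 2L])
  t_stat <- beta[2L] / se
  list(
    beta1 = beta[2L], se = se, t = t_stat,
    p = 2 * pt(-abs(t_stat), length(y) - 2)
  )
}

# residual sum-of-squares (or cross-products matrix) of y on design X,
# via QR only — no lm(), no anova()
rss_oracle <- function(x_mat, y) {
  r <- qr.resid(qr(x_mat), y)
  if (is.matrix(y)) crossprod(r) else sum(r^2)
}

# sequential designs for the species/size/interaction decomposition
seq_designs <- function(species, size) {
  f <- factor(species)
  dummies <- sapply(levels(f)[-1L], function(l) as.numeric(f == l))
  x0 <- matrix(1, length(size), 1L)
  x1 <- cbind(x0, dummies)
  x2 <- cbind(x1, size)
  x3 <- cbind(x2, dummies * size)
  list(x0, x1, x2, x3)
}

# brute-force sequential (Type I) ANCOVA via nested-model RSS comparison
ancova_oracle <- function(species, size, y) {
  ds <- seq_designs(species, size)
  rss <- vapply(ds, rss_oracle, numeric(1), y = y)
  k <- nlevels(factor(species))
  df <- c(k - 1L, 1L, k - 1L)
  df_res <- length(y) - ncol(ds[[4L]])
  ss <- rss[1:3] - rss[2:4]
  ms_res <- rss[4L] / df_res
  f_stat <- (ss / df) / ms_res
  list(
    SS = ss, df = df, F = f_stat,
    P = pf(f_stat, df, df_res, lower.tail = FALSE),
    ss_resid = rss[4L], df_resid = df_res, ss_total = rss[1L]
  )
}

# sequential MANCOVA Pillai traces from explicit cross-product matrices
pillai_oracle <- function(species, size, y) {
  ds <- seq_designs(species, size)
  s_mats <- lapply(ds, rss_oracle, y = y)
  e <- s_mats[[4L]]
  k <- nlevels(factor(species))
  q <- c(k - 1L, 1L, k - 1L)
  v <- nrow(y) - ncol(ds[[4L]])
  p_dim <- ncol(y)
  out <- lapply(1:3, function(i) {
    h <- s_mats[[i]] - s_mats[[i + 1L]]
    tr <- sum(diag(h %*% solve(h + e)))
    s <- min(p_dim, q[i])
    m <- (abs(p_dim - q[i]) - 1) / 2
    nn <- (v - p_dim - 1) / 2
    f_stat <- ((2 * nn + s + 1) / (2 * m + s + 1)) * tr / (s - tr)
    list(
      pillai = tr, F = f_stat,
      df1 = s * (2 * m + s + 1), df2 = s * (2 * nn + s + 1)
    )
  })
  out
}

# Mk transition matrix, shared by the enumeration oracles
mk_p_oracle <- function(rate, t) {
  pc <- 0.5 * (1 - exp(-2 * rate * t))
  matrix(c(1 - pc, pc, pc, 1 - pc), 2L)
}

# brute-force likelihood: sum over every internal-state assignment
mk_enum_loglik <- function(tree, tip_states, rate) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  sidx <- ifelse(tip_states[tree$tip.label] == "allometric", 1L, 2L)
  total <- 0
  for (assig in 0:(2^nn - 1L)) {
    st <- c(sidx, as.integer(intToBits(assig))[seq_len(nn)] + 1L)
    pr <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * mk_p_oracle(rate, tree$edge.length[e])[
        st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]
      ]
    }
    total <- total + pr
  }
  log(total)
}

# brute-force marginal posterior of each internal node's state
mk_enum_marginals <- function(tree, tip_states, rate) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  sidx <- ifelse(tip_states[tree$tip.label] == "allometric", 1L, 2L)
  joint <- matrix(0, nn, 2L)
  for (assig in 0:(2^nn - 1L)) {
    internal <- as.integer(intToBits(assig))[seq_len(nn)] + 1L
    st <- c(sidx, internal)
    pr <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * mk_p_oracle(rate, tree$edge.length[e])[
        st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]
      ]
    }
    for (j in seq_len(nn)) joint[j, internal[j]] <- joint[j, internal[j]] + pr
  }
  joint / rowSums(joint)
}

# fixture tip regimes matching the synthetic Hydromantes tree
hydromantes_regimes <- function() {
  c(
    H_ambrosii = "isometric", H_flavus = "allometric", H_genei = "isometric",
    H_imperialis = "isometric", H_italicus = "isometric",
    H_sarrabusensis = "allometric", H_strinatii = "isometric",
    H_supramontis = "allometric"
  )
}

# a small, fast synthetic design for pipeline smoke tests
small_pipeline_params <- function() {
  convergent_ontogeny_params(
    n_species = 4L, noise_sd = 0.15,
    n_specimens = 12L
  )
}
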