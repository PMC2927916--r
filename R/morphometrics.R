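#' Foot-webbing sinuosity
#'
#' Sinuosity quantifies the degree of interdigital webbing as the ratio of
#' the distal foot-outline perimeter `p` (tip of digit one to tip of digit
#' five) to foot width `d`. A fully webbed foot whose outline runs straight
#' across the digit tips has sinuosity 1; sinuosity decreases as webbing
#' increases.
#'
#' @param perimeter_p numeric vector, outline perimeter in mm.
#' @param width_d numeric vector, foot width in mm (recycled against
#'   `perimeter_p`).
#' @return a data.frame with columns `perimeter_p`, `width_d` and
#'   `sinuosity` (`= perimeter_p / width_d`, always `>= 1`).
#' @examples
#' compute_sinuosity(12, 5)$sinuosity # 2.4
#' @export
compute_sinuosity <- function(perimeter_p, width_d) {
  if (!is.numeric(perimeter_p) || !is.numeric(width_d)) {
    stop_fm("perimeter and width must be numeric")
  }
  n <- max(length(perimeter_p), length(width_d))
  perimeter_p <- rep_len(perimeter_p, n)
  width_d <- rep_len(width_d, n)
  if (any(!is.finite(perimeter_p)) || any(!is.finite(width_d))) {
    stop_fm("invalid measurement: non-finite perimeter or width")
  }
  if (any(perimeter_p <= 0) || any(width_d <= 0)) {
    stop_fm("invalid measurement: perimeter and width must be positive")
  }
  if (any(perimeter_p < width_d)) {
    stop_fm(
      "invalid measurement: perimeter smaller than width ",
      "(sinuosity p/d cannot be below 1)"
    )
  }
  data.frame(
    perimeter_p = perimeter_p,
    width_d = width_d,
    sinuosity = perimeter_p / width_d
  )
}

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of the landmarks from their centroid. Scales
#' linearly under isotropic scaling of the configuration.
#'
#' @param coords a `p x 2` coordinate matrix, a `p x 2 x n` array, or a
#'   [landmark_set].
#' @return a positive number (or an `n`-vector for arrays/sets).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' centroid_size(sq) # sqrt(2)
#' @export
centroid_size <- function(coords) {
  if (inherits(coords, "landmark_set")) coords <- landmark_mm(coords)
  if (is.array(coords) && length(dim(coords)) == 3L) {
    return(apply(coords, 3L, centroid_size))
  }
  if (!is.matrix(coords) || ncol(coords) != 2L) {
    stop_fm("coords must be a p x 2 matrix")
  }
  if (!all(is.finite(coords))) stop_fm("coords contain non-finite values")
  cs <- sqrt(sum(sweep(coords, 2L, colMeans(coords))^2))
  if (cs == 0) {
    stop_fm("zero-size configuration: all landmarks are identical")
  }
  cs
}

# optimal rotation R (det +1) minimising ||from %*% R - to||_F
rotation_to <- function(from, to) {
  s <- svd(crossprod(from, to))
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

# centre a configuration and scale it to unit centroid size
center_scale <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

# proper rotation aligning the consensus with its principal axes, with a
# deterministic sign convention so the superimposition frame is canonical
canonical_rotation <- function(consensus) {
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  v <- e$vectors
  if (det(v) < 0) v[, 2L] <- -v[, 2L]
  cc <- consensus %*% v
  k <- which.max(abs(cc[, 1L]))
  if (cc[k, 1L] < 0) v <- -v
  v
}

#' Partial Procrustes distance between two configurations
#'
#' Centres both configurations, scales each to unit centroid size, rotates
#' the second onto the first by the closed-form two-configuration Procrustes
#' solution (rotation only, no reflection), and returns the root summed
#' squared difference.
#'
#' @param a,b `p x 2` coordinate matrices with the same landmark count.
#' @return a non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_fm("configurations have mismatched landmark counts")
  }
  a <- center_scale(a)
  b <- center_scale(b)
  sqrt(sum((a - b %*% rotation_to(b, a))^2))
}

#' Generalized Procrustes superimposition
#'
#' Iteratively centres every configuration, scales it to unit centroid size
#' and rotates it onto the running consensus (rotations only — feet are
#' handed anatomical objects, so reflections are never allowed), updating
#' the consensus until its root-mean-square change drops below `tol` or
#' `max_iter` is reached. The converged solution is put into a canonical
#' orientation (consensus principal axes, deterministic sign), which makes
#' the output invariant to arbitrary rotation, translation and scaling of
#' the raw inputs. Shape variables are the Kendall tangent-space
#' coordinates: the orthogonal projection of each aligned configuration
#' onto the tangent space at the consensus pole.
#'
#' @param coords a `p x 2 x n` array (`n >= 2`) or a [landmark_set]; all
#'   configurations must share the landmark count.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter maximum number of alignment sweeps. Non-convergence is
#'   flagged in the result, not raised as an error.
#' @return an object of class `gpa_fit`: a list with `tangent_coords`
#'   (`n x 2p` matrix), `aligned` (`p x 2 x n` array of unit-size aligned
#'   configurations), `centroid_sizes` (sizes of the raw configurations, in
#'   input units), `consensus` (`p x 2`, unit centroid size),
#'   `iterations_used` and `converged`.
#' @export
gpa <- function(coords, tol = 1e-8, max_iter = 100L) {
  ids <- NULL
  if (inherits(coords, "landmark_set")) {
    ids <- coords$specimen_id
    coords <- landmark_mm(coords)
  }
  if (is.list(coords) && !is.array(coords)) {
    dims <- vapply(coords, function(m) nrow(m), integer(1))
    if (length(unique(dims)) != 1L) {
      stop_fm("mismatched landmark counts across configurations")
    }
    coords <- array(
      unlist(coords),
      dim = c(dims[1L], 2L, length(coords)),
      dimnames = list(NULL, NULL, names(coords))
    )
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2L] != 2L) {
    stop_fm("coords must be a p x 2 x n array")
  }
  n <- dim(coords)[3L]
  p <- dim(coords)[1L]
  if (n < 2L) stop_fm("at least two configurations are required")
  if (!all(is.finite(coords))) stop_fm("coords contain non-finite values")
  ids <- ids %||% dimnames(coords)[[3L]] %||% sprintf("config_%03d", seq_len(n))

  sizes <- apply(coords, 3L, centroid_size)
  x <- coords
  for (i in seq_len(n)) x[, , i] <- center_scale(coords[, , i])

  consensus <- x[, , 1L]
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (i in seq_len(n)) x[, , i] <- x[, , i] %*% rotation_to(x[, , i], consensus)
    newcons <- center_scale(apply(x, c(1L, 2L), mean))
    delta <- sqrt(mean((newcons - consensus)^2))
    consensus <- newcons
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # final sweep against the converged consensus; the consensus field is
  # then the (centred, unit-size) mean of the aligned configurations
  for (i in seq_len(n)) x[, , i] <- x[, , i] %*% rotation_to(x[, , i], consensus)
  consensus <- center_scale(apply(x, c(1L, 2L), mean))
  v <- canonical_rotation(consensus)
  consensus <- consensus %*% v
  for (i in seq_len(n)) x[, , i] <- x[, , i] %*% v

  cvec <- vec_config(consensus) # unit norm: consensus is centred, unit size
  m <- t(apply(x, 3L, vec_config)) # n x 2p
  tangent <- m - (m %*% cvec) %*% t(cvec)
  rownames(tangent) <- ids
  dimnames(x)[[3L]] <- ids
  names(sizes) <- ids

  structure(
    list(
      tangent_coords = tangent,
      aligned = x,
      centroid_sizes = sizes,
      consensus = consensus,
      iterations_used = iterations,
      converged = converged,
      tol = tol
    ),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(
    "Generalized Procrustes superimposition\n",
    "  configurations: ", nrow(x$tangent_coords),
    "  landmarks: ", nrow(x$consensus), "\n",
    "  iterations: ", x$iterations_used,
    "  converged: ", x$converged, "\n",
    sep = ""
  )
  invisible(x)
}

# thin-plate spline kernel U(r) = r^2 log r^2, as a function of r^2
tps_kernel <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))

#' Thin-plate spline warp between two landmark configurations
#'
#' Standard two-dimensional thin-plate spline interpolation with radial
#' kernel `U(r) = r^2 log r^2`, decomposed into an affine part and a
#' bending (non-affine) part. The target displacements are multiplied by
#' `exaggeration` before the warp is solved, so the returned map carries
#' the reference landmarks exactly onto
#' `reference + exaggeration * (target - reference)`.
#'
#' @param reference,target `p x 2` coordinate matrices with the same
#'   landmark count; the reference must not be collinear.
#' @param exaggeration multiplier applied to the target displacements
#'   (deformation grids for subtle shape change are often drawn exaggerated).
#' @return a list with `warp` (a function mapping an `m x 2` matrix of
#'   points through the spline), `bending_energy` (non-negative; zero iff
#'   the map is affine), `weights`, `affine`, and the (exaggerated)
#'   `target` actually interpolated.
#' @export
tps_warp <- function(reference, target, exaggeration = 1) {
  if (!is.matrix(reference) || ncol(reference) != 2L) {
    stop_fm("reference must be a p x 2 matrix")
  }
  if (!identical(dim(reference), dim(target))) {
    stop_fm("reference and target have mismatched landmark counts")
  }
  if (!all(is.finite(reference)) || !all(is.finite(target))) {
    stop_fm("non-finite landmark coordinates")
  }
  p <- nrow(reference)
  if (qr(cbind(1, reference))$rank < 3L) {
    stop_fm(
      "singular bending-energy system: reference landmarks are collinear"
    )
  }
  tgt <- reference + exaggeration * (target - reference)
  k <- tps_kernel(as.matrix(dist(reference))^2)
  q <- cbind(1, reference)
  l <- rbind(cbind(k, q), cbind(t(q), matrix(0, 3L, 3L)))
  coefs <- tryCatch(
    solve(l, rbind(tgt, matrix(0, 3L, 2L))),
    error = function(e) {
      stop_fm("singular bending-energy system: ", conditionMessage(e))
    }
  )
  w <- coefs[seq_len(p), , drop = FALSE]
  affine <- coefs[p + 1:3, , drop = FALSE]
  be <- sum(diag(t(w) %*% k %*% w))
  warp <- function(pts) {
    pts <- rbind(pts)
    d2 <- outer(rowSums(pts^2), rowSums(reference^2), "+") -
      2 * tcrossprod(pts, reference)
    cbind(1, pts) %*% affine + tps_kernel(pmax(d2, 0)) %*% w
  }
  list(
    warp = warp,
    bending_energy = max(be, 0),
    weights = w,
    affine = affine,
    target = tgt
  )
}

#' Thin-plate spline deformation grid
#'
#' Builds a rectangular grid spanning the reference configuration (plus a
#' margin) and warps it through the thin-plate spline carrying the
#' reference onto the (optionally exaggerated) target. Used to visualise
#' ontogenetic shape change as a deformation of the consensus foot.
#'
#' @inheritParams tps_warp
#' @param grid_density number of grid points along the longer side.
#' @param margin fractional margin added around the reference bounding box.
#' @return an object of class `tps_grid` with the original and warped grid
#'   points, the grid dimensions, the warped landmarks and the bending
#'   energy. Has a `plot()` method.
#' @export
tps_grid <- function(reference, target, grid_density = 24L, exaggeration = 1,
                     margin = 0.1) {
  if (grid_density < 2L) stop_fm("grid_density must be at least 2")
  spline <- tps_warp(reference, target, exaggeration)
  rx <- range(reference[, 1L])
  ry <- range(reference[, 2L])
  span <- c(diff(rx), diff(ry))
  rx <- rx + margin * span[1L] * c(-1, 1)
  ry <- ry + margin * span[2L] * c(-1, 1)
  if (span[1L] >= span[2L]) {
    nx <- as.integer(grid_density)
    ny <- max(2L, as.integer(round(grid_density * diff(ry) / diff(rx))))
  } else {
    ny <- as.integer(grid_density)
    nx <- max(2L, as.integer(round(grid_density * diff(rx) / diff(ry))))
  }
  gx <- seq(rx[1L], rx[2L], length.out = nx)
  gy <- seq(ry[1L], ry[2L], length.out = ny)
  grid <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  structure(
    list(
      grid = grid,
      warped = spline$warp(grid),
      nx = nx,
      ny = ny,
      reference = reference,
      warped_landmarks = spline$warp(reference),
      bending_energy = spline$bending_energy,
      exaggeration = exaggeration
    ),
    class = "tps_grid"
  )
}

#' @export
plot.tps_grid <- function(x, show_landmarks = TRUE, ...) {
  w <- x$warped
  plot(w, type = "n", asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  idx <- matrix(seq_len(x$nx * x$ny), nrow = x$nx)
  for (j in seq_len(x$ny)) lines(w[idx[, j], , drop = FALSE], col = "grey40")
  for (i in seq_len(x$nx)) lines(w[idx[i, ], , drop = FALSE], col = "grey40")
  if (show_landmarks) {
    points(x$warped_landmarks, pch = 19, col = "black", cex = 0.9)
  }
  invisible(x)
}
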