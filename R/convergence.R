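#' Predicted juvenile and adult endpoint sets
#'
#' Collects, from a set of per-species trajectory models, the predicted
#' morphology of the smallest (juvenile) and largest (adult) observed
#' specimen of each species.
#'
#' @param models a [predict_trajectories()] result.
#' @return a list with matrices `juvenile` and `adult` (one row per
#'   species) and `response_kind`.
#' @export
endpoint_sets <- function(models) {
  if (inherits(models, "trajectory_model")) models <- list(models)
  if (length(models) < 2L) stop_fm("at least 2 species models are required")
  kinds <- unique(vapply(models, function(m) m$response_kind, character(1)))
  if (length(kinds) != 1L) {
    stop_fm(
      "mixed response kinds: ",
      paste(kinds, collapse = ", ")
    )
  }
  juv <- do.call(rbind, lapply(models, function(m) m$predicted_juvenile))
  adu <- do.call(rbind, lapply(models, function(m) m$predicted_adult))
  rownames(juv) <- rownames(adu) <-
    vapply(models, function(m) m$species_id, character(1))
  list(juvenile = juv, adult = adu, response_kind = kinds)
}

sum_pairwise_dist <- function(m) sum(dist(m))

#' Ontogenetic convergence statistic
#'
#' The summed pairwise Euclidean distance among the species' predicted
#' juvenile morphologies minus the same sum among their predicted adult
#' morphologies. A positive value means adults are more similar to one
#' another than juveniles are — ontogenetic convergence on a common adult
#' morphology.
#'
#' @param juveniles,adults matrices (or vectors) of predicted endpoint
#'   morphologies, one row per species, equal species counts.
#' @return a list with `statistic`, `sum_d_juv`, `sum_d_adult`.
#' @export
convergence_statistic <- function(juveniles, adults) {
  juveniles <- rbind(juveniles)
  adults <- rbind(adults)
  if (nrow(juveniles) != nrow(adults)) {
    stop_fm("juvenile and adult sets must have equal species counts")
  }
  if (nrow(juveniles) < 2L) stop_fm("at least 2 species are required")
  sj <- sum_pairwise_dist(juveniles)
  sa <- sum_pairwise_dist(adults)
  list(statistic = sj - sa, sum_d_juv = sj, sum_d_adult = sa)
}

#' Permutation test of ontogenetic convergence
#'
#' Tests whether interspecific variation in predicted morphology at the
#' adult end of species' ontogenetic trajectories is smaller than at the
#' juvenile end. The observed statistic is computed from per-species linear
#' regressions of the response on size (see [predict_trajectories()] and
#' [convergence_statistic()]). Each permutation randomises the
#' specimen-level predicted morphologies with respect to size: the pooled
#' fitted values (or, optionally, the raw responses) are shuffled against
#' the fixed (species, size) design, the per-species regressions are refit,
#' new juvenile and adult endpoint predictions are obtained and the
#' statistic recomputed. The significance level is the proportion of
#' permuted statistics larger than or equal to the observed one (ties count
#' towards the numerator; by default the observed value is not added to the
#' permutation set).
#'
#' @param response numeric vector (sinuosity) or `n x q` matrix (tangent
#'   coordinates).
#' @param species species labels, one per specimen.
#' @param size size covariate, one per specimen.
#' @param n_permutations number of permutations (at least 99; default
#'   9999).
#' @param seed RNG seed for the permutations.
#' @param shuffle what is permuted: `"raw"` (default — the observed
#'   specimen morphologies, which are exchangeable under the null so the
#'   test is exact) or `"fitted"` (the predicted morphologies along the
#'   trajectories; mirrors a literal randomisation of predicted values but
#'   compresses the permutation distribution, making the test
#'   anti-conservative under the null). The observed statistic is
#'   identical under both.
#' @param p_convention `"printed"` (`count(perm >= obs) / n_permutations`)
#'   or `"plus_one"` (`(count + 1) / (n_permutations + 1)`).
#' @param response_kind `"sinuosity"` or `"shape"`; inferred when missing.
#' @param keep_null keep the permutation distribution in the result.
#' @return an object of class `convergence_result`: `statistic`,
#'   `sum_d_juv`, `sum_d_adult`, `p_rand`, `n_permutations`, `seed`,
#'   `response_kind`, `endpoints` and (optionally) `null_statistics`.
#' @export
convergence_permutation_test <- function(response, species, size,
                                         n_permutations = 9999L,
                                         seed = NULL,
                                         shuffle = c("raw", "fitted"),
                                         p_convention = c("printed", "plus_one"),
                                         response_kind = NULL,
                                         keep_null = TRUE) {
  shuffle <- match.arg(shuffle)
  p_convention <- match.arg(p_convention)
  if (n_permutations < 99L) stop_fm("n_permutations must be at least 99")
  y <- if (is.matrix(response)) response else matrix(response, ncol = 1L)
  response_kind <- response_kind %||%
    if (ncol(y) > 1L) "shape" else "sinuosity"
  species <- as.character(species)
  n <- nrow(y)
  stopifnot(length(species) == n, length(size) == n)

  models <- predict_trajectories(y, species, size, response_kind)
  eps <- endpoint_sets(models)
  obs <- convergence_statistic(eps$juvenile, eps$adult)

  # endpoint predictions are linear in the responses: precompute, per
  # species, the 2 x n_s matrix mapping its responses to the fitted values
  # at its smallest and largest specimen, and stack into W (2S x n)
  sp_levels <- sort(unique(species))
  s_count <- length(sp_levels)
  w <- matrix(0, 2L * s_count, n)
  for (k in seq_len(s_count)) {
    idx <- which(species == sp_levels[k])
    x <- cbind(1, size[idx])
    a <- cbind(1, range(size[idx])) %*% solve(crossprod(x), t(x))
    w[k, idx] <- a[1L, ]
    w[s_count + k, idx] <- a[2L, ]
  }
  src <- y
  if (shuffle == "fitted") {
    src <- matrix(0, n, ncol(y))
    for (sp in sp_levels) {
      idx <- which(species == sp)
      x <- cbind(1, size[idx])
      src[idx, ] <- x %*% solve(crossprod(x), crossprod(x, y[idx, , drop = FALSE]))
    }
  }

  pair_i <- combn(s_count, 2L)
  stat_from_endpoints <- function(e) {
    juv <- e[seq_len(s_count), , drop = FALSE]
    adu <- e[s_count + seq_len(s_count), , drop = FALSE]
    dj <- sqrt(rowSums((juv[pair_i[1L, ], , drop = FALSE] -
      juv[pair_i[2L, ], , drop = FALSE])^2))
    da <- sqrt(rowSums((adu[pair_i[1L, ], , drop = FALSE] -
      adu[pair_i[2L, ], , drop = FALSE])^2))
    sum(dj) - sum(da)
  }

  null_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      stat_from_endpoints(w %*% src[sample.int(n), , drop = FALSE])
    }, numeric(1))
  })

  count_ge <- sum(null_stats >= obs$statistic)
  p_rand <- if (p_convention == "printed") {
    count_ge / n_permutations
  } else {
    (count_ge + 1) / (n_permutations + 1)
  }

  structure(
    list(
      statistic = obs$statistic,
      sum_d_juv = obs$sum_d_juv,
      sum_d_adult = obs$sum_d_adult,
      p_rand = p_rand,
      n_permutations = as.integer(n_permutations),
      seed = seed,
      response_kind = response_kind,
      shuffle = shuffle,
      p_convention = p_convention,
      endpoints = eps,
      null_statistics = if (keep_null) null_stats
    ),
    class = "convergence_result"
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(
    sprintf(
      paste0(
        "Ontogenetic convergence test (%s)\n",
        "  sum D_juv = %.4f, sum D_adult = %.4f\n",
        "  statistic (sum D_juv - sum D_adult) = %.4f\n",
        "  P_rand = %.4g  (%d permutations, %s morphologies shuffled)\n"
      ),
      x$response_kind, x$sum_d_juv, x$sum_d_adult, x$statistic,
      x$p_rand, x$n_permutations, x$shuffle
    )
  )
  invisible(x)
}
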