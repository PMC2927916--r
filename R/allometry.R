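#' Per-species regressions of sinuosity on size
#'
#' Ordinary least-squares regression of foot-webbing sinuosity on a size
#' measure, fitted for each species separately, with the two-sided t test
#' on the slope. The slope sign and significance are what
#' [code_trajectories()] uses to classify each species' growth as
#' allometric or isometric.
#'
#' @param table specimen data.frame with columns `species_id`, `sinuosity`
#'   and the chosen size column.
#' @param size_field size covariate: `"foot_length"` (default, matching the
#'   usual reporting of these regressions) or `"foot_width"`.
#' @return a data.frame with one row per species: `species_id`, `beta1`,
#'   `se_beta`, `t_stat`, `p_value`, `n`. Species with fewer than 3
#'   specimens are excluded with a warning.
#' @export
fit_species_regressions <- function(table,
                                    size_field = c("foot_length", "foot_width")) {
  size_field <- match.arg(size_field)
  check_specimen_cols(table, c("species_id", "sinuosity", size_field))
  split_tab <- split(table, table$species_id)
  small <- names(split_tab)[vapply(split_tab, nrow, integer(1)) < 3L]
  if (length(small)) {
    warn_fm(
      "excluding species with fewer than 3 specimens: ",
      paste(small, collapse = ", ")
    )
    split_tab <- split_tab[setdiff(names(split_tab), small)]
  }
  if (!length(split_tab)) stop_fm("no species with at least 3 specimens")
  out <- lapply(names(split_tab), function(sp) {
    d <- split_tab[[sp]]
    fit <- lm(d$sinuosity ~ d[[size_field]])
    cf <- suppressWarnings(summary(fit))$coefficients
    data.frame(
      species_id = sp,
      beta1 = cf[2L, 1L],
      se_beta = cf[2L, 2L],
      t_stat = cf[2L, 3L],
      p_value = cf[2L, 4L],
      n = nrow(d)
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Code growth trajectories as allometric or isometric
#'
#' A species is coded `"allometric"` when its sinuosity-on-size regression
#' slope is significant (`p_value < alpha_level`, strict inequality; a p
#' value exactly at the threshold, or unavailable, codes as isometric) and
#' `"isometric"` otherwise.
#'
#' @param results data.frame from [fit_species_regressions()].
#' @param alpha_level significance level in (0, 1).
#' @return a named character vector, species -> regime.
#' @export
code_trajectories <- function(results, alpha_level = 0.05) {
  stopifnot(
    is.numeric(alpha_level), length(alpha_level) == 1L,
    alpha_level > 0, alpha_level < 1
  )
  p <- results$p_value
  regime <- ifelse(!is.na(p) & p < alpha_level, "allometric", "isometric")
  setNames(regime, results$species_id)
}

check_specimen_cols <- function(table, cols) {
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop_fm(
      "specimen table lacks columns: ",
      paste(missing_cols, collapse = ", ")
    )
  }
}

size_label <- function(size_field) {
  c(foot_length = "Foot Length", foot_width = "Foot Width")[[size_field]]
}

#' ANCOVA of foot webbing on species and size
#'
#' Fits `sinuosity ~ species + size + species:size` and returns the
#' sequential (Type I, entry-order) analysis-of-variance table: sums of
#' squares, mean squares, degrees of freedom, F against the residual mean
#' square and p values, plus the residual row. A significant interaction
#' indicates species-specific ontogenetic trajectories.
#'
#' @inheritParams fit_species_regressions
#' @return a data.frame of class `ancova_table` with columns `term`, `SS`,
#'   `MS`, `df`, `F`, `P`.
#' @export
ancova_webbing <- function(table, size_field = c("foot_length", "foot_width")) {
  size_field <- match.arg(size_field)
  check_specimen_cols(table, c("species_id", "sinuosity", size_field))
  species <- factor(table$species_id)
  if (nlevels(species) < 2L) stop_fm("at least 2 species are required")
  if (min(table(species)) < 3L) {
    stop_fm("every species needs at least 3 specimens")
  }
  d <- data.frame(
    sinuosity = table$sinuosity,
    species = species,
    size = table[[size_field]]
  )
  fit <- lm(sinuosity ~ species + size + species:size, data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    bad_terms <- unique(ifelse(grepl(":", bad), "species:size",
      ifelse(grepl("^species", bad), "species", "size")
    ))
    stop_fm(
      "rank-deficient design; collinear term(s): ",
      paste(bad_terms, collapse = ", ")
    )
  }
  a <- anova(fit)
  lab <- size_label(size_field)
  out <- data.frame(
    term = c("Species", lab, paste("Species ×", lab), "Residuals"),
    SS = a$`Sum Sq`,
    MS = a$`Mean Sq`,
    df = a$Df,
    F = a$`F value`,
    P = a$`Pr(>F)`
  )
  class(out) <- c("ancova_table", "data.frame")
  out
}

#' MANCOVA of foot shape on species and size
#'
#' Multivariate analysis of covariance of the Procrustes tangent
#' coordinates on species, a size covariate and their interaction, using
#' Pillai's trace with its standard approximate-F transform and sequential
#' (entry-order) hypothesis matrices. The tangent coordinates are first
#' projected onto their non-degenerate principal subspace (Procrustes
#' superimposition leaves four dimensions without variance); Pillai's trace
#' is invariant under this full-rank reduction. If the response dimension
#' reaches the residual degrees of freedom it is truncated further, with a
#' warning.
#'
#' @param shapes a [gpa()] fit, or an `n x q` matrix of shape variables.
#' @param species factor or character vector of species labels, one per
#'   specimen row.
#' @param size size covariate; defaults to the centroid sizes stored in
#'   `shapes`.
#' @param size_scale `"raw"` (default) or `"log"`.
#' @return a data.frame of class `mancova_table` with columns `term`,
#'   `pillai_trace`, `approx_F`, `df_num`, `df_den`, `P`.
#' @export
mancova_shape <- function(shapes, species, size = NULL,
                          size_scale = c("raw", "log")) {
  size_scale <- match.arg(size_scale)
  if (inherits(shapes, "gpa_fit")) {
    y <- shapes$tangent_coords
    size <- size %||% shapes$centroid_sizes
  } else {
    y <- as.matrix(shapes)
  }
  if (is.null(size)) stop_fm("a size covariate is required")
  species <- factor(species)
  n <- nrow(y)
  stopifnot(length(species) == n, length(size) == n)
  if (nlevels(species) < 2L) stop_fm("at least 2 species are required")
  x <- if (size_scale == "log") log(size) else as.numeric(size)

  # project onto the non-degenerate principal subspace
  pr <- stats::prcomp(y, center = TRUE)
  keep <- pr$sdev^2 > max(pr$sdev^2) * 1e-10
  yk <- pr$x[, keep, drop = FALSE]
  df_resid <- n - 2L * nlevels(species)
  if (ncol(yk) >= df_resid) {
    warn_fm(
      "response dimension (", ncol(yk), ") reaches the residual df (",
      df_resid, "); truncating to the leading ", df_resid - 1L,
      " principal axes"
    )
    yk <- yk[, seq_len(df_resid - 1L), drop = FALSE]
  }
  if (n <= ncol(yk)) stop_fm("more response dimensions than specimens")

  d <- data.frame(species = species, size = x)
  lab <- if (size_scale == "log") "log(Centroid Size)" else "Centroid Size"
  terms_lab <- c("Species", lab, paste("Species ×", lab))
  if (ncol(yk) > 1L) {
    fit <- manova(yk ~ species + size + species:size, data = d)
    s <- summary(fit, test = "Pillai")$stats
    out <- data.frame(
      term = terms_lab,
      pillai_trace = s[1:3, "Pillai"],
      approx_F = s[1:3, "approx F"],
      df_num = s[1:3, "num Df"],
      df_den = s[1:3, "den Df"],
      P = s[1:3, "Pr(>F)"],
      row.names = NULL
    )
  } else {
    # a single response collapses to the univariate sequential ANCOVA:
    # Pillai = SS_effect / (SS_effect + SS_error), approx F = ANCOVA F
    a <- anova(lm(yk ~ species + size + species:size, data = d))
    ss <- a$`Sum Sq`
    out <- data.frame(
      term = terms_lab,
      pillai_trace = ss[1:3] / (ss[1:3] + ss[4L]),
      approx_F = a$`F value`[1:3],
      df_num = a$Df[1:3],
      df_den = a$Df[4L],
      P = a$`Pr(>F)`[1:3],
      row.names = NULL
    )
  }
  attr(out, "response_rank") <- ncol(yk)
  attr(out, "df_residual") <- df_resid
  class(out) <- c("mancova_table", "data.frame")
  out
}

#' Shape regression scores
#'
#' Projects each specimen's tangent coordinates onto the normalised common
#' regression vector of shape on (log) size, pooled across species. The
#' result is one scalar per specimen — a one-dimensional summary of
#' multivariate allometry suitable for plotting against log centroid size.
#'
#' @param shapes a [gpa()] fit or an `n x q` shape matrix.
#' @param size size covariate; defaults to the centroid sizes stored in
#'   `shapes`.
#' @param size_scale `"log"` (default, the conventional choice for
#'   regression scores) or `"raw"`.
#' @return a named numeric vector of scores.
#' @export
regression_scores <- function(shapes, size = NULL,
                              size_scale = c("log", "raw")) {
  size_scale <- match.arg(size_scale)
  if (inherits(shapes, "gpa_fit")) {
    y <- shapes$tangent_coords
    size <- size %||% shapes$centroid_sizes
  } else {
    y <- as.matrix(shapes)
  }
  if (is.null(size)) stop_fm("a size covariate is required")
  stopifnot(length(size) == nrow(y))
  x <- if (size_scale == "log") log(size) else as.numeric(size)
  yc <- scale(y, center = TRUE, scale = FALSE)
  xc <- x - mean(x)
  b <- as.numeric(crossprod(yc, xc)) / sum(xc^2)
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12) {
    stop_fm(
      "the pooled shape-on-size regression vector is zero; ",
      "the data appear isometric"
    )
  }
  scores <- as.numeric(yc %*% (b / nb))
  names(scores) <- rownames(y)
  scores
}

#' Species-specific predicted ontogenetic trajectories
#'
#' Fits a (possibly multivariate) linear regression of the response on size
#' for each species and stores the fitted response at the smallest and
#' largest observed specimen — the predicted juvenile and adult
#' morphologies used by the convergence test.
#'
#' @param response numeric vector (e.g. sinuosity) or `n x q` matrix (e.g.
#'   tangent coordinates).
#' @param species species labels, one per specimen.
#' @param size size covariate, one per specimen.
#' @param response_kind `"sinuosity"` or `"shape"`; inferred from the
#'   response dimension when missing.
#' @return a list of class `trajectory_models`; each element is a
#'   `trajectory_model` with `species_id`, `response_kind`, `intercept`,
#'   `slope`, `size_min`, `size_max`, `predicted_juvenile`,
#'   `predicted_adult` and `n`.
#' @export
predict_trajectories <- function(response, species, size,
                                 response_kind = NULL) {
  y <- if (is.matrix(response)) response else matrix(response, ncol = 1L)
  response_kind <- response_kind %||%
    if (ncol(y) > 1L) "shape" else "sinuosity"
  species <- as.character(species)
  stopifnot(length(species) == nrow(y), length(size) == nrow(y))
  counts <- table(species)
  if (min(counts) < 3L) {
    stop_fm(
      "every species needs at least 3 specimens; offending: ",
      paste(names(counts)[counts < 3L], collapse = ", ")
    )
  }
  models <- lapply(sort(unique(species)), function(sp) {
    idx <- species == sp
    xs <- size[idx]
    if (var(xs) == 0) stop_fm("species ", sp, " has no size variation")
    fit <- lm(y[idx, , drop = FALSE] ~ xs)
    cf <- coef(fit) # 2 x q
    if (!is.matrix(cf)) cf <- cbind(cf) # keep matrix form for q = 1
    pred <- function(s) as.numeric(cf[1L, ] + cf[2L, ] * s)
    structure(
      list(
        species_id = sp,
        response_kind = response_kind,
        intercept = as.numeric(cf[1L, ]),
        slope = as.numeric(cf[2L, ]),
        size_min = min(xs),
        size_max = max(xs),
        predicted_juvenile = pred(min(xs)),
        predicted_adult = pred(max(xs)),
        n = sum(idx)
      ),
      class = "trajectory_model"
    )
  })
  names(models) <- vapply(models, function(m) m$species_id, character(1))
  class(models) <- "trajectory_models"
  models
}

#' @export
print.trajectory_models <- function(x, ...) {
  cat(
    "Predicted ontogenetic trajectories (", x[[1L]]$response_kind, ") for ",
    length(x), " species\n",
    sep = ""
  )
  invisible(x)
}

#' Allometric power-law fit of foot area on body weight
#'
#' Fits `A = b * W^alpha` by ordinary least squares on the log-log scale:
#' `log A = log b + alpha log W`. Rows with missing or non-positive area or
#' weight are excluded with a warning.
#'
#' @param table specimen data.frame with `foot_area` and `body_weight`
#'   columns, or a numeric vector of areas.
#' @param weight numeric vector of body weights when `table` is a vector.
#' @return an object of class `power_law_fit`: list with `alpha`, `b`,
#'   `r_squared`, `n`.
#' @export
fit_power_law <- function(table, weight = NULL) {
  if (is.data.frame(table)) {
    check_specimen_cols(table, c("foot_area", "body_weight"))
    area <- table$foot_area
    weight <- table$body_weight
  } else {
    area <- as.numeric(table)
  }
  if (is.null(weight)) stop_fm("body weights are required")
  bad <- is.na(area) | is.na(weight) | area <= 0 | weight <= 0
  if (any(bad)) {
    warn_fm(
      "excluding ", sum(bad),
      " specimen(s) with missing or non-positive area/weight"
    )
  }
  area <- area[!bad]
  weight <- weight[!bad]
  if (length(area) < 3L) {
    stop_fm("fewer than 3 usable specimens for the power-law fit")
  }
  if (var(log(weight)) == 0) {
    stop_fm("no weight variation: the exponent is not identifiable")
  }
  fit <- lm(log(area) ~ log(weight))
  structure(
    list(
      alpha = unname(coef(fit)[2L]),
      b = unname(exp(coef(fit)[1L])),
      r_squared = suppressWarnings(summary(fit))$r.squared,
      n = length(area)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(
    sprintf(
      "Allometric foot-growth fit: A = b W^alpha, alpha = %.4g, b = %.4g (R^2 = %.3f, n = %d)\n",
      x$alpha, x$b, x$r_squared, x$n
    )
  )
  invisible(x)
}

#' Illustrative growth-parameter reference values
#'
#' Synthetic reference entries for comparing a fitted foot-growth power law
#' against other plethodontid salamanders: a cave-dwelling
#' *Chiropterotriton magnipes*-like entry whose foot growth is adapted for
#' climbing, and two *Bolitoglossa*-like tropical arboreal entries. The
#' numbers are illustrative stand-ins constructed for this package, not
#' published measurements.
#'
#' @return a data.frame with columns `label`, `alpha`, `b`.
#' @export
growth_reference_table <- function() {
  data.frame(
    label = c(
      "Chiropterotriton magnipes-like (cave, climbing-adapted)",
      "Bolitoglossa webbed-like (arboreal)",
      "Bolitoglossa unwebbed-like (arboreal)"
    ),
    alpha = c(0.75, 1.10, 1.25),
    b = c(0.14, 0.45, 0.60)
  )
}

#' Compare fitted growth parameters with reference species
#'
#' Ranks reference `(alpha, b)` pairs by Euclidean distance to the fit in
#' `(alpha, log b)` space (the scale on which the power law is linear) and
#' labels the nearest.
#'
#' @param fit a [fit_power_law()] result (or list with `alpha` and `b`).
#' @param references data.frame with columns `label`, `alpha`, `b`.
#' @return a data.frame sorted by distance with columns `label`, `alpha`,
#'   `b`, `distance`, `rank`; the first row is the nearest reference.
#' @export
compare_growth_parameters <- function(fit, references = growth_reference_table()) {
  stopifnot(all(c("alpha", "b") %in% names(fit)))
  if (!is.data.frame(references) || nrow(references) < 1L) {
    stop_fm("at least one reference (label, alpha, b) is required")
  }
  d <- sqrt((references$alpha - fit$alpha)^2 +
    (log(references$b) - log(fit$b))^2)
  ord <- order(d, references$label)
  out <- references[ord, , drop = FALSE]
  out$distance <- d[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
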