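#' Template salamander foot shape
#'
#' A stylised nine-landmark right-foot configuration: the tips of digits
#' one to five interleaved with the four interdigital notch points, centred
#' and scaled to unit centroid size. The `webbing` parameter moves the
#' notch landmarks distally (towards the digit tips), emulating increasing
#' interdigital webbing.
#'
#' @param webbing degree of webbing in `[0, 1]`; 0 gives deep notches
#'   (unwebbed), 1 an almost straight distal outline (fully webbed).
#' @return a `9 x 2` matrix with unit centroid size.
#' @export
salamander_mean_shape <- function(webbing = 0.85) {
  stopifnot(is.numeric(webbing), length(webbing) == 1L, webbing >= 0, webbing <= 1)
  tip_angle <- seq(150, 30, length.out = 5L) * pi / 180
  tip_r <- c(0.75, 0.92, 1.0, 0.95, 0.8)
  notch_angle <- (tip_angle[-5L] + tip_angle[-1L]) / 2
  notch_r <- (0.45 + 0.4 * webbing) * (tip_r[-5L] + tip_r[-1L]) / 2
  ang <- c(rbind(tip_angle, c(notch_angle, NA)))
  ang <- ang[!is.na(ang)]
  r <- c(rbind(tip_r, c(notch_r, NA)))
  r <- r[!is.na(r)]
  center_scale(cbind(r * cos(ang), r * sin(ang)))
}

#' Direction of shape change with increasing webbing
#'
#' The unit 18-vector (column-major: all x then all y) pointing from the
#' unwebbed towards the webbed variant of the template foot
#' ([salamander_mean_shape()]); multiplied by a magnitude it serves as the
#' allometric shape vector of the generator (displacement of tangent
#' coordinates per unit log centroid size).
#'
#' @return a unit-norm numeric vector of length 18.
#' @export
webbing_shape_vector <- function() {
  v <- vec_config(salamander_mean_shape(1)) - vec_config(salamander_mean_shape(0.3))
  v / sqrt(sum(v^2))
}

#' Species-level ontogeny parameters for the generator
#'
#' Describes one species' ontogenetic trajectory: a linear sinuosity-on-size
#' trajectory (slope 0 for isometric growth, negative for allometric growth,
#' since sinuosity falls as webbing increases), a mean shape plus an
#' allometric shape vector in tangent space, and a power-law relation of
#' foot area to body weight.
#'
#' @param species_id species label.
#' @param regime `"isometric"` or `"allometric"`.
#' @param sinuosity_intercept intercept of the sinuosity trajectory
#'   (dimensionless; sinuosity at foot length 0).
#' @param sinuosity_slope slope of sinuosity on foot length (per mm); must
#'   be 0 for isometric species and negative for allometric species.
#' @param size_range numeric length-2, min and max foot length (mm).
#' @param n_specimens number of specimens (at least 3).
#' @param mean_shape `9 x 2` matrix: the shape at log centroid size 0.
#' @param allometric_shape_vector numeric length-18 displacement of the
#'   vectorised shape per unit log centroid size; must be the zero vector
#'   for isometric species.
#' @param sinuosity_noise_sd sd of the additive Gaussian noise on the
#'   sinuosity ratio scale (per species; realisations below the geometric
#'   floor of 1 are redrawn).
#' @param shape_noise_sd isotropic landmark noise sd on the unit-size shape
#'   scale (dimensionless).
#' @param growth_alpha,growth_b parameters of the foot-growth power law
#'   `A = b * W^alpha` (area in mm^2, weight in g).
#' @param area_noise_sd log-scale sd of the multiplicative area noise.
#' @return an object of class `species_ontogeny_params`.
#' @export
ontogeny_params <- function(species_id,
                            regime = c("isometric", "allometric"),
                            sinuosity_intercept,
                            sinuosity_slope,
                            size_range,
                            n_specimens,
                            mean_shape = salamander_mean_shape(),
                            allometric_shape_vector = numeric(18L),
                            sinuosity_noise_sd = 0,
                            shape_noise_sd = 0.01,
                            growth_alpha = 0.75,
                            growth_b = 0.14,
                            area_noise_sd = 0.1) {
  regime <- match.arg(regime)
  stopifnot(
    is.character(species_id), length(species_id) == 1L,
    is.numeric(sinuosity_intercept), length(sinuosity_intercept) == 1L,
    is.numeric(sinuosity_slope), length(sinuosity_slope) == 1L,
    is.numeric(size_range), length(size_range) == 2L,
    is.matrix(mean_shape), ncol(mean_shape) == 2L,
    length(allometric_shape_vector) == 2L * nrow(mean_shape),
    sinuosity_noise_sd >= 0, shape_noise_sd >= 0, area_noise_sd >= 0,
    growth_alpha > 0, growth_b > 0
  )
  if (n_specimens < 3L) stop_fm("n_specimens must be at least 3")
  if (size_range[1L] <= 0 || size_range[1L] >= size_range[2L]) {
    stop_fm("size_range must satisfy 0 < min < max")
  }
  if (regime == "isometric") {
    if (sinuosity_slope != 0) {
      stop_fm("isometric regime requires sinuosity_slope == 0")
    }
    if (any(allometric_shape_vector != 0)) {
      stop_fm("isometric regime requires a zero allometric_shape_vector")
    }
  } else if (sinuosity_slope >= 0) {
    stop_fm(
      "allometric regime requires a negative sinuosity_slope ",
      "(sinuosity decreases as webbing increases)"
    )
  }
  structure(
    list(
      species_id = species_id,
      regime = regime,
      sinuosity_intercept = sinuosity_intercept,
      sinuosity_slope = sinuosity_slope,
      size_range = as.numeric(size_range),
      n_specimens = as.integer(n_specimens),
      mean_shape = mean_shape,
      allometric_shape_vector = as.numeric(allometric_shape_vector),
      sinuosity_noise_sd = sinuosity_noise_sd,
      shape_noise_sd = shape_noise_sd,
      growth_alpha = growth_alpha,
      growth_b = growth_b,
      area_noise_sd = area_noise_sd
    ),
    class = "species_ontogeny_params"
  )
}

# sinuosity noise sd implied by a target slope standard error under a
# uniform size design: se(beta) = sd / sqrt(sum((x - xbar)^2)), with
# sum((x - xbar)^2) ~= n * range^2 / 12 for x uniform on the range
sinuosity_noise_from_se <- function(se_beta, size_range, n) {
  se_beta * (diff(size_range) / sqrt(12)) * sqrt(n - 1)
}

#' Calibrated ontogeny parameters for the eight European cave salamanders
#'
#' The generator's reference fixture: eight species, five isometric and
#' three allometric (*H. (S.) flavus*, *H. (S.) sarrabusensis* and
#' *H. (S.) supramontis*), 330 specimens in all (24–54 per species). The
#' allometric sinuosity slopes, their standard errors and the adult
#' sinuosity means (2.38–2.73 across species) follow published ontogenetic
#' series for these species; the within-species noise sd is set so that the
#' slope standard error implied by each species' design matches the
#' published value. The three allometric species share one allometric shape
#' vector and reach a common webbed adult shape at their maximum size.
#'
#' @param shape_slope magnitude of the shared allometric shape vector
#'   (tangent displacement per unit log centroid size).
#' @param shape_noise_sd isotropic landmark noise sd (unit-shape scale).
#' @return a list of eight [ontogeny_params()] objects.
#' @export
hydromantes_params <- function(shape_slope = 0.05, shape_noise_sd = 0.01) {
  adult_shape <- salamander_mean_shape(0.85)
  v <- shape_slope * webbing_shape_vector()
  spec <- list(
    # species,        regime,       slope,     se_beta,   n,  min, max, adult sinuosity
    list("H_ambrosii", "isometric", 0, 0.0066539, 40L, 3.5, 14, 2.42),
    list("H_flavus", "allometric", -0.03461, 0.01234, 47L, 4, 20, 2.55),
    list("H_genei", "isometric", 0, 0.010382, 36L, 4, 18, 2.66),
    list("H_imperialis", "isometric", 0, 0.006966, 45L, 4, 20, 2.50),
    list("H_italicus", "isometric", 0, 0.010279, 38L, 3.5, 13, 2.71),
    list("H_sarrabusensis", "allometric", -0.05263, 0.02109, 24L, 4, 14, 2.60),
    list("H_strinatii", "isometric", 0, 0.009891, 46L, 3.5, 14, 2.38),
    list("H_supramontis", "allometric", -0.03503, 0.00878, 54L, 4, 22, 2.45)
  )
  lapply(spec, function(s) {
    size_range <- c(s[[6L]], s[[7L]])
    allo <- s[[2L]] == "allometric"
    # intercept chosen so the trajectory hits the adult value at max size
    intercept <- s[[8L]] - s[[3L]] * size_range[2L]
    vect <- if (allo) v else numeric(18L)
    # allometric species converge on the common webbed adult shape at max size
    mshape <- if (allo) {
      adult_shape - log(size_range[2L]) * mat_config(v)
    } else {
      adult_shape
    }
    ontogeny_params(
      species_id = s[[1L]],
      regime = s[[2L]],
      sinuosity_intercept = intercept,
      sinuosity_slope = s[[3L]],
      size_range = size_range,
      n_specimens = s[[5L]],
      mean_shape = mshape,
      allometric_shape_vector = vect,
      sinuosity_noise_sd = sinuosity_noise_from_se(s[[4L]], size_range, s[[5L]]),
      shape_noise_sd = shape_noise_sd
    )
  })
}

#' Shared-trajectory null parameters
#'
#' A null fixture for calibrating the convergence permutation test: every
#' species follows the same flat sinuosity trajectory (common intercept,
#' slope 0) with i.i.d. noise, so specimens are exchangeable and the
#' permutation null holds exactly.
#'
#' @param n_species number of species.
#' @param intercept common sinuosity level.
#' @param noise_sd common within-species sinuosity sd.
#' @param size_range,n_specimens design shared by every species.
#' @return a list of [ontogeny_params()] objects.
#' @export
shared_trajectory_params <- function(n_species = 8L, intercept = 2.55,
                                     noise_sd = 0.25,
                                     size_range = c(4, 20),
                                     n_specimens = 41L) {
  lapply(seq_len(n_species), function(i) {
    ontogeny_params(
      species_id = sprintf("sp%02d", i),
      regime = "isometric",
      sinuosity_intercept = intercept,
      sinuosity_slope = 0,
      size_range = size_range,
      n_specimens = n_specimens,
      sinuosity_noise_sd = noise_sd
    )
  })
}

#' Convergent-ontogeny alternative parameters
#'
#' An alternative fixture in which all species share one adult sinuosity
#' value (a common adult optimum) while their juvenile values are dispersed:
#' species `j` starts `juvenile_spread * (j-1)/(n-1)` above the adult value
#' and descends linearly to it.
#'
#' @param n_species number of species.
#' @param adult_value common sinuosity at maximum size.
#' @param juvenile_spread range of juvenile sinuosity values above
#'   `adult_value`.
#' @param noise_sd within-species sinuosity sd.
#' @param size_range,n_specimens design shared by every species.
#' @return a list of [ontogeny_params()] objects.
#' @export
convergent_ontogeny_params <- function(n_species = 8L, adult_value = 2.55,
                                       juvenile_spread = 0.7,
                                       noise_sd = 0.25,
                                       size_range = c(4, 20),
                                       n_specimens = 41L) {
  lapply(seq_len(n_species), function(i) {
    delta <- juvenile_spread * (i - 1L) / (n_species - 1L)
    slope <- -delta / diff(size_range)
    ontogeny_params(
      species_id = sprintf("sp%02d", i),
      regime = if (slope < 0) "allometric" else "isometric",
      sinuosity_intercept = adult_value + delta - slope * size_range[1L],
      sinuosity_slope = slope,
      size_range = size_range,
      n_specimens = n_specimens,
      sinuosity_noise_sd = noise_sd
    )
  })
}

#' Simulate a phylogeny
#'
#' A rooted, bifurcating pure-birth tree with strictly positive branch
#' lengths and unique tip labels, for exercising the comparative stages of
#' the pipeline when no tree is supplied.
#'
#' @param n_species number of tips (at least 2).
#' @param seed RNG seed; the same seed reproduces the same tree exactly.
#' @param tip_labels optional character vector of tip labels.
#' @return an [ape::rphylo()] `phylo` object.
#' @export
generate_tree <- function(n_species, seed = 1L, tip_labels = NULL) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 2L) {
    stop_fm("invalid parameter: n_species must be at least 2")
  }
  n_species <- as.integer(n_species)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  tree$tip.label <- if (is.null(tip_labels)) {
    sprintf("sp%02d", seq_len(n_species))
  } else {
    if (length(tip_labels) != n_species) {
      stop_fm("tip_labels must have length n_species")
    }
    as.character(tip_labels)
  }
  tree
}

#' Synthetic phylogeny of the European cave salamanders
#'
#' A fixture tree whose topology mirrors the relationships of the eight
#' European *Hydromantes (Speleomantes)* species — a Sardinian clade in
#' which the three allometric species are nested together with the
#' isometric *H. imperialis*, and a mainland clade — with made-up branch
#' lengths (the published molecular tree is not redistributed).
#'
#' @return a `phylo` object with 8 tips.
#' @export
hydromantes_tree <- function() {
  path <- system.file("extdata", "hydromantes_tree_synthetic.nwk",
    package = "footmorph"
  )
  if (path == "") stop_fm("fixture tree not found; is footmorph installed?")
  ape::read.tree(path)
}

#' Generate a synthetic specimen dataset
#'
#' Draws, for each species in `params`: foot lengths uniform over the
#' species' size range; sinuosity from the species' linear trajectory plus
#' Gaussian noise (redrawn while below the geometric floor of 1, with the
#' number of redraws reported); foot width as a fixed fraction of foot
#' length and perimeter as `sinuosity * width`; body weight log-uniform
#' over `weight_range` (a fraction subsequently set missing, as some museum
#' specimens cannot be weighed); foot area from the species' power law with
#' multiplicative log-normal noise; and a landmark configuration equal to
#' the species' mean shape displaced along its allometric shape vector by
#' log centroid size, plus isotropic landmark noise, scaled to the
#' specimen's size and then pushed through nuisance rotation, translation
#' and digitiser scaling so that the Procrustes stage has real work to do.
#' The digitiser scale is recorded per specimen (the TPS `SCALE=` record),
#' so coordinates in mm are recoverable via [landmark_mm()].
#'
#' @param params list of [ontogeny_params()] objects.
#' @param tree optional `phylo`; if given, every species must be a tip.
#' @param seed RNG seed; identical `(params, seed)` reproduce the dataset
#'   bit-identically.
#' @param width_ratio foot width as a fraction of foot length.
#' @param weight_range body-weight range (g), sampled log-uniformly.
#' @param prop_weight_missing expected fraction of specimens with missing
#'   body weight.
#' @param translation_range nuisance translations are uniform on
#'   `[-translation_range, translation_range]` mm per axis.
#' @param scale_range nuisance digitiser scale is log-uniform over this
#'   range.
#' @param max_resample cap on sinuosity redraws per species.
#' @return an object of class `synthetic_dataset`: list with `specimens`
#'   (data.frame), `landmarks` ([landmark_set]), `tree`, `truth` (the
#'   `params`), `seed` and `resample_count`.
#' @export
generate_dataset <- function(params, tree = NULL, seed = 1L,
                             width_ratio = 0.55,
                             weight_range = c(0.5, 10),
                             prop_weight_missing = 0.05,
                             translation_range = 10,
                             scale_range = c(0.5, 2),
                             max_resample = 10000L) {
  if (inherits(params, "species_ontogeny_params")) params <- list(params)
  ok <- vapply(params, inherits, logical(1), "species_ontogeny_params")
  if (!length(params) || !all(ok)) {
    stop_fm("params must be a list of ontogeny_params() objects")
  }
  species <- vapply(params, function(p) p$species_id, character(1))
  if (anyDuplicated(species)) stop_fm("duplicate species_id in params")
  if (!is.null(tree)) {
    missing_sp <- setdiff(species, tree$tip.label)
    if (length(missing_sp)) {
      stop_fm(
        "species absent from the tree: ",
        paste(missing_sp, collapse = ", ")
      )
    }
  }
  with_seed(seed, {
    rows <- list()
    confs <- list()
    scales <- numeric(0)
    resample_count <- 0L
    for (p in params) {
      n <- p$n_specimens
      len <- runif(n, p$size_range[1L], p$size_range[2L])
      noise_sd <- p$sinuosity_noise_sd %||% 0
      sinu <- p$sinuosity_intercept + p$sinuosity_slope * len +
        rnorm(n, sd = noise_sd)
      tries <- 0L
      while (any(bad <- sinu < 1)) {
        tries <- tries + 1L
        if (tries > max_resample) {
          stop_fm(
            "could not draw sinuosity >= 1 for species ", p$species_id,
            " within ", max_resample, " redraws"
          )
        }
        resample_count <- resample_count + sum(bad)
        sinu[bad] <- p$sinuosity_intercept + p$sinuosity_slope * len[bad] +
          rnorm(sum(bad), sd = noise_sd)
      }
      width <- width_ratio * len
      perimeter <- sinu * width
      weight <- exp(runif(n, log(weight_range[1L]), log(weight_range[2L])))
      area <- p$growth_b * weight^p$growth_alpha *
        exp(rnorm(n, sd = p$area_noise_sd))
      weight[runif(n) < prop_weight_missing] <- NA_real_

      lcs <- log(len)
      vmat <- mat_config(p$allometric_shape_vector)
      ids <- sprintf("%s_%03d", p$species_id, seq_len(n))
      cs_real <- numeric(n)
      for (i in seq_len(n)) {
        shp <- p$mean_shape + lcs[i] * vmat +
          matrix(rnorm(2L * nrow(p$mean_shape), sd = p$shape_noise_sd),
            ncol = 2L
          )
        mm <- len[i] * shp
        cs_real[i] <- centroid_size(mm)
        theta <- runif(1L, 0, 2 * pi)
        rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
        shift <- runif(2L, -translation_range, translation_range)
        u <- exp(runif(1L, log(scale_range[1L]), log(scale_range[2L])))
        raw <- sweep(mm %*% rot, 2L, shift, "+") * u
        confs[[ids[i]]] <- raw
        scales <- c(scales, 1 / u)
      }
      rows[[p$species_id]] <- data.frame(
        specimen_id = ids,
        species_id = p$species_id,
        foot_length = len,
        foot_width = width,
        perimeter = perimeter,
        sinuosity = sinu,
        foot_area = area,
        body_weight = weight,
        log_centroid_size = log(cs_real)
      )
    }
    specimens <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    coords <- array(
      unlist(confs),
      dim = c(nrow(params[[1L]]$mean_shape), 2L, nrow(specimens))
    )
    landmarks <- landmark_set(
      coords, specimens$specimen_id,
      species_id = specimens$species_id, scale = scales
    )
    structure(
      list(
        specimens = specimens,
        landmarks = landmarks,
        tree = tree,
        truth = params,
        seed = seed,
        resample_count = resample_count
      ),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  tab <- table(x$specimens$species_id)
  cat(
    "Synthetic ontogenetic dataset: ", nrow(x$specimens), " specimens, ",
    length(tab), " species (", min(tab), "-", max(tab), " each), seed ",
    x$seed, "\n",
    sep = ""
  )
  if (x$resample_count > 0) {
    cat("  sinuosity redraws below the floor of 1:", x$resample_count, "\n")
  }
  invisible(x)
}
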