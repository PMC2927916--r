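#' Pipeline run configuration
#'
#' Describes one reproducible end-to-end run: either a synthetic-generation
#' block (ontogeny parameters plus an optional tree) or paths to existing
#' inputs (TPS landmarks, specimen CSV, newick tree) — exactly one of the
#' two — together with the analysis settings and the master seed from which
#' every stage seed is derived.
#'
#' @param out_dir output directory for the run.
#' @param synthetic list with `params` (list of [ontogeny_params()]) and
#'   optionally `tree` (a `phylo`); mutually exclusive with `inputs`.
#' @param inputs list with paths `tps`, `specimens`, `tree`; mutually
#'   exclusive with `synthetic`.
#' @param size_field size covariate for the webbing analyses.
#' @param alpha_level significance level for regime coding.
#' @param n_permutations permutations for the convergence tests.
#' @param seed master seed; the generator uses `seed`, the sinuosity and
#'   shape convergence tests use `seed + 101` and `seed + 102`.
#' @param mancova_size_scale `"raw"` or `"log"` centroid size in the
#'   MANCOVA.
#' @param shuffle permutation scheme, see
#'   [convergence_permutation_test()].
#' @param make_plots also write diagnostic figures (PDF).
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       synthetic = NULL,
                       inputs = NULL,
                       size_field = c("foot_length", "foot_width"),
                       alpha_level = 0.05,
                       n_permutations = 9999L,
                       seed = 1L,
                       mancova_size_scale = c("raw", "log"),
                       shuffle = c("raw", "fitted"),
                       make_plots = FALSE) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop_fm("exactly one of 'synthetic' or 'inputs' must be given")
  }
  if (!is.null(inputs)) {
    need <- c("tps", "specimens", "tree")
    if (!all(need %in% names(inputs))) {
      stop_fm("inputs must name paths: ", paste(need, collapse = ", "))
    }
  }
  structure(
    list(
      out_dir = out_dir,
      synthetic = synthetic,
      inputs = inputs,
      size_field = match.arg(size_field),
      alpha_level = alpha_level,
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed),
      mancova_size_scale = match.arg(mancova_size_scale),
      shuffle = match.arg(shuffle),
      make_plots = isTRUE(make_plots)
    ),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_fm(
      "pipeline stage '", name, "' failed: ", conditionMessage(e),
      " (outputs written so far are retained)"
    )
  })
}

#' Run the full ontogenetic-allometry pipeline
#'
#' Chains every stage into one reproducible run: simulate (or load) the
#' specimen data, superimpose the landmarks, fit the webbing and shape
#' allometry models, code growth regimes, test ontogenetic convergence for
#' both the sinuosity and the shape response, reconstruct ancestral growth
#' regimes on the phylogeny, fit the foot-growth power law and compare it
#' with reference species. All tables are written as CSV into `out_dir`
#' together with a JSON manifest (settings, stage seeds, package and R
#' versions, input checksums); re-running with the same configuration
#' reproduces every numeric output bit-identically.
#'
#' @param config a [run_config()].
#' @return the assembled results list, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out, "inputs")
  dir.create(in_dir, showWarnings = FALSE)

  # ---- stage: inputs (simulate or copy), always re-read through own readers
  paths <- run_stage("inputs", {
    if (!is.null(config$synthetic)) {
      tree <- config$synthetic$tree %||%
        generate_tree(
          length(config$synthetic$params),
          seed = config$seed,
          tip_labels = vapply(
            config$synthetic$params,
            function(p) p$species_id, character(1)
          )
        )
      ds <- generate_dataset(config$synthetic$params, tree, seed = config$seed)
      p <- list(
        tps = file.path(in_dir, "landmarks.tps"),
        specimens = file.path(in_dir, "specimens.csv"),
        tree = file.path(in_dir, "tree.nwk")
      )
      write_tps(ds$landmarks, p$tps)
      write_specimens(ds$specimens, p$specimens)
      ape::write.tree(tree, file = p$tree)
      p$resample_count <- ds$resample_count
      p
    } else {
      config$inputs
    }
  })

  landmarks <- run_stage("read-landmarks", read_tps(paths$tps))
  specimens <- run_stage("read-specimens", read_specimens(paths$specimens))
  tree <- run_stage("read-tree", ape::read.tree(paths$tree))
  if (!all(specimens$specimen_id %in% landmarks$specimen_id)) {
    stop_fm("pipeline stage 'inputs' failed: specimens without landmarks")
  }
  # landmark order follows the specimen table
  ord <- match(specimens$specimen_id, landmarks$specimen_id)
  landmarks <- landmark_set(
    landmarks$coords[, , ord, drop = FALSE],
    specimens$specimen_id,
    species_id = specimens$species_id,
    scale = landmarks$scale[ord]
  )

  # ---- stage: Procrustes superimposition
  shapes <- run_stage("gpa", gpa(landmarks))
  specimens$log_centroid_size <- log(shapes$centroid_sizes)
  run_stage("write-aligned", {
    aligned <- data.frame(
      specimen_id = specimens$specimen_id,
      species_id = specimens$species_id,
      centroid_size = unname(shapes$centroid_sizes),
      shapes$tangent_coords
    )
    names(aligned)[-(1:3)] <- c(
      sprintf("x%d", seq_len(nrow(shapes$consensus))),
      sprintf("y%d", seq_len(nrow(shapes$consensus)))
    )
    write.csv(aligned, file.path(out, "aligned_shapes.csv"), row.names = FALSE)
  })

  # ---- stage: allometry statistics
  regressions <- run_stage(
    "species-regressions",
    fit_species_regressions(specimens, config$size_field)
  )
  regimes <- code_trajectories(regressions, config$alpha_level)
  ancova <- run_stage("ancova", ancova_webbing(specimens, config$size_field))
  mancova <- run_stage(
    "mancova",
    mancova_shape(shapes, specimens$species_id,
      size_scale = config$mancova_size_scale
    )
  )
  scores <- run_stage("regression-scores", regression_scores(shapes))
  run_stage("write-allometry", {
    write.csv(regressions, file.path(out, "species_regressions.csv"),
      row.names = FALSE
    )
    write.csv(
      data.frame(species_id = names(regimes), regime = unname(regimes)),
      file.path(out, "regimes.csv"),
      row.names = FALSE
    )
    write.csv(ancova, file.path(out, "ancova_webbing.csv"), row.names = FALSE)
    write.csv(mancova, file.path(out, "mancova_shape.csv"), row.names = FALSE)
    write.csv(
      data.frame(
        specimen_id = specimens$specimen_id,
        log_centroid_size = specimens$log_centroid_size,
        regression_score = unname(scores)
      ),
      file.path(out, "regression_scores.csv"),
      row.names = FALSE
    )
  })

  # ---- stage: convergence tests (sinuosity and shape)
  size_col <- specimens[[config$size_field]]
  conv_sin <- run_stage("convergence-sinuosity", convergence_permutation_test(
    specimens$sinuosity, specimens$species_id, size_col,
    n_permutations = config$n_permutations, seed = config$seed + 101L,
    shuffle = config$shuffle, response_kind = "sinuosity"
  ))
  conv_shape <- run_stage("convergence-shape", convergence_permutation_test(
    shapes$tangent_coords, specimens$species_id,
    specimens$log_centroid_size,
    n_permutations = config$n_permutations, seed = config$seed + 102L,
    shuffle = config$shuffle, response_kind = "shape"
  ))
  run_stage("write-convergence", {
    write.csv(
      data.frame(
        response = c("sinuosity", "shape"),
        sum_d_juv = c(conv_sin$sum_d_juv, conv_shape$sum_d_juv),
        sum_d_adult = c(conv_sin$sum_d_adult, conv_shape$sum_d_adult),
        statistic = c(conv_sin$statistic, conv_shape$statistic),
        p_rand = c(conv_sin$p_rand, conv_shape$p_rand),
        n_permutations = config$n_permutations
      ),
      file.path(out, "convergence.csv"),
      row.names = FALSE
    )
    write.csv(
      data.frame(
        permutation = seq_len(config$n_permutations),
        sinuosity = conv_sin$null_statistics,
        shape = conv_shape$null_statistics
      ),
      file.path(out, "convergence_null_distributions.csv"),
      row.names = FALSE
    )
  })

  # ---- stage: ancestral reconstruction
  asr <- run_stage("ancestral-states", {
    pruned <- prune_to_species(tree, names(regimes))
    reconstruct_ancestral_states(pruned, regimes)
  })
  run_stage("write-asr", {
    write.csv(
      data.frame(
        node = rownames(asr$node_probs),
        p_allometric = asr$node_probs[, "allometric"],
        p_isometric = asr$node_probs[, "isometric"],
        ml_state = unname(asr$ml_state)
      ),
      file.path(out, "asr_node_probabilities.csv"),
      row.names = FALSE
    )
    write.csv(asr$transitions, file.path(out, "asr_transitions.csv"),
      row.names = FALSE
    )
    write_annotated_tree(asr, file.path(out, "asr_annotated_tree.nwk"))
  })

  # ---- stage: foot-growth power law
  growth <- run_stage("power-law", fit_power_law(specimens))
  growth_cmp <- compare_growth_parameters(growth)
  run_stage("write-growth", {
    write.csv(
      data.frame(
        alpha = growth$alpha, b = growth$b,
        r_squared = growth$r_squared, n = growth$n
      ),
      file.path(out, "growth_fit.csv"),
      row.names = FALSE
    )
    write.csv(growth_cmp, file.path(out, "growth_comparison.csv"),
      row.names = FALSE
    )
  })

  results <- list(
    specimens = specimens,
    shapes = shapes,
    regressions = regressions,
    regimes = regimes,
    ancova = ancova,
    mancova = mancova,
    scores = scores,
    convergence_sinuosity = conv_sin,
    convergence_shape = conv_shape,
    asr = asr,
    growth = growth,
    growth_comparison = growth_cmp,
    tree = tree
  )

  if (config$make_plots) {
    run_stage("plots", write_pipeline_plots(results, config, out))
  }

  # ---- manifest
  run_stage("manifest", {
    input_files <- unlist(paths[c("tps", "specimens", "tree")])
    manifest <- list(
      package = "footmorph",
      package_version = as.character(utils::packageVersion("footmorph")),
      r_version = R.version.string,
      seed = config$seed,
      stage_seeds = list(
        generator = config$seed,
        convergence_sinuosity = config$seed + 101L,
        convergence_shape = config$seed + 102L
      ),
      settings = list(
        size_field = config$size_field,
        alpha_level = config$alpha_level,
        n_permutations = config$n_permutations,
        mancova_size_scale = config$mancova_size_scale,
        shuffle = config$shuffle
      ),
      inputs = as.list(setNames(
        unname(tools::md5sum(input_files)),
        basename(input_files)
      )),
      resample_count = paths$resample_count %||% NA,
      gpa = list(
        iterations = shapes$iterations_used,
        converged = shapes$converged
      )
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  })

  invisible(results)
}

# Fig-2-style ontogeny panels and a deformation-grid figure
write_pipeline_plots <- function(results, config, out) {
  sp <- factor(results$specimens$species_id)
  cols <- setNames(hcl.colors(nlevels(sp), "Dark 3"), levels(sp))
  size_col <- results$specimens[[config$size_field]]
  cexs <- 0.5 + 1.5 * (size_col - min(size_col)) / diff(range(size_col))

  pdf(file.path(out, "ontogeny_panels.pdf"), width = 10, height = 10)
  par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  plot(size_col, results$specimens$sinuosity,
    col = cols[sp], pch = 19, cex = cexs,
    xlab = size_label(config$size_field), ylab = "Sinuosity (p/d)"
  )
  title("Foot webbing vs size")
  traj <- predict_trajectories(
    results$specimens$sinuosity,
    results$specimens$species_id, size_col
  )
  plot(size_col, results$specimens$sinuosity,
    type = "n",
    xlab = size_label(config$size_field), ylab = "Predicted sinuosity"
  )
  for (m in traj) {
    segments(m$size_min, m$predicted_juvenile, m$size_max, m$predicted_adult,
      col = cols[m$species_id], lwd = 2
    )
  }
  title("Species-specific predicted trajectories")
  lcs <- results$specimens$log_centroid_size
  plot(lcs, results$scores,
    col = cols[sp], pch = 19, cex = cexs,
    xlab = "log(Centroid Size)", ylab = "Shape regression score"
  )
  title("Shape allometry")
  straj <- predict_trajectories(
    matrix(results$scores, ncol = 1),
    results$specimens$species_id, lcs,
    response_kind = "shape"
  )
  plot(lcs, results$scores,
    type = "n",
    xlab = "log(Centroid Size)", ylab = "Predicted score"
  )
  for (m in straj) {
    segments(m$size_min, m$predicted_juvenile, m$size_max, m$predicted_adult,
      col = cols[m$species_id], lwd = 2
    )
  }
  title("Predicted shape trajectories")
  dev.off()

  # deformation grids: consensus -> mean predicted juvenile / adult shape
  eps <- results$convergence_shape$endpoints
  cons <- results$shapes$consensus
  juv_mean <- mat_config(colMeans(eps$juvenile)) + cons
  adu_mean <- mat_config(colMeans(eps$adult)) + cons
  pdf(file.path(out, "deformation_grids.pdf"), width = 10, height = 5)
  par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  plot(tps_grid(cons, juv_mean, exaggeration = 2))
  title("Juvenile (exaggerated x2)")
  plot(tps_grid(cons, adu_mean, exaggeration = 2))
  title("Adult (exaggerated x2)")
  dev.off()

  pdf(file.path(out, "ancestral_states.pdf"), width = 7, height = 7)
  tr <- results$asr$tree
  nt <- length(tr$tip.label)
  plot(tr, label.offset = 0.01)
  state_col <- c(allometric = "firebrick", isometric = "steelblue", ambiguous = "grey")
  ape::tiplabels(pch = 19, col = state_col[results$asr$ml_state[seq_len(nt)]])
  ape::nodelabels(
    pie = results$asr$node_probs[nt + seq_len(tr$Nnode), ],
    piecol = state_col[1:2], cex = 0.5
  )
  dev.off()
  invisible(NULL)
}
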