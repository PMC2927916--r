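REGIMES <- c("allometric", "isometric")

#' Prune a phylogeny to a set of species
#'
#' Returns the induced subtree on the kept tips, suppressing degree-two
#' nodes and summing their branch lengths, so patristic distances among the
#' kept tips are unchanged.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return a `phylo`.
#' @export
prune_to_species <- function(tree, keep) {
  if (!inherits(tree, "phylo")) stop_fm("tree must be a phylo object")
  keep <- as.character(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop_fm("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop_fm("at least 2 tips must be kept")
  ape::keep.tip(tree, keep)
}

check_mk_inputs <- function(tree, tip_states, rate = 1) {
  if (!inherits(tree, "phylo")) stop_fm("tree must be a phylo object")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop_fm("tree must have strictly positive branch lengths")
  }
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips)) {
    stop_fm(
      "missing tip state(s) for: ",
      paste(missing_tips, collapse = ", ")
    )
  }
  st <- as.character(tip_states[tree$tip.label])
  bad <- setdiff(unique(st), REGIMES)
  if (length(bad)) {
    stop_fm(
      "tip states must be 'allometric' or 'isometric'; found: ",
      paste(bad, collapse = ", ")
    )
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop_fm("rate must be a positive number")
  }
  st
}

# transition probability matrix of the 2-state equal-rates model:
# P(change) = (1 - exp(-2 q t)) / 2
mk_pmat <- function(rate, t) {
  pc <- 0.5 * (1 - exp(-2 * rate * t))
  matrix(c(1 - pc, pc, pc, 1 - pc), 2L)
}

# Felsenstein pruning: per-node conditional likelihoods (rescaled) and the
# total log-likelihood under a flat (1/2, 1/2) root prior
mk_down_pass <- function(tree, tipmat, rate) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  partial <- matrix(1, nt + nn, 2L)
  partial[seq_len(nt), ] <- tipmat
  logscale <- numeric(nt + nn)
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1L]
    ch <- post$edge[e, 2L]
    msg <- mk_pmat(rate, post$edge.length[e]) %*% partial[ch, ]
    partial[par, ] <- partial[par, ] * as.numeric(msg)
    logscale[par] <- logscale[par] + logscale[ch]
    m <- max(partial[par, ])
    if (m > 0 && m < 1e-100) {
      partial[par, ] <- partial[par, ] / m
      logscale[par] <- logscale[par] + log(m)
    }
  }
  root <- nt + 1L
  lik <- sum(0.5 * partial[root, ])
  loglik <- if (lik > 0) log(lik) + logscale[root] else -1e8
  list(partial = partial, logscale = logscale, loglik = loglik, post = post)
}

tip_state_matrix <- function(st) {
  tipmat <- matrix(0, length(st), 2L)
  tipmat[cbind(seq_along(st), match(st, REGIMES))] <- 1
  tipmat
}

#' Log-likelihood of tip regimes under the two-state Mk model
#'
#' Felsenstein pruning over the two-state symmetric (equal-rates) Markov
#' model of discrete character evolution, with change probability
#' `(1 - exp(-2 * rate * t)) / 2` along a branch of length `t` and a flat
#' (1/2, 1/2) prior on the root state. As `rate -> 0` with tips in
#' conflicting states the likelihood vanishes (returned as an
#' underflow-safe large negative log-likelihood); as `rate -> Inf` tip
#' states become independent coin flips and the log-likelihood approaches
#' `n_tips * log(1/2)`.
#'
#' @param tree a rooted `phylo` with positive branch lengths.
#' @param tip_states named character vector (tip label -> `"allometric"` or
#'   `"isometric"`).
#' @param rate transition rate, per branch-length unit (positive).
#' @return the log-likelihood (scalar).
#' @export
mk_log_likelihood <- function(tree, tip_states, rate) {
  st <- check_mk_inputs(tree, tip_states, rate)
  mk_down_pass(tree, tip_state_matrix(st), rate)$loglik
}

# marginal state probabilities at every node via an inside-outside pass
mk_marginals <- function(tree, tipmat, rate) {
  down <- mk_down_pass(tree, tipmat, rate)
  post <- down$post
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  root <- nt + 1L
  up <- matrix(0, nt + nn, 2L)
  up[root, ] <- 0.5
  # per-edge messages from below: P(t_e) %*% partial[child]
  msgs <- matrix(0, nrow(post$edge), 2L)
  for (e in seq_len(nrow(post$edge))) {
    msgs[e, ] <- mk_pmat(rate, post$edge.length[e]) %*%
      down$partial[post$edge[e, 2L], ]
  }
  children_edges <- split(seq_len(nrow(post$edge)), post$edge[, 1L])
  # preorder = reverse postorder over edges
  for (e in rev(seq_len(nrow(post$edge)))) {
    par <- post$edge[e, 1L]
    ch <- post$edge[e, 2L]
    sib <- setdiff(children_edges[[as.character(par)]], e)
    s <- up[par, ]
    for (se in sib) s <- s * msgs[se, ]
    m <- max(s)
    if (m > 0) s <- s / m
    up[ch, ] <- as.numeric(t(mk_pmat(rate, post$edge.length[e])) %*% s)
  }
  marg <- down$partial * up
  marg <- marg / pmax(rowSums(marg), .Machine$double.xmin)
  colnames(marg) <- REGIMES
  list(marginals = marg, loglik = down$loglik)
}

#' Marginal ancestral state probabilities at a fixed rate
#'
#' Computes, for every node of the tree, the marginal posterior probability
#' of each regime given the tip states and a fixed transition rate of the
#' two-state equal-rates Mk model (flat root prior). Rows sum to one; tip
#' rows put probability one on the observed state.
#'
#' @inheritParams mk_log_likelihood
#' @return a matrix with one row per node (tips first, then internal
#'   nodes) and columns `allometric`, `isometric`.
#' @export
marginal_state_probabilities <- function(tree, tip_states, rate) {
  st <- check_mk_inputs(tree, tip_states, rate)
  m <- mk_marginals(tree, tip_state_matrix(st), rate)$marginals
  nt <- length(tree$tip.label)
  rownames(m) <- c(
    tree$tip.label,
    sprintf("node_%d", nt + seq_len(tree$Nnode))
  )
  m
}

#' Maximum-likelihood ancestral reconstruction of growth regime
#'
#' Optimises the transition rate of the two-state equal-rates Mk model (a
#' coarse grid scan on the log scale followed by golden-section refinement
#' within the bracketing interval), then computes marginal ancestral state
#' probabilities at every internal node by combining the conditional
#' likelihoods of the subtree below each node with the likelihood of the
#' rest of the tree. The maximum-likelihood state of a node is the argmax
#' of its marginal probabilities; exact ties are reported as
#' `"ambiguous"`, never broken silently. Evolutionary transitions are the
#' branches whose endpoint states differ (tips use their observed states).
#'
#' @inheritParams mk_log_likelihood
#' @param rate_bounds length-2 positive interval searched for the rate.
#' @param tol optimisation tolerance on the log-rate.
#' @return an object of class `ancestral_states`: `ml_rate`,
#'   `log_likelihood`, `node_probs` (matrix over all nodes, tips included,
#'   rows summing to 1), `ml_state`, `transitions` (data.frame of branches
#'   whose endpoint states differ), `states`, `tree`.
#' @export
reconstruct_ancestral_states <- function(tree, tip_states,
                                         rate_bounds = c(1e-6, 100),
                                         tol = 1e-8) {
  st <- check_mk_inputs(tree, tip_states)
  stopifnot(
    length(rate_bounds) == 2L, all(rate_bounds > 0),
    rate_bounds[1L] < rate_bounds[2L]
  )
  tipmat <- tip_state_matrix(st)
  nt <- length(tree$tip.label)

  if (length(unique(st)) == 1L) {
    warn_fm(
      "all tips share one state; the likelihood is monotone in the rate, ",
      "which is pinned to the lower bound"
    )
    ml_rate <- rate_bounds[1L]
  } else {
    nll <- function(lr) -mk_down_pass(tree, tipmat, exp(lr))$loglik
    grid <- seq(log(rate_bounds[1L]), log(rate_bounds[2L]), length.out = 40L)
    vals <- vapply(grid, nll, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(1L, k - 1L)]
    hi <- grid[min(length(grid), k + 1L)]
    opt <- optimize(nll, c(lo, hi), tol = tol)
    ml_rate <- exp(opt$minimum)
    if (nll(log(ml_rate)) > vals[k]) ml_rate <- exp(grid[k])
  }

  mar <- mk_marginals(tree, tipmat, ml_rate)
  marg <- mar$marginals
  node_ids <- c(tree$tip.label, sprintf("node_%d", nt + seq_len(tree$Nnode)))
  rownames(marg) <- node_ids

  ml_state <- character(nrow(marg))
  for (i in seq_len(nrow(marg))) {
    if (abs(marg[i, 1L] - marg[i, 2L]) < 1e-12) {
      ml_state[i] <- "ambiguous"
    } else {
      ml_state[i] <- REGIMES[which.max(marg[i, ])]
    }
  }
  ml_state[seq_len(nt)] <- st # tips are observed
  names(ml_state) <- node_ids

  ed <- tree$edge
  keep <- ml_state[ed[, 1L]] != "ambiguous" & ml_state[ed[, 2L]] != "ambiguous" &
    ml_state[ed[, 1L]] != ml_state[ed[, 2L]]
  transitions <- data.frame(
    parent = node_ids[ed[keep, 1L]],
    child = node_ids[ed[keep, 2L]],
    from = unname(ml_state[ed[keep, 1L]]),
    to = unname(ml_state[ed[keep, 2L]])
  )

  structure(
    list(
      ml_rate = ml_rate,
      log_likelihood = mar$loglik,
      node_probs = marg,
      ml_state = ml_state,
      transitions = transitions,
      states = REGIMES,
      tree = tree
    ),
    class = "ancestral_states"
  )
}

#' @export
print.ancestral_states <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  root <- nt + 1L
  cat(
    sprintf(
      paste0(
        "Mk (equal-rates, 2-state) ancestral reconstruction\n",
        "  ML rate = %.6g, log-likelihood = %.4f\n",
        "  root state: %s (P = %.3f)\n",
        "  inferred transitions: %d\n"
      ),
      x$ml_rate, x$log_likelihood, x$ml_state[root],
      max(x$node_probs[root, ]), nrow(x$transitions)
    )
  )
  invisible(x)
}

#' Write a newick tree annotated with reconstructed node states
#'
#' Stores the maximum-likelihood state of each internal node as its node
#' label and writes the tree in newick format.
#'
#' @param asr an [reconstruct_ancestral_states()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(asr, path) {
  stopifnot(inherits(asr, "ancestral_states"))
  tree <- asr$tree
  nt <- length(tree$tip.label)
  tree$node.label <- unname(asr$ml_state[nt + seq_len(tree$Nnode)])
  ape::write.tree(tree, file = path)
  invisible(path)
}
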