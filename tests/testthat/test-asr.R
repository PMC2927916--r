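test_that("pruning preserves patristic distances among kept tips", {
  t4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  kept <- prune_to_species(t4, c("a", "b"))
  expect_setequal(kept$tip.label, c("a", "b"))
  expect_equal(ape::cophenetic.phylo(kept)["a", "b"], 2)
  # identity pruning round-trips the topology
  same <- prune_to_species(t4, t4$tip.label)
  expect_equal(
    ape::cophenetic.phylo(same)[t4$tip.label, t4$tip.label],
    ape::cophenetic.phylo(t4)[t4$tip.label, t4$tip.label]
  )
  set.seed(51)
  t10 <- generate_tree(10, seed = 5)
  full_d <- ape::cophenetic.phylo(t10)
  for (i in 1:5) {
    keep <- sample(t10$tip.label, sample(2:9, 1L))
    sub <- prune_to_species(t10, keep)
    expect_equal(
      ape::cophenetic.phylo(sub)[keep, keep],
      full_d[keep, keep],
      tolerance = 1e-12
    )
  }
  expect_error(prune_to_species(t10, c("sp01", "ghost")), "ghost")
})

test_that("pruning likelihood equals enumeration on small trees", {
  rates <- exp(seq(log(1e-4), log(10), length.out = 20L))
  set.seed(52)
  for (nt in 3:6) {
    tree <- generate_tree(nt, seed = 100 + nt)
    st <- setNames(
      sample(c("allometric", "isometric"), nt, replace = TRUE),
      tree$tip.label
    )
    st[1L] <- "allometric"
    st[2L] <- "isometric" # force a conflict
    for (r in rates) {
      expect_equal(
        mk_log_likelihood(tree, st, r),
        mk_enum_loglik(tree, st, r),
        tolerance = 1e-10
      )
    }
  }
})

test_that("the Mk likelihood has the stated limiting behaviour", {
  tree <- generate_tree(5, seed = 53)
  st <- setNames(
    c("allometric", "isometric", "isometric", "allometric", "isometric"),
    tree$tip.label
  )
  # conflicting tips with a vanishing rate: likelihood collapses
  expect_lt(mk_log_likelihood(tree, st, 1e-12), -20)
  expect_lt(
    mk_log_likelihood(tree, st, 1e-6),
    mk_log_likelihood(tree, st, 0.5)
  )
  # saturation: states become independent coin flips
  expect_equal(
    mk_log_likelihood(tree, st, 1e4),
    5 * log(0.5),
    tolerance = 1e-6
  )
  expect_error(mk_log_likelihood(tree, st[-1L], 1), "missing tip state")
  expect_error(mk_log_likelihood(tree, st, -1), "positive")
})

test_that("likelihood is invariant to tip order and newick rotation", {
  tree <- generate_tree(6, seed = 54)
  st <- setNames(
    c(
      "allometric", "isometric", "allometric",
      "isometric", "isometric", "allometric"
    ),
    tree$tip.label
  )
  ll <- mk_log_likelihood(tree, st, 0.7)
  expect_equal(mk_log_likelihood(tree, st[sample(6)], 0.7), ll)
  # newick text carries limited branch-length precision
  rot <- ape::read.tree(text = ape::write.tree(ape::rotate(tree, 8L)))
  expect_equal(mk_log_likelihood(rot, st, 0.7), ll, tolerance = 1e-9)
})

test_that("marginal reconstructions equal brute-force posteriors", {
  set.seed(55)
  for (nt in c(4L, 6L)) {
    tree <- generate_tree(nt, seed = 200 + nt)
    st <- setNames(
      sample(c("allometric", "isometric"), nt, replace = TRUE),
      tree$tip.label
    )
    st[1:2] <- c("allometric", "isometric")
    asr <- reconstruct_ancestral_states(tree, st)
    enum <- mk_enum_marginals(tree, st, asr$ml_rate)
    internal <- asr$node_probs[nt + seq_len(tree$Nnode), ]
    expect_equal(unname(internal), unname(enum), tolerance = 1e-10)
    expect_equal(unname(rowSums(asr$node_probs)), rep(1, nt + tree$Nnode),
      tolerance = 1e-12
    )
    # tips are observed: probability one on their state
    for (i in seq_len(nt)) {
      expect_equal(unname(asr$node_probs[i, st[tree$tip.label[i]]]), 1)
    }
  }
})

test_that("the optimised rate dominates a probe grid of alternatives", {
  tree <- hydromantes_tree()
  st <- hydromantes_regimes()
  asr <- reconstruct_ancestral_states(tree, st)
  for (r in exp(seq(log(1e-4), log(50), length.out = 20L))) {
    expect_gte(
      asr$log_likelihood + 1e-9,
      mk_log_likelihood(tree, st, r)
    )
  }
})

test_that("uniform tip states pin the rate and yield a flat reconstruction", {
  tree <- generate_tree(5, seed = 56)
  st <- setNames(rep("isometric", 5L), tree$tip.label)
  expect_warning(asr <- reconstruct_ancestral_states(tree, st), "pinned")
  expect_true(all(asr$node_probs[, "isometric"] >= 0.5))
  expect_true(all(asr$ml_state == "isometric"))
  expect_equal(nrow(asr$transitions), 0L)
})

test_that("the fixture tree reproduces the qualitative evolutionary pattern", {
  asr <- reconstruct_ancestral_states(hydromantes_tree(), hydromantes_regimes())
  root <- length(asr$tree$tip.label) + 1L
  # isometry ancestral for the European lineage, with a gain of allometry
  # inside the Sardinian clade and a reversal in H. imperialis
  expect_equal(unname(asr$ml_state[root]), "isometric")
  expect_gte(nrow(asr$transitions), 2L)
  expect_true("H_imperialis" %in% asr$transitions$child)
})

test_that("reconstruction agrees with an independent ER implementation", {
  tree <- hydromantes_tree()
  st <- hydromantes_regimes()
  asr <- reconstruct_ancestral_states(tree, st)
  tipf <- factor(st[tree$tip.label], levels = c("allometric", "isometric"))
  ac <- ape::ace(tipf, tree, type = "discrete", model = "ER")
  expect_equal(asr$ml_rate, unname(ac$rates), tolerance = 1e-4)
  # ace's likelihood omits the flat root prior: offset is exactly log 2
  expect_equal(asr$log_likelihood, ac$loglik - log(2), tolerance = 1e-6)
  nt <- length(tree$tip.label)
  expect_equal(
    unname(asr$node_probs[nt + seq_len(tree$Nnode), ]),
    unname(ac$lik.anc),
    tolerance = 1e-6
  )
})

test_that("annotated trees carry the reconstructed node states", {
  asr <- reconstruct_ancestral_states(hydromantes_tree(), hydromantes_regimes())
  tmp <- tempfile(fileext = ".nwk")
  on.exit(unlink(tmp))
  write_annotated_tree(asr, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(
    sort(unique(back$node.label)),
    sort(unique(unname(asr$ml_state[9:15])))
  )
})
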