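# Exact within-set games, adjusted baselines, the multistage driver and its
# oracles.

test_that("two-player game splits the surplus by marginal contributions", {
  vals <- list("1" = 1, "2" = 2, "1,2" = 5)
  value <- function(idx) vals[[paste(idx, collapse = ",")]]
  phi <- exact_within_set_shapley(value, c("p1", "p2"), baseline = 0)
  expect_equal(unname(phi), c(2, 3))
})

test_that("additive games return each player's own term", {
  set.seed(3)
  for (m in 2:5) {
    cc <- rnorm(m)
    value <- function(idx) sum(cc[idx])
    phi <- exact_within_set_shapley(value, paste0("p", 1:m), baseline = 0)
    expect_equal(unname(phi), cc, tolerance = 1e-12)
  }
})

test_that("bitmask enumeration agrees with the permutation-ordering oracle", {
  set.seed(5)
  for (m in 2:5) {
    vals <- rnorm(2^m - 1)
    value <- function(idx) {
      mask <- sum(bitwShiftL(1L, idx - 1L))
      vals[mask]
    }
    baseline <- rnorm(1)
    phi <- exact_within_set_shapley(value, paste0("p", 1:m), baseline)
    oracle <- perm_shapley(value, m, baseline)
    expect_equal(unname(phi), oracle, tolerance = 1e-12)
    # efficiency against the full coalition
    expect_equal(sum(phi), value(1:m) - baseline, tolerance = 1e-9)
  }
})

test_that("game size guard refuses combinatorial blow-ups", {
  value <- function(idx) length(idx)
  expect_error(exact_within_set_shapley(value, paste0("p", 1:25), 0,
                                        max_game_size = 20),
               "max_game_size")
})

test_that("adjusted baselines satisfy the two equivalent forms", {
  expect_equal(adjusted_baseline(70, 3), 67)
  expect_equal(adjusted_baseline(70, 0), 70)
  # E0 + sum(other same-level phis) == v_full - phi(target) on a real run
  w <- toy_world(n = 10, seed = 21)
  res <- multistage_shapley(w$tree, w$predictor, w$cohort$subjects[[1]],
                            w$reference)
  stage1 <- res$table[res$table$parent_id == "root", ]
  for (k in seq_len(nrow(stage1))) {
    lhs <- res$e0 + sum(stage1$phi[-k])
    rhs <- res$v_full - stage1$phi[k]
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("efficiency and hierarchical consistency hold for all surrogate kinds", {
  for (kind in c("linear", "cross_set_interaction", "within_set_nonlinear")) {
    w <- toy_world(n = 8, seed = 31, kind = kind)
    for (s in w$cohort$subjects) {
      res <- multistage_shapley(w$tree, w$predictor, s, w$reference)
      chk <- verify_efficiency(res, tol = 1e-6)
      expect_true(chk$pass)
      # left + right hemisphere phis reproduce each set's phi
      tab <- res$table
      for (set in c("SET1", "SET2", "SET3")) {
        hemis <- tab$phi[tab$parent_id == paste0("root/", set)]
        expect_equal(sum(hemis), tab$phi[tab$node_id == paste0("root/", set)],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("multistage equals the flat brute-force game when interactions stay within blocks", {
  for (kind in c("linear", "within_set_nonlinear")) {
    w <- toy_world(n = 5, seed = 41, kind = kind)
    for (s in w$cohort$subjects) {
      res <- multistage_shapley(w$tree, w$predictor, s, w$reference)
      bf <- brute_force_shapley(w$predictor, s, w$reference, w$tree$atlas)
      expect_equal(res$leaf_phi, bf, tolerance = 1e-10)
    }
  }
})

test_that("cross-set interactions deviate from the flat game inside the interacting sets only", {
  w <- toy_world(n = 5, seed = 51, kind = "cross_set_interaction")
  ids <- w$predictor$meta$interaction_leaf_ids  # one leaf in SET1, one in SET2
  untouched <- 8:11  # SET3 leaves: outside both interacting level-1 sets
  worst_dev <- 0
  for (s in w$cohort$subjects) {
    res <- multistage_shapley(w$tree, w$predictor, s, w$reference)
    bf <- brute_force_shapley(w$predictor, s, w$reference, w$tree$atlas)
    diff <- abs(res$leaf_phi - bf)
    worst_dev <- max(worst_dev, max(diff[ids + 1L]))
    expect_lt(max(diff[untouched + 1L]), 1e-8)  # additive sets stay exact
    expect_true(verify_efficiency(res, tol = 1e-6)$pass)
  }
  expect_gt(worst_dev, 1e-4)  # the documented approximation error exists
})

test_that("the linear surrogate matches its closed-form attribution", {
  w <- toy_world(n = 10, seed = 61)
  for (s in w$cohort$subjects[1:5]) {
    res <- multistage_shapley(w$tree, w$predictor, s, w$reference)
    expect_equal(res$leaf_phi, linear_shapley_oracle(w$predictor, s, w$reference),
                 tolerance = 1e-9)
  }
})

test_that("a flat 8-set tree reproduces the flat 8-leaf game", {
  atlas8 <- region_atlas(data.frame(leaf_id = 0:7,
                                    leaf_name = paste0("R", 0:7),
                                    atlas_label = 1:8, hemisphere = "midline"))
  spec <- as.list(setNames(paste0("R", 0:7), paste0("G", 0:7)))
  tree <- partition_tree(spec, atlas8)
  set.seed(71)
  w <- rnorm(8)
  pred <- new_predictor(function(x) 50 + sum(w * x), e0 = 50)
  s <- subject_payload("s", 60, rnorm(8))
  r <- reference_payload(rnorm(8))
  res <- multistage_shapley(tree, pred, s, r)
  bf <- brute_force_shapley(pred, s, r, atlas8)
  expect_equal(unname(res$leaf_phi), unname(bf), tolerance = 1e-10)
})

test_that("a pure two-leaf interaction splits symmetrically", {
  pred <- new_predictor(function(x) x[1] * x[2], e0 = 0)
  s <- subject_payload("s", 60, c(1, 1))
  r <- reference_payload(c(0, 0), "zero")
  bf <- brute_force_shapley(pred, s, r, atlas2(), e0 = 0)
  expect_equal(unname(bf), c(0.5, 0.5))
  expect_error(
    brute_force_shapley(pred, subject_payload("s", 60, rnorm(21)),
                        reference_payload(rnorm(21)),
                        region_atlas(data.frame(leaf_id = 0:20,
                                                leaf_name = paste0("L", 0:20),
                                                atlas_label = 1:21,
                                                hemisphere = "midline"))),
    "refused")
})

test_that("null players get zero and exchangeable leaves get equal shares", {
  w <- toy_world(n = 5, seed = 81)
  weights <- w$predictor$meta$weights
  weights[3] <- 0  # leaf_id 2 ignored by the model
  # a coherent baseline (E0 = prediction at the reference payload) is what
  # makes the null-player axiom exact; any E0-reference gap is otherwise
  # shared 1/L across all leaves
  e0 <- sum(weights * w$reference$features)
  pred <- new_predictor(function(x) sum(weights * x), e0 = e0)
  s <- w$cohort$subjects[[1]]
  res <- multistage_shapley(w$tree, pred, s, w$reference)
  expect_lt(abs(res$leaf_phi[3]), 1e-9)

  # two leaves with identical roles and identical values
  feats <- s$features
  feats[1] <- feats[2]
  s2 <- subject_payload("sym", s$age, feats)
  ref2 <- reference_payload(rep(0.8, 12))
  wsym <- w$predictor$meta$weights
  wsym[2] <- wsym[1]
  pred_sym <- new_predictor(function(x) sum(wsym * x), e0 = 63.5)
  res_sym <- multistage_shapley(w$tree, pred_sym, s2, ref2)
  expect_equal(res_sym$leaf_phi[[1]], res_sym$leaf_phi[[2]], tolerance = 1e-12)
})

test_that("attributions are linear in the predictor", {
  w <- toy_world(n = 3, seed = 91)
  s <- w$cohort$subjects[[1]]
  set.seed(92)
  w1 <- rnorm(12); w2 <- rnorm(12)
  a <- 0.7; b <- -1.3
  p1 <- new_predictor(function(x) sum(w1 * x), e0 = 10)
  p2 <- new_predictor(function(x) sum(w2 * x), e0 = 4)
  p12 <- new_predictor(function(x) a * sum(w1 * x) + b * sum(w2 * x),
                       e0 = a * 10 + b * 4)
  r1 <- multistage_shapley(w$tree, p1, s, w$reference)$leaf_phi
  r2 <- multistage_shapley(w$tree, p2, s, w$reference)$leaf_phi
  r12 <- multistage_shapley(w$tree, p12, s, w$reference)$leaf_phi
  expect_equal(r12, a * r1 + b * r2, tolerance = 1e-9)
})

test_that("caching changes the evaluation count, never the attributions", {
  for (kind in c("linear", "cross_set_interaction")) {
    w <- toy_world(n = 3, seed = 101, kind = kind)
    w$predictor$batch_fn <- NULL  # scalar path both times
    s <- w$cohort$subjects[[1]]
    acc_on <- new_accountant(); acc_off <- new_accountant()
    res_on <- multistage_shapley(w$tree, w$predictor, s, w$reference,
                                 accountant = acc_on, use_cache = TRUE)
    res_off <- multistage_shapley(w$tree, w$predictor, s, w$reference,
                                  accountant = acc_off, use_cache = FALSE)
    expect_identical(res_on$leaf_phi, res_off$leaf_phi)  # bit-for-bit
    expect_lt(acc_on$n_eval, acc_off$n_eval)
  }
})

test_that("distinct evaluations match the cached-convention analytic count", {
  for (tree in list(toy_partition(), uneven_tree())) {
    spec <- cohort_spec(2, tree, seed = 111)
    cohort <- simulate_cohort(spec)
    pred <- make_predictor("linear", tree, spec)
    ref <- cohort_reference(cohort$subjects)
    expected <- count_operations(tree, "cached")$total
    for (use_batch in c(TRUE, FALSE)) {
      p <- pred
      if (!use_batch) p$batch_fn <- NULL
      acc <- new_accountant()
      multistage_shapley(tree, p, cohort$subjects[[1]], ref, accountant = acc)
      expect_equal(acc$n_eval, expected)
    }
  }
})

test_that("batch and scalar predictor paths agree", {
  w <- toy_world(n = 4, seed = 121, kind = "cross_set_interaction")
  s <- w$cohort$subjects[[1]]
  p_scalar <- w$predictor; p_scalar$batch_fn <- NULL
  res_b <- multistage_shapley(w$tree, w$predictor, s, w$reference)
  res_s <- multistage_shapley(w$tree, p_scalar, s, w$reference)
  expect_equal(res_b$leaf_phi, res_s$leaf_phi, tolerance = 1e-12)
})

test_that("verify_efficiency localizes a perturbed game", {
  w <- toy_world(n = 3, seed = 131)
  res <- multistage_shapley(w$tree, w$predictor, w$cohort$subjects[[1]],
                            w$reference)
  expect_true(verify_efficiency(res, tol = 1e-6)$pass)
  res$table$phi[res$table$node_id == "root/SET2/SET2.L"] <-
    res$table$phi[res$table$node_id == "root/SET2/SET2.L"] + 1.0
  chk <- verify_efficiency(res, tol = 1e-6)
  expect_false(chk$pass)
  failing <- chk$games$parent_id[!chk$games$pass]
  expect_true("root/SET2" %in% failing)
})
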