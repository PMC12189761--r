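# Reference curves, region contributions, and RBADI deviations.

# Minimal result objects: leaf vectors with controlled values.
fake_result <- function(id, age, phi, hash = "tree0") {
  structure(list(subject_id = id, age = age, v_full = NA_real_, e0 = 0,
                 leaf_phi = phi, tree_hash = hash,
                 manifest = list(tree_hash = hash, e0 = 0)),
            class = "shapley_result")
}

phi_names <- function(L) setNames(seq_len(L) * 0, paste0("R", seq_len(L)))

test_that("region contributions average leaf vectors", {
  r1 <- fake_result("a", 60, c(R1 = 1, R2 = -1))
  r2 <- fake_result("b", 62, c(R1 = 3, R2 = 1))
  cs <- region_contributions(list(r1, r2))
  expect_equal(cs$contribution, c(2, 0))
  expect_equal(attr(cs, "n"), 2L)
  expect_equal(region_contributions(list(r1))$contribution, c(1, -1))
  r3 <- fake_result("c", 61, c(R1 = 0, R2 = 0), hash = "other")
  expect_error(region_contributions(list(r1, r3)), "different partition trees")
})

test_that("contributions of an ignored leaf vanish through the cohort mean", {
  w <- toy_world(n = 12, seed = 141)
  weights <- w$predictor$meta$weights
  weights[5] <- 0
  e0 <- sum(weights * w$reference$features)  # coherent baseline: E0 = v(ref)
  pred <- new_predictor(function(x) sum(weights * x), e0 = e0,
                        batch_fn = function(X) as.numeric(X %*% weights))
  results <- multistage_shapley_cohort(w$tree, pred, w$cohort$subjects,
                                       w$reference)
  cs <- region_contributions(results)
  expect_lt(abs(cs$contribution[5]), 1e-9)
})

test_that("window-0 curves are exact per-age means and center their own cohort", {
  set.seed(151)
  ages <- rep(60:64, each = 8)
  results <- lapply(seq_along(ages), function(i) {
    fake_result(paste0("s", i), ages[i],
                setNames(rnorm(3), c("R1", "R2", "R3")))
  })
  curve <- build_reference(results, ages, window = 0L, min_n = 1L)
  M <- do.call(rbind, lapply(results, `[[`, "leaf_phi"))
  for (a in 60:64) {
    expect_equal(unname(curve$phi_std[match(a, curve$ages), ]),
                 unname(colMeans(M[ages == a, , drop = FALSE])))
  }
  # RBADI of the building cohort has exactly zero mean within each age
  tab <- cohort_rbadi(results, curve, ages = ages)
  for (a in 60:64) {
    sub <- tab[tab$rounded_age == a, c("R1", "R2", "R3")]
    expect_equal(unname(colMeans(sub)), c(0, 0, 0))
  }
})

test_that("pooled windows equal count-weighted moving averages of per-age means", {
  set.seed(161)
  ages <- sample(rep(70:75, times = c(4, 9, 2, 7, 5, 6)))
  results <- lapply(seq_along(ages), function(i) {
    fake_result(paste0("s", i), ages[i], setNames(rnorm(2), c("R1", "R2")))
  })
  curve <- build_reference(results, ages, window = 1L, min_n = 1L)
  M <- do.call(rbind, lapply(results, `[[`, "leaf_phi"))
  for (a in 70:75) {
    sel <- ages >= a - 1 & ages <= a + 1
    expect_equal(unname(curve$phi_std[match(a, curve$ages), ]),
                 unname(colMeans(M[sel, , drop = FALSE])))
    expect_equal(curve$n_per_age[match(a, curve$ages)], sum(sel))
  }
})

test_that("thin ages widen their window until min_n and record it", {
  ages <- c(rep(60, 12), rep(63, 12), 61)  # age 61 and 62 are thin
  results <- lapply(seq_along(ages), function(i) {
    fake_result(paste0("s", i), ages[i], c(R1 = ages[i] * 1.0))
  })
  curve <- build_reference(results, ages, window = 0L, min_n = 10L)
  k61 <- match(61, curve$ages)
  expect_gte(curve$n_per_age[k61], 10L)
  expect_gt(curve$window_used[k61], curve$window)
})

test_that("degenerate and empty reference cohorts are handled", {
  expect_error(build_reference(list(), numeric()), "empty")
  one_age <- lapply(1:5, function(i) fake_result(paste0("s", i), 70, c(R1 = 2)))
  expect_warning(curve <- build_reference(one_age, rep(70, 5), min_n = 1L),
                 "single integer age")
  expect_equal(unname(curve$phi_std[1, ]), 2)
})

test_that("RBADI subtracts the age-standard vector at the rounded age", {
  ages <- rep(60:70, each = 12)
  set.seed(171)
  results <- lapply(seq_along(ages), function(i) {
    fake_result(paste0("s", i), ages[i], setNames(rnorm(2), c("R1", "R2")))
  })
  curve <- build_reference(results, ages)
  at <- curve$phi_std[match(65, curve$ages), ]
  same <- fake_result("same", 65.2, at)
  rb <- compute_rbadi(same, curve)
  expect_equal(unname(rb$deviations), c(0, 0))
  expect_equal(rb$rounded_age, 65L)
  shifted <- fake_result("shift", 64.9, at + c(0.7, 0))
  rb2 <- compute_rbadi(shifted, curve)
  expect_equal(unname(rb2$deviations), c(0.7, 0))
  # out-of-range ages clamp with a flag
  old <- fake_result("old", 95, at)
  rb3 <- compute_rbadi(old, curve)
  expect_true(rb3$clamped)
  expect_equal(rb3$age_used, 70L)
  # tree mismatch refused
  other <- fake_result("x", 65, at, hash = "other")
  expect_error(compute_rbadi(other, curve), "different partition trees")
})

test_that("ages round half away from zero", {
  expect_equal(rbadi:::round_half_away(c(64.5, 63.49, -2.5)), c(65, 63, -3))
})

test_that("cohort_rbadi vectorizes with group pass-through", {
  expect_equal(nrow(cohort_rbadi(list(),
                                 structure(list(leaf_names = c("R1", "R2")),
                                           class = "reference_curve"))), 0L)
  ages <- rep(60:64, each = 10)
  set.seed(181)
  results <- lapply(seq_along(ages), function(i) {
    fake_result(paste0("s", i), ages[i], setNames(rnorm(2), c("R1", "R2")))
  })
  curve <- build_reference(results, ages, window = 0L, min_n = 1L)
  tab <- cohort_rbadi(results, curve, group = rep(c("hc", "dz"), 25))
  expect_equal(nrow(tab), 50L)
  expect_setequal(unique(tab$group), c("hc", "dz"))
  expect_true(all(c("rounded_age", "age_used", "clamped", "R1", "R2") %in% names(tab)))
})

test_that("constant shifts move curve and deviations consistently", {
  ages <- rep(60:64, each = 10)
  set.seed(191)
  base_phis <- lapply(seq_along(ages), function(i) setNames(rnorm(2), c("R1", "R2")))
  results <- lapply(seq_along(ages), function(i) {
    fake_result(paste0("s", i), ages[i], base_phis[[i]])
  })
  shifted <- lapply(seq_along(ages), function(i) {
    fake_result(paste0("s", i), ages[i], base_phis[[i]] + c(3, 0))
  })
  c0 <- build_reference(results, ages, window = 1L, min_n = 1L)
  c1 <- build_reference(shifted, ages, window = 1L, min_n = 1L)
  expect_equal(c1$phi_std[, "R1"], c0$phi_std[, "R1"] + 3)
  # healthy-cohort RBADI is invariant under the shift
  t0 <- cohort_rbadi(results, c0)
  t1 <- cohort_rbadi(shifted, c1)
  expect_equal(t1$R1, t0$R1, tolerance = 1e-12)
})
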