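# Shared fixtures and independent oracles, built in code at test time.

# Independent Shapley oracle: average marginal contribution over all m!
# player orderings. Takes the same coalition-value function signature as
# exact_within_set_shapley (integer member indices, never empty).
perm_shapley <- function(value, m, baseline) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    }
    out
  }
  phi <- numeric(m)
  orderings <- perms(seq_len(m))
  for (ord in orderings) {
    prev <- baseline
    for (pos in seq_len(m)) {
      cur <- value(sort(ord[seq_len(pos)]))
      phi[ord[pos]] <- phi[ord[pos]] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(orderings)
}

# Two-leaf atlas used across minimal-tree tests.
atlas2 <- function() {
  region_atlas(data.frame(leaf_id = 0:1, leaf_name = c("A1", "B1"),
                          atlas_label = 1:2,
                          hemisphere = c("left", "right")))
}

# A calibrated toy world: 12-leaf tree, cohort, surrogate, mean reference.
toy_world <- function(n = 30, seed = 7, kind = "linear", noise_sd = 0.11) {
  tree <- toy_partition()
  spec <- cohort_spec(n, tree, noise_sd = noise_sd, seed = seed)
  cohort <- simulate_cohort(spec)
  predictor <- make_predictor(kind, tree, spec)
  reference <- cohort_reference(cohort$subjects)
  list(tree = tree, spec = spec, cohort = cohort, predictor = predictor,
       reference = reference)
}

# An uneven tree: mixed game sizes and a pass-through, 9 leaves.
uneven_tree <- function() {
  atlas <- region_atlas(data.frame(
    leaf_id = 0:8,
    leaf_name = paste0("L", 0:8),
    atlas_label = 1:9,
    hemisphere = c(rep("left", 4), rep("right", 3), "midline", "midline")))
  spec <- list(
    X = list(X.a = c("L0", "L1", "L2"), X.b = "L3"),
    Y = list(Y.a = c("L4", "L5"), Y.b = "L6"),
    Z = list(Z.mid = c("L7", "L8")))
  partition_tree(spec, atlas)
}
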