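# Exact within-set Shapley games and the multistage driver with adjusted
# baselines. Stage 1 plays one game among the root's anatomical sets with the
# training-mean baseline E0; every later stage replays each parent node's
# children with the baseline v(full) - phi(parent), which absorbs all other
# same-level contributions and makes the child values sum exactly to the
# parent's (hierarchical consistency).

#' Multistage Shapley configuration
#'
#' @param tol Absolute tolerance (years) for the efficiency and consistency
#'   identities; violations beyond `10 * tol` flag the result with a warning
#'   rather than aborting (third-party predictors may be mildly
#'   non-deterministic; the user decides).
#' @param max_game_size Refuse games with more members (2^m blow-up guard).
#' @return A list of class `shapley_config`.
#' @export
shapley_config <- function(tol = 1e-6, max_game_size = 20L) {
  stopifnot(tol >= 0, max_game_size >= 2)
  structure(list(tol = tol, max_game_size = as.integer(max_game_size)),
            class = "shapley_config")
}

# phi for all m members from the 2^m coalition values.
# v: numeric vector indexed by coalition bitmask + 1; v[1] is the baseline.
# Weights |S|!(m-|S|-1)!/m! computed as 1/(m*choose(m-1,|S|)), exact in
# double precision for m <= 20. Subsets enumerated by bitmask.
shapley_from_values <- function(v, m) {
  n_masks <- 2L^m
  stopifnot(length(v) == n_masks)
  sizes <- popcount(0:(n_masks - 1L))
  w <- 1 / (m * choose(m - 1L, 0:(m - 1L)))
  masks <- 0:(n_masks - 1L)
  phi <- numeric(m)
  for (j in 0:(m - 1L)) {
    bit <- bitwShiftL(1L, j)
    S <- masks[bitwAnd(masks, bit) == 0L]
    phi[j + 1L] <- sum(w[sizes[S + 1L] + 1L] * (v[S + bit + 1L] - v[S + 1L]))
  }
  phi
}

#' Exact Shapley values for one within-set game
#'
#' @param value Function taking an integer vector of member indices (subset
#'   of `1:m`, never empty) and returning the coalition's value in years.
#' @param members Character labels of the game's members.
#' @param baseline Value assigned to the empty coalition (years).
#' @param max_game_size Guard against combinatorial blow-up.
#' @return Named numeric vector of member attributions; they sum to
#'   `value(1:m) - baseline` up to floating round-off.
#' @export
exact_within_set_shapley <- function(value, members, baseline,
                                     max_game_size = 20L) {
  m <- length(members)
  if (m > max_game_size) {
    stop("game with ", m, " members exceeds max_game_size = ", max_game_size)
  }
  v <- numeric(2L^m)
  v[1L] <- baseline
  for (mask in 1:(2L^m - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    v[mask + 1L] <- value(idx)
  }
  setNames(shapley_from_values(v, m), members)
}

#' Adjusted baseline for a child game
#'
#' The empty-coalition value of the game inside a parent node: the full
#' prediction minus the parent's own attribution. Equivalently `E0` plus the
#' attributions of every other same-level node, which is what makes the
#' children's values sum back to the parent's.
#'
#' @param v_full Full-payload prediction (years).
#' @param parent_phi The parent node's attribution (years).
#' @return Baseline in years.
#' @export
adjusted_baseline <- function(v_full, parent_phi) {
  stopifnot(is.finite(v_full), is.finite(parent_phi))
  v_full - parent_phi
}

#' Multistage hierarchical Shapley attribution for one subject
#'
#' Plays one exact Shapley game per internal tree node, top-down. The root's
#' game uses the predictor baseline `E0`; the game inside node `p` uses the
#' adjusted baseline `v_full - phi(p)`, holds every leaf outside `p` at the
#' subject's values, activates the leaves under the child coalition and masks
#' the rest of `p` with the reference payload. Empty coalitions take the
#' baseline unevaluated; a node with a single child passes its attribution
#' through without a game. The result carries attributions for every tree
#' node plus the final leaf-level vector.
#'
#' @param tree A `partition_tree`.
#' @param predictor A [new_predictor()]; its `e0` is the stage-1 baseline.
#' @param subject A [subject_payload()].
#' @param reference A [reference_payload()] for masking.
#' @param config A [shapley_config()].
#' @param accountant Optional [new_accountant()] (one is created if missing).
#' @param use_cache Serve repeated coalitions from a per-subject cache.
#' @param plan Precomputed `plan_games(tree)`; pass when looping over a
#'   cohort to avoid re-walking the tree.
#' @return A `shapley_result`: per-node table, leaf vector, diagnostics and a
#'   manifest.
#' @export
multistage_shapley <- function(tree, predictor, subject, reference,
                               config = shapley_config(),
                               accountant = NULL, use_cache = TRUE,
                               plan = NULL) {
  if (is.null(plan)) plan <- plan_games(tree)
  atlas <- tree$atlas
  L <- nrow(atlas)
  if (is.numeric(subject$features) && length(subject$features) != L) {
    stop("subject '", subject$subject_id, "' has ", length(subject$features),
         " features; atlas has ", L, " leaves")
  }
  if (is.null(accountant)) accountant <- new_accountant()
  cache <- if (use_cache) new_eval_cache() else NULL
  e0 <- predictor$e0

  v_full <- evaluate_coalition(predictor, subject, atlas$leaf_id, reference,
                               cache = cache, accountant = accountant,
                               atlas = atlas, stage = 0L)

  phi_tab <- new.env(parent = emptyenv())
  phi_tab[["root"]] <- v_full - e0
  rows <- vector("list", length(plan))

  for (gi in seq_along(plan)) {
    g <- plan[[gi]]
    parent_phi <- phi_tab[[g$parent_id]]
    baseline <- adjusted_baseline(v_full, parent_phi)
    if (g$m == 1L) {
      phis <- parent_phi
    } else {
      if (g$m > config$max_game_size) {
        stop("game at '", g$parent_id, "' has ", g$m,
             " members; exceeds max_game_size = ", config$max_game_size)
      }
      v <- numeric(2L^g$m)
      v[1L] <- baseline
      bits <- bitwShiftL(1L, 0:(g$m - 1L))
      pending <- list()   # masked payload rows awaiting a batch prediction
      pend_mask <- integer()
      for (mask in 1:(2L^g$m - 1L)) {
        sel <- bitwAnd(mask, bits) != 0L
        active <- c(g$outside_leaves,
                    unlist(g$member_leafsets[sel], use.names = FALSE))
        if (!is.null(predictor$batch_fn) && is.numeric(subject$features)) {
          active <- sort(active)
          key <- mask_key(active)
          if (!is.null(cache) && !is.null(cache[[key]])) {
            account_hit(accountant)
            v[mask + 1L] <- cache[[key]]
          } else {
            pending[[length(pending) + 1L]] <-
              apply_mask(subject, active, reference, atlas = atlas)
            pend_mask <- c(pend_mask, mask)
          }
        } else {
          v[mask + 1L] <- evaluate_coalition(
            predictor, subject, active, reference, cache = cache,
            accountant = accountant, atlas = atlas, stage = g$stage)
        }
      }
      if (length(pending)) {
        preds <- unname(predictor$batch_fn(do.call(rbind, pending)))
        if (any(!is.finite(preds))) {
          stop("predictor returned a non-finite value for subject '",
               subject$subject_id, "' in game '", g$parent_id, "'")
        }
        for (k in seq_along(pend_mask)) {
          mask <- pend_mask[k]
          v[mask + 1L] <- preds[k]
          sel <- bitwAnd(mask, bits) != 0L
          active <- sort(c(g$outside_leaves,
                           unlist(g$member_leafsets[sel], use.names = FALSE)))
          if (!is.null(cache)) cache[[mask_key(active)]] <- preds[k]
          account_eval(accountant, g$stage)
        }
      }
      phis <- shapley_from_values(v, g$m)
    }
    for (k in seq_along(g$member_ids)) phi_tab[[g$member_ids[k]]] <- phis[k]
    rows[[gi]] <- data.frame(
      stage = g$stage, node_id = g$member_ids, label = g$member_labels,
      parent_id = g$parent_id, phi = unname(phis), baseline = unname(baseline),
      pass_through = g$m == 1L, stringsAsFactors = FALSE)
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  leaf_phi <- vapply(atlas$leaf_name, function(nm) phi_tab[[nm]], 0)

  # diagnostics: per-game consistency and stage-1 efficiency
  cons <- vapply(plan, function(g) {
    parent_phi <- if (g$parent_id == "root") v_full - e0 else phi_tab[[g$parent_id]]
    abs(sum(vapply(g$member_ids, function(id) phi_tab[[id]], 0)) - parent_phi)
  }, 0)
  stage1 <- table$phi[table$parent_id == "root"]
  eff <- abs(sum(stage1) - (v_full - e0))
  flagged <- eff > 10 * config$tol || max(cons) > 10 * config$tol
  if (flagged) {
    warning("identity residuals exceed 10x tolerance for subject '",
            subject$subject_id, "' (efficiency ", format(eff),
            ", consistency ", format(max(cons)), ")")
  }

  structure(list(
    subject_id = subject$subject_id,
    age = subject$age,
    v_full = v_full,
    e0 = e0,
    table = table,
    leaf_phi = leaf_phi,
    diagnostics = list(efficiency_residual = eff,
                       max_consistency_residual = max(cons),
                       flagged = flagged),
    accountant = accountant,
    tree_hash = tree$hash,
    manifest = list(predictor = predictor$name,
                    masking = reference$provenance,
                    e0 = e0, tol = config$tol, tree_hash = tree$hash)
  ), class = "shapley_result")
}

#' Multistage attribution over a cohort
#'
#' @param tree,predictor,reference,config As in [multistage_shapley()].
#' @param subjects List of [subject_payload()]s.
#' @return List of `shapley_result`s, one per subject.
#' @export
multistage_shapley_cohort <- function(tree, predictor, subjects, reference,
                                      config = shapley_config()) {
  plan <- plan_games(tree)
  lapply(subjects, function(s) {
    multistage_shapley(tree, predictor, s, reference, config = config,
                       plan = plan)
  })
}

#' Flat exact Shapley over individual leaves (test oracle)
#'
#' The unstaged game the multistage workflow approximates: one coalition per
#' subset of leaves, \eqn{2^L} values, feasible only for small L. Leaves
#' outside `leaves` (when a subset is given) are held at subject values.
#'
#' @param predictor A [new_predictor()].
#' @param subject A [subject_payload()].
#' @param reference A [reference_payload()].
#' @param leaves Leaf_ids forming the game; default all atlas leaves.
#' @param atlas The [region_atlas()]; default inferred length for vector
#'   payloads is not attempted — pass the atlas used to build the payloads.
#' @param e0 Empty-coalition value; defaults to `predictor$e0`.
#' @return Named numeric vector of per-leaf attributions.
#' @export
brute_force_shapley <- function(predictor, subject, reference, atlas,
                                leaves = NULL, e0 = predictor$e0) {
  if (is.null(leaves)) leaves <- atlas$leaf_id
  m <- length(leaves)
  if (m > 20L) stop("flat game over ", m, " leaves refused (2^m blow-up)")
  outside <- setdiff(atlas$leaf_id, leaves)
  n_masks <- 2L^m
  bits <- bitwShiftL(1L, 0:(m - 1L))
  v <- numeric(n_masks)
  v[1L] <- e0
  if (!is.null(predictor$batch_fn) && is.numeric(subject$features)) {
    payloads <- matrix(0, n_masks - 1L, length(subject$features))
    for (mask in 1:(n_masks - 1L)) {
      sel <- bitwAnd(mask, bits) != 0L
      payloads[mask, ] <- apply_mask(subject, c(outside, leaves[sel]),
                                     reference, atlas = atlas)
    }
    v[2:n_masks] <- unname(predictor$batch_fn(payloads))
  } else {
    for (mask in 1:(n_masks - 1L)) {
      sel <- bitwAnd(mask, bits) != 0L
      v[mask + 1L] <- evaluate_coalition(predictor, subject,
                                         c(outside, leaves[sel]), reference,
                                         atlas = atlas, stage = NA)
    }
  }
  setNames(shapley_from_values(v, m),
           atlas$leaf_name[match(leaves, atlas$leaf_id)])
}

#' Check the efficiency and consistency identities of a result
#'
#' Efficiency: stage-1 attributions sum to `v_full - E0`. Consistency: within
#' every game the children's attributions sum to the parent's.
#'
#' @param result A `shapley_result`.
#' @param tol Absolute tolerance in years.
#' @return A list with `pass`, `efficiency_residual`, and a per-game
#'   data.frame `games` (`parent_id`, `residual`, `pass`).
#' @export
verify_efficiency <- function(result, tol = 1e-6) {
  tab <- result$table
  phi_of <- function(id) {
    if (id == "root") return(result$v_full - result$e0)
    tab$phi[match(id, tab$node_id)]
  }
  parents <- unique(tab$parent_id)
  res <- vapply(parents, function(p) {
    abs(sum(tab$phi[tab$parent_id == p]) - phi_of(p))
  }, 0)
  games <- data.frame(parent_id = parents, residual = unname(res),
                      pass = unname(res) <= tol, stringsAsFactors = FALSE)
  eff <- abs(sum(tab$phi[tab$parent_id == "root"]) - (result$v_full - result$e0))
  list(pass = all(games$pass) && eff <= tol,
       efficiency_residual = eff, games = games)
}

#' @export
print.shapley_result <- function(x, ...) {
  cat("shapley_result for subject", x$subject_id, "\n")
  cat(sprintf("  v_full = %.3f years, E0 = %.3f, v_full - E0 = %.3f\n",
              x$v_full, x$e0, x$v_full - x$e0))
  cat(sprintf("  %d leaf attributions; efficiency residual %.2e, max consistency residual %.2e%s\n",
              length(x$leaf_phi), x$diagnostics$efficiency_residual,
              x$diagnostics$max_consistency_residual,
              if (x$diagnostics$flagged) " [FLAGGED]" else ""))
  top <- sort(abs(x$leaf_phi), decreasing = TRUE)[1:min(5, length(x$leaf_phi))]
  cat("  largest |phi|:", paste(sprintf("%s=%.3f", names(top), x$leaf_phi[names(top)]),
                                collapse = ", "), "\n")
  invisible(x)
}
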