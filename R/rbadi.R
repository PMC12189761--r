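# Age-standard Shapley reference curves and the Regional Brain Aging
# Disparity Index: a subject's leaf-level attribution vector minus the mean
# attribution of strictly healthy peers of the same (rounded) age.

leaf_matrix <- function(results) {
  hashes <- unique(vapply(results, `[[`, "", "tree_hash"))
  if (length(hashes) != 1L) {
    stop("results computed on different partition trees (", length(hashes),
         " distinct tree hashes)")
  }
  M <- do.call(rbind, lapply(results, `[[`, "leaf_phi"))
  rownames(M) <- vapply(results, `[[`, "", "subject_id")
  M
}

#' Mean regional contributions over a reference cohort
#'
#' The per-leaf arithmetic mean of the leaf-level attribution vectors over a
#' (strictly healthy) cohort: the population-level importance of each region
#' for the predictor.
#'
#' @param results List of `shapley_result`s sharing one tree.
#' @return A `contribution_summary`: data.frame (`leaf_name`, `contribution`)
#'   with attributes `n` (cohort size) and `tree_hash`.
#' @export
region_contributions <- function(results) {
  if (length(results) == 0L) stop("empty cohort of results")
  M <- leaf_matrix(results)
  out <- data.frame(leaf_name = colnames(M), contribution = colMeans(M),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- nrow(M)
  attr(out, "tree_hash") <- results[[1]]$tree_hash
  class(out) <- c("contribution_summary", "data.frame")
  out
}

#' Build an age-standard Shapley reference curve
#'
#' For every integer age `a` spanned by the cohort's rounded ages, the curve
#' holds the pooled mean leaf-attribution vector over all reference subjects
#' whose rounded age lies in `[a - window, a + window]` (endpoints
#' inclusive). Ages with fewer than `min_n` contributors have their window
#' widened symmetrically by one year at a time until `min_n` is reached; the
#' widening is recorded per age. Ages are rounded half away from zero.
#'
#' @param results List of `shapley_result`s from the reference cohort.
#' @param ages Chronological ages in years, one per result.
#' @param window Half-width of the age window in years (default 1).
#' @param min_n Minimum contributors per retained age (default 10).
#' @return A `reference_curve`: list with `ages` (integer grid), `phi_std`
#'   (age x leaf matrix), `n_per_age`, `window`, `window_used` (after any
#'   widening), `tree_hash`, `leaf_names`.
#' @export
build_reference <- function(results, ages, window = 1L, min_n = 10L) {
  if (length(results) == 0L) stop("empty reference cohort")
  if (length(ages) != length(results)) {
    stop("ages and results differ in length")
  }
  M <- leaf_matrix(results)
  r_age <- as.integer(round_half_away(ages))
  grid <- seq(min(r_age), max(r_age))
  if (length(grid) < 2L) {
    warning("reference cohort spans a single integer age; degenerate curve")
  }
  phi_std <- matrix(NA_real_, length(grid), ncol(M),
                    dimnames = list(grid, colnames(M)))
  n_per_age <- integer(length(grid))
  window_used <- integer(length(grid))
  for (k in seq_along(grid)) {
    w <- as.integer(window)
    repeat {
      sel <- r_age >= grid[k] - w & r_age <= grid[k] + w
      if (sum(sel) >= min_n || w > diff(range(r_age))) break
      w <- w + 1L
    }
    if (sum(sel) == 0L) stop("no reference subjects near age ", grid[k])
    phi_std[k, ] <- colMeans(M[sel, , drop = FALSE])
    n_per_age[k] <- sum(sel)
    window_used[k] <- w
  }
  structure(list(ages = grid, phi_std = phi_std, n_per_age = n_per_age,
                 window = as.integer(window), window_used = window_used,
                 min_n = as.integer(min_n),
                 tree_hash = results[[1]]$tree_hash,
                 leaf_names = colnames(M)),
            class = "reference_curve")
}

curve_at_age <- function(curve, rounded_age) {
  clamped <- min(max(rounded_age, min(curve$ages)), max(curve$ages))
  list(phi_std = curve$phi_std[match(clamped, curve$ages), ],
       clamped = clamped != rounded_age, age_used = clamped)
}

#' Regional Brain Aging Disparity Index for one subject
#'
#' The subject's leaf-level attribution vector minus the age-standard vector
#' at their rounded chronological age. Positive entries mark regions
#' contributing more predicted age than same-aged healthy peers. Applies to
#' any group (healthy, chronic disease, MCI/AD, prodromal/confirmed PD);
#' only the curve must come from the strictly healthy reference.
#'
#' @param result A `shapley_result`.
#' @param age Chronological age in years (defaults to the result's age).
#' @param curve A [build_reference()] curve sharing the result's tree.
#' @return An `rbadi_vector`: list with `subject_id`, `rounded_age`,
#'   `age_used`, `clamped`, `deviations` (named numeric, years).
#' @export
compute_rbadi <- function(result, curve, age = result$age) {
  if (!identical(result$tree_hash, curve$tree_hash)) {
    stop("result and reference curve come from different partition trees")
  }
  r_age <- as.integer(round_half_away(age))
  at <- curve_at_age(curve, r_age)
  structure(list(subject_id = result$subject_id,
                 rounded_age = r_age,
                 age_used = at$age_used,
                 clamped = at$clamped,
                 deviations = result$leaf_phi - at$phi_std),
            class = "rbadi_vector")
}

#' RBADI table for a cohort
#'
#' @param results List of `shapley_result`s.
#' @param curve A [build_reference()] curve.
#' @param ages Ages in years; default taken from the results.
#' @param group Optional group labels carried through to the output.
#' @return A data.frame: `subject_id`, `group`, `age`, `rounded_age`,
#'   `age_used`, `clamped`, then one column per leaf.
#' @export
cohort_rbadi <- function(results, curve,
                         ages = vapply(results, `[[`, 0, "age"),
                         group = NA_character_) {
  if (length(results) == 0L) {
    out <- data.frame(subject_id = character(), group = character(),
                      age = numeric(), rounded_age = integer(),
                      age_used = integer(), clamped = logical())
    for (nm in curve$leaf_names) out[[nm]] <- numeric()
    return(out)
  }
  group <- rep_len(group, length(results))
  rows <- lapply(seq_along(results), function(i) {
    rb <- compute_rbadi(results[[i]], curve, age = ages[i])
    cbind(data.frame(subject_id = rb$subject_id, group = group[i],
                     age = ages[i], rounded_age = rb$rounded_age,
                     age_used = rb$age_used, clamped = rb$clamped,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(rb$deviations), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.reference_curve <- function(x, ...) {
  cat("reference_curve: ages", min(x$ages), "-", max(x$ages),
      "(window +/-", x$window, "years,", length(x$leaf_names), "leaves)\n")
  cat("  contributors per age:", paste(range(x$n_per_age), collapse = "-"), "\n")
  if (any(x$window_used > x$window)) {
    cat("  window widened at", sum(x$window_used > x$window), "age(s) to reach min_n =",
        x$min_n, "\n")
  }
  invisible(x)
}

#' @export
print.rbadi_vector <- function(x, ...) {
  cat("rbadi_vector for subject", x$subject_id, "(rounded age", x$rounded_age)
  if (x$clamped) cat(", clamped to", x$age_used)
  cat(")\n")
  top <- order(abs(x$deviations), decreasing = TRUE)[1:min(5, length(x$deviations))]
  cat("  largest |deviation|:",
      paste(sprintf("%s=%+.3f", names(x$deviations)[top], x$deviations[top]),
            collapse = ", "), "\n")
  invisible(x)
}
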