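# Coalition valuation: turns a black-box age predictor into the value
# function v(S) by replacing inactive leaves with reference values.

#' Construct a subject payload
#'
#' @param subject_id Character id.
#' @param age Chronological age in years.
#' @param features Either a numeric vector with one entry per atlas leaf
#'   (leaf_id order), or a volume payload from [volume_features()].
#' @param sex Optional categorical.
#' @return A `subject_payload`.
#' @export
subject_payload <- function(subject_id, age, features, sex = NA_character_) {
  if (is.numeric(features)) {
    if (!all(is.finite(features))) stop("non-finite feature values for ", subject_id)
  } else if (!inherits(features, "volume_features")) {
    stop("features must be a numeric vector or volume_features")
  }
  structure(list(subject_id = as.character(subject_id), age = as.numeric(age),
                 sex = sex, features = features),
            class = "subject_payload")
}

#' Volume-form features: a 3D array plus an integer-labelled atlas grid
#'
#' @param volume Numeric 3D array (e.g. a gray-matter density map).
#' @param labels Integer array of identical shape; voxel values are atlas
#'   labels (0 = background).
#' @return A `volume_features` object.
#' @export
volume_features <- function(volume, labels) {
  if (!identical(dim(volume), dim(labels))) {
    stop("volume and label grids have different shapes")
  }
  structure(list(volume = volume, labels = labels), class = "volume_features")
}

#' Reference payload used to mask inactive leaves
#'
#' @param features Same feature form as the subjects it will mask.
#' @param provenance One of `"zero"`, `"cohort_mean"`, `"user_supplied"`.
#' @return A `reference_payload`.
#' @export
reference_payload <- function(features,
                              provenance = c("user_supplied", "zero", "cohort_mean")) {
  provenance <- match.arg(provenance)
  if (is.numeric(features) && !all(is.finite(features))) {
    stop("non-finite reference values")
  }
  structure(list(features = features, provenance = provenance),
            class = "reference_payload")
}

#' Element-wise mean reference over a cohort
#'
#' The default masking payload: replacing a leaf with the cohort mean keeps
#' masked inputs near the data manifold for smooth predictors.
#'
#' @param cohort List of [subject_payload()]s with homogeneous feature form.
#' @return A `reference_payload` with provenance `"cohort_mean"`.
#' @export
cohort_reference <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  feats <- lapply(cohort, `[[`, "features")
  vec <- vapply(feats, is.numeric, logical(1))
  if (all(vec)) {
    M <- do.call(rbind, feats)
    reference_payload(colMeans(M), "cohort_mean")
  } else if (!any(vec)) {
    vols <- lapply(feats, `[[`, "volume")
    mean_vol <- Reduce(`+`, vols) / length(vols)
    reference_payload(volume_features(mean_vol, feats[[1]]$labels), "cohort_mean")
  } else {
    stop("cohort mixes vector and volume feature forms")
  }
}

#' Coalition mask
#'
#' @param active_leaves Integer vector of active (unmasked) leaf_ids.
#' @param atlas Optional [region_atlas()] to validate against.
#' @return Integer vector of class `coalition_mask`.
#' @export
coalition_mask <- function(active_leaves, atlas = NULL) {
  active <- sort(unique(as.integer(active_leaves)))
  if (!is.null(atlas) && length(setdiff(active, atlas$leaf_id))) {
    stop("mask references leaves outside the atlas")
  }
  structure(active, class = "coalition_mask")
}

#' Mask a payload down to a coalition
#'
#' Leaves in the mask keep the subject's values; every other leaf carries the
#' reference value. Vector payloads swap entries; volume payloads swap all
#' voxels whose atlas label belongs to an inactive leaf. Inputs are not
#' modified.
#'
#' @param subject A [subject_payload()].
#' @param mask Integer vector (or [coalition_mask()]) of active leaf_ids.
#' @param reference A [reference_payload()] of compatible shape.
#' @param atlas Required for volume payloads (maps leaf_ids to voxel labels).
#' @return The masked features, in the subject's feature form.
#' @export
apply_mask <- function(subject, mask, reference, atlas = NULL) {
  x <- subject$features
  r <- reference$features
  active <- as.integer(mask)
  if (is.numeric(x)) {
    if (!is.numeric(r) || length(r) != length(x)) {
      stop("reference payload incompatible with subject payload")
    }
    out <- r
    out[active + 1L] <- x[active + 1L]
    names(out) <- names(x)
    out
  } else {
    if (!inherits(r, "volume_features") ||
        !identical(dim(x$volume), dim(r$volume))) {
      stop("reference payload incompatible with subject payload")
    }
    if (is.null(atlas)) stop("volume masking requires an atlas")
    inactive <- setdiff(atlas$leaf_id, active)
    inactive_labels <- atlas$atlas_label[match(inactive, atlas$leaf_id)]
    vol <- x$volume
    swap <- x$labels %in% inactive_labels
    vol[swap] <- r$volume[swap]
    volume_features(vol, x$labels)
  }
}

#' Wrap a deterministic age predictor
#'
#' The contract: `fn` maps a feature payload (numeric leaf vector, or
#' `volume_features`) to a predicted age in years, deterministically — the
#' Shapley decomposition is ill-defined under a stochastic value function, so
#' dropout or other eval-mode concerns are the caller's responsibility. `e0`
#' is the declared baseline, conventionally the mean chronological age of the
#' predictor's training targets.
#'
#' @param fn Function features -> predicted age (years).
#' @param e0 Baseline value in years for the empty coalition.
#' @param name Label recorded in manifests.
#' @param batch_fn Optional vectorized form: a function taking a matrix (one
#'   payload per row) and returning one prediction per row; used by batch
#'   drivers, never required.
#' @return A `predictor`.
#' @export
new_predictor <- function(fn, e0, name = "user", batch_fn = NULL) {
  stopifnot(is.function(fn), is.finite(e0))
  structure(list(fn = fn, e0 = as.numeric(e0), name = name, batch_fn = batch_fn),
            class = "predictor")
}

#' Evaluation accountant
#'
#' Tracks model evaluations, cache hits and distinct coalitions per stage;
#' the audited counts are compared against [count_operations()] analytics.
#'
#' @return An environment of class `eval_accountant` with fields `n_eval`,
#'   `n_hit`, and `per_stage` (named vector of evaluations by stage).
#' @export
new_accountant <- function() {
  acc <- new.env(parent = emptyenv())
  acc$n_eval <- 0L
  acc$n_hit <- 0L
  acc$per_stage <- numeric()
  class(acc) <- "eval_accountant"
  acc
}

account_eval <- function(acc, stage) {
  if (is.null(acc)) return(invisible())
  acc$n_eval <- acc$n_eval + 1L
  key <- paste0("stage", stage)
  acc$per_stage[key] <- (if (key %in% names(acc$per_stage)) acc$per_stage[[key]] else 0) + 1
  invisible()
}

account_hit <- function(acc) {
  if (is.null(acc)) return(invisible())
  acc$n_hit <- acc$n_hit + 1L
  invisible()
}

#' @export
print.eval_accountant <- function(x, ...) {
  cat("eval_accountant:", x$n_eval, "model evaluations,", x$n_hit, "cache hits\n")
  if (length(x$per_stage)) print(x$per_stage)
  invisible(x)
}

new_eval_cache <- function() new.env(parent = emptyenv())

mask_key <- function(active) paste(active, collapse = ",")

#' Evaluate the value function on one coalition
#'
#' Returns the predictor's output on the masked payload. Identical
#' (subject, mask) pairs within a run are served from the cache and counted
#' as hits; every miss increments the accountant. Empty coalitions are never
#' evaluated — callers assign them the stage baseline.
#'
#' @param predictor A [new_predictor()].
#' @param subject A [subject_payload()].
#' @param mask Active leaf_ids.
#' @param reference A [reference_payload()].
#' @param cache Optional environment from `new_eval_cache()`.
#' @param accountant Optional [new_accountant()].
#' @param atlas Needed for volume payloads.
#' @param stage Stage label for accounting.
#' @return Predicted age in years.
#' @export
evaluate_coalition <- function(predictor, subject, mask, reference,
                               cache = NULL, accountant = NULL,
                               atlas = NULL, stage = NA) {
  active <- sort(unique(as.integer(mask)))
  key <- mask_key(active)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    account_hit(accountant)
    return(cache[[key]])
  }
  payload <- apply_mask(subject, active, reference, atlas = atlas)
  v <- unname(predictor$fn(payload))
  if (!is.finite(v)) {
    stop("predictor returned a non-finite value for subject '",
         subject$subject_id, "', coalition {", key, "}")
  }
  account_eval(accountant, stage)
  if (!is.null(cache)) cache[[key]] <- v
  v
}
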