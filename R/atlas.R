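#' Region atlas tables
#'
#' A region atlas is the flat list of leaf regions the partition tree is built
#' over: one row per region with a dense 0-based `leaf_id`, a unique
#' `leaf_name` (e.g. `"Thalamus.L"`), the positive integer `atlas_label`
#' matching voxel values in an optional labelled volume, and a `hemisphere`
#' tag (`left`, `right` or `midline`).
#'
#' @param df A data.frame with columns `leaf_id`, `leaf_name`, `atlas_label`,
#'   `hemisphere`.
#' @return An object of class `region_atlas` (a validated data.frame).
#' @export
region_atlas <- function(df) {
  req <- c("leaf_id", "leaf_name", "atlas_label", "hemisphere")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("atlas table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$leaf_id <- as.integer(df$leaf_id)
  df$atlas_label <- as.integer(df$atlas_label)
  df$leaf_name <- as.character(df$leaf_name)
  df$hemisphere <- as.character(df$hemisphere)
  n <- nrow(df)
  if (n < 1L) stop("atlas table is empty")
  if (!identical(sort(df$leaf_id), 0:(n - 1L))) {
    stop("leaf_ids must be dense 0..L-1 without duplicates")
  }
  if (anyDuplicated(df$leaf_name)) stop("duplicate leaf_name in atlas")
  if (anyDuplicated(df$atlas_label)) stop("duplicate atlas_label in atlas")
  if (any(df$atlas_label <= 0L)) {
    stop("atlas_label must be positive (0 is reserved for background)")
  }
  bad <- setdiff(unique(df$hemisphere), c("left", "right", "midline"))
  if (length(bad)) stop("unknown hemisphere value(s): ", paste(bad, collapse = ", "))
  df <- df[order(df$leaf_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_atlas", "data.frame")
  df
}

#' Read a region atlas from a tab-separated table
#'
#' @param path Path to a TSV with header columns
#'   `leaf_id`, `leaf_name`, `atlas_label`, `hemisphere`.
#' @return A `region_atlas`.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  region_atlas(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' The default 116-region AAL-style atlas
#'
#' Ships the standard AAL-116 parcellation (90 cerebral regions, 18 cerebellar
#' hemisphere regions, 8 vermis regions) with the conventional odd/even
#' left/right label numbering.
#'
#' @return A `region_atlas` with 116 leaves.
#' @export
default_aal_atlas <- function() {
  path <- system.file("extdata", "aal116_atlas.tsv", package = "rbadi", mustWork = TRUE)
  read_atlas(path)
}

n_leaves <- function(atlas) nrow(atlas)

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas with", nrow(x), "leaves\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}
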