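# Readers and writers: subject tables, attribution results, reference
# curves. All numeric output is written at 17 significant digits so every
# file round-trips through its reader bit-exactly.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

write_table_exact <- function(df, path, sep) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read a subject table
#'
#' CSV or TSV (by extension) with columns `subject_id`, `age`, optional
#' `sex`/`group`, and one numeric column per atlas leaf name.
#'
#' @param path File path.
#' @param atlas A [region_atlas()] the leaf columns must cover.
#' @return A data.frame.
#' @export
read_subject_table <- function(path, atlas) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("subject_id", "age") %in% names(df))) {
    stop("subject table needs 'subject_id' and 'age' columns")
  }
  missing_cols <- setdiff(atlas$leaf_name, names(df))
  if (length(missing_cols)) {
    stop("subject table lacks leaf column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         if (length(missing_cols) > 5) " ..." else "")
  }
  df
}

#' Write a subject table
#'
#' @param df Data.frame as produced by [simulate_cohort()]`$table`.
#' @param path Output path; `.tsv` writes tab-separated, anything else CSV.
#' @export
write_subject_table <- function(df, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  write_table_exact(df, path, sep)
  invisible(path)
}

#' Write multistage attribution results
#'
#' Emits three files under `dir`: `<prefix>_long.tsv` (subject_id, stage,
#' node_id, label, parent_id, phi, baseline), `<prefix>_leaf.csv` (one row
#' per subject: subject_id, age, then one column per leaf) and
#' `<prefix>_manifest.json` (tree hash, masking scheme, E0, tolerance,
#' package version).
#'
#' @param results List of `shapley_result`s.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the three paths.
#' @export
write_shapley_results <- function(results, dir, prefix = "shapley") {
  if (length(results) == 0L) stop("no results to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(results, function(r) {
    cbind(data.frame(subject_id = r$subject_id, stringsAsFactors = FALSE),
          r$table[, c("stage", "node_id", "label", "parent_id", "phi", "baseline")])
  }))
  p_long <- file.path(dir, paste0(prefix, "_long.tsv"))
  write_table_exact(long, p_long, "\t")

  wide <- data.frame(subject_id = vapply(results, `[[`, "", "subject_id"),
                     age = vapply(results, `[[`, 0, "age"),
                     v_full = vapply(results, `[[`, 0, "v_full"),
                     stringsAsFactors = FALSE)
  wide <- cbind(wide, as.data.frame(do.call(rbind, lapply(results, `[[`, "leaf_phi")),
                                    check.names = FALSE))
  p_wide <- file.path(dir, paste0(prefix, "_leaf.csv"))
  write_table_exact(wide, p_wide, ",")

  m <- results[[1]]$manifest
  m$n_subjects <- length(results)
  m$package_version <- as.character(utils::packageVersion("rbadi"))
  p_man <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(m, p_man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(long = p_long, leaf = p_wide, manifest = p_man))
}

#' Read a leaf-vector table back into lightweight results
#'
#' Reconstructs the minimal `shapley_result` objects (subject_id, age,
#' leaf_phi, tree_hash) that [build_reference()], [region_contributions()]
#' and [cohort_rbadi()] consume, from the wide CSV plus its manifest.
#'
#' @param path Path to a `<prefix>_leaf.csv` written by
#'   [write_shapley_results()].
#' @param manifest_path Defaults to the sibling `<prefix>_manifest.json`.
#' @return List of lightweight `shapley_result`s.
#' @export
read_leaf_vectors <- function(path,
                              manifest_path = sub("_leaf\\.csv$", "_manifest.json", path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  leaf_cols <- setdiff(names(df), c("subject_id", "age", "v_full"))
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(subject_id = df$subject_id[i], age = df$age[i],
                   v_full = if ("v_full" %in% names(df)) df$v_full[i] else NA_real_,
                   e0 = man$e0,
                   leaf_phi = setNames(as.numeric(df[i, leaf_cols]), leaf_cols),
                   tree_hash = man$tree_hash, manifest = man),
              class = "shapley_result")
  })
}

#' Write an age-standard reference curve
#'
#' TSV (`age`, `n`, `window_used`, then one column per leaf) plus a JSON
#' metadata sidecar (window, min_n, tree hash, leaf names).
#'
#' @param curve A [build_reference()] curve.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Invisibly the two paths.
#' @export
write_reference_curve <- function(curve, prefix) {
  df <- data.frame(age = curve$ages, n = curve$n_per_age,
                   window_used = curve$window_used)
  df <- cbind(df, as.data.frame(curve$phi_std, check.names = FALSE))
  p_tsv <- paste0(prefix, ".tsv")
  write_table_exact(df, p_tsv, "\t")
  p_json <- paste0(prefix, ".json")
  jsonlite::write_json(list(window = curve$window, min_n = curve$min_n,
                            tree_hash = curve$tree_hash,
                            leaf_names = curve$leaf_names),
                       p_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = p_tsv, json = p_json))
}

#' Read an age-standard reference curve
#'
#' @param prefix The path prefix passed to [write_reference_curve()].
#' @return A `reference_curve`.
#' @export
read_reference_curve <- function(prefix) {
  p_tsv <- paste0(prefix, ".tsv")
  p_json <- paste0(prefix, ".json")
  if (!file.exists(p_tsv) || !file.exists(p_json)) {
    stop("reference curve files not found at prefix: ", prefix)
  }
  df <- utils::read.delim(p_tsv, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(p_json, simplifyVector = TRUE)
  leaf_cols <- setdiff(names(df), c("age", "n", "window_used"))
  if (!identical(sort(leaf_cols), sort(meta$leaf_names))) {
    stop("reference curve TSV columns do not match its metadata leaf names")
  }
  phi_std <- as.matrix(df[, meta$leaf_names, drop = FALSE])
  rownames(phi_std) <- df$age
  structure(list(ages = as.integer(df$age), phi_std = phi_std,
                 n_per_age = as.integer(df$n), window = as.integer(meta$window),
                 window_used = as.integer(df$window_used),
                 min_n = as.integer(meta$min_n), tree_hash = meta$tree_hash,
                 leaf_names = meta$leaf_names),
            class = "reference_curve")
}

#' Read a NIfTI volume as a plain array
#'
#' Thin wrapper over the RNifti reader for subject volumes and integer atlas
#' label volumes.
#'
#' @param path NIfTI file path.
#' @return A numeric array.
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package")
  }
  as.array(RNifti::readNifti(path))
}
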