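# Hierarchical feature partitions: the tree of anatomical sets, hemisphere
# subsets and atlas leaves that structures every multistage Shapley game.

new_partition_node <- function(node_id, label, level, children = list(),
                               leaf_id = NULL) {
  structure(list(node_id = node_id, label = label, level = level,
                 children = children, leaf_id = leaf_id),
            class = "partition_node")
}

is_leaf_node <- function(node) !is.null(node$leaf_id)

# All leaf_ids under a node, in document order.
node_leafset <- function(node) {
  if (is_leaf_node(node)) return(node$leaf_id)
  unlist(lapply(node$children, node_leafset), use.names = FALSE)
}

#' Load a hierarchical partition file
#'
#' Partition files are nested maps (YAML, or an equivalent JSON rendering):
#' each key names a partition node and maps either to another map (its child
#' nodes) or to a list of leaves (names matching `atlas$leaf_name`, or 0-based
#' `leaf_id` integers). The top-level map holds the root's children; a single
#' top-level key named `root` is unwrapped. A node with exactly one child is a
#' pass-through: its child inherits the node's attribution without a game.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` partition file.
#' @param atlas A [region_atlas()] every referenced leaf must resolve against.
#' @return A validated `partition_tree`.
#' @export
load_partition <- function(path, atlas) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.list(spec) && length(spec) == 1L && identical(names(spec), "root")) {
    spec <- spec[["root"]]
  }
  partition_tree(spec, atlas)
}

#' Build a partition tree from a nested list
#'
#' @param spec Named nested list: values are either nested named lists
#'   (internal nodes) or vectors of leaf names / 0-based leaf ids.
#' @param atlas A [region_atlas()].
#' @return A `partition_tree` object; construction fails on any structural
#'   violation (duplicate leaves across siblings, unresolvable leaves, empty
#'   nodes, incomplete coverage of the atlas).
#' @export
partition_tree <- function(spec, atlas) {
  if (!inherits(atlas, "region_atlas")) atlas <- region_atlas(atlas)

  resolve_leaf <- function(x, where) {
    if (is.character(x)) {
      id <- atlas$leaf_id[match(x, atlas$leaf_name)]
      if (anyNA(id)) {
        stop("leaf(s) not in atlas (under '", where, "'): ",
             paste(x[is.na(id)], collapse = ", "))
      }
      id
    } else if (is.numeric(x)) {
      id <- as.integer(x)
      bad <- !(id %in% atlas$leaf_id)
      if (any(bad)) {
        stop("leaf id(s) not in atlas (under '", where, "'): ",
             paste(id[bad], collapse = ", "))
      }
      id
    } else {
      stop("cannot interpret leaf reference under '", where, "'")
    }
  }

  build <- function(spec, node_id, label, level) {
    if (is.list(spec) && !is.null(names(spec)) && length(spec) > 0 &&
        all(nzchar(names(spec)))) {
      children <- vector("list", length(spec))
      for (k in seq_along(spec)) {
        lab <- names(spec)[k]
        children[[k]] <- build(spec[[k]], paste(node_id, lab, sep = "/"),
                               lab, level + 1L)
      }
      new_partition_node(node_id, label, level, children = children)
    } else {
      leaves <- resolve_leaf(unlist(spec, use.names = FALSE), node_id)
      if (length(leaves) == 0L) stop("empty node: ", node_id)
      kids <- lapply(leaves, function(id) {
        new_partition_node(atlas$leaf_name[atlas$leaf_id == id],
                           atlas$leaf_name[atlas$leaf_id == id],
                           level + 1L, leaf_id = id)
      })
      new_partition_node(node_id, label, level, children = kids)
    }
  }

  if (!is.list(spec) || is.null(names(spec)) || length(spec) == 0L) {
    stop("partition spec must be a non-empty named list")
  }
  root <- build(spec, "root", "root", 0L)

  # sibling disjointness with parents named
  check_disjoint <- function(node) {
    if (is_leaf_node(node)) return(invisible())
    sets <- lapply(node$children, node_leafset)
    all_ids <- unlist(sets, use.names = FALSE)
    dup <- unique(all_ids[duplicated(all_ids)])
    if (length(dup)) {
      owners <- vapply(dup[1], function(d) {
        paste(vapply(node$children[vapply(sets, function(s) d %in% s, logical(1))],
                     `[[`, "", "node_id"), collapse = "' and '")
      }, "")
      stop("leaf ", dup[1], " (", atlas$leaf_name[atlas$leaf_id == dup[1]],
           ") assigned to both '", owners, "'")
    }
    for (ch in node$children) check_disjoint(ch)
  }
  check_disjoint(root)

  depth <- local({
    d <- function(node) if (is_leaf_node(node)) node$level else max(vapply(node$children, d, 0L))
    d(root)
  })
  tree <- structure(list(root = root, atlas = atlas, depth = depth),
                    class = "partition_tree")
  rep <- validate_partition(tree)
  if (nrow(rep)) {
    stop("invalid partition: ", paste(rep$message, collapse = "; "))
  }
  tree$hash <- tree_hash(tree)
  tree
}

# Canonical serialization used for hashing and manifests.
tree_canonical <- function(tree) {
  ser <- function(node) {
    if (is_leaf_node(node)) return(sprintf("%s=%d", node$label, node$leaf_id))
    sprintf("%s(%s)", node$label,
            paste(vapply(node$children, ser, ""), collapse = ","))
  }
  ser(tree$root)
}

tree_hash <- function(tree) md5_string(tree_canonical(tree))

#' Validate a partition tree
#'
#' Reporting companion to [partition_tree()]: checks sibling disjointness,
#' coverage (each node's leaf set is the union of its children's; the root
#' covers every atlas leaf), and non-emptiness, and returns all violations
#' rather than failing on the first.
#'
#' @param tree A `partition_tree` (possibly hand-built).
#' @return A data.frame with columns `type`, `node_id`, `message`; zero rows
#'   iff the tree is valid.
#' @export
validate_partition <- function(tree) {
  out <- list()
  add <- function(type, node_id, message) {
    out[[length(out) + 1L]] <<- data.frame(type = type, node_id = node_id,
                                           message = message)
  }
  walk <- function(node) {
    if (is_leaf_node(node)) return(invisible())
    if (length(node$children) == 0L) {
      add("empty_node", node$node_id, paste0("node '", node$node_id, "' has no children"))
      return(invisible())
    }
    sets <- lapply(node$children, node_leafset)
    all_ids <- unlist(sets, use.names = FALSE)
    dup <- unique(all_ids[duplicated(all_ids)])
    for (d in dup) {
      add("disjointness", node$node_id,
          paste0("leaf ", d, " appears in more than one child of '", node$node_id, "'"))
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  covered <- node_leafset(tree$root)
  orphan <- setdiff(tree$atlas$leaf_id, covered)
  for (o in orphan) {
    add("coverage", "root",
        paste0("atlas leaf ", o, " (", tree$atlas$leaf_name[tree$atlas$leaf_id == o],
               ") is not covered by the root"))
  }
  stray <- setdiff(covered, tree$atlas$leaf_id)
  for (s in stray) add("coverage", "root", paste0("leaf ", s, " is not in the atlas"))
  if (length(out) == 0L) {
    data.frame(type = character(), node_id = character(), message = character())
  } else {
    do.call(rbind, out)
  }
}

#' The default three-stage AAL-116 partition
#'
#' Level 1 holds eight anatomical sets — temporal lobe (TL), frontal lobe
#' (FL), prefrontal cortex (PFC), parietal lobe (PL), occipital lobe (OL),
#' subcortical structures (SC), cerebellum (CB) and cerebellar vermis (CV).
#' Level 2 splits the seven bilateral sets by hemisphere (fourteen subsets;
#' the midline CV passes through), and level 3 holds the 116 atlas leaves.
#' Construction validates the per-hemisphere leaf-count multiset
#' \{10, 4, 12, 8, 6, 5, 9\} (and 8 for CV) that the staged operation counts
#' rest on.
#'
#' @return A `partition_tree` with 116 leaves.
#' @export
default_aal_partition <- function() {
  path <- system.file("extdata", "aal116_partition.yaml", package = "rbadi",
                      mustWork = TRUE)
  tree <- load_partition(path, default_aal_atlas())
  lvl1 <- tree$root$children
  if (length(lvl1) != 8L) {
    stop("default partition corrupted: expected 8 level-1 sets, found ", length(lvl1))
  }
  hemi_sizes <- integer()
  cv_size <- NA_integer_
  for (set in lvl1) {
    sizes <- vapply(set$children, function(h) length(node_leafset(h)), 0L)
    if (length(sizes) == 1L) cv_size <- sizes else hemi_sizes <- c(hemi_sizes, sizes)
  }
  expected <- sort(rep(c(10L, 4L, 12L, 8L, 6L, 5L, 9L), 2L))
  if (!identical(sort(hemi_sizes), expected) || !identical(cv_size, 8L)) {
    stop("default partition corrupted: hemisphere leaf counts do not match ",
         "the expected multiset {10,4,12,8,6,5,9} x2 + {8}")
  }
  if (length(node_leafset(tree$root)) != 116L) {
    stop("default partition corrupted: expected 116 leaves")
  }
  tree
}

# Flatten the tree into the ordered list of games the multistage driver plays.
# Each internal node contributes one entry; m == 1 entries are pass-throughs.
# `stage` is the node's level + 1 (the root's game is stage 1).
plan_games <- function(tree) {
  all_leaves <- node_leafset(tree$root)
  games <- list()
  walk <- function(node) {
    if (is_leaf_node(node)) return(invisible())
    members <- node$children
    games[[length(games) + 1L]] <<- list(
      parent_id = node$node_id,
      parent_label = node$label,
      level = node$level,
      stage = node$level + 1L,
      m = length(members),
      member_ids = vapply(members, `[[`, "", "node_id"),
      member_labels = vapply(members, `[[`, "", "label"),
      member_is_leaf = vapply(members, is_leaf_node, logical(1)),
      member_leafsets = lapply(members, node_leafset),
      inside_leaves = node_leafset(node),
      outside_leaves = setdiff(all_leaves, node_leafset(node))
    )
    for (ch in members) walk(ch)
  }
  walk(tree$root)
  games[order(vapply(games, `[[`, 0L, "level"))]
}

#' Audit the operation counts of a partition tree
#'
#' Computes, per stage, the number of coalition evaluations the staged
#' workflow needs, and compares with the \eqn{2^L} evaluations a single flat
#' Shapley game over all \eqn{L} leaves would take. Under the `paper`
#' convention each within-set game of \eqn{m} members costs \eqn{2^m}
#' evaluations. Under the `cached` convention empty coalitions are never
#' evaluated and the full-member coalition of every game coincides with the
#' one shared full-payload prediction, so each game adds \eqn{2^m - 2}
#' distinct evaluations plus one shared evaluation per subject.
#'
#' @param tree A `partition_tree`.
#' @param convention `"paper"` or `"cached"`.
#' @return A `complexity_audit` list: `per_stage` (named integer vector),
#'   `total`, `n_leaves`, `naive_decimal` (exact \eqn{2^L} as a string),
#'   `naive_log10`, `naive_sci`, `reduction` (orders of magnitude,
#'   `floor(log10(naive/total))`), `shared_full_eval`.
#' @export
count_operations <- function(tree, convention = c("paper", "cached")) {
  convention <- match.arg(convention)
  games <- plan_games(tree)
  games <- Filter(function(g) g$m >= 2L, games)
  stages <- vapply(games, `[[`, 0L, "stage")
  cost <- vapply(games, function(g) {
    if (convention == "paper") 2^g$m else 2^g$m - 2
  }, 0)
  per_stage <- tapply(cost, stages, sum)
  per_stage <- setNames(as.numeric(per_stage),
                        paste0("stage", names(per_stage)))
  shared <- if (convention == "cached") 1 else 0
  total <- sum(per_stage) + shared
  L <- length(node_leafset(tree$root))
  naive_log10 <- log10_pow2(L)
  structure(list(
    convention = convention,
    per_stage = per_stage,
    shared_full_eval = shared,
    total = total,
    n_leaves = L,
    naive_decimal = pow2_decimal(L),
    naive_log10 = naive_log10,
    naive_sci = sci_from_log10(naive_log10),
    reduction = floor(naive_log10 - log10(total))
  ), class = "complexity_audit")
}

#' @export
print.complexity_audit <- function(x, ...) {
  cat("Staged Shapley operation count (", x$convention, " convention)\n", sep = "")
  for (s in names(x$per_stage)) {
    cat(sprintf("  %-8s %s\n", s, format(x$per_stage[[s]], big.mark = ",")))
  }
  if (x$shared_full_eval) cat("  shared full-payload evaluation: 1\n")
  cat(sprintf("  total    %s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  naive 2^%d = %s (%s)\n", x$n_leaves, x$naive_sci, x$naive_decimal))
  cat(sprintf("  reduction: %d orders of magnitude\n", x$reduction))
  invisible(x)
}

#' @export
print.partition_tree <- function(x, ...) {
  cat("partition_tree:", length(node_leafset(x$root)), "leaves, depth", x$depth, "\n")
  lvl1 <- vapply(x$root$children, `[[`, "", "label")
  cat("level-1 sets:", paste(lvl1, collapse = ", "), "\n")
  invisible(x)
}
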