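#' Build a taxonomy tree with recursive mean values
#'
#' Constructs the rooted tree underlying the microbiome-image embedding. Every
#' leaf is one taxon (a complete root-to-leaf taxonomy path, all at the same
#' depth; see [complete_taxonomy()]); each internal node's value is the mean of
#' its children's values, computed recursively from the leaf values.
#'
#' @param taxa Character vector of complete taxonomy paths (uniform depth).
#' @param values Numeric leaf values, parallel to `taxa` (e.g., one sample's
#'   preprocessed abundances, or mean training abundances for ordering).
#' @return A `taxonomy_tree`: list with `taxa`, `depth`, `keys` (per-depth list
#'   of node keys per leaf), `node_values` (per-depth named numeric vectors)
#'   and `leaf_values`.
#' @export
#' @examples
#' tr <- build_taxonomy_tree(
#'   c("k__B;p__P;c__C;o__O;f__F;g__G;s__a", "k__B;p__P;c__C;o__O;f__F;g__G;s__b"),
#'   c(0.5, 0.3))
#' tr$node_values[[4]]  # order-level value: mean of the two species = 0.4
build_taxonomy_tree <- function(taxa, values) {
  if (!length(taxa)) stop("empty taxa list", call. = FALSE)
  stopifnot(length(taxa) == length(values))
  mat <- parse_taxonomy(taxa)
  depths <- apply(mat, 1L, function(r) max(which(!is.na(r))))
  d <- unique(depths)
  if (length(d) != 1L)
    stop("taxa have unequal depths; run complete_taxonomy() first", call. = FALSE)
  pref <- mat[, seq_len(d), drop = FALSE]
  for (r in seq_len(d)) pref[, r] <- paste0(unname(tax_ranks())[r], pref[, r])
  keys <- vector("list", d)
  for (r in seq_len(d)) {
    keys[[r]] <- apply(pref[, seq_len(r), drop = FALSE], 1L, paste, collapse = ";")
  }
  if (anyDuplicated(keys[[d]]))
    stop("duplicate leaf paths; merge taxa first", call. = FALSE)
  node_values <- vector("list", d)
  node_values[[d]] <- stats::setNames(as.numeric(values), keys[[d]])
  child_of <- function(r) {
    # parent key of each depth-(r+1) node
    kk <- unique(keys[[r + 1L]])
    idx <- match(kk, keys[[r + 1L]])
    stats::setNames(keys[[r]][idx], kk)
  }
  for (r in rev(seq_len(d - 1L))) {
    parents <- child_of(r)
    vals <- node_values[[r + 1L]][names(parents)]
    agg <- tapply(vals, parents, mean)
    node_values[[r]] <- stats::setNames(as.numeric(agg), names(agg))
  }
  structure(list(taxa = taxa, depth = d, keys = keys,
                 node_values = node_values,
                 leaf_values = stats::setNames(as.numeric(values), taxa)),
            class = "taxonomy_tree")
}

.dfs_leaf_order <- function(tree, ordering = c("abundance", "lexicographic")) {
  ordering <- match.arg(ordering)
  d <- tree$depth
  n <- length(tree$taxa)
  # iterative DFS over node keys; children sorted by policy
  recurse <- function(r, key) {
    if (r == d) return(which(tree$keys[[d]] == key))
    child_keys <- unique(tree$keys[[r + 1L]][tree$keys[[r]] == key])
    vals <- tree$node_values[[r + 1L]][child_keys]
    ord <- if (identical(ordering, "abundance")) {
      order(-vals, child_keys)
    } else {
      order(child_keys)
    }
    unlist(lapply(child_keys[ord], function(k) recurse(r + 1L, k)), use.names = FALSE)
  }
  roots <- unique(tree$keys[[1L]])
  vals <- tree$node_values[[1L]][roots]
  ord <- if (identical(ordering, "abundance")) order(-vals, roots) else order(roots)
  unlist(lapply(roots[ord], function(k) recurse(1L, k)), use.names = FALSE)
}

#' Render a taxonomy tree as a microbiome image
#'
#' Produces the levels-by-leaves matrix consumed by the convolutional
#' predictor: leaves are ordered by a depth-first traversal with children at
#' each node sorted by the ordering policy (default: descending node value,
#' ties lexicographic); row `r`, column `c` holds the value of leaf `c`'s
#' ancestor at rank `r`. The bottom row is the leaf vector itself, and each row
#' is constant within a block of leaves sharing the rank-`r` ancestor.
#'
#' @param tree A [build_taxonomy_tree()] result.
#' @param ordering `"abundance"` (default) or `"lexicographic"`.
#' @return A `microbiome_image`: numeric matrix `depth x n_leaves` with
#'   attribute `leaf_order` (the taxa in column order).
#' @export
to_image <- function(tree, ordering = c("abundance", "lexicographic")) {
  ordering <- match.arg(ordering)
  ord <- .dfs_leaf_order(tree, ordering)
  d <- tree$depth
  img <- matrix(NA_real_, d, length(ord))
  for (r in seq_len(d)) {
    img[r, ] <- unname(tree$node_values[[r]][tree$keys[[r]][ord]])
  }
  structure(img, leaf_order = tree$taxa[ord],
            class = c("microbiome_image", "matrix", "array"))
}

#' Precompute the linear map from leaf vectors to images
#'
#' Because every image cell is a fixed convex combination of leaf values
#' (nested means down the tree), rendering a batch of samples reduces to one
#' sparse matrix product. The map is frozen at training time (leaf order taken
#' from mean training abundances) and reused for held-out donors and inside
#' the genetic algorithm, where thousands of candidate profiles are imaged per
#' generation.
#'
#' @param taxa Complete taxonomy paths (one per leaf, uniform depth).
#' @param ordering_values Leaf values used only to fix the column order
#'   (typically mean training abundance).
#' @param ordering Ordering policy, as in [to_image()].
#' @return List with `taxa` (input axis), `leaf_order`, `perm` (column
#'   permutation), `depth`, `width`, and `map`, a sparse
#'   `n_leaves x (depth * width)` matrix: `X[, perm] %*% map` yields one
#'   column-major flattened image per row of `X`.
#' @export
taxonomy_image_map <- function(taxa, ordering_values,
                               ordering = c("abundance", "lexicographic")) {
  ordering <- match.arg(ordering)
  tree <- build_taxonomy_tree(taxa, ordering_values)
  ord <- .dfs_leaf_order(tree, ordering)
  d <- tree$depth
  n <- length(taxa)
  keys_ord <- lapply(tree$keys, function(k) k[ord])
  # leaf-weight vector per node, bottom-up: w_node = mean of children weights
  weights <- vector("list", d)  # per depth: named list node key -> sparse weights
  leaf_keys <- keys_ord[[d]]
  weights[[d]] <- lapply(seq_len(n), function(i) {
    w <- numeric(0); w[as.character(i)] <- 1; w
  })
  names(weights[[d]]) <- leaf_keys
  for (r in rev(seq_len(d - 1L))) {
    node_keys <- unique(keys_ord[[r]])
    weights[[r]] <- lapply(node_keys, function(k) {
      child_keys <- unique(keys_ord[[r + 1L]][keys_ord[[r]] == k])
      acc <- numeric(0)
      for (ck in child_keys) {
        w <- weights[[r + 1L]][[ck]]
        for (nm in names(w)) acc[nm] <- (if (nm %in% names(acc)) acc[[nm]] else 0) +
            w[[nm]] / length(child_keys)
      }
      acc
    })
    names(weights[[r]]) <- node_keys
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(d)) {
    for (c in seq_len(n)) {
      w <- weights[[r]][[keys_ord[[r]][c]]]
      leaf_pos <- as.integer(names(w))
      cell <- (c - 1L) * d + r
      ii <- c(ii, leaf_pos); jj <- c(jj, rep.int(cell, length(w)))
      xx <- c(xx, unname(w))
    }
  }
  map <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, d * n))
  list(taxa = taxa, leaf_order = tree$taxa[ord], perm = ord,
       depth = d, width = n, map = map)
}

#' Apply an image map to a sample matrix
#' @param imap A [taxonomy_image_map()].
#' @param x Numeric matrix, samples in rows, columns on `imap$taxa`.
#' @return Matrix `nrow(x) x (depth * width)` of column-major flattened images.
#' @export
apply_image_map <- function(imap, x) {
  stopifnot(ncol(x) == length(imap$taxa))
  as.matrix(x[, imap$perm, drop = FALSE] %*% imap$map)
}
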