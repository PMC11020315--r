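# Time-calibration of a fossil topology from taxon appearance dates using
# the 'equal' branch-sharing method: node ages start as the oldest
# descendant tip age, the root is pushed back by a fixed extension, and
# each chain of zero-length branches shares, in equal parts, the time
# available from the nearest ancestral branch of positive length.

#' Time-calibrate a topology with the 'equal' method
#'
#' Tip ages are taxon first-appearance dates (FAD, Ma). Each internal node
#' age is initialised to the maximum FAD among its descendant tips, the
#' root age is extended by `root_extension` Myr, and zero-length branches
#' are then removed by sliding internal-node ages so that every chain of
#' zero-length branches shares equally in the duration of the nearest
#' ancestral positive branch.
#'
#' @param tree An `ape::phylo` topology, a newick string, or a path to a
#'   newick file. Branch lengths, if present, are ignored. Polytomies are
#'   accepted and treated as hard.
#' @param ages A data frame with columns `taxon`, `fad` (first appearance,
#'   Ma) and optionally `lad` (last appearance, Ma; `fad >= lad` checked).
#' @param root_extension Myr added to the root age (> 0 guarantees strictly
#'   positive branch lengths).
#' @return The tree (class `c("calibrated_phylo", "phylo")`) with branch
#'   lengths in Myr, a `root.time` attribute-style element (`$root.time`,
#'   as used by paleontological tree tools) and a `node_ages` attribute
#'   (ages in Ma for tips 1..n then internal nodes).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' ages <- tibble::tibble(taxon = c("A", "B", "C"), fad = c(100, 100, 100))
#' cal <- calibrate_equal(tr, ages, root_extension = 6)
#' cal$edge.length
#' @export
calibrate_equal <- function(tree, ages, root_extension = 0) {
  tree <- as_phylo(tree)
  ages <- as_tibble(ages)
  if (!all(c("taxon", "fad") %in% names(ages))) {
    zr_abort("`ages` needs columns `taxon` and `fad`", "zr_error_format")
  }
  if ("lad" %in% names(ages)) {
    bad <- which(!is.na(ages$lad) & ages$fad < ages$lad)
    if (length(bad) > 0) {
      zr_abort(paste0("FAD must be >= LAD for taxon/taxa: ",
                      paste(ages$taxon[bad], collapse = ", ")),
               "zr_error_validation")
    }
  }
  missing_taxa <- setdiff(tree$tip.label, ages$taxon)
  if (length(missing_taxa) > 0) {
    zr_abort(paste0("no age for taxon/taxa: ",
                    paste(missing_taxa, collapse = ", ")),
             "zr_error_validation")
  }
  if (root_extension < 0) {
    zr_abort("root_extension must be >= 0", "zr_error_validation")
  }

  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  age <- numeric(n_tip + n_node)
  age[seq_len(n_tip)] <- ages$fad[match(tree$tip.label, ages$taxon)]

  # postorder pass: node age = oldest descendant tip age
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  age[(n_tip + 1):(n_tip + n_node)] <- -Inf
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; c <- edges[i, 2]
    age[p] <- max(age[p], age[c])
  }
  age[root] <- age[root] + root_extension

  age <- redistribute_equal(tree, age, n_tip)

  parent_age <- age[tree$edge[, 1]]
  child_age <- age[tree$edge[, 2]]
  edge_length <- parent_age - child_age
  stopifnot(all(edge_length >= -1e-9))
  edge_length[edge_length < 0] <- 0
  if (root_extension > 0 && any(edge_length <= 0)) {
    zr_abort("internal error: zero-length branch survived redistribution",
             "zr_error_internal")
  }
  tree$edge.length <- edge_length
  tree$root.time <- age[root]
  attr(tree, "node_ages") <- age
  class(tree) <- c("calibrated_phylo", class(tree))
  tree
}

# Slide internal-node ages off zero-length branches. Working in preorder,
# the first zero-length edge found always hangs below a positive branch (or
# the root); the chain of equal-aged nodes below it is re-spaced evenly
# between the age of the positive branch's parent and the fixed age at the
# chain's bottom.
redistribute_equal <- function(tree, age, n_tip) {
  root <- n_tip + 1L
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  preorder <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2])
  eps <- 1e-12

  repeat {
    zero_child <- NA_integer_
    for (ch in preorder) {
      if (age[parent_of[ch]] - age[ch] <= eps) { zero_child <- ch; break }
    }
    if (is.na(zero_child)) break
    p <- parent_of[zero_child]
    if (p == root && age[root] - age[zero_child] <= eps) {
      # no time available anywhere above (root_extension = 0): leave as zero
      break
    }
    a <- if (p == root) root else parent_of[p]
    # descend the chain of equal-aged nodes from zero_child
    end <- zero_child
    repeat {
      kids <- children_of[[as.character(end)]]
      nxt <- kids[!is.na(kids) & age[kids] >= age[end] - eps]
      if (length(nxt) == 0) break
      end <- nxt[1]
    }
    # path a -> ... -> end; re-space the interior nodes evenly
    path <- end
    node <- end
    while (node != a) {
      node <- parent_of[node]
      path <- c(node, path)
    }
    k <- length(path) - 1L            # number of edges a -> end
    if (k < 2 || age[a] - age[end] <= eps) break  # nothing to share
    step <- (age[a] - age[end]) / k
    for (j in seq_len(k - 1L)) {
      age[path[j + 1L]] <- age[a] - j * step
    }
  }
  age
}

#' Node ages of a calibrated tree
#'
#' @param tree A tree from [calibrate_equal()].
#' @return Numeric vector of ages in Ma, indexed tips first (1..n) then
#'   internal nodes (n+1..n+m), as in `ape`'s node numbering.
#' @export
node_ages <- function(tree) {
  a <- attr(tree, "node_ages")
  if (is.null(a)) {
    zr_abort("tree has no node ages; use calibrate_equal()", "zr_error_domain")
  }
  a
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  zr_abort("`tree` must be a phylo object, a newick string, or a file path",
           "zr_error_format")
}
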