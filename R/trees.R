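#' Ultrametric tree data model
#'
#' An `ultrametric_tree` wraps a rooted, strictly binary [ape::phylo]
#' object together with node heights measured from the tips (height 0)
#' toward the root. It is the object the GMYC likelihood operates on:
#' a chronogram such as a BEAST maximum clade credibility tree, where
#' branch lengths are in substitutions/site (or any clock unit) and all
#' contemporaneous tips sit at height 0.
#'
#' Construction enforces three invariants: every tip height is 0 after
#' normalization, every internal node is strictly older than both of its
#' children after deterministic de-tying, and the tree is binary (exactly
#' `n - 1` internal nodes for `n` tips).
#'
#' Tip-height noise up to `tol_rel * root_height` (floating-point jitter
#' typical of MCC trees) is snapped to 0; larger deviations are rejected
#' with the worst-offending tip named. Tied or inverted node heights
#' within `1e-9 * root_height` are separated by subtracting
#' `i * epsilon` (deterministic traversal index `i`), because the
#' exponential waiting-time likelihood needs strictly positive
#' inter-event intervals. Polytomies are rejected rather than silently
#' resolved: a zero-branch resolution changes the likelihood and must be
#' the user's explicit choice.
#'
#' @param phy an [ape::phylo] tree with branch lengths.
#' @param tol_rel relative ultrametricity tolerance for tip heights,
#'   as a fraction of root height.
#' @return an object of class `ultrametric_tree`: a list with elements
#'   `phy` (the ape tree), `heights` (numeric, length `2n - 1`, indexed
#'   like ape nodes: tips `1..n`, root `n + 1`), `n_tips`, and
#'   `root_height`.
#' @seealso [parse_newick()], [branching_times()], [compute_ltt()]
#' @export
ultrametric_tree <- function(phy, tol_rel = 1e-6) {
  if (!inherits(phy, "phylo")) {
    stop("`phy` must be an ape 'phylo' object", call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; heights cannot be computed",
         call. = FALSE)
  }
  n <- length(phy$tip.label)
  if (n < 2) stop("tree must have at least 2 tips", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (phy$Nnode != n - 1L) {
    stop("tree is not strictly binary (", phy$Nnode, " internal nodes for ",
         n, " tips); resolve polytomies explicitly before use",
         call. = FALSE)
  }
  heights <- node_heights(phy)
  root_height <- heights[n + 1L]
  if (root_height <= 0) stop("root height must be positive", call. = FALSE)

  tip_dev <- abs(heights[seq_len(n)])
  tol <- tol_rel * root_height
  if (any(tip_dev > tol)) {
    worst <- which.max(tip_dev)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' at height %.6g (root height %.6g, tolerance %.3g)",
      phy$tip.label[worst], heights[worst], root_height, tol), call. = FALSE)
  }
  heights[seq_len(n)] <- 0
  heights <- detie_heights(phy, heights)

  structure(list(phy = phy, heights = heights, n_tips = n,
                 root_height = heights[n + 1L]),
            class = "ultrametric_tree")
}

## Heights from the tips: root depth minus node depth along edges.
node_heights <- function(phy) {
  n <- length(phy$tip.label)
  nnode <- n + phy$Nnode
  depth <- numeric(nnode)
  ## edges in ape preorder: parent before child after reorder()
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    depth[ord$edge[i, 2L]] <- depth[ord$edge[i, 1L]] + ord$edge.length[i]
  }
  max_depth <- max(depth[seq_len(n)])
  max_depth - depth
}

## De-tie exactly equal internal-node heights by subtracting
## (i - 1) * eps within each tie group, i the preorder index order.
## A parent always precedes its child in preorder, so a zero-length
## internal branch resolves to parent > child; the result is strictly
## ordered branching times, as the exponential waiting-time likelihood
## requires, and fully deterministic.
detie_heights <- function(phy, heights) {
  n <- length(phy$tip.label)
  eps <- 1e-9 * heights[n + 1L]
  ord <- ape::reorder.phylo(phy, "cladewise")
  pre <- integer(n + phy$Nnode)
  pre[n + 1L] <- 1L
  pre[ord$edge[, 2L]] <- seq_len(nrow(ord$edge)) + 1L
  internal <- (n + 1L):(2L * n - 1L)
  for (g in split(internal, factor(heights[internal]))) {
    if (length(g) < 2L) next
    g <- g[order(pre[g])]
    heights[g] <- heights[g] - (seq_along(g) - 1L) * eps
  }
  if (any(heights[internal] <= 0)) {
    stop("internal node at height <= 0 (zero-length terminal cherry); ",
         "the tree cannot carry a positive waiting-time density",
         call. = FALSE)
  }
  bad <- which(heights[phy$edge[, 1L]] <= heights[phy$edge[, 2L]])
  if (length(bad)) {
    stop("node height ordering could not be repaired at edge ",
         bad[1L], call. = FALSE)
  }
  heights
}

#' Parse a newick string into an ultrametric tree
#'
#' Reads a rooted binary newick tree with branch lengths, computes node
#' heights as distance-to-tips, validates ultrametricity (tips within
#' `tol_rel` of 0 relative to root height are snapped to 0), and applies
#' the deterministic de-tying rule. Duplicate tip labels, missing branch
#' lengths, polytomies, and non-ultrametric trees are rejected.
#'
#' @param text a newick string (or a length-1 character vector).
#' @param tol_rel relative ultrametricity tolerance.
#' @return an [ultrametric_tree()].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$root_height           # 2
#' branching_times(tr)      # 2 1
#' @export
parse_newick <- function(text, tol_rel = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("failed to parse newick string", call. = FALSE)
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length)) {
    stop("branch lengths are required on all edges", call. = FALSE)
  }
  ultrametric_tree(phy, tol_rel = tol_rel)
}

#' Read an ultrametric tree from a newick file
#' @param path path to a newick file (first tree is used).
#' @param tol_rel relative ultrametricity tolerance.
#' @return an [ultrametric_tree()].
#' @export
read_ultrametric_tree <- function(path, tol_rel = 1e-6) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt, tol_rel = tol_rel)
}

#' Serialize an ultrametric tree to newick
#'
#' Branch lengths are re-derived from the (possibly de-tied) node
#' heights and written with 10 significant digits, so
#' parse -> serialize -> parse round trips preserve topology and heights
#' to within 1e-9 relative.
#'
#' @param tree an [ultrametric_tree()].
#' @param path optional file path; when `NULL` the newick string is
#'   returned instead.
#' @return the newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ultrametric_tree"))
  phy <- tree$phy
  phy$edge.length <- tree$heights[phy$edge[, 1L]] - tree$heights[phy$edge[, 2L]]
  txt <- ape::write.tree(phy, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Branching times of an ultrametric tree
#'
#' Heights of all internal nodes, sorted in descending order from the
#' root height to the shallowest node. After de-tying the sequence is
#' strictly decreasing; length is `n - 1` for `n` tips.
#'
#' @param tree an [ultrametric_tree()].
#' @return a numeric vector of length `n - 1`, nonincreasing, first
#'   element equal to the root height.
#' @export
branching_times <- function(tree) {
  stopifnot(inherits(tree, "ultrametric_tree"))
  n <- tree$n_tips
  sort(tree$heights[(n + 1L):(2L * n - 1L)], decreasing = TRUE)
}

#' Lineage-through-time curve
#'
#' The step function counting ancestral lineages as a function of
#' height. Just below the root the count is 2; it increases by one at
#' each internal node going tipward and reaches `n` at height 0.
#'
#' @param tree an [ultrametric_tree()].
#' @return a data.frame with columns `height` (descending branching
#'   times) and `lineages` (2, 3, ..., n): the lineage count in force
#'   from that height down to the next row's height.
#' @export
compute_ltt <- function(tree) {
  bt <- branching_times(tree)
  data.frame(height = bt, lineages = seq.int(2L, tree$n_tips))
}

#' @export
print.ultrametric_tree <- function(x, ...) {
  cat(sprintf("ultrametric tree: %d tips, root height %.6g\n",
              x$n_tips, x$root_height))
  invisible(x)
}

## children lookup used throughout: list indexed by node id
child_list <- function(phy) {
  n <- length(phy$tip.label)
  out <- vector("list", n + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    out[[p]] <- c(out[[p]], phy$edge[i, 2L])
  }
  out
}

## tips under each node (list over all node ids)
tips_under <- function(phy) {
  n <- length(phy$tip.label)
  nnode <- n + phy$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(n)) out[[i]] <- i
  ord <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]
    out[[p]] <- c(out[[p]], out[[ord$edge[i, 2L]]])
  }
  out
}
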