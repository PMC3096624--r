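#' Node classification for the mixed Yule-coalescent model
#'
#' A `node_classification` labels every internal node of an
#' [ultrametric_tree()] as either `diversification` (between-species,
#' Yule branching) or `coalescent` (within-species branching). The
#' coalescent labels must be tip-ward closed: every internal descendant
#' of a coalescent node is itself coalescent, so coalescent nodes form
#' maximal subtrees. Each lineage crossing the species boundary then
#' roots one delimited entity: a maximal coalescent subtree is a
#' *cluster* (>= 2 tips), and a tip hanging directly from a
#' diversification node is a *singleton*.
#'
#' @param tree an [ultrametric_tree()].
#' @param coal logical vector over internal node ids (ape numbering:
#'   `n_tips + 1` ... `2 n_tips - 1`), `TRUE` for coalescent nodes.
#' @return an object of class `node_classification`: list with `tree`,
#'   `coal` (named by internal node id), plus derived `entities`
#'   (see [extract_entities()] for the user-facing view).
#' @export
node_classification <- function(tree, coal) {
  stopifnot(inherits(tree, "ultrametric_tree"))
  n <- tree$n_tips
  internal <- (n + 1L):(2L * n - 1L)
  coal <- as.logical(coal)
  if (length(coal) != n - 1L || anyNA(coal)) {
    stop("`coal` must be a logical vector of length n_tips - 1 without NAs",
         call. = FALSE)
  }
  names(coal) <- internal
  ## tip-ward closure: a coalescent node cannot have a diversification parent
  ## *below* it -- i.e. every child internal node of a coalescent node is
  ## coalescent
  kids <- child_list(tree$phy)
  for (nd in internal[coal]) {
    k <- kids[[nd]]
    k_int <- k[k > n]
    if (length(k_int) && !all(coal[as.character(k_int)])) {
      stop("classification not tip-ward closed at node ", nd, call. = FALSE)
    }
  }
  structure(list(tree = tree, coal = coal),
            class = "node_classification")
}

#' Classify nodes by a single threshold height
#'
#' Internal nodes strictly older than `threshold` are diversification
#' nodes; nodes at or below it are coalescent. A threshold at or above
#' the root height yields the single-coalescent null classification
#' (one cluster, no diversification nodes); a threshold below the
#' shallowest node makes every tip a singleton.
#'
#' @param tree an [ultrametric_tree()].
#' @param threshold height (distance from the tips), in
#'   `[0, root_height]` or slightly beyond.
#' @return a [node_classification()].
#' @export
classify_nodes <- function(tree, threshold) {
  stopifnot(inherits(tree, "ultrametric_tree"), is.numeric(threshold),
            length(threshold) == 1L, !is.na(threshold))
  n <- tree$n_tips
  internal <- (n + 1L):(2L * n - 1L)
  node_classification(tree, tree$heights[internal] <= threshold)
}

## Entity bookkeeping shared by the interval builder and the public
## extraction: returns a list with, per entity, its root node (cluster
## root or tip id), type, and tips; ordered by preorder position of the
## entity root so numbering is a deterministic traversal order.
entity_table <- function(cls) {
  tree <- cls$tree
  phy <- tree$phy
  n <- tree$n_tips
  coal <- cls$coal
  kids <- child_list(phy)
  tu <- tips_under(phy)

  parent <- integer(2L * n - 1L)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- n + 1L

  is_coal_node <- function(nd) nd > n && coal[[as.character(nd)]]

  roots <- integer(0)
  for (nd in c(root, phy$edge[, 2L])) {
    if (nd > n) {
      if (is_coal_node(nd) && (nd == root || !is_coal_node(parent[nd]))) {
        roots <- c(roots, nd)  # maximal coalescent subtree -> cluster
      }
    } else {
      if (!is_coal_node(parent[nd])) roots <- c(roots, nd)  # singleton
    }
  }
  ## preorder position of each node for deterministic entity numbering
  ord <- ape::reorder.phylo(phy, "cladewise")
  pre <- integer(2L * n - 1L)
  pre[root] <- 1L
  pre[ord$edge[, 2L]] <- seq_len(nrow(ord$edge)) + 1L
  roots <- roots[order(pre[roots])]

  lapply(roots, function(r) {
    tps <- sort(tu[[r]])
    list(root = r,
         type = if (r > n) "cluster" else "singleton",
         tips = tps,
         labels = phy$tip.label[tps])
  })
}

#' Extract delimited entities from a classification
#'
#' Partitions the tips into putative species: clusters (maximal
#' coalescent subtrees, >= 2 tips) and singletons. Entities are numbered
#' in preorder of their root node, so numbering is deterministic for a
#' given tree orientation.
#'
#' @param classification a [node_classification()].
#' @return a `species_assignment`: list with `entities` (named list,
#'   entity id -> character vector of tip labels), `type`
#'   (cluster/singleton per entity), `name` (NA until [name_species()]),
#'   `n_entities`, `n_clusters`, `n_singletons`.
#' @export
extract_entities <- function(classification) {
  stopifnot(inherits(classification, "node_classification"))
  et <- entity_table(classification)
  ids <- as.character(seq_along(et))
  ents <- stats::setNames(lapply(et, `[[`, "labels"), ids)
  type <- stats::setNames(vapply(et, `[[`, "", "type"), ids)
  species_assignment(ents, type)
}

#' Construct a species assignment
#'
#' @param entities named list: entity id -> character vector of
#'   individuals (or tip labels). Entities must be disjoint.
#' @param type character vector (`"cluster"`/`"singleton"`) per entity;
#'   inferred from entity sizes when missing.
#' @param name optional character vector of entity names (NA = unnamed).
#' @return an object of class `species_assignment`.
#' @export
species_assignment <- function(entities, type = NULL, name = NULL) {
  stopifnot(is.list(entities), !is.null(names(entities)))
  all_ind <- unlist(entities, use.names = FALSE)
  if (anyDuplicated(all_ind)) {
    stop("entities are not disjoint: ",
         paste(unique(all_ind[duplicated(all_ind)]), collapse = ", "),
         call. = FALSE)
  }
  sizes <- lengths(entities)
  if (is.null(type)) type <- ifelse(sizes >= 2L, "cluster", "singleton")
  if (is.null(name)) name <- rep(NA_character_, length(entities))
  structure(list(entities = entities,
                 type = stats::setNames(type, names(entities)),
                 name = stats::setNames(name, names(entities)),
                 n_entities = length(entities),
                 n_clusters = sum(type == "cluster"),
                 n_singletons = sum(type == "singleton")),
            class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  cat(sprintf("species assignment: %d entities (%d clusters, %d singletons)\n",
              x$n_entities, x$n_clusters, x$n_singletons))
  invisible(x)
}

#' Map entities of haplotype tips back to individuals
#'
#' GMYC runs on a collapsed-haplotype tree; this expands each entity's
#' tip labels (haplotype representatives) into the individuals they
#' stand for, using the [collapse_sequences()] map.
#'
#' @param assignment a [species_assignment()] whose entities contain
#'   haplotype representative names.
#' @param collapse_map a `collapse_map` (representative -> members).
#' @return a [species_assignment()] over individuals.
#' @export
expand_assignment <- function(assignment, collapse_map) {
  stopifnot(inherits(assignment, "species_assignment"))
  ents <- lapply(assignment$entities, function(tips) {
    miss <- setdiff(tips, names(collapse_map))
    if (length(miss)) {
      stop("tips not in collapse map: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    sort(unique(unlist(collapse_map[tips], use.names = FALSE)))
  })
  species_assignment(ents, type = unname(assignment$type),
                     name = unname(assignment$name))
}
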