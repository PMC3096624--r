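#' Support-annotated tree for a second locus
#'
#' Wraps a rooted tree whose tips are genotypes of a second marker
#' (e.g. a nuclear consensus tree) and whose internal-node labels carry
#' clade support (posterior probability in [0, 1]; empty labels become
#' NA), together with the genotype -> individuals mapping produced by
#' collapsing that marker. The mapping lets individuals delimited on
#' one locus be located on the other locus' tree, possibly many
#' individuals per tip.
#'
#' @param phy a rooted [ape::phylo]; `node.label` holds support values.
#' @param genotype_members named list (or `collapse_map`):
#'   tip label -> character vector of individuals carrying it.
#' @return an object of class `supported_tree`.
#' @export
supported_tree <- function(phy, genotype_members) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels in support tree", call. = FALSE)
  }
  supp <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    supp <- suppressWarnings(as.numeric(phy$node.label))
  }
  if (any(supp < 0 | supp > 1, na.rm = TRUE)) {
    stop("node supports must lie in [0, 1]", call. = FALSE)
  }
  genotype_members <- lapply(genotype_members, as.character)
  miss <- setdiff(names(genotype_members), phy$tip.label)
  if (length(miss)) {
    stop("genotypes absent from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(phy = phy, support = supp,
                 genotype_members = genotype_members),
            class = "supported_tree")
}

#' Read a newick tree with internal-node support labels
#' @param path newick file; internal node labels are support values.
#' @param genotype_members see [supported_tree()].
#' @return a [supported_tree()].
#' @export
read_supported_tree <- function(path, genotype_members) {
  phy <- ape::read.tree(path)
  supported_tree(phy, genotype_members)
}

#' Assess two-locus congruence of delimited species
#'
#' An entity delimited on locus A (e.g. mitochondrial GMYC species) is
#' flagged congruent (`"+"`) when all of its individuals form a unique,
#' supported clade on the locus-B tree: (a) the locus-B tips induced by
#' its individuals are exactly the tip set of one node (exclusivity;
#' a single tip counts trivially), (b) that node's support is at least
#' `pp_min` (waived for single tips, which have no subtending clade;
#' an NA support fails the test), and (c) no induced tip carries
#' individuals from any other entity -- a genotype shared across
#' entities breaks exclusivity.
#'
#' @param assignment a [species_assignment()] over individuals.
#' @param tree a [supported_tree()] whose genotype map covers every
#'   assigned individual.
#' @param pp_min minimum clade support (default 0.95).
#' @return data.frame with columns `entity`, `name`, `type`,
#'   `congruent` (`"+"`/`"-"`).
#' @export
assess_congruence <- function(assignment, tree, pp_min = 0.95) {
  stopifnot(inherits(assignment, "species_assignment"),
            inherits(tree, "supported_tree"))
  phy <- tree$phy
  n <- length(phy$tip.label)

  ## individual -> genotype tips (possibly several)
  ind2tip <- list()
  for (g in names(tree$genotype_members)) {
    for (ind in tree$genotype_members[[g]]) {
      ind2tip[[ind]] <- c(ind2tip[[ind]], g)
    }
  }
  all_ind <- unlist(assignment$entities, use.names = FALSE)
  unmapped <- setdiff(all_ind, names(ind2tip))
  if (length(unmapped)) {
    stop("individuals not mapped to any tip: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  ## entity of each individual, for the foreign-individual check
  ind_entity <- stats::setNames(
    rep(names(assignment$entities), lengths(assignment$entities)), all_ind)

  tu <- tips_under(phy)
  clade_sets <- lapply(tu[(n + 1L):(n + phy$Nnode)],
                       function(i) sort(phy$tip.label[i]))

  flag <- character(assignment$n_entities)
  for (i in seq_along(assignment$entities)) {
    inds <- assignment$entities[[i]]
    tips <- sort(unique(unlist(ind2tip[inds], use.names = FALSE)))
    ## (c) foreign individuals on any induced tip
    carried <- unique(unlist(tree$genotype_members[tips], use.names = FALSE))
    carried <- carried[carried %in% names(ind_entity)]
    if (any(ind_entity[carried] != names(assignment$entities)[i])) {
      flag[i] <- "-"
      next
    }
    if (length(tips) == 1L) {            # single tip: support waived
      flag[i] <- "+"
      next
    }
    hit <- which(vapply(clade_sets, identical, NA, y = tips))
    if (!length(hit)) {
      flag[i] <- "-"
      next
    }
    supp <- tree$support[hit[1L]]
    flag[i] <- if (!is.na(supp) && supp >= pp_min) "+" else "-"
  }
  data.frame(entity = names(assignment$entities),
             name = unname(assignment$name),
             type = unname(assignment$type),
             congruent = flag,
             stringsAsFactors = FALSE)
}

#' Name delimited species from topotypes and nominal identifications
#'
#' Two naming rules, applied in order. Rule 1 (topotypes): a *topotype
#' set* is the full group of topotype-flagged individuals of one
#' nominal species from one population (its type locality); an entity
#' containing a complete topotype set receives that species' name.
#' Several complete sets in one entity concatenate their names with
#' `"+"` (the delimitation lumped those species); complete sets of the
#' same species in different entities name each of them (the species
#' was split). Rule 2 (unambiguous identification): an entity with no
#' topotype-derived name is named after its members' nominal species
#' when they all agree and none is missing. Remaining entities are
#' labelled `"sp k"` with `k` a running index in entity order, so
#' indices are stable across runs.
#'
#' @param assignment a [species_assignment()] over individuals.
#' @param metadata data.frame with columns `individual`,
#'   `population`, `nominal_species`, `topotype` (0/1).
#' @return the assignment with its `name` field filled.
#' @export
name_species <- function(assignment, metadata) {
  stopifnot(inherits(assignment, "species_assignment"),
            is.data.frame(metadata))
  md <- metadata
  md$individual <- as.character(md$individual)
  topo <- md[md$topotype %in% 1L, , drop = FALSE]
  bad <- topo$individual[is.na(topo$nominal_species) |
                           !nzchar(topo$nominal_species)]
  if (length(bad)) {
    stop("topotype individuals without a nominal species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ## topotype sets keyed by (species, population)
  topo_sets <- split(topo$individual,
                     paste(topo$nominal_species, topo$population, sep = "\r"))
  set_species <- vapply(strsplit(names(topo_sets), "\r"), `[[`, "", 1L)

  nominal <- stats::setNames(as.character(md$nominal_species), md$individual)

  names_out <- rep(NA_character_, assignment$n_entities)
  for (i in seq_along(assignment$entities)) {
    members <- assignment$entities[[i]]
    hit <- vapply(topo_sets, function(s) all(s %in% members), NA)
    if (any(hit)) {
      names_out[i] <- paste(sort(unique(set_species[hit])), collapse = "+")
    }
  }
  sp_k <- 0L
  for (i in seq_along(assignment$entities)) {
    if (!is.na(names_out[i])) next
    ids <- nominal[assignment$entities[[i]]]
    if (!anyNA(ids) && all(nzchar(ids)) && length(unique(ids)) == 1L) {
      names_out[i] <- unique(ids)
    } else {
      sp_k <- sp_k + 1L
      names_out[i] <- paste("sp", sp_k)
    }
  }
  assignment$name <- stats::setNames(names_out, names(assignment$entities))
  assignment
}
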