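## Build an ape phylo from a node spec: merge events recorded as
## (left child, right child, height). `tips` is a character vector of
## tip labels; merges reference either tips (by label) or earlier
## merges (by negative index). Returns a phylo with branch lengths
## derived from heights (tips at 0).
phylo_from_merges <- function(tip_labels, merges) {
  n <- length(tip_labels)
  stopifnot(nrow(merges) == n - 1L)
  ## ape ids: tips 1..n, internal n+1..2n-1; merge i -> internal id;
  ## order merges by increasing height so the last is the root
  ord <- order(merges$height)
  merges <- merges[ord, ]
  remap <- order(ord)                      # old merge index -> new row
  node_id <- function(ref, i_row) {
    if (ref > 0) ref else n + remap[-ref]
  }
  edge <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  elen <- numeric(2L * (n - 1L))
  heights <- c(rep(0, n), merges$height)
  ## root must get id n+1 in ape convention-free form; renumber so the
  ## highest merge is n+1, descending
  new_id <- c(seq_len(n), n + rev(seq_len(n - 1L)))
  for (i in seq_len(n - 1L)) {
    p <- new_id[n + i]
    for (child_ref in c(merges$left[i], merges$right[i])) {
      cid0 <- node_id(child_ref, i)
      cid <- new_id[cid0]
      row <- which(edge[, 1L] == 0L)[1L]
      edge[row, ] <- c(p, cid)
      elen[row] <- heights[n + i] - heights[cid0]
    }
  }
  phy <- list(edge = edge, edge.length = elen, Nnode = n - 1L,
              tip.label = tip_labels)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

## coalesce `labels` at pair rate lambda2 * n * (n-1); returns merges
## data.frame(left, right, height) with refs as in phylo_from_merges,
## using RNG from the current stream
sim_coalescent_merges <- function(labels, lambda2, t0 = 0) {
  n <- length(labels)
  active_ref <- seq_len(n)          # positive = tip index within labels
  height <- t0
  merges <- data.frame(left = integer(n - 1L), right = integer(n - 1L),
                       height = numeric(n - 1L))
  for (i in seq_len(n - 1L)) {
    k <- length(active_ref)
    height <- height + stats::rexp(1L, rate = lambda2 * k * (k - 1L))
    pick <- sample.int(k, 2L)
    merges$left[i] <- active_ref[pick[1L]]
    merges$right[i] <- active_ref[pick[2L]]
    merges$height[i] <- height
    active_ref <- c(active_ref[-pick], -i)
  }
  merges
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Forward simulation with per-lineage birth rate `lambda1`: while `j`
#' lineages exist the waiting time to the next speciation is
#' Exponential(`j * lambda1`). Growth starts from a single lineage and
#' stops at `k` tips; the present is placed one further
#' Exponential(`k * lambda1`) waiting time after the last birth, so the
#' youngest species has a positive stem length (by memorylessness this
#' is the time at which the next, unrealized, speciation would occur).
#'
#' @param k number of species (>= 1).
#' @param lambda1 speciation rate (> 0).
#' @param seed integer seed.
#' @return list: `phy` (an [ape::phylo]; `NULL` when `k = 1`),
#'   `crown_height` (root height; NA when `k = 1`), `stem_age` (named
#'   per-species height of the subtending speciation; `Inf` for
#'   `k = 1`), `tip_labels`.
#' @export
simulate_yule <- function(k, lambda1, seed = 1L) {
  stopifnot(k >= 1)
  if (!is.finite(lambda1) || lambda1 <= 0) {
    stop("lambda1 must be positive", call. = FALSE)
  }
  local_seed(seed, {
    labels <- paste0("sp", seq_len(k))
    if (k == 1L) {
      return(list(phy = NULL, crown_height = NA_real_,
                  stem_age = c(sp1 = Inf), tip_labels = labels))
    }
    ## forward event times measured from the origin
    t <- 0
    birth_time <- numeric(k - 1L)          # time of j -> j+1 split
    parent_of <- integer(k)                # mother lineage of each newborn
    last_event <- numeric(k)               # last split a lineage took part in
    for (j in seq_len(k - 1L)) {
      t <- t + stats::rexp(1L, rate = j * lambda1)
      birth_time[j] <- t
      mother <- sample.int(j, 1L)
      parent_of[j + 1L] <- mother
      last_event[mother] <- t
      last_event[j + 1L] <- t
    }
    present <- t + stats::rexp(1L, rate = k * lambda1)

    ## build merges backward: split j joins lineage j+1 with its mother's
    ## lineage at height present - birth_time[j]
    merges <- data.frame(left = integer(k - 1L), right = integer(k - 1L),
                         height = numeric(k - 1L))
    active <- as.list(seq_len(k))          # lineage index -> current ref
    mi <- 0L
    for (j in rev(seq_len(k - 1L))) {
      mi <- mi + 1L
      merges$left[mi] <- active[[parent_of[j + 1L]]]
      merges$right[mi] <- active[[j + 1L]]
      merges$height[mi] <- present - birth_time[j]
      active[[parent_of[j + 1L]]] <- -mi
    }
    phy <- phylo_from_merges(labels, merges)
    ## a species' stem age is the height of its parent node: the most
    ## recent split its lineage took part in
    stem <- present - last_event
    list(phy = phy, crown_height = max(merges$height),
         stem_age = stats::setNames(stem, labels), tip_labels = labels)
  })
}

#' Simulate a single-population coalescent tree
#'
#' Pure coalescent genealogy for `n` contemporaneous samples: while `n`
#' lineages remain the waiting time to the next coalescence is
#' Exponential(`lambda2 * n * (n - 1)`) and a uniformly random pair
#' merges. This is the generative form of the GMYC null model.
#'
#' @param n sample size (>= 3 for use with the GMYC fit).
#' @param lambda2 coalescent rate (> 0).
#' @param seed integer seed.
#' @param labels optional tip labels (default `t1..tn`).
#' @return an [ultrametric_tree()].
#' @export
simulate_null_tree <- function(n, lambda2, seed = 1L,
                               labels = paste0("t", seq_len(n))) {
  stopifnot(n >= 2, length(labels) == n)
  if (!is.finite(lambda2) || lambda2 <= 0) {
    stop("lambda2 must be positive", call. = FALSE)
  }
  phy <- local_seed(seed, {
    phylo_from_merges(labels, sim_coalescent_merges(labels, lambda2))
  })
  ultrametric_tree(phy)
}

#' Simulate a mixed Yule-coalescent tree
#'
#' The generative mirror of the GMYC model: a Yule species tree with
#' rate `lambda1` sets the between-species branching; each species'
#' `n_j` samples then coalesce at rate `lambda2 * n (n - 1)`,
#' rejection-sampled until the within-species MRCA is younger than the
#' species' stem age (rescaling would distort the conditional
#' coalescent density the GMYC likelihood assumes); the species
#' genealogies are grafted onto the species tree to form one ultrametric
#' gene tree. With `k = 1` there is no constraint and the output reduces
#' to [simulate_null_tree()] in distribution.
#'
#' @param k number of species.
#' @param lambda1 speciation rate.
#' @param n_j samples per species: scalar or length-`k` vector.
#' @param lambda2 coalescent rate; delimitation is easy when
#'   `lambda2 / lambda1` is large (within-species branching much faster
#'   than speciation).
#' @param seed integer seed.
#' @param max_reject rejection budget per species before erroring with
#'   advice to increase the rate separation.
#' @return list: `tree` (an [ultrametric_tree()]) and `truth` (class
#'   `simulation_truth`): `lambda1`, `lambda2`, `partition` (tip ->
#'   species), `n_species`, `sample_sizes`, `oldest_mrca`,
#'   `youngest_species_node`, `threshold` (their midpoint; the true
#'   boundary lies between the two), `seed`.
#' @export
simulate_mixed_tree <- function(k, lambda1, n_j, lambda2, seed = 1L,
                                max_reject = 1e5) {
  stopifnot(k >= 1)
  if (!is.finite(lambda2) || lambda2 <= 0) {
    stop("lambda2 must be positive", call. = FALSE)
  }
  if (length(n_j) == 1L) n_j <- rep(n_j, k)
  stopifnot(length(n_j) == k, all(n_j >= 1))

  sp <- simulate_yule(k, lambda1, seed = seed)
  res <- local_seed(seed + 101L, {
    sub_merges <- vector("list", k)
    mrca <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      if (n_j[j] == 1L) next
      stem <- sp$stem_age[j]
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > max_reject) {
          stop("rejection budget exhausted for species ", j,
               "; increase lambda2/lambda1 separation", call. = FALSE)
        }
        m <- sim_coalescent_merges(seq_len(n_j[j]), lambda2)
        if (max(m$height) < stem) break
      }
      sub_merges[[j]] <- m
      mrca[j] <- max(m$height)
    }
    list(sub_merges = sub_merges, mrca = mrca)
  })

  tip_labels <- unlist(lapply(seq_len(k), function(j) {
    paste0(sp$tip_labels[j], "_i", seq_len(n_j[j]))
  }))
  partition <- stats::setNames(rep(sp$tip_labels, n_j), tip_labels)

  ## assemble a global merge list: per-species merges reference the
  ## species' own tips; species-tree merges join species subtree roots
  offset <- c(0L, cumsum(n_j))[seq_len(k)]
  merges <- data.frame(left = integer(0), right = integer(0),
                       height = numeric(0))
  sp_ref <- integer(k)     # current ref of each species' subtree root
  for (j in seq_len(k)) {
    if (n_j[j] == 1L) {
      sp_ref[j] <- offset[j] + 1L
      next
    }
    m <- res$sub_merges[[j]]
    m$left <- ifelse(m$left > 0, m$left + offset[j], m$left - nrow(merges))
    m$right <- ifelse(m$right > 0, m$right + offset[j], m$right - nrow(merges))
    merges <- rbind(merges, m)
    sp_ref[j] <- -nrow(merges)
  }
  if (k > 1L) {
    ## replay the species tree's merges via its own topology
    sp_tree <- ultrametric_tree(sp$phy)
    n <- k
    kids <- child_list(sp$phy)
    internal <- order(sp_tree$heights[(n + 1L):(2L * n - 1L)]) + n  # ascending
    node_ref <- integer(2L * n - 1L)
    for (i in seq_len(n)) {
      lab <- sp$phy$tip.label[i]
      node_ref[i] <- sp_ref[match(lab, sp$tip_labels)]
    }
    for (nd in internal) {
      ch <- kids[[nd]]
      merges <- rbind(merges, data.frame(
        left = node_ref[ch[1L]], right = node_ref[ch[2L]],
        height = sp_tree$heights[nd]))
      node_ref[nd] <- -nrow(merges)
    }
  }
  phy <- phylo_from_merges(tip_labels, merges)
  tree <- ultrametric_tree(phy)

  oldest_mrca <- if (all(is.na(res$mrca))) NA_real_ else
    max(res$mrca, na.rm = TRUE)
  youngest_sp <- if (k > 1L) {
    min(ultrametric_tree(sp$phy)$heights[(k + 1L):(2L * k - 1L)])
  } else NA_real_
  thr <- if (!is.na(oldest_mrca) && !is.na(youngest_sp)) {
    (oldest_mrca + youngest_sp) / 2
  } else NA_real_
  truth <- structure(list(
    lambda1 = lambda1, lambda2 = lambda2,
    partition = partition, n_species = k,
    sample_sizes = stats::setNames(n_j, sp$tip_labels),
    oldest_mrca = oldest_mrca, youngest_species_node = youngest_sp,
    threshold = thr, seed = seed), class = "simulation_truth")
  list(tree = tree, truth = truth)
}

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Simulate a Jukes-Cantor alignment on a tree
#'
#' Evolves an equal-frequency root sequence along the tree under the
#' Jukes-Cantor model: over a branch of length `t` each site changes
#' with probability `(3/4)(1 - exp(-4 mu t / 3))`, uniformly to one of
#' the other three bases. Afterwards, with probability `het_rate` per
#' tip site, the base is replaced by the two-fold IUPAC code combining
#' it with a random distinct base, emulating diploid heterozygote calls
#' in chromatogram-derived sequences.
#'
#' @param tree an [ultrametric_tree()] (tip labels become record
#'   names).
#' @param bp alignment length (>= 1).
#' @param mu substitution rate multiplier on branch lengths.
#' @param het_rate per-site probability of an injected heterozygote
#'   code at each tip.
#' @param seed integer seed.
#' @return a [dna_alignment()].
#' @export
simulate_alignment <- function(tree, bp, mu = 1, het_rate = 0, seed = 1L) {
  stopifnot(inherits(tree, "ultrametric_tree"), bp >= 1,
            mu >= 0, het_rate >= 0, het_rate <= 1)
  phy <- tree$phy
  n <- tree$n_tips
  bases <- c("A", "C", "G", "T")
  local_seed(seed, {
    seqs <- vector("list", 2L * n - 1L)
    root <- n + 1L
    seqs[[root]] <- sample(bases, bp, replace = TRUE)
    ord <- ape::reorder.phylo(phy, "cladewise")
    for (i in seq_len(nrow(ord$edge))) {
      p <- ord$edge[i, 1L]
      ch <- ord$edge[i, 2L]
      t_br <- tree$heights[p] - tree$heights[ch]
      p_change <- 0.75 * (1 - exp(-4 * mu * t_br / 3))
      s <- seqs[[p]]
      hit <- which(stats::runif(bp) < p_change)
      if (length(hit)) {
        cur <- s[hit]
        new <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
        s[hit] <- new
      }
      seqs[[ch]] <- s
    }
    out <- vapply(seq_len(n), function(i) {
      s <- seqs[[i]]
      if (het_rate > 0) {
        hit <- which(stats::runif(bp) < het_rate)
        for (h in hit) {
          other <- sample(setdiff(bases, s[h]), 1L)
          key <- paste(sort(c(s[h], other)), collapse = "")
          s[h] <- IUPAC2[[key]]
        }
      }
      paste(s, collapse = "")
    }, "")
    dna_alignment(stats::setNames(out, phy$tip.label))
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "simulation truth: %d species, lambda1 = %g, lambda2 = %g, seed = %d\n",
    x$n_species, x$lambda1, x$lambda2, x$seed))
  if (!is.na(x$threshold)) {
    cat(sprintf("  true boundary in (%.4g, %.4g)\n",
                x$oldest_mrca, x$youngest_species_node))
  }
  invisible(x)
}

#' Write simulation truth and metadata tables
#'
#' Emits the truth TSV (tip, species) and a metadata TSV compatible
#' with [name_species()] (individual, population, nominal_species,
#' topotype, species_group), treating each species' first individual's
#' population as its type locality.
#'
#' @param truth a `simulation_truth`.
#' @param dir output directory.
#' @param pops_per_species populations to spread each species over.
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation_tables <- function(truth, dir, pops_per_species = 2L) {
  stopifnot(inherits(truth, "simulation_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tips <- names(truth$partition)
  sp <- unname(truth$partition)
  pop_idx <- integer(length(tips))
  for (s in unique(sp)) {
    idx <- which(sp == s)
    pop_idx[idx] <- rep_len(seq_len(pops_per_species), length(idx))
  }
  md <- data.frame(
    individual = tips,
    population = paste0(sp, "_pop", pop_idx),
    nominal_species = sp,
    topotype = as.integer(pop_idx == 1L),
    species_group = "simulated")
  truth_df <- data.frame(tip = tips, species = sp)
  p1 <- file.path(dir, "truth.tsv")
  p2 <- file.path(dir, "metadata.tsv")
  write_tsv_with_header(truth_df, p1, seed = truth$seed)
  write_tsv_with_header(md, p2, seed = truth$seed)
  invisible(c(truth = p1, metadata = p2))
}
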