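IUPAC_HET <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
ALN_ALPHABET <- c("A", "C", "G", "T", IUPAC_HET, "N", "?", "-")

#' Aligned sequence container
#'
#' A `dna_alignment` holds equal-length, upper-case DNA sequences over
#' the IUPAC nucleotide alphabet plus gap (`-`) and unknown (`?`, `N`).
#' `U` is mapped to `T` on construction and comparison is always
#' case-insensitive. Heterozygous positions of diploid markers are
#' expected as two-fold IUPAC ambiguity codes (R, Y, S, W, K, M, ...),
#' which the collapsing rule treats as characters in their own right.
#'
#' @param seqs named character vector of sequences; names are unique
#'   individual (or haplotype) identifiers.
#' @return an object of class `dna_alignment`: list with `seq` (named
#'   character vector), `bp` (alignment length), `n` (record count).
#' @export
dna_alignment <- function(seqs) {
  if (!is.character(seqs) || is.null(names(seqs)) ||
      anyDuplicated(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("`seqs` must be a character vector with unique nonempty names",
         call. = FALSE)
  }
  if (!length(seqs)) stop("empty alignment", call. = FALSE)
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  bp <- unique(nchar(seqs))
  if (length(bp) != 1L) {
    stop("sequences have unequal lengths: ",
         paste(sort(bp), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1L]]),
                 ALN_ALPHABET)
  if (length(bad)) {
    stop("invalid characters in alignment: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  structure(list(seq = seqs, bp = bp, n = length(seqs)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d bp\n", x$n, x$bp))
  invisible(x)
}

#' Read an alignment from FASTA
#'
#' Uses Biostrings for parsing (as a raw `BStringSet`, since `?` is not
#' in the DNA alphabet), then validates through [dna_alignment()].
#'
#' @param path FASTA file path.
#' @return a [dna_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))   # first token of the header
  dna_alignment(stats::setNames(as.character(ss), nm))
}

#' Write an alignment to FASTA (80-column wrap, IUPAC preserved)
#' @param aln a [dna_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  ss <- Biostrings::BStringSet(aln$seq)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Collapse identical sequences into haplotypes/genotypes
#'
#' Groups records by exact full-length string identity
#' (case-insensitive). Heterozygote ambiguity codes, `N`, `?` and `-`
#' each count as their own character and are never matched against a
#' compatible homozygous state, so `ACGT` and `ACRT` are different
#' haplotypes. Each group is represented by its lexicographically
#' smallest member name; groups appear in order of first occurrence, so
#' collapsing an already-collapsed alignment is the identity.
#'
#' @param aln a [dna_alignment()].
#' @return list with `alignment` (one record per unique sequence, named
#'   by representative) and `map` (class `collapse_map`: representative
#'   -> sorted member names).
#' @examples
#' aln <- dna_alignment(c(x = "ACGT", y = "ACGT", z = "ACRT"))
#' collapse_sequences(aln)$map
#' @export
collapse_sequences <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  groups <- split(names(aln$seq), factor(aln$seq, levels = unique(aln$seq)))
  reps <- vapply(groups, function(g) min(g), "")
  uniq <- stats::setNames(names(groups), reps)  # rep -> sequence
  map <- stats::setNames(lapply(groups, function(g) sort(g)), reps)
  class(map) <- "collapse_map"
  list(alignment = dna_alignment(uniq), map = map)
}

#' @export
print.collapse_map <- function(x, ...) {
  cat(sprintf("collapse map: %d groups, %d members\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

## alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seq, ""), use.names = FALSE),
              nrow = aln$n, ncol = aln$bp, byrow = TRUE)
  rownames(m) <- names(aln$seq)
  m
}

#' Alignment variation statistics
#'
#' Computes the per-data-set summary row: alignment length `bp`, number
#' of distinct sequences `K` (haplotypes for mtDNA, genotypes for a
#' nuclear marker), number of polymorphic sites `S` (>= 2 counted
#' states), number of parsimony-informative sites `S_i` (>= 2 states
#' each carried by >= 2 sequences), and `pct_Si = round(100 S_i / bp)`.
#'
#' Under the default `ambiguity_policy = "missing"` only A/C/G/T are
#' counted as states (ambiguity codes, `N`, `?` and gaps are excluded
#' from the site tally); under `"state"` every distinct symbol is its
#' own state. Collapsing, by contrast, always uses strict symbol
#' identity regardless of this flag.
#'
#' @param aln a [dna_alignment()].
#' @param ambiguity_policy `"missing"` (default) or `"state"`.
#' @return list of class `alignment_stats`: `bp`, `K`, `S`, `S_i`,
#'   `pct_Si`, `n`.
#' @export
alignment_stats <- function(aln, ambiguity_policy = c("missing", "state")) {
  stopifnot(inherits(aln, "dna_alignment"))
  ambiguity_policy <- match.arg(ambiguity_policy)
  m <- aln_matrix(aln)
  counted <- if (ambiguity_policy == "missing") c("A", "C", "G", "T")
             else ALN_ALPHABET
  S <- 0L
  S_i <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    tab <- tab[names(tab) %in% counted]
    if (length(tab) >= 2L) {
      S <- S + 1L
      if (sum(tab >= 2L) >= 2L) S_i <- S_i + 1L
    }
  }
  K <- length(collapse_sequences(aln)$map)
  structure(list(bp = aln$bp, K = K, S = S, S_i = S_i,
                 pct_Si = round(100 * S_i / aln$bp), n = aln$n),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf("n = %d, bp = %d, K = %d, S = %d, S_i = %d (%d%%)\n",
              x$n, x$bp, x$K, x$S, x$S_i, x$pct_Si))
  invisible(x)
}

#' Subsample one individual per population
#'
#' Draws exactly one record per population uniformly at random, with a
#' fixed seed so the reduced data set is reproducible. Populations are
#' processed in sorted order from one seeded RNG stream; the caller's
#' RNG state is left untouched.
#'
#' @param aln a [dna_alignment()].
#' @param metadata data.frame with columns `individual` and
#'   `population` covering every record, or a named character vector
#'   individual -> population.
#' @param seed integer seed.
#' @return a [dna_alignment()] with one record per population.
#' @export
subsample_one_per_population <- function(aln, metadata, seed = 1L) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.data.frame(metadata)) {
    pop <- stats::setNames(as.character(metadata$population),
                           as.character(metadata$individual))
  } else {
    pop <- metadata
  }
  miss <- setdiff(names(aln$seq), names(pop))
  if (length(miss)) {
    stop("records missing from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pop <- pop[names(aln$seq)]
  keep <- local_seed(seed, {
    unlist(lapply(split(names(pop), pop)[sort(unique(pop))], function(g) {
      g[sample.int(length(g), 1L)]
    }), use.names = FALSE)
  })
  dna_alignment(aln$seq[names(aln$seq) %in% keep])
}

#' Read the individual metadata table
#'
#' TSV with columns `individual`, `population`, `nominal_species`,
#' `topotype` (0/1) and optionally `species_group`. Lines starting with
#' `#` are ignored.
#'
#' @param path TSV file path.
#' @return a data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("individual", "population", "nominal_species", "topotype")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  md$individual <- as.character(md$individual)
  md$topotype <- as.integer(md$topotype)
  md
}
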