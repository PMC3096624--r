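test_that("alignment construction validates and normalizes input", {
  aln <- dna_alignment(c(x = "acgu", y = "ACGT"))
  expect_equal(unname(aln$seq), c("ACGT", "ACGT"))
  expect_equal(aln$bp, 4L)
  expect_error(dna_alignment(c(x = "ACG", y = "ACGT")), "unequal")
  expect_error(dna_alignment(c(x = "ACGT", x = "ACGT")), "unique")
  expect_error(dna_alignment(c(x = "ACXT")), "invalid characters")
})

test_that("collapsing groups exact duplicates with the strict IUPAC
           identity rule", {
  aln <- dna_alignment(c(x = "ACGT", y = "ACGT", z = "ACGA"))
  cs <- collapse_sequences(aln)
  expect_equal(length(cs$map), 2L)
  expect_equal(cs$map[["x"]], c("x", "y"))
  expect_equal(cs$map[["z"]], "z")

  ## heterozygote code is its own character: R matches neither A nor G
  aln2 <- dna_alignment(c(x = "ACGT", y = "ACRT"))
  expect_equal(length(collapse_sequences(aln2)$map), 2L)
  ## same for N, ? and gap against plain bases
  aln3 <- dna_alignment(c(a = "ACGT", b = "ACGN", c = "ACG?", d = "ACG-"))
  expect_equal(length(collapse_sequences(aln3)$map), 4L)
  ## but case differences collapse
  aln4 <- dna_alignment(c(a = "acgt", b = "ACGT"))
  expect_equal(length(collapse_sequences(aln4)$map), 1L)
})

test_that("collapsing is idempotent and invariant to record order", {
  set.seed(5)
  seqs <- stats::setNames(
    sample(c("ACGT", "ACRT", "AC-T", "ACGA"), 12, replace = TRUE),
    paste0("i", 1:12))
  aln <- dna_alignment(seqs)
  cs <- collapse_sequences(aln)
  ## idempotent: collapsing the collapsed alignment is the identity
  cs2 <- collapse_sequences(cs$alignment)
  expect_identical(cs2$alignment$seq, cs$alignment$seq)
  expect_true(all(lengths(cs2$map) == 1L))
  ## order-invariant K and groups
  perm <- sample(length(seqs))
  cs_p <- collapse_sequences(dna_alignment(seqs[perm]))
  expect_equal(length(cs_p$map), length(cs$map))
  expect_identical(cs_p$map[sort(names(cs_p$map))],
                   cs$map[sort(names(cs$map))])
  ## K never exceeds the record count
  expect_lte(length(cs$map), aln$n)
})

test_that("alignment statistics match the hand-counted toy and respect
           the ambiguity policy", {
  aln <- dna_alignment(c(a = "AAAAAA", b = "AAAAAT",
                         c = "AAAAGT", d = "AAAAGT"))
  st <- alignment_stats(aln)
  ## site 5: A,A,G,G informative; site 6: A,T,T,T polymorphic only
  expect_equal(st$S, 2L)
  expect_equal(st$S_i, 1L)
  expect_equal(st$K, 3L)
  expect_equal(st$bp, 6L)
  expect_equal(st$pct_Si, round(100 * 1 / 6))

  ident <- dna_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT",
                           d = "ACGT"))
  st0 <- alignment_stats(ident)
  expect_equal(c(st0$S, st0$S_i, st0$K), c(0L, 0L, 1L))

  ## ambiguity policy: R-vs-A site is invisible under "missing",
  ## polymorphic (and informative when duplicated) under "state"
  amb <- dna_alignment(c(a = "AR", b = "AR", c = "AA", d = "AA"))
  expect_equal(alignment_stats(amb, "missing")$S, 0L)
  st_state <- alignment_stats(amb, "state")
  expect_equal(st_state$S, 1L)
  expect_equal(st_state$S_i, 1L)
})

test_that("S and S_i are invariant to reordering and renaming", {
  set.seed(9)
  tr <- simulate_null_tree(8, lambda2 = 2, seed = 9)
  aln <- simulate_alignment(tr, bp = 100, mu = 0.5, het_rate = 0.02,
                            seed = 9)
  st <- alignment_stats(aln)
  perm <- sample(aln$n)
  renamed <- stats::setNames(aln$seq[perm], paste0("r", seq_len(aln$n)))
  st2 <- alignment_stats(dna_alignment(renamed))
  expect_equal(st2$S, st$S)
  expect_equal(st2$S_i, st$S_i)
  expect_true(st$S_i <= st$S && st$S <= st$bp)
})

test_that("one-per-population subsampling is deterministic and exact", {
  seqs <- stats::setNames(rep("ACGT", 6), paste0("i", 1:6))
  aln <- dna_alignment(seqs)
  md <- data.frame(individual = names(seqs),
                   population = rep(c("p1", "p2", "p3"), each = 2))
  sub <- subsample_one_per_population(aln, md, seed = 11)
  expect_equal(sub$n, 3L)
  pops <- md$population[match(names(sub$seq), md$individual)]
  expect_setequal(pops, c("p1", "p2", "p3"))
  ## determinism
  sub2 <- subsample_one_per_population(aln, md, seed = 11)
  expect_identical(sub2$seq, sub$seq)
  ## different seed is allowed to differ, caller RNG untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(subsample_one_per_population(aln, md, seed = 2))
  expect_identical(runif(1), before)
  ## missing metadata errors
  expect_error(subsample_one_per_population(aln, md[-1, ], seed = 1),
               "missing from metadata")
})

test_that("a 144-population table subsamples to 144 records", {
  n_pop <- 144L
  ids <- paste0("ind", seq_len(3L * n_pop))
  md <- data.frame(individual = ids,
                   population = rep(paste0("pop", seq_len(n_pop)), 3))
  aln <- dna_alignment(stats::setNames(rep("ACGTACGT", length(ids)), ids))
  sub <- subsample_one_per_population(aln, md, seed = 4)
  expect_equal(sub$n, n_pop)
})

test_that("FASTA round trip preserves sequences, names and IUPAC codes", {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  seqs <- c(h1 = strrep("ACGTRYKM", 30), h2 = strrep("AC?T-NSW", 30))
  aln <- dna_alignment(seqs)
  write_fasta_alignment(aln, tf)
  ## 80-column wrap
  expect_true(all(nchar(readLines(tf)) <= 80))
  aln2 <- read_fasta_alignment(tf)
  expect_identical(aln2$seq, aln$seq)
})

test_that("metadata reader enforces required columns", {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines("individual\tpopulation\nA\tp1", tf)
  expect_error(read_metadata(tf), "lacks columns")
})
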