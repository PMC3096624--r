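## Run `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All stochastic operations in
## the package route through this, so results are reproducible and the
## user's RNG state is never disturbed.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## TSV writer with a provenance header: package version, seed, digest.
write_tsv_with_header <- function(df, path, seed = NA, extra = character(0)) {
  hdr <- c(
    sprintf("# gmycdelim %s",
            as.character(utils::packageVersion("gmycdelim"))),
    sprintf("# seed: %s", seed),
    extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
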