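# Internal helpers shared across modules.

# Derive an independent RNG stream seed from a global seed so that adding an
# emitter never perturbs the draws of another. Kept strictly below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 2047L + as.integer(stream)
}

# Evaluate `expr` under a derived seed without disturbing the caller's RNG.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Reverse complement of a plain character scalar.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Positionwise mismatch count between two equal-length character scalars.
count_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Substitute bases at `positions` of sequence `x` with a uniformly chosen
# different base; returns list(seq, alt) where alt is the new base per position.
mutate_positions <- function(x, positions) {
  if (length(positions) == 0L)
    return(list(seq = x, alt = character(0)))
  r <- charToRaw(x)
  old <- rawToChar(r[positions], multiple = TRUE)
  # draw one of the three alternatives per site
  pick <- sample.int(3L, length(positions), replace = TRUE)
  alt <- vapply(seq_along(positions), function(i) {
    setdiff(BASES, old[i])[pick[i]]
  }, character(1))
  r[positions] <- charToRaw(paste(alt, collapse = ""))
  list(seq = rawToChar(r), alt = alt)
}

# round half away from zero (assembler-style coverage rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
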