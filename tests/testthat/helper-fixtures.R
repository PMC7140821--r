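# Shared fixtures: all synthetic, built in code at test time.

# one 12-column hit row (or several, vectorized)
mk_hits <- function(query, subject, bitscore, identity = 100,
                    aln_len = 1000, q_start = 1, q_end = aln_len,
                    s_start = 1, s_end = aln_len, evalue = 0,
                    mismatches = 0) {
  data.frame(query_id = query, subject_id = subject,
             identity_pct = identity, aln_len = aln_len,
             mismatches = mismatches, gap_opens = 0L,
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

# compact diploid simulation: one 600-kb chromosome, fixed block layout,
# 60 genes — enough structure for every stage, fast enough for unit tests
small_config <- function(seed = 11, ...) {
  sim_config(
    seed = seed,
    n_chromosomes = 1L,
    chrom_len = 6e5,
    block_spec = list(data.frame(
      len = c(150000L, 120000L, 180000L, 150000L),
      class = c("high", "low", "high", "low"))),
    n_genes = 60L,
    n_contaminants = 3L,
    ...)
}

small_assembly <- function(seed = 11, ...) {
  emit_assembly(simulate_diploid(small_config(seed, ...)))
}

# brute-force Nx oracle: scan every prefix of the descending-sorted lengths
oracle_nx <- function(lengths, frac) {
  l <- sort(lengths, decreasing = TRUE)
  total <- sum(l)
  for (i in seq_along(l)) {
    if (sum(l[seq_len(i)]) >= frac * total) return(l[i])
  }
  stop("unreachable")
}

# truth allele-pair keys for comparing pairings
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
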