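# Simulator structure, determinism, and the statistical properties the
# downstream stages rely on.

test_that("zero heterozygosity collapses the genome to one merged phase", {
  cfg <- small_config(snp_rate_high = 0, snp_rate_low = 0)
  sim <- simulate_diploid(cfg)
  expect_identical(as.character(sim$hap_a), as.character(sim$hap_b))
  expect_true(all(sim$truth$genes$true_phase == "merged"))
  expect_equal(nrow(sim$truth$snps), 0)
  # no separated contigs, no inter-haplotype variants
  asm <- emit_assembly(sim)
  dv <- emit_depth_and_vcf(asm)
  expect_equal(sum(dv$variants$gt == "0/1"), 0)
})

test_that("the same seed reproduces byte-identical genomes", {
  a <- simulate_diploid(small_config(seed = 5))
  b <- simulate_diploid(small_config(seed = 5))
  expect_identical(as.character(a$hap_a), as.character(b$hap_a))
  expect_identical(as.character(a$hap_b), as.character(b$hap_b))
  expect_identical(a$truth, b$truth)
  c <- simulate_diploid(small_config(seed = 6))
  expect_false(identical(as.character(a$hap_a), as.character(c$hap_a)))
})

test_that("p_high_het = 1 separates every gene", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_len = 5e5,
                    p_high_het = 1, n_genes = 40, n_contaminants = 0)
  sim <- simulate_diploid(cfg)
  expect_true(all(sim$truth$genes$true_phase == "separated"))
})

test_that("assembly emission yields two contigs per high run, one per low run", {
  # [high, low, high] -> 2 + 1 + 2 genome contigs
  asm <- small_assembly()  # block_spec high/low/high/low
  gct <- asm$contig_table[asm$contig_table$origin %in%
                            c("hapA", "hapB", "merged"), ]
  expect_equal(nrow(gct), 2 + 1 + 2 + 1)
  expect_equal(sum(gct$origin == "merged"), 2)

  # all-low genome with no contaminants: n_chromosomes + 1 organelle
  cfg <- sim_config(seed = 2, n_chromosomes = 2, chrom_len = 3e5,
                    p_high_het = 0, n_genes = 20, n_contaminants = 0)
  asm2 <- emit_assembly(simulate_diploid(cfg))
  expect_equal(length(asm2$contigs), 2 + 1)
})

test_that("recorded orientation flips match the emitted reverse complements", {
  asm <- small_assembly()
  sim <- asm$sim
  ct <- asm$contig_table
  for (i in which(ct$origin %in% c("hapA", "merged"))) {
    src <- substr(as.character(sim$hap_a[[ct$lg[i]]]),
                  ct$run_start[i], ct$run_end[i])
    emitted <- as.character(asm$contigs[[ct$contig_id[i]]])
    if (ct$orientation[i] == "-")
      src <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(src)))
    expect_identical(emitted, src)
  }
})

test_that("truth partner relation is an involution with no fixed points", {
  gm <- small_assembly()$gene_models
  sep <- gm[gm$true_phase == "separated", ]
  expect_true(all(!is.na(sep$partner)))
  expect_true(all(sep$partner != sep$model_id))
  back <- gm$partner[match(sep$partner, gm$model_id)]
  expect_identical(back, sep$model_id)
  expect_true(all(is.na(gm$partner[gm$true_phase == "merged"])))
})

test_that("depth tracks have the advertised means and cover every position once", {
  asm <- small_assembly()
  dv <- emit_depth_and_vcf(asm)
  ct <- asm$contig_table
  expect_identical(vapply(dv$depth, length, 1L)[ct$contig_id],
                   setNames(as.integer(ct$length), ct$contig_id))
  md <- contig_mean_depth(dv$depth)
  sep_id <- ct$contig_id[ct$origin == "hapA"][1]
  mer_id <- ct$contig_id[ct$origin == "merged"][1]
  expect_gt(md[sep_id], 97)   # haploid 100x over >= 120 kb
  expect_lt(md[sep_id], 103)
  ratio <- md[mer_id] / md[sep_id]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  org_id <- ct$contig_id[ct$origin == "organelle"]
  expect_gt(md[org_id], 4500)  # 50 x 100-fold
  cont_id <- ct$contig_id[ct$origin == "contaminant"][1]
  expect_lt(md[cont_id], 3)
})

test_that("heterozygous calls concentrate on merged contigs", {
  asm <- small_assembly()
  dv <- emit_depth_and_vcf(asm)
  ct <- asm$contig_table
  het <- dv$variants[dv$variants$gt == "0/1", ]
  origin <- ct$origin[match(het$contig, ct$contig_id)]
  per_bp <- table(origin) / tapply(ct$length, ct$origin, sum)[names(table(origin))]
  # merged regions carry true inter-haplotype variants (snp_rate_low);
  # separated contigs only the much rarer spurious calls (false_het_rate)
  expect_gt(per_bp[["merged"]], 10 * max(per_bp[["hapA"]], per_bp[["hapB"]]))
})

test_that("the relative reference diverges at the requested rate", {
  sim <- simulate_diploid(small_config())
  r0 <- emit_relative_reference(sim, divergence = 0)
  expect_identical(as.character(r0$reference[[1]]),
                   as.character(sim$hap_a[[1]]))

  r15 <- emit_relative_reference(sim, divergence = 0.15)
  a <- charToRaw(as.character(sim$hap_a[[1]]))
  b <- charToRaw(as.character(r15$reference[[1]]))
  ident <- 100 * mean(a == b)
  expect_gt(ident, 83)
  expect_lt(ident, 87)
})

test_that("a recorded inversion flips expected orientations of its contigs", {
  sim <- simulate_diploid(small_config())
  asm <- emit_assembly(sim)
  rr <- emit_relative_reference(sim, divergence = 0.05, n_inversions = 1)
  expect_equal(nrow(rr$inversions), 1)
  base <- expected_orientations(asm, emit_relative_reference(sim, 0.05))
  flipped <- expected_orientations(asm, rr)
  ct <- asm$contig_table
  inside <- ct$contig_id[!is.na(ct$lg) &
    ct$lg == rr$inversions$chrom &
    ct$run_start >= rr$inversions$start &
    ct$run_end <= rr$inversions$end]
  outside <- setdiff(names(base), inside)
  expect_true(all(flipped[inside] != base[inside]))
  expect_identical(flipped[outside], base[outside])
})

test_that("exact-truth hit tables reflect the simulated placements", {
  sim <- simulate_diploid(small_config())
  asm <- emit_assembly(sim)
  rr <- emit_relative_reference(sim, divergence = 0)
  ch <- chunk_reference(rr$reference)
  hits <- emit_hit_tables(ch, asm, rr, mode = "exact-truth")
  # zero divergence: every chunk's best hit is a perfect match (hits on the
  # other haplotype's contig legitimately sit at ~98%)
  best <- hits[!duplicated(hits$query_id), ]  # ordered by score per chunk
  expect_true(all(best$identity_pct == 100))
  # hits land on contigs from the chunk's own chromosome region
  ct <- asm$contig_table
  m <- match(hits$subject_id, ct$contig_id)
  expect_true(all(ct$lg[m] == sub("^LG_", "", ch$table$chrom_id[
    match(hits$query_id, ch$table$chunk_id)])))
  expect_error(emit_hit_tables(ch, asm, rr, mode = "nonsense"),
               "unknown mode")
})

test_that("paralog-confusion decoys are deterministic and ambiguity-filtered", {
  sim <- simulate_diploid(small_config())
  asm <- emit_assembly(sim)
  rr <- emit_relative_reference(sim, divergence = 0.05)
  ch <- chunk_reference(rr$reference)
  h1 <- emit_hit_tables(ch, asm, rr, mode = "paralog-confusion",
                        decoy_fraction = 0.2)
  h2 <- emit_hit_tables(ch, asm, rr, mode = "paralog-confusion",
                        decoy_fraction = 0.2)
  expect_identical(h1, h2)
  decoyed <- attr(h1, "decoyed_chunks")
  expect_equal(length(decoyed), floor(0.2 * nrow(ch$table)))
  anchors <- filter_chunk_hits(h1, ch)
  expect_equal(intersect(anchors$chunk_id, decoyed), character(0))
})
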