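# Score-ratio gene filtering, representative transcripts, annotation
# transfer, RBH allele pairing with the margin rule, and the haploid
# gene-number estimate.

test_that("gene-model filtering applies inclusive ratio and coverage floors", {
  qlen <- c(gKeep = 1000, gRatio = 1000, gCov = 1000, gNoHit = 1000)
  hits <- attach_query_coverage(rbind(
    mk_hits("gKeep", "db1", 50, q_start = 1, q_end = 300, aln_len = 300),
    mk_hits("gKeep", "db2", 20, q_start = 1, q_end = 900, aln_len = 900),
    mk_hits("gRatio", "db1", 48, q_start = 1, q_end = 300, aln_len = 300),
    mk_hits("gCov", "db1", 180, q_start = 1, q_end = 200, aln_len = 200)),
    qlen)
  self <- c(gKeep = 200, gRatio = 200, gCov = 200, gNoHit = 200)
  fg <- filter_gene_models(hits, self)
  expect_equal(fg$kept[fg$gene_id == "gKeep"], TRUE)    # ratio exactly 0.25
  expect_equal(fg$score_ratio[fg$gene_id == "gKeep"], 0.25)
  expect_equal(fg$kept[fg$gene_id == "gRatio"], FALSE)  # 0.24 < 0.25
  expect_equal(fg$kept[fg$gene_id == "gCov"], FALSE)    # ratio 0.9, qcov 0.2
  expect_equal(fg$kept[fg$gene_id == "gNoHit"], FALSE)  # no db hit
  expect_error(filter_gene_models(hits, c(gKeep = 0)), "gKeep")

  # monotone in both thresholds
  n_base <- sum(fg$kept)
  for (r in c(0.3, 0.5, 0.9))
    expect_lte(sum(filter_gene_models(hits, self, min_ratio = r)$kept),
               n_base)
  for (qc in c(0.3, 0.5, 0.9))
    expect_lte(sum(filter_gene_models(hits, self, min_qcov = qc)$kept),
               n_base)
})

test_that("representative transcript encodes the longest peptide", {
  tr <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    transcript_id = c("g1.1", "g1.2", "g2.1", "g3.2", "g3.1"),
    pep_len = c(100, 455, 77, 300, 300),
    cds_len = c(303, 1368, 234, 912, 900),
    stringsAsFactors = FALSE)
  rep <- pick_representative(tr)
  expect_equal(rep$transcript_id[rep$gene_id == "g1"], "g1.2")
  expect_equal(rep$transcript_id[rep$gene_id == "g2"], "g2.1")
  expect_equal(rep$transcript_id[rep$gene_id == "g3"], "g3.2")  # longer CDS
  # equal peptide and CDS: lexicographically smallest id
  tie <- data.frame(gene_id = "g4", transcript_id = c("g4.b", "g4.a"),
                    pep_len = 10, cds_len = 33, stringsAsFactors = FALSE)
  expect_equal(pick_representative(tie)$transcript_id, "g4.a")
})

test_that("annotation transfer prefers RBH, then best hit under the cutoff", {
  ref <- c(R1 = "kinase", R2 = "transporter", R3 = "unknown protein")
  rbh <- data.frame(id_a = "gA", id_b = "R1", stringsAsFactors = FALSE)
  fb <- rbind(
    mk_hits("gB", "R2", 500, evalue = 1e-5),
    mk_hits("gC", "R2", 400, evalue = 1e-3),   # above cutoff
    mk_hits("gD", "R9", 300, evalue = 1e-8))   # unknown reference id
  expect_warning(
    ann <- transfer_annotation(c("gA", "gB", "gC", "gD"), rbh, fb, ref),
    "R9")
  expect_equal(ann$provenance, c("rbh", "best_hit", "none", "none"))
  expect_equal(ann$annotation[1:2], c("kinase", "transporter"))
  expect_true(all(is.na(ann$annotation[3:4])))
})

test_that("allele pairing demands reciprocity and the 99% margin", {
  # boundary: second best at exactly 99% of best is still valid
  h <- rbind(
    mk_hits("a", c("b", "x"), c(100, 99)),
    mk_hits("b", c("a", "x"), c(100, 98)),
    mk_hits("x", "a", 10))
  p <- pair_alleles(h)
  expect_equal(nrow(p), 1)
  expect_true(p$valid)
  expect_equal(c(p$gene_a, p$gene_b), c("a", "b"))
  expect_equal(p$margin_a, 0.99)

  # second best above the margin: candidate pair, not valid
  h2 <- rbind(
    mk_hits("a", c("b", "x"), c(100, 99.5)),
    mk_hits("b", c("a", "x"), c(100, 90)),
    mk_hits("x", "a", 10))
  p2 <- pair_alleles(h2)
  expect_equal(nrow(p2), 1)
  expect_false(p2$valid)

  # no reciprocity: a's best is b but b's best is c
  h3 <- rbind(
    mk_hits("a", "b", 100),
    mk_hits("b", c("c", "a"), c(200, 100)),
    mk_hits("c", "b", 200))
  p3 <- pair_alleles(h3)
  expect_false(any(p3$gene_a == "a" | p3$gene_b == "a"))

  # exact tie for best: ambiguous, no pair
  h4 <- rbind(
    mk_hits("a", c("b", "c"), c(100, 100)),
    mk_hits("b", "a", 100),
    mk_hits("c", "a", 100))
  expect_equal(nrow(pair_alleles(h4)), 0)

  # self-hits are ignored
  h5 <- rbind(mk_hits("a", c("a", "b"), c(500, 100)),
              mk_hits("b", c("b", "a"), c(500, 100)))
  p5 <- pair_alleles(h5)
  expect_equal(nrow(p5), 1)
  expect_true(p5$valid)
})

test_that("pairing is a matching and tightening the margin never adds pairs", {
  set.seed(14)
  genes <- sprintf("m%03d", 1:60)
  rows <- list()
  for (i in seq(1, 60, by = 2)) {
    s <- runif(1, 500, 2000)
    rows[[length(rows) + 1L]] <- mk_hits(genes[i], genes[i + 1], s)
    rows[[length(rows) + 1L]] <- mk_hits(genes[i + 1], genes[i], s)
    # noise hits at random lower scores
    rows[[length(rows) + 1L]] <-
      mk_hits(genes[i], sample(genes[-c(i, i + 1)], 1), s * runif(1, 0.3, 1.1))
  }
  h <- do.call(rbind, rows)
  p99 <- pair_alleles(h, margin = 0.99)
  ids <- c(p99$gene_a[p99$valid], p99$gene_b[p99$valid])
  expect_equal(anyDuplicated(ids), 0)  # degree <= 1
  p95 <- pair_alleles(h, margin = 0.95)
  expect_lte(sum(p95$valid), sum(p99$valid))
  expect_lte(sum(pair_alleles(h, margin = 0.5)$valid), sum(p95$valid))
})

test_that("synthetic allele pairing is near-perfect and decoys are rejected", {
  asm <- small_assembly()
  hits <- emit_cds_hit_table(asm)
  p <- pair_alleles(hits)
  truth <- asm$gene_models[asm$gene_models$true_phase == "separated" &
                             grepl("_A$", asm$gene_models$model_id), ]
  got <- pair_key(p$gene_a[p$valid], p$gene_b[p$valid])
  want <- pair_key(truth$model_id, truth$partner)
  expect_gte(mean(got %in% want), 0.95)  # precision
  expect_gte(mean(want %in% got), 0.90)  # recall

  hd <- emit_cds_hit_table(asm, mode = "paralog-confusion",
                           decoy_fraction = 0.3)
  decoyed <- attr(hd, "decoyed_models")
  expect_gt(length(decoyed), 0)
  pd <- pair_alleles(hd)
  valid_ids <- c(pd$gene_a[pd$valid], pd$gene_b[pd$valid])
  expect_equal(intersect(valid_ids, decoyed), character(0))
  # decoys never create wrong pairs
  gotd <- pair_key(pd$gene_a[pd$valid], pd$gene_b[pd$valid])
  expect_true(all(gotd %in% want))
})

test_that("haploid gene-number arithmetic subtracts allelic copies", {
  est <- estimate_haploid_genes(1000, 400)
  expect_equal(est$n_allelic_copies, 200)
  expect_equal(est$haploid_estimate, 800)
  expect_equal(est$haploid_estimate_rounded, 1000)
  expect_equal(estimate_haploid_genes(500, 0)$haploid_estimate, 500)
  expect_equal(estimate_haploid_genes(500, 0)$n_allelic_copies, 0)
  expect_error(estimate_haploid_genes(100, 101), "exceeds")

  # synthetic: the estimate recovers the simulator's true gene count
  asm <- small_assembly()
  gm <- asm$gene_models
  md <- gene_mean_depth(emit_depth_and_vcf(asm)$depth, gm)
  cls <- classify_genes(md)
  n_sep <- sum(cls$phase_class == "separated")
  est2 <- estimate_haploid_genes(nrow(gm), n_sep)
  n_true <- length(unique(gm$gene_id))
  expect_lt(abs(est2$haploid_estimate - n_true) / n_true, 0.05)
})
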