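# Reference chunking, the built-in aligner, anchor filtering, linkage-group
# assignment, ordering/orientation and scaffold materialization.

test_that("chunking skips short chromosomes and drops remainders", {
  chroms <- c(exact = strrep("A", 100000),
              short = strrep("A", 99999))
  ch <- chunk_reference(chroms)
  expect_equal(nrow(ch$table), 100)
  expect_true(all(ch$table$chrom_id == "exact"))
  expect_equal(ch$table$index, 0:99)
  expect_equal(ch$table$start, 0:99 * 1000 + 1)

  tiny <- chunk_reference(c(t = strrep("A", 2500)),
                          map_config(min_chrom_len = 1))
  expect_equal(nrow(tiny$table), 2)  # 500-bp remainder dropped
  expect_true(all(Biostrings::width(tiny$seqs) == 1000))
})

test_that("the naive aligner finds exact, mutated and reverse-strand matches", {
  set.seed(31)
  ctg <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  chunk <- substr(ctg, 2001, 3000)
  chunks <- list(
    table = data.frame(chunk_id = "k0", chrom_id = "x", index = 0L,
                       start = 2001L, length = 1000L,
                       stringsAsFactors = FALSE),
    seqs = Biostrings::DNAStringSet(c(k0 = chunk)))

  h <- naive_chunk_align(chunks, c(ctg = ctg))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$q_cov, 1.0)
  expect_equal(c(h$s_start, h$s_end), c(2001, 3000))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctg)))
  h2 <- naive_chunk_align(chunks, c(rc = rc))
  expect_equal(nrow(h2), 1)
  expect_gt(h2$s_start, h2$s_end)  # minus-strand convention
  expect_equal(sort(c(h2$s_start, h2$s_end)), c(3001, 4000))

  # 15% mismatches: identity within [83, 87], matching a positionwise oracle
  pos <- sample.int(1000, 150)
  mchunk <- strsplit(chunk, "")[[1]]
  mchunk[pos] <- vapply(mchunk[pos],
                        function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                        character(1))
  mchunk <- paste(mchunk, collapse = "")
  chunks$seqs <- Biostrings::DNAStringSet(c(k0 = mchunk))
  h3 <- naive_chunk_align(chunks, c(ctg = ctg), min_score = 50)
  h3 <- h3[h3$subject_id == "ctg", ][1, ]
  oracle_mm <- sum(charToRaw(mchunk) != charToRaw(chunk))
  expect_equal(h3$identity_pct, 100 * (1 - oracle_mm / 1000))
  expect_gte(h3$identity_pct, 83)
  expect_lte(h3$identity_pct, 87)
})

test_that("anchor filtering applies inclusive floors and the strict ambiguity rule", {
  chunks <- list(table = data.frame(
    chunk_id = c("k0", "k1", "k2"), chrom_id = "LG1", index = 0:2,
    start = c(1, 1001, 2001), length = 1000, stringsAsFactors = FALSE))
  qlen <- c(k0 = 1000, k1 = 1000, k2 = 1000)

  # boundary hit: identity exactly 70, coverage exactly 0.70 -> anchor
  h <- attach_query_coverage(
    mk_hits("k0", "c1", 500, identity = 70, aln_len = 700,
            s_start = 101, s_end = 800), qlen)
  a <- filter_chunk_hits(h, chunks)
  expect_equal(nrow(a), 1)
  expect_equal(a$contig_pos, floor((101 + 800) / 2))
  expect_equal(a$map_pos, 0)
  expect_equal(a$lg, "LG1")

  # below either floor: no anchor
  h2 <- attach_query_coverage(rbind(
    mk_hits("k0", "c1", 500, identity = 69.9, aln_len = 700),
    mk_hits("k1", "c1", 500, identity = 90, aln_len = 699)), qlen)
  expect_equal(nrow(filter_chunk_hits(h2, chunks)), 0)

  # second hit at 90.5% of top: chunk excluded; at exactly 90.0%: kept
  h3 <- attach_query_coverage(rbind(
    mk_hits("k1", "c1", 100, aln_len = 1000),
    mk_hits("k1", "c2", 90.5, aln_len = 1000),
    mk_hits("k2", "c1", 100, aln_len = 1000),
    mk_hits("k2", "c2", 90.0, aln_len = 1000)), qlen)
  a3 <- filter_chunk_hits(h3, chunks)
  expect_equal(a3$chunk_id, "k2")
  expect_equal(a3$contig_id, "c1")
})

test_that("tightening identity or coverage floors never adds anchors", {
  set.seed(99)
  chunks <- list(table = data.frame(
    chunk_id = sprintf("k%03d", 0:199), chrom_id = "LG1", index = 0:199,
    start = 0:199 * 1000 + 1, length = 1000, stringsAsFactors = FALSE))
  qlen <- setNames(rep(1000, 200), chunks$table$chunk_id)
  hits <- attach_query_coverage(mk_hits(
    query = sample(chunks$table$chunk_id, 600, TRUE),
    subject = sample(paste0("c", 1:8), 600, TRUE),
    bitscore = runif(600, 100, 2000),
    identity = runif(600, 50, 100),
    aln_len = sample(400:1000, 600, TRUE)), qlen)
  base <- nrow(filter_chunk_hits(hits, chunks))
  for (ident in c(75, 80, 90)) {
    n <- nrow(filter_chunk_hits(hits, chunks, map_config(min_identity = ident)))
    expect_lte(n, base)
  }
  for (qc in c(0.75, 0.85, 0.95)) {
    n <- nrow(filter_chunk_hits(hits, chunks, map_config(min_qcov = qc)))
    expect_lte(n, base)
  }
  # anchor creation is per-chunk exclusive
  expect_lte(base, nrow(chunks$table))
})

test_that("linkage groups need a strict anchor majority and a support floor", {
  anc <- function(contig, lg, n) {
    data.frame(chunk_id = paste0(lg, seq_len(n)), contig_id = contig,
               contig_pos = seq_len(n) * 100, lg = lg,
               map_pos = seq_len(n), score = 100,
               s_start = 1, s_end = 1, stringsAsFactors = FALSE)
  }
  a <- rbind(anc("cMaj", "lg1", 5), anc("cMaj", "lg2", 1),
             anc("cFew", "lg1", 2),
             anc("cTie", "lg1", 3), anc("cTie", "lg2", 3))
  asg <- assign_linkage_groups(a)
  expect_equal(asg$lg[asg$contig_id == "cMaj"], "lg1")
  expect_true(is.na(asg$lg[asg$contig_id == "cFew"]))   # below support floor
  expect_true(is.na(asg$lg[asg$contig_id == "cTie"]))   # no strict majority
})

test_that("ordering sorts by mean map position and orients by rank correlation", {
  a <- data.frame(
    chunk_id = paste0("k", 1:6),
    contig_id = c("late", "late", "late", "early", "early", "early"),
    contig_pos = c(1000, 5000, 9000, 1000, 5000, 9000),
    lg = "LG1",
    map_pos = c(10, 9, 8, 1, 2, 3),
    score = 100, s_start = 1, s_end = 1, stringsAsFactors = FALSE)
  asg <- assign_linkage_groups(a)
  plan <- order_and_orient(a, asg, all_contigs = c("early", "late", "lost"))
  pl <- plan$placements
  expect_equal(pl$contig_id, c("early", "late"))  # mean 2.0 before mean 9.0
  expect_equal(pl$orientation[pl$contig_id == "late"], "-")
  expect_equal(pl$orientation[pl$contig_id == "early"], "+")
  expect_equal(plan$unplaced, "lost")

  # single-anchor contigs cannot be oriented
  single <- a[c(1, 4, 5), ]
  single$contig_id <- c("one", "two", "two")
  asg2 <- assign_linkage_groups(single, map_config(min_anchors_per_contig = 1))
  plan2 <- order_and_orient(single, asg2)
  expect_equal(
    plan2$placements$orientation[plan2$placements$contig_id == "one"], "?")
})

test_that("scaffold materialization conserves sequence and writes valid AGP", {
  contigs <- c(c1 = strrep("ACGT", 250), c2 = strrep("GGCC", 250))
  plan <- structure(list(
    placements = data.frame(
      lg = "LG1", position = 1:2, contig_id = c("c1", "c2"),
      orientation = c("+", "-"), n_anchors = c(5L, 5L),
      mean_map_pos = c(1, 2), rho = c(1, -1), stringsAsFactors = FALSE),
    unplaced = character(0)), class = "scaffold_plan")
  sc <- write_scaffolds(plan, contigs)
  expect_equal(Biostrings::width(sc$scaffolds)[[1]], 2100)  # 1000+100+1000
  expect_equal(sc$report$placed_bp, 2000)
  expect_equal(sc$report$total_bp, 2000)
  # the minus-oriented contig appears reverse-complemented after the gap
  s <- as.character(sc$scaffolds[[1]])
  expect_equal(substr(s, 1101, 2100),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(contigs[["c2"]]))))
  expect_equal(substr(s, 1001, 1100), strrep("N", 100))
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(sc$agp, f)
  agp <- read_agp(f)
  expect_equal(agp$component_type, c("W", "N", "W"))
  expect_equal(agp$object_end[3], 2100)

  # zero placed contigs: everything lands in the unplaced set
  plan0 <- structure(list(placements = plan$placements[0, ],
                          unplaced = c("c1", "c2")),
                     class = "scaffold_plan")
  sc0 <- write_scaffolds(plan0, contigs)
  expect_length(sc0$scaffolds, 0)
  expect_equal(sc0$report$unplaced_bp, 2000)
  expect_error(write_scaffolds(plan, contigs["c1"]), "c2")
})

test_that("the scaffolder recovers the truth on a clean synthetic genome", {
  sim <- simulate_diploid(small_config())
  asm <- emit_assembly(sim)
  rr <- emit_relative_reference(sim, divergence = 0.10)
  ch <- chunk_reference(rr$reference)
  hits <- emit_hit_tables(ch, asm, rr, mode = "exact-truth")
  anchors <- filter_chunk_hits(hits, ch)
  asg <- assign_linkage_groups(anchors)
  ct <- asm$contig_table
  retained <- ct$contig_id[ct$origin %in% c("hapA", "hapB", "merged")]
  plan <- order_and_orient(anchors, asg, all_contigs = retained)
  pl <- plan$placements

  # every placed contig on its true linkage group
  truth_lg <- setNames(paste0("LG_", ct$lg), ct$contig_id)
  expect_true(all(pl$lg == truth_lg[pl$contig_id]))
  # perfect order and orientation among placed contigs
  truth_ord <- setNames(ct$order_index, ct$contig_id)
  tau <- cor(pl$position, truth_ord[pl$contig_id], method = "kendall")
  expect_equal(tau, 1.0)
  expected <- expected_orientations(asm, rr)
  expect_identical(unname(pl$orientation), unname(expected[pl$contig_id]))
  # conservation: placed + unplaced is exactly the retained assembly
  sc <- write_scaffolds(plan, asm$contigs)
  lens <- setNames(ct$length, ct$contig_id)
  expect_equal(sc$report$total_bp, sum(lens[retained]))
})
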