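# Synthetic diploid genomes with block-structured heterozygosity, mock
# assemblies (phase-separated contig pairs + merged consensus contigs +
# contaminants + one organelle), depth tracks, variant calls, a diverged
# relative's pseudochromosomes and alignment hit tables — all with a truth
# table, so the whole curation pipeline is testable without external data.
#
# One global seed drives a per-emitter derived RNG stream, so adding or
# re-running one emitter never perturbs the draws of another.

STREAM_GENOME <- 1L
STREAM_ASSEMBLY <- 2L
STREAM_DEPTH <- 3L
STREAM_RELREF <- 4L
STREAM_HITS <- 5L
STREAM_CDS <- 7L

#' Simulation configuration
#'
#' Parameters of the synthetic diploid genome. Defaults describe a compact
#' but structurally faithful caricature of a highly heterozygous diploid
#' plant genome: two 2-Mbp chromosomes with alternating high- and
#' low-heterozygosity blocks, ~500 genes, haploid short-read depth of
#' 100-fold with Poisson noise, a handful of low-coverage contaminant
#' contigs and one very-high-depth organelle contig.
#'
#' @param seed Integer global seed; fixed seed implies byte-identical
#'   outputs across all emitters.
#' @param n_chromosomes,chrom_len Number and length (bp) of chromosomes.
#' @param block_len_mean Mean heterozygosity-block length (bp); block
#'   lengths are exponential, truncated below at `min_block_len`.
#' @param min_block_len Minimum block length (bp).
#' @param p_high_het Probability that a block is high-heterozygosity.
#' @param snp_rate_high,snp_rate_low Per-bp SNP rate between the two
#'   haplotypes inside high-/low-heterozygosity blocks.
#' @param n_genes,gene_len Number of genes to place (non-overlapping, each
#'   inside one block) and their length (bp).
#' @param gene_margin Distance (bp) kept between a gene and its block edge.
#' @param haploid_depth Mean per-haplotype read depth (fold).
#' @param depth_noise `"poisson"` or `"negbin"` per-position depth noise.
#' @param nb_size Negative-binomial size (dispersion) when
#'   `depth_noise = "negbin"`.
#' @param n_contaminants Number of contaminant contigs (kinds cycle through
#'   cross-sequenced plant, black-listed bacterium, nt-only bacterium).
#' @param contaminant_len,contaminant_depth Contaminant contig length (bp)
#'   and mean depth (fold).
#' @param organelle_len Organelle (plastid) contig length (bp).
#' @param organelle_depth_multiplier Organelle depth as a multiple of
#'   `haploid_depth`.
#' @param false_het_rate Per-bp rate of spurious heterozygous calls on
#'   phase-separated contigs (mapping noise).
#' @param hom_rate Per-bp rate of homozygous-alt calls on any contig
#'   (consensus deviations); exercises the genotype filter.
#' @param block_spec Optional explicit block layout overriding the random
#'   one: a list with one `data.frame(len, class)` per chromosome, `class`
#'   in `{"high","low"}`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_len = 2e6,
                       block_len_mean = 250000,
                       min_block_len = 120000,
                       p_high_het = 0.5,
                       snp_rate_high = 0.02,
                       snp_rate_low = 0.0005,
                       n_genes = 500L,
                       gene_len = 3000L,
                       gene_margin = 500L,
                       haploid_depth = 100,
                       depth_noise = c("poisson", "negbin"),
                       nb_size = 20,
                       n_contaminants = 4L,
                       contaminant_len = 120000L,
                       contaminant_depth = 1,
                       organelle_len = 150000L,
                       organelle_depth_multiplier = 50,
                       false_het_rate = 2e-5,
                       hom_rate = 1e-5,
                       block_spec = NULL) {
  depth_noise <- match.arg(depth_noise)
  stopifnot(
    snp_rate_high >= 0, snp_rate_high <= 1,
    snp_rate_low >= 0, snp_rate_low <= 1,
    p_high_het >= 0, p_high_het <= 1,
    haploid_depth > 0, n_chromosomes >= 1, chrom_len >= min_block_len
  )
  structure(as.list(environment()), class = "sim_config")
}

# split `total` items over `weights` exactly (largest-remainder rounding)
apportion <- function(total, weights) {
  if (total == 0L) return(integer(length(weights)))
  share <- total * weights / sum(weights)
  out <- floor(share)
  rem <- total - sum(out)
  if (rem > 0L) {
    extra <- order(share - out, decreasing = TRUE)[seq_len(rem)]
    out[extra] <- out[extra] + 1L
  }
  as.integer(out)
}

#' Simulate a diploid genome with heterozygosity blocks
#'
#' Generates haplotype A as random sequence, partitions each chromosome
#' into blocks, and derives haplotype B by substituting bases at
#' `snp_rate_high` (high-het blocks) or `snp_rate_low` (low-het blocks).
#' Genes are placed non-overlapping inside blocks and flagged by their
#' block's class: genes in high-heterozygosity blocks will be represented
#' by two phase-separated gene models after assembly, genes in
#' low-heterozygosity blocks by one merged model. If the high rate is zero
#' the haplotypes are identical, so every block (and gene) is merged.
#'
#' @param config A [sim_config()].
#' @return A `hc_sim` list: `hap_a`, `hap_b`
#'   ([Biostrings::DNAStringSet]), `truth` (list with `blocks`, `genes`,
#'   `snps` data frames) and `config`.
#' @export
simulate_diploid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, STREAM_GENOME, {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    blocks_l <- list()
    genes_l <- list()
    snps_l <- list()
    hap_a <- character(length(chroms))
    hap_b <- character(length(chroms))
    names(hap_a) <- names(hap_b) <- chroms
    # genes per chromosome, proportional to length
    genes_per_chrom <- apportion(config$n_genes,
                                 rep(config$chrom_len, length(chroms)))
    gene_no <- 0L
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      a <- random_dna(config$chrom_len)
      blocks <- draw_blocks(config, ci)
      blocks$chrom <- ch
      # SNPs between haplotypes, per block
      pos_l <- lapply(seq_len(nrow(blocks)), function(i) {
        rate <- if (blocks$class[i] == "high") config$snp_rate_high
                else config$snp_rate_low
        len <- blocks$end[i] - blocks$start[i] + 1L
        n <- rbinom(1L, len, rate)
        if (n == 0L) return(integer(0))
        sort(sample.int(len, n)) + blocks$start[i] - 1L
      })
      pos <- unlist(pos_l)
      mut <- mutate_positions(a, pos)
      hap_a[ch] <- a
      hap_b[ch] <- mut$seq
      if (length(pos) > 0L) {
        r <- charToRaw(a)
        snps_l[[ch]] <- data.frame(
          chrom = ch, pos = pos,
          a_base = rawToChar(r[pos], multiple = TRUE),
          b_base = mut$alt, stringsAsFactors = FALSE)
      }
      # gene placement: apportion over blocks by usable length, then slot
      usable <- blocks$end - blocks$start + 1L - 2L * config$gene_margin
      k <- apportion(genes_per_chrom[ci], pmax(usable, 0L))
      for (i in seq_len(nrow(blocks))) {
        if (k[i] == 0L) next
        slot <- floor(usable[i] / k[i])
        if (slot < config$gene_len)
          stop("n_genes too large to place without overlap (block ",
               i, " on ", ch, ")")
        off <- sample.int(slot - config$gene_len + 1L, k[i],
                          replace = TRUE) - 1L
        gstart <- blocks$start[i] + config$gene_margin +
          (seq_len(k[i]) - 1L) * slot + off
        genes_l[[length(genes_l) + 1L]] <- data.frame(
          gene_id = sprintf("g%04d", gene_no + seq_len(k[i])),
          chrom = ch,
          start = gstart,
          end = gstart + config$gene_len - 1L,
          block_id = blocks$block_id[i],
          true_phase = if (blocks$class[i] == "high") "separated" else "merged",
          stringsAsFactors = FALSE)
        gene_no <- gene_no + k[i]
      }
      blocks_l[[ch]] <- blocks
    }
    truth <- list(
      blocks = do.call(rbind, blocks_l)[, c("chrom", "block_id", "start",
                                            "end", "class")],
      genes = do.call(rbind, genes_l),
      snps = if (length(snps_l) > 0L) do.call(rbind, snps_l)
             else data.frame(chrom = character(0), pos = integer(0),
                             a_base = character(0), b_base = character(0))
    )
    rownames(truth$blocks) <- rownames(truth$genes) <-
      rownames(truth$snps) <- NULL
    structure(list(
      hap_a = Biostrings::DNAStringSet(hap_a),
      hap_b = Biostrings::DNAStringSet(hap_b),
      truth = truth,
      config = config
    ), class = "hc_sim")
  })
}

# Block layout for one chromosome: explicit spec, or exponential lengths
# with iid class labels. A zero high-het SNP rate degenerates every block
# to "low" (the haplotypes are identical there).
draw_blocks <- function(config, chrom_index) {
  if (!is.null(config$block_spec)) {
    bs <- config$block_spec[[chrom_index]]
    stopifnot(all(bs$class %in% c("high", "low")))
    len <- as.integer(bs$len)
    cls <- as.character(bs$class)
  } else {
    len <- integer(0)
    while (sum(len) < config$chrom_len) {
      l <- max(config$min_block_len,
               round(rexp(1L, 1 / config$block_len_mean)))
      len <- c(len, as.integer(l))
    }
    over <- sum(len) - config$chrom_len
    len[length(len)] <- len[length(len)] - as.integer(over)
    if (len[length(len)] < config$min_block_len && length(len) > 1L) {
      len[length(len) - 1L] <- len[length(len) - 1L] + len[length(len)]
      len <- len[-length(len)]
    }
    cls <- ifelse(runif(length(len)) < config$p_high_het, "high", "low")
  }
  if (config$snp_rate_high == 0) cls[] <- "low"
  end <- cumsum(len)
  data.frame(
    block_id = sprintf("b%02d", seq_along(len)),
    start = c(1L, head(end, -1L) + 1L),
    end = end,
    class = cls,
    stringsAsFactors = FALSE)
}

# Coalesce consecutive same-class blocks into runs; contig boundaries fall
# at class switches (phase-separated stretches cannot be joined to merged
# consensus across a switch).
block_runs <- function(blocks) {
  out <- lapply(split(blocks, blocks$chrom), function(b) {
    b <- b[order(b$start), ]
    grp <- cumsum(c(TRUE, b$class[-1L] != b$class[-nrow(b)]))
    runs <- do.call(rbind, lapply(split(seq_len(nrow(b)), grp), function(ix) {
      data.frame(chrom = b$chrom[ix[1L]],
                 start = min(b$start[ix]), end = max(b$end[ix]),
                 class = b$class[ix[1L]], stringsAsFactors = FALSE)
    }))
    runs$run_index <- seq_len(nrow(runs))
    runs
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Emit a mock assembly from a simulated diploid genome
#'
#' Each run of consecutive high-heterozygosity blocks yields two contigs
#' (one per haplotype); each low-heterozygosity run yields one merged
#' contig carrying haplotype A's sequence. Contaminant contigs and one
#' organelle contig are appended. Contig orientation is randomized
#' (recorded in the truth table) and the output order shuffled.
#'
#' @param sim A `hc_sim` from [simulate_diploid()].
#' @return A `hc_assembly` list: `contigs` ([Biostrings::DNAStringSet] in
#'   emitted order), `contig_table` (truth per contig: origin, linkage
#'   group, order index, orientation, run coordinates), `gene_models`
#'   (truth per gene model incl. `partner`), plus the embedded `sim`.
#' @export
emit_assembly <- function(sim) {
  stopifnot(inherits(sim, "hc_sim"))
  config <- sim$config
  with_stream(config$seed, STREAM_ASSEMBLY, {
    runs <- block_runs(sim$truth$blocks)
    seqs <- character(0)
    ct_l <- list()
    for (i in seq_len(nrow(runs))) {
      r <- runs[i, ]
      sub_a <- substr(as.character(sim$hap_a[[r$chrom]]), r$start, r$end)
      base <- sprintf("ctg_%s_r%02d", r$chrom, r$run_index)
      if (r$class == "high") {
        sub_b <- substr(as.character(sim$hap_b[[r$chrom]]), r$start, r$end)
        ids <- paste0(base, c("_A", "_B"))
        seqs[ids] <- c(sub_a, sub_b)
        ct_l[[i]] <- data.frame(
          contig_id = ids, origin = c("hapA", "hapB"),
          lg = r$chrom, order_index = r$run_index,
          run_start = r$start, run_end = r$end,
          length = nchar(sub_a), stringsAsFactors = FALSE)
      } else {
        id <- paste0(base, "_M")
        seqs[id] <- sub_a
        ct_l[[i]] <- data.frame(
          contig_id = id, origin = "merged",
          lg = r$chrom, order_index = r$run_index,
          run_start = r$start, run_end = r$end,
          length = nchar(sub_a), stringsAsFactors = FALSE)
      }
    }
    ct <- do.call(rbind, ct_l)
    # random orientation for genome contigs
    ct$orientation <- ifelse(runif(nrow(ct)) < 0.5, "+", "-")
    flip <- ct$orientation == "-"
    seqs[ct$contig_id[flip]] <- vapply(seqs[ct$contig_id[flip]],
                                       revcomp_chr, character(1))
    # contaminants: kinds cycle cross-sequenced plant / black-listed
    # bacterium / nt-only bacterium
    if (config$n_contaminants > 0L) {
      kinds <- rep(c("cross", "black", "nt"),
                   length.out = config$n_contaminants)
      ids <- sprintf("contam_%02d", seq_len(config$n_contaminants))
      for (id in ids) seqs[id] <- random_dna(config$contaminant_len)
      ct <- rbind(ct, data.frame(
        contig_id = ids, origin = "contaminant", lg = NA_character_,
        order_index = NA_integer_, run_start = NA_integer_,
        run_end = NA_integer_, length = config$contaminant_len,
        orientation = "+", stringsAsFactors = FALSE))
      ct$contam_kind <- NA_character_
      ct$contam_kind[match(ids, ct$contig_id)] <- kinds
    } else {
      ct$contam_kind <- NA_character_
    }
    seqs["organelle_pt"] <- random_dna(config$organelle_len)
    ct <- rbind(ct, data.frame(
      contig_id = "organelle_pt", origin = "organelle", lg = NA_character_,
      order_index = NA_integer_, run_start = NA_integer_,
      run_end = NA_integer_, length = config$organelle_len,
      orientation = "+", contam_kind = NA_character_,
      stringsAsFactors = FALSE))
    # gene models on contigs
    gm <- gene_models_on_contigs(sim$truth$genes, ct)
    # shuffle emitted contig order
    ord <- sample.int(length(seqs))
    contigs <- Biostrings::DNAStringSet(seqs[ord])
    rownames(ct) <- NULL
    structure(list(contigs = contigs, contig_table = ct,
                   gene_models = gm, sim = sim, config = config),
              class = "hc_assembly")
  })
}

# Project truth genes onto contig coordinates (handling orientation flips);
# separated genes yield an _A/_B model pair, merged genes one _M model.
gene_models_on_contigs <- function(genes, ct) {
  gct <- ct[ct$origin %in% c("hapA", "hapB", "merged"), ]
  out <- list()
  for (i in seq_len(nrow(gct))) {
    c_row <- gct[i, ]
    g <- genes[genes$chrom == c_row$lg &
               genes$start >= c_row$run_start &
               genes$end <= c_row$run_end, ]
    if (nrow(g) == 0L) next
    s0 <- g$start - c_row$run_start + 1L
    e0 <- g$end - c_row$run_start + 1L
    if (c_row$orientation == "-") {
      s <- c_row$length - e0 + 1L
      e <- c_row$length - s0 + 1L
      strand <- "-"
    } else {
      s <- s0; e <- e0; strand <- "+"
    }
    suffix <- switch(c_row$origin, hapA = "_A", hapB = "_B", merged = "_M")
    partner_suffix <- switch(c_row$origin, hapA = "_B", hapB = "_A",
                             merged = NA_character_)
    out[[length(out) + 1L]] <- data.frame(
      model_id = paste0(g$gene_id, suffix),
      gene_id = g$gene_id,
      contig = c_row$contig_id,
      start = s, end = e, strand = strand,
      true_phase = g$true_phase,
      partner = if (is.na(partner_suffix)) NA_character_
                else paste0(g$gene_id, partner_suffix),
      stringsAsFactors = FALSE)
  }
  gm <- do.call(rbind, out)
  gm <- gm[order(gm$model_id), ]
  rownames(gm) <- NULL
  gm
}

#' Emit a read-depth track and heterozygous variant calls
#'
#' Per-position depth is drawn around the haploid mean on phase-separated
#' contigs, twice that on merged contigs (reads of both alleles map to the
#' one consensus), `contaminant_depth` on contaminants and
#' `organelle_depth_multiplier * haploid_depth` on the organelle.
#' Heterozygous (0/1) records are placed on merged contigs at the
#' inter-haplotype difference positions; phase-separated contigs receive
#' only a low rate of spurious het calls, and a sprinkling of homozygous
#' 1/1 records exercises genotype filtering.
#'
#' @param asm A `hc_assembly` from [emit_assembly()].
#' @return List with `depth` (a [depth_track()]) and `variants` (a
#'   `data.frame` with `contig`, `pos`, `ref`, `alt`, `gt`).
#' @export
emit_depth_and_vcf <- function(asm) {
  stopifnot(inherits(asm, "hc_assembly"))
  config <- asm$config
  with_stream(config$seed, STREAM_DEPTH, {
    ct <- asm$contig_table
    mu <- c(hapA = config$haploid_depth, hapB = config$haploid_depth,
            merged = 2 * config$haploid_depth,
            contaminant = config$contaminant_depth,
            organelle =
              config$organelle_depth_multiplier * config$haploid_depth)
    track <- lapply(seq_len(nrow(ct)), function(i) {
      m <- mu[[ct$origin[i]]]
      n <- ct$length[i]
      if (config$depth_noise == "poisson") rpois(n, m)
      else rnbinom(n, size = config$nb_size, mu = m)
    })
    names(track) <- ct$contig_id
    class(track) <- "depth_track"

    seqs <- setNames(as.character(asm$contigs), names(asm$contigs))
    snps <- asm$sim$truth$snps
    var_l <- list()
    comp <- function(x) chartr("ACGT", "TGCA", x)
    for (i in seq_len(nrow(ct))) {
      c_row <- ct[i, ]
      sq <- seqs[[c_row$contig_id]]
      if (c_row$origin == "merged" && nrow(snps) > 0L) {
        s <- snps[snps$chrom %in% c_row$lg &
                  snps$pos >= c_row$run_start & snps$pos <= c_row$run_end, ]
        if (nrow(s) > 0L) {
          local <- s$pos - c_row$run_start + 1L
          ref <- s$a_base; alt <- s$b_base
          if (c_row$orientation == "-") {
            local <- c_row$length - local + 1L
            ref <- comp(ref); alt <- comp(alt)
          }
          ord <- order(local)
          var_l[[length(var_l) + 1L]] <- data.frame(
            contig = c_row$contig_id, pos = local[ord],
            ref = ref[ord], alt = alt[ord], gt = "0/1",
            stringsAsFactors = FALSE)
        }
      }
      if (c_row$origin %in% c("hapA", "hapB") && config$false_het_rate > 0) {
        n <- rbinom(1L, c_row$length, config$false_het_rate)
        if (n > 0L) {
          p <- sort(sample.int(c_row$length, n))
          ref <- substring(sq, p, p)
          alt <- vapply(ref, function(b)
            sample(setdiff(BASES, b), 1L), character(1))
          var_l[[length(var_l) + 1L]] <- data.frame(
            contig = c_row$contig_id, pos = p, ref = ref, alt = unname(alt),
            gt = "0/1", stringsAsFactors = FALSE)
        }
      }
      if (config$hom_rate > 0) {
        n <- rbinom(1L, c_row$length, config$hom_rate)
        if (n > 0L) {
          p <- sort(sample.int(c_row$length, n))
          ref <- substring(sq, p, p)
          alt <- vapply(ref, function(b)
            sample(setdiff(BASES, b), 1L), character(1))
          var_l[[length(var_l) + 1L]] <- data.frame(
            contig = c_row$contig_id, pos = p, ref = ref, alt = unname(alt),
            gt = "1/1", stringsAsFactors = FALSE)
        }
      }
    }
    variants <- if (length(var_l) > 0L) do.call(rbind, var_l)
      else data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0))
    variants <- variants[order(variants$contig, variants$pos), ]
    rownames(variants) <- NULL
    list(depth = track, variants = variants)
  })
}

#' Emit a diverged relative's pseudochromosomes
#'
#' Produces the scaffolding reference: a mutated copy of haplotype A
#' (substitutions at `divergence`), optionally with whole-run inversions
#' recorded in the truth. Pseudochromosome ids are `LG_<chrom>`.
#'
#' @param sim A `hc_sim`.
#' @param divergence Per-bp substitution rate in `[0, 0.3]`.
#' @param n_inversions Number of inversions; each reverse-complements one
#'   randomly chosen block run (so contig-level expected orientations stay
#'   well defined).
#' @return A `hc_relref` list: `reference` ([Biostrings::DNAStringSet]),
#'   `rel_variants` (chrom, pos of substitutions), `inversions`
#'   (chrom, start, end), `divergence`.
#' @export
emit_relative_reference <- function(sim, divergence = 0.1,
                                    n_inversions = 0L) {
  stopifnot(inherits(sim, "hc_sim"), divergence >= 0, divergence <= 0.3)
  config <- sim$config
  with_stream(config$seed, STREAM_RELREF, {
    runs <- block_runs(sim$truth$blocks)
    ref <- character(0)
    var_l <- list()
    for (ch in names(sim$hap_a)) {
      a <- as.character(sim$hap_a[[ch]])
      n <- rbinom(1L, nchar(a), divergence)
      pos <- if (n > 0L) sort(sample.int(nchar(a), n)) else integer(0)
      mut <- mutate_positions(a, pos)
      ref[paste0("LG_", ch)] <- mut$seq
      if (n > 0L)
        var_l[[ch]] <- data.frame(chrom = ch, pos = pos,
                                  stringsAsFactors = FALSE)
    }
    inv_l <- list()
    if (n_inversions > 0L) {
      pick <- sample.int(nrow(runs), min(n_inversions, nrow(runs)))
      for (i in pick) {
        r <- runs[i, ]
        key <- paste0("LG_", r$chrom)
        sq <- ref[[key]]
        seg <- substr(sq, r$start, r$end)
        ref[key] <- paste0(substr(sq, 1L, r$start - 1L), revcomp_chr(seg),
                           substr(sq, r$end + 1L, nchar(sq)))
        inv_l[[length(inv_l) + 1L]] <- data.frame(
          chrom = r$chrom, start = r$start, end = r$end,
          stringsAsFactors = FALSE)
      }
    }
    structure(list(
      reference = Biostrings::DNAStringSet(ref),
      rel_variants = if (length(var_l) > 0L) do.call(rbind, var_l)
        else data.frame(chrom = character(0), pos = integer(0)),
      inversions = if (length(inv_l) > 0L) do.call(rbind, inv_l)
        else data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)),
      divergence = divergence
    ), class = "hc_relref")
  })
}

#' Expected contig orientations given reference inversions
#'
#' The orientation the scaffolder should recover for each genome contig:
#' the emission flip recorded in the truth table, combined with any
#' reference inversion covering the contig's run.
#'
#' @param asm A `hc_assembly`.
#' @param relref A `hc_relref`.
#' @return Named character vector (`"+"`/`"-"`) over genome contigs.
#' @export
expected_orientations <- function(asm, relref) {
  ct <- asm$contig_table
  ct <- ct[ct$origin %in% c("hapA", "hapB", "merged"), ]
  inv <- relref$inversions
  flip_by_inv <- vapply(seq_len(nrow(ct)), function(i) {
    any(inv$chrom == ct$lg[i] & inv$start <= ct$run_start[i] &
        inv$end >= ct$run_end[i])
  }, logical(1))
  ori <- ifelse(xor(ct$orientation == "-", flip_by_inv), "-", "+")
  setNames(ori, ct$contig_id)
}

#' Emit chunk-vs-assembly alignment hit tables
#'
#' Generates the outfmt-6 hit table an aligner would produce for reference
#' chunks against the mock assembly, without running an external aligner.
#' In mode `"exact-truth"` each chunk hits the contig(s) that carry its
#' source region (both haplotype contigs in phase-separated regions, the
#' consensus contig in merged regions) with exact coordinates; identity and
#' score come from a positionwise comparison of the actual sequences. Mode
#' `"paralog-confusion"` additionally gives a deterministic fraction of
#' chunks a decoy second hit scoring above `decoy_min_ratio` of the top
#' hit, to exercise the ambiguity filter.
#'
#' @param chunks Result of [chunk_reference()] on the relative's
#'   pseudochromosomes.
#' @param asm A `hc_assembly`.
#' @param relref The `hc_relref` the chunks were cut from.
#' @param mode `"exact-truth"` or `"paralog-confusion"`.
#' @param decoy_fraction Fraction of chunks (with hits) receiving a decoy.
#' @param decoy_min_ratio Decoy bitscore ratio lower bound (exclusive).
#' @param min_hit_len Minimum chunk/contig overlap (bp) emitted as a hit.
#' @return Hit `data.frame` with `q_len`/`q_cov` attached, ordered by chunk
#'   then descending bitscore.
#' @export
emit_hit_tables <- function(chunks, asm, relref,
                            mode = c("exact-truth", "paralog-confusion"),
                            decoy_fraction = 0.2, decoy_min_ratio = 0.9,
                            min_hit_len = 100L) {
  if (!is.character(mode) || !all(mode %in% c("exact-truth",
                                              "paralog-confusion")))
    stop("unknown mode")
  mode <- match.arg(mode)
  stopifnot(inherits(asm, "hc_assembly"), inherits(relref, "hc_relref"))
  config <- asm$config
  with_stream(config$seed, STREAM_HITS, {
    tab <- chunks$table
    cseq <- setNames(as.character(chunks$seqs), names(chunks$seqs))
    aseq <- setNames(as.character(asm$contigs), names(asm$contigs))
    ct <- asm$contig_table
    gct <- ct[ct$origin %in% c("hapA", "hapB", "merged"), ]
    inv <- relref$inversions
    rows <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      chrom <- sub("^LG_", "", tab$chrom_id[i])
      clen <- tab$length[i]
      cs <- tab$start[i]; ce <- cs + clen - 1L
      # map the chunk interval from reference to haplotype-A coordinates
      ii <- which(inv$chrom == chrom & inv$start <= cs & inv$end >= ce)
      inv_flip <- length(ii) > 0L
      if (inv_flip) {
        as_ <- inv$start[ii[1L]] + inv$end[ii[1L]] - ce
        ae_ <- inv$start[ii[1L]] + inv$end[ii[1L]] - cs
      } else {
        straddle <- any(inv$chrom == chrom &
                        inv$start <= ce & inv$end >= cs)
        if (straddle && length(ii) == 0L) next  # partial overlap: no clean hit
        as_ <- cs; ae_ <- ce
      }
      cand <- gct[gct$lg == chrom & gct$run_start <= ae_ &
                  gct$run_end >= as_, ]
      if (nrow(cand) == 0L) next
      sub_rows <- list()
      for (j in seq_len(nrow(cand))) {
        cc <- cand[j, ]
        os <- max(as_, cc$run_start); oe <- min(ae_, cc$run_end)
        ov <- oe - os + 1L
        if (ov < min_hit_len) next
        # query coordinates on the chunk
        qs0 <- os - as_ + 1L; qe0 <- oe - as_ + 1L
        if (inv_flip) {
          q_start <- clen - qe0 + 1L; q_end <- clen - qs0 + 1L
        } else {
          q_start <- qs0; q_end <- qe0
        }
        # subject coordinates on the contig
        s0 <- os - cc$run_start + 1L; e0 <- oe - cc$run_start + 1L
        if (cc$orientation == "-") {
          s_lo <- cc$length - e0 + 1L; s_hi <- cc$length - s0 + 1L
        } else {
          s_lo <- s0; s_hi <- e0
        }
        minus <- xor(cc$orientation == "-", inv_flip)
        qsub <- substr(cseq[[tab$chunk_id[i]]], q_start, q_end)
        ssub <- substr(aseq[[cc$contig_id]], s_lo, s_hi)
        if (minus) ssub <- revcomp_chr(ssub)
        mm <- count_mismatches(qsub, ssub)
        score <- 2 * (ov - mm) - 3 * mm
        if (score <= 0) next
        sub_rows[[length(sub_rows) + 1L]] <- data.frame(
          query_id = tab$chunk_id[i], subject_id = cc$contig_id,
          identity_pct = 100 * (1 - mm / ov), aln_len = ov,
          mismatches = mm, gap_opens = 0L,
          q_start = q_start, q_end = q_end,
          s_start = if (minus) s_hi else s_lo,
          s_end = if (minus) s_lo else s_hi,
          evalue = 0, bitscore = score, stringsAsFactors = FALSE)
      }
      if (length(sub_rows) > 0L)
        rows[[i]] <- do.call(rbind, sub_rows)
    }
    hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(hits))
      hits <- as.data.frame(setNames(
        c(list(character(0), character(0)), replicate(10, numeric(0), FALSE)),
        HIT_COLS))
    hits <- hits[order(hits$query_id, -hits$bitscore), ]
    if (mode == "paralog-confusion" && nrow(hits) > 0L) {
      with_hits <- unique(hits$query_id)
      n_decoy <- floor(decoy_fraction * nrow(tab))
      if (n_decoy > length(with_hits))
        stop("decoy_fraction too large for the number of chunks with hits")
      decoyed <- sort(sample(with_hits, n_decoy))
      decoys <- lapply(decoyed, function(q) {
        top <- hits[hits$query_id == q, ][1L, ]
        other <- setdiff(gct$contig_id, top$subject_id)
        d <- top
        d$subject_id <- sample(other, 1L)
        d$bitscore <- top$bitscore *
          runif(1L, decoy_min_ratio + 1e-6, 0.999)
        d$s_start <- 1L; d$s_end <- d$aln_len
        d
      })
      hits <- rbind(hits, do.call(rbind, decoys))
      hits <- hits[order(hits$query_id, -hits$bitscore), ]
      attr(hits, "decoyed_chunks") <- decoyed
    }
    rownames(hits) <- NULL
    q_len <- setNames(tab$length, tab$chunk_id)
    finish_hits(hits, q_len)
  })
}

#' Emit contamination-screening hit tables
#'
#' Deterministic white-list (relative genome), black-list (bacterial
#' genomes), nt, cross-sequenced-plant and organelle-reference hit tables
#' matching the truth table: genome contigs hit the white list, the
#' contaminant kinds hit their respective lists, and the organelle contig
#' hits the organelle reference over 90\% of its length.
#'
#' @param asm A `hc_assembly`.
#' @return Named list of hit data frames: `white`, `black`, `nt`, `cross`,
#'   `organelle`.
#' @export
emit_screen_hit_tables <- function(asm) {
  stopifnot(inherits(asm, "hc_assembly"))
  ct <- asm$contig_table
  mk <- function(q, subject, identity, alen, evalue, score) {
    if (length(q) == 0L)
      return(as.data.frame(setNames(
        c(list(character(0), character(0)),
          replicate(10, numeric(0), FALSE)), HIT_COLS)))
    data.frame(query_id = q, subject_id = subject,
               identity_pct = identity, aln_len = alen,
               mismatches = round(alen * (100 - identity) / 100),
               gap_opens = 0L, q_start = 1L, q_end = alen,
               s_start = 1L, s_end = alen,
               evalue = evalue, bitscore = score,
               stringsAsFactors = FALSE)
  }
  genome <- ct$contig_id[ct$origin %in% c("hapA", "hapB", "merged")]
  black <- ct$contig_id[ct$contam_kind %in% "black"]
  ntc <- ct$contig_id[ct$contam_kind %in% "nt"]
  cross <- ct$contig_id[ct$contam_kind %in% "cross"]
  org <- ct$contig_id[ct$origin == "organelle"]
  org_len <- ct$length[ct$origin == "organelle"]
  list(
    white = mk(genome, "relative_genome", 85, 5000, 1e-180, 5000),
    black = mk(black, "bacteria_refseq", 98, 8000, 1e-80, 3000),
    nt = mk(ntc, "nt_bacterium", 96, 4000, 1e-30, 800),
    cross = mk(cross, "arabidopsis_chr1", 100, 2000, 0, 4000),
    organelle = mk(org, "relative_plastid", 95,
                   as.integer(floor(0.9 * org_len)), 0, 20000)
  )
}

#' Emit an all-vs-all CDS hit table for allele pairing
#'
#' For every phase-separated gene model pair the two allelic coding
#' sequences are compared positionwise (in chromosome-forward orientation)
#' and reported as reciprocal hits with the resulting score — the rows an
#' all-vs-all CDS search would retain. Unrelated random genes share no
#' meaningful similarity and produce no rows. Mode `"paralog-confusion"`
#' adds, for a deterministic fraction of pairs, a decoy second-best hit
#' scoring above `decoy_min_ratio` of the best, which the pairing margin
#' rule must reject.
#'
#' @param asm A `hc_assembly`.
#' @param mode `"exact-truth"` or `"paralog-confusion"`.
#' @param decoy_fraction Fraction of allele pairs receiving a decoy.
#' @param decoy_min_ratio Decoy score ratio lower bound (exclusive);
#'   defaults above the pairing margin of 0.99.
#' @return Hit `data.frame`; with decoys, attribute `decoyed_models` names
#'   the affected query models.
#' @export
emit_cds_hit_table <- function(asm,
                               mode = c("exact-truth", "paralog-confusion"),
                               decoy_fraction = 0.1,
                               decoy_min_ratio = 0.992) {
  mode <- match.arg(mode)
  stopifnot(inherits(asm, "hc_assembly"))
  config <- asm$config
  with_stream(config$seed, STREAM_CDS, {
    gm <- asm$gene_models
    sep <- gm[gm$true_phase == "separated", ]
    seqs <- setNames(as.character(asm$contigs), names(asm$contigs))
    fwd_seq <- function(row) {
      s <- substr(seqs[[row$contig]], row$start, row$end)
      if (row$strand == "-") revcomp_chr(s) else s
    }
    pairs <- sep[grepl("_A$", sep$model_id), ]
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, ]
      b <- sep[sep$model_id == a$partner, ]
      if (nrow(b) != 1L) next
      sa <- fwd_seq(a); sb <- fwd_seq(b)
      mm <- count_mismatches(sa, sb)
      len <- nchar(sa)
      score <- 2 * (len - mm) - 3 * mm
      if (score <= 0) next
      base <- data.frame(
        identity_pct = 100 * (1 - mm / len), aln_len = len,
        mismatches = mm, gap_opens = 0L, q_start = 1L, q_end = len,
        s_start = 1L, s_end = len, evalue = 0, bitscore = score,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(query_id = a$model_id, subject_id = b$model_id,
                         stringsAsFactors = FALSE), base)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(query_id = b$model_id, subject_id = a$model_id,
                         stringsAsFactors = FALSE), base)
    }
    hits <- do.call(rbind, rows)
    if (is.null(hits))
      hits <- as.data.frame(setNames(
        c(list(character(0), character(0)),
          replicate(10, numeric(0), FALSE)), HIT_COLS))
    hits <- hits[, HIT_COLS]
    if (mode == "paralog-confusion" && nrow(hits) > 0L) {
      qs <- sort(unique(hits$query_id[grepl("_A$", hits$query_id)]))
      n_decoy <- floor(decoy_fraction * length(qs))
      decoyed <- sort(sample(qs, n_decoy))
      decoys <- lapply(decoyed, function(q) {
        top <- hits[hits$query_id == q, ][1L, ]
        others <- setdiff(unique(hits$query_id),
                          c(q, top$subject_id))
        d <- top
        d$subject_id <- sample(others, 1L)
        d$bitscore <- top$bitscore * runif(1L, decoy_min_ratio + 1e-6, 0.9999)
        d
      })
      hits <- rbind(hits, do.call(rbind, decoys))
      attr(hits, "decoyed_models") <- decoyed
    }
    hits <- hits[order(hits$query_id, -hits$bitscore), ]
    rownames(hits) <- NULL
    hits
  })
}
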