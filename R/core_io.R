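# Readers/writers for the formats the pipeline touches and assembly-level
# statistics. Sequences are handled as Biostrings DNAStringSet; tabular data
# as plain data.frames (data.table used internally for fast file I/O).

HIT_COLS <- c("query_id", "subject_id", "identity_pct", "aln_len",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "evalue", "bitscore")

#' Assembly statistics (N50/N90, size, GC)
#'
#' Computes contig-level assembly statistics in the convention used by
#' assembler reports: N50 (N90) is the length of the contig at which the
#' cumulative sum over descending-sorted contig lengths first reaches at
#' least 50\% (90\%) of the total assembly size. GC is computed over non-N
#' bases; lowercase is treated as uppercase.
#'
#' @param contigs A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a FASTA file.
#' @return A one-row `data.frame` with columns `n_contigs`, `total_bp`,
#'   `max_len`, `gc_percent`, `n50`, `n90`.
#' @examples
#' assembly_stats(c(a = "ATGC", b = "GGGGCCCC"))
#' @export
assembly_stats <- function(contigs) {
  seqs <- as_dna(contigs)
  if (length(seqs) == 0L) stop("no sequences")
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  bad <- which(af[, "other"] > 0L)
  if (length(bad) > 0L) {
    # baseOnly lumps N with other IUPAC codes; N alone is legal
    afn <- Biostrings::alphabetFrequency(seqs[bad])
    legal <- rowSums(afn[, c("A", "C", "G", "T", "N"), drop = FALSE])
    truly_bad <- bad[legal < rowSums(afn)]
    if (length(truly_bad) > 0L)
      stop("illegal characters in sequence: ",
           paste(names(seqs)[truly_bad], collapse = ", "))
  }
  lens <- Biostrings::width(seqs)
  total <- sum(as.numeric(lens))
  acgt <- colSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- 100 * (acgt[["G"]] + acgt[["C"]]) / sum(acgt)
  data.frame(
    n_contigs = length(lens),
    total_bp = total,
    max_len = max(lens),
    gc_percent = gc,
    n50 = nx_length(lens, 0.5),
    n90 = nx_length(lens, 0.9),
    row.names = NULL
  )
}

#' Nx contig-length statistic
#'
#' The length of the contig at which the cumulative sum over
#' descending-sorted lengths first reaches at least `frac` of the total
#' (N50 at `frac = 0.5`, N90 at `frac = 0.9`).
#'
#' @param lengths Numeric vector of contig lengths (bp).
#' @param frac Fraction of the total to reach, in (0, 1].
#' @return The Nx length.
#' @examples
#' nx_stat(c(40, 30, 20, 10), 0.5)  # 30
#' @export
nx_stat <- function(lengths, frac = 0.5) {
  stopifnot(length(lengths) >= 1L, frac > 0, frac <= 1)
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(l)
  l[which(cs >= frac * cs[length(cs)])[1L]]
}

nx_length <- nx_stat

#' Sequencing coverage as fold of a genome size
#'
#' `round(total_bases / genome_size)` with half-away-from-zero rounding, the
#' convention behind statements such as "about 207x coverage".
#'
#' @param total_bases Total sequenced bases (bp).
#' @param genome_size Haploid genome size (bp); must be positive.
#' @return Integer-valued fold coverage.
#' @examples
#' coverage_fold(66.7e9, 322e6)  # 207
#' @export
coverage_fold <- function(total_bases, genome_size) {
  if (!is.numeric(genome_size) || genome_size <= 0)
    stop("genome_size must be > 0")
  round_half_away(total_bases / genome_size)
}

# Coerce character vector / file path to DNAStringSet.
as_dna <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) {
    up <- toupper(x)
    bad <- grepl("[^ACGTN]", up)
    if (any(bad))
      stop("illegal characters in sequence: ",
           paste(names(x)[bad] %||% which(bad), collapse = ", "))
    return(Biostrings::DNAStringSet(up))
  }
  stop("cannot interpret input as sequences")
}

#' Read pairwise alignment hits (BLAST outfmt-6 dialect)
#'
#' Reads a 12-column tab-separated hit table (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bitscore). Query coordinates must be
#' ascending; minus-strand matches are encoded on the subject coordinates
#' only (`s_start > s_end`), as BLAST does. When a query length table is
#' supplied, the fraction of the query covered by each alignment is attached
#' as `q_cov`.
#'
#' @param path Path to the tab-separated hit file.
#' @param q_len Optional named numeric vector mapping every query id to its
#'   length in bp.
#' @return A `data.frame` of hits in file order, with `q_len`/`q_cov`
#'   columns when `q_len` was given.
#' @export
read_blast_hits <- function(path, q_len = NULL) {
  raw <- if (file.size(path) == 0L) data.table::data.table()
    else data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character", fill = FALSE)
  if (nrow(raw) == 0L) {
    hits <- as.data.frame(setNames(
      c(list(character(0), character(0)), replicate(10, numeric(0), FALSE)),
      HIT_COLS))
    return(finish_hits(hits, q_len))
  }
  if (ncol(raw) != 12L)
    stop("expected 12 tab-separated columns, found ", ncol(raw))
  setnames(raw, HIT_COLS)
  hits <- as.data.frame(raw)
  num_cols <- HIT_COLS[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(hits[[cc]]))
    bad <- which(is.na(v) & !is.na(hits[[cc]]))
    if (length(bad) > 0L)
      stop("non-numeric value in column '", cc, "' at line ", bad[1L])
    hits[[cc]] <- v
  }
  finish_hits(hits, q_len)
}

finish_hits <- function(hits, q_len) {
  if (any(hits$q_end < hits$q_start))
    stop("q_end < q_start at line ",
         which(hits$q_end < hits$q_start)[1L],
         ": query coordinates must be ascending")
  if (!is.null(q_len)) {
    unknown <- setdiff(unique(hits$query_id), names(q_len))
    if (length(unknown) > 0L)
      stop("query id(s) missing from length table: ",
           paste(head(unknown, 5L), collapse = ", "))
    hits$q_len <- as.numeric(q_len[hits$query_id])
    hits$q_cov <- (abs(hits$q_end - hits$q_start) + 1) / hits$q_len
  }
  hits
}

#' Attach query lengths and coverage fractions to a hit table
#'
#' @param hits Hit `data.frame` in the layout of [read_blast_hits()].
#' @param q_len Named numeric vector mapping every query id to its length.
#' @return `hits` with `q_len` and `q_cov` columns.
#' @export
attach_query_coverage <- function(hits, q_len) {
  finish_hits(hits, q_len)
}

#' Write hits in 12-column outfmt-6 layout
#'
#' @param hits Hit `data.frame` as returned by [read_blast_hits()]; extra
#'   columns (`q_len`, `q_cov`) are dropped on output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_blast_hits <- function(hits, path) {
  data.table::fwrite(hits[, HIT_COLS, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-position read depth track
#'
#' Builds a depth track from a samtools-depth-like table (contig, 1-based
#' position, depth). Positions absent from the table are depth 0; every
#' contig's vector spans its full length, so `contig_lengths` must cover all
#' contigs in the table.
#'
#' @param x A `data.frame` with columns `contig`, `pos`, `depth`, or the
#'   path to a 3-column tab-separated file of that layout.
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @return A `depth_track` object: a named list of integer vectors, one per
#'   contig, of length equal to the contig.
#' @export
depth_track <- function(x, contig_lengths) {
  if (is.character(x) && length(x) == 1L) {
    x <- data.table::fread(x, header = FALSE, sep = "\t",
                           col.names = c("contig", "pos", "depth"))
    x <- as.data.frame(x)
  }
  stopifnot(all(c("contig", "pos", "depth") %in% names(x)))
  missing <- setdiff(unique(as.character(x$contig)), names(contig_lengths))
  if (length(missing) > 0L)
    stop("contig(s) in depth table but not in lengths: ",
         paste(head(missing, 5L), collapse = ", "))
  track <- lapply(names(contig_lengths), function(ct) {
    v <- integer(contig_lengths[[ct]])
    rows <- x$contig == ct
    if (any(rows)) v[x$pos[rows]] <- as.integer(x$depth[rows])
    v
  })
  names(track) <- names(contig_lengths)
  structure(track, class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("depth_track with", length(x), "contigs,",
      format(sum(vapply(x, length, 1L)), big.mark = ","), "positions\n")
  invisible(x)
}

#' Mean read depth per contig
#'
#' @param track A `depth_track` (see [depth_track()]).
#' @return Named numeric vector of mean depths.
#' @export
contig_mean_depth <- function(track) {
  vapply(track, mean, numeric(1))
}

#' Write a depth track as a 3-column TSV
#'
#' Emits every position of every contig (including zero-depth positions) in
#' samtools-depth layout: contig, 1-based position, depth.
#'
#' @param track A `depth_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_tsv <- function(track, path) {
  dt <- data.table::rbindlist(lapply(names(track), function(ct) {
    data.table::data.table(contig = ct, pos = seq_along(track[[ct]]),
                           depth = track[[ct]])
  }))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

AGP_COLS <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "component_id", "component_beg",
              "component_end", "orientation")

#' Read an AGP v2.1 file
#'
#' @param path Path to an AGP file; `#`-prefixed header lines are skipped.
#' @return A `data.frame` with the nine AGP columns; for gap rows the
#'   component columns hold gap length / gap type / linkage as in the spec.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(as.data.frame(setNames(replicate(9, character(0), FALSE), AGP_COLS)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L))
    stop("AGP rows must have 9 tab-separated fields")
  agp <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(agp) <- AGP_COLS
  for (cc in c("object_beg", "object_end", "part_number"))
    agp[[cc]] <- as.numeric(agp[[cc]])
  agp
}

#' Write an AGP v2.1 file
#'
#' @param agp `data.frame` with the nine AGP columns (see [read_agp()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  out <- agp[, AGP_COLS, drop = FALSE]
  body <- do.call(paste, c(lapply(out, function(x) {
    if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else as.character(x)
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports `gene` features from a GFF3 file; 1-based inclusive coordinates
#' (GFF3 convention) are kept as-is.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  data.frame(
    gene_id = as.character(gr$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per row plus a matching `mRNA` and single-span
#' `CDS` child, the minimal structure downstream consumers need.
#'
#' @param genes `data.frame` with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  esc <- function(x) gsub("[\t\n;=]", "_", x)
  g <- esc(genes$gene_id)
  lines <- c(
    "##gff-version 3",
    as.vector(rbind(
      sprintf("%s\thapcurate\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              genes$contig, genes$start, genes$end, genes$strand, g),
      sprintf("%s\thapcurate\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              genes$contig, genes$start, genes$end, genes$strand, g, g),
      sprintf("%s\thapcurate\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              genes$contig, genes$start, genes$end, genes$strand, g, g)
    ))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read heterozygosity-relevant fields from a VCF
#'
#' Extracts CHROM, POS, REF, ALT and the first sample's GT from a VCF v4.x
#' file (via \pkg{vcfR}).
#'
#' @param path Path to a VCF file.
#' @return `data.frame` with columns `contig`, `pos`, `ref`, `alt`, `gt`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  data.frame(
    contig = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    gt = as.character(gt[, 1L]),
    stringsAsFactors = FALSE
  )
}

#' Write a minimal single-sample VCF
#'
#' Writes CHROM/POS/REF/ALT plus a GT-only FORMAT column for one sample —
#' the fields consumed by the haplophase analysis.
#'
#' @param variants `data.frame` with columns `contig`, `pos`, `ref`, `alt`,
#'   `gt`.
#' @param path Output path.
#' @param sample Sample name for the header.
#' @param contig_lengths Optional named vector; when given, `##contig`
#'   header lines are emitted.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, path, sample = "sample1",
                      contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=hapcurate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  hdr <- c(hdr,
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  variants$contig, as.integer(variants$pos),
                  variants$ref, variants$alt, variants$gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}
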