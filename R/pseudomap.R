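# Pseudo-genetic-map scaffolding: a related species' pseudochromosomes are
# cut into 1-kb chunks whose known order serves as a map; filtered chunk
# hits anchor assembly contigs onto (linkage group, map position), and a
# single-map ordering/orientation step arranges the contigs into scaffolds.

#' Pseudo-genetic-map configuration
#'
#' @param chunk_len Reference chunk length (bp).
#' @param min_chrom_len Minimum pseudochromosome length chunked (bp).
#' @param min_identity Minimum percent identity of a considered hit
#'   (inclusive).
#' @param min_qcov Minimum fraction of the chunk covered by the alignment
#'   (inclusive).
#' @param ambiguity_ratio A chunk yields no anchor when its second hit
#'   scores strictly more than this fraction of the top hit.
#' @param min_anchors_per_contig Contigs with fewer anchors stay unplaced.
#' @param orient_min_abs_rho Minimum |rank correlation| between contig and
#'   map positions for a called orientation; below it the orientation is
#'   `"?"`.
#' @param gap_len N-gap length (bp) between consecutive contigs in a
#'   scaffold.
#' @return A `map_config` list.
#' @export
map_config <- function(chunk_len = 1000L,
                       min_chrom_len = 100000L,
                       min_identity = 70,
                       min_qcov = 0.70,
                       ambiguity_ratio = 0.90,
                       min_anchors_per_contig = 3L,
                       orient_min_abs_rho = 0.3,
                       gap_len = 100L) {
  stopifnot(ambiguity_ratio > 0, ambiguity_ratio < 1, chunk_len >= 1)
  structure(as.list(environment()), class = "map_config")
}

#' Cut reference pseudochromosomes into map chunks
#'
#' Chromosomes shorter than `min_chrom_len` are skipped; the trailing
#' remainder shorter than `chunk_len` is dropped. Chunk ids encode
#' chromosome and 0-based ordinal index, and the chunk order along each
#' chromosome is the pseudo genetic map.
#'
#' @param chromosomes A [Biostrings::DNAStringSet], named character vector
#'   or FASTA path.
#' @param config A [map_config()].
#' @return List with `table` (`chunk_id`, `chrom_id`, `index`, `start`,
#'   `length`) and `seqs` (chunk [Biostrings::DNAStringSet]).
#' @export
chunk_reference <- function(chromosomes, config = map_config()) {
  seqs <- as_dna(chromosomes)
  keep <- Biostrings::width(seqs) >= config$min_chrom_len
  seqs <- seqs[keep]
  tab_l <- list()
  chunk_seqs <- character(0)
  for (ch in names(seqs)) {
    len <- length(seqs[[ch]])
    n <- len %/% config$chunk_len
    if (n == 0L) next
    idx <- seq_len(n) - 1L
    start <- idx * config$chunk_len + 1L
    ids <- sprintf("%s.%06d", ch, idx)
    s <- as.character(seqs[[ch]])
    chunk_seqs[ids] <- substring(s, start, start + config$chunk_len - 1L)
    tab_l[[ch]] <- data.frame(chunk_id = ids, chrom_id = ch, index = idx,
                              start = start, length = config$chunk_len,
                              stringsAsFactors = FALSE)
  }
  tab <- if (length(tab_l) > 0L) do.call(rbind, tab_l)
    else data.frame(chunk_id = character(0), chrom_id = character(0),
                    index = integer(0), start = integer(0),
                    length = integer(0))
  rownames(tab) <- NULL
  list(table = tab,
       seqs = Biostrings::DNAStringSet(chunk_seqs))
}

#' Naive seed-and-extend chunk aligner
#'
#' A self-contained ungapped aligner for testing the map stages without an
#' external alignment tool: shared k-mers between chunk and contig (both
#' strands) seed candidate diagonals; each distinct diagonal is evaluated
#' by a full positionwise comparison of the overlapping span, scored
#' `2*matches - 3*mismatches`. One hit row is reported per distinct local
#' match with score above `min_score`, ordered by chunk then descending
#' score. Minus-strand matches carry `s_start > s_end`.
#'
#' @param chunks Result of [chunk_reference()] (or any named sequences via
#'   a list with `seqs`).
#' @param contigs Contig sequences ([Biostrings::DNAStringSet], named
#'   character vector or FASTA path).
#' @param k Seed k-mer length (>= 8).
#' @param seed_stride Sample a seed every this many bp along the chunk.
#' @param min_score Minimum reported score.
#' @return Hit `data.frame` with `q_len`/`q_cov` attached.
#' @export
naive_chunk_align <- function(chunks, contigs, k = 12L, seed_stride = 25L,
                              min_score = 100) {
  stopifnot(k >= 8L)
  cont <- as_dna(contigs)
  cseqs <- setNames(as.character(cont), names(cont))
  qseqs <- setNames(as.character(chunks$seqs), names(chunks$seqs))
  # k-mer index over contigs, both strands folded into forward coordinates
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (ct in names(cseqs)) {
    s <- cseqs[[ct]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    for (i in seq_len(n)) {
      key <- kmers[i]
      index[[key]] <- rbind(index[[key]],
                            cbind(match(ct, names(cseqs)), i))
    }
  }
  rows <- list()
  for (q in names(qseqs)) {
    qs <- qseqs[[q]]
    qlen <- nchar(qs)
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") qs else revcomp_chr(qs)
      starts <- unique(c(seq(1L, max(1L, qlen - k + 1L), by = seed_stride),
                         max(1L, qlen - k + 1L)))
      seen <- new.env(hash = TRUE, parent = emptyenv())
      for (sp in starts) {
        key <- substr(qq, sp, sp + k - 1L)
        hitpos <- index[[key]]
        if (is.null(hitpos)) next
        for (r in seq_len(nrow(hitpos))) {
          ct <- names(cseqs)[hitpos[r, 1L]]
          diag <- hitpos[r, 2L] - sp
          dkey <- paste(ct, diag, strand)
          if (!is.null(seen[[dkey]])) next
          seen[[dkey]] <- TRUE
          # overlap of the full chunk on this diagonal, clipped at edges
          slen <- nchar(cseqs[[ct]])
          a_start <- max(1L, 1L + diag) - diag   # on qq
          a_end <- min(qlen, slen - diag)
          if (a_end <= a_start) next
          sub_q <- substr(qq, a_start, a_end)
          sub_s <- substr(cseqs[[ct]], a_start + diag, a_end + diag)
          mm <- count_mismatches(sub_q, sub_s)
          ov <- a_end - a_start + 1L
          score <- 2 * (ov - mm) - 3 * mm
          if (score < min_score) next
          if (strand == "+") {
            q_start <- a_start; q_end <- a_end
            s_start <- a_start + diag; s_end <- a_end + diag
          } else {
            q_start <- qlen - a_end + 1L; q_end <- qlen - a_start + 1L
            s_start <- a_end + diag; s_end <- a_start + diag
          }
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = q, subject_id = ct,
            identity_pct = 100 * (1 - mm / ov), aln_len = ov,
            mismatches = mm, gap_opens = 0L,
            q_start = q_start, q_end = q_end,
            s_start = s_start, s_end = s_end,
            evalue = 0, bitscore = score, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits))
    hits <- as.data.frame(setNames(
      c(list(character(0), character(0)), replicate(10, numeric(0), FALSE)),
      HIT_COLS))
  hits <- hits[order(hits$query_id, -hits$bitscore), ]
  rownames(hits) <- NULL
  finish_hits(hits, setNames(nchar(qseqs), names(qseqs)))
}

#' Filter chunk hits into pseudo-genetic-map anchors
#'
#' Per chunk: hits below the identity or query-coverage floor (both
#' inclusive boundaries) are dropped; if two or more hits survive and the
#' second one's bitscore strictly exceeds `ambiguity_ratio` times the top
#' bitscore the chunk is ambiguous (close paralog or repeat) and yields no
#' anchor; otherwise the top hit becomes an anchor with the chunk's
#' ordinal index as map position and the subject-interval midpoint as the
#' contig position.
#'
#' @param hits Hit `data.frame` with `q_cov` (see
#'   [attach_query_coverage()]).
#' @param chunks Result of [chunk_reference()]; maps chunk ids to linkage
#'   group (chromosome) and map index.
#' @param config A [map_config()].
#' @return `data.frame` of anchors: `chunk_id`, `contig_id`, `contig_pos`,
#'   `lg`, `map_pos`, `score`, `s_start`, `s_end`.
#' @export
filter_chunk_hits <- function(hits, chunks, config = map_config()) {
  if (!"q_cov" %in% names(hits))
    stop("hits need a q_cov column (attach chunk lengths)")
  tab <- chunks$table
  h <- hits[hits$identity_pct >= config$min_identity &
            hits$q_cov >= config$min_qcov, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(chunk_id = character(0), contig_id = character(0),
                      contig_pos = numeric(0), lg = character(0),
                      map_pos = integer(0), score = numeric(0),
                      s_start = numeric(0), s_end = numeric(0)))
  h <- h[order(h$query_id, -h$bitscore), ]
  anchors <- lapply(split(h, h$query_id), function(g) {
    if (nrow(g) >= 2L &&
        g$bitscore[2L] > config$ambiguity_ratio * g$bitscore[1L])
      return(NULL)
    g[1L, ]
  })
  anchors <- do.call(rbind, anchors[!vapply(anchors, is.null, logical(1))])
  if (is.null(anchors) || nrow(anchors) == 0L)
    return(data.frame(chunk_id = character(0), contig_id = character(0),
                      contig_pos = numeric(0), lg = character(0),
                      map_pos = integer(0), score = numeric(0),
                      s_start = numeric(0), s_end = numeric(0)))
  m <- match(anchors$query_id, tab$chunk_id)
  if (anyNA(m))
    stop("hit query id(s) not found in the chunk table: ",
         paste(head(anchors$query_id[is.na(m)], 5L), collapse = ", "))
  out <- data.frame(
    chunk_id = anchors$query_id,
    contig_id = anchors$subject_id,
    contig_pos = floor((anchors$s_start + anchors$s_end) / 2),
    lg = tab$chrom_id[m],
    map_pos = tab$index[m],
    score = anchors$bitscore,
    s_start = anchors$s_start, s_end = anchors$s_end,
    stringsAsFactors = FALSE)
  out <- out[order(out$lg, out$map_pos), ]
  rownames(out) <- NULL
  out
}

#' Assign contigs to linkage groups by anchor majority
#'
#' A contig is assigned to the linkage group holding a strict majority of
#' its anchors; contigs with fewer than `min_anchors_per_contig` anchors,
#' or without a strict majority, stay unplaced.
#'
#' @param anchors Anchor `data.frame` from [filter_chunk_hits()].
#' @param config A [map_config()].
#' @return `data.frame` with `contig_id`, `lg` (`NA` for unplaced),
#'   `n_anchors`.
#' @export
assign_linkage_groups <- function(anchors, config = map_config()) {
  if (nrow(anchors) == 0L)
    return(data.frame(contig_id = character(0), lg = character(0),
                      n_anchors = integer(0)))
  per <- lapply(split(anchors, anchors$contig_id), function(g) {
    n <- nrow(g)
    tab <- sort(table(g$lg), decreasing = TRUE)
    lg <- NA_character_
    if (n >= config$min_anchors_per_contig &&
        tab[1L] > n / 2 &&
        (length(tab) == 1L || tab[1L] > tab[2L]))
      lg <- names(tab)[1L]
    data.frame(contig_id = g$contig_id[1L], lg = lg, n_anchors = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Order and orient contigs within linkage groups
#'
#' Within each linkage group contigs are sorted by the mean map position
#' of their anchors (ties by median, then contig id). Orientation is the
#' sign of the Spearman rank correlation between contig position and map
#' position over the contig's anchors on its assigned group; correlations
#' below `orient_min_abs_rho` in absolute value, or contigs with fewer
#' than two anchors, get orientation `"?"` (emitted as `+`).
#'
#' @param anchors Anchor `data.frame` from [filter_chunk_hits()].
#' @param assignments `data.frame` from [assign_linkage_groups()].
#' @param all_contigs Optional character vector of every retained contig;
#'   contigs without an assignment are reported as unplaced.
#' @param config A [map_config()].
#' @return A `scaffold_plan`: list with `placements` (`lg`, `position`,
#'   `contig_id`, `orientation`, `n_anchors`, `mean_map_pos`, `rho`) and
#'   `unplaced` (character vector).
#' @export
order_and_orient <- function(anchors, assignments, all_contigs = NULL,
                             config = map_config()) {
  placed_ids <- assignments$contig_id[!is.na(assignments$lg)]
  unplaced <- assignments$contig_id[is.na(assignments$lg)]
  if (!is.null(all_contigs))
    unplaced <- union(unplaced, setdiff(all_contigs,
                                        assignments$contig_id))
  rows <- list()
  for (ci in placed_ids) {
    lg <- assignments$lg[assignments$contig_id == ci]
    a <- anchors[anchors$contig_id == ci & anchors$lg == lg, ]
    rho <- if (nrow(a) >= 2L && length(unique(a$map_pos)) > 1L &&
               length(unique(a$contig_pos)) > 1L)
      suppressWarnings(cor(a$contig_pos, a$map_pos, method = "spearman"))
    else NA_real_
    ori <- if (is.na(rho) || abs(rho) < config$orient_min_abs_rho) "?"
           else if (rho < 0) "-" else "+"
    rows[[length(rows) + 1L]] <- data.frame(
      lg = lg, contig_id = ci, orientation = ori,
      n_anchors = nrow(a), mean_map_pos = mean(a$map_pos),
      median_map_pos = median(a$map_pos), rho = rho,
      stringsAsFactors = FALSE)
  }
  placements <- do.call(rbind, rows)
  if (is.null(placements)) {
    placements <- data.frame(
      lg = character(0), position = integer(0), contig_id = character(0),
      orientation = character(0), n_anchors = integer(0),
      mean_map_pos = numeric(0), rho = numeric(0))
  } else {
    placements <- placements[order(placements$lg, placements$mean_map_pos,
                                   placements$median_map_pos,
                                   placements$contig_id), ]
    placements$position <- stats::ave(seq_len(nrow(placements)),
                                      placements$lg, FUN = seq_along)
    placements <- placements[, c("lg", "position", "contig_id",
                                 "orientation", "n_anchors",
                                 "mean_map_pos", "rho")]
  }
  rownames(placements) <- NULL
  structure(list(placements = placements, unplaced = sort(unplaced)),
            class = "scaffold_plan")
}

#' @export
print.scaffold_plan <- function(x, ...) {
  cat("scaffold_plan:", nrow(x$placements), "contigs placed on",
      length(unique(x$placements$lg)), "linkage groups;",
      length(x$unplaced), "unplaced\n")
  invisible(x)
}

#' Materialize a scaffold plan as AGP + FASTA
#'
#' Builds one scaffold per linkage group with `gap_len` N bases between
#' consecutive contigs (`-`-oriented contigs are reverse-complemented;
#' `"?"` is emitted as `+`), plus an AGP v2.1 description and a
#' placed/unplaced report.
#'
#' @param plan A `scaffold_plan` from [order_and_orient()].
#' @param contigs Contig sequences covering every contig in the plan.
#' @param config A [map_config()] (supplies `gap_len`).
#' @return List with `scaffolds` ([Biostrings::DNAStringSet]), `unplaced`
#'   ([Biostrings::DNAStringSet]), `agp` (`data.frame`), `report`
#'   (one-row `data.frame`: placed/unplaced counts and bp).
#' @export
write_scaffolds <- function(plan, contigs, config = map_config()) {
  seqs <- as_dna(contigs)
  all_ids <- c(plan$placements$contig_id, plan$unplaced)
  missing <- setdiff(all_ids, names(seqs))
  if (length(missing) > 0L)
    stop("contig(s) in plan missing from FASTA: ",
         paste(head(missing, 5L), collapse = ", "))
  cs <- setNames(as.character(seqs), names(seqs))
  gap <- strrep("N", config$gap_len)
  scaff <- character(0)
  agp_l <- list()
  pl <- plan$placements
  for (lg in unique(pl$lg)) {
    rows <- pl[pl$lg == lg, ]
    rows <- rows[order(rows$position), ]
    sid <- paste0("scaffold_", lg)
    pieces <- character(0)
    at <- 1L
    part <- 0L
    for (i in seq_len(nrow(rows))) {
      if (i > 1L) {
        part <- part + 1L
        agp_l[[length(agp_l) + 1L]] <- data.frame(
          object = sid, object_beg = at, object_end = at + config$gap_len - 1L,
          part_number = part, component_type = "N",
          component_id = as.character(config$gap_len),
          component_beg = "scaffold", component_end = "yes",
          orientation = "align_genus", stringsAsFactors = FALSE)
        pieces <- c(pieces, gap)
        at <- at + config$gap_len
      }
      ci <- rows$contig_id[i]
      s <- cs[[ci]]
      ori <- rows$orientation[i]
      emit_ori <- if (ori == "-") "-" else "+"
      if (emit_ori == "-") s <- revcomp_chr(s)
      part <- part + 1L
      agp_l[[length(agp_l) + 1L]] <- data.frame(
        object = sid, object_beg = at, object_end = at + nchar(s) - 1L,
        part_number = part, component_type = "W", component_id = ci,
        component_beg = "1", component_end = as.character(nchar(s)),
        orientation = emit_ori, stringsAsFactors = FALSE)
      pieces <- c(pieces, s)
      at <- at + nchar(s)
    }
    scaff[sid] <- paste(pieces, collapse = "")
  }
  agp <- if (length(agp_l) > 0L) do.call(rbind, agp_l)
    else as.data.frame(setNames(replicate(9, character(0), FALSE), AGP_COLS))
  placed_bp <- sum(nchar(cs[pl$contig_id]))
  unplaced_bp <- sum(nchar(cs[plan$unplaced]))
  report <- data.frame(
    placed_contigs = nrow(pl), placed_bp = placed_bp,
    unplaced_contigs = length(plan$unplaced), unplaced_bp = unplaced_bp,
    total_bp = placed_bp + unplaced_bp)
  list(
    scaffolds = if (length(scaff) > 0L) Biostrings::DNAStringSet(scaff)
      else Biostrings::DNAStringSet(),
    unplaced = if (length(plan$unplaced) > 0L)
      Biostrings::DNAStringSet(cs[plan$unplaced])
      else Biostrings::DNAStringSet(),
    agp = agp, report = report)
}
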