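# Downstream contig purging: length cutoff, white/black-list
# classification, low-coverage contaminant screen, organelle detection.
# Stages run in that order; each stage only relabels contigs still
# "retained", so the final labels partition the input set.

#' Contig-filter configuration
#'
#' @param min_contig_len Minimum contig length kept (bp); contigs of
#'   exactly this length survive.
#' @param low_cov_threshold Mean-depth threshold (fold) below which a
#'   contig enters the low-coverage contaminant screen.
#' @param blast_evalue_cutoff E-value cutoff for black-list / nt hits.
#' @param perfect_match_min_len Minimum length (bp) of a 100%-identity hit
#'   for the cross-contamination rule.
#' @param organelle_depth_factor Organelle calls require mean depth at
#'   least this multiple of the median retained genome-contig depth.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_contig_len = 100000,
                          low_cov_threshold = 3,
                          blast_evalue_cutoff = 1e-10,
                          perfect_match_min_len = 500,
                          organelle_depth_factor = 5) {
  stopifnot(min_contig_len > 0, low_cov_threshold > 0,
            blast_evalue_cutoff > 0, perfect_match_min_len > 0,
            organelle_depth_factor > 0)
  structure(as.list(environment()), class = "filter_config")
}

#' Partition contigs by a minimum-length cutoff
#'
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param config A [filter_config()].
#' @return List with character vectors `kept` and `too_short`.
#' @export
apply_length_filter <- function(contig_lengths, config = filter_config()) {
  keep <- contig_lengths >= config$min_contig_len
  list(kept = names(contig_lengths)[keep],
       too_short = names(contig_lengths)[!keep])
}

#' Classify contigs by white/black/cross-contamination hit lists
#'
#' Precedence: a perfect match (100\% identity over at least
#' `perfect_match_min_len`) against a genome sequenced in parallel marks a
#' contig `cross_contaminant`; otherwise a black-list hit at the e-value
#' cutoff with no white-list hit marks it `blacklist`; anything else —
#' including contigs with no hits at all — stays `retained`. A contig with
#' both white- and black-list hits is retained (white list dominates) with
#' a warning.
#'
#' @param contig_ids Character vector of contigs to classify.
#' @param white_hits,black_hits,cross_hits Hit data frames (outfmt-6
#'   layout, `query_id` = contig).
#' @param config A [filter_config()].
#' @return Named character vector of labels over `contig_ids`.
#' @export
classify_by_lists <- function(contig_ids, white_hits, black_hits,
                              cross_hits, config = filter_config()) {
  lab <- setNames(rep("retained", length(contig_ids)), contig_ids)
  perfect <- cross_hits$query_id[
    cross_hits$identity_pct == 100 &
    cross_hits$aln_len >= config$perfect_match_min_len]
  white <- unique(white_hits$query_id)
  black <- unique(black_hits$query_id[
    black_hits$evalue <= config$blast_evalue_cutoff])
  conflicted <- intersect(intersect(black, white), contig_ids)
  if (length(conflicted) > 0L)
    warning("contig(s) match both white and black list; retained: ",
            paste(head(conflicted, 5L), collapse = ", "))
  lab[intersect(setdiff(black, white), contig_ids)] <- "blacklist"
  lab[intersect(unique(perfect), contig_ids)] <- "cross_contaminant"
  lab
}

#' Screen low-coverage contigs against an nt-style hit table
#'
#' Contigs with mean depth strictly below the threshold *and* a
#' bacterial/fungal hit at the e-value cutoff are labelled
#' `low_coverage_contaminant`; low coverage alone is not sufficient.
#'
#' @param contig_ids Contigs still retained.
#' @param mean_depths Named numeric vector covering every contig in
#'   `contig_ids`.
#' @param nt_hits Hit data frame from the nt comparison.
#' @param config A [filter_config()].
#' @return Named character vector: `low_coverage_contaminant` or
#'   `retained`.
#' @export
screen_low_coverage <- function(contig_ids, mean_depths, nt_hits,
                                config = filter_config()) {
  missing <- setdiff(contig_ids, names(mean_depths))
  if (length(missing) > 0L)
    stop("no mean depth for contig(s): ",
         paste(head(missing, 5L), collapse = ", "))
  hit <- unique(nt_hits$query_id[nt_hits$evalue <= config$blast_evalue_cutoff])
  low <- contig_ids[mean_depths[contig_ids] < config$low_cov_threshold]
  lab <- setNames(rep("retained", length(contig_ids)), contig_ids)
  lab[intersect(low, hit)] <- "low_coverage_contaminant"
  lab
}

#' Detect organelle contigs by similarity plus very high coverage
#'
#' A contig is labelled only if its best organelle-reference hit covers at
#' least half of the contig *and* its mean depth is at least
#' `organelle_depth_factor` times the median depth of the retained genome
#' contigs — similarity alone is not sufficient.
#'
#' @param contig_ids Contigs still retained.
#' @param mean_depths Named numeric vector of contig mean depths.
#' @param organelle_hits Hit data frame vs organelle references
#'   (`query_id` = contig); `subject_id` decides the organelle type via
#'   `organelle_types`.
#' @param genome_contig_ids Contigs over which the median reference depth
#'   is taken (retained, non-organelle genome contigs).
#' @param config A [filter_config()].
#' @param organelle_types Named character vector mapping hit subject ids to
#'   `"plastid"` or `"mitochondrion"`; unmapped subjects default to
#'   `"plastid"`.
#' @return Named character vector: `plastid`, `mitochondrion` or
#'   `retained`.
#' @export
detect_organelles <- function(contig_ids, mean_depths, organelle_hits,
                              genome_contig_ids,
                              config = filter_config(),
                              organelle_types = NULL) {
  if (length(genome_contig_ids) == 0L)
    stop("no retained genome contigs to take a median depth over")
  med <- median(mean_depths[genome_contig_ids])
  lab <- setNames(rep("retained", length(contig_ids)), contig_ids)
  h <- organelle_hits[organelle_hits$query_id %in% contig_ids, , drop = FALSE]
  if (nrow(h) == 0L) return(lab)
  # best (highest-scoring) hit per contig; its contig coverage must be >= 0.5
  if (!"q_cov" %in% names(h))
    stop("organelle hits need a q_cov column ",
         "(attach contig lengths via read_blast_hits(q_len = ...))")
  h <- h[order(h$query_id, -h$bitscore), ]
  best <- h[!duplicated(h$query_id), ]
  for (i in seq_len(nrow(best))) {
    ct <- best$query_id[i]
    if (is.na(best$q_cov[i])) next
    if (best$q_cov[i] >= 0.5 &&
        mean_depths[[ct]] >= config$organelle_depth_factor * med) {
      typ <- if (!is.null(organelle_types) &&
                 best$subject_id[i] %in% names(organelle_types))
        organelle_types[[best$subject_id[i]]] else "plastid"
      lab[ct] <- typ
    }
  }
  lab
}

#' Run the full contig filter
#'
#' Stages in order: length purge; white/black/cross-list classification;
#' low-coverage contaminant screen; organelle detection. Each stage only
#' touches contigs still retained, so the labels partition the input and
#' the procedure is idempotent.
#'
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param mean_depths Named numeric vector of contig mean depths (fold).
#' @param white_hits,black_hits,cross_hits,nt_hits,organelle_hits Hit data
#'   frames (any may be empty); `organelle_hits` must carry `q_cov`.
#' @param config A [filter_config()].
#' @param organelle_types Optional subject-to-type map, see
#'   [detect_organelles()].
#' @return `data.frame` with columns `contig_id`, `length`, `mean_depth`,
#'   `label`; attribute `"counts"` holds the per-label tally.
#' @export
filter_contigs <- function(contig_lengths, mean_depths,
                           white_hits, black_hits, cross_hits, nt_hits,
                           organelle_hits, config = filter_config(),
                           organelle_types = NULL) {
  ids <- names(contig_lengths)
  missing <- setdiff(ids, names(mean_depths))
  if (length(missing) > 0L)
    stop("no mean depth for contig(s): ",
         paste(head(missing, 5L), collapse = ", "))
  lab <- setNames(rep("retained", length(ids)), ids)
  lf <- apply_length_filter(contig_lengths, config)
  lab[lf$too_short] <- "too_short"
  cur <- lf$kept
  cl <- classify_by_lists(cur, white_hits, black_hits, cross_hits, config)
  lab[names(cl)] <- cl
  cur <- names(cl)[cl == "retained"]
  sl <- screen_low_coverage(cur, mean_depths, nt_hits, config)
  lab[names(sl)] <- sl
  cur <- names(sl)[sl == "retained"]
  ol <- detect_organelles(cur, mean_depths, organelle_hits,
                          genome_contig_ids = cur, config = config,
                          organelle_types = organelle_types)
  lab[names(ol)] <- ol
  out <- data.frame(contig_id = ids,
                    length = as.numeric(contig_lengths[ids]),
                    mean_depth = as.numeric(mean_depths[ids]),
                    label = unname(lab[ids]),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$label)
  out
}
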