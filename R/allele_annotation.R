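# Gene-model post-processing: database score-ratio filtering,
# representative-transcript selection, annotation transfer, CDS-based
# reciprocal-best-hit allele pairing with a score-margin rule, and the
# haploid gene-number estimate.

#' Filter gene models by database score ratio and query coverage
#'
#' Each gene's best database bitscore is normalized by its self-score (the
#' score of the peptide searched against the predicted-peptide set, i.e.
#' its self-alignment). A gene is kept iff the ratio is at least
#' `min_ratio` *and* the best alignment covers at least `min_qcov` of the
#' query (both boundaries inclusive); genes without any database hit are
#' discarded.
#'
#' @param db_hits Hit `data.frame` (`query_id` = gene) with `bitscore` and
#'   `q_cov`; hits from several databases may be concatenated.
#' @param self_scores Named numeric vector of self-scores covering every
#'   gene to be decided; all must be positive.
#' @param min_ratio,min_qcov Inclusive thresholds.
#' @return `data.frame` with `gene_id`, `self_score`, `best_db_score`,
#'   `score_ratio`, `best_qcov`, `kept`.
#' @export
filter_gene_models <- function(db_hits, self_scores,
                               min_ratio = 0.25, min_qcov = 0.25) {
  bad <- names(self_scores)[self_scores <= 0]
  if (length(bad) > 0L)
    stop("non-positive self score for gene(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (!"q_cov" %in% names(db_hits))
    stop("db_hits need a q_cov column (attach query lengths)")
  h <- db_hits[order(db_hits$query_id, -db_hits$bitscore), ]
  best <- h[!duplicated(h$query_id), ]
  m <- match(names(self_scores), best$query_id)
  out <- data.frame(
    gene_id = names(self_scores),
    self_score = as.numeric(self_scores),
    best_db_score = best$bitscore[m],
    best_qcov = best$q_cov[m],
    stringsAsFactors = FALSE)
  out$score_ratio <- out$best_db_score / out$self_score
  out$kept <- !is.na(out$score_ratio) &
    out$score_ratio >= min_ratio & out$best_qcov >= min_qcov
  out
}

#' Pick the representative transcript per gene
#'
#' The representative is the transcript encoding the longest peptide;
#' ties break by longest CDS, then lexicographically smallest transcript
#' id.
#'
#' @param transcripts `data.frame` with `gene_id`, `transcript_id`,
#'   `pep_len` (aa) and optionally `cds_len` (nt).
#' @return `data.frame` with one row per gene: `gene_id`,
#'   `transcript_id`, `pep_len`.
#' @export
pick_representative <- function(transcripts) {
  stopifnot(all(c("gene_id", "transcript_id", "pep_len") %in%
                names(transcripts)))
  tr <- transcripts
  if (!"cds_len" %in% names(tr)) tr$cds_len <- 3 * tr$pep_len
  tr <- tr[order(tr$gene_id, -tr$pep_len, -tr$cds_len, tr$transcript_id), ]
  out <- tr[!duplicated(tr$gene_id), c("gene_id", "transcript_id",
                                       "pep_len")]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two sequence sets
#'
#' @param hits_ab Hits of set A queried against set B.
#' @param hits_ba Hits of set B queried against set A.
#' @return `data.frame` with `id_a`, `id_b` for each mutual best pair
#'   (best by bitscore in both directions; exact ties for best make a
#'   query unmatched).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_of <- function(h) {
    if (nrow(h) == 0L)
      return(data.frame(query_id = character(0),
                        subject_id = character(0)))
    h <- h[order(h$query_id, -h$bitscore), ]
    per <- split(h, h$query_id)
    do.call(rbind, lapply(per, function(g) {
      if (nrow(g) >= 2L && g$bitscore[2L] == g$bitscore[1L])
        return(NULL)  # ambiguous best
      g[1L, c("query_id", "subject_id")]
    }))
  }
  ba <- best_of(hits_ab)
  bb <- best_of(hits_ba)
  if (is.null(ba) || is.null(bb) || nrow(ba) == 0L || nrow(bb) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0)))
  m <- merge(ba, bb, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"))
  out <- data.frame(id_a = m$query_id, id_b = m$subject_id,
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Transfer functional annotation from a reference gene set
#'
#' Reciprocal-best-hit partners receive the reference description with
#' provenance tag `rbh`; remaining genes with a hit at
#' `e <= evalue_cutoff` receive the top hit's description with tag
#' `best_hit`; everything else is tagged `none`. Reference ids missing
#' from the annotation table give a warning and tag `none`.
#'
#' @param gene_ids Genes to annotate.
#' @param rbh `data.frame` from [reciprocal_best_hits()] with `id_a` =
#'   gene, `id_b` = reference id.
#' @param fallback_hits Hit `data.frame` of genes vs the reference set.
#' @param ref_annotation Named character vector: reference id ->
#'   description.
#' @param evalue_cutoff Inclusive e-value cutoff for the fallback path.
#' @return `data.frame` with `gene_id`, `annotation`, `provenance`
#'   (`rbh`/`best_hit`/`none`).
#' @export
transfer_annotation <- function(gene_ids, rbh, fallback_hits,
                                ref_annotation, evalue_cutoff = 1e-4) {
  ann <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
  prov <- setNames(rep("none", length(gene_ids)), gene_ids)
  miss <- character(0)
  for (i in seq_len(nrow(rbh))) {
    g <- rbh$id_a[i]
    if (!g %in% gene_ids) next
    r <- rbh$id_b[i]
    if (r %in% names(ref_annotation)) {
      ann[g] <- ref_annotation[[r]]
      prov[g] <- "rbh"
    } else miss <- c(miss, r)
  }
  rest <- gene_ids[prov == "none"]
  if (length(rest) > 0L && nrow(fallback_hits) > 0L) {
    h <- fallback_hits[fallback_hits$query_id %in% rest &
                       fallback_hits$evalue <= evalue_cutoff, , drop = FALSE]
    if (nrow(h) > 0L) {
      h <- h[order(h$query_id, -h$bitscore), ]
      top <- h[!duplicated(h$query_id), ]
      for (i in seq_len(nrow(top))) {
        r <- top$subject_id[i]
        if (r %in% names(ref_annotation)) {
          ann[top$query_id[i]] <- ref_annotation[[r]]
          prov[top$query_id[i]] <- "best_hit"
        } else miss <- c(miss, r)
      }
    }
  }
  if (length(miss) > 0L)
    warning("reference id(s) missing from the annotation table: ",
            paste(head(unique(miss), 5L), collapse = ", "))
  data.frame(gene_id = gene_ids, annotation = unname(ann[gene_ids]),
             provenance = unname(prov[gene_ids]), stringsAsFactors = FALSE)
}

#' Pair alleles of phase-separated genes by reciprocal best CDS hits
#'
#' Candidate pairs are mutual best hits in an all-vs-all CDS comparison
#' restricted to phase-separated gene models (self-hits excluded; exact
#' score ties for best make a gene ambiguous and unpaired). A candidate
#' pair is *valid* — i.e. represents the two alleles of one gene — iff in
#' both directions the second-best match (excluding self and the
#' reciprocal partner) scores at most `margin` times the best match;
#' absence of a second hit passes. Each gene occurs in at most one valid
#' pair.
#'
#' @param cds_hits Hit `data.frame` among phase-separated gene models.
#' @param margin Inclusive second-best/best score-ratio bound.
#' @return `data.frame` of candidate pairs (canonical id order):
#'   `gene_a`, `gene_b`, `score_ab`, `score_ba`, `margin_a`, `margin_b`,
#'   `valid`.
#' @export
pair_alleles <- function(cds_hits, margin = 0.99) {
  h <- cds_hits[cds_hits$query_id != cds_hits$subject_id, , drop = FALSE]
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score_ab = numeric(0), score_ba = numeric(0),
                      margin_a = numeric(0), margin_b = numeric(0),
                      valid = logical(0))
  if (nrow(h) == 0L) return(empty)
  h <- h[order(h$query_id, -h$bitscore, h$subject_id), ]
  per <- split(h, h$query_id)
  best <- lapply(per, function(g) {
    if (nrow(g) >= 2L && g$bitscore[2L] == g$bitscore[1L])
      return(NULL)  # tie for best: ambiguous
    g[1L, ]
  })
  best <- best[!vapply(best, is.null, logical(1))]
  rows <- list()
  for (q in names(best)) {
    b <- best[[q]]$subject_id
    if (q >= b) next                      # canonical order, visit once
    if (is.null(best[[b]]) || best[[b]]$subject_id != q) next  # not mutual
    margin_of <- function(gene, partner) {
      g <- per[[gene]]
      second <- g$bitscore[g$subject_id != partner]
      if (length(second) == 0L) return(0)
      max(second) / g$bitscore[1L]
    }
    ma <- margin_of(q, b)
    mb <- margin_of(b, q)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = q, gene_b = b,
      score_ab = best[[q]]$bitscore, score_ba = best[[b]]$bitscore,
      margin_a = ma, margin_b = mb,
      valid = ma <= margin && mb <= margin,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$gene_a), ]
  rownames(out) <- NULL
  out
}

#' Haploid gene-number estimate
#'
#' Phase-separated gene models represent two allelic copies of one gene,
#' so the haploid gene number is the total minus the number of duplicated
#' copies: `n_total - floor(n_separated / 2)` (or minus an externally
#' supplied copy count).
#'
#' @param n_total Total predicted gene models.
#' @param n_separated Gene models classified phase-separated.
#' @param n_allelic_copies Optional externally determined duplicate-copy
#'   count overriding `floor(n_separated / 2)`.
#' @return List with `n_allelic_copies`, `haploid_estimate`, and
#'   `haploid_estimate_rounded` (nearest thousand).
#' @export
estimate_haploid_genes <- function(n_total, n_separated,
                                   n_allelic_copies = NULL) {
  if (n_separated > n_total)
    stop("n_separated exceeds n_total")
  copies <- if (is.null(n_allelic_copies)) floor(n_separated / 2)
            else n_allelic_copies
  est <- n_total - copies
  list(n_allelic_copies = copies,
       haploid_estimate = est,
       haploid_estimate_rounded = round_half_away(est / 1000) * 1000)
}
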