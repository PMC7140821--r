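# Per-gene read depth, haplophase classification (low / phase-separated /
# merged / high) and heterozygous-variant summaries per class.

#' Depth bin boundaries for haplophase classification
#'
#' Half-open bins with inclusive lower bounds: `low` below `t_low`,
#' `separated` in `[t_low, t_mid)`, `merged` in `[t_mid, t_high)`, `high`
#' at and above `t_high`. Defaults reflect a haploid read depth around
#' 100-fold (haploid peak bracketed by 50/150, diploid by 150/250).
#'
#' @param t_low,t_mid,t_high Increasing positive fold-depth boundaries.
#' @return A `depth_bins` list.
#' @export
depth_bins <- function(t_low = 50, t_mid = 150, t_high = 250) {
  stopifnot(0 < t_low, t_low < t_mid, t_mid < t_high)
  structure(list(t_low = t_low, t_mid = t_mid, t_high = t_high),
            class = "depth_bins")
}

#' Mean read depth per gene
#'
#' Arithmetic mean of the per-position depth over the gene span
#' `[start, end]`; positions absent from the track count as zero.
#'
#' @param track A [depth_track()].
#' @param genes `data.frame` with `gene_id` (or `model_id`), `contig`,
#'   `start`, `end`.
#' @param contig_lengths Optional named vector: contigs known to the
#'   assembly but absent from the track are treated as all-zero depth;
#'   genes on contigs absent from both raise an error.
#' @return Named numeric vector of mean depths per gene.
#' @export
gene_mean_depth <- function(track, genes, contig_lengths = NULL) {
  ids <- genes$model_id %||% genes$gene_id
  known <- union(names(track), names(contig_lengths))
  bad <- setdiff(unique(genes$contig), known)
  if (length(bad) > 0L)
    stop("gene(s) on contig(s) absent from assembly and depth track: ",
         paste(head(bad, 5L), collapse = ", "))
  out <- vapply(seq_len(nrow(genes)), function(i) {
    v <- track[[genes$contig[i]]]
    s <- genes$start[i]; e <- genes$end[i]
    if (is.null(v)) return(0)
    span <- e - s + 1L
    inside <- v[s:min(e, length(v))]
    sum(inside[!is.na(inside)]) / span
  }, numeric(1))
  setNames(out, ids)
}

#' Classify genes into haplophase classes by mean depth
#'
#' @param mean_depths Named numeric vector of per-gene mean depths.
#' @param bins A [depth_bins()].
#' @return `data.frame` with `gene_id`, `mean_depth`, `phase_class`
#'   (ordered factor low < separated < merged < high); attribute
#'   `"summary"` holds counts and fractions per class.
#' @export
classify_genes <- function(mean_depths, bins = depth_bins()) {
  if (anyNA(mean_depths))
    stop("unset mean depth for gene(s): ",
         paste(head(names(mean_depths)[is.na(mean_depths)], 5L),
               collapse = ", "))
  cls <- cut(mean_depths,
             breaks = c(-Inf, bins$t_low, bins$t_mid, bins$t_high, Inf),
             labels = c("low", "separated", "merged", "high"),
             right = FALSE, ordered_result = TRUE)
  out <- data.frame(gene_id = names(mean_depths),
                    mean_depth = as.numeric(mean_depths),
                    phase_class = cls, stringsAsFactors = FALSE)
  counts <- table(out$phase_class)
  attr(out, "summary") <- data.frame(
    phase_class = names(counts),
    n = as.integer(counts),
    fraction = as.numeric(counts) / nrow(out))
  out
}

#' Estimate depth bins from the per-gene depth distribution
#'
#' Automates the visual threshold choice on a bimodal depth histogram:
#' the haploid peak `c` is the mode of a kernel-smoothed density of the
#' depths restricted to the lower half of the observed range, and the bins
#' are `(0.5c, 1.5c, 2.5c)`. When too few genes fall into the lower half
#' for a stable mode the defaults are returned with attribute
#' `"fallback" = TRUE`.
#'
#' @param mean_depths Numeric vector of per-gene mean depths (>= 100 genes
#'   recommended).
#' @param min_lower_n Minimum number of depths in the lower half required
#'   to fit the mode.
#' @return A [depth_bins()] with attributes `haploid_peak` and `fallback`.
#' @export
estimate_bins <- function(mean_depths, min_lower_n = 30L) {
  x <- mean_depths[is.finite(mean_depths)]
  if (length(x) == 0L) stop("no depths to estimate bins from")
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    ctr <- x[1L]
    b <- depth_bins(0.5 * ctr, 1.5 * ctr, 2.5 * ctr)
    attr(b, "haploid_peak") <- ctr
    attr(b, "fallback") <- FALSE
    return(b)
  }
  cutoff <- (min(x) + max(x)) / 2
  lower <- x[x <= cutoff]
  if (length(lower) < min_lower_n) {
    b <- depth_bins()
    attr(b, "haploid_peak") <- NA_real_
    attr(b, "fallback") <- TRUE
    return(b)
  }
  d <- density(lower)
  ctr <- d$x[which.max(d$y)]
  b <- depth_bins(0.5 * ctr, 1.5 * ctr, 2.5 * ctr)
  attr(b, "haploid_peak") <- ctr
  attr(b, "fallback") <- FALSE
  b
}

is_het_gt <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    a <- a[a != "."]
    length(unique(a)) >= 2L
  }, logical(1))
}

#' Heterozygous variants per gene, summarized by haplophase class
#'
#' Counts VCF records with a heterozygous genotype (any two distinct
#' alleles, e.g. 0/1 or 0|2) overlapping each gene span, and summarizes
#' the counts by phase class: median, upper quartile, and the ratio of
#' merged to separated medians. Reads from both alleles mapping onto one
#' merged consensus make merged genes variant-dense; phase-separated genes
#' stay near zero.
#'
#' @param variants `data.frame` with `contig`, `pos`, `gt` (e.g. from
#'   [read_vcf_genotypes()] or [emit_depth_and_vcf()]).
#' @param genes `data.frame` with `gene_id`/`model_id`, `contig`, `start`,
#'   `end`.
#' @param classes Optional classification from [classify_genes()] to
#'   summarize against.
#' @param known_contigs Optional character vector of assembly contigs;
#'   records on contigs outside it are skipped with a warning.
#' @return Named integer vector `het_count` per gene; when `classes` is
#'   given, attribute `"summary"` holds the per-class table and
#'   `"merged_vs_separated"` the median ratio.
#' @export
het_per_gene <- function(variants, genes, classes = NULL,
                         known_contigs = NULL) {
  ids <- genes$model_id %||% genes$gene_id
  if (!is.null(known_contigs)) {
    unknown <- setdiff(unique(variants$contig), known_contigs)
    if (length(unknown) > 0L) {
      warning("skipping variant record(s) on unknown contig(s): ",
              paste(head(unknown, 5L), collapse = ", "))
      variants <- variants[variants$contig %in% known_contigs, ,
                           drop = FALSE]
    }
  }
  het <- variants[is_het_gt(variants$gt), , drop = FALSE]
  counts <- integer(nrow(genes))
  if (nrow(het) > 0L) {
    vg <- GenomicRanges::GRanges(het$contig,
                                 IRanges::IRanges(het$pos, het$pos))
    gg <- GenomicRanges::GRanges(genes$contig,
                                 IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(vg, gg)
    tab <- table(S4Vectors::subjectHits(ov))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  out <- setNames(counts, ids)
  if (!is.null(classes)) {
    cls <- classes$phase_class[match(ids, classes$gene_id)]
    summ <- do.call(rbind, lapply(split(counts, cls), function(v) {
      data.frame(n_genes = length(v),
                 median_het = if (length(v)) median(v) else NA_real_,
                 upper_quartile = if (length(v))
                   unname(quantile(v, 0.75)) else NA_real_)
    }))
    summ <- cbind(phase_class = rownames(summ), summ)
    rownames(summ) <- NULL
    med_m <- summ$median_het[summ$phase_class == "merged"]
    med_s <- summ$median_het[summ$phase_class == "separated"]
    attr(out, "summary") <- summ
    attr(out, "merged_vs_separated") <-
      if (length(med_m) == 1L && length(med_s) == 1L &&
          !is.na(med_m) && !is.na(med_s)) med_m / max(1, med_s)
      else NA_real_
  }
  out
}
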