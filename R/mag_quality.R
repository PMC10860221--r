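#' High-quality MAG filtering
#'
#' Retains metagenome-assembled genomes with completeness strictly above
#' `min_completeness` and contamination strictly below
#' `max_contamination` (defaults 90 and 5: the usual high-quality
#' thresholds). Both inequalities are strict, so a MAG at exactly 90\%
#' completeness or exactly 5\% contamination is excluded; boundary cases
#' are reported via a message so they can be audited.
#'
#' @param mags A `mags` bundle table.
#' @param min_completeness,max_contamination Thresholds (percent).
#' @return The retained rows of `mags`.
#' @export
filter_high_quality <- function(mags, min_completeness = 90,
                                max_contamination = 5) {
  if (any(is.na(mags$completeness) | is.na(mags$contamination))) {
    stop("filter_high_quality(): missing completeness/contamination for ",
         id_list(mags$mag_id[is.na(mags$completeness) | is.na(mags$contamination)]),
         call. = FALSE)
  }
  boundary <- mags$completeness == min_completeness |
    mags$contamination == max_contamination
  if (any(boundary)) {
    message("filter_high_quality(): ", sum(boundary),
            " MAG(s) at an exact threshold were excluded (strict inequality): ",
            id_list(mags$mag_id[boundary]))
  }
  mags[mags$completeness > min_completeness &
         mags$contamination < max_contamination, ]
}

#' Restrict genes to the analysable universe
#'
#' A gene is analysable when its MAG passed the high-quality filter and
#' carries a species-level classification. Genes on high-quality MAGs
#' without a species call are counted and reported as an excluded
#' fraction (two decimal places), mirroring the usual quality-control
#' statistic for this filtering step.
#'
#' @param genes A `genes` bundle table.
#' @param hq_mags Output of [filter_high_quality()].
#' @return A list: `genes` (retained rows, with `species`, `phylum`
#'   columns joined from the MAG), `n_hq` (genes on high-quality MAGs),
#'   `n_excluded_unclassified`, `pct_excluded_unclassified`.
#' @export
analysable_genes <- function(genes, hq_mags) {
  g <- dplyr::inner_join(
    genes,
    hq_mags[, c("mag_id", "species", "phylum", "species_classified")],
    by = "mag_id")
  n_hq <- nrow(g)
  keep <- g$species_classified
  n_excluded <- sum(!keep)
  out <- g[keep, c("gene_id", "mag_id", "sample_id", "cluster_id",
                   "species", "phylum")]
  list(genes = out,
       n_hq = n_hq,
       n_excluded_unclassified = n_excluded,
       pct_excluded_unclassified = if (n_hq > 0) pct_of(n_excluded, n_hq, 2) else NA_real_)
}
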