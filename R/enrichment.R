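#' Build the phylum contingency table for enrichment testing
#'
#' Compares the phylum distribution of engrafted donor strains with the
#' distribution of engrafted strains that contributed to HGT. Counting
#' unit (`mode`):
#' \describe{
#'   \item{engraftment}{default — one unit per engraftment call, i.e.
#'     per (recipient, engrafted species) instance;}
#'   \item{species}{one unit per distinct engrafted species;}
#'   \item{events}{events-weighted — one unit per engraftment-dependent
#'     event.}
#' }
#' Phyla with zero counts in both columns are dropped (and named in a
#' message) before testing.
#'
#' @param engraftment An `engraftment` bundle table, restricted to the
#'   cohort of interest (e.g. one sex).
#' @param ed_events Matching output of [filter_engraftment_dependent()].
#' @param phylum_lookup Named character vector species -> phylum for
#'   engrafted species missing from MAG taxonomy (manual fill-in);
#'   looked up for every engrafted species.
#' @param mode Counting unit, see above.
#' @return A matrix with phyla as rows and columns `engrafted`,
#'   `engrafted_with_hgt`.
#' @export
phylum_contingency <- function(engraftment, ed_events, phylum_lookup,
                               mode = c("engraftment", "species", "events")) {
  mode <- match.arg(mode)
  miss <- setdiff(unique(engraftment$species), names(phylum_lookup))
  if (length(miss) > 0) {
    stop("phylum_contingency(): no phylum for engrafted species ",
         id_list(miss), call. = FALSE)
  }
  eng <- dplyr::distinct(engraftment, .data$recipient_id, .data$species)
  eng$phylum <- unname(phylum_lookup[eng$species])
  hgt_keys <- unique(paste(ed_events$participant_id,
                           ed_events$engrafted_species))
  eng$with_hgt <- paste(eng$recipient_id, eng$species) %in% hgt_keys

  count_units <- function(df) {
    switch(mode,
           engraftment = dplyr::count(df, .data$phylum, name = "n"),
           species = dplyr::count(dplyr::distinct(df, .data$species,
                                                  .data$phylum),
                                  .data$phylum, name = "n"),
           events = {
             ev <- ed_events
             ev$phylum <- unname(phylum_lookup[ev$engrafted_species])
             keys <- paste(df$recipient_id, df$species)
             ev <- ev[paste(ev$participant_id, ev$engrafted_species) %in% keys, ]
             dplyr::count(ev, .data$phylum, name = "n")
           })
  }
  all_units <- count_units(eng)
  hgt_units <- count_units(eng[eng$with_hgt, ])
  phyla <- sort(unique(c(all_units$phylum, hgt_units$phylum)))
  tab <- cbind(
    engrafted = setNames(rep(0L, length(phyla)), phyla),
    engrafted_with_hgt = 0L)
  tab[all_units$phylum, "engrafted"] <- all_units$n
  tab[hgt_units$phylum, "engrafted_with_hgt"] <- hgt_units$n
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    message("phylum_contingency(): dropping all-zero phylum row(s): ",
            paste(phyla[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  tab
}

check_contingency <- function(table) {
  if (!is.matrix(table) || any(table < 0) || nrow(table) < 2 ||
      ncol(table) < 2) {
    stop("need a nonnegative contingency matrix with >= 2 rows and columns",
         call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("zero expected cell count; pool sparse categories before testing",
         call. = FALSE)
  }
  expected
}

#' Pearson chi-squared test of a contingency table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expectations from the
#' row/column margins, no continuity correction; p from the upper tail
#' of the chi-squared distribution with `(r - 1)(c - 1)` df. Errors on a
#' zero expected cell with advice to pool categories.
#'
#' @param table Nonnegative count matrix (phyla x condition).
#' @return List: `chi2`, `df`, `p`, `expected`.
#' @export
chi_squared <- function(table) {
  expected <- check_contingency(table)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = expected)
}

#' Post-hoc standardized-residual tests
#'
#' Per-cell standardized (adjusted) residuals
#' `r = (O - E) / sqrt(E (1 - rowmargin/n)(1 - colmargin/n))`, two-sided
#' normal p-values `2 * pnorm(-|r|)`, and Benjamini-Hochberg adjustment
#' across all cells. Direction is `"over"` for positive residuals
#' (observed above expected) and `"under"` otherwise.
#'
#' @param table Nonnegative count matrix.
#' @return Tibble: `row`, `col`, `observed`, `expected`, `residual`,
#'   `p_value`, `p_adjusted`, `direction`.
#' @export
posthoc_residuals <- function(table) {
  check_contingency(table)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  r <- res$stdres
  p <- 2 * pnorm(-abs(r))
  adj <- matrix(bh_adjust(as.vector(p)), nrow = nrow(p))
  idx <- expand.grid(row = seq_len(nrow(table)), col = seq_len(ncol(table)))
  tibble::tibble(
    row = rownames(table)[idx$row] %||% as.character(idx$row),
    col = colnames(table)[idx$col] %||% as.character(idx$col),
    observed = as.vector(table)[idx$row + (idx$col - 1) * nrow(table)],
    expected = as.vector(res$expected)[idx$row + (idx$col - 1) * nrow(table)],
    residual = as.vector(r)[idx$row + (idx$col - 1) * nrow(table)],
    p_value = as.vector(p)[idx$row + (idx$col - 1) * nrow(table)],
    p_adjusted = as.vector(adj)[idx$row + (idx$col - 1) * nrow(table)],
    direction = ifelse(as.vector(r)[idx$row + (idx$col - 1) * nrow(table)] > 0,
                       "over", "under"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: `adj_(i) = min_(j >= i)
#' (p_(j) * m / j)` on the sorted p-values, capped at 1, returned in the
#' original order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("bh_adjust(): p-values must be in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Background phylum distribution of donor genes
#'
#' Fraction of analysable donor genes (on high-quality, species-
#' classified MAGs) per phylum — the reference distribution against
#' which engrafted and engrafted-with-HGT phylum profiles are displayed.
#'
#' @param bundle An [hgt_bundle()].
#' @param analysable Optional precomputed [analysable_genes()] result.
#' @param sex Optional: restrict to donors of one sex.
#' @return Tibble: `phylum`, `n_genes`, `fraction` (sums to 1).
#' @export
background_distribution <- function(bundle, analysable = NULL, sex = NULL) {
  if (is.null(analysable)) {
    analysable <- analysable_genes(bundle$genes,
                                   filter_high_quality(bundle$mags))
  }
  ag <- dplyr::inner_join(analysable$genes,
                          bundle$samples[, c("sample_id", "subject_id")],
                          by = "sample_id")
  ag <- dplyr::left_join(ag, bundle$design, by = "subject_id")
  ag <- ag[ag$role == "donor", ]
  if (!is.null(sex)) ag <- ag[ag$sex == sex, ]
  if (nrow(ag) == 0) {
    stop("background_distribution(): no analysable donor genes", call. = FALSE)
  }
  out <- dplyr::count(ag, .data$phylum, name = "n_genes")
  out$fraction <- out$n_genes / sum(out$n_genes)
  out[order(-out$n_genes), ]
}
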