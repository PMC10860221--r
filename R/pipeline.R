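#' Pipeline run configuration
#'
#' @param donor_scope Donor scope for detection (see [detect_htgcs()]).
#' @param min_completeness,max_contamination MAG quality thresholds
#'   (percent; strict inequalities).
#' @param enrichment_mode Counting unit for [phylum_contingency()].
#' @param retention_threshold CPM threshold for [retention()].
#' @param n_perm Permutations for PERMANOVA.
#' @param seed Seed for all stochastic stages (permutations).
#' @return A `run_config` list; its hash is stamped on all outputs.
#' @export
run_config <- function(donor_scope = "sex_cohort", min_completeness = 90,
                       max_contamination = 5,
                       enrichment_mode = "engraftment",
                       retention_threshold = 0, n_perm = 999, seed = 1L) {
  config <- as.list(environment())
  class(config) <- "run_config"
  config
}

#' Run the full HGT analysis pipeline
#'
#' Executes the stages in order — MAG quality filtering, HTGC detection,
#' arm comparison, specificity partition, engraftment-dependent
#' filtering, donor attribution and species-pair matrix, phylum
#' enrichment, richness-normalised rate model, retention and abundance
#' model, functional profiling — each stage consuming the previous
#' stage's output. Record counts in and out of every filter are logged
#' in the run summary, and re-running with the same bundle and config is
#' deterministic.
#'
#' @param bundle An [hgt_bundle()].
#' @param config A [run_config()].
#' @return A list of class `hgt_results`: figure-level tables
#'   (`fig1_normalized_rates`, `fig2_specificity`, `fig3_attribution`,
#'   `fig4_enrichment`, `fig5_retention`, `fig6_functions`), the
#'   intermediate objects (`events`, `ed_events`, `frequencies`,
#'   `arm_comparison`, `rate_lmm`, `retention`, `retention_lmm`,
#'   `background`), and `summary` (named list for the JSON run summary).
#' @export
run_pipeline <- function(bundle, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  validate_bundle(bundle)
  log <- list()

  hq <- filter_high_quality(bundle$mags, config$min_completeness,
                            config$max_contamination)
  log$mags_total <- nrow(bundle$mags)
  log$mags_high_quality <- nrow(hq)
  log$pct_high_quality <- pct_of(nrow(hq), nrow(bundle$mags))

  analysable <- analysable_genes(bundle$genes, hq)
  log$genes_on_hq_mags <- analysable$n_hq
  log$genes_excluded_unclassified <- analysable$n_excluded_unclassified
  log$pct_excluded_unclassified <- analysable$pct_excluded_unclassified
  log$genes_analysable <- nrow(analysable$genes)

  events <- detect_htgcs(bundle, donor_scope = config$donor_scope,
                         analysable = analysable)
  log$n_events <- nrow(events)
  log$n_htgc_clusters <- dplyr::n_distinct(events$cluster_id)

  frequencies <- htgc_frequency(events, bundle, analysable = analysable)
  arm_comparison <- compare_arms(frequencies)
  spec_part <- classify_specificity(events)

  ed_events <- filter_engraftment_dependent(events, bundle$engraftment)
  log$n_engraftment_dependent_events <- nrow(ed_events)
  attribution <- donor_attribution(ed_events)
  pair_matrix <- species_pair_matrix(ed_events)

  phylum_lookup <- species_phylum_lookup(bundle)
  enrichment <- lapply(c("female", "male"), function(sx) {
    eng <- bundle$engraftment[
      bundle$engraftment$recipient_id %in%
        bundle$design$subject_id[bundle$design$sex == sx], , drop = FALSE]
    ed <- ed_events[ed_events$sex == sx, ]
    if (is.null(eng) || nrow(eng) == 0 || nrow(ed) == 0) return(NULL)
    tab <- phylum_contingency(eng, ed, phylum_lookup,
                              mode = config$enrichment_mode)
    if (nrow(tab) < 2) return(NULL)
    chi <- chi_squared(tab)
    ph <- posthoc_residuals(tab)
    ph$sex <- sx
    ph$chi2 <- chi$chi2
    ph$chi2_df <- chi$df
    ph$chi2_p <- chi$p
    ph
  })
  enrichment <- dplyr::bind_rows(enrichment)
  background <- tryCatch(background_distribution(bundle, analysable),
                         error = function(e) NULL)

  rate_lmm <- if (!is.null(bundle$waafle)) hgt_rate_lmm(bundle)
  ret <- if (!is.null(bundle$abundance) && nrow(ed_events) > 0) {
    retention(ed_events, bundle, config$retention_threshold)
  }
  ret_lmm <- if (!is.null(ret) && nrow(ret$series) > 0) {
    retention_lmm(ret$series)
  }

  functions_tbl <- NULL
  if (!is.null(ret) && !is.null(bundle$cog) && nrow(ret$series) > 0) {
    functions_tbl <- dplyr::bind_rows(
      compare_timepoints(ret$series, bundle$cog, level = "class",
                         n_perm = config$n_perm, seed = config$seed),
      compare_timepoints(ret$series, bundle$cog, level = "category",
                         n_perm = config$n_perm, seed = config$seed))
    shares <- lapply(sort(unique(ed_events$sex)), function(sx) {
      cl <- unique(ed_events$cluster_id[ed_events$sex == sx])
      sh <- class_shares(classify_clusters(bundle$cog, cl))
      sh$sex <- sx
      sh
    })
    log$class_shares <- dplyr::bind_rows(shares)
  }

  results <- structure(list(
    fig1_normalized_rates = if (!is.null(bundle$waafle)) {
      w <- normalize_hgt_rate(bundle$waafle)
      w <- dplyr::inner_join(w, bundle$samples, by = "sample_id")
      dplyr::left_join(w, bundle$design, by = "subject_id")
    },
    fig2_specificity = spec_part$counts,
    fig3_attribution = attribution$pairs,
    fig4_enrichment = enrichment,
    fig5_retention = if (!is.null(ret)) ret$summary,
    fig6_functions = functions_tbl,
    events = flatten_events(events),
    ed_events = ed_events,
    frequencies = frequencies,
    arm_comparison = arm_comparison,
    specificity = spec_part$partition,
    species_pairs = pair_matrix,
    background = background,
    rate_lmm = rate_lmm,
    retention = ret,
    retention_lmm = ret_lmm,
    summary = summarise_run(log, arm_comparison, rate_lmm, ret, ret_lmm),
    config = config), class = "hgt_results")
  results
}

species_phylum_lookup <- function(bundle) {
  m <- bundle$mags[bundle$mags$species_classified, c("species", "phylum")]
  m <- dplyr::distinct(m)
  setNames(m$phylum, m$species)
}

flatten_events <- function(events) {
  if (nrow(events) == 0) {
    out <- events
    out$donor_side <- NULL
    out$donor_ids <- character()
    out$donor_species <- character()
    return(out)
  }
  out <- events
  out$donor_ids <- vapply(events$donor_side, function(d) {
    paste(sort(unique(d$donor_id)), collapse = ";")
  }, character(1))
  out$donor_species <- vapply(events$donor_side, function(d) {
    paste(sort(unique(d$donor_species)), collapse = ";")
  }, character(1))
  out$donor_side <- NULL
  out
}

summarise_run <- function(log, arm_comparison, rate_lmm, ret, ret_lmm) {
  s <- log
  s$class_shares <- NULL
  s$wilcoxon_overall_p <- arm_comparison$p_value[arm_comparison$comparison == "overall"]
  if (!is.null(rate_lmm)) {
    w26 <- rate_lmm$coefficients[rate_lmm$coefficients$term == "timepointweek26", ]
    if (nrow(w26) == 1) {
      s$rate_lmm_week26_estimate <- w26$estimate
      s$rate_lmm_week26_ci <- c(w26$ci_low, w26$ci_high)
    }
    s$rate_lmm_lrt_p <- rate_lmm$lrt_p_interactions
  }
  if (!is.null(ret)) {
    s$retention <- ret$summary
  }
  if (!is.null(ret_lmm)) {
    s$retention_lmm_lrt_p <- ret_lmm$lrt_p_interactions
  }
  s
}

#' @exportS3Method base::print
print.hgt_results <- function(x, ...) {
  cat("<hgt_results>\n")
  cat(sprintf("  events: %d (%d clusters); engraftment-dependent: %d\n",
              x$summary$n_events, x$summary$n_htgc_clusters,
              x$summary$n_engraftment_dependent_events))
  cat(sprintf("  arm comparison (overall) p = %s\n",
              format(x$summary$wilcoxon_overall_p, digits = 3)))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Writes every figure-level table plus the flattened event tables as
#' TSV (via [write_results()], which stamps version and config hash) and
#' the JSON run summary.
#'
#' @param results An `hgt_results` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_pipeline_results <- function(results, out_dir) {
  tables <- list(
    fig1_normalized_rates = results$fig1_normalized_rates,
    fig2_specificity = results$fig2_specificity,
    fig3_attribution = results$fig3_attribution,
    fig4_enrichment = results$fig4_enrichment,
    fig5_retention = results$fig5_retention,
    fig6_functions = results$fig6_functions,
    htgcs = results$events,
    events_engraftment = results$ed_events,
    frequency = results$frequencies,
    arm_comparison = results$arm_comparison,
    specificity = results$specificity,
    species_pair_matrix = results$species_pairs,
    summary = summary_for_json(results$summary))
  write_results(tables, out_dir, config = unclass(results$config))
}

summary_for_json <- function(s) {
  if (!is.null(s$retention)) s$retention <- as.data.frame(s$retention)
  s
}
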