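#' Detect horizontally transferred gene clusters (HTGCs)
#'
#' Per-participant time-course set logic. A gene cluster is called
#' horizontally transferred into a participant when, on analysable genes
#' only (high-quality, species-classified MAGs):
#' \enumerate{
#'   \item at least one gene of the cluster occurs in the participant's
#'     week-6 sample,
#'   \item no gene of the cluster occurs in the participant's baseline
#'     sample,
#'   \item at least one gene of the cluster occurs in an in-scope donor
#'     sample, and
#'   \item the species of the recipient week-6 gene's MAG differs from
#'     the species of at least one in-scope donor occurrence's MAG
#'     (discordance; vertical persistence of the same species is not
#'     transfer).
#' }
#' Each distinct qualifying recipient gene is one transfer event, so a
#' cluster can contribute several events. A recipient gene is judged
#' against its own MAG's species; other same-cluster genes in the sample
#' are their own events. FMT and placebo participants run through the
#' identical code path — the treatment arm is never consulted.
#'
#' @param bundle An [hgt_bundle()].
#' @param participants Recipient ids to analyse (default: all recipients).
#' @param donor_scope `"sex_cohort"` (all sex-matched donors; default) or
#'   `"assigned"` (the participant's assigned donors, requires
#'   `bundle$donor_assignment`).
#' @param discordance `"any"` (default: at least one in-scope donor
#'   occurrence has a different species) or `"all"` (every donor
#'   occurrence must differ).
#' @param analysable Optional precomputed [analysable_genes()] result to
#'   avoid refiltering.
#' @return A tibble with one row per transfer event: `participant_id`,
#'   `arm`, `sex`, `timepoint`, `cluster_id`, `recipient_gene_id`,
#'   `recipient_species`, `recipient_phylum`, and a `donor_side`
#'   list-column of tibbles (`donor_id`, `donor_sample_id`,
#'   `donor_species`, `donor_phylum`) holding every in-scope donor
#'   occurrence of the cluster.
#' @export
detect_htgcs <- function(bundle, participants = NULL,
                         donor_scope = c("sex_cohort", "assigned"),
                         discordance = c("any", "all"),
                         analysable = NULL) {
  donor_scope <- match.arg(donor_scope)
  discordance <- match.arg(discordance)
  design <- bundle$design
  recipients <- design$subject_id[design$role == "recipient"]
  if (is.null(participants)) participants <- recipients
  unknown <- setdiff(participants, recipients)
  if (length(unknown) > 0) {
    stop("detect_htgcs(): unknown participant(s): ", id_list(unknown),
         call. = FALSE)
  }
  tp_by_subject <- split(bundle$samples$timepoint, bundle$samples$subject_id)
  lacking <- participants[!vapply(participants, function(p) {
    all(c("baseline", "week6") %in% (tp_by_subject[[p]] %||% character()))
  }, logical(1))]
  if (length(lacking) > 0) {
    stop("detect_htgcs(): missing baseline or week6 sample for: ",
         id_list(lacking), call. = FALSE)
  }
  if (donor_scope == "assigned" && is.null(bundle$donor_assignment)) {
    stop("detect_htgcs(): donor_scope = 'assigned' requires a donor_assignment table",
         call. = FALSE)
  }

  if (is.null(analysable)) {
    analysable <- analysable_genes(bundle$genes,
                                   filter_high_quality(bundle$mags))
  }
  ag <- dplyr::inner_join(analysable$genes,
                          bundle$samples[, c("sample_id", "subject_id", "timepoint")],
                          by = "sample_id")
  ag <- dplyr::left_join(ag, design, by = "subject_id")

  donor_occ <- ag[ag$role == "donor",
                  c("cluster_id", "subject_id", "sample_id", "species",
                    "phylum", "sex")]
  names(donor_occ) <- c("cluster_id", "donor_id", "donor_sample_id",
                        "donor_species", "donor_phylum", "donor_sex")

  w6 <- ag[ag$subject_id %in% participants & ag$timepoint == "week6", ]
  baseline_keys <- unique(paste(ag$subject_id, ag$cluster_id)[
    ag$subject_id %in% participants & ag$timepoint == "baseline"])
  cand <- w6[!paste(w6$subject_id, w6$cluster_id) %in% baseline_keys, ]

  if (nrow(cand) == 0) return(empty_events())

  hits <- dplyr::inner_join(cand, donor_occ, by = "cluster_id",
                            relationship = "many-to-many")
  hits <- hits[hits$donor_sex == hits$sex, ]
  if (donor_scope == "assigned") {
    da_keys <- paste(bundle$donor_assignment$recipient_id,
                     bundle$donor_assignment$donor_id)
    hits <- hits[paste(hits$subject_id, hits$donor_id) %in% da_keys, ]
  }
  if (nrow(hits) == 0) return(empty_events())

  by_gene <- dplyr::group_by(hits, .data$gene_id)
  qual <- dplyr::summarise(
    by_gene,
    participant_id = .data$subject_id[1], arm = .data$arm[1],
    sex = .data$sex[1], cluster_id = .data$cluster_id[1],
    recipient_species = .data$species[1], recipient_phylum = .data$phylum[1],
    n_discordant = sum(.data$donor_species != .data$species[1]),
    n_occ = dplyr::n(),
    donor_side = list(dplyr::pick("donor_id", "donor_sample_id",
                                  "donor_species", "donor_phylum")),
    .groups = "drop")
  keep <- if (discordance == "any") qual$n_discordant >= 1 else
    qual$n_discordant == qual$n_occ
  qual <- qual[keep, ]
  if (nrow(qual) == 0) return(empty_events())

  out <- tibble::tibble(
    participant_id = qual$participant_id, arm = qual$arm, sex = qual$sex,
    timepoint = "week6", cluster_id = qual$cluster_id,
    recipient_gene_id = qual$gene_id,
    recipient_species = qual$recipient_species,
    recipient_phylum = qual$recipient_phylum,
    donor_side = qual$donor_side)
  out[order(out$participant_id, out$cluster_id, out$recipient_gene_id), ]
}

empty_events <- function() {
  tibble::tibble(participant_id = character(), arm = character(),
                 sex = character(), timepoint = character(),
                 cluster_id = character(), recipient_gene_id = character(),
                 recipient_species = character(),
                 recipient_phylum = character(), donor_side = list())
}

#' Flatten the donor side of detected events
#'
#' @param events Output of [detect_htgcs()].
#' @return A tibble with one row per (event, donor occurrence).
#' @export
event_donor_occurrences <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(participant_id = character(),
                          recipient_gene_id = character(),
                          cluster_id = character(), donor_id = character(),
                          donor_sample_id = character(),
                          donor_species = character(),
                          donor_phylum = character()))
  }
  tidyr::unnest(events[, c("participant_id", "recipient_gene_id",
                           "cluster_id", "donor_side")],
                "donor_side")
}

#' Per-participant HTGC frequency
#'
#' The percentage of a participant's distinct analysable week-6 gene
#' clusters that were called horizontally transferred:
#' `100 * n_htgc / n_clusters`.
#'
#' @param events Output of [detect_htgcs()].
#' @param bundle The bundle the events came from.
#' @param analysable Optional precomputed [analysable_genes()] result.
#' @return Tibble: `participant_id`, `arm`, `sex`, `n_htgc`,
#'   `n_clusters`, `freq_pct` (unrounded percent in `[0, 100]`).
#'   Participants with no events appear with `freq_pct = 0`.
#' @export
htgc_frequency <- function(events, bundle, analysable = NULL) {
  if (is.null(analysable)) {
    analysable <- analysable_genes(bundle$genes,
                                   filter_high_quality(bundle$mags))
  }
  design <- bundle$design
  ag <- dplyr::inner_join(analysable$genes,
                          bundle$samples[, c("sample_id", "subject_id", "timepoint")],
                          by = "sample_id")
  w6 <- ag[ag$timepoint == "week6", ]
  denom <- dplyr::summarise(dplyr::group_by(w6, .data$subject_id),
                            n_clusters = dplyr::n_distinct(.data$cluster_id),
                            .groups = "drop")
  rec <- design[design$role == "recipient",
                c("subject_id", "arm", "sex")]
  denom <- dplyr::inner_join(rec, denom, by = "subject_id")
  if (any(denom$n_clusters == 0) || nrow(denom) == 0) {
    stop("htgc_frequency(): zero analysable week-6 clusters; frequency undefined",
         call. = FALSE)
  }
  num <- dplyr::summarise(dplyr::group_by(events, .data$participant_id),
                          n_htgc = dplyr::n_distinct(.data$cluster_id),
                          .groups = "drop")
  out <- dplyr::left_join(denom, num,
                          by = c(subject_id = "participant_id"))
  out$n_htgc[is.na(out$n_htgc)] <- 0L
  tibble::tibble(participant_id = out$subject_id, arm = out$arm,
                 sex = out$sex, n_htgc = out$n_htgc,
                 n_clusters = out$n_clusters,
                 freq_pct = 100 * out$n_htgc / out$n_clusters)
}

#' Compare HTGC frequency between trial arms
#'
#' Two-sided Wilcoxon rank-sum tests of per-participant HTGC frequency,
#' FMT versus placebo, overall and within each sex. The exact null
#' distribution is enumerated when both groups have at most eight
#' untied observations; otherwise the normal approximation with tie
#' correction (and continuity correction) is used.
#'
#' @param frequencies Output of [htgc_frequency()] (or any tibble with
#'   `arm`, `sex` and a `freq_pct` column).
#' @return Tibble: `comparison` (overall/female/male), `n_fmt`,
#'   `n_placebo`, `statistic` (W), `p_value`.
#' @export
compare_arms <- function(frequencies) {
  run_test <- function(df, label) {
    x <- df$freq_pct[df$arm == "FMT"]
    y <- df$freq_pct[df$arm == "placebo"]
    if (label == "overall" && (length(x) == 0 || length(y) == 0)) {
      stop("compare_arms(): an arm is empty", call. = FALSE)
    }
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(comparison = label, n_fmt = length(x),
                            n_placebo = length(y), statistic = NA_real_,
                            p_value = NA_real_))
    }
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- length(x) <= 8 && length(y) <= 8 && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    tibble::tibble(comparison = label, n_fmt = length(x),
                   n_placebo = length(y),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  dplyr::bind_rows(
    run_test(frequencies, "overall"),
    run_test(frequencies[frequencies$sex == "female", ], "female"),
    run_test(frequencies[frequencies$sex == "male", ], "male"))
}

#' Partition detected clusters by arm specificity
#'
#' Within each sex, a detected cluster is FMT-specific when it was called
#' only in FMT recipients, placebo-specific when only in placebo
#' recipients, and shared otherwise. The three sets partition the union
#' of detected clusters for that sex.
#'
#' @param events Output of [detect_htgcs()].
#' @return A list: `partition` (tibble `sex`, `cluster_id`,
#'   `specificity`) and `counts` (tibble `sex`, `specificity`,
#'   `n_clusters`).
#' @export
classify_specificity <- function(events) {
  if (nrow(events) == 0) {
    return(list(partition = tibble::tibble(sex = character(),
                                           cluster_id = character(),
                                           specificity = character()),
                counts = tibble::tibble(sex = character(),
                                        specificity = character(),
                                        n_clusters = integer())))
  }
  by_cluster <- dplyr::summarise(
    dplyr::group_by(events, .data$sex, .data$cluster_id),
    in_fmt = any(.data$arm == "FMT"),
    in_placebo = any(.data$arm == "placebo"), .groups = "drop")
  by_cluster$specificity <- dplyr::case_when(
    by_cluster$in_fmt & by_cluster$in_placebo ~ "shared",
    by_cluster$in_fmt ~ "fmt_specific",
    TRUE ~ "placebo_specific")
  partition <- by_cluster[order(by_cluster$sex, by_cluster$cluster_id),
                          c("sex", "cluster_id", "specificity")]
  counts <- dplyr::count(partition, .data$sex, .data$specificity,
                         name = "n_clusters")
  list(partition = partition, counts = counts)
}

#' Histogram of per-cluster transfer-event counts
#'
#' Counts, for each detected cluster, its total number of transfer
#' events, and bins the clusters at width 1 from 1 to `max_bin` with a
#' terminal `"20+"`-style bin. Bin counts sum to the number of clusters.
#'
#' @param events Output of [detect_htgcs()], optionally pre-filtered
#'   (e.g. to one sex or one specificity class).
#' @param max_bin Last unit-width bin (default 20).
#' @return Tibble: `bin` (factor `1`, ..., `20`, `20+`), `n_clusters`.
#' @export
event_histogram <- function(events, max_bin = 20) {
  levels <- c(as.character(seq_len(max_bin)), paste0(max_bin, "+"))
  if (nrow(events) == 0) {
    return(tibble::tibble(bin = factor(character(), levels = levels),
                          n_clusters = integer()))
  }
  per_cluster <- dplyr::count(events, .data$cluster_id, name = "n_events")
  bin <- ifelse(per_cluster$n_events > max_bin, paste0(max_bin, "+"),
                as.character(per_cluster$n_events))
  out <- dplyr::count(
    tibble::tibble(bin = factor(bin, levels = levels)), .data$bin,
    name = "n_clusters", .drop = FALSE)
  out
}
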