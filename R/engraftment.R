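#' Filter transfer events to engraftment-dependent ones
#'
#' Restricts detected transfer events to those whose donor side includes
#' a species recorded as having engrafted in that recipient at week 6.
#' Matching is on (recipient, species); the donor id is reported when the
#' engraftment call pins it down uniquely. The result is deduplicated to
#' distinct (recipient, cluster, recipient gene, engrafted species); when
#' an event's donor side matches several engrafted species it therefore
#' appears once per engrafted species for attribution purposes, while
#' event totals elsewhere count distinct recipient genes.
#'
#' @param events Output of [detect_htgcs()].
#' @param engraftment An `engraftment` bundle table (week-6 calls).
#' @return Tibble: the event fields plus `engrafted_species`,
#'   `engrafted_donor_id` (NA when ambiguous), `engrafted_phylum`.
#' @export
filter_engraftment_dependent <- function(events, engraftment) {
  empty <- tibble::tibble(
    participant_id = character(), arm = character(), sex = character(),
    timepoint = character(), cluster_id = character(),
    recipient_gene_id = character(), recipient_species = character(),
    recipient_phylum = character(), engrafted_species = character(),
    engrafted_phylum = character(), engrafted_donor_id = character())
  if (nrow(events) == 0 || is.null(engraftment) || nrow(engraftment) == 0) {
    return(empty)
  }
  occ <- event_donor_occurrences(events)
  eng <- dplyr::summarise(
    dplyr::group_by(engraftment, .data$recipient_id, .data$species),
    engrafted_donor_id = if (dplyr::n_distinct(.data$donor_id) == 1)
      .data$donor_id[1] else NA_character_,
    .groups = "drop")
  hit <- dplyr::inner_join(
    occ, eng,
    by = c(participant_id = "recipient_id", donor_species = "species"),
    relationship = "many-to-many")
  hit <- dplyr::distinct(hit, .data$participant_id, .data$recipient_gene_id,
                         .data$cluster_id, .data$donor_species,
                         .data$donor_phylum, .data$engrafted_donor_id)
  ev <- events[, c("participant_id", "arm", "sex", "timepoint", "cluster_id",
                   "recipient_gene_id", "recipient_species",
                   "recipient_phylum")]
  out <- dplyr::inner_join(ev, hit,
                           by = c("participant_id", "recipient_gene_id",
                                  "cluster_id"))
  out <- dplyr::rename(out, engrafted_species = "donor_species",
                       engrafted_phylum = "donor_phylum")
  # an engrafted species identical to the recipient species is vertical
  # persistence, not transfer
  out <- out[out$engrafted_species != out$recipient_species, ]
  out <- dplyr::distinct(out, .data$participant_id, .data$cluster_id,
                         .data$recipient_gene_id, .data$engrafted_species,
                         .keep_all = TRUE)
  out[order(out$participant_id, out$cluster_id, out$recipient_gene_id,
            out$engrafted_species), ]
}

#' Attribute engraftment-dependent events to donors
#'
#' Counts events per (donor, recipient) pair — the table behind an
#' alluvial donor-to-recipient flow — plus per-donor totals within each
#' sex. Events without a uniquely attributable donor are reported under
#' donor id `"(ambiguous)"`.
#'
#' @param ed_events Output of [filter_engraftment_dependent()].
#' @return List: `pairs` (tibble `donor_id`, `recipient_id`, `sex`,
#'   `n_events`) and `donor_totals` (tibble `sex`, `donor_id`,
#'   `n_events`).
#' @export
donor_attribution <- function(ed_events) {
  ev <- ed_events
  ev$donor_id <- ifelse(is.na(ev$engrafted_donor_id), "(ambiguous)",
                        ev$engrafted_donor_id)
  pairs <- dplyr::count(ev, .data$donor_id,
                        recipient_id = .data$participant_id, .data$sex,
                        name = "n_events")
  donor_totals <- dplyr::count(ev, .data$sex, .data$donor_id,
                               name = "n_events")
  list(pairs = pairs[order(pairs$donor_id, pairs$recipient_id), ],
       donor_totals = donor_totals)
}

#' Species-pair transfer matrix
#'
#' Counts engraftment-dependent events for every (engrafted donor
#' species, recipient species) pair, carrying both species' phyla so the
#' matrix can be displayed grouped by phylum. The diagonal (same species
#' on both sides) is structurally zero — such pairs are vertical
#' persistence and are excluded upstream.
#'
#' @param ed_events Output of [filter_engraftment_dependent()].
#' @param phylum_lookup Optional named character vector
#'   (species -> phylum) supplying phyla for species absent from MAG
#'   taxonomy (the manual fill-in step).
#' @return Tibble: `engrafted_species`, `engrafted_phylum`,
#'   `recipient_species`, `recipient_phylum`, `n_events`; entries are
#'   positive integers summing to the event count.
#' @export
species_pair_matrix <- function(ed_events, phylum_lookup = NULL) {
  ev <- ed_events
  if (!is.null(phylum_lookup)) {
    fill <- function(phy, sp) {
      miss <- is.na(phy) & sp %in% names(phylum_lookup)
      phy[miss] <- phylum_lookup[sp[miss]]
      phy
    }
    ev$engrafted_phylum <- fill(ev$engrafted_phylum, ev$engrafted_species)
    ev$recipient_phylum <- fill(ev$recipient_phylum, ev$recipient_species)
  }
  missing_phy <- unique(c(ev$engrafted_species[is.na(ev$engrafted_phylum)],
                          ev$recipient_species[is.na(ev$recipient_phylum)]))
  if (length(missing_phy) > 0) {
    stop("species_pair_matrix(): no phylum for species ",
         id_list(missing_phy),
         "; supply them via phylum_lookup", call. = FALSE)
  }
  if (nrow(ev) == 0) {
    return(tibble::tibble(engrafted_species = character(),
                          engrafted_phylum = character(),
                          recipient_species = character(),
                          recipient_phylum = character(),
                          n_events = integer()))
  }
  out <- dplyr::count(ev, .data$engrafted_species, .data$engrafted_phylum,
                      .data$recipient_species, .data$recipient_phylum,
                      name = "n_events")
  out[order(out$engrafted_phylum, out$engrafted_species,
            out$recipient_phylum, out$recipient_species), ]
}
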