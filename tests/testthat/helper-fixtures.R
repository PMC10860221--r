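# Shared fixtures and independent oracles, all built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

with_seed_local <- function(seed, code) {
  withr::local_seed(seed)
  force(code)
}

# Minimal hand-built trial: one donor (D1) and one recipient (R1) per the
# smallest valid design, extensible via extra_* arguments.
toy_bundle <- function(extra_mags = NULL, extra_genes = NULL,
                       recipients = "R1", arms = "FMT", sexes = "female",
                       validate = TRUE) {
  design <- tibble::tibble(
    subject_id = c("D1", recipients),
    role = c("donor", rep("recipient", length(recipients))),
    arm = c(NA_character_, arms),
    sex = c(sexes[1], sexes))
  samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = "D1|donation1", subject_id = "D1",
                   timepoint = "donation1"),
    tidyr::crossing(subject_id = recipients,
                    timepoint = c("baseline", "week6")) |>
      dplyr::mutate(sample_id = paste0(subject_id, "|", timepoint)))
  mags <- dplyr::bind_rows(
    lapply(samples$sample_id, function(sid) {
      tibble::tibble(mag_id = paste0("m|", sid), sample_id = sid,
                     completeness = 95, contamination = 1,
                     phylum = "Firmicutes", species = "spA",
                     species_classified = TRUE)
    }))
  genes <- tibble::tibble(
    gene_id = paste0("g|", samples$sample_id), mag_id = paste0("m|", samples$sample_id),
    sample_id = samples$sample_id, cluster_id = "c_base")
  hgt_bundle(design = design,
             samples = samples[, c("sample_id", "subject_id", "timepoint")],
             mags = dplyr::bind_rows(mags, extra_mags),
             genes = dplyr::bind_rows(genes, extra_genes),
             validate = validate)
}

# A richer hand-built detection fixture: recipient R1 (female, FMT) with
# baseline/week6, donor D1 (female) with one sample. Gene placement is
# parameterised so each detection criterion can be switched on and off.
detect_fixture <- function(week6_genes, baseline_clusters = character(),
                           donor_genes, recipients = "R1", arms = "FMT") {
  mk_mag <- function(sid, species, hq = TRUE, classified = TRUE) {
    tibble::tibble(mag_id = paste0("m|", sid, "|", species), sample_id = sid,
                   completeness = if (hq) 95 else 80,
                   contamination = if (hq) 1 else 8,
                   phylum = "Firmicutes",
                   species = if (classified) species else NA_character_,
                   species_classified = classified)
  }
  design <- tibble::tibble(
    subject_id = c("D1", recipients),
    role = c("donor", rep("recipient", length(recipients))),
    arm = c(NA_character_, arms),
    sex = "female")
  samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = "D1|donation1", subject_id = "D1",
                   timepoint = "donation1"),
    tidyr::crossing(subject_id = recipients,
                    timepoint = c("baseline", "week6")) |>
      dplyr::mutate(sample_id = paste0(subject_id, "|", timepoint)))
  mags <- list(); genes <- list()
  add <- function(sid, species, cluster, gene_suffix = "") {
    mags[[length(mags) + 1]] <<- mk_mag(sid, species)
    genes[[length(genes) + 1]] <<- tibble::tibble(
      gene_id = paste0("g|", sid, "|", species, "|", cluster, gene_suffix),
      mag_id = paste0("m|", sid, "|", species), sample_id = sid,
      cluster_id = cluster)
  }
  for (i in seq_len(nrow(week6_genes))) {
    w <- week6_genes[i, ]
    add(paste0(w$recipient, "|week6"), w$species, w$cluster,
        gene_suffix = w$suffix %||% "")
  }
  for (cl in baseline_clusters) {
    add(paste0(recipients[1], "|baseline"), "spBase", cl)
  }
  for (i in seq_len(nrow(donor_genes))) {
    d <- donor_genes[i, ]
    add("D1|donation1", d$species, d$cluster)
  }
  mags <- dplyr::distinct(dplyr::bind_rows(mags), mag_id, .keep_all = TRUE)
  hgt_bundle(design = design,
             samples = samples[, c("sample_id", "subject_id", "timepoint")],
             mags = mags, genes = dplyr::bind_rows(genes), validate = FALSE)
}

# Independent brute-force detection oracle: nested loops over genes and
# samples, no joins, no shared code with detect_htgcs().
brute_force_detect <- function(bundle, donor_scope = "sex_cohort") {
  d <- bundle$design; s <- bundle$samples
  m <- bundle$mags; g <- bundle$genes
  hq <- m[m$completeness > 90 & m$contamination < 5 & m$species_classified, ]
  events <- list()
  for (p in d$subject_id[d$role == "recipient"]) {
    sex <- d$sex[d$subject_id == p]
    if (donor_scope == "sex_cohort") {
      donors <- d$subject_id[d$role == "donor" & d$sex == sex]
    } else {
      donors <- bundle$donor_assignment$donor_id[
        bundle$donor_assignment$recipient_id == p]
    }
    donor_sids <- s$sample_id[s$subject_id %in% donors]
    w6_sid <- s$sample_id[s$subject_id == p & s$timepoint == "week6"]
    bl_sid <- s$sample_id[s$subject_id == p & s$timepoint == "baseline"]
    for (i in seq_len(nrow(g))) {
      if (!g$sample_id[i] %in% w6_sid) next
      if (!g$mag_id[i] %in% hq$mag_id) next
      cl <- g$cluster_id[i]
      sp <- hq$species[hq$mag_id == g$mag_id[i]]
      # baseline absence on analysable genes
      bl_present <- FALSE
      for (j in seq_len(nrow(g))) {
        if (g$sample_id[j] %in% bl_sid && g$cluster_id[j] == cl &&
            g$mag_id[j] %in% hq$mag_id) bl_present <- TRUE
      }
      if (bl_present) next
      # any in-scope discordant donor occurrence
      discordant <- FALSE
      for (j in seq_len(nrow(g))) {
        if (g$sample_id[j] %in% donor_sids && g$cluster_id[j] == cl &&
            g$mag_id[j] %in% hq$mag_id) {
          dsp <- hq$species[hq$mag_id == g$mag_id[j]]
          if (dsp != sp) discordant <- TRUE
        }
      }
      if (discordant) {
        events[[length(events) + 1]] <- data.frame(
          participant_id = p, cluster_id = cl,
          recipient_gene_id = g$gene_id[i])
      }
    }
  }
  if (length(events) == 0) {
    return(data.frame(participant_id = character(), cluster_id = character(),
                      recipient_gene_id = character()))
  }
  out <- do.call(rbind, events)
  out[order(out$participant_id, out$cluster_id, out$recipient_gene_id), ]
}

# Small simulator configuration for oracle-scale tests (< 200 genes).
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               n_donors_per_sex = c(female = 1L, male = 1L),
               n_recipients_per_arm_per_sex = 1L,
               n_species = 8L, n_clusters_per_species = 2L,
               species_per_subject = 3L, donors_per_recipient = 1L,
               n_donor_samples = 1L,
               decoy_lowq_mags_per_sample = 0L,
               decoy_unclassified_mags_per_sample = 0L,
               background_acquisition_rate = 0.3,
               engraftment_rate = 0.5,
               transfer_rate_given_engraftment = 0.5)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Boosted configuration for experiments that need hundreds of
# engraftment-dependent events (enrichment power, retention scale).
boosted_config <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               n_recipients_per_arm_per_sex = 12L,
               n_clusters_per_species = 5L,
               engraftment_rate = 0.4,
               transfer_rate_given_engraftment = 0.3,
               mean_extra_clusters_per_transfer = 1.5,
               decoy_lowq_mags_per_sample = 0L,
               decoy_unclassified_mags_per_sample = 0L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
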