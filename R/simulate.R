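#' Synthetic FMT trial configuration
#'
#' Builds the configuration for [simulate_trial()]. Defaults describe a
#' desk-scale two-arm, sex-stratified FMT trial: nine stool donors (five
#' female, four male), recipients sampled at baseline and weeks 6/12/26,
#' four sex-matched donors assigned per recipient, a gut community drawn
#' from a species pool whose phylum composition matches the high-quality
#' MAG census of such trials (Firmicutes 68.2\%, Bacteroidetes 21.8\%,
#' Actinobacteria 4.2\%, remainder 5.8\%), donor-derived strain
#' engraftment at week 6, engraftment-dependent gene-cluster transfer
#' biased toward Bacteroidetes donors, an arm-independent background
#' acquisition process, cluster retention through weeks 12 and 26, and a
#' week-26 drift in richness-normalised contig-level HGT counts.
#'
#' @param seed Master seed; every generated table draws from its own
#'   substream derived from it.
#' @param n_donors_per_sex Named vector `c(female =, male =)`.
#' @param n_recipients_per_arm_per_sex Recipients per arm per sex.
#' @param n_species Size of the species pool.
#' @param phylum_weights Named probabilities, summing to 1, giving the
#'   phylum of each pool species.
#' @param n_clusters_per_species Gene clusters in each species' core
#'   repertoire (repertoires are disjoint, so a cluster's "home" species
#'   is unambiguous).
#' @param species_per_subject Community size for every donor and every
#'   recipient baseline.
#' @param donors_per_recipient Sex-matched donors assigned per recipient.
#' @param n_donor_samples Donation samples per donor.
#' @param background_acquisition_rate Probability, per candidate donor-
#'   cohort cluster, that a recipient acquires it by week 6 independent of
#'   arm (the environmental/background HGT process).
#' @param engraftment_rate Probability, per donor species novel to the
#'   recipient, of week-6 establishment. Applied identically in the
#'   placebo arm as environmental turnover (not recorded as engraftment),
#'   so community size stays arm-balanced.
#' @param bacteroidetes_hgt_multiplier Multiplier (>= 1) on
#'   `transfer_rate_given_engraftment` for engrafted Bacteroidetes.
#' @param transfer_rate_given_engraftment Probability an engrafted
#'   species transfers clusters to a resident species.
#' @param mean_extra_clusters_per_transfer Poisson mean for clusters
#'   transferred beyond the first in one transfer episode.
#' @param retention_prob_week12,retention_prob_week26 Per planted cluster
#'   retention probabilities (independent draws; week-26 re-detection
#'   after a week-12 loss is allowed).
#' @param drift_effect_week26 Additive effect on the richness-normalised
#'   contig-level HGT count at week 26.
#' @param cpm_lognormal_mu,cpm_lognormal_sigma Log-scale location/scale
#'   of planted-cluster CPM abundances.
#' @param cog_unannotated_prob,cog_poor_prob Probability a cluster has no
#'   COG annotation; probability an annotated letter is R/S.
#' @param cog_shift_week26 Plants a week-26 functional shift: the
#'   week-26 retention probability of clusters outside the metabolism
#'   class is divided by `1 + cog_shift_week26` (0 = no shift).
#' @param waafle_base_rate,waafle_subject_sd Baseline richness-normalised
#'   contig HGT rate and the between-subject SD of its random intercept.
#' @param waafle_mean_contigs Mean assembled contigs per sample.
#' @param decoy_lowq_mags_per_sample,decoy_unclassified_mags_per_sample
#'   Per sample: low-quality MAGs (excluded by the quality filter) and
#'   high-quality MAGs with no species classification (excluded by the
#'   taxonomy filter), each carrying `decoy_genes_per_mag` genes.
#' @param decoy_genes_per_mag Genes carried by each decoy MAG.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_donors_per_sex = c(female = 5L, male = 4L),
                       n_recipients_per_arm_per_sex = 10L,
                       n_species = 60L,
                       phylum_weights = c(Firmicutes = 0.682,
                                          Bacteroidetes = 0.218,
                                          Actinobacteria = 0.042,
                                          Proteobacteria = 0.058),
                       n_clusters_per_species = 10L,
                       species_per_subject = 22L,
                       donors_per_recipient = 4L,
                       n_donor_samples = 2L,
                       background_acquisition_rate = 0.1,
                       engraftment_rate = 0.25,
                       bacteroidetes_hgt_multiplier = 4,
                       transfer_rate_given_engraftment = 0.05,
                       mean_extra_clusters_per_transfer = 1,
                       retention_prob_week12 = 0.858,
                       retention_prob_week26 = 0.803,
                       drift_effect_week26 = 0.37,
                       cpm_lognormal_mu = 3,
                       cpm_lognormal_sigma = 1,
                       cog_unannotated_prob = 0.21,
                       cog_poor_prob = 0.28,
                       cog_shift_week26 = 0,
                       waafle_base_rate = 0.2,
                       waafle_subject_sd = 0.08,
                       waafle_mean_contigs = 5000,
                       decoy_lowq_mags_per_sample = 2L,
                       decoy_unclassified_mags_per_sample = 1L,
                       decoy_genes_per_mag = 8L) {
  config <- as.list(environment())
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  errors <- character()
  probs <- c("background_acquisition_rate", "engraftment_rate",
             "transfer_rate_given_engraftment", "retention_prob_week12",
             "retention_prob_week26", "cog_unannotated_prob", "cog_poor_prob")
  for (p in probs) {
    v <- config[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      errors <- c(errors, sprintf("%s must be a probability in [0,1]", p))
    }
  }
  w <- config$phylum_weights
  if (is.null(names(w)) || any(names(w) == "") || any(w < 0) ||
      abs(sum(w) - 1) > 1e-9) {
    errors <- c(errors, "phylum_weights must be named, nonnegative and sum to 1 (tol 1e-9)")
  }
  nd <- config$n_donors_per_sex
  if (!all(c("female", "male") %in% names(nd)) || any(nd < 1)) {
    errors <- c(errors, "need at least one donor per sex (named vector female/male)")
  }
  if (config$n_recipients_per_arm_per_sex < 1) {
    errors <- c(errors, "need at least one recipient per arm per sex")
  }
  if (config$bacteroidetes_hgt_multiplier < 1) {
    errors <- c(errors, "bacteroidetes_hgt_multiplier must be >= 1")
  }
  if (config$species_per_subject > config$n_species) {
    errors <- c(errors, "species_per_subject cannot exceed n_species")
  }
  abort_many(errors, "sim_config")
  invisible(config)
}

#' Simulate a complete synthetic FMT trial
#'
#' Generates a validated [hgt_bundle()] together with planted ground
#' truth, so every downstream stage can be checked against known answers.
#' Planted horizontally transferred clusters satisfy the detection
#' criteria by construction: present at the recipient's week 6, absent at
#' baseline, present in a sex-matched donor, and carried by a recipient
#' MAG whose species differs from the donor-side species. Background
#' acquisitions occur at the same rate in both arms; engraftment-
#' dependent transfers occur only in FMT recipients, from engrafted donor
#' species, with Bacteroidetes donors transferring more often.
#' Identical seeds give identical output; each generated table draws
#' from its own RNG substream, so adding a table never perturbs others.
#'
#' @param config A [sim_config()].
#' @return A list with elements `bundle` (an [hgt_bundle()]) and `truth`
#'   (list of `planted_htgcs`, `planted_engraftments`, `retained_at`).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed

  # -- taxonomy: species pool and disjoint cluster catalog ----------------
  species <- with_stream(seed, "taxonomy", {
    tibble::tibble(
      species_id = sprintf("s%03d", seq_len(config$n_species)),
      phylum = sample(names(config$phylum_weights), config$n_species,
                      replace = TRUE, prob = config$phylum_weights))
  })
  catalog <- tidyr::crossing(species, k = seq_len(config$n_clusters_per_species))
  catalog$cluster_id <- sprintf("cl|%s|%02d", catalog$species_id, catalog$k)
  catalog$k <- NULL

  # -- subjects, communities, assignment ---------------------------------
  design <- build_design(config)
  donors <- design[design$role == "donor", ]
  recipients <- design[design$role == "recipient", ]

  comm <- with_stream(seed, "community", {
    communities <- lapply(design$subject_id, function(id) {
      sample(species$species_id, config$species_per_subject)
    })
    names(communities) <- design$subject_id
    assignment <- dplyr::bind_rows(lapply(seq_len(nrow(recipients)), function(i) {
      r <- recipients[i, ]
      cohort <- donors$subject_id[donors$sex == r$sex]
      k <- min(config$donors_per_recipient, length(cohort))
      tibble::tibble(recipient_id = r$subject_id,
                     donor_id = sort(sample(cohort, k)))
    }))
    list(communities = communities, assignment = assignment)
  })
  communities <- comm$communities
  assignment <- comm$assignment

  donor_species <- dplyr::bind_rows(lapply(donors$subject_id, function(d) {
    tibble::tibble(donor_id = d, species_id = communities[[d]])
  }))

  # -- week-6 turnover and engraftment -----------------------------------
  turn <- with_stream(seed, "engraftment", {
    novel <- list(); engraft <- list()
    for (i in seq_len(nrow(recipients))) {
      r <- recipients[i, ]
      baseline <- communities[[r$subject_id]]
      # both arms draw week-6 turnover candidates from an equally sized
      # donor-species pool (the assigned donors; for placebo this models
      # environmental exposure to the same species reservoir), keeping
      # community size and background HTGC opportunity arm-balanced
      pool <- donor_species[donor_species$donor_id %in%
                              assignment$donor_id[assignment$recipient_id == r$subject_id], ]
      candidates <- unique(pool$species_id[!pool$species_id %in% baseline])
      take <- candidates[runif(length(candidates)) < config$engraftment_rate]
      if (length(take) > 0) {
        novel[[r$subject_id]] <- take
        if (r$arm == "FMT") {
          # attribute each engrafted species to one carrying assigned donor
          src <- unname(vapply(take, function(sp) {
            carriers <- pool$donor_id[pool$species_id == sp]
            carriers[sample.int(length(carriers), 1)]
          }, character(1)))
          engraft[[r$subject_id]] <- tibble::tibble(
            recipient_id = r$subject_id, donor_id = src, species = take,
            timepoint = "week6")
        }
      }
    }
    list(novel = novel, engraftment = dplyr::bind_rows(engraft))
  })
  novel <- turn$novel
  engraftment <- turn$engraftment
  if (nrow(engraftment) == 0) {
    engraftment <- tibble::tibble(recipient_id = character(),
                                  donor_id = character(),
                                  species = character(),
                                  timepoint = character())
  }

  phylum_of <- setNames(species$phylum, species$species_id)

  # -- engraftment-dependent transfers -----------------------------------
  transfers <- with_stream(seed, "transfer", {
    out <- list()
    if (nrow(engraftment) > 0) {
      eng <- dplyr::distinct(engraftment, .data$recipient_id, .data$species,
                             .keep_all = TRUE)
      for (i in seq_len(nrow(eng))) {
        e <- eng[i, ]
        mult <- if (phylum_of[[e$species]] == "Bacteroidetes") {
          config$bacteroidetes_hgt_multiplier
        } else 1
        p <- min(1, config$transfer_rate_given_engraftment * mult)
        if (runif(1) >= p) next
        target <- sample(communities[[e$recipient_id]], 1)
        n_cl <- 1L + rpois(1, config$mean_extra_clusters_per_transfer)
        repertoire <- catalog$cluster_id[catalog$species_id == e$species]
        picked <- sample(repertoire, min(n_cl, length(repertoire)))
        out[[length(out) + 1L]] <- tibble::tibble(
          recipient_id = e$recipient_id, cluster_id = picked,
          donor_id = e$donor_id, donor_species = e$species,
          recipient_species = target, engraftment_dependent = TRUE)
      }
    }
    dplyr::bind_rows(out)
  })

  # -- background acquisitions (arm-independent) -------------------------
  background <- with_stream(seed, "background", {
    out <- list()
    for (i in seq_len(nrow(recipients))) {
      r <- recipients[i, ]
      baseline <- communities[[r$subject_id]]
      cohort <- donor_species[donor_species$donor_id %in%
                                donors$subject_id[donors$sex == r$sex], ]
      present <- c(baseline, novel[[r$subject_id]])
      cand_species <- unique(cohort$species_id[!cohort$species_id %in% present])
      cand <- catalog[catalog$species_id %in% cand_species, ]
      hit <- runif(nrow(cand)) < config$background_acquisition_rate
      if (!any(hit)) next
      got <- cand[hit, ]
      src_donor <- unname(vapply(got$species_id, function(sp) {
        carriers <- unique(cohort$donor_id[cohort$species_id == sp])
        carriers[sample.int(length(carriers), 1)]
      }, character(1)))
      out[[length(out) + 1L]] <- tibble::tibble(
        recipient_id = r$subject_id, cluster_id = got$cluster_id,
        donor_id = src_donor, donor_species = got$species_id,
        recipient_species = sample(baseline, nrow(got), replace = TRUE),
        engraftment_dependent = FALSE)
    }
    dplyr::bind_rows(out)
  })

  planted <- dplyr::bind_rows(transfers, background)
  if (nrow(planted) > 0) {
    # engraftment-dependent record wins if both processes hit one cluster
    planted <- planted[order(planted$recipient_id, planted$cluster_id,
                             !planted$engraftment_dependent), ]
    planted <- dplyr::distinct(planted, .data$recipient_id, .data$cluster_id,
                               .keep_all = TRUE)
    # a transfer target equal to the source species would be vertical, not
    # horizontal; the source is never a baseline member so this cannot
    # arise, but guard anyway
    planted <- planted[planted$recipient_species != planted$donor_species, ]
  } else {
    planted <- tibble::tibble(recipient_id = character(), cluster_id = character(),
                              donor_id = character(), donor_species = character(),
                              recipient_species = character(),
                              engraftment_dependent = logical())
  }

  # -- COG annotation of the catalog -------------------------------------
  cog <- with_stream(seed, "cog", simulate_cog(catalog$cluster_id, config))

  # -- retention ----------------------------------------------------------
  # cog_shift_week26 > 0 plants a week-26 functional shift: clusters
  # outside the metabolism class are retained less often, tilting the
  # week-26 functional composition toward metabolism
  retained_at <- with_stream(seed, "retention", {
    if (nrow(planted) == 0) {
      tibble::tibble(recipient_id = character(), cluster_id = character(),
                     week12 = logical(), week26 = logical())
    } else {
      metabolism <- metabolism_clusters(cog)
      p26 <- ifelse(planted$cluster_id %in% metabolism,
                    config$retention_prob_week26,
                    config$retention_prob_week26 / (1 + config$cog_shift_week26))
      tibble::tibble(
        recipient_id = planted$recipient_id, cluster_id = planted$cluster_id,
        week12 = runif(nrow(planted)) < config$retention_prob_week12,
        week26 = runif(nrow(planted)) < p26)
    }
  })

  # -- assemble samples, MAGs, genes -------------------------------------
  samples <- build_samples(design, config)
  sample_species <- build_sample_species(samples, design, communities, novel)

  mags <- with_stream(seed, "quality", {
    n <- nrow(sample_species)
    tibble::tibble(
      mag_id = paste0("m|", sample_species$sample_id, "|", sample_species$species_id),
      sample_id = sample_species$sample_id,
      completeness = runif(n, 90.5, 100),
      contamination = runif(n, 0, 4.5),
      phylum = unname(phylum_of[sample_species$species_id]),
      species = sample_species$species_id,
      species_classified = TRUE)
  })

  community_genes <- dplyr::inner_join(sample_species, catalog,
                                       by = "species_id",
                                       relationship = "many-to-many")
  community_genes <- tibble::tibble(
    gene_id = paste0("g|", community_genes$sample_id, "|",
                     community_genes$species_id, "|", community_genes$cluster_id),
    mag_id = paste0("m|", community_genes$sample_id, "|", community_genes$species_id),
    sample_id = community_genes$sample_id,
    cluster_id = community_genes$cluster_id)

  planted_genes <- build_planted_genes(planted, retained_at, samples)

  decoys <- with_stream(seed, "decoys",
                        build_decoys(samples, species, catalog, config))

  mags_all <- dplyr::bind_rows(mags, decoys$mags)
  genes_all <- dplyr::bind_rows(community_genes, planted_genes, decoys$genes)

  # -- abundance for planted clusters ------------------------------------
  abundance <- with_stream(seed, "abundance",
                           build_abundance(planted, retained_at, cog, config))

  bundle <- hgt_bundle(design = design, samples = samples, mags = mags_all,
                       genes = genes_all, donor_assignment = assignment,
                       engraftment = engraftment, abundance = abundance,
                       cog = cog, validate = FALSE)
  bundle$waafle <- simulate_waafle_counts(config, bundle)
  validate_bundle(bundle)

  list(bundle = bundle,
       truth = list(planted_htgcs = planted,
                    planted_engraftments = engraftment,
                    retained_at = retained_at))
}

build_design <- function(config) {
  nd <- config$n_donors_per_sex
  nr <- config$n_recipients_per_arm_per_sex
  donors <- tibble::tibble(
    subject_id = c(sprintf("DF%02d", seq_len(nd[["female"]])),
                   sprintf("DM%02d", seq_len(nd[["male"]]))),
    role = "donor",
    arm = NA_character_,
    sex = rep(c("female", "male"), times = c(nd[["female"]], nd[["male"]])))
  recip <- tidyr::crossing(sex = c("female", "male"),
                           arm = c("FMT", "placebo"), i = seq_len(nr))
  recip <- tibble::tibble(
    subject_id = sprintf("T%s%s%02d", ifelse(recip$sex == "female", "F", "M"),
                         ifelse(recip$arm == "FMT", "T", "P"), recip$i),
    role = "recipient", arm = recip$arm, sex = recip$sex)
  dplyr::bind_rows(donors, recip)
}

build_samples <- function(design, config) {
  donors <- design[design$role == "donor", ]
  recipients <- design[design$role == "recipient", ]
  d <- tidyr::crossing(subject_id = donors$subject_id,
                       timepoint = sprintf("donation%d", seq_len(config$n_donor_samples)))
  r <- tidyr::crossing(subject_id = recipients$subject_id,
                       timepoint = RECIPIENT_TIMEPOINTS)
  out <- dplyr::bind_rows(d, r)
  tibble::tibble(sample_id = paste0(out$subject_id, "|", out$timepoint),
                 subject_id = out$subject_id, timepoint = out$timepoint)
}

build_sample_species <- function(samples, design, communities, novel) {
  role_of <- setNames(design$role, design$subject_id)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    sp <- communities[[s$subject_id]]
    if (role_of[[s$subject_id]] == "recipient" && s$timepoint != "baseline") {
      sp <- c(sp, novel[[s$subject_id]])
    }
    tibble::tibble(sample_id = s$sample_id, species_id = sp)
  })
  dplyr::bind_rows(rows)
}

build_planted_genes <- function(planted, retained_at, samples) {
  if (nrow(planted) == 0) {
    return(tibble::tibble(gene_id = character(), mag_id = character(),
                          sample_id = character(), cluster_id = character()))
  }
  p <- dplyr::left_join(planted, retained_at,
                        by = c("recipient_id", "cluster_id"))
  long <- dplyr::bind_rows(
    tibble::tibble(p[c("recipient_id", "cluster_id", "recipient_species")],
                   timepoint = "week6"),
    tibble::tibble(p[p$week12, c("recipient_id", "cluster_id", "recipient_species")],
                   timepoint = "week12"),
    tibble::tibble(p[p$week26, c("recipient_id", "cluster_id", "recipient_species")],
                   timepoint = "week26"))
  sid <- paste0(long$recipient_id, "|", long$timepoint)
  stopifnot(all(sid %in% samples$sample_id))
  tibble::tibble(
    gene_id = paste0("g|", sid, "|", long$recipient_species, "|",
                     long$cluster_id, "|hgt"),
    mag_id = paste0("m|", sid, "|", long$recipient_species),
    sample_id = sid,
    cluster_id = long$cluster_id)
}

build_decoys <- function(samples, species, catalog, config) {
  n_lq <- config$decoy_lowq_mags_per_sample
  n_uc <- config$decoy_unclassified_mags_per_sample
  gpm <- config$decoy_genes_per_mag
  if (n_lq + n_uc == 0 || gpm == 0) {
    empty_m <- tibble::tibble(mag_id = character(), sample_id = character(),
                              completeness = numeric(), contamination = numeric(),
                              phylum = character(), species = character(),
                              species_classified = logical())
    empty_g <- tibble::tibble(gene_id = character(), mag_id = character(),
                              sample_id = character(), cluster_id = character())
    return(list(mags = empty_m, genes = empty_g))
  }
  per_sample <- n_lq + n_uc
  sid <- rep(samples$sample_id, each = per_sample)
  idx <- rep(seq_len(per_sample), times = nrow(samples))
  is_lq <- idx <= n_lq
  n <- length(sid)
  sp <- sample(species$species_id, n, replace = TRUE)
  phylum_of <- setNames(species$phylum, species$species_id)
  mags <- tibble::tibble(
    mag_id = paste0("m|", sid, "|decoy", idx),
    sample_id = sid,
    completeness = ifelse(is_lq, runif(n, 50, 89.9), runif(n, 90.5, 100)),
    contamination = ifelse(is_lq, runif(n, 0, 15), runif(n, 0, 4.5)),
    phylum = ifelse(is_lq, unname(phylum_of[sp]), NA_character_),
    species = ifelse(is_lq, sp, NA_character_),
    species_classified = is_lq)
  gene_mag <- rep(mags$mag_id, each = gpm)
  gene_sample <- rep(mags$sample_id, each = gpm)
  clusters <- sample(catalog$cluster_id, length(gene_mag), replace = TRUE)
  genes <- tibble::tibble(
    gene_id = paste0("g|", gene_mag, "|", seq_along(gene_mag)),
    mag_id = gene_mag, sample_id = gene_sample, cluster_id = clusters)
  list(mags = mags, genes = genes)
}

simulate_cog <- function(cluster_ids, config) {
  n <- length(cluster_ids)
  class_map <- cog_class_map()
  functional <- names(class_map)[!class_map %in%
                                   c("poorly characterised")]
  poor <- names(class_map)[class_map == "poorly characterised"]
  annotated <- runif(n) >= config$cog_unannotated_prob
  n_letters <- 1L + (runif(n) < 0.2)
  cats <- character(n)
  for (i in which(annotated)) {
    from_poor <- runif(1) < config$cog_poor_prob
    pool <- if (from_poor) poor else functional
    cats[i] <- paste(sort(sample(pool, min(n_letters[i], length(pool)))),
                     collapse = "")
  }
  tibble::tibble(cluster_id = cluster_ids, categories = cats)
}

build_abundance <- function(planted, retained_at, cog, config) {
  if (nrow(planted) == 0) {
    return(tibble::tibble(cluster_id = character(), sample_id = character(),
                          cpm = numeric()))
  }
  p <- dplyr::left_join(planted, retained_at,
                        by = c("recipient_id", "cluster_id"))
  rows <- lapply(c("week6", "week12", "week26"), function(tp) {
    present <- switch(tp, week6 = rep(TRUE, nrow(p)), week12 = p$week12,
                      week26 = p$week26)
    cpm <- ifelse(present,
                  rlnorm(nrow(p), config$cpm_lognormal_mu,
                         config$cpm_lognormal_sigma), 0)
    tibble::tibble(cluster_id = p$cluster_id,
                   sample_id = paste0(p$recipient_id, "|", tp),
                   cpm = cpm)
  })
  dplyr::bind_rows(rows)
}

metabolism_clusters <- function(cog) {
  class_map <- cog_class_map()
  met_letters <- names(class_map)[class_map == "metabolism"]
  has_met <- vapply(strsplit(cog$categories, ""), function(ls) {
    any(ls %in% met_letters)
  }, logical(1))
  cog$cluster_id[has_met]
}

#' Simulate per-sample contig-level HGT call counts
#'
#' Emulates the per-sample summary of a contig-level HGT caller: each
#' sample gets a number of assembled contigs, a count of contigs flagged
#' as HGT, and its species richness (taken from the bundle's classified
#' MAGs). Counts are Poisson with mean `richness * rate`, where the rate
#' is `waafle_base_rate` plus a subject-level random intercept and, at
#' week 26, `drift_effect_week26` — so HGT counts correlate with
#' richness, carry no arm or sex effect, and drift upward at week 26.
#'
#' @param config A [sim_config()].
#' @param bundle An [hgt_bundle()] with `samples` and `mags`.
#' @return A `waafle` bundle table.
#' @export
simulate_waafle_counts <- function(config, bundle) {
  stopifnot(inherits(config, "sim_config"))
  richness <- dplyr::summarise(
    dplyr::group_by(bundle$mags[bundle$mags$species_classified, ], .data$sample_id),
    species_richness = dplyr::n_distinct(.data$species), .groups = "drop")
  s <- dplyr::left_join(bundle$samples, richness, by = "sample_id")
  s$species_richness[is.na(s$species_richness)] <- 1
  with_stream(config$seed, "waafle", {
    subjects <- unique(s$subject_id)
    u <- setNames(rnorm(length(subjects), 0, config$waafle_subject_sd), subjects)
    rate <- config$waafle_base_rate + u[s$subject_id] +
      ifelse(s$timepoint == "week26", config$drift_effect_week26, 0)
    rate <- pmax(rate, 1e-6)
    n_contigs <- pmax(round(rnorm(nrow(s), config$waafle_mean_contigs,
                                  0.1 * config$waafle_mean_contigs)), 100)
    n_hgt <- pmin(rpois(nrow(s), s$species_richness * rate), n_contigs)
    tibble::tibble(sample_id = s$sample_id,
                   n_hgt_contigs = as.numeric(n_hgt),
                   n_contigs = as.numeric(n_contigs),
                   species_richness = as.numeric(s$species_richness))
  })
}
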