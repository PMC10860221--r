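w6 <- function(...) tibble::tibble(recipient = "R1", suffix = "", ...)

test_that("the four detection criteria behave on hand-built fixtures", {
  # qualifying event: cluster at week6 on species A, absent at baseline,
  # donor carries it on species B
  b <- detect_fixture(week6_genes = w6(species = "spA", cluster = "c1"),
                      donor_genes = tibble::tibble(species = "spB", cluster = "c1"))
  ev <- detect_htgcs(b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$cluster_id, "c1")
  expect_equal(ev$recipient_species, "spA")
  expect_equal(ev$donor_side[[1]]$donor_species, "spB")

  # baseline presence vetoes the call
  b2 <- detect_fixture(week6_genes = w6(species = "spA", cluster = "c1"),
                       baseline_clusters = "c1",
                       donor_genes = tibble::tibble(species = "spB", cluster = "c1"))
  expect_equal(nrow(detect_htgcs(b2)), 0)

  # concordant donor species only: vertical persistence, not transfer
  b3 <- detect_fixture(week6_genes = w6(species = "spA", cluster = "c1"),
                       donor_genes = tibble::tibble(species = "spA", cluster = "c1"))
  expect_equal(nrow(detect_htgcs(b3)), 0)

  # no donor occurrence at all
  b4 <- detect_fixture(week6_genes = w6(species = "spA", cluster = "c1"),
                       donor_genes = tibble::tibble(species = "spB", cluster = "c9"))
  expect_equal(nrow(detect_htgcs(b4)), 0)
})

test_that("two distinct week-6 genes in one cluster are two events, one cluster", {
  b <- detect_fixture(
    week6_genes = tibble::tibble(recipient = "R1",
                                 species = c("spA", "spA"),
                                 cluster = "c1", suffix = c("_1", "_2")),
    donor_genes = tibble::tibble(species = "spB", cluster = "c1"))
  ev <- detect_htgcs(b)
  expect_equal(nrow(ev), 2)
  expect_equal(dplyr::n_distinct(ev$cluster_id), 1)
})

test_that("discordance mode 'all' requires every donor occurrence to differ", {
  b <- detect_fixture(week6_genes = w6(species = "spA", cluster = "c1"),
                      donor_genes = tibble::tibble(species = c("spA", "spB"),
                                                   cluster = "c1"))
  expect_equal(nrow(detect_htgcs(b, discordance = "any")), 1)
  expect_equal(nrow(detect_htgcs(b, discordance = "all")), 0)
})

test_that("precondition failures raise errors", {
  b <- toy_bundle()
  expect_error(detect_htgcs(b, participants = "ghost"), "unknown participant")
  b2 <- toy_bundle(validate = FALSE)
  b2$samples <- b2$samples[b2$samples$timepoint != "baseline", ]
  b2$genes <- b2$genes[b2$genes$sample_id %in% b2$samples$sample_id, ]
  b2$mags <- b2$mags[b2$mags$sample_id %in% b2$samples$sample_id, ]
  expect_error(detect_htgcs(b2), "missing baseline or week6")
})

test_that("detection equals the brute-force oracle on small simulated trials", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_trial(tiny_config(seed = seed))
    expect_lte(nrow(sim$bundle$genes), 200)
    got <- detect_htgcs(sim$bundle)
    oracle <- brute_force_detect(sim$bundle)
    expect_identical(
      data.frame(participant_id = got$participant_id,
                 cluster_id = got$cluster_id,
                 recipient_gene_id = got$recipient_gene_id),
      data.frame(participant_id = oracle$participant_id,
                 cluster_id = oracle$cluster_id,
                 recipient_gene_id = oracle$recipient_gene_id,
                 row.names = NULL),
      label = paste("seed", seed))
  }
})

test_that("assigned donor scope matches the oracle and is a subset of the cohort scope", {
  sim <- simulate_trial(tiny_config(seed = 8))
  got <- detect_htgcs(sim$bundle, donor_scope = "assigned")
  oracle <- brute_force_detect(sim$bundle, donor_scope = "assigned")
  expect_equal(sort(got$recipient_gene_id), sort(oracle$recipient_gene_id))
  cohort <- detect_htgcs(sim$bundle, donor_scope = "sex_cohort")
  expect_true(all(got$recipient_gene_id %in% cohort$recipient_gene_id))
})

test_that("adding a donor sample never shrinks the detected set", {
  sim <- simulate_trial(sim_config(seed = 31, n_donor_samples = 2L))
  b_full <- sim$bundle
  # drop one donor sample
  drop_sid <- grep("donation2", b_full$samples$sample_id, value = TRUE)[1]
  b_less <- b_full
  b_less$samples <- b_less$samples[b_less$samples$sample_id != drop_sid, ]
  b_less$mags <- b_less$mags[b_less$mags$sample_id != drop_sid, ]
  b_less$genes <- b_less$genes[b_less$genes$sample_id != drop_sid, ]
  b_less$waafle <- b_less$waafle[b_less$waafle$sample_id != drop_sid, ]
  ev_less <- detect_htgcs(b_less)
  ev_full <- detect_htgcs(b_full)
  k_less <- paste(ev_less$participant_id, ev_less$recipient_gene_id)
  k_full <- paste(ev_full$participant_id, ev_full$recipient_gene_id)
  expect_true(all(k_less %in% k_full))
})

test_that("HTGC frequency is the percentage of detected clusters", {
  sim <- simulate_trial(tiny_config(seed = 2))
  ev <- detect_htgcs(sim$bundle)
  freq <- htgc_frequency(ev, sim$bundle)
  # recompute by hand for each participant
  hq <- filter_high_quality(sim$bundle$mags)
  ag <- analysable_genes(sim$bundle$genes, hq)$genes
  ag <- dplyr::inner_join(ag, sim$bundle$samples, by = "sample_id")
  for (i in seq_len(nrow(freq))) {
    p <- freq$participant_id[i]
    denom <- dplyr::n_distinct(ag$cluster_id[ag$subject_id == p &
                                               ag$timepoint == "week6"])
    num <- dplyr::n_distinct(ev$cluster_id[ev$participant_id == p])
    expect_equal(freq$freq_pct[i], 100 * num / denom)
  }
  expect_true(all(freq$freq_pct >= 0 & freq$freq_pct <= 100))
})

test_that("frequency edge cases: zero, interior, and full", {
  f <- function(n_htgc, n_clusters) 100 * n_htgc / n_clusters
  expect_equal(f(0, 50), 0)
  expect_equal(f(2, 50), 4)
  expect_equal(f(50, 50), 100)
})

test_that("arm comparison uses the exact Wilcoxon null for small untied groups", {
  freq <- tibble::tibble(
    participant_id = sprintf("p%d", 1:6),
    arm = rep(c("FMT", "placebo"), each = 3),
    sex = "female",
    freq_pct = c(1, 2, 3, 4, 5, 6))
  res <- compare_arms(freq)
  expect_equal(res$p_value[res$comparison == "overall"], 0.1)
  # identical groups: p = 1 under midranks
  freq$freq_pct <- rep(c(1, 2, 3), 2)
  res2 <- compare_arms(freq)
  expect_equal(res2$p_value[res2$comparison == "overall"], 1)
  # an empty arm errors
  expect_error(compare_arms(freq[freq$arm == "FMT", ]), "empty")
})

test_that("specificity partition covers the detected clusters exactly once per sex", {
  sim <- simulate_trial(sim_config(seed = 13))
  ev <- detect_htgcs(sim$bundle)
  part <- classify_specificity(sim_events <- ev)
  by_sex <- split(ev, ev$sex)
  for (sx in names(by_sex)) {
    detected <- unique(by_sex[[sx]]$cluster_id)
    in_part <- part$partition$cluster_id[part$partition$sex == sx]
    expect_setequal(in_part, detected)
    expect_false(anyDuplicated(in_part) > 0)
  }
  # recovered partition equals the partition computed from planted truth
  truth <- sim$truth$planted_htgcs
  design <- sim$bundle$design
  arm_of <- setNames(design$arm, design$subject_id)
  sex_of <- setNames(design$sex, design$subject_id)
  truth$arm <- arm_of[truth$recipient_id]
  truth$sex <- sex_of[truth$recipient_id]
  want <- dplyr::summarise(
    dplyr::group_by(truth, sex, cluster_id),
    specificity = if (all(arm == "FMT")) "fmt_specific"
    else if (all(arm == "placebo")) "placebo_specific" else "shared",
    .groups = "drop")
  got <- part$partition
  merged <- dplyr::inner_join(want, got, by = c("sex", "cluster_id"),
                              suffix = c("_want", "_got"))
  expect_equal(nrow(merged), nrow(want))
  expect_equal(merged$specificity_got, merged$specificity_want)
})

test_that("event histogram bins at width 1 with a terminal 20+ bin", {
  ev1 <- tibble::tibble(cluster_id = "c1")
  h1 <- event_histogram(ev1)
  expect_equal(h1$n_clusters[h1$bin == "1"], 1)
  expect_equal(sum(h1$n_clusters), 1)

  ev2 <- tibble::tibble(cluster_id = rep("c1", 25))
  h2 <- event_histogram(ev2)
  expect_equal(h2$n_clusters[h2$bin == "20+"], 1)
  expect_equal(sum(h2$n_clusters), 1)

  sim <- simulate_trial(tiny_config(seed = 3))
  ev <- detect_htgcs(sim$bundle)
  h <- event_histogram(ev)
  expect_equal(sum(h$n_clusters), dplyr::n_distinct(ev$cluster_id))
})
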