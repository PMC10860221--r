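test_that("richness normalisation is the plain ratio", {
  w <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                      n_hgt_contigs = c(0, 30, 30),
                      n_contigs = c(100, 100, 100),
                      species_richness = c(40, 60, 120))
  n <- normalize_hgt_rate(w)
  expect_equal(n$normalized, c(0, 0.5, 0.25))
  w$species_richness[1] <- 0
  expect_error(normalize_hgt_rate(w), "positive")
})

test_that("the mixed model reduces to OLS with no random-effect variance", {
  set.seed(42)
  df <- tidyr::crossing(subject = sprintf("s%02d", 1:20),
                        timepoint = c("t1", "t2"))
  df$arm <- ifelse(as.integer(sub("s", "", df$subject)) <= 10, "FMT",
                   "placebo")
  # purely fixed-effect data: no subject-level variation
  df$y <- 1 + 0.5 * (df$arm == "FMT") + 0.3 * (df$timepoint == "t2") +
    rnorm(nrow(df), 0, 0.1)
  fit <- suppressWarnings(suppressMessages(
    fit_lmm(df, "y", c("arm", "timepoint"), "subject",
            refs = list(arm = "placebo", timepoint = "t1"))))
  ols <- stats::lm(y ~ arm + timepoint,
                   data = transform(df, arm = factor(arm, c("placebo", "FMT")),
                                    timepoint = factor(timepoint)))
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)), tolerance = 1e-6)
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$estimate))
  expect_true(all(fit$coefficients$ci_high >= fit$coefficients$estimate))
})

test_that("a constant response yields zero effect estimates", {
  df <- tidyr::crossing(subject = sprintf("s%02d", 1:10),
                        timepoint = c("t1", "t2"))
  df$y <- 5
  fit <- suppressWarnings(suppressMessages(
    fit_lmm(df, "y", "timepoint", "subject")))
  non_int <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_true(all(abs(non_int$estimate) < 1e-10))
})

test_that("a single simulated trial recovers the planted week-26 drift", {
  sim <- simulate_trial(sim_config(seed = 77))
  fit <- hgt_rate_lmm(sim$bundle)
  w26 <- fit$coefficients[fit$coefficients$term == "timepointweek26", ]
  expect_equal(w26$estimate, 0.37, tolerance = 0.25)
  expect_lt(w26$ci_low, 0.37)
  expect_gt(w26$ci_high, 0.37)
  arm <- fit$coefficients[fit$coefficients$term == "armFMT", ]
  expect_lt(arm$ci_low, 0)
  expect_gt(arm$ci_high, 0)
})

mk_retention_fixture <- function(n_units = 4, cpm12 = NULL, cpm26 = NULL) {
  units <- tibble::tibble(
    participant_id = "R1", arm = "FMT", sex = "female", timepoint = "week6",
    cluster_id = sprintf("c%02d", seq_len(n_units)),
    recipient_gene_id = sprintf("g%02d", seq_len(n_units)),
    recipient_species = "spA", recipient_phylum = "Firmicutes",
    engrafted_species = "spB", engrafted_phylum = "Bacteroidetes",
    engrafted_donor_id = "D1")
  samples <- tibble::tibble(
    sample_id = paste0("R1|", c("baseline", "week6", "week12", "week26")),
    subject_id = "R1",
    timepoint = c("baseline", "week6", "week12", "week26"))
  ab <- dplyr::bind_rows(
    tibble::tibble(cluster_id = units$cluster_id, sample_id = "R1|week6",
                   cpm = 10),
    tibble::tibble(cluster_id = units$cluster_id, sample_id = "R1|week12",
                   cpm = cpm12 %||% rep(10, n_units)),
    tibble::tibble(cluster_id = units$cluster_id, sample_id = "R1|week26",
                   cpm = cpm26 %||% rep(10, n_units)))
  bundle <- list(samples = samples, abundance = ab)
  list(units = units, bundle = bundle)
}

test_that("retention is the fraction of week-6 units with positive later abundance", {
  fx <- mk_retention_fixture(4, cpm12 = c(10, 10, 0, 10),
                             cpm26 = c(0, 0, 10, 10))
  res <- retention(fx$units, fx$bundle)
  s <- res$summary
  expect_equal(s$retained_pct[s$timepoint == "week12"], 75)
  expect_equal(s$retained_pct[s$timepoint == "week26"], 50)
  # full retention
  fx2 <- mk_retention_fixture(3)
  expect_equal(retention(fx2$units, fx2$bundle)$summary$retained_pct,
               c(100, 100))
})

test_that("duplicate events of one cluster collapse to one retention unit", {
  fx <- mk_retention_fixture(1)
  two_events <- dplyr::bind_rows(fx$units,
                                 dplyr::mutate(fx$units,
                                               recipient_gene_id = "g99"))
  res <- retention(two_events, fx$bundle)
  expect_equal(res$summary$n_detected, c(1, 1))
})

test_that("units with no week-6 abundance go to QC and leave the denominator", {
  fx <- mk_retention_fixture(3)
  fx$bundle$abundance <- fx$bundle$abundance[
    !(fx$bundle$abundance$cluster_id == "c01" &
        fx$bundle$abundance$sample_id == "R1|week6"), ]
  res <- retention(fx$units, fx$bundle)
  expect_equal(res$qc_missing_week6$cluster_id, "c01")
  expect_equal(res$summary$n_detected, c(2, 2))
})

test_that("retention recovers the planted rate on a simulated trial", {
  sim <- simulate_trial(boosted_config(seed = 23))
  ev <- detect_htgcs(sim$bundle)
  ed <- filter_engraftment_dependent(ev, sim$bundle$engraftment)
  res <- retention(ed, sim$bundle)
  s <- res$summary
  pooled12 <- sum(s$n_retained[s$timepoint == "week12"]) /
    sum(s$n_detected[s$timepoint == "week12"])
  n <- sum(s$n_detected[s$timepoint == "week12"])
  se <- sqrt(0.858 * (1 - 0.858) / n)
  expect_lt(abs(pooled12 - 0.858), 4 * se)
})

test_that("the abundance mixed model finds planted declines and is deterministic", {
  set.seed(9)
  units <- tidyr::crossing(recipient_id = sprintf("R%02d", 1:12),
                           cluster_id = sprintf("c%02d", 1:6))
  series <- tidyr::crossing(units, timepoint = c("week6", "week12", "week26"))
  series$sex <- ifelse(as.integer(sub("R", "", series$recipient_id)) <= 6,
                       "female", "male")
  subj_eff <- rnorm(12, 0, 0.5)
  names(subj_eff) <- sprintf("R%02d", 1:12)
  series$cpm <- 10 + subj_eff[series$recipient_id] +
    ifelse(series$timepoint == "week26", -3, 0) + rnorm(nrow(series), 0, 1)
  fit1 <- retention_lmm(series)
  fit2 <- retention_lmm(series)
  w26 <- fit1$coefficients[fit1$coefficients$term == "timepointweek26", ]
  expect_lt(w26$estimate, 0)
  expect_lt(w26$ci_high, 0)
  expect_identical(fit1$coefficients, fit2$coefficients)

  # constant abundance: timepoint estimates cover zero
  series$cpm <- 10 + subj_eff[series$recipient_id]
  fit0 <- suppressWarnings(retention_lmm(series))
  tp <- fit0$coefficients[grepl("timepoint", fit0$coefficients$term), ]
  expect_true(all(abs(tp$estimate) < 1e-8))
})
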