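#' Richness-normalised contig-level HGT rate
#'
#' Divides each sample's contig-level HGT call count by its species
#' richness, the per-sample normalisation that removes the tendency of
#' richer communities to show more transfer signatures.
#'
#' @param waafle A `waafle` bundle table.
#' @return The table with a `normalized` column
#'   (`n_hgt_contigs / species_richness`).
#' @export
normalize_hgt_rate <- function(waafle) {
  if (any(waafle$species_richness <= 0)) {
    stop("normalize_hgt_rate(): species_richness must be positive for ",
         id_list(waafle$sample_id[waafle$species_richness <= 0]),
         call. = FALSE)
  }
  waafle$normalized <- waafle$n_hgt_contigs / waafle$species_richness
  waafle
}

#' Fit a linear mixed model with a participant random intercept
#'
#' REML fit of `response ~ fixed effects + (1 | subject)` via
#' \pkg{lme4}, with treatment-coded factors at stated reference levels.
#' A likelihood-ratio test compares the full model (all pairwise and
#' higher interactions between the fixed effects) against the reduced
#' additive model, using maximum-likelihood refits; the reduced model is
#' what is reported. Confidence intervals are Wald 95\% intervals and
#' p-values use the normal approximation to the Wald statistic (at trial
#' sample sizes the difference from a t-approximation is immaterial).
#' Singular fits are recorded as a warning flag in the result, with
#' estimates still returned.
#'
#' @param data A data frame.
#' @param response Response column name.
#' @param fixed_effects Character vector of fixed-effect column names.
#' @param subject Grouping column for the random intercept.
#' @param refs Named list column -> reference level for factor coding.
#' @return List of class `hgt_lmm`: `coefficients` (tibble `term`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`), `lrt_p_interactions`,
#'   `singular`, `n_obs`, `n_subjects`, `model` (the lme4 fit).
#' @export
fit_lmm <- function(data, response, fixed_effects, subject,
                    refs = list()) {
  df <- as.data.frame(data)
  for (col in fixed_effects) {
    if (!col %in% names(df)) stop("fit_lmm(): missing column ", col, call. = FALSE)
    if (!is.numeric(df[[col]])) {
      lev <- unique(as.character(df[[col]]))
      ref <- refs[[col]]
      if (!is.null(ref)) {
        if (!ref %in% lev) {
          stop("fit_lmm(): reference level '", ref, "' absent from ", col,
               call. = FALSE)
        }
        lev <- c(ref, setdiff(sort(lev), ref))
      } else lev <- sort(lev)
      df[[col]] <- factor(df[[col]], levels = lev)
    }
  }
  if (min(table(df[[subject]])) < 2) {
    warning("fit_lmm(): some subjects have a single observation; the random intercept may be weakly identified")
  }
  constant <- vapply(fixed_effects, function(col) {
    length(unique(df[[col]])) < 2
  }, logical(1))
  if (any(constant)) {
    message("fit_lmm(): dropping constant fixed effect(s): ",
            paste(fixed_effects[constant], collapse = ", "))
    fixed_effects <- fixed_effects[!constant]
    if (length(fixed_effects) == 0) {
      stop("fit_lmm(): no non-constant fixed effects", call. = FALSE)
    }
  }
  additive <- paste(fixed_effects, collapse = " + ")
  full_fx <- paste(fixed_effects, collapse = " * ")
  f_red <- as.formula(paste0(response, " ~ ", additive, " + (1|", subject, ")"))
  f_full <- as.formula(paste0(response, " ~ ", full_fx, " + (1|", subject, ")"))

  fit <- lme4::lmer(f_red, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)

  lrt_p <- tryCatch({
    m_red <- lme4::lmer(f_red, data = df, REML = FALSE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
    m_full <- lme4::lmer(f_full, data = df, REML = FALSE,
                         control = lme4::lmerControl(check.conv.singular = "ignore"))
    stats::anova(m_red, m_full)[["Pr(>Chisq)"]][2]
  }, error = function(e) NA_real_)

  est <- lme4::fixef(fit)
  # vcov can fail on degenerate (zero-variance) fits; report zero SEs then
  se <- tryCatch(sqrt(diag(as.matrix(vcov(fit)))),
                 error = function(e) rep(0, length(est)))
  p <- ifelse(se > 0, 2 * pnorm(-abs(est / se)), NA_real_)
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est),
    ci_low = unname(est - 1.96 * se), ci_high = unname(est + 1.96 * se),
    p_value = unname(p))

  structure(list(coefficients = coefs, lrt_p_interactions = lrt_p,
                 singular = singular, n_obs = nrow(df),
                 n_subjects = length(unique(df[[subject]])), model = fit),
            class = "hgt_lmm")
}

#' @exportS3Method base::print
print.hgt_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model (%d obs, %d subjects%s)\n", x$n_obs,
              x$n_subjects, if (x$singular) "; singular fit" else ""))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  cat(sprintf("LRT full (interactions) vs reduced: p = %s\n",
              format(x$lrt_p_interactions, digits = 3)))
  invisible(x)
}

#' Mixed model of richness-normalised HGT rates over the trial
#'
#' Convenience wrapper: joins the normalised contig-level HGT rates of
#' recipient samples to the trial design and fits
#' `normalized ~ arm + sex + timepoint + (1 | subject)` with references
#' placebo / female / baseline.
#'
#' @param bundle An [hgt_bundle()] with a `waafle` table.
#' @return An `hgt_lmm` (see [fit_lmm()]).
#' @export
hgt_rate_lmm <- function(bundle) {
  w <- normalize_hgt_rate(bundle$waafle)
  w <- dplyr::inner_join(w, bundle$samples, by = "sample_id")
  w <- dplyr::inner_join(w, bundle$design, by = "subject_id")
  w <- w[w$role == "recipient", ]
  w$timepoint <- factor(w$timepoint, levels = RECIPIENT_TIMEPOINTS)
  fit_lmm(w, "normalized", c("arm", "sex", "timepoint"), "subject_id",
          refs = list(arm = "placebo", sex = "female",
                      timepoint = "baseline"))
}

#' Retention of engraftment-dependent HTGCs
#'
#' Deduplicates engraftment-dependent events to distinct
#' (recipient, cluster) units — several events of one cluster involving
#' different genes are one retention unit, because abundance is measured
#' for the whole cluster — then scores a unit as retained at a later
#' timepoint when its cluster abundance there is strictly positive
#' (`cpm > retention_threshold`, default 0). Units with no week-6
#' abundance record are listed in a QC table and excluded from
#' denominators. Re-detection is allowed: the week-26 retained set need
#' not be a subset of the week-12 one.
#'
#' @param ed_events Output of [filter_engraftment_dependent()].
#' @param bundle The bundle (needs `abundance` and `samples`).
#' @param retention_threshold CPM strictly above this counts as present.
#' @return List: `summary` (tibble `sex`, `timepoint`, `n_detected`,
#'   `n_retained`, `retained_pct`), `series` (tibble `recipient_id`,
#'   `sex`, `cluster_id`, `timepoint`, `cpm`), `qc_missing_week6`
#'   (tibble of excluded units).
#' @export
retention <- function(ed_events, bundle, retention_threshold = 0) {
  if (is.null(bundle$abundance)) {
    stop("retention(): bundle has no abundance table", call. = FALSE)
  }
  units <- dplyr::distinct(ed_events, recipient_id = .data$participant_id,
                           .data$sex, .data$cluster_id)
  ab <- dplyr::inner_join(bundle$abundance,
                          bundle$samples[, c("sample_id", "subject_id", "timepoint")],
                          by = "sample_id")
  series <- dplyr::inner_join(
    units, ab, by = c(recipient_id = "subject_id", cluster_id = "cluster_id"))
  series <- series[series$timepoint %in% c("week6", "week12", "week26"),
                   c("recipient_id", "sex", "cluster_id", "timepoint", "cpm")]

  has_w6 <- unique(paste(series$recipient_id, series$cluster_id)[
    series$timepoint == "week6"])
  qc <- units[!paste(units$recipient_id, units$cluster_id) %in% has_w6, ]
  units_ok <- units[paste(units$recipient_id, units$cluster_id) %in% has_w6, ]
  series <- series[paste(series$recipient_id, series$cluster_id) %in% has_w6, ]

  summarise_tp <- function(tp) {
    pres <- series[series$timepoint == tp & series$cpm > retention_threshold, ]
    pres_keys <- unique(paste(pres$recipient_id, pres$cluster_id))
    by_sex <- dplyr::group_by(units_ok, .data$sex)
    dplyr::summarise(
      by_sex, timepoint = tp, n_detected = dplyr::n(),
      n_retained = sum(paste(.data$recipient_id, .data$cluster_id) %in% pres_keys),
      retained_pct = pct_of(.data$n_retained, .data$n_detected),
      .groups = "drop")
  }
  summary <- dplyr::bind_rows(summarise_tp("week12"), summarise_tp("week26"))
  list(summary = summary[order(summary$sex, summary$timepoint), ],
       series = series[order(series$recipient_id, series$cluster_id,
                             match(series$timepoint, RECIPIENT_TIMEPOINTS)), ],
       qc_missing_week6 = qc)
}

#' Mixed model of retained-cluster abundance over time
#'
#' Fits `cpm ~ sex + timepoint + (1 | recipient)` on the deduplicated
#' abundance series from [retention()], with references female / week6;
#' interactions are assessed by likelihood-ratio test and excluded from
#' the reported (reduced) model, per [fit_lmm()].
#'
#' @param series The `series` tibble from [retention()].
#' @return An `hgt_lmm`.
#' @export
retention_lmm <- function(series) {
  df <- as.data.frame(series)
  df$timepoint <- factor(df$timepoint,
                         levels = c("week6", "week12", "week26"))
  fit_lmm(df, "cpm", c("sex", "timepoint"), "recipient_id",
          refs = list(sex = "female", timepoint = "week6"))
}
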