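#' Trial data bundle
#'
#' The pipeline consumes a *bundle*: a named list of tibbles summarising a
#' donor/recipient FMT trial as produced by the usual upstream tools
#' (assembly, binning, quality scoring, taxonomy, gene clustering, strain
#' profiling, abundance mapping, functional annotation). Sequence-level
#' data never enter the package; every table is plain TSV.
#'
#' Component tables (snake_case headers, tab-separated):
#' \describe{
#'   \item{design}{`subject_id`, `role` (donor/recipient), `arm`
#'     (FMT/placebo; `NA` for donors), `sex` (female/male).}
#'   \item{samples}{`sample_id`, `subject_id`, `timepoint` (baseline,
#'     week6, week12, week26 for recipients; donation1, donation2, ... for
#'     donors).}
#'   \item{mags}{`mag_id`, `sample_id`, `completeness` (percent),
#'     `contamination` (percent), `phylum`, `species`,
#'     `species_classified` (logical).}
#'   \item{genes}{`gene_id`, `mag_id`, `sample_id`, `cluster_id` — one row
#'     per predicted gene, `cluster_id` naming its >95\%-identity
#'     non-redundant catalog cluster.}
#'   \item{donor_assignment}{optional; `recipient_id`, `donor_id`.}
#'   \item{engraftment}{optional; `recipient_id`, `donor_id`, `species`,
#'     `timepoint` (week6) — strain-level donor engraftment calls.}
#'   \item{abundance}{optional; `cluster_id`, `sample_id`, `cpm` (copies
#'     per million reads).}
#'   \item{waafle}{optional; `sample_id`, `n_hgt_contigs`, `n_contigs`,
#'     `species_richness` — per-sample contig-level HGT call counts.}
#'   \item{cog}{optional; `cluster_id`, `categories` (string of COG
#'     single-letter categories, empty when unannotated).}
#' }
#'
#' @param design,samples,mags,genes Required tables (see above).
#' @param donor_assignment,engraftment,abundance,waafle,cog Optional
#'   tables; `NULL` when absent.
#' @param validate Validate cross-references immediately (default TRUE).
#' @return An object of class `hgt_bundle` (a named list of tibbles).
#' @seealso [read_bundle()], [write_bundle()], [validate_bundle()]
#' @export
hgt_bundle <- function(design, samples, mags, genes,
                       donor_assignment = NULL, engraftment = NULL,
                       abundance = NULL, waafle = NULL, cog = NULL,
                       validate = TRUE) {
  bundle <- structure(
    list(design = tibble::as_tibble(design),
         samples = tibble::as_tibble(samples),
         mags = tibble::as_tibble(mags),
         genes = tibble::as_tibble(genes),
         donor_assignment = if (!is.null(donor_assignment)) tibble::as_tibble(donor_assignment),
         engraftment = if (!is.null(engraftment)) tibble::as_tibble(engraftment),
         abundance = if (!is.null(abundance)) tibble::as_tibble(abundance),
         waafle = if (!is.null(waafle)) tibble::as_tibble(waafle),
         cog = if (!is.null(cog)) tibble::as_tibble(cog)),
    class = "hgt_bundle")
  if (validate) validate_bundle(bundle)
  bundle
}

#' @exportS3Method base::print
print.hgt_bundle <- function(x, ...) {
  cat("<hgt_bundle>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  %-17s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

RECIPIENT_TIMEPOINTS <- c("baseline", "week6", "week12", "week26")
COG_ALPHABET <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                  "L", "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V",
                  "W", "Y", "Z")

bundle_schemas <- function() {
  list(
    design = c(subject_id = "character", role = "character",
               arm = "character", sex = "character"),
    samples = c(sample_id = "character", subject_id = "character",
                timepoint = "character"),
    mags = c(mag_id = "character", sample_id = "character",
             completeness = "numeric", contamination = "numeric",
             phylum = "character", species = "character",
             species_classified = "logical"),
    genes = c(gene_id = "character", mag_id = "character",
              sample_id = "character", cluster_id = "character"),
    donor_assignment = c(recipient_id = "character", donor_id = "character"),
    engraftment = c(recipient_id = "character", donor_id = "character",
                    species = "character", timepoint = "character"),
    abundance = c(cluster_id = "character", sample_id = "character",
                  cpm = "numeric"),
    waafle = c(sample_id = "character", n_hgt_contigs = "numeric",
               n_contigs = "numeric", species_richness = "numeric"),
    cog = c(cluster_id = "character", categories = "character")
  )
}

check_schema <- function(tbl, name, errors) {
  schema <- bundle_schemas()[[name]]
  missing <- setdiff(names(schema), names(tbl))
  if (length(missing) > 0) {
    errors <- c(errors, sprintf("table '%s': missing column(s) %s", name,
                                paste(missing, collapse = ", ")))
  }
  errors
}

# list ids (first few) for readable integrity errors
id_list <- function(ids, max = 8) {
  ids <- unique(ids)
  shown <- paste(utils::head(ids, max), collapse = ", ")
  if (length(ids) > max) shown <- paste0(shown, ", ... (", length(ids), " total)")
  shown
}

#' Validate a trial bundle
#'
#' Checks column schemas, field domains and every cross-table reference.
#' All failures are collected and reported together (not just the first),
#' so a malformed input can be fixed in one pass.
#'
#' @param bundle An [hgt_bundle()].
#' @return The bundle, invisibly; errors otherwise.
#' @export
validate_bundle <- function(bundle) {
  errors <- character()
  for (nm in names(bundle)) {
    if (is.null(bundle[[nm]])) next
    errors <- check_schema(bundle[[nm]], nm, errors)
  }
  abort_many(errors, "bundle schema")

  d <- bundle$design
  s <- bundle$samples

  if (anyDuplicated(d$subject_id)) {
    errors <- c(errors, sprintf("design: duplicate subject_id(s): %s",
                                id_list(d$subject_id[duplicated(d$subject_id)])))
  }
  bad_role <- !d$role %in% c("donor", "recipient")
  if (any(bad_role)) {
    errors <- c(errors, sprintf("design: invalid role for %s",
                                id_list(d$subject_id[bad_role])))
  }
  bad_sex <- !d$sex %in% c("female", "male")
  if (any(bad_sex)) {
    errors <- c(errors, sprintf("design: invalid sex for %s",
                                id_list(d$subject_id[bad_sex])))
  }
  # arm defined iff recipient
  arm_bad <- (d$role == "recipient" & (is.na(d$arm) | !d$arm %in% c("FMT", "placebo"))) |
    (d$role == "donor" & !is.na(d$arm))
  if (any(arm_bad, na.rm = TRUE)) {
    errors <- c(errors, sprintf("design: arm must be FMT/placebo for recipients and NA for donors: %s",
                                id_list(d$subject_id[arm_bad])))
  }

  if (anyDuplicated(s$sample_id)) {
    errors <- c(errors, sprintf("samples: duplicate sample_id(s): %s",
                                id_list(s$sample_id[duplicated(s$sample_id)])))
  }
  orphan <- !s$subject_id %in% d$subject_id
  if (any(orphan)) {
    errors <- c(errors, sprintf("samples: subject_id not in design: %s",
                                id_list(s$subject_id[orphan])))
  }
  rec_samples <- dplyr::inner_join(s, d, by = c(subject_id = "subject_id"))
  bad_tp <- rec_samples$role == "recipient" &
    !rec_samples$timepoint %in% RECIPIENT_TIMEPOINTS
  if (any(bad_tp)) {
    errors <- c(errors, sprintf("samples: invalid recipient timepoint(s) for %s",
                                id_list(rec_samples$sample_id[bad_tp])))
  }
  # every recipient has baseline + week6; donors >= 1 sample
  for (role_i in c("recipient", "donor")) {
    subj <- d$subject_id[d$role == role_i]
    have <- split(rec_samples$timepoint[rec_samples$role == role_i],
                  rec_samples$subject_id[rec_samples$role == role_i])
    if (role_i == "recipient") {
      lacking <- subj[!vapply(subj, function(id) {
        all(c("baseline", "week6") %in% (have[[id]] %||% character()))
      }, logical(1))]
      if (length(lacking) > 0) {
        errors <- c(errors, sprintf("design: recipient(s) missing baseline or week6 sample: %s",
                                    id_list(lacking)))
      }
    } else {
      lacking <- subj[!subj %in% names(have)]
      if (length(lacking) > 0) {
        errors <- c(errors, sprintf("design: donor(s) with no sample: %s",
                                    id_list(lacking)))
      }
    }
  }

  m <- bundle$mags
  if (anyDuplicated(m$mag_id)) {
    errors <- c(errors, sprintf("mags: duplicate mag_id(s): %s",
                                id_list(m$mag_id[duplicated(m$mag_id)])))
  }
  if (any(is.na(m$completeness) | is.na(m$contamination))) {
    errors <- c(errors, sprintf("mags: missing quality value(s) for %s",
                                id_list(m$mag_id[is.na(m$completeness) | is.na(m$contamination)])))
  }
  bad_q <- !is.na(m$completeness) & (m$completeness < 0 | m$completeness > 100) |
    !is.na(m$contamination) & m$contamination < 0
  if (any(bad_q)) {
    errors <- c(errors, sprintf("mags: completeness must be in [0,100] and contamination >= 0: %s",
                                id_list(m$mag_id[bad_q])))
  }
  orphan_mag <- !m$sample_id %in% s$sample_id
  if (any(orphan_mag)) {
    errors <- c(errors, sprintf("mags: sample_id not in samples: %s",
                                id_list(m$sample_id[orphan_mag])))
  }

  g <- bundle$genes
  if (anyDuplicated(g$gene_id)) {
    errors <- c(errors, sprintf("genes: duplicate gene_id(s): %s",
                                id_list(g$gene_id[duplicated(g$gene_id)])))
  }
  if (any(is.na(g$cluster_id) | g$cluster_id == "")) {
    errors <- c(errors, sprintf("genes: empty cluster_id for %s",
                                id_list(g$gene_id[is.na(g$cluster_id) | g$cluster_id == ""])))
  }
  # gene's MAG must exist and sit in the same sample
  gm <- dplyr::left_join(g, m[, c("mag_id", "sample_id")], by = "mag_id",
                         suffix = c("", ".mag"))
  dangling <- is.na(gm$sample_id.mag)
  if (any(dangling)) {
    errors <- c(errors, sprintf("genes: mag_id not in mags: %s",
                                id_list(g$mag_id[dangling])))
  }
  mismatch <- !dangling & gm$sample_id != gm$sample_id.mag
  if (any(mismatch)) {
    errors <- c(errors, sprintf("genes: gene and its MAG are in different samples: %s",
                                id_list(g$gene_id[mismatch])))
  }

  if (!is.null(bundle$donor_assignment)) {
    da <- bundle$donor_assignment
    errors <- c(errors, check_assignment(da, d))
  }

  if (!is.null(bundle$engraftment)) {
    e <- bundle$engraftment
    ed <- dplyr::left_join(e, d, by = c(recipient_id = "subject_id"))
    not_fmt <- is.na(ed$arm) | ed$arm != "FMT"
    if (any(not_fmt)) {
      errors <- c(errors, sprintf("engraftment: recipient not in FMT arm: %s",
                                  id_list(e$recipient_id[not_fmt])))
    }
    dsex <- setNames(d$sex, d$subject_id)
    mism <- dsex[e$donor_id] != dsex[e$recipient_id]
    if (any(mism, na.rm = TRUE) || anyNA(mism)) {
      errors <- c(errors, sprintf("engraftment: donor not sex-matched (or unknown) for %s",
                                  id_list(e$recipient_id[is.na(mism) | mism])))
    }
    if (any(e$timepoint != "week6")) {
      errors <- c(errors, "engraftment: timepoint must be week6")
    }
  }

  if (!is.null(bundle$abundance)) {
    a <- bundle$abundance
    if (any(a$cpm < 0, na.rm = TRUE)) {
      errors <- c(errors, sprintf("abundance: negative cpm for %s",
                                  id_list(a$cluster_id[a$cpm < 0])))
    }
    key <- paste(a$cluster_id, a$sample_id)
    if (anyDuplicated(key)) {
      errors <- c(errors, sprintf("abundance: duplicate (cluster_id, sample_id): %s",
                                  id_list(key[duplicated(key)])))
    }
    orphan_a <- !a$sample_id %in% s$sample_id
    if (any(orphan_a)) {
      errors <- c(errors, sprintf("abundance: sample_id not in samples: %s",
                                  id_list(a$sample_id[orphan_a])))
    }
  }

  if (!is.null(bundle$waafle)) {
    w <- bundle$waafle
    if (any(w$n_hgt_contigs > w$n_contigs)) {
      errors <- c(errors, sprintf("waafle: n_hgt_contigs > n_contigs for %s",
                                  id_list(w$sample_id[w$n_hgt_contigs > w$n_contigs])))
    }
    if (any(w$n_contigs <= 0 | w$species_richness <= 0)) {
      errors <- c(errors, sprintf("waafle: n_contigs and species_richness must be positive: %s",
                                  id_list(w$sample_id[w$n_contigs <= 0 | w$species_richness <= 0])))
    }
    if (any(w$n_hgt_contigs < 0)) {
      errors <- c(errors, sprintf("waafle: negative n_hgt_contigs for %s",
                                  id_list(w$sample_id[w$n_hgt_contigs < 0])))
    }
  }

  if (!is.null(bundle$cog)) {
    letters_used <- unique(unlist(strsplit(bundle$cog$categories[!is.na(bundle$cog$categories)], "")))
    unknown <- setdiff(letters_used, COG_ALPHABET)
    if (length(unknown) > 0) {
      errors <- c(errors, sprintf("cog: unknown COG letter(s): %s",
                                  paste(unknown, collapse = ", ")))
    }
  }

  abort_many(errors, "bundle")
  invisible(bundle)
}

check_assignment <- function(da, d) {
  errors <- character()
  dsex <- setNames(d$sex, d$subject_id)
  drole <- setNames(d$role, d$subject_id)
  bad_ref <- !(da$recipient_id %in% d$subject_id) | !(da$donor_id %in% d$subject_id)
  if (any(bad_ref)) {
    errors <- c(errors, sprintf("donor_assignment: unknown subject(s): %s",
                                id_list(c(da$recipient_id, da$donor_id)[c(bad_ref, bad_ref)])))
    return(errors)
  }
  if (any(drole[da$donor_id] != "donor") || any(drole[da$recipient_id] != "recipient")) {
    errors <- c(errors, "donor_assignment: roles inverted in one or more rows")
  }
  mism <- dsex[da$donor_id] != dsex[da$recipient_id]
  if (any(mism)) {
    errors <- c(errors, sprintf("donor_assignment: donor not sex-matched for %s",
                                id_list(da$recipient_id[mism])))
  }
  errors
}

bundle_col_types <- function(name) {
  schema <- bundle_schemas()[[name]]
  codes <- c(character = "c", numeric = "d", logical = "l")
  do.call(readr::cols, as.list(setNames(codes[schema], names(schema))))
}

#' Read a trial bundle from a directory of TSV files
#'
#' Expects files named `<table>.tsv` for each component of
#' [hgt_bundle()]; `design`, `samples`, `mags` and `genes` are required,
#' the rest are read when present.
#'
#' @param dir Directory containing the TSV tables.
#' @param validate Validate after reading (default TRUE).
#' @return An [hgt_bundle()].
#' @export
read_bundle <- function(dir, validate = TRUE) {
  stopifnot(dir.exists(dir))
  read1 <- function(name, required = FALSE) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) {
      if (required) stop("read_bundle(): missing required table ", name, call. = FALSE)
      return(NULL)
    }
    tbl <- readr::read_tsv(path, col_types = bundle_col_types(name),
                           na = "NA", progress = FALSE)
    missing <- setdiff(names(bundle_schemas()[[name]]), names(tbl))
    if (length(missing) > 0) {
      stop(sprintf("read_bundle(): table '%s' is missing column(s): %s",
                   name, paste(missing, collapse = ", ")), call. = FALSE)
    }
    # empty character columns come back logical-NA-free; coerce "" to ""
    tbl
  }
  bundle <- hgt_bundle(
    design = read1("design", required = TRUE),
    samples = read1("samples", required = TRUE),
    mags = read1("mags", required = TRUE),
    genes = read1("genes", required = TRUE),
    donor_assignment = read1("donor_assignment"),
    engraftment = read1("engraftment"),
    abundance = read1("abundance"),
    waafle = read1("waafle"),
    cog = read1("cog"),
    validate = validate)
  bundle
}

#' Write a trial bundle to a directory of TSV files
#'
#' Inverse of [read_bundle()]: every non-NULL component table is written
#' as `<table>.tsv` with a fixed column order, so write-then-read
#' round-trips exactly and identical bundles produce byte-identical
#' directories.
#'
#' @param bundle An [hgt_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("write_bundle(): cannot create ", dir, call. = FALSE)
  for (nm in names(bundle)) {
    tbl <- bundle[[nm]]
    if (is.null(tbl)) next
    tbl <- tbl[, names(bundle_schemas()[[nm]])]
    readr::write_tsv(tbl, file.path(dir, paste0(nm, ".tsv")), na = "NA",
                     progress = FALSE)
  }
  invisible(dir)
}

#' Write pipeline result tables
#'
#' Writes each result table as TSV with deterministic column order, a
#' `pipeline_version` and `config_hash` column stamped on every row, and
#' a JSON run summary alongside.
#'
#' @param results Named list of data frames (result tables) plus,
#'   optionally, a `summary` element (named list of scalars) for the JSON
#'   run summary.
#' @param out_dir Output directory.
#' @param config The run configuration used; hashed into every output.
#' @return Paths written, invisibly.
#' @export
write_results <- function(results, out_dir, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("write_results(): cannot create ", out_dir, call. = FALSE)
  ver <- as.character(packageVersion("fmthgt"))
  hash <- config_hash(config)
  summary <- results$summary %||% list()
  results$summary <- NULL
  paths <- character()
  for (nm in names(results)) {
    tbl <- results[[nm]]
    if (is.null(tbl)) next
    tbl <- as.data.frame(tbl)
    tbl <- tbl[, sort_result_columns(names(tbl)), drop = FALSE]
    tbl$pipeline_version <- rep(ver, nrow(tbl))
    tbl$config_hash <- rep(hash, nrow(tbl))
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tbl), path, na = "NA", progress = FALSE)
    paths <- c(paths, path)
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(
    c(list(pipeline_version = ver, config_hash = hash), summary),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(paths, summary_path))
}

# key/id columns first, then the rest in given order — deterministic
sort_result_columns <- function(cols) {
  keys <- intersect(c("participant_id", "recipient_id", "subject_id",
                      "donor_id", "sample_id", "cluster_id", "gene_id",
                      "sex", "arm", "timepoint"), cols)
  c(keys, setdiff(cols, keys))
}
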