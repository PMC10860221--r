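#' Input dialect adapters
#'
#' Thin readers that translate the native output formats of common
#' upstream tools into the canonical bundle tables of [hgt_bundle()].
#' They parse format, never recompute: quality scores, taxonomy strings,
#' cluster membership and annotation letters are taken as given.
#'
#' @name adapters
NULL

#' Read a CheckM-style quality table
#'
#' @param path TSV with columns `Bin Id`, `Completeness`, `Contamination`.
#' @return Tibble with `mag_id`, `completeness`, `contamination`.
#' @rdname adapters
#' @export
read_checkm <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("Bin Id", "Completeness", "Contamination")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    stop("read_checkm(): missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(mag_id = tbl[["Bin Id"]],
                 completeness = as.numeric(tbl[["Completeness"]]),
                 contamination = as.numeric(tbl[["Contamination"]]))
}

#' Read a GTDB-Tk classification summary
#'
#' Splits the `classification` string at `;p__` and `;s__` to recover the
#' phylum and species; an empty species field marks the MAG as not
#' classified to species level.
#'
#' @param path TSV with columns `user_genome`, `classification`.
#' @return Tibble with `mag_id`, `phylum`, `species`, `species_classified`.
#' @rdname adapters
#' @export
read_gtdbtk <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c("user_genome", "classification"), names(tbl))
  if (length(missing) > 0) {
    stop("read_gtdbtk(): missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pull_rank <- function(cls, prefix) {
    out <- rep(NA_character_, length(cls))
    hit <- regmatches(cls, regexpr(paste0(prefix, "[^;]*"), cls))
    has <- grepl(prefix, cls, fixed = TRUE)
    out[has] <- sub(prefix, "", hit, fixed = TRUE)
    out
  }
  phylum <- pull_rank(tbl$classification, "p__")
  species <- pull_rank(tbl$classification, "s__")
  classified <- !is.na(species) & species != ""
  tibble::tibble(mag_id = tbl$user_genome,
                 phylum = ifelse(is.na(phylum) | phylum == "", NA_character_, phylum),
                 species = ifelse(classified, species, NA_character_),
                 species_classified = classified)
}

#' Read cd-hit `.clstr` cluster membership
#'
#' Parses the plain-text `.clstr` format (`>Cluster N` headers followed
#' by member lines with the sequence id between `>` and `...`). The
#' representative flag (`*`) is ignored: membership is what the pipeline
#' consumes.
#'
#' @param path A `.clstr` file.
#' @return Tibble with `gene_id`, `cluster_id` (`"cN"`).
#' @rdname adapters
#' @export
read_cdhit_clstr <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, ">Cluster")
  if (!any(is_header)) stop("read_cdhit_clstr(): no '>Cluster' headers found",
                            call. = FALSE)
  cluster_no <- cumsum(is_header)
  members <- lines[!is_header]
  member_cluster <- cluster_no[!is_header]
  ids <- sub(".*>", "", sub("\\.\\.\\..*", "", members))
  header_ids <- sub(">Cluster[[:space:]]+", "", lines[is_header])
  tibble::tibble(gene_id = ids,
                 cluster_id = paste0("c", header_ids[member_cluster]))
}

#' Read eggNOG-mapper annotations
#'
#' @param path TSV with columns `query` (or `#query`) and `COG_category`;
#'   `-` or empty means no classification.
#' @return Tibble with `cluster_id`, `categories`.
#' @rdname adapters
#' @export
read_eggnog <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "##", progress = FALSE)
  qcol <- intersect(c("query", "#query"), names(tbl))[1]
  if (is.na(qcol) || !"COG_category" %in% names(tbl)) {
    stop("read_eggnog(): need columns query/#query and COG_category",
         call. = FALSE)
  }
  cats <- tbl$COG_category
  cats[is.na(cats) | cats == "-"] <- ""
  tibble::tibble(cluster_id = tbl[[qcol]], categories = gsub("[^A-Z]", "", cats))
}

#' Summarise WAAFLE per-sample contig calls
#'
#' Each input file holds one sample's per-contig calls with a `call`
#' column; contigs called `lgt` count as HGT contigs. Species richness
#' must be supplied separately (it comes from profiling, not WAAFLE).
#'
#' @param paths Named character vector: sample_id -> per-contig TSV.
#' @param species_richness Named integer vector: sample_id -> richness.
#' @return A `waafle` bundle table.
#' @rdname adapters
#' @export
read_waafle_calls <- function(paths, species_richness) {
  stopifnot(!is.null(names(paths)), all(names(paths) %in% names(species_richness)))
  rows <- lapply(names(paths), function(sid) {
    tbl <- readr::read_tsv(paths[[sid]], col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (!"call" %in% names(tbl)) {
      stop("read_waafle_calls(): missing 'call' column in ", paths[[sid]],
           call. = FALSE)
    }
    tibble::tibble(sample_id = sid,
                   n_hgt_contigs = sum(tbl$call == "lgt"),
                   n_contigs = nrow(tbl),
                   species_richness = as.numeric(species_richness[[sid]]))
  })
  dplyr::bind_rows(rows)
}
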