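#' COG letter-to-class mapping
#'
#' The standard grouping of COG single-letter functional categories into
#' the four major classes: information storage and processing (A, B, J,
#' K, L), cellular processes and signaling (D, M, N, O, T, U, V, W, Y,
#' Z), metabolism (C, E, F, G, H, I, P, Q), and poorly characterised
#' (R, S). Clusters without any annotation fall in "no classification".
#'
#' @return Named character vector letter -> class.
#' @export
cog_class_map <- function() {
  c(A = "information storage and processing",
    B = "information storage and processing",
    J = "information storage and processing",
    K = "information storage and processing",
    L = "information storage and processing",
    D = "cellular processes and signaling",
    M = "cellular processes and signaling",
    N = "cellular processes and signaling",
    O = "cellular processes and signaling",
    T = "cellular processes and signaling",
    U = "cellular processes and signaling",
    V = "cellular processes and signaling",
    W = "cellular processes and signaling",
    Y = "cellular processes and signaling",
    Z = "cellular processes and signaling",
    C = "metabolism", E = "metabolism", F = "metabolism", G = "metabolism",
    H = "metabolism", I = "metabolism", P = "metabolism", Q = "metabolism",
    R = "poorly characterised", S = "poorly characterised")
}

#' Classify gene clusters into COG categories and major classes
#'
#' Multi-valued, per-category accounting: a cluster annotated "EG"
#' contributes one unit to category E and one to G (hence twice to
#' metabolism); a cluster with no annotation contributes one unit to
#' "no classification". Unknown letters are an error naming the letter.
#'
#' @param cog A `cog` bundle table.
#' @param clusters Optional cluster ids to restrict to (e.g. the
#'   engraftment-dependent HTGCs); clusters absent from `cog` are
#'   treated as unannotated.
#' @return Tibble: `cluster_id`, `category` (letter or NA), `class`.
#' @export
classify_clusters <- function(cog, clusters = NULL) {
  map <- cog_class_map()
  tbl <- cog
  if (!is.null(clusters)) {
    tbl <- dplyr::left_join(tibble::tibble(cluster_id = unique(clusters)),
                            cog, by = "cluster_id")
    tbl$categories[is.na(tbl$categories)] <- ""
  }
  letters_used <- setdiff(unique(unlist(strsplit(tbl$categories, ""))), "")
  unknown <- setdiff(letters_used, names(map))
  if (length(unknown) > 0) {
    stop("classify_clusters(): unknown COG letter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  splits <- strsplit(tbl$categories, "")
  n_cat <- vapply(splits, length, integer(1))
  annotated <- tibble::tibble(
    cluster_id = rep(tbl$cluster_id[n_cat > 0], n_cat[n_cat > 0]),
    category = unlist(splits[n_cat > 0]))
  annotated$class <- unname(map[annotated$category])
  blank <- tibble::tibble(cluster_id = tbl$cluster_id[n_cat == 0],
                          category = NA_character_,
                          class = "no classification")
  out <- dplyr::bind_rows(annotated, blank)
  out[order(out$cluster_id, out$category, na.last = TRUE), ]
}

#' Summarise class shares of a cluster set
#'
#' Counts clusters per major class (a cluster annotated in several
#' classes counts once in each; for the headline percentages the three
#' functional classes are pooled as "functional classification") and
#' reports percentages of the cluster set size.
#'
#' @param classified Output of [classify_clusters()].
#' @return Tibble: `group` (functional classification / poorly
#'   characterised / no classification), `n_clusters`, `pct`.
#' @export
class_shares <- function(classified) {
  per_cluster <- dplyr::distinct(classified, .data$cluster_id, .data$class)
  per_cluster$group <- dplyr::case_when(
    per_cluster$class %in% c("information storage and processing",
                             "cellular processes and signaling",
                             "metabolism") ~ "functional classification",
    per_cluster$class == "poorly characterised" ~ "poorly characterised",
    TRUE ~ "no classification")
  # headline accounting is exclusive in precedence order: any functional
  # class first, else poorly characterised, else none
  precedence <- c("functional classification", "poorly characterised",
                  "no classification")
  best <- dplyr::summarise(
    dplyr::group_by(per_cluster, .data$cluster_id),
    group = precedence[min(match(.data$group, precedence))],
    .groups = "drop")
  n_total <- nrow(best)
  out <- dplyr::count(best, .data$group, name = "n_clusters")
  out$pct <- pct_of(out$n_clusters, n_total)
  out <- out[match(precedence, out$group), ]
  out <- out[!is.na(out$group), ]
  out
}

#' Bray-Curtis dissimilarity between two composition vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))` on nonnegative vectors;
#' 0 for identical vectors, 1 for disjoint support.
#'
#' @param x,y Equal-length nonnegative numeric vectors, not both all
#'   zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) + sum(y) == 0) {
    stop("bray_curtis(): both vectors are all zero", call. = FALSE)
  }
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param mat Samples x features nonnegative matrix.
#' @return A symmetric `dist`-like matrix of pairwise dissimilarities.
#' @export
bray_curtis_matrix <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(all(mat >= 0))
  if (any(rowSums(mat) == 0)) {
    stop("bray_curtis_matrix(): all-zero row(s)", call. = FALSE)
  }
  n <- nrow(mat)
  tot <- rowSums(mat)
  minsum <- matrix(0, n, n)
  for (i in seq_len(n)) {
    minsum[i, ] <- rowSums(pmin(mat, rep(mat[i, ], each = n)))
  }
  d <- 1 - 2 * minsum / outer(tot, tot, "+")
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix. The total sum of squared dissimilarities `sum(d_ij^2) / n` is
#' partitioned into within-group (`sum over groups of within-group
#' d_ij^2 / n_g`) and between-group parts, giving
#' `F = (SS_between / (k - 1)) / (SS_within / (n - k))`. Significance
#' comes from permuting group labels: `p = (1 + #{F* >= F}) / (1 +
#' n_perm)` (the +1 correction, so the smallest attainable p is
#' `1 / (n_perm + 1)`). With `n_perm = "exhaustive"` all distinct label
#' assignments are enumerated and the p-value is exact.
#'
#' @param mat Samples x features nonnegative matrix, or a precomputed
#'   symmetric dissimilarity matrix (`is_distance = TRUE`).
#' @param groups Group labels, length `nrow(mat)`; >= 2 groups.
#' @param n_perm Number of label permutations (default 999), or
#'   `"exhaustive"`.
#' @param seed Seed for the permutation stream.
#' @param is_distance Interpret `mat` as a dissimilarity matrix.
#' @return List: `pseudo_f`, `r_squared`, `p`, `n_perm`, `df_between`,
#'   `df_within`.
#' @export
permanova <- function(mat, groups, n_perm = 999, seed = 1L,
                      is_distance = FALSE) {
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2) stop("permanova(): need >= 2 groups", call. = FALSE)
  d <- if (is_distance) as.matrix(mat) else bray_curtis_matrix(mat)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  if (all(d == 0)) {
    stop("permanova(): degenerate (all-zero) dissimilarity matrix",
         call. = FALSE)
  }
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  glevels <- unique(groups)
  ss_within <- function(labels) {
    # (1/2) sum_g (1_g' D2 1_g) / n_g via one indicator matrix product
    ind <- outer(labels, glevels, "==") * 1
    ng <- colSums(ind)
    sum(colSums((d2 %*% ind) * ind) / ng) / 2
  }
  f_stat <- function(labels) {
    sw <- ss_within(labels)
    sa <- ss_total - sw
    (sa / (k - 1)) / (sw / (n - k))
  }
  f_obs <- f_stat(groups)

  if (identical(n_perm, "exhaustive")) {
    perms <- all_label_permutations(groups)
    f_perm <- vapply(perms, f_stat, numeric(1))
    # the identity assignment is part of the exact distribution
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) f_stat(sample(groups)), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(pseudo_f = f_obs,
       r_squared = (ss_total - ss_within(groups)) / ss_total,
       p = p, n_perm = n_used, df_between = k - 1, df_within = n - k)
}

# all distinct assignments of the multiset of labels to positions
all_label_permutations <- function(groups) {
  n <- length(groups)
  if (n > 10) {
    stop("exhaustive enumeration is limited to n <= 10 samples", call. = FALSE)
  }
  ux <- unique(groups)
  counts <- as.list(table(factor(groups, levels = ux)))
  res <- vector("list", 0)
  recurse <- function(prefix, counts) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (u in ux) {
      if (counts[[u]] > 0) {
        counts[[u]] <- counts[[u]] - 1L
        recurse(c(prefix, u), counts)
        counts[[u]] <- counts[[u]] + 1L
      }
    }
  }
  recurse(character(0), counts)
  res
}

#' PERMANOVA of HTGC functional composition across timepoints
#'
#' Builds, separately per sex, a composition matrix whose rows are
#' (engraftment-dependent HTGC, timepoint) units and whose features are
#' either the four major COG classes or the individual COG categories; a
#' cluster's CPM at that timepoint is credited in full to each of its
#' categories (multi-annotation is counted separately), rows are closed
#' to relative abundance, and group labels are the timepoints. Rows with
#' zero total (cluster absent at that timepoint) are dropped; a
#' timepoint with no rows is excluded with a warning.
#'
#' @param series Abundance series from [retention()].
#' @param cog A `cog` bundle table.
#' @param level `"class"` (default) or `"category"`.
#' @param n_perm,seed Passed to [permanova()].
#' @return Tibble: `sex`, `level`, `pseudo_f`, `r_squared`, `p_value`,
#'   `n_rows`.
#' @export
compare_timepoints <- function(series, cog, level = c("class", "category"),
                               n_perm = 999, seed = 1L) {
  level <- match.arg(level)
  classified <- classify_clusters(cog, unique(series$cluster_id))
  feature <- if (level == "class") classified$class else
    ifelse(is.na(classified$category), "none", classified$category)
  cl_feat <- tibble::tibble(cluster_id = classified$cluster_id,
                            feature = feature)
  out <- lapply(sort(unique(series$sex)), function(sx) {
    s <- series[series$sex == sx & series$cpm > 0, ]
    long <- dplyr::inner_join(s, cl_feat, by = "cluster_id",
                              relationship = "many-to-many")
    comp <- dplyr::summarise(
      dplyr::group_by(long, .data$recipient_id, .data$cluster_id,
                      .data$timepoint, .data$feature),
      cpm = sum(.data$cpm), .groups = "drop")
    wide <- tidyr::pivot_wider(comp, names_from = "feature",
                               values_from = "cpm", values_fill = 0)
    feat_cols <- setdiff(names(wide),
                         c("recipient_id", "cluster_id", "timepoint"))
    mat <- as.matrix(wide[, feat_cols])
    present_tp <- table(wide$timepoint)
    absent <- setdiff(c("week6", "week12", "week26"), names(present_tp))
    if (length(absent) > 0) {
      warning("compare_timepoints(): no observations at ",
              paste(absent, collapse = ", "), " for sex ", sx)
    }
    if (length(present_tp) < 2 || nrow(mat) < 3) {
      return(tibble::tibble(sex = sx, level = level, pseudo_f = NA_real_,
                            r_squared = NA_real_, p_value = NA_real_,
                            n_rows = nrow(mat)))
    }
    rel <- mat / rowSums(mat)
    res <- tryCatch(
      permanova(rel, wide$timepoint, n_perm = n_perm, seed = seed),
      error = function(e) {
        # identical compositions everywhere: nothing to test
        list(pseudo_f = NA_real_, r_squared = NA_real_, p = NA_real_)
      })
    tibble::tibble(sex = sx, level = level, pseudo_f = res$pseudo_f,
                   r_squared = res$r_squared, p_value = res$p,
                   n_rows = nrow(mat))
  })
  dplyr::bind_rows(out)
}
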