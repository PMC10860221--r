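test_that("the COG letter map covers the alphabet with one class per letter", {
  map <- cog_class_map()
  expect_setequal(names(map), c(LETTERS[1:23], "Y", "Z")) # A..W, Y, Z (no X)
  expect_equal(unname(map["S"]), "poorly characterised")
  expect_equal(unname(map["K"]), "information storage and processing")
  expect_equal(unname(map["E"]), "metabolism")
  expect_equal(unname(map["T"]), "cellular processes and signaling")
  expect_false(any(duplicated(names(map))))
})

test_that("cluster classification is multi-valued with per-category accounting", {
  cog <- tibble::tibble(cluster_id = c("c1", "c2", "c3"),
                        categories = c("EG", "", "S"))
  cl <- classify_clusters(cog)
  c1 <- cl[cl$cluster_id == "c1", ]
  expect_setequal(c1$category, c("E", "G"))
  expect_true(all(c1$class == "metabolism"))
  expect_equal(cl$class[cl$cluster_id == "c2"], "no classification")
  expect_equal(cl$class[cl$cluster_id == "c3"], "poorly characterised")
  # restricting to clusters absent from the annotation table = unannotated
  cl2 <- classify_clusters(cog, clusters = c("c1", "c9"))
  expect_equal(cl2$class[cl2$cluster_id == "c9"], "no classification")
  expect_error(classify_clusters(tibble::tibble(cluster_id = "c1",
                                                categories = "X")),
               "unknown COG letter.*X")
})

test_that("Bray-Curtis matches hand values and its defining properties", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 0), c(0, 2, 3)), 1)
  expect_equal(bray_curtis(c(1, 2, 3), c(3, 2, 1)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all zero")
  set.seed(11)
  for (i in 1:25) {
    x <- rexp(6); y <- rexp(6)
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
  }
})

test_that("the dissimilarity matrix agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(3)
  m <- matrix(rexp(40), 8, 5)
  own <- bray_curtis_matrix(m)
  ref <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(own), unname(ref), tolerance = 1e-12)
})

test_that("permanova matches vegan::adonis2 on statistic and R2", {
  skip_if_not_installed("vegan")
  set.seed(4)
  m <- matrix(rexp(75), 15, 5)
  g <- rep(c("a", "b", "c"), each = 5)
  own <- permanova(m, g, n_perm = 999, seed = 8)
  ref <- vegan::adonis2(vegan::vegdist(m, "bray") ~ g, permutations = 499)
  expect_equal(own$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(own$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_lt(abs(own$p - ref$`Pr(>F)`[1]), 0.08) # both Monte-Carlo
})

test_that("permanova p is invariant to common scaling and respects the +1 floor", {
  set.seed(6)
  base <- matrix(rexp(30), 10, 3)
  m <- rbind(base, 0)
  m[10, ] <- c(5, 5, 5)
  m <- m[1:10, ]
  g <- rep(c("a", "b"), each = 5)
  p1 <- permanova(m, g, n_perm = 199, seed = 5)$p
  p2 <- permanova(m * 7.3, g, n_perm = 199, seed = 5)$p
  expect_equal(p1, p2)
  # disjoint support: maximal separation reaches the permutation floor
  # (groups of 10, so a random relabelling almost never reproduces the
  # partition and ties the maximal F)
  disj <- rbind(cbind(matrix(rexp(30), 10, 3), 0, 0, 0),
                cbind(0, 0, 0, matrix(rexp(30), 10, 3)))
  res <- permanova(disj, rep(c("a", "b"), each = 10), n_perm = 999, seed = 5)
  expect_equal(res$p, 1 / (999 + 1))
  expect_error(permanova(matrix(1, 4, 2), rep(c("a", "b"), 2),
                         n_perm = 99), "degenerate")
})

test_that("exhaustive permanova equals the exact permutation distribution", {
  set.seed(13)
  m <- matrix(rexp(24), 6, 4)
  g <- rep(c("a", "b"), each = 3)
  ex <- permanova(m, g, n_perm = "exhaustive")
  expect_equal(ex$n_perm, 20) # choose(6,3)
  # Monte-Carlo estimate converges to the exact value
  mc <- permanova(m, g, n_perm = 1999, seed = 2)
  expect_lt(abs(ex$p - mc$p), 0.06)
  # exact p is a multiple of 1/20
  expect_equal(ex$p * 20, round(ex$p * 20))
})

test_that("headline class shares reproduce planted annotation mixes", {
  # 139 clusters: 76 functional, 37 poorly characterised, 26 unannotated
  cog <- tibble::tibble(
    cluster_id = sprintf("c%03d", 1:139),
    categories = c(rep("E", 40), rep("KT", 36), rep("S", 20), rep("R", 17),
                   rep("", 26)))
  shares <- class_shares(classify_clusters(cog))
  expect_equal(shares$n_clusters, c(76, 37, 26))
  expect_equal(shares$pct, c(54.7, 26.6, 18.7))
})

test_that("timepoint comparison is deterministic and null under identical composition", {
  series <- tidyr::crossing(recipient_id = sprintf("R%02d", 1:8),
                            cluster_id = sprintf("c%02d", 1:5),
                            timepoint = c("week6", "week12", "week26"))
  series$sex <- "female"
  series$cpm <- 10
  cog <- tibble::tibble(cluster_id = sprintf("c%02d", 1:5),
                        categories = c("E", "K", "S", "", "T"))
  r1 <- compare_timepoints(series, cog, n_perm = 199, seed = 4)
  r2 <- compare_timepoints(series, cog, n_perm = 199, seed = 4)
  expect_identical(r1, r2)
  expect_gt(r1$p_value[1], 0.9) # identical composition cannot separate groups
})

test_that("a planted week-26 functional shift is detected with power", {
  hits <- 0
  for (i in 1:10) {
    sim <- simulate_trial(boosted_config(seed = 400 + i,
                                         cog_shift_week26 = 6,
                                         retention_prob_week12 = 1,
                                         retention_prob_week26 = 1))
    ev <- detect_htgcs(sim$bundle)
    ed <- filter_engraftment_dependent(ev, sim$bundle$engraftment)
    res <- retention(ed, sim$bundle)
    cmp <- compare_timepoints(res$series, sim$bundle$cog, n_perm = 199,
                              seed = 1)
    hits <- hits + any(cmp$p_value < 0.05, na.rm = TRUE)
  }
  expect_gte(hits, 8)
})
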