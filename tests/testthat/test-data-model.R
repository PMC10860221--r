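test_that("minimal one-donor/one-recipient bundle validates with 2 subjects", {
  b <- toy_bundle()
  expect_s3_class(b, "hgt_bundle")
  expect_equal(nrow(b$design), 2)
  expect_invisible(validate_bundle(b))
})

test_that("dangling and inconsistent references are rejected with offending ids", {
  bad_gene <- tibble::tibble(gene_id = "g|orphan", mag_id = "m|nope",
                             sample_id = "R1|week6", cluster_id = "cX")
  expect_error(toy_bundle(extra_genes = bad_gene), "mag_id not in mags.*m\\|nope")

  # all failures reported together, not just the first
  b <- toy_bundle(validate = FALSE)
  b$genes <- dplyr::bind_rows(
    b$genes,
    tibble::tibble(gene_id = "g|orphan", mag_id = "m|nope",
                   sample_id = "R1|week6", cluster_id = "cX"),
    tibble::tibble(gene_id = "g|empty", mag_id = "m|R1|week6",
                   sample_id = "R1|week6", cluster_id = ""))
  err <- tryCatch(validate_bundle(b), error = function(e) conditionMessage(e))
  expect_match(err, "mag_id not in mags")
  expect_match(err, "empty cluster_id")
})

test_that("missing required columns produce a schema error naming the column", {
  b <- toy_bundle(validate = FALSE)
  b$mags$completeness <- NULL
  expect_error(validate_bundle(b), "missing column\\(s\\) completeness")
})

test_that("single-field corruptions of a valid bundle are all detected", {
  sim <- simulate_trial(tiny_config(seed = 3))
  corruptions <- list(
    function(b) { b$design$role[1] <- "patient"; b },
    function(b) { b$design$sex[1] <- "unknown"; b },
    function(b) { b$design$arm[b$design$role == "donor"][1] <- "FMT"; b },
    function(b) { b$samples$subject_id[1] <- "ghost"; b },
    function(b) { b$samples$sample_id[2] <- b$samples$sample_id[1]; b },
    function(b) { b$mags$completeness[1] <- 120; b },
    function(b) { b$mags$contamination[1] <- -2; b },
    function(b) { b$mags$completeness[1] <- NA_real_; b },
    function(b) { b$genes$mag_id[1] <- "m|ghost"; b },
    function(b) { b$genes$gene_id[2] <- b$genes$gene_id[1]; b },
    function(b) { b$abundance$cpm[1] <- -1; b },
    function(b) { b$waafle$n_hgt_contigs[1] <- b$waafle$n_contigs[1] + 1; b },
    function(b) { b$cog$categories[1] <- "X!"; b })
  for (i in seq_along(corruptions)) {
    b <- corruptions[[i]](sim$bundle)
    expect_error(validate_bundle(b), label = paste("corruption", i))
  }
})

test_that("write_bundle/read_bundle round-trips a synthetic trial exactly", {
  sim <- simulate_trial(tiny_config(seed = 7))
  dir <- withr::local_tempdir()
  write_bundle(sim$bundle, dir)
  back <- read_bundle(dir)
  for (nm in names(sim$bundle)) {
    expect_equal(as.data.frame(back[[nm]]),
                 as.data.frame(sim$bundle[[nm]][, names(back[[nm]])]),
                 label = nm)
  }
})

test_that("identical bundles yield byte-identical TSV directories", {
  sim1 <- simulate_trial(tiny_config(seed = 11))
  sim2 <- simulate_trial(tiny_config(seed = 11))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(sim1$bundle, d1)
  write_bundle(sim2$bundle, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("write_results stamps version and config hash and handles empty tables", {
  dir <- withr::local_tempdir()
  empty <- tibble::tibble(cluster_id = character(), n = integer())
  write_results(list(htgcs = empty, summary = list(n_events = 0)),
                dir, config = list(seed = 1))
  tsv <- readLines(file.path(dir, "htgcs.tsv"))
  expect_length(tsv, 1) # headers only
  expect_match(tsv, "pipeline_version\tconfig_hash")
  js <- jsonlite::read_json(file.path(dir, "run_summary.json"))
  expect_equal(js$n_events, 0)
  expect_match(js$config_hash, "^[0-9a-f]{32}$")
  # same config -> same hash; different config -> different hash
  expect_identical(config_hash(list(seed = 1)), js$config_hash)
  expect_false(identical(config_hash(list(seed = 2)), js$config_hash))
})

test_that("dialect adapters parse upstream tool formats", {
  dir <- withr::local_tempdir()
  writeLines(c("Bin Id\tCompleteness\tContamination\tExtra",
               "bin.1\t97.5\t1.2\tx", "bin.2\t55.0\t9.9\ty"),
             file.path(dir, "checkm.tsv"))
  cm <- read_checkm(file.path(dir, "checkm.tsv"))
  expect_equal(cm$completeness, c(97.5, 55.0))

  writeLines(c("user_genome\tclassification",
               "bin.1\td__Bacteria;p__Bacteroidota;c__X;o__Y;f__Z;g__G;s__Bacteroides uniformis",
               "bin.2\td__Bacteria;p__Firmicutes;c__X;o__Y;f__Z;g__G;s__"),
             file.path(dir, "gtdbtk.tsv"))
  gt <- read_gtdbtk(file.path(dir, "gtdbtk.tsv"))
  expect_equal(gt$species, c("Bacteroides uniformis", NA))
  expect_equal(gt$species_classified, c(TRUE, FALSE))
  expect_equal(gt$phylum, c("Bacteroidota", "Firmicutes"))

  writeLines(c(">Cluster 0", "0\t300nt, >geneA... *", "1\t299nt, >geneB... at +/95.31%",
               ">Cluster 1", "0\t120nt, >geneC... *"),
             file.path(dir, "cat.clstr"))
  cl <- read_cdhit_clstr(file.path(dir, "cat.clstr"))
  expect_equal(cl$gene_id, c("geneA", "geneB", "geneC"))
  expect_equal(cl$cluster_id, c("c0", "c0", "c1"))

  writeLines(c("#query\tCOG_category", "cl1\tEG", "cl2\t-", "cl3\tS"),
             file.path(dir, "eggnog.tsv"))
  eg <- read_eggnog(file.path(dir, "eggnog.tsv"))
  expect_equal(eg$categories, c("EG", "", "S"))

  writeLines(c("contig\tcall", "k1\tlgt", "k2\tno_lgt", "k3\tunclassified"),
             file.path(dir, "waafle_s1.tsv"))
  wf <- read_waafle_calls(c(s1 = file.path(dir, "waafle_s1.tsv")),
                          c(s1 = 40))
  expect_equal(wf$n_hgt_contigs, 1)
  expect_equal(wf$n_contigs, 3)
})
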