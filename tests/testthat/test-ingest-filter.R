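test_that("feature tables round-trip through TSV", {
  sim <- small_sim(seed = 2, individuals = 3, n_features = 20,
                   depth = 1000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(sim$table, path)
  back <- read_feature_table(path)
  expect_equal(back, sim$table[rownames(back), colnames(back)])
  expect_setequal(rownames(back), rownames(sim$table))

  md_path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(sim$metadata, md_path)
  md <- read_metadata(md_path)
  expect_equal(md$seq_count, sim$metadata$seq_count)
})

test_that("BIOM (JSON, dense) input matches the TSV path", {
  path <- withr::local_tempfile(fileext = ".biom")
  writeLines(paste0(
    '{"id":"t","format":"Biological Observation Matrix 1.0.0",',
    '"format_url":"http://biom-format.org","type":"OTU table",',
    '"generated_by":"paravec-test","date":"2026-01-01T00:00:00",',
    '"matrix_type":"dense","matrix_element_type":"int","shape":[2,3],',
    '"rows":[{"id":"f1","metadata":null},{"id":"f2","metadata":null}],',
    '"columns":[{"id":"s1","metadata":null},{"id":"s2","metadata":null},',
    '{"id":"s3","metadata":null}],"data":[[1,2,3],[4,5,6]]}'), path)
  m <- read_feature_table(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["s2", "f2"], 5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(m, tsv)
  expect_equal(read_feature_table(tsv), m)
})

test_that("malformed tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts1", "f1\t1\t2", "f2\t0\t1"), path)
  expect_error(read_feature_table(path), class = "paravec_validation_error")
  writeLines(c("feature_id\ts1\ts2", "f1\t1\t2", "f1\t0\t1"), path)
  expect_error(read_feature_table(path), class = "paravec_validation_error")
  expect_error(read_feature_table("does/not/exist.tsv"),
               class = "paravec_io_error")
})

test_that("the filter fixture yields exactly its documented survivors", {
  fx <- make_filter_fixture()
  exp <- attr(fx, "expected")
  res <- apply_sample_filters(fx$table, fx$metadata, filter_config())
  ids <- res$metadata$sample_id

  removed <- attr(res$report, "removed_samples")
  expect_identical(removed$missing_individual_id, exp$removed_no_individual)
  expect_identical(removed$duplicate_individual, exp$removed_duplicate)
  expect_identical(removed$health, exp$removed_health)
  expect_identical(removed$age_category, exp$removed_age)
  expect_identical(removed$low_sequence_count, exp$removed_low_reads)
  expect_identical(removed$species_below_min_individuals,
                   exp$removed_small_species)

  expect_true(all(exp$fixed_survivors %in% ids))
  d_kept <- grep("^D", ids, value = TRUE)
  expect_length(d_kept, exp$n_subsampled)
  expect_true(all(d_kept %in% exp$subsample_pool))
  expect_setequal(ids, c(exp$fixed_survivors, d_kept))
  # the filtered table is aligned with the filtered metadata
  expect_identical(rownames(res$table), ids)
})

test_that("boundary cases sit on the documented side of each threshold", {
  fx <- make_filter_fixture()
  res <- apply_sample_filters(fx$table, fx$metadata)
  ids <- res$metadata$sample_id
  expect_true("A02" %in% ids)          # exactly 1000 reads kept
  expect_false("B06" %in% ids)         # 999 reads dropped
  expect_true(all(c("A01", "A02", "A03") %in% ids))  # exactly 3 kept
  expect_false(any(grepl("^C", ids)))  # 2 individuals dropped

  specialists <- assign_diet_specialists(res$metadata)
  expect_equal(specialists[["egret"]], "meat-fish")   # 0.70 inclusive
  expect_equal(specialists[["deermouse"]], "seeds")
  expect_false("finch" %in% names(specialists))       # 0.69 dropped
})

test_that("filtering is deterministic and idempotent", {
  fx <- make_filter_fixture()
  r1 <- apply_sample_filters(fx$table, fx$metadata,
                             filter_config(subsample_seed = 4))
  r2 <- apply_sample_filters(fx$table, fx$metadata,
                             filter_config(subsample_seed = 4))
  expect_identical(r1$metadata$sample_id, r2$metadata$sample_id)
  r3 <- apply_sample_filters(fx$table, fx$metadata,
                             filter_config(subsample_seed = 9))
  again <- apply_sample_filters(r3$table, r3$metadata,
                                filter_config(subsample_seed = 9))
  expect_identical(again$metadata$sample_id, r3$metadata$sample_id)
  expect_true(all(again$report$samples_removed == 0))
})

test_that("all-pass input is returned unchanged with a zero report", {
  sim <- small_sim(seed = 3, individuals = 4, n_features = 20,
                   depth = 1500)
  res <- apply_sample_filters(sim$table, sim$metadata)
  expect_setequal(res$metadata$sample_id, sim$metadata$sample_id)
  expect_true(all(res$report$samples_removed == 0))
})

test_that("conflicting within-species diet fractions raise an error", {
  fx <- make_filter_fixture()
  md <- fx$metadata
  md$diet_plants[md$sample_id == "A01"] <- 0.10
  expect_error(assign_diet_specialists(md),
               class = "paravec_validation_error")
  # split diets below threshold are dropped
  md2 <- fx$metadata[fx$metadata$species == "vole", ]
  md2$diet_plants <- 0.5; md2$diet_seeds <- 0.5
  expect_length(assign_diet_specialists(md2), 0)
})

test_that("divergence times equal MRCA depth and obey ultrametric geometry", {
  cherry <- ape::read.tree(text = "(a:50,b:50);")
  expect_equal(divergence_time(cherry, "a", "b"), 50)
  expect_equal(divergence_time(cherry, "a", "a"), 0)

  bal <- ape::read.tree(text = "((a:30,b:30):50,(c:30,d:30):50);")
  expect_equal(divergence_time(bal, "a", "c"), 80)
  expect_equal(divergence_time(bal, "a", "b"), 30)
  expect_equal(divergence_time(bal, "a", "c"),
               divergence_time(bal, "c", "a"))
  expect_error(divergence_time(bal, "a", "zzz"),
               class = "paravec_lookup_error")

  # three-point condition: the two largest pairwise times of any triple
  # are equal on an ultrametric tree
  tr <- simulate_tree(12, 70, seed = 31)
  tips <- tr$tip.label
  set.seed(1)
  for (rep in 1:20) {
    tri <- sample(tips, 3)
    tt <- sort(c(divergence_time(tr, tri[1], tri[2]),
                 divergence_time(tr, tri[1], tri[3]),
                 divergence_time(tr, tri[2], tri[3])))
    expect_lt(abs(tt[2] - tt[3]), 1e-6)
  }
})

test_that("non-ultrametric trees are read with a warning", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:10,b:50):5,c:100);", path)
  expect_warning(read_tree(path), "ultrametric")
})
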