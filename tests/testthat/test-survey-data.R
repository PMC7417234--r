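test_that("observation tables round-trip through CSV unchanged", {
  tab <- observation_table(make_obs_df())
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(tab, path)
  back <- read_observations(path)
  expect_s3_class(back, "obs_table")
  expect_equal(nrow(back), 4)
  for (col in c("object_id", "klass", "temperature", "dist_edge",
                "perp_distance"))
    expect_equal(back[[col]], tab[[col]])
  expect_equal(as.Date(back$date), as.Date(tab$date))
  # byte-stable across writes
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(tab, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("an empty table writes a header-only file and reads back empty", {
  tab <- observation_table(make_obs_df()[0, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(tab, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_observations(path)), 0)
})

test_that("klass values are case-folded under the default schema", {
  df <- make_obs_df(klass = c("Duplicate", "FALSE_POSITIVE",
                              "unique detection", "Missed"))
  tab <- observation_table(df)
  expect_equal(tab$klass, c("duplicate", "false_positive",
                            "unique_detection", "missed"))
})

test_that("schema and validation failures are specific", {
  df <- make_obs_df()
  expect_error(observation_table(df[, setdiff(names(df), "wind_speed")]),
               "wind_speed")
  bad <- df; bad$klass[2] <- "ghost"
  expect_error(observation_table(bad), "invalid klass.*ghost")
  bad <- df; bad$dist_edge[3] <- -1
  expect_error(observation_table(bad), "negative dist_edge")
  bad <- df; bad$perp_distance[1] <- 80
  expect_error(observation_table(bad), "strip half-width")
  bad <- df; bad$dist_nearest[1] <- NA
  expect_error(observation_table(bad), "dist_nearest absent")
  bad <- df; bad$object_id[2] <- bad$object_id[1]
  expect_error(observation_table(bad), "not unique")
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(observation_table(df), path)
  expect_error(read_observations(path, obs_schema(klass = "Fate")),
               "mapped column not in file")
})

test_that("split_by_date partitions exactly by date", {
  sim <- simulate_observations(quick_config(), seed = 11)
  tab <- sim$table
  dates <- sort(unique(as.Date(tab$date)))
  # trivial extremes
  expect_equal(nrow(split_by_date(tab, as.Date(character(0)))$test), 0)
  expect_equal(nrow(split_by_date(tab, dates)$train), 0)
  expect_error(split_by_date(tab, as.Date("1999-01-01")), "not present")
  # random subsets partition exactly
  set.seed(42)
  for (i in 1:5) {
    sub <- sample(dates, sample(length(dates), 1))
    sp <- split_by_date(tab, sub)
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tab))
    expect_equal(nrow(sp$test), sum(as.Date(tab$date) %in% sub))
    expect_length(intersect(sp$train$object_id, sp$test$object_id), 0)
  }
})

test_that("distance bins are half-open with the last bin closed", {
  df <- make_obs_df(klass = rep("unique_detection", 4))
  df$perp_distance <- c(0, 14.99, 15, 74.99)
  tab <- observation_table(df)
  counts <- bin_counts(tab, keep = "unique_detection")
  expect_equal(as.integer(counts[1, ]), c(2L, 1L, 0L, 0L, 1L))
})

test_that("bin_counts conserves totals and ignores row order", {
  sim <- simulate_observations(quick_config(), seed = 5)
  tab <- sim$table
  keep <- c("unique_detection", "duplicate")
  counts <- bin_counts(tab, keep = keep)
  expect_equal(sum(counts), sum(tab$klass %in% keep))
  shuffled <- tab[sample(nrow(tab)), ]
  counts2 <- bin_counts(shuffled, keep = keep)
  expect_equal(counts[rownames(counts2), ], counts2[rownames(counts2), ])
  # empty table -> all-zero array
  expect_equal(sum(bin_counts(tab[0, ])), 0)
  # out-of-strip distance is an error naming the object
  bad <- tab
  j <- which(bad$klass %in% keep)[1]
  bad$perp_distance[j] <- 74.5
  expect_error(bin_counts(bad, bin_edges = c(0, 15, 30), keep = keep),
               bad$object_id[j])
})

test_that("uniform simulated distances spread evenly over bins", {
  df <- make_obs_df(klass = rep("unique_detection", 100))
  df$object_id <- paste0("u", 1:100)
  set.seed(8)
  df$perp_distance <- runif(100, 0, 75)
  counts <- bin_counts(observation_table(df), keep = "unique_detection")
  expect_equal(sum(counts), 100)
  expect_true(all(abs(counts - 20) < 3.5 * sqrt(100 * 0.2 * 0.8)))
})

test_that("transect count arrays round-trip through CSV", {
  sim <- simulate_transect_counts(sim_config(), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transect_counts(sim$counts, path)
  back <- read_transect_counts(path)
  expect_equal(back$counts, sim$counts$counts)
  expect_equal(back$bin_edges, sim$counts$bin_edges)
  expect_equal(back$transect_covs, sim$counts$transect_covs,
               tolerance = 1e-12)
  expect_equal(back$visit_covs, sim$counts$visit_covs, tolerance = 1e-12)
  expect_equal(back$site, sim$counts$site)
})

test_that("transect count invariants are enforced", {
  expect_error(transect_counts(array(-1L, c(1, 1, 5))), "non-negative")
  expect_error(transect_counts(array(0L, c(1, 1, 4))), "distance bins")
  expect_error(
    transect_counts(array(0L, c(2, 1, 5)),
                    transect_covs = data.frame(forest = c(50, 130))),
    "\\[0, 100\\]")
})
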