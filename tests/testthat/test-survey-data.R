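test_that("reading a well-formed file preserves records and round-trips", {
  rec <- make_records(n_images = 2L, labels = c("coral_live", "sand"),
                      taxa = "Pocillopora", states = "pale")
  path <- write_records_csv(rec)
  ds <- read_point_counts(path)
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds$records), 100L)

  out <- tempfile(fileext = ".csv")
  write_point_counts(ds, out)
  ds2 <- read_point_counts(out)
  expect_equal(ds2$records, ds$records)
})

test_that("schema mapping renames columns and missing columns error", {
  rec <- make_records(n_images = 1L)
  names(rec)[names(rec) == "site_id"] <- "Site"
  path <- write_records_csv(rec)
  ds <- read_point_counts(path, schema = c(site_id = "Site"))
  expect_equal(unique(ds$records$site_id), "S01")
  expect_error(read_point_counts(path), "site_id")
})

test_that("unknown labels and misplaced bleach states are rejected with rows", {
  rec <- make_records(n_images = 1L)
  rec$label[7] <- "coralz"
  expect_error(read_point_counts(write_records_csv(rec)), "coralz.*7")

  rec2 <- make_records(n_images = 1L, labels = "sand")
  rec2$bleach_state[3] <- "pale"
  expect_error(read_point_counts(write_records_csv(rec2)),
               "non-coral label.*3")

  rec3 <- make_records(n_images = 1L)
  rec3$bleach_state[5] <- NA
  expect_error(read_point_counts(write_records_csv(rec3)),
               "without bleach_state")
})

test_that("cover is the exclusive-category proportion and sums to one", {
  rec <- make_records(n_images = 10L,
                      labels = c(rep("coral_live", 12), rep("sand", 38)))
  cov <- compute_cover(as_survey(rec))
  expect_equal(cov$cover[cov$category == "coral_live"], 120 / 500)
  expect_equal(cov$n_points[1], 500L)

  all_sand <- compute_cover(as_survey(make_records(labels = "sand")))
  expect_equal(all_sand$cover[all_sand$category == "sand"], 1)
  expect_true(all(all_sand$cover[all_sand$category != "sand"] == 0))

  # conservation on generated multi-site data
  set.seed(11)
  world <- simulate_site_set(scenario_config(n_sites = 4L, seed = 11))
  cov2 <- compute_cover(world$surveys, detail = "label_taxon")
  sums <- tapply(cov2$cover,
                 paste(cov2$site_id, cov2$depth_band, cov2$year), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("cover estimates are unbiased for multinomial images", {
  set.seed(21)
  p <- c(coral_live = 0.3, sand = 0.5, macroalgae = 0.2)
  n_pts <- 100L
  est <- replicate(1000, {
    draw <- sample(names(p), n_pts, replace = TRUE, prob = p)
    rec <- make_records(n_images = 2L, points_per_image = 50L,
                        labels = draw, taxa = "Acropora",
                        states = "normal")
    cov <- compute_cover(as_survey(rec))
    cov$cover[cov$category == "coral_live"]
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - p[["coral_live"]]), 3 * se + 1e-12)
})

test_that("community matrix shares, rare-taxon filter, and idempotence", {
  rec <- make_records(n_images = 1L, points_per_image = 40L,
                      labels = "coral_live",
                      taxa = c(rep("Acropora", 30), rep("Favia", 10)))
  cov <- compute_cover(as_survey(rec, 40L, 1L), detail = "label_taxon")
  m <- build_community_matrix(cov)
  expect_equal(unname(m[1, "Acropora"]), 0.75)
  expect_equal(unname(m[1, "Favia"]), 0.25)

  # a taxon at 0.4% of pooled coral observations is dropped at 0.005
  taxa <- c(rep("Acropora", 498), rep("Heliopora", 2))
  rec2 <- make_records(n_images = 10L, labels = "coral_live", taxa = taxa)
  cov2 <- compute_cover(as_survey(rec2, 50L, 10L), detail = "label_taxon")
  m2 <- build_community_matrix(cov2, min_share = 0.005)
  expect_false("Heliopora" %in% colnames(m2))
  expect_equal(unname(m2[1, "Acropora"]), 1)

  # min_share = 0 keeps everything; renormalization is the identity
  m0 <- build_community_matrix(cov2, min_share = 0)
  expect_equal(unname(m0[1, ]), c(498, 2) / 500,
               ignore_attr = TRUE)

  # idempotence: every retained taxon clears the threshold again
  pooled <- colSums(m2) / sum(m2)
  expect_true(all(pooled > attr(m2, "min_share")))

  # no live coral is an error
  cov3 <- compute_cover(as_survey(make_records(labels = "sand")),
                        detail = "label_taxon")
  expect_error(build_community_matrix(cov3), "no live coral")
})

test_that("taxon summaries give live fractions and Porites abundance", {
  taxa <- c(rep("Acropora", 10), rep("Porites_rus", 10))
  labs <- c(rep("coral_live", 6), rep("coral_turf_dead", 4),
            rep("coral_live", 10))
  rec <- make_records(n_images = 1L, points_per_image = 20L,
                      labels = labs, taxa = taxa)
  ts <- taxon_summaries(as_survey(rec, 20L, 1L))
  lf <- ts$live_fraction
  expect_equal(lf$live_fraction[lf$taxon == "Acropora"], 0.6)
  expect_equal(lf$live_fraction[lf$taxon == "Porites_rus"], 1)
  expect_equal(ts$ra_por$RA_POR, 10 / 16)

  only_rus <- make_records(labels = "coral_live", taxa = "Porites_rus")
  expect_equal(taxon_summaries(as_survey(only_rus))$ra_por$RA_POR, 1)
  no_por <- make_records(labels = "coral_live", taxa = "Acropora")
  expect_equal(taxon_summaries(as_survey(no_por))$ra_por$RA_POR, 0)
})
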