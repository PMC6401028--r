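# Shared fixture builders: all test data is generated in code.

# A long-format point-count data.frame. `labels`/`taxa`/`states` are
# recycled over points within each image.
make_records <- function(n_images = 2L, points_per_image = 50L,
                         labels = "coral_live", taxa = "Acropora",
                         states = "normal", site_id = "S01",
                         atoll = "ATL1", depth_band = "shallow_3_5m",
                         year = 2010L, transect = "T1") {
  n <- n_images * points_per_image
  lab <- rep_len(labels, n)
  data.frame(
    site_id = site_id, atoll = atoll, depth_band = depth_band,
    year = year, transect = transect,
    image = rep(seq_len(n_images), each = points_per_image),
    point = rep(seq_len(points_per_image), n_images),
    label = lab,
    taxon = ifelse(lab %in% coral_labels(), rep_len(taxa, n),
                   NA_character_),
    bleach_state = ifelse(lab %in% c("coral_live", "coral_bleached",
                                     "coral_recently_dead"),
                          rep_len(states, n), NA_character_),
    stringsAsFactors = FALSE)
}

as_survey <- function(records, points_per_image = 50L,
                      images_per_transect = 25L) {
  reefpulse:::new_survey_dataset(records, points_per_image,
                                 images_per_transect)
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

random_tally <- function() {
  p <- rgamma(7, shape = 0.7)
  bleach_tally(p / sum(p), n = sample(5:200, 1))
}

# Independent brute-force DHW oracle: O(n * window) rolling sum of
# thresholded hotspots.
dhw_oracle <- function(sst, mmm, window = 12L, hotspot_min = 1) {
  hs <- pmax(0, sst - mmm)
  hs[hs < hotspot_min] <- 0
  vapply(seq_along(hs), function(t) {
    sum(hs[max(1L, t - window + 1L):t])
  }, numeric(1))
}

make_sst <- function(sst, start = "2000-01-03", site_id = "X",
                     baseline = NULL) {
  weeks <- seq(as.Date(start), by = 7L, length.out = length(sst))
  yrs <- as.integer(format(range(weeks), "%Y"))
  sst_series(site_id, weeks, sst, baseline = baseline %||% yrs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lower_d <- function(m) m[lower.tri(m)]

# Replicated full-scenario analyses shared by the power and sign-recovery
# checks; computed once per session and summarized immediately so the
# replicate worlds themselves are not kept in memory.
.rp_cache <- new.env(parent = emptyenv())

scenario_replicate_analyses <- function(n_reps = 200L, base_seed = 20000L) {
  key <- paste0("reps_", n_reps, "_", base_seed)
  if (!exists(key, envir = .rp_cache)) {
    rows <- lapply(seq_len(n_reps), function(i) {
      world <- simulate_site_set(scenario_config(seed = base_seed + i))
      st <- world$site_table
      b <- bri_table(world$surveys)
      tab <- merge(b, st, by = c("site_id", "depth_band"))
      fit <- fit_response_model(tab, "bri", smooth = c("PAR", "fDHW4"))
      cover <- compute_cover(world$surveys, detail = "label_taxon")
      cm <- build_community_matrix(cover)
      bc <- bray_curtis(cm)
      pd <- st[match(sub("\\|.*$", "", rownames(cm)), st$site_id), ]
      terms <- c("pop_metric", "fDHW4", "CV_SST", "chl_a")
      terms <- terms[vapply(terms, function(v) {
        length(unique(pd[[v]])) > 1L
      }, logical(1))]
      pt <- permanova(bc, pd, terms, n_perm = 199L,
                      seed = base_seed + i)
      data.frame(pop_p = pt$p[pt$term == "pop_metric"],
                 dir_par = unname(fit$effect_direction["PAR"]),
                 dir_fdhw4 = unname(fit$effect_direction["fDHW4"]))
    })
    assign(key, do.call(rbind, rows), envir = .rp_cache)
  }
  get(key, envir = .rp_cache)
}
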