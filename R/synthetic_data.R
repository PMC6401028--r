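# Synthetic scenario generator: ENSO-modulated weekly SST regimes,
# severity-graded bleaching surveys, and disturbance-structured coral
# communities with the statistical structure the analysis pipeline assumes.

#' Default taxon susceptibility to heat stress
#'
#' Relative bleaching susceptibility in [0, 1]: high for *Acropora* and
#' *Pocillopora*, low for the stress-tolerant taxa (*Porites rus*, massive
#' *Porites*, *Heliopora*).
#' @return Named numeric vector over the coral taxa.
#' @export
default_susceptibility <- function() {
  c(Acropora = 1.0, Pocillopora = 0.9, Montipora = 0.6, Favia = 0.5,
    Favites = 0.5, Porites_branching = 0.4, Porites_massive = 0.2,
    Porites_rus = 0.15, Heliopora = 0.2, unidentified = 0.5)
}

#' Scenario configuration for the synthetic generator
#'
#' Bundles every knob of the synthetic study system. The defaults describe
#' an equatorial atoll chain: mean SST 29 C with a ~2 C seasonal range,
#' an AR(1) interannual (ENSO-like) SST component whose amplitude decays
#' away from the equator, planted heat-stress events in designated years,
#' an ordered-categorical bleaching response driven by event heat stress
#' (positive), winter light (positive) and historical heat-stress frequency
#' (negative, the thermal-history buffer), and Dirichlet-distributed coral
#' communities in which the weedy *Porites rus* share grows with the local
#' human-population metric.
#'
#' @param n_sites Number of sites (default 14).
#' @param n_atolls Number of atoll groups (default 3).
#' @param seed Integer seed; every random draw in the scenario flows from
#'   it (per-site substreams are derived deterministically).
#' @param ... Overrides for any default listed below.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 14L, n_atolls = 3L, seed = 1L, ...) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    n_atolls = as.integer(n_atolls),
    seed = as.integer(seed),
    # SST regime
    years = c(1985L, 2012L),
    baseline = c(1985L, 2009L),
    mean_sst = 29,
    seasonal_amplitude = 1,        # C; ~2 C annual range
    seasonal_peak_week = 15L,      # boreal spring peak
    # equatorial sites vary about twice as much year-to-year as seasonally:
    # AR(1) stationary sd = 2 x the seasonal sinusoid's sd (1/sqrt(2))
    enso_amplitude = 1.4,          # C, stationary sd of the AR(1) component
    enso_lat_scale = 2,            # e-folding of the amplitude in deg lat
    enso_annual_corr = 0.5,        # 1-year-lag autocorrelation of the AR(1)
    noise_sd = 0.25,               # C, white measurement noise
    event_years = c(2004L, 2009L),
    event_boost = 2,               # C added during planted events
    event_duration = 24L,          # weeks, starting 1 Dec of the event year
    # site geography: atoll latitude centers spanning the chain
    atoll_lats = c(0.9, 1.9, 3.0),
    lat_jitter = 0.4,
    # bleaching response (latent ordered-logit scale)
    beta_stress = 0.05,            # per C-week of event max DHW (weak)
    beta_par = 0.6,                # per unit of winter PAR anomaly
    beta_history = 8,              # per unit of fDHW4 (dominant buffer)
    par_ref = 30,                  # response reference PAR: the dose from
                                   # light stays positive over the realistic
                                   # winter range (see par_mean below)
    threshold_base = 2,            # first severity cutpoint (latent scale)
    threshold_step = 1,            # equal spacing of the remaining cutpoints
    severity_sdlog = 0.6,          # lognormal colony-frailty sd (log scale)
    susceptibility = default_susceptibility(),
    # survey design
    points_per_image = 50L,
    images_per_transect = 25L,
    coral_cover = 0.35,
    noncoral_shares = c(turf_algae = 0.35, sand = 0.25, macroalgae = 0.15,
                        cca = 0.1, rubble = 0.15),
    # community structure
    community_concentration = 300,
    community_base = c(Acropora = 0.18, Pocillopora = 0.12,
                       Montipora = 0.12, Favia = 0.08, Favites = 0.06,
                       Porites_branching = 0.12, Porites_massive = 0.12,
                       Porites_rus = 0.12, Heliopora = 0.08),
    pop_effect = 2,                # log-odds slope of P. rus weight
    # environment gradients: latitude trend + independent local variation
    par_mean = 40,                 # mol photons m-2 d-1, winter PAR level
    par_lat_slope = 1,             # winter PAR rise per deg |lat|
    par_noise_sd = 2.5,            # local cloudiness variation in PAR
    # human context: one atoll is the urbanized center
    village_pop_urban = c(4000, 12000),
    village_pop_rural = c(100, 900),
    coast_dist_km = c(0.5, 3))
  cfg <- modifyList(cfg, list(...))
  if (length(cfg$atoll_lats) != cfg$n_atolls) {
    cfg$atoll_lats <- seq(0.9, 3.0, length.out = cfg$n_atolls)
  }
  stopifnot(cfg$enso_amplitude >= 0, cfg$noise_sd >= 0,
            cfg$seasonal_amplitude >= 0, cfg$event_duration > 0,
            all(cfg$susceptibility >= 0 & cfg$susceptibility <= 1),
            all(cfg$community_base > 0))
  class(cfg) <- "scenario_config"
  cfg
}

site_substream <- function(cfg, i, stage = 0L) {
  (cfg$seed * 10007L + i * 97L + stage) %% 2147483647L
}

enso_sd_at <- function(cfg, lat) {
  cfg$enso_amplitude * exp(-abs(lat) / cfg$enso_lat_scale)
}

# unit-sd AR(1) weekly path with the configured 1-year lag correlation;
# drawn from the current RNG state
standard_ar_path <- function(cfg, n) {
  phi <- cfg$enso_annual_corr^(1 / 52)
  z <- numeric(n)
  z[1] <- rnorm(1)
  innov_sd <- sqrt(1 - phi^2)
  for (t in seq_len(n)[-1]) z[t] <- phi * z[t - 1] + rnorm(1, sd = innov_sd)
  z
}

#' Simulate a weekly SST series for one site
#'
#' Weekly SST = mean + seasonal sinusoid + AR(1) interannual component
#' (stationary sd set by the ENSO amplitude at the site's latitude, 1-year
#' lag correlation `enso_annual_corr`) + white noise + planted event boosts
#' (a constant warm anomaly for `event_duration` weeks starting 1 December
#' of each event year, so the anomaly spans the warm season). A fixed seed
#' gives bit-identical output.
#'
#' @param cfg A `scenario_config`.
#' @param lat Site latitude in decimal degrees.
#' @param site_id Site identifier.
#' @param seed Integer seed for this series.
#' @param ar_path Optional standardized (unit-sd) interannual anomaly path
#'   shared across sites; the basin-scale ENSO state is one process, so a
#'   multi-site scenario passes the same path to every site, scaled by the
#'   site's latitude-dependent amplitude. `NULL` draws a site-private path.
#' @return An `sst_series`.
#' @export
simulate_sst <- function(cfg, lat, site_id = "S01", seed = cfg$seed,
                         ar_path = NULL) {
  if (cfg$event_duration <= 0) stop_rp("event duration must be positive")
  weeks <- seq(as.Date(sprintf("%d-01-04", cfg$years[1])),
               as.Date(sprintf("%d-12-28", cfg$years[2])), by = 7L)
  n <- length(weeks)
  woy <- as.numeric(format(weeks, "%j")) / 7
  seasonal <- cfg$seasonal_amplitude *
    cos(2 * pi * (woy - cfg$seasonal_peak_week) / 52.18)

  set.seed(seed)
  sd_ar <- enso_sd_at(cfg, lat)
  if (is.null(ar_path)) ar_path <- standard_ar_path(cfg, n)
  if (length(ar_path) != n) stop_rp("ar_path length must match the series")
  ar <- sd_ar * ar_path
  noise <- if (cfg$noise_sd > 0) rnorm(n, sd = cfg$noise_sd) else numeric(n)

  boost <- numeric(n)
  for (y in cfg$event_years) {
    start <- as.Date(sprintf("%d-12-01", y))
    idx <- which(weeks >= start)[seq_len(cfg$event_duration)]
    idx <- idx[!is.na(idx)]
    boost[idx] <- boost[idx] + cfg$event_boost
  }

  sst_series(site_id, weeks, cfg$mean_sst + seasonal + ar + noise + boost,
             baseline = cfg$baseline)
}

severity_thresholds <- function(cfg) {
  cfg$threshold_base + cfg$threshold_step * (0:5)
}

severity_to_label <- function(sev) {
  states <- bleach_states()
  label <- ifelse(sev <= 2L, "coral_live",
                  ifelse(sev == 7L, "coral_recently_dead", "coral_bleached"))
  list(label = label, bleach_state = states[sev])
}

#' Simulate a photo-quadrat survey for one site
#'
#' Each point is benthic substrate or coral according to the configured
#' coral cover; coral points draw a taxon from the site's true community
#' and a bleaching severity from an ordered-categorical model: the latent
#' stress dose is the taxon susceptibility times the site-level score
#' `beta_stress * MaxDHW + beta_par * (PAR - par_ref) -
#' beta_history * fDHW4`, scaled per point by a lognormal colony frailty
#' and cut at equally spaced thresholds into the seven severity
#' categories. A site with a non-positive stress score shows no bleaching.
#'
#' @param cfg A `scenario_config`.
#' @param site_id,atoll,depth_band,year Survey identifiers.
#' @param max_dhw Event maximum DHW at the site (C-week).
#' @param par Boreal-winter PAR at the site.
#' @param fdhw4 Historical frequency of DHW > 4 years at the site.
#' @param community Named vector of true taxon shares (summing to 1).
#' @param seed Integer seed.
#' @return A `survey_dataset` for one transect.
#' @export
simulate_survey <- function(cfg, site_id, atoll, max_dhw, par, fdhw4,
                            community, depth_band = "shallow_3_5m",
                            year = 2010L, seed = cfg$seed) {
  if (length(community) == 0L || abs(sum(community) - 1) > 1e-9) {
    stop_rp("true community shares must be non-empty and sum to 1")
  }
  set.seed(seed)
  n_pts <- cfg$points_per_image * cfg$images_per_transect
  ncs <- cfg$noncoral_shares / sum(cfg$noncoral_shares) *
    (1 - cfg$coral_cover)
  cat_probs <- c(coral = cfg$coral_cover, ncs)
  draw <- sample(names(cat_probs), n_pts, replace = TRUE, prob = cat_probs)

  label <- draw
  taxon <- rep(NA_character_, n_pts)
  state <- rep(NA_character_, n_pts)
  is_coral <- draw == "coral"
  n_coral <- sum(is_coral)
  if (n_coral > 0L) {
    tx <- sample(names(community), n_coral, replace = TRUE,
                 prob = community)
    eta_site <- cfg$beta_stress * max_dhw +
      cfg$beta_par * (par - cfg$par_ref) - cfg$beta_history * fdhw4
    eta <- cfg$susceptibility[tx] * eta_site
    # multiplicative colony frailty: a zero stress dose stays zero, so an
    # unstressed site shows no bleaching at all
    latent <- eta * exp(rnorm(n_coral, 0, cfg$severity_sdlog))
    sev <- 1L + rowSums(outer(latent, severity_thresholds(cfg), `>`))
    mapped <- severity_to_label(sev)
    label[is_coral] <- mapped$label
    taxon[is_coral] <- tx
    state[is_coral] <- mapped$bleach_state
  }
  records <- data.frame(
    site_id = site_id, atoll = atoll, depth_band = depth_band,
    year = as.integer(year), transect = "T1",
    image = rep(seq_len(cfg$images_per_transect),
                each = cfg$points_per_image),
    point = rep(seq_len(cfg$points_per_image), cfg$images_per_transect),
    label = label, taxon = taxon, bleach_state = state,
    stringsAsFactors = FALSE)
  new_survey_dataset(validate_survey_records(records),
                     cfg$points_per_image, cfg$images_per_transect)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  setNames(g / sum(g), names(alpha))
}

#' Simulate a complete multi-site scenario
#'
#' Emits a full study system: site geography with latitude-structured
#' ENSO amplitude, per-site weekly SST (1985-2012 span with planted
#' 2004 and 2009 heat-stress events), derived thermal metrics, a village
#' table and the standardized population metric, true coral communities
#' with the planted population effect on the *Porites rus* share,
#' photo-quadrat surveys of the post-event year, and the true-parameter
#' record needed for recovery tests.
#'
#' @param cfg A `scenario_config` (its `seed` drives everything).
#' @return List with `surveys` (one pooled `survey_dataset`), `sst` (named
#'   list of `sst_series`), `site_table` (per-site predictors incl.
#'   thermal metrics, PAR, chl a, wave height, exposure, `pop_metric`,
#'   `RA_POR`), `villages`, `communities` (true shares), `truth`
#'   (generator parameters), `event_window`.
#' @export
simulate_site_set <- function(cfg = scenario_config()) {
  if (cfg$n_sites < 4L) stop_rp("a scenario needs >= 4 sites")
  set.seed(cfg$seed)
  i <- seq_len(cfg$n_sites)
  atoll_idx <- rep(seq_len(cfg$n_atolls), length.out = cfg$n_sites)
  atoll <- paste0("ATL", atoll_idx)
  site_id <- sprintf("S%02d", i)
  lat <- cfg$atoll_lats[atoll_idx] +
    runif(cfg$n_sites, -cfg$lat_jitter, cfg$lat_jitter)
  long <- 173 + 0.2 * atoll_idx + runif(cfg$n_sites, -0.1, 0.1)

  # villages: the first atoll is the urbanized center
  urban <- atoll_idx == 1L
  pop <- ifelse(urban,
                runif(cfg$n_sites, cfg$village_pop_urban[1],
                      cfg$village_pop_urban[2]),
                runif(cfg$n_sites, cfg$village_pop_rural[1],
                      cfg$village_pop_rural[2]))
  villages <- data.frame(
    site_id = site_id, village_id = sprintf("V%02d", i),
    population = round(pop),
    coast_dist_km = round(runif(cfg$n_sites, cfg$coast_dist_km[1],
                                cfg$coast_dist_km[2]), 2))
  pop_tab <- population_metric(villages)

  # environment: winter light rises and chlorophyll falls away from the
  # equator in this system
  par_w <- cfg$par_mean + cfg$par_lat_slope * (abs(lat) - 2) +
    rnorm(cfg$n_sites, sd = cfg$par_noise_sd)
  chl <- pmax(0.05, 0.4 - 0.06 * abs(lat) + rnorm(cfg$n_sites, sd = 0.03))
  chl_avg <- pmax(0.05, chl + rnorm(cfg$n_sites, sd = 0.02))
  waveh <- pmax(0.4, 1.1 + 0.12 * abs(lat) + rnorm(cfg$n_sites, sd = 0.1))
  expos <- sample(1:4, cfg$n_sites, replace = TRUE)

  # one basin-scale ENSO realization shared by every site
  set.seed(site_substream(cfg, 0L, 4L))
  n_weeks <- length(seq(as.Date(sprintf("%d-01-04", cfg$years[1])),
                        as.Date(sprintf("%d-12-28", cfg$years[2])),
                        by = 7L))
  enso_path <- standard_ar_path(cfg, n_weeks)
  sst <- lapply(i, function(j) {
    simulate_sst(cfg, lat[j], site_id[j],
                 seed = site_substream(cfg, j, 1L), ar_path = enso_path)
  })
  names(sst) <- site_id
  event_window <- as.Date(c(sprintf("%d-11-01", max(cfg$event_years)),
                            sprintf("%d-06-30", max(cfg$event_years) + 1L)))
  thermal <- climate_metric_table(sst, event_window)

  # true communities: P. rus Dirichlet weight tilted by the population
  # metric on the log scale (centered so the average site is unchanged)
  pm <- pop_tab$pop_metric[match(site_id, pop_tab$site_id)]
  communities <- lapply(i, function(j) {
    w <- cfg$community_base
    w["Porites_rus"] <- w["Porites_rus"] * exp(cfg$pop_effect * (pm[j] - 1))
    w <- w / sum(w)
    set.seed(site_substream(cfg, j, 2L))
    rdirichlet1(cfg$community_concentration * w)
  })
  names(communities) <- site_id

  surveys <- lapply(i, function(j) {
    th <- thermal[thermal$site_id == site_id[j], ]
    simulate_survey(cfg, site_id[j], atoll[j], max_dhw = th$MaxDHW_event,
                    par = par_w[j], fdhw4 = th$fDHW4,
                    community = communities[[j]],
                    year = max(cfg$event_years) + 1L,
                    seed = site_substream(cfg, j, 3L))
  })
  pooled <- new_survey_dataset(
    do.call(rbind, lapply(surveys, `[[`, "records")),
    cfg$points_per_image, cfg$images_per_transect)

  env <- data.frame(site_id = site_id, atoll = atoll, lat = lat,
                    long = long, depth = 4, PAR = par_w, chl_a = chl,
                    chl_a_avg = chl_avg, waveh = waveh, expos = expos)
  ts <- taxon_summaries(pooled)
  site_table <- assemble_site_table(env, thermal = thermal,
                                    ra_por = ts$ra_por, pop = pop_tab)

  list(surveys = pooled, sst = sst, site_table = site_table,
       villages = villages, communities = communities,
       truth = list(beta_stress = cfg$beta_stress,
                    beta_par = cfg$beta_par,
                    beta_history = cfg$beta_history,
                    pop_effect = cfg$pop_effect,
                    susceptibility = cfg$susceptibility,
                    lat = setNames(lat, site_id),
                    enso_sd = setNames(enso_sd_at(cfg, lat), site_id)),
       event_window = event_window)
}
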