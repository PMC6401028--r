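# Human-disturbance population metric and the joined per-site predictor
# table.

#' Population metric of local human disturbance
#'
#' For each site the raw metric is the sum over the designated closest
#' village(s) of village population divided by the along-coast distance to
#' the site (persons per km). The metric is then standardized by dividing by
#' its mean across all sites, so the standardized values average exactly 1.
#'
#' @param villages A data.frame with columns `site_id, village_id,
#'   population, coast_dist_km`, listing the closest village(s) of each
#'   site (one row per site-village pair).
#' @param standardize If `TRUE` (default), divide by the across-site mean.
#' @return A data.frame with columns `site_id, pop_raw, pop_metric`
#'   (`pop_metric` absent when `standardize = FALSE`).
#' @export
population_metric <- function(villages, standardize = TRUE) {
  assert_cols(villages, c("site_id", "village_id", "population",
                          "coast_dist_km"), "village table")
  if (any(villages$population < 0)) stop_rp("negative village population")
  if (any(villages$coast_dist_km <= 0)) {
    stop_rp("coastline distance must be > 0 km")
  }
  raw <- tapply(villages$population / villages$coast_dist_km,
                villages$site_id, sum)
  out <- data.frame(site_id = names(raw), pop_raw = as.numeric(raw),
                    row.names = NULL)
  if (standardize) {
    if (nrow(out) < 2L) {
      stop_rp("standardization needs >= 2 sites, found %d", nrow(out))
    }
    out$pop_metric <- out$pop_raw / mean(out$pop_raw)
  }
  out
}

#' Assemble the per-site predictor table
#'
#' Joins the site environment table (light, chlorophyll, wave height,
#' exposure, position, depth) with thermal metrics, coral-community
#' relative-abundance summaries, and the population metric into one row per
#' site (or site x depth band). Sites present in only some sources are kept
#' with explicit `NA`s and listed in a join report attribute; with
#' `strict = TRUE` they are an error.
#'
#' @param env Data.frame of site environment values; must contain `site_id`
#'   and typically `lat, long, depth, PAR, chl_a, chl_a_avg, waveh, expos`.
#'   Duplicate `site_id` (for a shared `depth_band`, when present) is an
#'   error.
#' @param thermal Optional data.frame from [climate_metric_table()].
#' @param ra_por Optional data.frame with `site_id` and `RA_POR` (see
#'   [taxon_summaries()]); a `depth_band` column is honoured if `env` has
#'   one.
#' @param pop Optional data.frame from [population_metric()].
#' @param strict If `TRUE`, any site missing from a supplied source is an
#'   error.
#' @return A data.frame, one row per site (x depth band), with attribute
#'   `join_report` listing site ids absent from each source.
#' @export
assemble_site_table <- function(env, thermal = NULL, ra_por = NULL,
                                pop = NULL, strict = FALSE) {
  assert_cols(env, "site_id", "environment table")
  key_cols <- intersect(c("site_id", "depth_band"), names(env))
  if (anyDuplicated(env[key_cols])) {
    stop_rp("duplicate site_id in environment table")
  }
  if (any(!is.na(env$expos %||% NA) & !(env$expos %in% 1:4))) {
    stop_rp("exposure class must be an integer 1-4")
  }
  out <- env
  report <- list()
  join_one <- function(tbl, name, by) {
    by <- intersect(by, intersect(names(out), names(tbl)))
    miss <- setdiff(unique(out$site_id), unique(tbl$site_id))
    if (length(miss)) {
      if (strict) stop_rp("site(s) missing from %s: %s", name,
                          paste(miss, collapse = ", "))
      report[[name]] <<- miss
    }
    merge(out, tbl, by = by, all.x = TRUE, sort = FALSE)
  }
  if (!is.null(thermal)) out <- join_one(thermal, "thermal", "site_id")
  if (!is.null(ra_por)) {
    out <- join_one(ra_por[, intersect(c("site_id", "depth_band", "year",
                                         "RA_POR"), names(ra_por))],
                    "ra_por", c("site_id", "depth_band"))
  }
  if (!is.null(pop)) {
    out <- join_one(pop[, c("site_id", "pop_metric")], "population",
                    "site_id")
  }
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "join_report") <- report
  out
}
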