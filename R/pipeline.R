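# Pipeline orchestration: run every analysis stage from a config, write
# per-stage tables, and record a reproducible run manifest.

default_pipeline_config <- function() {
  list(
    simulate = NULL,              # scenario_config overrides, or NULL
    inputs = NULL,                # list(point_counts=, sst=, environment=,
                                  #      villages=) file paths
    event_window = NULL,          # c(start, end); inferred when simulating
    screen_predictors = c("MaxDHW_event", "MaxSST_event", "WkDHW4",
                          "WkDHW8", "PAR", "CV_SST", "sigma_mon",
                          "sigma_wk", "MaxSST_avg", "MMM", "MaxDHW_avg",
                          "WkDHW4_avg", "WkDHW8_avg", "fDHW4", "fDHW8",
                          "depth", "chl_a", "chl_a_avg", "expos", "waveh",
                          "RA_POR", "lat", "long"),
    permanova_terms = c("pop_metric", "fDHW4", "CV_SST", "chl_a"),
    n_perm = 999L,
    nmds_restarts = 20L,
    min_share = 0.005,
    sufficiency = list(n_reps = 1000L, top_k = 4L, cv_threshold = 0.25))
}

read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  modifyList(default_pipeline_config(), cfg %||% list())
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data ingestion (or synthetic-scenario generation),
#' benthic cover and BRI computation, thermal metric derivation, site-table
#' assembly, Bonferroni-screened univariate regressions, GAM/GLM fitting
#' and comparison, Bray-Curtis NMDS, sequential PERMANOVA, and the Monte
#' Carlo image-sufficiency analysis. Each stage's table is written to
#' `out_dir` as delimited text and a YAML run manifest records the config
#' snapshot, seed, input digests, package version and stage outputs.
#'
#' @param config A list or path to a YAML file. Supply either a `simulate`
#'   stanza (overrides for [scenario_config()]) or an `inputs` stanza with
#'   file paths `point_counts`, `sst`, `environment`, `villages` (and an
#'   `event_window`).
#' @param out_dir Output directory (created; must be empty or absent —
#'   stage outputs are write-once per run).
#' @param seed Integer seed applied to every stochastic stage.
#' @param quiet Suppress progress messages.
#' @return The run manifest, invisibly; all stage results are in the
#'   `results` element.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("reefpulse_run"),
                         seed = 1L, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop_rp("config must contain a 'simulate' stanza or an 'inputs' stanza")
  }
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stop_rp("output directory %s exists and is not empty", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(
                     utils::packageVersion("reefpulse")),
                   seed = as.integer(seed), config = cfg,
                   outputs = list(), input_digests = list(),
                   warnings = character())
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e) {
      stop_rp("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write_rp_table(as.data.frame(df), path)
    manifest$outputs[[name]] <<- path
    path
  }
  results <- list()

  # -- ingest / simulate ----------------------------------------------------
  if (!is.null(cfg$simulate)) {
    scen <- stage("simulate", {
      do.call(scenario_config, modifyList(list(seed = as.integer(seed)),
                                          cfg$simulate))
    })
    world <- stage("simulate", simulate_site_set(scen))
    ds <- world$surveys
    sst <- world$sst
    site_table <- world$site_table
    event_window <- world$event_window
    results$truth <- world$truth
    emit(ds$records, "point_counts")
  } else {
    inp <- cfg$inputs
    for (f in c("point_counts", "sst", "environment", "villages")) {
      if (is.null(inp[[f]])) stop_rp("inputs stanza is missing '%s'", f)
      manifest$input_digests[[f]] <- unname(tools::md5sum(inp[[f]]))
    }
    if (is.null(cfg$event_window)) {
      stop_rp("config must give event_window when reading field inputs")
    }
    event_window <- as.Date(unlist(cfg$event_window))
    ds <- stage("ingest", read_point_counts(inp$point_counts))
    sst <- stage("ingest", read_sst_series(inp$sst))
    env <- stage("ingest", read_rp_table(inp$environment))
    villages <- stage("ingest", read_rp_table(inp$villages))
    thermal <- stage("climate", climate_metric_table(sst, event_window))
    ts <- taxon_summaries(ds)
    pop <- population_metric(villages)
    site_table <- stage("site_table",
                        assemble_site_table(env, thermal = thermal,
                                            ra_por = ts$ra_por, pop = pop))
  }

  # -- cover, community, BRI ------------------------------------------------
  cover <- stage("cover", compute_cover(ds, detail = "label_taxon"))
  results$cover <- cover
  emit(cover, "cover")
  comm <- stage("community", build_community_matrix(cover,
                                                    min_share = cfg$min_share))
  results$community <- comm
  emit(data.frame(row_id = rownames(comm), comm, check.names = FALSE),
       "community_matrix")
  bri <- stage("bri", bri_table(ds))
  results$bri <- bri
  emit(bri, "bri")
  emit(stage("climate", site_table), "site_table")
  results$site_table <- site_table

  # -- univariate screen ----------------------------------------------------
  model_tab <- merge(bri[bri$depth_band == bri$depth_band[1], ],
                     site_table, by = c("site_id", "depth_band"),
                     all.x = TRUE)
  preds <- intersect(cfg$screen_predictors, names(model_tab))
  screen <- stage("screen", {
    univariate_screen(model_tab$bri, model_tab[preds])
  })
  results$screen <- screen
  emit(screen, "univariate_screen")

  # -- GAM / GLM comparison -------------------------------------------------
  models <- stage("models", {
    fits <- list(
      par_fdhw4 = fit_response_model(model_tab, "bri",
                                     smooth = c("PAR", "fDHW4")),
      history_chl = fit_response_model(model_tab, "bri",
                                       smooth = c("CV_SST", "fDHW4",
                                                  "chl_a")),
      glm_interaction = fit_response_model(model_tab, "bri",
                                           linear = c("PAR", "fDHW4"),
                                           interaction = c("PAR", "fDHW4")))
    list(fits = fits,
         comparison = compare_models(fits,
                                     nested_pairs = list(c("par_fdhw4",
                                                           "glm_interaction"))))
  })
  results$models <- models
  emit(models$comparison$ranking, "model_ranking")

  # -- ordination and PERMANOVA --------------------------------------------
  bc <- stage("nmds", bray_curtis(comm))
  ord <- stage("nmds", nmds(bc, n_restarts = cfg$nmds_restarts,
                            seed = seed))
  results$nmds <- ord
  emit(data.frame(row_id = rownames(ord$points),
                  NMDS1 = ord$points[, 1], NMDS2 = ord$points[, 2],
                  stress = ord$stress), "nmds")

  # PERMANOVA rows are sites; community rows may be site|depth|year keys
  perm_data <- site_table[match(sub("\\|.*$", "", rownames(comm)),
                                site_table$site_id), , drop = FALSE]
  terms <- intersect(cfg$permanova_terms, names(perm_data))
  degenerate <- terms[vapply(terms, function(v) {
    length(unique(perm_data[[v]])) <= 1L
  }, logical(1))]
  if (length(degenerate)) {
    manifest$warnings <- c(manifest$warnings,
                           sprintf("PERMANOVA term(s) dropped as constant: %s",
                                   paste(degenerate, collapse = ", ")))
    terms <- setdiff(terms, degenerate)
  }
  perm <- stage("permanova", permanova(bc, perm_data, terms,
                                       n_perm = cfg$n_perm, seed = seed))
  results$permanova <- perm
  emit(perm, "permanova")

  # -- sampling sufficiency -------------------------------------------------
  suff <- stage("sufficiency", {
    r1 <- ds$records
    first <- r1[r1$site_id == r1$site_id[1] &
                  r1$depth_band == r1$depth_band[1] &
                  r1$year == r1$year[1] &
                  r1$transect == r1$transect[1], , drop = FALSE]
    one <- new_survey_dataset(first, ds$points_per_image,
                              ds$images_per_transect)
    curve <- cover_cv_curve(one, n_reps = cfg$sufficiency$n_reps,
                            top_k = cfg$sufficiency$top_k, seed = seed)
    list(curve = curve,
         minimal = minimal_images(curve, cfg$sufficiency$cv_threshold))
  })
  results$sufficiency <- suff
  emit(suff$curve, "sufficiency_curve")

  manifest$results <- results
  yaml::write_yaml(
    manifest[c("package_version", "seed", "config", "outputs",
               "input_digests", "warnings")],
    file.path(out_dir, "manifest.yml"))
  manifest$out_dir <- out_dir
  say("pipeline complete: %s", out_dir)
  invisible(manifest)
}
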