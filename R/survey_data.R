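# Photo-quadrat point-count surveys: data model, reader, cover and
# community computations.

new_survey_dataset <- function(records, points_per_image = 50L,
                               images_per_transect = 25L) {
  structure(
    list(records = records,
         points_per_image = as.integer(points_per_image),
         images_per_transect = as.integer(images_per_transect)),
    class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<survey_dataset> %d point records | %d site(s), %d transect(s)\n",
    nrow(r), length(unique(r$site_id)),
    nrow(unique(r[c("site_id", "depth_band", "year", "transect")]))))
  cat(sprintf("  design: %d points/image x %d images/transect\n",
              x$points_per_image, x$images_per_transect))
  invisible(x)
}

survey_record_cols <- function() {
  c("site_id", "atoll", "depth_band", "year", "transect",
    "image", "point", "label", "taxon", "bleach_state")
}

validate_survey_records <- function(records) {
  assert_cols(records, survey_record_cols(), "point-count table")
  records$year <- as.integer(records$year)
  records$image <- as.integer(records$image)
  records$point <- as.integer(records$point)
  for (col in c("taxon", "bleach_state")) {
    records[[col]][!is.na(records[[col]]) & records[[col]] == ""] <- NA
  }

  bad_label <- !(records$label %in% benthic_labels())
  if (any(bad_label)) {
    offending <- unique(records$label[bad_label])
    stop_rp("unknown benthic label(s): %s (rows %s)",
            paste(offending, collapse = ", "),
            paste(head(which(bad_label), 10L), collapse = ", "))
  }
  bad_state <- !is.na(records$bleach_state) &
    !(records$bleach_state %in% bleach_states())
  if (any(bad_state)) {
    stop_rp("unknown bleach state(s): %s (rows %s)",
            paste(unique(records$bleach_state[bad_state]), collapse = ", "),
            paste(head(which(bad_state), 10L), collapse = ", "))
  }

  scoreable <- records$label %in% bleach_scoreable_labels()
  extra <- !scoreable & !is.na(records$bleach_state)
  if (any(extra)) {
    stop_rp("bleach_state given for non-coral label at row(s) %s",
            paste(head(which(extra), 10L), collapse = ", "))
  }
  missing_state <- scoreable & is.na(records$bleach_state)
  if (any(missing_state)) {
    stop_rp("coral point without bleach_state at row(s) %s",
            paste(head(which(missing_state), 10L), collapse = ", "))
  }

  coral <- records$label %in% coral_labels()
  records$taxon[coral & is.na(records$taxon)] <- "unidentified"
  bad_taxon <- coral & !(records$taxon %in% coral_taxa())
  if (any(bad_taxon)) {
    stop_rp("unknown coral taxon/taxa: %s",
            paste(unique(records$taxon[bad_taxon]), collapse = ", "))
  }

  key <- paste(records$site_id, records$depth_band, records$year,
               records$transect, records$image, records$point)
  if (anyDuplicated(key)) {
    stop_rp("duplicate point index within image at row(s) %s",
            paste(head(which(duplicated(key)), 10L), collapse = ", "))
  }
  records
}

#' Read a photo-quadrat point-count table
#'
#' Reads a long-format delimited text file (comma default, tab accepted) with
#' one row per scored point and validates it against the controlled benthic
#' vocabulary: unknown labels, bleach states on non-coral points, and
#' duplicate point indices are hard errors naming the offending rows.
#'
#' @param path Path to the delimited file. A header row is required with
#'   columns `site_id, atoll, depth_band, year, transect, image, point,
#'   label, taxon, bleach_state` (or names mapped through `schema`).
#' @param schema Optional named character vector mapping the canonical column
#'   names to the file's column names, e.g. `c(site_id = "Site")`.
#' @param points_per_image,images_per_transect Survey design constants
#'   (defaults 50 points in each of 25 images per transect).
#' @param sep Field separator; `NULL` auto-detects comma vs tab.
#' @return A `survey_dataset` object.
#' @export
read_point_counts <- function(path, schema = NULL, points_per_image = 50L,
                              images_per_transect = 25L, sep = NULL) {
  df <- read_rp_table(path, sep = sep)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df)) {
        stop_rp("schema maps %s to missing column %s", canon, schema[[canon]])
      }
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  records <- validate_survey_records(df)
  new_survey_dataset(records, points_per_image, images_per_transect)
}

#' Write a survey dataset back to delimited text
#'
#' @param ds A `survey_dataset`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_point_counts <- function(ds, path, sep = ",") {
  write_rp_table(ds$records[survey_record_cols()], path, sep = sep)
}

group_key <- function(records) {
  paste(records$site_id, records$depth_band, records$year, sep = "|")
}

#' Compute benthic cover from point counts
#'
#' Cover is computed on the pooled transect for each site / depth band /
#' year group: the fraction of all scored points falling in each benthic
#' category. All categories of the controlled vocabulary are reported, with
#' zero-count categories included as 0, so fractions over the mutually
#' exclusive categories sum to one within each group.
#'
#' @param ds A `survey_dataset`.
#' @param detail `"label"` (default) reports the benthic labels as-is;
#'   `"label_taxon"` additionally splits coral labels by taxon, producing
#'   categories such as `coral_live:Acropora` (needed to build a taxon
#'   community matrix).
#' @param by_transect If `TRUE`, compute per replicate transect instead of
#'   pooling the whole group (non-default; pooled cover is the standard).
#' @return A data.frame with columns `site_id, depth_band, year`
#'   (and `transect` if `by_transect`), `category`, `cover`, `n_points`.
#' @export
compute_cover <- function(ds, detail = c("label", "label_taxon"),
                          by_transect = FALSE) {
  detail <- match.arg(detail)
  r <- ds$records
  if (nrow(r) == 0L) stop_rp("empty survey dataset")
  cat_col <- if (detail == "label") {
    r$label
  } else {
    ifelse(r$label %in% coral_labels(),
           paste(r$label, r$taxon, sep = ":"), r$label)
  }
  grp <- if (by_transect) paste(group_key(r), r$transect, sep = "|") else
    group_key(r)
  out <- list()
  for (g in unique(grp)) {
    idx <- grp == g
    n <- sum(idx)
    tab <- table(cat_col[idx])
    cats <- sort(unique(c(names(tab),
                          if (detail == "label") benthic_labels())))
    cover <- as.numeric(tab[cats]) / n
    cover[is.na(cover)] <- 0
    meta <- r[idx, c("site_id", "depth_band", "year"), drop = FALSE][1, ]
    block <- data.frame(meta, row.names = NULL)
    if (by_transect) block$transect <- r$transect[idx][1]
    block <- block[rep(1L, length(cats)), , drop = FALSE]
    block$category <- cats
    block$cover <- cover
    block$n_points <- n
    out[[g]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a coral community matrix of relative abundances
#'
#' Converts a taxon-detailed cover table into a sites-by-taxa matrix of each
#' taxon's share of live coral. Rare taxa whose share of the total live-coral
#' observations pooled across all rows does not exceed `min_share` are
#' dropped, and rows are renormalized to sum to one. The applied threshold is
#' recorded as an attribute.
#'
#' @param cover A cover table from [compute_cover()] with
#'   `detail = "label_taxon"`.
#' @param min_share Pooled-share threshold below or at which a taxon is
#'   dropped (default 0.005, i.e. keep taxa representing more than 0.5% of
#'   live-coral observations).
#' @param by `"site_depth_year"` (default) keeps one row per group;
#'   `"site"` pools depth bands and years per site.
#' @return A numeric matrix with row labels identifying the group and
#'   alphabetically ordered taxon columns; attributes `min_share` and
#'   `empty_rows` (labels of groups with no live coral, whose rows are all
#'   zero).
#' @export
build_community_matrix <- function(cover, min_share = 0.005,
                                   by = c("site_depth_year", "site")) {
  by <- match.arg(by)
  live <- cover[grepl("^coral_live:", cover$category), , drop = FALSE]
  if (nrow(live) == 0L) stop_rp("cover table contains no live coral")
  live$taxon <- sub("^coral_live:", "", live$category)
  live$points <- live$cover * live$n_points
  live$row_id <- if (by == "site") live$site_id else
    paste(live$site_id, live$depth_band, live$year, sep = "|")

  counts <- tapply(live$points, list(live$row_id, live$taxon), sum,
                   default = 0)
  counts <- counts[, sort(colnames(counts)), drop = FALSE]
  if (sum(counts) <= 0) stop_rp("no live coral observations anywhere")

  pooled_share <- colSums(counts) / sum(counts)
  keep <- pooled_share > min_share
  if (!any(keep)) stop_rp("rare-taxon filter removed every taxon")
  counts <- counts[, keep, drop = FALSE]

  rs <- rowSums(counts)
  empty <- rs <= 0
  shares <- counts
  shares[!empty, ] <- counts[!empty, , drop = FALSE] / rs[!empty]
  shares[empty, ] <- 0
  m <- as.matrix(shares)
  attr(m, "min_share") <- min_share
  attr(m, "empty_rows") <- rownames(m)[empty]
  m
}

#' Per-site taxon summaries: live fractions and Porites relative abundance
#'
#' For each site / depth band / year group, computes the fraction of each
#' taxon's coral-derived points (live, bleached, recently dead, turf-covered
#' dead, CCA-covered dead) that are alive, and the relative abundance of
#' stress-tolerant *Porites* (massive *Porites* plus *Porites rus*) within
#' the live coral community (`RA_POR`).
#'
#' @param ds A `survey_dataset`.
#' @return A list with `live_fraction` (data.frame site_id, depth_band,
#'   year, taxon, live_fraction, n_coral_points; `live_fraction` is `NA`
#'   when a taxon has no coral points in the group) and `ra_por`
#'   (data.frame site_id, depth_band, year, RA_POR).
#' @export
taxon_summaries <- function(ds) {
  r <- ds$records
  coral <- r[r$label %in% coral_labels(), , drop = FALSE]
  if (nrow(coral) == 0L) stop_rp("dataset contains no coral points")
  coral$grp <- group_key(coral)

  lf <- list()
  ra <- list()
  for (g in unique(coral$grp)) {
    cg <- coral[coral$grp == g, , drop = FALSE]
    meta <- cg[1, c("site_id", "depth_band", "year"), drop = FALSE]
    taxa <- sort(unique(cg$taxon))
    n_tax <- vapply(taxa, function(t) sum(cg$taxon == t), numeric(1))
    n_live <- vapply(taxa, function(t)
      sum(cg$taxon == t & cg$label == "coral_live"), numeric(1))
    frac <- ifelse(n_tax > 0, n_live / n_tax, NA_real_)
    lf[[g]] <- data.frame(meta, taxon = taxa, live_fraction = frac,
                          n_coral_points = n_tax, row.names = NULL)
    live <- cg[cg$label == "coral_live", , drop = FALSE]
    ra_por <- if (nrow(live) == 0L) NA_real_ else
      sum(live$taxon %in% c("Porites_massive", "Porites_rus")) / nrow(live)
    ra[[g]] <- data.frame(meta, RA_POR = ra_por, row.names = NULL)
  }
  lf <- do.call(rbind, lf); rownames(lf) <- NULL
  ra <- do.call(rbind, ra); rownames(ra) <- NULL
  list(live_fraction = lf, ra_por = ra)
}
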