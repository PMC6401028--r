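# Monte Carlo analysis of how many photo-quadrat images are needed for a
# stable cover estimate.

#' Monte Carlo cover-variability curve over image subsample sizes
#'
#' For each subsample size n, draws n images (without replacement by
#' default) from a transect's image set `n_reps` times, computes the
#' percent cover of all live coral and of the `top_k` most common coral
#' taxa from the pooled points of the drawn images, and summarizes each
#' category's variability as the coefficient of variation (sample sd /
#' mean) of the replicate estimates. The most common taxa are determined
#' from the full image set before any resampling.
#'
#' @param ds A `survey_dataset` restricted to a single site / depth band /
#'   year / transect (an error otherwise).
#' @param n_range Integer vector of subsample sizes (default 1 to the
#'   number of available images; values beyond availability are dropped).
#' @param n_reps Replicates per subsample size (default 1000, minimum 2).
#' @param top_k Number of most common coral taxa tracked in addition to
#'   total live coral (default 4).
#' @param replace Sample images with replacement (default `FALSE`; without
#'   replacement the CV at n = all images is exactly 0).
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   output.
#' @return A data.frame of class `rp_sufficiency` with columns
#'   `category, n_images, cv` (`cv` is `NA` where the mean estimate is 0);
#'   attributes `n_reps`, `seed`, `replace`.
#' @export
cover_cv_curve <- function(ds, n_range = NULL, n_reps = 1000L, top_k = 4L,
                           replace = FALSE, seed = NULL) {
  if (n_reps < 2L) stop_rp("n_reps must be >= 2")
  r <- ds$records
  if (nrow(unique(r[c("site_id", "depth_band", "year", "transect")])) != 1L) {
    stop_rp("cover_cv_curve expects a single transect")
  }
  images <- sort(unique(r$image))
  n_img <- length(images)
  n_range <- sort(unique(as.integer(n_range %||% seq_len(n_img))))
  n_range <- n_range[n_range >= 1L & n_range <= n_img]
  if (!length(n_range)) stop_rp("n_range contains no feasible sizes")

  live <- r$label == "coral_live"
  taxon_counts <- sort(table(r$taxon[live]), decreasing = TRUE)
  top_taxa <- names(head(taxon_counts, top_k))
  categories <- c("live_coral", top_taxa)

  # per-image category counts and totals, so a draw is a row sum
  img_idx <- match(r$image, images)
  counts <- matrix(0, n_img, length(categories),
                   dimnames = list(NULL, categories))
  counts[, "live_coral"] <- tabulate(img_idx[live], n_img)
  for (t in top_taxa) {
    counts[, t] <- tabulate(img_idx[live & r$taxon == t], n_img)
  }
  pts_per_img <- tabulate(img_idx, n_img)

  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (n in n_range) {
    est <- matrix(0, n_reps, length(categories))
    for (rep in seq_len(n_reps)) {
      draw <- sample.int(n_img, n, replace = replace)
      est[rep, ] <- 100 * colSums(counts[draw, , drop = FALSE]) /
        sum(pts_per_img[draw])
    }
    mu <- colMeans(est)
    cv <- ifelse(mu > 0, apply(est, 2L, sd) / mu, NA_real_)
    rows[[as.character(n)]] <- data.frame(
      category = categories, n_images = n, cv = cv, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "replace") <- replace
  class(out) <- c("rp_sufficiency", "data.frame")
  out
}

#' Smallest image count with all categories below a CV threshold
#'
#' @param curve Output of [cover_cv_curve()].
#' @param cv_threshold CV threshold (default 0.25).
#' @return List with `n` (smallest qualifying image count, `NA` if the
#'   threshold is never reached) and `reached` (logical).
#' @export
minimal_images <- function(curve, cv_threshold = 0.25) {
  ns <- sort(unique(curve$n_images))
  for (n in ns) {
    cvs <- curve$cv[curve$n_images == n]
    if (all(is.na(cvs) | cvs < cv_threshold)) {
      return(list(n = n, reached = TRUE))
    }
  }
  list(n = NA_integer_, reached = FALSE)
}
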