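# Bleaching Response Index (BRI): severity tallies and the weighted index.

#' Tally bleaching-severity categories
#'
#' Counts scored coral points (live, bleached, recently dead) in each of the
#' seven ordered severity categories — normal, pale, 0–20%, 20–50%, 50–80%,
#' 80–100% bleached, recently dead — and returns the proportions.
#'
#' @param ds A `survey_dataset`.
#' @param site,depth_band,year,taxon Optional scope filters; `NULL` pools
#'   over the corresponding dimension (`taxon = NULL` means all corals).
#' @return A `bleach_tally`: list with `c` (named numeric vector of 7
#'   proportions summing to one), `n` (number of scored points) and `scope`.
#' @export
tally_bleach_states <- function(ds, site = NULL, depth_band = NULL,
                                year = NULL, taxon = NULL) {
  r <- ds$records
  keep <- !is.na(r$bleach_state)
  if (!is.null(site)) keep <- keep & r$site_id %in% site
  if (!is.null(depth_band)) keep <- keep & r$depth_band %in% depth_band
  if (!is.null(year)) keep <- keep & r$year %in% year
  if (!is.null(taxon)) keep <- keep & r$taxon %in% taxon
  scope <- list(site = site, depth_band = depth_band, year = year,
                taxon = taxon %||% "all")
  if (!any(keep)) {
    stop_rp("no scored coral points in scope [site=%s depth=%s year=%s taxon=%s]",
            paste(site %||% "all", collapse = ","),
            paste(depth_band %||% "all", collapse = ","),
            paste(year %||% "all", collapse = ","),
            paste(taxon %||% "all", collapse = ","))
  }
  states <- factor(r$bleach_state[keep], levels = bleach_states())
  counts <- table(states)
  n <- sum(counts)
  structure(list(c = setNames(as.numeric(counts) / n, bleach_states()),
                 n = as.integer(n), scope = scope),
            class = "bleach_tally")
}

#' Construct a bleach tally directly from proportions
#'
#' @param c Numeric vector of 7 non-negative proportions over the severity
#'   categories, summing to one.
#' @param n Number of scored colonies/points behind the proportions.
#' @param scope Optional scope annotation.
#' @return A `bleach_tally`.
#' @export
bleach_tally <- function(c, n, scope = list()) {
  if (length(c) != 7L) stop_rp("a bleach tally has 7 severity proportions")
  if (any(c < 0)) stop_rp("severity proportions must be non-negative")
  if (abs(sum(c) - 1) > 1e-9) stop_rp("severity proportions must sum to 1")
  if (n < 1) stop_rp("n must be >= 1")
  structure(list(c = setNames(as.numeric(c), bleach_states()),
                 n = as.integer(n), scope = scope),
            class = "bleach_tally")
}

#' Compute the Bleaching Response Index from a severity tally
#'
#' The BRI is the weighted mean of the proportions in the seven ordered
#' severity categories. Under the default convention the categories
#' normal → recently dead carry weights 0–6 and the sum is divided by 6, so
#' the index runs from 0 (all colonies normal) to 1 (all recently dead).
#' The alternative `"printed"` convention weights the categories 1–7 and
#' still divides by 6, following a published variant of the formula in which
#' an implicit zero-weight category precedes the seven scored ones.
#'
#' @param t A `bleach_tally`.
#' @param convention `"zero_based"` (default) or `"printed"`.
#' @param percent If `TRUE`, return the index on a 0–100 scale.
#' @return A `bri_record`: list with `bri`, `n`, `scope`, `convention`.
#' @export
compute_bri <- function(t, convention = c("zero_based", "printed"),
                        percent = FALSE) {
  convention <- match.arg(convention)
  stopifnot(inherits(t, "bleach_tally"))
  w <- switch(convention, zero_based = 0:6, printed = 1:7)
  bri <- sum(w * t$c) / 6
  if (percent) bri <- 100 * bri
  structure(list(bri = bri, n = t$n, scope = t$scope,
                 convention = convention, percent = percent),
            class = "bri_record")
}

#' @export
print.bri_record <- function(x, ...) {
  cat(sprintf("<bri_record> BRI = %.4f (n = %d, %s)\n",
              x$bri, x$n, x$convention))
  invisible(x)
}

#' Pool bleach tallies by their point counts
#'
#' @param tallies A list of `bleach_tally` objects.
#' @return A single `bleach_tally` whose proportions are the n-weighted
#'   mean of the components.
#' @export
pool_tallies <- function(tallies) {
  stopifnot(length(tallies) >= 1L,
            all(vapply(tallies, inherits, logical(1), "bleach_tally")))
  ns <- vapply(tallies, `[[`, numeric(1), "n")
  cs <- vapply(tallies, `[[`, numeric(7), "c")
  bleach_tally(as.numeric(cs %*% ns) / sum(ns), sum(ns))
}

#' BRI per site (and optionally per taxon)
#'
#' @param ds A `survey_dataset`.
#' @param by_taxon If `TRUE`, one row per site/depth/year/taxon; otherwise
#'   pooled over taxa.
#' @param ... Passed to [compute_bri()].
#' @return A data.frame with columns `site_id, depth_band, year`
#'   (`taxon` if requested), `bri`, `n`.
#' @export
bri_table <- function(ds, by_taxon = FALSE, ...) {
  r <- ds$records
  scored <- r[!is.na(r$bleach_state), , drop = FALSE]
  if (nrow(scored) == 0L) stop_rp("no scored coral points in dataset")
  keys <- unique(scored[, c("site_id", "depth_band", "year",
                            if (by_taxon) "taxon"), drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, , drop = FALSE]
    t <- tally_bleach_states(ds, site = k$site_id,
                             depth_band = k$depth_band, year = k$year,
                             taxon = if (by_taxon) k$taxon)
    b <- compute_bri(t, ...)
    data.frame(k, bri = b$bri, n = b$n, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(out$site_id, out$depth_band, out$year), , drop = FALSE]
}

#' Year-to-year change in BRI
#'
#' Defined as BRI in the earlier event minus BRI in the later event, so a
#' positive value means the earlier bleaching response was stronger.
#'
#' @param bri_earlier,bri_later BRI values (numeric or `bri_record`).
#' @return Numeric difference.
#' @export
delta_bri <- function(bri_earlier, bri_later) {
  val <- function(b) if (inherits(b, "bri_record")) b$bri else as.numeric(b)
  val(bri_earlier) - val(bri_later)
}
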