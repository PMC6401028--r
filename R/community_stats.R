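# Community analysis from first principles: Bray-Curtis dissimilarity,
# non-metric multidimensional scaling (Kruskal stress-1, isotonic
# regression + Guttman majorization), and sequential-SS PERMANOVA.

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk), in [0, 1]:
#' 0 for identical composition, 1 for disjoint support.
#'
#' @param m Non-negative numeric matrix, rows = sites, columns = taxa.
#' @return A symmetric `dist`-compatible matrix with zero diagonal and the
#'   input row names as labels.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop_rp("Bray-Curtis requires non-negative abundances")
  zero_rows <- rowSums(m) == 0
  if (any(zero_rows)) {
    stop_rp("all-zero row(s): %s (dissimilarity undefined)",
            paste(rownames(m)[zero_rows] %||% which(zero_rows),
                  collapse = ", "))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  d
}

lower_tri <- function(d) d[lower.tri(d)]

nmds_stress <- function(conf_d, dhat) {
  sqrt(sum((conf_d - dhat)^2) / sum(conf_d^2))
}

# Disparities by monotone (isotonic) regression of configuration distances
# on the rank order of the input dissimilarities.
nmds_disparities <- function(diss_order, conf_d) {
  dhat <- numeric(length(conf_d))
  dhat[diss_order] <- stats::isoreg(conf_d[diss_order])$yf
  dhat
}

#' Non-metric multidimensional scaling
#'
#' Finds a k-dimensional configuration whose inter-point distances are, in
#' rank order, as close as possible to the input dissimilarities, by
#' minimizing Kruskal's stress-1. Disparities are obtained by isotonic
#' regression of the configuration distances on the dissimilarity ranks,
#' and the configuration is updated by Guttman majorization. The best of
#' `n_restarts` starts (the first from classical metric scaling, the rest
#' random) is returned, centered and rotated to its principal axes with
#' each axis flipped to a non-negative coordinate sum, so results are
#' deterministic under a fixed seed.
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k Number of ordination axes (default 2).
#' @param n_restarts Number of starts (default 20).
#' @param max_iter Maximum majorization iterations per start (default 500).
#' @param tol Stress-change convergence tolerance (default 1e-8).
#' @param seed Optional integer seed for the random starts.
#' @return List of class `rp_nmds`: `points` (n x k), `stress` (stress-1),
#'   `converged`, `n_restarts`, `seed`.
#' @export
nmds <- function(d, k = 2L, n_restarts = 20L, max_iter = 500L, tol = 1e-8,
                 seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L || n < k) stop_rp("NMDS needs at least max(3, k) sites")
  if (!is.null(seed)) set.seed(seed)
  diss <- lower_tri(d)
  diss_order <- order(diss)

  run_start <- function(X) {
    stress_old <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      conf_d <- lower_tri(as.matrix(dist(X)))
      if (all(conf_d == 0)) break   # degenerate collapse
      dhat <- nmds_disparities(diss_order, conf_d)
      stress <- nmds_stress(conf_d, dhat)
      if (is.finite(stress_old) && abs(stress_old - stress) < tol) {
        converged <- TRUE
        break
      }
      stress_old <- stress
      # Guttman transform toward the disparities
      Dm <- matrix(0, n, n)
      Dm[lower.tri(Dm)] <- conf_d
      Dm <- Dm + t(Dm)
      R <- matrix(0, n, n)
      R[lower.tri(R)] <- dhat
      R <- R + t(R)
      Bm <- ifelse(Dm > 0, -R / Dm, 0)
      diag(Bm) <- -rowSums(Bm)
      X <- Bm %*% X / n
    }
    conf_d <- lower_tri(as.matrix(dist(X)))
    dhat <- nmds_disparities(diss_order, conf_d)
    list(X = X, stress = nmds_stress(conf_d, dhat), converged = converged)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1L) {
      cm <- suppressWarnings(stats::cmdscale(d, k = k))
      if (ncol(cm) < k) cbind(cm, matrix(rnorm(n * (k - ncol(cm)), sd = 1e-4),
                                         n)) else cm
    } else {
      matrix(rnorm(n * k), n, k)
    }
    res <- run_start(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }

  # canonical orientation: centered, principal axes, non-negative axis sums
  X <- scale(best$X, scale = FALSE)
  sv <- svd(X)
  X <- sv$u %*% diag(sv$d, k)
  flip <- ifelse(colSums(X) < 0, -1, 1)
  X <- sweep(X, 2L, flip, `*`)
  rownames(X) <- rownames(d)
  structure(list(points = X, stress = best$stress,
                 converged = best$converged, n_restarts = n_restarts,
                 seed = seed),
            class = "rp_nmds")
}

#' @export
print.rp_nmds <- function(x, ...) {
  cat(sprintf("<rp_nmds> %d sites, %d axes, stress = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# All permutations of 1..n (n small), for exhaustive permutation tests.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[s, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' PERMANOVA with sequential (Type I) sums of squares
#'
#' Partitions a dissimilarity matrix over an ordered list of model terms.
#' Squared dissimilarities are Gower-centered into an inner-product matrix
#' G; each term's sum of squares is the increase in trace(H G) as the
#' term's columns are added to the cumulative hat matrix H. Pseudo-F per
#' term is (SS_term / df_term) / (SS_resid / df_resid), and p-values come
#' from unrestricted permutation of observation rows: exhaustive when all
#' n! arrangements do not exceed `n_perm`, Monte Carlo otherwise with
#' p = (1 + #\{F* >= F\}) / (1 + n_perm).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param data Data.frame of covariates, rows aligned with `d`.
#' @param terms Character vector of column names in `data`, in model order
#'   (continuous columns enter with 1 df; factors/characters are
#'   dummy-coded with levels - 1 df).
#' @param n_perm Number of permutations (default 999, minimum 99).
#' @param seed Optional integer seed.
#' @return Data.frame of class `rp_permanova` with one row per term plus
#'   `Residual` and `Total`: columns `term, Df, SumsOfSqs, MeanSqs,
#'   F.model, R2, p`; attribute `n_perm_used` records the permutation
#'   count and `exhaustive` whether enumeration was complete.
#' @export
permanova <- function(d, data, terms, n_perm = 999L, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(nrow(data) == n)
  if (n_perm < 99L) stop_rp("n_perm must be >= 99")
  assert_cols(data, terms, "PERMANOVA data")
  if (anyNA(data[terms])) stop_rp("missing values in PERMANOVA terms")

  # Gower-centered inner-product matrix from squared dissimilarities
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J

  # cumulative hat matrices
  X <- matrix(1, n, 1L)
  hats <- list()
  dfs <- integer(length(terms))
  rank_prev <- 1L
  for (i in seq_along(terms)) {
    v <- data[[terms[i]]]
    cols <- if (is.numeric(v)) matrix(as.numeric(v), n) else
      model.matrix(~ f, data.frame(f = factor(v)))[, -1, drop = FALSE]
    X <- cbind(X, cols)
    qr_x <- qr(X)
    dfs[i] <- qr_x$rank - rank_prev
    if (dfs[i] <= 0L) {
      stop_rp("term %s adds no degrees of freedom (aliased)", terms[i])
    }
    rank_prev <- qr_x$rank
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    hats[[i]] <- tcrossprod(Q)
  }
  df_resid <- n - rank_prev
  if (df_resid <= 0L) stop_rp("no residual degrees of freedom")

  # with G double-centered the intercept contributes nothing to trace(H G),
  # so sequential SS are the successive increments of trace(H_k G)
  ss_decomp <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    list(terms = diff(c(0, tr)), resid = sum(diag(Gp)) - tr[length(tr)],
         total = sum(diag(Gp)))
  }

  obs <- ss_decomp(G)
  f_obs <- (obs$terms / dfs) / (obs$resid / df_resid)

  f_perm <- function(p) {
    dec <- ss_decomp(G[p, p])
    (dec$terms / dfs) / (dec$resid / df_resid)
  }

  n_arrangements <- factorial(n)
  exhaustive <- is.finite(n_arrangements) && n_arrangements <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    f_star <- apply(perms, 1L, f_perm)
    f_star <- matrix(f_star, nrow = length(terms))
    p_vals <- rowMeans(f_star >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- numeric(length(terms))
    for (b in seq_len(n_perm)) {
      fs <- f_perm(sample.int(n))
      count <- count + (fs >= f_obs - 1e-12)
    }
    p_vals <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(dfs, df_resid, n - 1L),
    SumsOfSqs = c(obs$terms, obs$resid, obs$total),
    MeanSqs = c(obs$terms / dfs, obs$resid / df_resid, NA),
    F.model = c(f_obs, NA, NA),
    R2 = c(obs$terms / obs$total, obs$resid / obs$total, 1),
    p = c(p_vals, NA, NA), row.names = NULL)
  attr(out, "n_perm_used") <- n_used
  attr(out, "exhaustive") <- exhaustive
  class(out) <- c("rp_permanova", "data.frame")
  out
}
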