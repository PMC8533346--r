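#' Two-tailed critical t-value
#'
#' Critical t at significance `alpha` for the pooled-variance statistic
#' whose variance estimate carries `2n - 1` degrees of freedom. For
#' `n = 500` and `alpha = 0.01` this evaluates to 2.58 at two decimals.
#'
#' @param n trials per group.
#' @param alpha two-tailed significance level.
#' @export
critical_t <- function(n = 500, alpha = 0.01) {
  stats::qt(1 - alpha / 2, df = 2 * n - 1)
}

#' Pointwise t-series between two trial ensembles
#'
#' Computes, at every time point, `t = (m1 - m2) / sqrt(s^2 / n)` with the
#' pooled variance `s^2 = ((n-1) s1^2 + (n-1) s2^2) / (2n - 1)` — the
#' as-published form, implemented verbatim. `var_form = "welch"` switches
#' to the textbook unpooled statistic `(m1 - m2) / sqrt(s1^2/n + s2^2/n)`
#' for sensitivity analyses.
#'
#' @param x1,x2 trials x time matrices with equal trial counts and time
#'   axes.
#' @param var_form `"printed"` (default) or `"welch"`.
#' @return A list of class `nm_tseries`: `t` (per time point; `NA` where
#'   the pooled variance vanishes), `n`, `var_form`.
#' @export
t_series <- function(x1, x2, var_form = c("printed", "welch")) {
  var_form <- match.arg(var_form)
  stopifnot(is.matrix(x1), is.matrix(x2), ncol(x1) == ncol(x2),
            nrow(x1) == nrow(x2), nrow(x1) >= 2)
  n <- nrow(x1)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colMeans(x1^2) - m1^2) * n / (n - 1)
  v2 <- (colMeans(x2^2) - m2^2) * n / (n - 1)
  se2 <- if (var_form == "printed")
    ((n - 1) * v1 + (n - 1) * v2) / (2 * n - 1) / n
  else v1 / n + v2 / n
  t <- (m1 - m2) / sqrt(se2)
  t[se2 <= 0] <- NA_real_
  structure(list(t = t, n = n, var_form = var_form), class = "nm_tseries")
}

#' @export
print.nm_tseries <- function(x, ...) {
  cat("<nm_tseries>", length(x$t), "time points, n =", x$n,
      "per group,", sum(is.na(x$t)), "undefined\n")
  invisible(x)
}

#' Extract suprathreshold temporal clusters
#'
#' Maximal runs of consecutive time points with `|t| >= critical`. Each
#' cluster carries its area (the integral of `|t|` over the run, in
#' seconds since `dt` is in seconds) and its length in ms. Clusters are
#' returned sorted by descending area with their rank.
#'
#' @param ts an [t_series()] result or a numeric t-vector.
#' @param critical critical t-value.
#' @param dt time step between consecutive points, seconds.
#' @return A tibble with columns `rank`, `start`, `end` (indices),
#'   `start_s`, `length_ms`, `area_s`, `sign`.
#' @export
extract_clusters <- function(ts, critical = 2.58, dt) {
  t <- if (inherits(ts, "nm_tseries")) ts$t else ts
  above <- !is.na(t) & abs(t) >= critical
  empty <- tibble::tibble(rank = integer(), start = integer(),
                          end = integer(), start_s = numeric(),
                          length_ms = numeric(), area_s = numeric(),
                          sign = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- purrr::map_dfr(keep, function(k) {
    i <- starts[k]:ends[k]
    tibble::tibble(start = starts[k], end = ends[k],
                   start_s = (starts[k] - 1) * dt,
                   length_ms = r$lengths[k] * dt * 1000,
                   area_s = sum(abs(t[i])) * dt,
                   sign = sign(mean(t[i])))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$area_s))
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}

#' Discard clusters below the prestimulus baseline
#'
#' Removes observed clusters whose area does not exceed the largest
#' cluster area found in the baseline (prestimulus) comparison.
#'
#' @param clusters tibble from [extract_clusters()].
#' @param baseline_area largest baseline cluster area (0 if none).
#' @return Filtered tibble, ranks recomputed.
#' @export
baseline_filter <- function(clusters, baseline_area) {
  out <- dplyr::filter(clusters, .data$area_s > baseline_area)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Largest baseline cluster from split prestimulus activity
#'
#' Splits the prestimulus trials in half along time, computes the t-series
#' between the halves and returns the largest suprathreshold cluster area
#' (0 when there is none).
#'
#' @param x_pre trials x time prestimulus matrix.
#' @inheritParams extract_clusters
#' @param var_form passed to [t_series()].
#' @export
baseline_max_area <- function(x_pre, critical = 2.58, dt,
                              var_form = "printed") {
  half <- ncol(x_pre) %/% 2
  ts <- t_series(x_pre[, seq_len(half), drop = FALSE],
                 x_pre[, half + seq_len(half), drop = FALSE],
                 var_form = var_form)
  cl <- extract_clusters(ts, critical, dt)
  if (nrow(cl)) max(cl$area_s) else 0
}

# Ranked cluster areas (descending) of each row of a t-matrix.
ranked_areas_by_row <- function(tmat, critical, dt) {
  apply(tmat, 1, function(t) {
    above <- !is.na(t) & abs(t) >= critical
    if (!any(above)) return(numeric(0))
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    a <- vapply(keep, function(k) sum(abs(t[starts[k]:ends[k]])) * dt,
                numeric(1))
    sort(a, decreasing = TRUE)
  }, simplify = FALSE)
}

# t-matrix for a batch of permutations. `pool` is the (2n x T) stacked
# data; `pick` is a (B x 2n) logical matrix selecting group 1 per
# permutation.
perm_t_matrix <- function(pool, pick, n, var_form) {
  tot <- colSums(pool); tot2 <- colSums(pool^2)
  s1 <- pick %*% pool
  q1 <- pick %*% pool^2
  m1 <- s1 / n
  m2 <- sweep(-s1, 2, tot, "+") / n
  v1 <- (q1 - n * m1^2) / (n - 1)
  v2 <- (sweep(-q1, 2, tot2, "+") - n * m2^2) / (n - 1)
  se2 <- if (var_form == "printed")
    ((n - 1) * v1 + (n - 1) * v2) / (2 * n - 1) / n
  else (v1 + v2) / n
  t <- (m1 - m2) / sqrt(se2)
  t[se2 <= 0] <- NA_real_
  t
}

#' Permutation p-values for ranked clusters
#'
#' Builds, for each observed cluster rank, a null distribution of
#' same-ranked cluster areas by randomly reassigning trials between the
#' two groups (preserving group sizes), recomputing the t-series and its
#' ranked cluster areas for every permutation. Permutations are added in
#' batches until the deepest observed rank has accumulated at least
#' `n_perm_min` null areas, or `max_perm` permutations have been spent.
#' The p-value of the r-th observed cluster is the proportion of r-th
#' ranked null areas larger than it.
#'
#' @param x1,x2 trials x time matrices (post- and prestimulus ensembles).
#' @param clusters observed clusters (tibble from [extract_clusters()],
#'   possibly after [baseline_filter()]).
#' @inheritParams extract_clusters
#' @param n_perm_min minimum null-sample count for the deepest rank.
#' @param max_perm hard cap on permutations.
#' @param var_form passed to the t statistic.
#' @param seed optional seed making the permutation draw reproducible.
#' @return `clusters` with columns `p` and `n_null` appended.
#' @export
permutation_p <- function(x1, x2, clusters, critical = 2.58, dt,
                          n_perm_min = 1000, max_perm = 20 * n_perm_min,
                          var_form = "printed", seed = NULL) {
  if (!nrow(clusters)) {
    return(dplyr::mutate(clusters, p = numeric(0), n_null = integer(0)))
  }
  n <- nrow(x1)
  pool <- rbind(x1, x2)
  n_ranks <- nrow(clusters)
  body <- function() {
    null_areas <- purrr::map(seq_len(n_ranks), function(i) numeric(0))
    total <- 0L
    batch <- max(200L, n_perm_min %/% 4L)
    while (total < max_perm &&
           length(null_areas[[n_ranks]]) < n_perm_min) {
      b <- min(batch, max_perm - total)
      pick <- t(vapply(seq_len(b), function(i) {
        z <- logical(2 * n); z[sample.int(2 * n, n)] <- TRUE; z
      }, logical(2 * n)))
      storage.mode(pick) <- "double"
      tmat <- perm_t_matrix(pool, pick, n, var_form)
      areas <- ranked_areas_by_row(tmat, critical, dt)
      for (r in seq_len(n_ranks)) {
        got <- unlist(purrr::map(areas, function(a)
          if (length(a) >= r) a[r] else NULL))
        null_areas[[r]] <- c(null_areas[[r]], got)
      }
      total <- total + b
    }
    list(null_areas = null_areas, total = total)
  }
  res <- if (is.null(seed)) body() else with_seed(seed, body)
  clusters$p <- vapply(seq_len(n_ranks), function(r) {
    nl <- res$null_areas[[r]]
    if (!length(nl)) return(0)
    mean(nl > clusters$area_s[r])
  }, numeric(1))
  clusters$n_null <- vapply(res$null_areas, length, integer(1))
  attr(clusters, "n_perm") <- res$total
  clusters
}

#' Temporal clustering nonparametric test
#'
#' The full pipeline for testing an evoked response against baseline:
#' pointwise t-series between the post- and prestimulus ensembles,
#' suprathreshold clustering at the critical t-value, removal of clusters
#' no larger than the biggest cluster obtained from splitting the
#' prestimulus activity in half, and permutation p-values for the
#' survivors.
#'
#' @param x_post,x_pre trials x time matrices, equal dimensions, aligned
#'   so that column `j` of both is the same latency within its window.
#' @param dt sampling interval, seconds.
#' @param critical critical t-value (`2.58` corresponds to p = 0.01
#'   two-tailed at the published sample size).
#' @param n_perm_min minimum permutation count per rank.
#' @param max_perm hard cap on permutations.
#' @param baseline `"split_pre"` (default) or `"none"`.
#' @param var_form `"printed"` or `"welch"`.
#' @param seed optional permutation seed.
#' @return An object of class `nm_cluster_test` with the t-series, the
#'   cluster table (with p-values), and the baseline area.
#' @export
cluster_test <- function(x_post, x_pre, dt, critical = 2.58,
                         n_perm_min = 1000, max_perm = 20 * n_perm_min,
                         baseline = c("split_pre", "none"),
                         var_form = c("printed", "welch"), seed = NULL) {
  baseline <- match.arg(baseline)
  var_form <- match.arg(var_form)
  ts <- t_series(x_post, x_pre, var_form = var_form)
  cl <- extract_clusters(ts, critical, dt)
  base_area <- if (baseline == "split_pre")
    baseline_max_area(x_pre, critical, dt, var_form) else 0
  cl <- baseline_filter(cl, base_area)
  cl <- permutation_p(x_post, x_pre, cl, critical, dt,
                      n_perm_min = n_perm_min, max_perm = max_perm,
                      var_form = var_form, seed = seed)
  structure(list(tseries = ts, clusters = cl, baseline_area = base_area,
                 dt = dt, critical = critical, n = ts$n,
                 var_form = var_form),
            class = "nm_cluster_test")
}

#' @export
print.nm_cluster_test <- function(x, ...) {
  cat("<nm_cluster_test> n =", x$n, "per group; |t| >=", x$critical,
      "; baseline area", signif(x$baseline_area, 4), "s\n")
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}

#' Bonferroni-corrected pointwise t-test
#'
#' The conservative alternative to temporal clustering: a pointwise test
#' at `alpha` divided by the number of time points.
#'
#' @inheritParams t_series
#' @param alpha familywise significance level.
#' @return A list with the significant-point `mask`, the t-series, and
#'   the corrected per-point alpha.
#' @export
bonferroni_test <- function(x1, x2, alpha = 0.01,
                            var_form = c("printed", "welch")) {
  ts <- t_series(x1, x2, var_form = match.arg(var_form))
  df <- 2 * ts$n - 1
  pvals <- 2 * stats::pt(-abs(ts$t), df = df)
  alpha_c <- alpha / length(ts$t)
  mask <- !is.na(pvals) & pvals < alpha_c
  list(mask = mask, tseries = ts, alpha_corrected = alpha_c)
}

#' Propagation metrics from a cluster test
#'
#' The first (earliest) significant poststimulus cluster quantifies how
#' much of the stimulus reached the population under test: its area (s)
#' and length (ms) grow with the amount of propagated information. An
#' explicit none-record is returned when no cluster is significant.
#'
#' @param test an [cluster_test()] result.
#' @param alpha significance level on the permutation p-values.
#' @return One-row tibble: `found`, `area_s`, `length_ms`, `p`,
#'   `start_s`.
#' @export
propagation_metrics <- function(test, alpha = 0.01) {
  stopifnot(inherits(test, "nm_cluster_test"))
  sig <- dplyr::filter(test$clusters, .data$p < alpha)
  if (!nrow(sig)) {
    return(tibble::tibble(found = FALSE, area_s = NA_real_,
                          length_ms = NA_real_, p = NA_real_,
                          start_s = NA_real_))
  }
  first <- dplyr::slice_min(sig, .data$start_s, n = 1, with_ties = FALSE)
  tibble::tibble(found = TRUE, area_s = first$area_s,
                 length_ms = first$length_ms, p = first$p,
                 start_s = first$start_s)
}
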