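#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster test
#'
#' @param x an [cluster_test()] result.
#' @param ... unused.
#' @return The cluster tibble (rank, timing, area, length, sign, p).
#' @export
tidy.nm_cluster_test <- function(x, ...) tibble::as_tibble(x$clusters)

#' One-row summary of a cluster test
#'
#' @param x an [cluster_test()] result.
#' @param alpha significance level.
#' @param ... unused.
#' @export
glance.nm_cluster_test <- function(x, alpha = 0.01, ...) {
  tibble::tibble(n = x$n, critical = x$critical,
                 baseline_area_s = x$baseline_area,
                 n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$p < alpha),
                 min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_)
}

#' @export
tidy.nm_targets <- function(x, ...) {
  tibble::tibble(population = c("pyramidal", "inhibitory"),
                 v_target = c(x$v_p, x$v_i))
}

#' @export
tidy.nm_spectrum <- function(x, ...) {
  tibble::tibble(freq = x$freq, psd = x$mean_psd, db = x$db)
}

#' @export
tidy.nm_threshold <- function(x, ...) x$distribution

#' @export
tidy.nm_evoked <- function(x, ...) tidy(x$test)

#' @export
glance.nm_evoked <- function(x, ...) glance(x$test)
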