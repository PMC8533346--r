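#' Local field potential from synaptic currents
#'
#' The LFP proxy of a population is the sum of the absolute AMPAergic and
#' GABAergic synaptic currents, `LFP = |I_AMPA| + |I_GABA|`; action
#' potentials are too fast and too attenuated to contribute.
#'
#' @param i_ampa,i_gaba synaptic currents (vectorized).
#' @return LFP series in mV-scale model units.
#' @export
compute_lfp <- function(i_ampa, i_gaba) abs(i_ampa) + abs(i_gaba)

#' Remove the prestimulus temporal mean
#'
#' Subtracts, per trial, the mean of the signal over the prestimulus
#' window from the whole trial. Adding a constant offset to the input
#' leaves the output unchanged, and the prestimulus mean of the output is
#' exactly zero.
#'
#' @param x trials x time matrix (or a single-trial numeric vector).
#' @param time time axis in seconds.
#' @param window half-open window `[from, to)` in seconds over which the
#'   mean is taken; defaults to the first five seconds.
#' @return Same shape as `x`.
#' @export
demean_prestimulus <- function(x, time, window = c(0, 5)) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  idx <- window_index(time, window[1], window[2])
  if (!length(idx)) stop("demeaning window lies outside the trial")
  out <- x - rowMeans(x[, idx, drop = FALSE])
  if (vec) drop(out) else out
}

#' Amplitude distribution at fixed bin width
#'
#' Histogram of pooled signal values at the given bin width, normalized by
#' the total number of events.
#'
#' @param values numeric vector (pooled samples).
#' @param bin bin width (0.5 mV for membrane/LFP, 0.5 Hz for rates).
#' @return A tibble of class `nm_distribution` with columns `mid`,
#'   `count`, `prop`; `sum(prop) == 1`.
#' @export
amplitude_distribution <- function(values, bin = 0.5) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  lo <- floor(min(values) / bin) * bin
  hi <- ceiling(max(values) / bin) * bin
  if (hi <= lo) hi <- lo + bin
  breaks <- seq(lo, hi + bin / 2, by = bin)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  out <- tibble::tibble(mid = h$mids, count = h$counts,
                        prop = h$counts / sum(h$counts))
  attr(out, "bin") <- bin
  class(out) <- c("nm_distribution", class(out))
  out
}

# Gaussian-kernel smoothing of binned counts on the support axis.
smooth_counts <- function(mid, count, c_smooth) {
  if (c_smooth <= 0) return(count)
  k <- outer(mid, mid, function(a, b) exp(-(a - b)^2 / (2 * c_smooth^2)))
  as.vector(k %*% count) / rowSums(k)
}

# Indices of strict local maxima of a numeric vector (ends included).
local_maxima <- function(y) {
  n <- length(y)
  if (n == 1) return(1L)
  up <- c(TRUE, y[-1] > y[-n])     # rises into i
  down <- c(y[-n] > y[-1], TRUE)   # falls after i
  which(up & down)
}

#' Up/Down threshold from a bimodal amplitude distribution
#'
#' Smooths the binned LFP distribution with a Gaussian kernel of width
#' `c_smooth` on the amplitude axis, locates its two principal modes (the
#' two largest local maxima separated by a local minimum; ties broken
#' toward the larger separation), and returns their midpoint. Samples
#' above the threshold are Up states, the rest Down states. A unimodal
#' distribution yields an explicit no-bimodality result, which is how the
#' waking regime is recognized.
#'
#' @param values pooled signal values, or an [amplitude_distribution()].
#' @param bin bin width used when `values` is raw data.
#' @param c_smooth Gaussian kernel width on the amplitude axis (55 mV for
#'   the pyramidal LFP, 5 mV for the inhibitory one).
#' @param min_peak_frac minimum height of a candidate mode relative to
#'   the tallest one. Guards against isolated outlier bins at the edge of
#'   the support masquerading as a second mode: genuine Up/Down modes are
#'   of comparable height (observed well above 0.3 of the main peak)
#'   while edge artifacts sit below 0.01.
#' @return A list of class `nm_threshold`: `bimodal` (logical),
#'   `threshold`, `peaks` (the two mode positions), and the smoothed
#'   distribution.
#' @export
updown_threshold <- function(values, bin = 0.5, c_smooth = 55,
                             min_peak_frac = 0.05) {
  dist <- if (inherits(values, "nm_distribution")) values
          else amplitude_distribution(values, bin)
  sm <- smooth_counts(dist$mid, dist$count, c_smooth)
  ix <- local_maxima(sm)
  ix <- ix[sm[ix] >= min_peak_frac * max(sm)]
  res <- list(bimodal = FALSE, threshold = NA_real_,
              peaks = c(NA_real_, NA_real_),
              distribution = dplyr::mutate(tibble::as_tibble(dist),
                                           smoothed = sm / sum(sm)))
  if (length(ix) >= 2) {
    ord <- ix[order(sm[ix], decreasing = TRUE)]
    cand <- sort(ord[1:2])
    # prefer an equally tall but wider pair when heights tie
    if (length(ix) > 2) {
      top <- sm[ord[1:2]]
      ties <- ix[sm[ix] >= min(top) * (1 - 1e-12)]
      if (length(ties) > 2) cand <- range(ties)
    }
    between <- sm[cand[1]:cand[2]]
    if (min(between) < min(sm[cand[1]], sm[cand[2]])) {  # separated by a dip
      res$bimodal <- TRUE
      res$peaks <- dist$mid[cand]
      res$threshold <- mean(dist$mid[cand])
    }
  }
  class(res) <- "nm_threshold"
  res
}

#' @export
print.nm_threshold <- function(x, ...) {
  if (x$bimodal)
    cat("<nm_threshold> bimodal; peaks at", x$peaks[1], "and", x$peaks[2],
        "; threshold", x$threshold, "\n")
  else cat("<nm_threshold> no bimodality detected\n")
  invisible(x)
}

#' Label samples as Up or Down states
#'
#' @param values signal samples.
#' @param threshold an [updown_threshold()] result or a numeric threshold.
#' @return Character vector `"up"` / `"down"`.
#' @export
label_updown <- function(values, threshold) {
  th <- if (inherits(threshold, "nm_threshold")) {
    if (!threshold$bimodal) stop("no bimodality: Up/Down labels undefined")
    threshold$threshold
  } else threshold
  ifelse(values > th, "up", "down")
}

#' Per-state amplitude distributions
#'
#' Distributions of a signal split by Up/Down label, each normalized by
#' the total number of events across both labels so that the two
#' proportions sum to one overall.
#'
#' @param values signal samples.
#' @param labels `"up"`/`"down"` labels from [label_updown()], same length.
#' @param bin bin width.
#' @return A tibble with columns `label`, `mid`, `count`, `prop`.
#' @export
split_distributions <- function(values, labels, bin = 0.5) {
  stopifnot(length(values) == length(labels))
  total <- length(values)
  purrr::map_dfr(unique(labels), function(lb) {
    d <- amplitude_distribution(values[labels == lb], bin)
    tibble::tibble(label = lb, mid = d$mid, count = d$count,
                   prop = d$count / total)
  })
}

#' Mode (peak bin center) of a distribution
#'
#' @param dist a tibble with `mid` and `count` (or `prop`) columns.
#' @return The bin center with the highest count.
#' @export
distribution_mode <- function(dist) dist$mid[which.max(dist$count)]

#' Averaged power spectral density of an ensemble signal
#'
#' Welch-style estimate matching the analysis pipeline: each trial is cut
#' into Hann-tapered windows (2 s, 90% overlap), the PSD of each window is
#' obtained from the short-time Fourier transform amplitude with the usual
#' taper power correction, windows are averaged within a trial and the
#' trial PSDs are kept so the across-trial mean and dispersion can be
#' formed. One-sided density in (signal units)^2/Hz.
#'
#' @param x trials x time matrix (or one trial as a vector).
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @return Object of class `nm_spectrum`: `freq` (Hz), `psd` (trials x
#'   freq matrix), `mean_psd`, `db` (`log10` of the mean PSD re 1).
#' @export
lfp_spectrum <- function(x, fs, window_s = 2, overlap = 0.9) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nfft <- round(window_s * fs)
  if (ncol(x) < nfft) stop("window longer than the signal")
  n_over <- round(nfft * overlap)
  win <- signal::hanning(nfft)
  u <- fs * sum(win^2)  # density normalization incl. taper power
  freq <- NULL
  psd <- t(apply(x, 1, function(tr) {
    sg <- signal::specgram(tr, n = nfft, Fs = fs, window = win,
                           overlap = n_over)
    if (is.null(freq)) freq <<- as.numeric(sg$f)
    # average the STFT power over windows, one-sided density (double all
    # positive frequencies; DC kept single)
    S <- sg$S
    if (is.null(dim(S))) S <- matrix(S, ncol = 1)  # single-window signal
    p <- rowMeans(Mod(S)^2) / u
    dbl <- rep(2, length(p)); dbl[1] <- 1
    p * dbl
  }))
  structure(list(freq = freq, psd = psd, mean_psd = colMeans(psd),
                 db = log10(pmax(colMeans(psd), .Machine$double.xmin)),
                 fs = fs, window_s = window_s, overlap = overlap),
            class = "nm_spectrum")
}

#' @export
print.nm_spectrum <- function(x, ...) {
  cat("<nm_spectrum>", nrow(x$psd), "trial(s),",
      length(x$freq), "frequencies up to", max(x$freq), "Hz\n")
  invisible(x)
}

#' Decibel scale
#'
#' `dB = log10(P / Pr)` with reference power `Pr = 1` (mV)^2/Hz.
#'
#' @param p power spectral density values.
#' @param pr reference PSD.
#' @export
to_db <- function(p, pr = 1) log10(p / pr)

#' High/low frequency band power ratio
#'
#' Per-trial `log10` ratio of summed power above `high` Hz over summed
#' power below `low` Hz. The distribution of this ratio across trials
#' separates waking (ratio high) from NREM dynamics (ratio low).
#'
#' @param spectrum an [lfp_spectrum()] result.
#' @param high lower edge of the high band, Hz.
#' @param low upper edge of the low band, Hz.
#' @return A tibble with columns `trial` and `ratio`.
#' @export
band_ratio <- function(spectrum, high = 30, low = 4) {
  stopifnot(inherits(spectrum, "nm_spectrum"))
  hi <- spectrum$freq > high
  lo <- spectrum$freq < low
  if (!any(hi) || !any(lo)) stop("PSD does not resolve both bands")
  num <- rowSums(spectrum$psd[, hi, drop = FALSE])
  den <- rowSums(spectrum$psd[, lo, drop = FALSE])
  if (any(den <= 0)) stop("zero power in the low band")
  tibble::tibble(trial = seq_along(num), ratio = log10(num / den))
}
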