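# Shared, lazily built fixtures. Everything is generated in code with
# fixed seeds; the cache only avoids re-simulating within one test run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, build(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

unit_fixtures <- function() fixture("unit", function() make_fixtures("unit"))

# A minimal hand-built ensemble wrapper for analysis-path tests where the
# signals are synthetic by construction.
synthetic_ensemble <- function(lfp, v_p, v_i, record_dt = 1,
                               state = "nrem") {
  structure(list(
    time = (seq_len(ncol(lfp)) - 1) * record_dt / 1000,
    signals = list(list(lfp_p = lfp, v_p = v_p, v_i = v_i,
                        rate_p = pmax(v_p + 66, 0) / 1000,
                        rate_i = pmax(v_i + 64, 0) / 1000)),
    seeds = seq_len(nrow(lfp)),
    network = network_config(column_params(state)),
    cfg = integration_config(n_trials = nrow(lfp), record_dt = record_dt),
    master_seed = 0L
  ), class = "nm_ensemble")
}

# AR(1) null trials: rows are independent trials sharing no signal.
ar1_trials <- function(n_trials, n_time, phi = 0.95, sd = 1) {
  t(vapply(seq_len(n_trials), function(i)
    as.numeric(stats::arima.sim(list(ar = phi), n_time, sd = sd)),
    numeric(n_time)))
}

# Brute-force cluster extraction used as the oracle for the rle-based
# implementation: walks the series point by point.
brute_clusters <- function(t, critical, dt) {
  above <- !is.na(t) & abs(t) >= critical
  out <- list()
  i <- 1L
  while (i <= length(t)) {
    if (above[i]) {
      j <- i
      while (j < length(t) && above[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <-
        data.frame(start = i, end = j,
                   area_s = sum(abs(t[i:j])) * dt,
                   length_ms = (j - i + 1L) * dt * 1000)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(NULL)
  d <- do.call(rbind, out)
  d[order(-d$area_s), ]
}
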