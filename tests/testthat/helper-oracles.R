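# Independent brute-force oracles for the descriptor operators. These are
# deliberately written as naive point-by-point loops, sharing no code with
# the package implementations.

oracle_interp <- function(v, i, x) {
  ord <- order(v)
  v <- v[ord]; i <- i[ord]
  for (k in seq_len(length(v) - 1)) {
    if (x >= v[k] && x <= v[k + 1]) {
      f <- if (v[k + 1] == v[k]) 0 else (x - v[k]) / (v[k + 1] - v[k])
      return(i[k] + f * (i[k + 1] - i[k]))
    }
  }
  stop("query outside range")
}

# chord-corrected currents and trapezoid area over [lo, hi], including
# interpolated endpoint nodes
oracle_chord_area <- function(v, i, lo, hi) {
  ord <- order(v)
  v <- v[ord]; i <- i[ord]
  i_lo <- oracle_interp(v, i, lo)
  i_hi <- oracle_interp(v, i, hi)
  keep <- v > lo & v < hi
  vs <- c(lo, v[keep], hi)
  is <- c(i_lo, i[keep], i_hi)
  resid <- numeric(length(vs))
  for (k in seq_along(vs)) {
    chord_k <- i_lo + (vs[k] - lo) / (hi - lo) * (i_hi - i_lo)
    resid[k] <- is[k] - chord_k
  }
  area <- 0
  for (k in seq_len(length(vs) - 1)) {
    area <- area + (vs[k + 1] - vs[k]) * (resid[k] + resid[k + 1]) / 2
  }
  list(potentials = vs, residuals = resid, area = area)
}

# all level crossings in scan order, interpolated
oracle_crossings <- function(v, i, level) {
  out <- numeric(0)
  for (k in seq_len(length(v) - 1)) {
    if (i[k] == level) out <- c(out, v[k])
    else if ((i[k] - level) * (i[k + 1] - level) < 0) {
      f <- (level - i[k]) / (i[k + 1] - i[k])
      out <- c(out, v[k] + f * (v[k + 1] - v[k]))
    }
  }
  if (length(v) && i[length(v)] == level) out <- c(out, v[length(v)])
  out
}

oracle_peak <- function(v, i, lo, hi, sense = "max") {
  best_i <- NA_real_; best_v <- NA_real_
  for (k in seq_along(v)) {
    if (v[k] < lo || v[k] > hi) next
    better <- is.na(best_i) ||
      (sense == "max" && (i[k] > best_i || (i[k] == best_i && v[k] < best_v))) ||
      (sense == "min" && (i[k] < best_i || (i[k] == best_i && v[k] < best_v)))
    if (better) { best_i <- i[k]; best_v <- v[k] }
  }
  list(current = best_i, potential = best_v)
}

# random DPV trace on an ascending grid
random_dpv <- function(n = 50, lo = -600, hi = 2000,
                       route = "propionate_esterification") {
  v <- seq(lo, hi, length.out = n)
  i <- cumsum(rnorm(n)) + rnorm(1, 0, 5)
  voltammogram(v, i, default_scan_params(route), sample_id = "rand")
}

dpv_from <- function(v, i, route = "propionate_esterification",
                     stream = "standard") {
  voltammogram(v, i, default_scan_params(route), stream = stream,
               sample_id = "test")
}

cv_from <- function(v, i) {
  voltammogram(v, i, default_scan_params("butyrate_dissociation"),
               sample_id = "test")
}

# triangle CV grid -600 -> 1100 -> -600 at `step` mV
cv_grid <- function(step = 10) {
  c(seq(-600, 1100, by = step), seq(1100 - step, -600, by = -step))
}
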