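# Algorithmic ECG delineation. The study set markers manually; here fiducials
# are detected automatically, and ground-truth annotations always take
# precedence when supplied.
#
# T-end convention: tangent method — a line fitted to the maximal-downslope
# segment of the T wave is extrapolated to the isoelectric baseline. Under
# AV dissociation the atrial P train marches through the QRS-T complex, so
# before fiducial measurement the delineator estimates the periodic P train
# from clean diastolic P waves (smallest period consistent with the
# candidate peak times, then phase/period by least squares), builds an
# average P template, and subtracts it at every predicted P position. Q
# onset, QRS end and T end are all measured on the cleaned signal.

local_maxima <- function(x, min_value, min_dist) {
  cand <- which(x >= min_value)
  if (!length(cand)) return(integer(0))
  # split into contiguous regions, take the argmax of each
  brk <- c(0, which(diff(cand) > min_dist), length(cand))
  peaks <- integer(0)
  for (k in seq_len(length(brk) - 1L)) {
    idx <- cand[(brk[k] + 1L):brk[k + 1L]]
    peaks <- c(peaks, idx[which.max(x[idx])])
  }
  peaks
}

# linear extrapolation of a limb to `level`; idx are 1-based samples
limb_intercept_ms <- function(x, idx, level = 0) {
  if (length(idx) < 2) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, idx), x[idx])
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] == 0) return(NA_real_)
  (level - b[1]) / b[2] - 1  # to 0-based ms
}

# smallest period (ms) consistent with candidate P-peak times: candidate
# inter-peak gaps are integer multiples of the true period, so scan periods
# from short to long and keep the first one under which every gap sits close
# to a multiple; refine phase + period by least squares on beat numbers.
fit_p_train <- function(p_cand, dur_ms, pp_range = c(350, 1500),
                        tol_ms = 4) {
  if (length(p_cand) < 4) return(NULL)
  d <- diff(p_cand)
  d <- d[d > 100]
  if (length(d) < 3) return(NULL)
  grid <- seq(pp_range[1], min(pp_range[2], max(d)), by = 0.25)
  # score every candidate period by the fraction of gaps it explains and
  # take the shortest period achieving the maximum (rational subharmonics
  # of the true period explain only a subset of the gaps)
  score <- vapply(grid, function(g) {
    k <- pmax(1, round(d / g))
    mean(abs(d - k * g) < tol_ms)
  }, 0)
  if (max(score) < 0.6) return(NULL)
  pp <- grid[which(score >= max(score) - 0.02)[1]]
  # least-squares phase/period on beat numbers, with one outlier-rejection
  # pass (a distorted P overlapping another wave lands off the grid)
  for (pass in 1:2) {
    kk <- cumsum(c(0, round(diff(p_cand) / pp)))
    fit <- stats::lm.fit(cbind(1, kk), p_cand)
    t0 <- fit$coefficients[1]; pp <- fit$coefficients[2]
    if (!is.finite(pp) || pp < pp_range[1]) return(NULL)
    keep <- abs(fit$residuals) < tol_ms
    if (all(keep) || sum(keep) < 4) break
    p_cand <- p_cand[keep]
  }
  k_all <- floor(-t0 / pp):ceiling((dur_ms - t0) / pp)
  pred <- t0 + k_all * pp
  list(pp = pp, peaks = pred[pred > 0 & pred < dur_ms])
}

#' Delineate an ECG trace
#'
#' Detects beats and per-beat fiducials (Q onset, QRS end, T end) on the
#' `ECG` channel; estimates and annotates the atrial P train. When
#' ground-truth `annotations` are supplied they are returned unchanged.
#'
#' @param trace a `signal_trace` with an `ECG` channel (1 kHz)
#' @param annotations optional `beat_annotations` ground truth (passed
#'   through verbatim)
#' @return a `beat_annotations`
#' @export
delineate <- function(trace, annotations = NULL) {
  if (!is.null(annotations)) {
    stopifnot(inherits(annotations, "beat_annotations"))
    return(annotations)
  }
  stopifnot(inherits(trace, "signal_trace"))
  assert_that(trace$sampling_rate_hz == 1000, "spec",
              "delineation requires a 1 kHz trace")
  x <- trace_channel(trace, "ECG")
  n <- length(x)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  amp_max <- max(abs(x))
  thr <- max(0.4 * amp_max, 0.2, 8 * sigma)
  peaks <- local_maxima(abs(x), thr, 180)
  if (!length(peaks)) tdx_error("no_beats", "no beats detected in ECG channel")

  # beat classes from the coupling interval
  cls <- rep("regular", length(peaks))
  if (length(peaks) > 2) {
    cpl <- c(Inf, diff(peaks))
    med_rr <- stats::median(diff(peaks))
    cls[cpl < 0.8 * med_rr] <- "ectopic"
    # first complex of a fast run: flagged by the short interval to its
    # successor plus amplitude dissimilarity
    lead_in <- which(cls == "regular" &
                       c(cls[-1] == "ectopic", FALSE) &
                       c(diff(peaks) < 0.6 * med_rr, FALSE))
    amp_reg <- stats::median(abs(x[peaks[cls == "regular"]]))
    lead_in <- lead_in[abs(x[peaks[lead_in]]) > 1.15 * amp_reg]
    cls[lead_in] <- "ectopic"
  }
  reg <- which(cls == "regular")
  rr_ms <- if (length(reg) > 1) stats::median(diff(peaks[reg])) else n

  # ---- P-train estimation & subtraction ----------------------------------
  # candidate P peaks: prominent small local maxima in late diastole
  clean <- rep(FALSE, n)
  for (j in seq_along(reg)) {
    b <- reg[j]
    lo <- round(peaks[b] + 0.45 * rr_ms)
    hi <- if (b < length(peaks)) peaks[b + 1L] - 180L else n - 1L
    if (hi > lo) clean[lo:hi] <- TRUE
  }
  xc <- ifelse(clean & abs(x) < 0.8 * thr, x, -Inf)
  p_cand <- local_maxima(xc, max(0.06, 6 * sigma), 120)
  # prominence check: a genuine P peak rises above its surroundings on both
  # sides (rejects argmax points on a monotone T-wave tail)
  if (length(p_cand)) {
    okp <- vapply(p_cand, function(p) {
      l <- max(1L, p - 45L); r <- min(n, p + 45L)
      x[p] - max(x[l], x[r]) > 0.03 &&
        x[p] >= x[max(1L, p - 25L)] && x[p] >= x[min(n, p + 25L)]
    }, logical(1))
    p_cand <- p_cand[okp]
  }
  y <- x
  p_onsets <- numeric(0)
  p_train <- fit_p_train(p_cand - 1, n)
  if (!is.null(p_train)) {
    hw <- 90L
    usable <- p_cand[p_cand > hw & p_cand <= n - hw]
    if (length(usable) >= 3) {
      tmpl <- rowMeans(vapply(usable,
                              function(p) x[(p - hw):(p + hw)],
                              numeric(2L * hw + 1L)))
      tmpl <- tmpl - stats::median(tmpl[c(1:20, (2 * hw - 18):(2 * hw + 1))])
      sup <- which(tmpl > 0.05 * max(tmpl))
      on_off <- hw + 1L - min(sup)  # samples from P onset to P peak
      for (p in p_train$peaks) {
        i <- round(p) + 1L
        lo <- i - hw; hi <- i + hw
        if (lo >= 1 && hi <= n) y[lo:hi] <- y[lo:hi] - tmpl
      }
      p_onsets <- p_train$peaks - on_off
      p_onsets <- p_onsets[p_onsets >= 0]
    }
  }
  base <- stats::median(y)

  # ---- QRS onset/offset on the cleaned signal ----------------------------
  edge <- function(pk, dir) {
    a <- abs(y[pk]); sgn <- sign(y[pk])
    th <- max(0.02 * a, 4 * sigma)
    i <- pk
    below <- 0L
    while (i > 1 && i < n && below < 3L) {
      i <- i + dir
      below <- if (abs(y[i]) < th) below + 1L else 0L
    }
    i0 <- i - dir * 2L  # first sample below threshold
    idx <- sort(i0 + (-dir) * (0:7))
    idx <- idx[idx >= 1 & idx <= n]
    est <- limb_intercept_ms(sgn * y, idx)
    if (!is.finite(est)) est <- i0 - 1
    est
  }
  q_on <- vapply(peaks, edge, 0, dir = -1L)
  qrs_end <- vapply(peaks, edge, 0, dir = +1L)

  # ---- T end (tangent method on the cleaned signal) ----------------------
  t_end <- rep(NA_real_, length(peaks))
  for (b in reg) {
    lo <- round(qrs_end[b]) + 15L
    hi <- min(round(q_on[b] + 0.80 * rr_ms),
              if (b < length(peaks)) round(q_on[b + 1]) - 15L else n - 1L)
    if (hi - lo < 60) next
    seg <- (lo:hi) + 1L
    pk <- seg[which.max(y[seg])]
    a_t <- y[pk] - base
    if (a_t < max(0.05, 6 * sigma)) next
    after <- pk:max(seg)
    band <- after[y[after] - base < 0.85 * a_t & y[after] - base > 0.15 * a_t]
    if (length(band) < 4) next
    # keep the contiguous stretch adjacent to the peak (the descending limb)
    gaps <- which(diff(band) > 3)
    if (length(gaps)) band <- band[1:gaps[1]]
    if (length(band) < 4) next
    est <- limb_intercept_ms(y, band, level = base)
    # keep only plausible placements; implausible fits stay unresolved
    if (is.finite(est) && est > qrs_end[b] + 20 &&
        est < q_on[b] + 0.9 * rr_ms) t_end[b] <- est
  }

  ord <- order(q_on)
  beats <- data.frame(
    beat = seq_along(peaks), class = cls[ord], p_on = NA_real_,
    q_on = q_on[ord], qrs_end = qrs_end[ord], t_end = t_end[ord],
    stringsAsFactors = FALSE)
  for (b in seq_len(nrow(beats))) {
    prior <- p_onsets[p_onsets <= beats$q_on[b]]
    if (length(prior)) beats$p_on[b] <- max(prior)
  }
  beat_annotations(beats, p_waves = p_onsets)
}
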