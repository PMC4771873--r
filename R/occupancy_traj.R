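# Desk-scale trajectory statistics: per-site S1-S4 occupancy fractions and
# permeation-event detection on synthetic axial ion trajectories standing in
# for MD output.

#' Axial site windows of the selectivity filter
#'
#' Splits the filter span (default 1.2 nm, i.e. ~12 Angstrom) into equal
#' axial windows for the four ion-binding sites, S4 at the cavity end and S1
#' at the extracellular end; the cavity lies below the filter and the
#' extracellular bath above. A hysteresis margin around the filter defines
#' the entry/exit thresholds used by the permeation-event detector: an ion
#' must drop fully below `lower_threshold` and subsequently rise fully above
#' `upper_threshold` (or vice versa) to score a crossing, so partial
#' excursions into the filter are never counted. The window positions are a
#' package convention, not a measured quantity.
#'
#' @param filter_base Axial coordinate of the cavity end of the filter (nm).
#' @param filter_span Filter length (nm), default 1.2.
#' @param n_sites Number of equal site windows, default 4 (S1..S4).
#' @param hysteresis Threshold margin beyond the filter ends (nm).
#' @return An object of class `site_definition` with a `windows` data.frame
#'   (site, lo, hi; S1 first) and the two detector thresholds.
#' @export
site_definition <- function(filter_base = 0, filter_span = 1.2, n_sites = 4,
                            hysteresis = 0.05) {
  stopifnot(filter_span > 0, n_sites >= 1, hysteresis >= 0)
  edges <- seq(filter_base, filter_base + filter_span, length.out = n_sites + 1)
  # S1 is the extracellular (top) window
  windows <- data.frame(
    site = paste0("S", seq_len(n_sites)),
    lo = rev(edges[-length(edges)]),
    hi = rev(edges[-1]))
  structure(list(windows = windows,
                 lower_threshold = filter_base - hysteresis,
                 upper_threshold = filter_base + filter_span + hysteresis,
                 filter_base = filter_base, filter_span = filter_span,
                 hysteresis = hysteresis),
            class = "site_definition")
}

#' Per-frame axial ion coordinates
#'
#' @param positions Numeric matrix, frames x ions: axial coordinate (nm) of
#'   each tracked ion at each frame. Ions parked in the bulk are simply far
#'   outside the filter windows.
#' @param dt_ns Frame interval in nanoseconds (> 0).
#' @return An object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(positions, dt_ns = 1) {
  positions <- as.matrix(positions)
  stopifnot(is.numeric(positions), dt_ns > 0)
  if (any(!is.finite(positions))) stop("positions must be finite")
  structure(list(positions = positions, dt_ns = dt_ns,
                 n_frames = nrow(positions), n_ions = ncol(positions)),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("Ion trajectory: %d frames x %d ions, dt = %g ns (%.3g us)\n",
              x$n_frames, x$n_ions, x$dt_ns, x$n_frames * x$dt_ns / 1000))
  invisible(x)
}

# Hysteresis crossing detector for one ion's coordinate series. Returns
# frame indices at which the ion clears the far threshold of a full passage.
.detect_one_ion <- function(p, lo, hi) {
  mark <- integer(length(p))
  mark[p <= lo] <- -1L
  mark[p >= hi] <- 1L
  idx <- which(mark != 0L)
  if (length(idx) < 2)
    return(list(outward = integer(0), inward = integer(0)))
  r <- rle(mark[idx])
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  run_start_frame <- idx[starts]
  v <- r$values
  k <- seq_along(v)[-1]
  out_runs <- k[v[k] == 1L & v[k - 1L] == -1L]
  in_runs <- k[v[k] == -1L & v[k - 1L] == 1L]
  list(outward = run_start_frame[out_runs], inward = run_start_frame[in_runs])
}

#' Detect complete permeation events
#'
#' An outward event is one ion's passage from below the cavity-side threshold
#' to above the extracellular threshold; the event is attributed to the frame
#' at which the ion clears the far threshold. Both thresholds must be fully
#' crossed (hysteresis), so excursions that reach into the filter and return
#' are ignored. Inward events are the mirror image; time-reversing a
#' trajectory swaps the two counts.
#'
#' @param traj An [ion_trajectory()].
#' @param sites A [site_definition()].
#' @return List with `outward`/`inward` counts, event times in microseconds
#'   (`outward_times_us`, `inward_times_us`) and the total `rate_per_us`
#'   (outward events per microsecond of trajectory).
#' @export
detect_permeation_events <- function(traj, sites = site_definition()) {
  stopifnot(inherits(traj, "ion_trajectory"),
            inherits(sites, "site_definition"))
  if (traj$n_frames == 0 || traj$n_ions == 0) {
    warning("empty trajectory: no permeation events")
    return(list(outward = 0L, inward = 0L,
                outward_times_us = numeric(0), inward_times_us = numeric(0),
                rate_per_us = NaN))
  }
  lo <- sites$lower_threshold
  hi <- sites$upper_threshold
  out_frames <- integer(0)
  in_frames <- integer(0)
  for (j in seq_len(traj$n_ions)) {
    ev <- .detect_one_ion(traj$positions[, j], lo, hi)
    out_frames <- c(out_frames, ev$outward)
    in_frames <- c(in_frames, ev$inward)
  }
  dur_us <- traj$n_frames * traj$dt_ns / 1000
  list(outward = length(out_frames), inward = length(in_frames),
       outward_times_us = sort(out_frames) * traj$dt_ns / 1000,
       inward_times_us = sort(in_frames) * traj$dt_ns / 1000,
       rate_per_us = length(out_frames) / dur_us)
}

#' Per-site occupancy fractions
#'
#' Fraction of frames in which at least one ion sits inside each site window
#' (binary indicator per site; several sites may be occupied simultaneously,
#' so the fractions need not sum to 1).
#'
#' @param traj An [ion_trajectory()].
#' @param sites A [site_definition()].
#' @return Named numeric vector of class `site_occupancy` (S1..Sn, each in
#'   [0, 1]).
#' @export
site_occupancy_fractions <- function(traj, sites = site_definition()) {
  stopifnot(inherits(traj, "ion_trajectory"),
            inherits(sites, "site_definition"))
  if (traj$n_frames == 0) stop("trajectory has zero frames")
  w <- sites$windows
  occ <- vapply(seq_len(nrow(w)), function(i) {
    inside <- traj$positions >= w$lo[i] & traj$positions < w$hi[i]
    mean(rowSums(inside) > 0)
  }, numeric(1))
  structure(occ, names = w$site, class = "site_occupancy")
}

#' Expected simultaneous ion count in the filter
#'
#' Sum of the per-site occupancy fractions: the expectation of the number of
#' occupied sites under the per-site indicator decomposition. For the TRAAK
#' occupancies (0.58, 0.97, 0.65, 0.46) this gives 2.66 ions.
#'
#' @param occ A [site_occupancy_fractions()] result (or plain numeric vector
#'   of fractions).
#' @return Mean simultaneous ion count.
#' @export
expected_total_occupancy <- function(occ) {
  stopifnot(is.numeric(occ), all(occ >= 0), all(occ <= 1))
  sum(occ)
}

# Relative path of a complete outward crossing, frames ending at the event
# frame (clears the upper threshold on its last frame). Geometry assumes the
# default site_definition.
.CROSS_PATH <- c(-0.30, 0.15, 0.45, 0.75, 1.05, 1.30)
# Partial excursion reaching S2 and returning (a labeled distractor).
.EXCURSION_PATH <- c(-0.30, 0.45, 0.75, 0.45, -0.30)
.PARK_BELOW <- -3
.PARK_ABOVE <- 4.2

# Place a path into a column of the position matrix, ending at frame f_end.
.place_path <- function(col, path, f_end) {
  f0 <- f_end - length(path) + 1L
  col[f0:f_end] <- path
  col
}

#' Generate a synthetic permeation trajectory
#'
#' Poisson-distributed complete outward (and optionally inward) crossings at
#' a prescribed rate, partial-excursion distractors that enter the filter and
#' return, and four resident ions whose per-frame presence reproduces a
#' target per-site occupancy profile in expectation. Resident presence
#' probabilities are thinned to compensate for the frames that transiting
#' ions spend inside each window, so the recovered occupancy is unbiased.
#' The generator emits only complete crossings plus labeled distractors, so
#' the detector count equals the drawn crossing count exactly.
#'
#' @param rate Outward crossing rate, events per microsecond (>= 0). The
#'   default, 20 events/us, is the depolarised-filter rate the TRAAK
#'   trajectory fixtures emulate.
#' @param duration Trajectory length in microseconds (> 0).
#' @param occupancy_profile Target per-site occupancy fractions, named
#'   S1..S4. Default is the TRAAK profile (0.58, 0.97, 0.65, 0.46).
#' @param dt_ns Frame interval, ns (default 1).
#' @param distractor_rate Rate of partial excursions reaching S2, per us.
#' @param inward_rate Inward crossing rate, per us (default 0).
#' @param seed Optional RNG seed for reproducibility.
#' @param sites A [site_definition()]; must be the default geometry.
#' @return An [ion_trajectory()] with attribute `truth` (drawn event counts
#'   and frames).
#' @export
generate_trajectory <- function(rate = 20, duration = 10,
                                occupancy_profile = c(S1 = 0.58, S2 = 0.97,
                                                      S3 = 0.65, S4 = 0.46),
                                dt_ns = 1, distractor_rate = 2,
                                inward_rate = 0, seed = NULL,
                                sites = site_definition()) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate < 0)
    stop("rate must be a finite number >= 0")
  stopifnot(duration > 0, dt_ns > 0, distractor_rate >= 0, inward_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * 1000 / dt_ns)
  lp <- length(.CROSS_PATH)
  if (n < lp + 1) stop("duration too short for a complete crossing")

  n_out <- stats::rpois(1, rate * duration)
  n_in <- stats::rpois(1, inward_rate * duration)
  n_dis <- stats::rpois(1, distractor_rate * duration)
  f_out <- if (n_out) sort(sample.int(n - lp, n_out, replace = FALSE) + lp)
           else integer(0)
  f_in <- if (n_in) sort(sample.int(n - lp, n_in, replace = FALSE) + lp)
          else integer(0)
  f_dis <- if (n_dis) sample.int(n - length(.EXCURSION_PATH), n_dis,
                                 replace = FALSE) + length(.EXCURSION_PATH)
           else integer(0)

  w <- sites$windows
  in_window <- function(path, i) sum(path >= w$lo[i] & path < w$hi[i])
  # expected per-frame probability that a transiting ion covers each site
  lam <- vapply(seq_len(nrow(w)), function(i) {
    ((rate + inward_rate) * in_window(.CROSS_PATH, i) +
       distractor_rate * in_window(.EXCURSION_PATH, i)) * dt_ns / 1000
  }, numeric(1))
  q <- 1 - exp(-lam)
  prof <- occupancy_profile[w$site]
  if (any(is.na(prof)) || any(prof < 0) || any(prof > 1))
    stop("occupancy_profile must give fractions in [0, 1] for ",
         paste(w$site, collapse = ", "))
  p_res <- pmin(pmax((prof - q) / (1 - q), 0), 1)

  n_ion <- nrow(w) + n_out + n_in + n_dis
  pos <- matrix(.PARK_BELOW, n, n_ion)
  # resident ions, one per site, jittered within the window
  half <- (w$hi - w$lo) / 2
  for (i in seq_len(nrow(w))) {
    present <- stats::runif(n) < p_res[i]
    centre <- (w$lo[i] + w$hi[i]) / 2
    jitter <- stats::runif(n, -0.6 * half[i], 0.6 * half[i])
    pos[present, i] <- centre + jitter[present]
  }
  col <- nrow(w)
  for (f in f_out) {
    col <- col + 1L
    pos[, col] <- .place_path(pos[, col], .CROSS_PATH, f)
    if (f < n) pos[(f + 1):n, col] <- .PARK_ABOVE
  }
  for (f in f_in) {
    col <- col + 1L
    pos[, col] <- .PARK_ABOVE
    pos[, col] <- .place_path(pos[, col], rev(.CROSS_PATH), f)
    if (f < n) pos[(f + 1):n, col] <- .PARK_BELOW
  }
  for (f in f_dis) {
    col <- col + 1L
    pos[, col] <- .place_path(pos[, col], .EXCURSION_PATH, f)
  }
  traj <- ion_trajectory(pos, dt_ns = dt_ns)
  attr(traj, "truth") <- list(n_outward = n_out, n_inward = n_in,
                              n_distractor = n_dis,
                              outward_frames = f_out, inward_frames = f_in)
  traj
}
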