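#' Dead-time model
#'
#' Non-paralyzable dead time: after each recorded event the acquisition is
#' blind for `tau` seconds. The instantaneous recorded rate is estimated in
#' sliding windows of `window` seconds and inverted into per-event livetime
#' weights.
#'
#' @param tau dead time per event, s (nominal 5e-6).
#' @param window rate-estimation window, s (must exceed `tau`).
#' @return list of class `deadtime_model`.
#' @export
deadtime_model <- function(tau = 5e-6, window = 1e-3) {
  if (tau < 0) stop("tau must be >= 0")
  if (window <= tau) stop("window must be > tau")
  structure(list(tau = tau, window = window), class = "deadtime_model")
}

#' Livetime weights for recorded events
#'
#' Estimates the instantaneous *recorded* rate r(t) around each event by
#' counting recorded events in a sliding window (clamped to the observed
#' time span), and returns the non-paralyzable livetime inversion
#' `w = 1 / (1 - r * tau)`. For a Poisson stream of true rate lambda the
#' recorded rate is lambda / (1 + lambda tau), so the weight recovers
#' exactly the factor (1 + lambda tau) lost to dead time.
#'
#' @param timestamps event times, s, sorted ascending.
#' @param model a [deadtime_model()].
#' @return numeric per-event weights (>= 1).
#' @export
livetime_weights <- function(timestamps, model = deadtime_model()) {
  n <- length(timestamps)
  if (n == 0) return(numeric(0))
  if (is.unsorted(timestamps)) stop("timestamps must be sorted ascending")
  if (model$tau == 0) return(rep(1, n))
  w <- model$window
  hi <- findInterval(timestamps + w / 2, timestamps)
  lo <- findInterval(timestamps - w / 2, timestamps)
  cnt <- hi - lo
  span <- pmin(timestamps + w / 2, timestamps[n]) -
    pmax(timestamps - w / 2, timestamps[1])
  span <- pmax(span, model$tau)
  r <- cnt / span
  occ <- r * model$tau
  if (any(occ >= 0.9)) stop("dead-time correction out of validity (r * tau >= 0.9)")
  1 / (1 - occ)
}

#' Origin-classification windows
#'
#' Disjoint half-open windows `[z_min, z_max)` of PCA position along the
#' beam axis assigning each PCA to the range shifter (RS), the patient, or
#' neither. RS fragments are anatomy-independent and are excluded from the
#' morphological comparison but drive the positioning-systematic study.
#'
#' @param range_shifter,patient numeric length-2 `[z_min, z_max)` windows,
#'   mm along the beam axis.
#' @return list of class `origin_windows`.
#' @export
origin_windows <- function(range_shifter, patient) {
  stopifnot(length(range_shifter) == 2L, length(patient) == 2L)
  if (max(range_shifter[1], patient[1]) < min(range_shifter[2], patient[2])) {
    stop("origin windows must be disjoint")
  }
  structure(list(range_shifter = as.numeric(range_shifter),
                 patient = as.numeric(patient)), class = "origin_windows")
}

#' Classify PCA origin
#'
#' @param s_beam PCA positions along the beam axis, mm.
#' @param windows an [origin_windows()].
#' @return character vector: `"range_shifter"`, `"patient"` or `"other"`.
#' @export
classify_origin <- function(s_beam, windows) {
  out <- rep("other", length(s_beam))
  rs <- windows$range_shifter; pt <- windows$patient
  out[s_beam >= rs[1] & s_beam < rs[2]] <- "range_shifter"
  out[s_beam >= pt[1] & s_beam < pt[2]] <- "patient"
  out
}

#' Build a 1D emission profile
#'
#' Weighted histogram of PCA position along the beam axis for one SPB and
#' one fraction, carrying per-bin summed weights, summed squared weights and
#' raw counts.
#'
#' @param s_beam PCA positions along the beam axis, mm.
#' @param weights per-event weights (livetime); default 1.
#' @param edges uniform bin edges, mm (see [profile_edges()]).
#' @param spb_id,fraction_id identifiers carried in the profile.
#' @return list of class `emission_profile`: `edges`, `w`, `sumw2`,
#'   `counts` (per bin) and `n_raw` (all entries, in or out of range).
#' @export
build_profile <- function(s_beam, weights = NULL, edges, spb_id = NA,
                          fraction_id = NA) {
  if (is.null(weights)) weights <- rep(1, length(s_beam))
  stopifnot(length(weights) == length(s_beam))
  nb <- length(edges) - 1L
  bin <- findInterval(s_beam, edges, rightmost.closed = FALSE)
  ok <- bin >= 1L & bin <= nb & s_beam < edges[nb + 1L]
  b <- bin[ok]
  w <- as.numeric(tapply2(weights[ok], b, nb))
  s2 <- as.numeric(tapply2(weights[ok]^2, b, nb))
  cnt <- as.numeric(tapply2(rep(1, sum(ok)), b, nb))
  structure(list(spb_id = spb_id, fraction_id = fraction_id,
                 edges = as.numeric(edges), w = w, sumw2 = s2,
                 counts = cnt, n_raw = length(s_beam)),
            class = "emission_profile")
}

tapply2 <- function(v, bin, nb) {
  out <- numeric(nb)
  if (length(v)) {
    s <- rowsum(v, bin)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Uniform profile bin edges
#'
#' @param z_range `[lo, hi)` range covered, mm.
#' @param width bin width, mm (default 5).
#' @return numeric edges spanning at least `z_range`.
#' @export
profile_edges <- function(z_range = c(-15, 165), width = 5) {
  seq(z_range[1], z_range[1] + width * ceiling(diff(z_range) / width), by = width)
}

#' Leading-edge mask of a reference profile
#'
#' The rising edge of the emission profile is the region most sensitive to
#' mm-scale misalignment between fractions; its bins are excluded from the
#' chi-square sum. The mask marks as excluded (FALSE) every bin up to and
#' including the first bin whose content exceeds `threshold` of the profile
#' maximum; all later bins are included (TRUE).
#'
#' @param reference an [build_profile()] emission profile.
#' @param threshold fraction of the profile maximum ending the leading edge
#'   (default 0.5).
#' @return logical per-bin mask; TRUE = included in the comparison.
#' @export
leading_edge_mask <- function(reference, threshold = 0.5) {
  w <- reference$w
  if (all(w == 0)) {
    warning("all-zero reference profile: all bins excluded")
    return(rep(FALSE, length(w)))
  }
  stop_bin <- which(w > threshold * max(w))[1]
  mask <- seq_along(w) > stop_bin
  mask
}
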