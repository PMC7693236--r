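#' Chi-square comparison of two emission profiles
#'
#' Gaussian per-bin chi-square between two binned emission profiles, with
#' per-bin variances propagated from the summed squared weights and an
#' optional positioning-systematic band added in quadrature. Two
#' normalizations are available:
#'
#' * `"yield"` (default): both profiles are divided by the same external
#'   normalization `norm` (the SPB's planned ion count); the comparison is
#'   then sensitive to absolute emission yield per delivered ion, which is
#'   what makes the dead-time correction matter between sessions delivered
#'   at different beam intensities. No degree of freedom is lost.
#' * `"shape"`: each profile is divided by its own total (unit area); one
#'   degree of freedom is lost to the normalization constraint. In this
#'   mode, with unit weights, no systematics and equal totals, the statistic
#'   reduces exactly to the textbook two-histogram form
#'   sum (n_i - m_i)^2 / (n_i + m_i).
#'
#' Bins excluded by `mask` or with zero content in both profiles are
#' skipped. Fewer than 2 usable bins yields an undefined result
#' (`valid = FALSE`).
#'
#' @param ref,test [build_profile()] objects on identical binning.
#' @param mask logical per-bin mask (TRUE = use); see [leading_edge_mask()].
#' @param sigma_sys per-bin systematic sigma on the normalized scale (same
#'   length as bins), or NULL.
#' @param normalize `"yield"` or `"shape"`.
#' @param norm external normalization (scalar or `c(ref, test)`) used by the
#'   `"yield"` mode.
#' @return list: `chi2`, `ndf`, `p_chi2`, `n_bins_used`, `valid`.
#' @export
chi2_profiles <- function(ref, test, mask = NULL, sigma_sys = NULL,
                          normalize = c("yield", "shape"), norm = 1) {
  normalize <- match.arg(normalize)
  if (length(ref$w) != length(test$w) ||
      max(abs(ref$edges - test$edges)) > 1e-9) {
    stop("profiles must share identical binning")
  }
  nb <- length(ref$w)
  if (is.null(mask)) mask <- rep(TRUE, nb)
  if (is.null(sigma_sys)) sigma_sys <- rep(0, nb)
  if (normalize == "shape") {
    Nr <- sum(ref$w); Nt <- sum(test$w)
  } else {
    norm <- rep_len(norm, 2L)
    Nr <- norm[1]; Nt <- norm[2]
  }
  if (Nr <= 0 || Nt <= 0) {
    return(list(chi2 = NA_real_, ndf = NA_integer_, p_chi2 = NA_real_,
                n_bins_used = 0L, valid = FALSE))
  }
  p <- ref$w / Nr; q <- test$w / Nt
  vp <- ref$sumw2 / Nr^2; vq <- test$sumw2 / Nt^2
  use <- mask & (ref$w + test$w) > 0
  n_used <- sum(use)
  if (n_used < 2L) {
    return(list(chi2 = NA_real_, ndf = NA_integer_, p_chi2 = NA_real_,
                n_bins_used = n_used, valid = FALSE))
  }
  chi2 <- sum((p[use] - q[use])^2 /
                (vp[use] + vq[use] + sigma_sys[use]^2))
  ndf <- n_used - as.integer(normalize == "shape")
  list(chi2 = chi2, ndf = ndf,
       p_chi2 = stats::pchisq(chi2, df = ndf, lower.tail = FALSE),
       n_bins_used = n_used, valid = TRUE)
}

#' Two-sample Kolmogorov-Smirnov comparison of unbinned PCA positions
#'
#' Cross-check of the chi-square, free of the binning choice and sensitive
#' to shifted peaks. Both samples are restricted to a common window
#' (normally the unmasked z range of the reference profile).
#'
#' @param z_ref,z_test unbinned PCA positions along the beam axis, mm.
#' @param window `[lo, hi)` restriction, mm; NULL keeps everything.
#' @return asymptotic two-sample KS p-value, or NA if either restricted
#'   sample is empty.
#' @export
ks_profiles <- function(z_ref, z_test, window = NULL) {
  if (!is.null(window)) {
    z_ref <- z_ref[z_ref >= window[1] & z_ref < window[2]]
    z_test <- z_test[z_test >= window[1] & z_test < window[2]]
  }
  if (length(z_ref) == 0 || length(z_test) == 0) return(NA_real_)
  suppressWarnings(stats::ks.test(z_ref, z_test, exact = FALSE)$p.value)
}

#' Positioning systematic from range-shifter tracks
#'
#' The range shifter (RS) is an anatomy-independent fragment source, so any
#' apparent inter-fraction change of the RS emission profile reflects the
#' detector/patient positioning reproducibility. For each of `K` trials an
#' independent pose offset per axis is drawn from `Normal(0, sigma_xyz)`,
#' applied to the RS track coordinates, and the PCA profile is rebuilt. The
#' trial spread yields (a) a per-bin sigma of the unit-area RS profile, (b)
#' an effective longitudinal jitter `dz_eff` (sd of the profile mean shift,
#' scaled by sqrt(2) for two independently positioned sessions) and (c) a
#' relative acceptance jitter `dA_rel` (sd of the total RS yield, same
#' scaling). `dz_eff` and `dA_rel` propagate the systematic onto any SPB
#' profile via its own gradient, see [systematic_for_profile()]. The
#' ref-vs-test RS profile mean shift is returned as an alignment diagnostic.
#'
#' @param rs_tracks_ref,rs_tracks_test room-frame track tables of RS-labeled
#'   tracks in the two fractions.
#' @param plan the plan table (for the PB axes).
#' @param pose the [detector_pose()] carrying `sigma_xyz`.
#' @param edges profile bin edges used for the RS profiles, mm.
#' @param K number of shift trials (>= 50).
#' @param seed RNG seed for the trials.
#' @param max_tracks cap on RS tracks used per trial (deterministic
#'   thinning; the band is a smooth profile, so a subsample suffices).
#' @return list of class `systematic_band`: `sigma_rs` (per-bin),
#'   `dz_eff` (mm), `dA_rel`, `mean_shift` (mm, ref vs test diagnostic),
#'   `K`.
#' @export
positioning_systematic <- function(rs_tracks_ref, rs_tracks_test, plan, pose,
                                   edges, K = 100, seed = 1L,
                                   max_tracks = 5000) {
  nb <- length(edges) - 1L
  empty <- structure(list(sigma_rs = rep(0, nb), dz_eff = 0, dA_rel = 0,
                          mean_shift = NA_real_, K = K),
                     class = "systematic_band")
  if (nrow(rs_tracks_ref) == 0 || nrow(rs_tracks_test) == 0) {
    warning("no RS tracks available: zero systematic band")
    return(empty)
  }
  if (K < 1) return(empty)
  if (nrow(rs_tracks_ref) > max_tracks) {
    sel <- round(seq(1, nrow(rs_tracks_ref), length.out = max_tracks))
    rs_tracks_ref <- rs_tracks_ref[sel, , drop = FALSE]
  }
  rs_profile <- function(tr, dxyz = c(0, 0, 0)) {
    tr$x <- tr$x + dxyz[1]; tr$y <- tr$y + dxyz[2]; tr$z <- tr$z + dxyz[3]
    pca <- compute_pca(tr, plan)
    build_profile(pca$s_beam, edges = edges)
  }
  prof_mean <- function(pr) {
    mid <- (pr$edges[-1] + pr$edges[-length(pr$edges)]) / 2
    sum(mid * pr$w) / sum(pr$w)
  }
  base <- rs_profile(rs_tracks_ref)
  base_n <- base$w / max(sum(base$w), 1)
  mat <- matrix(0, nrow = K, ncol = nb)
  means <- numeric(K)
  totals <- numeric(K)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  for (k in seq_len(K)) {
    dxyz <- stats::rnorm(3, 0, pose$sigma_xyz)
    pr <- rs_profile(rs_tracks_ref, dxyz)
    tot <- sum(pr$w)
    mat[k, ] <- pr$w / max(tot, 1)
    means[k] <- prof_mean(pr)
    totals[k] <- tot
  }
  test_prof <- rs_profile(rs_tracks_test)
  structure(list(
    sigma_rs = apply(mat, 2, stats::sd),
    dz_eff = sqrt(2) * stats::sd(means),
    dA_rel = sqrt(2) * stats::sd(totals) / max(mean(totals), 1),
    mean_shift = prof_mean(test_prof) - prof_mean(base),
    K = K), class = "systematic_band")
}

#' Propagate the positioning systematic onto an SPB profile
#'
#' Converts the effective longitudinal jitter and acceptance jitter of a
#' [positioning_systematic()] band into a per-bin sigma for one SPB
#' comparison, on the normalized scale of the comparison:
#' `sigma_i^2 = (dP/dz_i * dz_eff)^2 + (P_i * dA_rel)^2` with `P` the
#' average of the two normalized profiles and `dP/dz` its central
#' difference.
#'
#' @param band a `systematic_band`.
#' @param ref,test the SPB profiles being compared.
#' @param normalize,norm as in [chi2_profiles()].
#' @return per-bin sigma vector on the normalized scale.
#' @export
systematic_for_profile <- function(band, ref, test,
                                   normalize = c("yield", "shape"), norm = 1) {
  normalize <- match.arg(normalize)
  if (normalize == "shape") {
    p <- ref$w / max(sum(ref$w), 1); q <- test$w / max(sum(test$w), 1)
  } else {
    norm <- rep_len(norm, 2L)
    p <- ref$w / norm[1]; q <- test$w / norm[2]
  }
  P <- (p + q) / 2
  dz <- if (!is.null(band$dz_band) && is.finite(band$dz_band)) {
    band$dz_band
  } else {
    band$dz_eff
  }
  h <- diff(ref$edges[1:2])
  nb <- length(P)
  grad <- numeric(nb)
  if (nb >= 3) grad[2:(nb - 1)] <- (P[3:nb] - P[1:(nb - 2)]) / (2 * h)
  if (nb >= 2) {
    grad[1] <- (P[2] - P[1]) / h
    grad[nb] <- (P[nb] - P[nb - 1]) / h
  }
  sqrt((grad * dz)^2 + (P * band$dA_rel)^2)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
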