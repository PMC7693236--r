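#' Comparison configuration
#'
#' Collects every tunable of the inter-fraction comparison. Defaults follow
#' the clinical operating point: flagging threshold 2%, at least 100 PCA
#' entries per SPB and side, 5 mm profile bins, non-paralyzable dead-time
#' correction with tau = 5 us, and the yield normalization (per planned
#' ion), which makes the comparison sensitive to dead-time miscorrection.
#'
#' @param alpha flagging threshold on the chi-square p-value.
#' @param min_entries minimum raw PCA entries per SPB on each side.
#' @param edges profile bin edges, mm.
#' @param windows an [origin_windows()].
#' @param deadtime a [deadtime_model()].
#' @param deadtime_correction apply livetime weights (set FALSE only to
#'   study the uncorrected behaviour).
#' @param pose the [detector_pose()] (carries `sigma_xyz` for the
#'   positioning systematic).
#' @param sys_trials shift trials for the positioning systematic (0
#'   disables the band).
#' @param seed seed for the systematic trials.
#' @param normalize `"yield"` or `"shape"`, see [chi2_profiles()].
#' @param leading_threshold leading-edge threshold, see
#'   [leading_edge_mask()].
#' @param align_correction realign the test fraction longitudinally by the
#'   RS-measured inter-fraction shift before comparing (the positioning
#'   correction); the residual band keeps a `transfer_frac` allowance for
#'   the imperfect transfer of the RS-measured shift to patient SPBs.
#' @param transfer_frac fraction of the measured shift retained as residual
#'   systematic after realignment.
#' @return list of class `compare_config`.
#' @export
compare_config <- function(alpha = 0.02, min_entries = 100,
                           edges = profile_edges(),
                           windows = default_origin_windows(),
                           deadtime = deadtime_model(),
                           deadtime_correction = TRUE,
                           pose = nominal_pose(),
                           sys_trials = 60, seed = 1L,
                           normalize = "yield",
                           leading_threshold = 0.5,
                           align_correction = TRUE,
                           transfer_frac = 0.25) {
  structure(list(alpha = alpha, min_entries = min_entries, edges = edges,
                 windows = windows, deadtime = deadtime,
                 deadtime_correction = deadtime_correction, pose = pose,
                 sys_trials = sys_trials, seed = seed, normalize = normalize,
                 leading_threshold = leading_threshold,
                 align_correction = align_correction,
                 transfer_frac = transfer_frac),
            class = "compare_config")
}

#' Default origin windows for the nominal setup
#'
#' RS window: the range-shifter slab z extent padded by 3 sigma of the 7 mm
#' single-track resolution; patient window: the phantom z extent with the
#' same padding upstream (kept disjoint from the RS window).
#'
#' @param rs_slab z extent of the range-shifter slab, mm.
#' @param patient_z z extent assigned to the patient, mm.
#' @return an [origin_windows()].
#' @export
default_origin_windows <- function(rs_slab = c(-80, -50),
                                   patient_z = c(-15, 165)) {
  pad <- 3 * 7
  origin_windows(range_shifter = c(rs_slab[1] - pad, rs_slab[2] + pad),
                 patient = patient_z)
}

process_fraction <- function(tracks, plan, config) {
  validate_tracks(tracks)
  tracks <- tracks[order(tracks$t), , drop = FALSE]
  w <- if (config$deadtime_correction) {
    livetime_weights(tracks$t, config$deadtime)
  } else rep(1, nrow(tracks))
  pca <- compute_pca(tracks, plan)
  pca$weight <- w
  pca$label <- classify_origin(pca$s_beam, config$windows)
  list(tracks = tracks, pca = pca,
       rs_tracks = tracks[pca$label == "range_shifter", , drop = FALSE],
       fraction_id = tracks$fraction_id[1])
}

#' Compare two fractions SPB by SPB
#'
#' Full per-SPB statistical comparison of two fractions of the same plan:
#' livetime weighting, PCA backprojection, origin classification, per-SPB
#' emission profiles, leading-edge masking, positioning-systematic band,
#' chi-square (primary) and KS (cross-check) tests, and flagging at
#' `p_chi2 < alpha` for SPBs with at least `min_entries` raw PCAs on both
#' sides.
#'
#' @param ref_tracks,test_tracks room-frame track tables of the reference
#'   and test fractions (same plan).
#' @param plan the shared [plan_table()].
#' @param membership SPB membership from [merge_into_spbs()]; if NULL it is
#'   computed from `plan` and `phantom` (the planning anatomy), making SPB
#'   definitions fraction-independent.
#' @param phantom planning [make_phantom()] (used only when `membership` is
#'   NULL).
#' @param config a [compare_config()].
#' @return object of class `fraction_report`: per-SPB `results` data frame
#'   (statistics, p-values, entries, flag, and the test-fraction PCA-cloud
#'   centroid `cx`, `cy`, `cz` of each SPB), `n_tested`, `n_flagged`,
#'   expected null flags, the flagged-SPB PCA cloud (test fraction), and
#'   the systematic band.
#' @export
compare_fractions <- function(ref_tracks, test_tracks, plan,
                              membership = NULL, phantom = NULL,
                              config = compare_config()) {
  if (is.null(membership)) {
    if (is.null(phantom)) stop("provide either membership or phantom")
    er <- compute_end_range(plan, phantom)
    membership <- merge_into_spbs(er)
  }
  ref <- process_fraction(ref_tracks, plan, config)
  test <- process_fraction(test_tracks, plan, config)

  # positioning correction: the RS is anatomy-independent, so the
  # inter-fraction shift of its PCA centroid measures the relative
  # misalignment of the two sessions; the test fraction is realigned by it.
  rs_z_ref <- ref$pca$s_beam[ref$pca$label == "range_shifter"]
  rs_z_test <- test$pca$s_beam[test$pca$label == "range_shifter"]
  meas_shift <- NA_real_
  shift_sem <- 0
  if (length(rs_z_ref) > 1 && length(rs_z_test) > 1) {
    meas_shift <- mean(rs_z_test) - mean(rs_z_ref)
    shift_sem <- sqrt(stats::var(rs_z_ref) / length(rs_z_ref) +
                        stats::var(rs_z_test) / length(rs_z_test))
    if (config$align_correction) {
      test$pca$s_beam <- test$pca$s_beam - meas_shift
      test$pca$z <- test$pca$z - meas_shift
    }
  }

  spb_of <- function(fr) membership$spb_id[match(fr$pca$pb_id, membership$pb_id)]
  ref_spb <- spb_of(ref); test_spb <- spb_of(test)
  pat_r <- ref$pca$label == "patient" & !is.na(ref_spb)
  pat_t <- test$pca$label == "patient" & !is.na(test_spb)
  n_r <- table(ref_spb[pat_r]); n_t <- table(test_spb[pat_t])
  shared <- intersect(names(n_r), names(n_t))
  if (length(shared) == 0) stop("no shared SPBs between the two fractions")
  tested <- shared[n_r[shared] >= config$min_entries &
                   n_t[shared] >= config$min_entries]

  band <- if (config$sys_trials > 0 && any(config$pose$sigma_xyz > 0)) {
    rs_edges <- profile_edges(config$windows$range_shifter,
                              width = diff(config$edges[1:2]))
    positioning_systematic(ref$rs_tracks, test$rs_tracks, plan,
                           config$pose, rs_edges,
                           K = config$sys_trials, seed = config$seed)
  } else {
    structure(list(sigma_rs = rep(0, length(config$edges) - 1L),
                   dz_eff = 0, dA_rel = 0, mean_shift = NA_real_, K = 0),
              class = "systematic_band")
  }
  band$mean_shift <- meas_shift
  # residual longitudinal systematic after realignment: imperfect transfer
  # of the RS-measured shift to patient geometry plus the measurement sem;
  # without realignment the full prior spread from the trials applies
  band$dz_band <- if (config$align_correction && is.finite(meas_shift)) {
    sqrt((config$transfer_frac * meas_shift)^2 + shift_sem^2)
  } else {
    band$dz_eff
  }

  spb_ions <- tapply(plan$n_ions,
                     membership$spb_id[match(plan$pb_id, membership$pb_id)],
                     sum)

  idx_r <- split(which(pat_r), ref_spb[pat_r])
  idx_t <- split(which(pat_t), test_spb[pat_t])
  rows <- vector("list", length(tested))
  clouds <- vector("list", length(tested))
  for (i in seq_along(tested)) {
    id <- tested[i]
    ir <- idx_r[[id]]; it <- idx_t[[id]]
    pr <- build_profile(ref$pca$s_beam[ir], ref$pca$weight[ir],
                        config$edges, id, ref$fraction_id)
    pt <- build_profile(test$pca$s_beam[it], test$pca$weight[it],
                        config$edges, id, test$fraction_id)
    mask <- leading_edge_mask(pr, config$leading_threshold)
    nrm <- rep(as.numeric(spb_ions[id]), 2)
    ssys <- systematic_for_profile(band, pr, pt, config$normalize, nrm)
    cs <- chi2_profiles(pr, pt, mask, ssys, config$normalize, nrm)
    if (!cs$valid) next
    first_used <- which(mask)[1]
    win <- c(config$edges[first_used], config$edges[length(config$edges)])
    pks <- ks_profiles(ref$pca$s_beam[ir], test$pca$s_beam[it], win)
    flg <- is.finite(cs$p_chi2) && cs$p_chi2 < config$alpha
    rows[[i]] <- data.frame(spb_id = id, chi2 = cs$chi2, ndf = cs$ndf,
                            p_chi2 = cs$p_chi2, p_ks = pks,
                            n_ref = as.integer(n_r[id]),
                            n_test = as.integer(n_t[id]),
                            flagged = flg,
                            cx = mean(test$pca$x[it]),
                            cy = mean(test$pca$y[it]),
                            cz = mean(test$pca$s_beam[it]))
    if (flg) {
      clouds[[i]] <- test$pca[it, c("x", "y", "z")]
    }
  }
  results <- do.call(rbind, rows)
  if (is.null(results)) stop("no SPB comparison was defined")
  cloud <- do.call(rbind, clouds)
  structure(list(
    reference_fraction_id = ref$fraction_id,
    test_fraction_id = test$fraction_id,
    results = results,
    n_tested = nrow(results),
    n_flagged = sum(results$flagged),
    expected_null_flags = config$alpha * nrow(results),
    alpha = config$alpha,
    flagged_pca_cloud = if (is.null(cloud)) {
      data.frame(x = numeric(), y = numeric(), z = numeric())
    } else cloud,
    band = band), class = "fraction_report")
}

#' @export
print.fraction_report <- function(x, ...) {
  cat("fraction comparison:", x$reference_fraction_id, "vs",
      x$test_fraction_id, "\n")
  cat(sprintf("  SPBs tested: %d   flagged at p < %.3g: %d (null expectation %.1f)\n",
              x$n_tested, x$alpha, x$n_flagged, x$expected_null_flags))
  cat(sprintf("  RS alignment diagnostic: mean shift %.2f mm, dz_eff %.2f mm\n",
              x$band$mean_shift, x$band$dz_eff))
  invisible(x)
}
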