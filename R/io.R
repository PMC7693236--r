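#' Read and write track lists
#'
#' Columnar track tables with header-named columns
#' `x,y,z,dx,dy,dz,t,pb_id,fraction_id`. The text form is plain CSV
#' (comma-separated, `.` decimal, `#` comment lines); the binary form is an
#' Arrow/Feather file (extension `.feather`, requires the `arrow` package)
#' whose round trip is bit-stable.
#'
#' @param tracks a [track_table()].
#' @param path output/input file; format chosen by extension (`.feather`
#'   for the binary container, anything else is CSV).
#' @return `write_tracks`: the path, invisibly. `read_tracks`: a validated
#'   [track_table()].
#' @export
write_tracks <- function(tracks, path) {
  if (grepl("\\.feather$", path)) {
    require_arrow()
    arrow::write_feather(as.data.frame(tracks), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# fragmon track list (mm, s; room frame)", con)
    utils::write.csv(as.data.frame(tracks), con, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- if (grepl("\\.feather$", path)) {
    require_arrow()
    as.data.frame(arrow::read_feather(path))
  } else {
    utils::read.csv(path, comment.char = "#")
  }
  need <- c("x", "y", "z", "dx", "dy", "dz", "t", "pb_id", "fraction_id")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("track file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tr$fraction_id <- as.character(tr$fraction_id)
  validate_tracks(tr)
  class(tr) <- c("track_table", "data.frame")
  tr
}

require_arrow <- function() {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the binary track container requires the 'arrow' package")
  }
}

#' Read and write plan spot lists
#'
#' Columnar text table `pb_id,x_mm,y_mm,energy_MeV_u,n_ions,field_deg` with
#' `#` comments; row order is delivery order.
#'
#' @param plan a [plan_table()].
#' @param path file path.
#' @export
write_plan <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fragmon plan spot list (delivery order)", con)
  utils::write.csv(as.data.frame(plan), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  pl <- utils::read.csv(path, comment.char = "#")
  need <- c("pb_id", "x_mm", "y_mm", "energy_MeV_u", "n_ions", "field_deg")
  miss <- setdiff(need, names(pl))
  if (length(miss)) {
    stop("plan file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  plan_table(pl$pb_id, pl$x_mm, pl$y_mm, pl$energy_MeV_u, pl$n_ions,
             pl$field_deg)
}

#' Write a fraction comparison report as JSON
#'
#' Per-SPB records (chi-square, ndf, p-values, entries, flag) plus the
#' summary block (tested/flagged counts, null expectation, alignment
#' diagnostics).
#'
#' @param report a `fraction_report` from [compare_fractions()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  out <- list(
    reference_fraction_id = report$reference_fraction_id,
    test_fraction_id = report$test_fraction_id,
    summary = list(n_tested = report$n_tested,
                   n_flagged = report$n_flagged,
                   expected_null_flags = report$expected_null_flags,
                   alpha = report$alpha,
                   rs_mean_shift_mm = report$band$mean_shift,
                   dz_eff_mm = report$band$dz_eff),
    results = report$results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Per-SPB emission profiles of one fraction
#'
#' Processes a fraction's tracks into dead-time-corrected, patient-labeled
#' per-SPB emission profiles (the persistent intermediate of the pipeline).
#'
#' @param tracks a room-frame [track_table()].
#' @param plan the [plan_table()].
#' @param membership SPB membership from [merge_into_spbs()].
#' @param config a [compare_config()].
#' @return named list of [build_profile()] objects, one per SPB with at
#'   least one patient PCA.
#' @export
fraction_profiles <- function(tracks, plan, membership,
                              config = compare_config()) {
  fr <- process_fraction(tracks, plan, config)
  spb <- membership$spb_id[match(fr$pca$pb_id, membership$pb_id)]
  pat <- which(fr$pca$label == "patient" & !is.na(spb))
  idx <- split(pat, spb[pat])
  lapply(idx, function(i) {
    build_profile(fr$pca$s_beam[i], fr$pca$weight[i], config$edges,
                  spb_id = spb[i[1]], fraction_id = fr$fraction_id)
  })
}

#' Profile store
#'
#' Writes/reads a per-fraction profile container: one record per SPB
#' (edges, weights, sumw2, counts, n_raw) plus run metadata (fraction id,
#' seed, configuration hash), as JSON.
#'
#' @param profiles named list from [fraction_profiles()].
#' @param path JSON file path.
#' @param metadata list of run metadata stored alongside (seed, hashes...).
#' @export
write_profile_store <- function(profiles, path, metadata = list()) {
  out <- list(metadata = metadata,
              profiles = lapply(profiles, function(p) {
                list(spb_id = p$spb_id, fraction_id = p$fraction_id,
                     edges = p$edges, w = p$w, sumw2 = p$sumw2,
                     counts = p$counts, n_raw = p$n_raw)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_store
#' @export
read_profile_store <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  profiles <- lapply(raw$profiles, function(p) {
    structure(list(spb_id = p$spb_id, fraction_id = p$fraction_id,
                   edges = as.numeric(p$edges), w = as.numeric(p$w),
                   sumw2 = as.numeric(p$sumw2),
                   counts = as.numeric(p$counts),
                   n_raw = as.integer(p$n_raw)),
              class = "emission_profile")
  })
  list(metadata = raw$metadata, profiles = profiles)
}

#' Configuration hash
#'
#' Stable md5 fingerprint of any R configuration object, recorded in output
#' artifacts for provenance.
#'
#' @param x any serializable object.
#' @return character md5 string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Per-fraction flagged-SPB count table
#'
#' Aggregates several comparison reports (each test fraction against the
#' common reference) into the per-session flag-count table used to follow a
#' progressing morphological change, with a Poisson uncertainty on each
#' count and the alpha x N null expectation for context.
#'
#' @param reports list of `fraction_report` objects.
#' @return `data.frame`: test fraction, SPBs tested, flags, Poisson error,
#'   null expectation.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(test_fraction_id = r$test_fraction_id,
               n_tested = r$n_tested,
               n_flagged = r$n_flagged,
               flag_err = sqrt(max(r$n_flagged, 1)),
               expected_null = r$expected_null_flags)
  }))
}
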