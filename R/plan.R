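#' Construct a treatment-plan spot table
#'
#' One row per pencil beam (PB), in delivery order: lateral spot position at
#' the isocenter plane, kinetic energy per nucleon, planned ion count and
#' field angle.
#'
#' @param pb_id integer PB identifiers (unique).
#' @param x_mm,y_mm spot lateral position at the isocenter plane, mm.
#' @param energy_MeV_u kinetic energy, MeV/u (sanity bounds 50-500).
#' @param n_ions planned ions per PB (>= 1).
#' @param field_deg field angle, degrees (room convention).
#' @return `data.frame` with class `plan_table`; row order is delivery order.
#' @export
plan_table <- function(pb_id, x_mm, y_mm, energy_MeV_u, n_ions, field_deg = 0) {
  pl <- data.frame(pb_id = as.integer(pb_id), x_mm = as.numeric(x_mm),
                   y_mm = as.numeric(y_mm),
                   energy_MeV_u = as.numeric(energy_MeV_u),
                   n_ions = as.numeric(n_ions),
                   field_deg = rep_len(as.numeric(field_deg), length(pb_id)))
  if (anyDuplicated(pl$pb_id)) stop("pb_id must be unique")
  if (any(pl$n_ions < 1)) stop("n_ions must be >= 1")
  if (any(pl$energy_MeV_u < 50 | pl$energy_MeV_u > 500)) {
    stop("energy_MeV_u outside sanity bounds [50, 500]")
  }
  class(pl) <- c("plan_table", "data.frame")
  pl
}

#' Bragg-Kleeman range-energy relation
#'
#' Range in water `R(E) = alpha * E^p` (mm, E in MeV/u) and its inverse.
#' Only relative end-range geometry matters for SPB grouping, so the
#' constants are configuration parameters with carbon-appropriate defaults.
#'
#' @param energy kinetic energy, MeV/u.
#' @param alpha,p Bragg-Kleeman constants (mm scale).
#' @return Range in water, mm.
#' @export
range_in_water <- function(energy, alpha = 0.0094, p = 1.75) {
  alpha * energy^p
}

#' @rdname range_in_water
#' @param range_mm range in water, mm.
#' @export
energy_for_range <- function(range_mm, alpha = 0.0094, p = 1.75) {
  (range_mm / alpha)^(1 / p)
}

#' End-range points of the plan's pencil beams
#'
#' For each PB the total range in water from the Bragg-Kleeman relation is
#' reduced by the range-shifter water-equivalent thickness, then consumed by
#' marching along +z through the phantom in fixed steps weighted by the
#' local relative density; the returned point is where the residual range is
#' exhausted. A PB whose range is spent before entering the phantom ends at
#' the entry face with `wepl = 0`.
#'
#' @param plan a [plan_table()].
#' @param phantom a [make_phantom()] object covering the PB axes.
#' @param range_shifter_wet range-shifter water-equivalent thickness, mm
#'   (nominal 30, a 3 cm solid-water slab).
#' @param alpha,p Bragg-Kleeman constants, see [range_in_water()].
#' @param step marching step, mm.
#' @return `data.frame`: `pb_id`, end-range point `x`, `y`, `z` (mm), and
#'   `wepl` (water-equivalent depth consumed inside the phantom, mm).
#' @export
compute_end_range <- function(plan, phantom, range_shifter_wet = 30,
                              alpha = 0.0094, p = 1.75, step = 1) {
  if (range_shifter_wet < 0) stop("range_shifter_wet must be >= 0")
  resid <- range_in_water(plan$energy_MeV_u, alpha, p) - range_shifter_wet
  z0 <- phantom$origin[3]
  key <- paste(plan$x_mm, plan$y_mm)
  cols <- !duplicated(key)
  prof <- column_density(phantom, plan$x_mm[cols], plan$y_mm[cols], step = step)
  cum <- apply(prof$dens * step, 2, cumsum)
  colmap <- match(key, key[cols])
  zend <- numeric(nrow(plan))
  wepl <- pmax(resid, 0)
  for (i in seq_len(nrow(plan))) {
    r <- resid[i]
    if (r <= 0) { zend[i] <- z0; wepl[i] <- 0; next }
    cw <- cum[, colmap[i]]
    k <- findInterval(r, cw) + 1L   # first step whose cumulative WEPL >= r
    if (k > length(cw)) stop("range beyond phantom for pb_id ", plan$pb_id[i])
    prev <- if (k == 1L) 0 else cw[k - 1L]
    dk <- (cw[k] - prev) / step     # local density in the crossing step
    zend[i] <- z0 + (k - 1L) * step + (r - prev) / max(dk, .Machine$double.eps)
  }
  data.frame(pb_id = plan$pb_id, x = plan$x_mm, y = plan$y_mm,
             z = zend, wepl = wepl)
}

#' Aggregate pencil beams into super pencil beams
#'
#' PBs whose end ranges fall in the same aggregation cell (a half-open box
#' grid anchored at the isocenter, cell boundaries at integer multiples of
#' the cell dimensions) are merged into super pencil beams (SPB) of at most
#' `max_members` PBs, filling consecutive SPBs in delivery order. Every PB
#' belongs to exactly one SPB.
#'
#' @param end_ranges output of [compute_end_range()], in delivery order.
#' @param cell aggregation-cell dimensions (x, y, z), mm; default 10 x 10 x
#'   6 mm.
#' @param max_members cap on PBs per SPB (default 75).
#' @return `data.frame` with one row per PB, in delivery order: `pb_id`,
#'   `spb_id`, cell indices `ci`, `cj`, `ck`. SPB ids are deterministic for
#'   identical inputs.
#' @export
merge_into_spbs <- function(end_ranges, cell = c(10, 10, 6), max_members = 75) {
  if (any(cell <= 0)) stop("cell dimensions must be > 0")
  if (nrow(end_ranges) == 0) {
    return(data.frame(pb_id = integer(), spb_id = character(),
                      ci = integer(), cj = integer(), ck = integer()))
  }
  ci <- floor(end_ranges$x / cell[1])
  cj <- floor(end_ranges$y / cell[2])
  ck <- floor(end_ranges$z / cell[3])
  key <- paste(ci, cj, ck, sep = ",")
  # delivery-order position within each cell -> consecutive chunks of <= cap
  chunk <- stats::ave(seq_len(nrow(end_ranges)), key,
                      FUN = function(v) ceiling(seq_along(v) / max_members))
  spb_key <- paste(key, chunk, sep = "#")
  # deterministic ids: cells ordered lexicographically by (ci, cj, ck, chunk)
  u <- unique(spb_key)
  parts <- do.call(rbind, strsplit(sub("#", ",", u), ","))
  ou <- u[order(as.integer(parts[, 1]), as.integer(parts[, 2]),
                as.integer(parts[, 3]), as.integer(parts[, 4]))]
  spb_id <- sprintf("spb_%04d", match(spb_key, ou))
  data.frame(pb_id = end_ranges$pb_id, spb_id = spb_id,
             ci = ci, cj = cj, ck = ck)
}

#' Per-SPB summary
#'
#' @param membership output of [merge_into_spbs()].
#' @param end_ranges matching [compute_end_range()] output.
#' @return `data.frame`: `spb_id`, member count, end-range centroid.
#' @export
spb_summary <- function(membership, end_ranges) {
  er <- end_ranges[match(membership$pb_id, end_ranges$pb_id), ]
  agg <- function(v) tapply(v, membership$spb_id, mean)
  n <- tapply(membership$pb_id, membership$spb_id, length)
  data.frame(spb_id = names(n), n_members = as.integer(n),
             cx = as.numeric(agg(er$x)), cy = as.numeric(agg(er$y)),
             cz = as.numeric(agg(er$z)), row.names = NULL)
}
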