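#' Build a voxel phantom
#'
#' A phantom is a voxel grid of density relative to water, emulating the
#' patient anatomy seen by the plan: a homogeneous body box with an optional
#' internal cavity whose filling state can be varied between fractions to
#' emulate the gradual emptying of, e.g., nasal cavities. Cavity voxels take
#' density `rho_empty + fill * (1 - rho_empty)`, so `fill = 1` reproduces
#' the intact body and `fill = 0` an air-like cavity.
#'
#' @param body_size body box edge lengths (x, y, z), mm.
#' @param body_origin position of the body box low corner, mm; the default
#'   centers the box laterally on the isocenter with the entry face at z = 0.
#' @param vox isotropic voxel edge, mm (plan voxels are 2 mm).
#' @param base_density body density relative to water.
#' @param cavity `NULL`, or a list with `box` (2 x 3 matrix: low and high
#'   corners, mm), `fill` in `[0, 1]`, and optionally `rho_empty`.
#' @return An object of class `phantom`: density array plus grid geometry.
#' @export
make_phantom <- function(body_size = c(120, 120, 160),
                         body_origin = c(-60, -60, 0),
                         vox = 2, base_density = 1, cavity = NULL) {
  n <- as.integer(round(body_size / vox))
  dens <- array(base_density, dim = n)
  ph <- structure(list(density = dens, vox = vox, origin = as.numeric(body_origin)),
                  class = "phantom")
  if (!is.null(cavity)) {
    fill <- cavity$fill
    if (is.null(fill) || fill < 0 || fill > 1) stop("cavity fill must be in [0, 1]")
    rho_empty <- if (is.null(cavity$rho_empty)) 0.05 else cavity$rho_empty
    box <- cavity$box
    lo <- pmin(box[1, ], box[2, ]); hi <- pmax(box[1, ], box[2, ])
    ilo <- floor((lo - ph$origin) / vox) + 1
    ihi <- ceiling((hi - ph$origin) / vox)
    if (any(ilo < 1) || any(ihi > n)) stop("cavity box extends outside the body")
    rho <- rho_empty + fill * (base_density - rho_empty)
    ph$density[ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3]] <- rho
  }
  ph
}

#' Density sampled along +z columns of a phantom
#'
#' Midpoint-sampled density profiles along beam-direction columns, used by
#' the end-range marcher.
#'
#' @param phantom a [make_phantom()] object.
#' @param x,y lateral column positions, mm (same length).
#' @param step sampling step along z, mm.
#' @return list with `z` (midpoint depths, mm) and `dens` (length(z) x
#'   length(x) matrix); depths outside the grid have density 0.
#' @keywords internal
column_density <- function(phantom, x, y, step = 1) {
  n <- dim(phantom$density)
  z0 <- phantom$origin[3]
  zmax <- z0 + n[3] * phantom$vox
  z <- seq(z0 + step / 2, zmax - step / 2, by = step)
  ix <- floor((x - phantom$origin[1]) / phantom$vox) + 1
  iy <- floor((y - phantom$origin[2]) / phantom$vox) + 1
  iz <- floor((z - z0) / phantom$vox) + 1
  dens <- matrix(0, nrow = length(z), ncol = length(x))
  ok <- ix >= 1 & ix <= n[1] & iy >= 1 & iy <= n[2]
  for (j in which(ok)) {
    dens[, j] <- phantom$density[ix[j], iy[j], ][iz]
  }
  list(z = z, dens = dens)
}

#' Water-equivalent path length along straight rays
#'
#' Marches each ray from its start point through the phantom grid in fixed
#' geometric steps, accumulating step x local relative density until the ray
#' leaves the grid.
#'
#' @param phantom a [make_phantom()] object.
#' @param start n x 3 matrix of start points, mm.
#' @param dir n x 3 matrix of unit directions.
#' @param step marching step, mm.
#' @return numeric vector of WEPL, mm.
#' @export
phantom_wepl <- function(phantom, start, dir, step = 1) {
  start <- rbind3(start); dir <- rbind3(dir, nrow(start))
  .ray_wepl(as.numeric(phantom$density), dim(phantom$density),
            phantom$origin, phantom$vox, start, dir, step)
}
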