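#' 2D PCA occupancy map in the horizontal plane
#'
#' Weighted 2D histogram of patient-labeled PCA positions in the (x, z)
#' plane of the active field frame, the projection in which range changes
#' show up as a displaced distal edge.
#'
#' @param pca data frame with `x` and `z` (or the axes named by `axes`).
#' @param weights per-event weights; default 1.
#' @param edges_x,edges_z uniform bin edges, mm.
#' @param axes which PCA coordinates span the map plane.
#' @return object of class `map2d`: `edges_x`, `edges_z`, `counts` matrix
#'   (x rows, z columns).
#' @export
build_map2d <- function(pca, weights = NULL,
                        edges_x = seq(-60, 60, by = 5),
                        edges_z = seq(-15, 165, by = 5),
                        axes = c("x", "z")) {
  vx <- pca[[axes[1]]]; vz <- pca[[axes[2]]]
  if (is.null(weights)) weights <- rep(1, length(vx))
  nx <- length(edges_x) - 1L; nz <- length(edges_z) - 1L
  bx <- findInterval(vx, edges_x)
  bz <- findInterval(vz, edges_z)
  ok <- bx >= 1 & bx <= nx & vx < edges_x[nx + 1] &
        bz >= 1 & bz <= nz & vz < edges_z[nz + 1]
  counts <- matrix(0, nx, nz)
  if (any(ok)) {
    idx <- (bz[ok] - 1L) * nx + bx[ok]
    s <- rowsum(weights[ok], idx)
    counts[as.integer(rownames(s))] <- s[, 1]
  }
  structure(list(edges_x = edges_x, edges_z = edges_z, counts = counts),
            class = "map2d")
}

#' Three-way overlap classification of two maps
#'
#' After normalizing both maps to equal totals, a cell is "present" in a
#' map when its content reaches `threshold_frac` of that map's maximum.
#' Cells are classified `both` (overlap), `only_ref`, `only_test` or
#' `neither` -- the orange/yellow/red reading of superimposed range maps.
#'
#' @param ref,test `map2d` objects on identical binning.
#' @param threshold_frac presence threshold as a fraction of the map
#'   maximum.
#' @return object of class `overlap_map`: `category` (character matrix) and
#'   the input edges.
#' @export
classify_overlap <- function(ref, test, threshold_frac = 0.05) {
  if (!isTRUE(all.equal(ref$edges_x, test$edges_x)) ||
      !isTRUE(all.equal(ref$edges_z, test$edges_z))) {
    stop("maps must share identical binning")
  }
  tot_r <- sum(ref$counts); tot_t <- sum(test$counts)
  a <- if (tot_r > 0) ref$counts / tot_r else ref$counts
  b <- if (tot_t > 0) test$counts / tot_t else test$counts
  pa <- a >= threshold_frac * max(a)
  pb <- b >= threshold_frac * max(b)
  if (max(a) == 0) pa[] <- FALSE
  if (max(b) == 0) pb[] <- FALSE
  cat_m <- matrix("neither", nrow(a), ncol(a))
  cat_m[pa & pb] <- "both"
  cat_m[pa & !pb] <- "only_ref"
  cat_m[!pa & pb] <- "only_test"
  structure(list(category = cat_m, edges_x = ref$edges_x,
                 edges_z = ref$edges_z, threshold_frac = threshold_frac),
            class = "overlap_map")
}

#' Distal-edge shift between two range maps
#'
#' For each lateral (x) column with at least `min_counts` entries in both
#' maps, the distal edge is the largest z at which the 3-bin-smoothed column
#' profile still reaches `edge_frac` of the column maximum; the shift is
#' `edge_test - edge_ref`. Invariant under a common rescaling of either
#' map's total.
#'
#' @param ref,test `map2d` objects on identical binning.
#' @param edge_frac edge threshold as a fraction of the column maximum.
#' @param min_counts per-column count floor; columns below it are excluded.
#' @return `data.frame`: column center `x` (mm), `edge_ref`, `edge_test`,
#'   `dz` (mm), for the retained columns.
#' @export
distal_edge_shift <- function(ref, test, edge_frac = 0.2, min_counts = 50) {
  if (!isTRUE(all.equal(ref$edges_x, test$edges_x)) ||
      !isTRUE(all.equal(ref$edges_z, test$edges_z))) {
    stop("maps must share identical binning")
  }
  zmid <- (ref$edges_z[-1] + ref$edges_z[-length(ref$edges_z)]) / 2
  xmid <- (ref$edges_x[-1] + ref$edges_x[-length(ref$edges_x)]) / 2
  smooth3 <- function(v) {
    n <- length(v)
    if (n < 3) return(v)
    out <- v
    out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
    out[1] <- mean(v[1:2]); out[n] <- mean(v[(n - 1):n])
    out
  }
  edge_of <- function(col) {
    s <- smooth3(col)
    m <- max(s)
    if (m <= 0) return(NA_real_)
    zmid[max(which(s >= edge_frac * m))]
  }
  rows <- lapply(seq_along(xmid), function(i) {
    cr <- ref$counts[i, ]; ct <- test$counts[i, ]
    if (sum(cr) < min_counts || sum(ct) < min_counts) return(NULL)
    er <- edge_of(cr); et <- edge_of(ct)
    if (is.na(er) || is.na(et)) return(NULL)
    data.frame(x = xmid[i], edge_ref = er, edge_test = et, dz = et - er)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(x = numeric(), edge_ref = numeric(),
                      edge_test = numeric(), dz = numeric())
  }
  out
}

#' Plot an overlap map
#'
#' Raster rendering of a [classify_overlap()] result with the conventional
#' coloring: overlap orange, reference-only yellow, test-only red.
#'
#' @param x an `overlap_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.overlap_map <- function(x, ...) {
  lev <- c("neither", "both", "only_ref", "only_test")
  m <- matrix(match(x$category, lev), nrow(x$category), ncol(x$category))
  graphics::image(x = x$edges_x, y = x$edges_z, z = m, zlim = c(1, 4),
                  col = c("white", "orange", "gold", "red"),
                  xlab = "x [mm]", ylab = "z [mm]", ...)
  invisible(x)
}
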