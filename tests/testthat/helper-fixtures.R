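# Shared fixtures: everything is generated in code at test time.

# A small, fast scenario used by most simulator-level tests: 5 x 5 spot
# grid, 6 energy slices, ~150 PBs, a few 10^3 recorded tracks.
tiny_scenario <- function(...) {
  args <- utils::modifyList(
    list(spot_x = seq(-16, 16, by = 8),
         spot_y = seq(-16, 16, by = 8),
         slice_z = seq(50, 90, by = 8),
         cavity_box = rbind(c(-12, -12, 25), c(12, 12, 41)),
         yield = 60),
    list(...))
  do.call(scenario_config, args)
}

# Independent PCA oracle: coarse grid search over the two line parameters
# followed by local numerical refinement of |P1(s) - P2(u)|^2. Never uses
# the closed form under test.
pca_oracle <- function(p1, d1, p2, d2) {
  f <- function(su) {
    a <- p1 + su[1] * d1
    b <- p2 + su[2] * d2
    sum((a - b)^2)
  }
  g <- seq(-1500, 1500, length.out = 81)
  A <- outer(g, d1) + rep(p1, each = length(g))   # points on line 1
  B <- outer(g, d2) + rep(p2, each = length(g))   # points on line 2
  d2mat <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  ij <- arrayInd(which.min(d2mat), dim(d2mat))
  best <- c(g[ij[1]], g[ij[2]])
  o <- stats::optim(best, f, method = "Nelder-Mead",
                    control = list(reltol = 1e-15, maxit = 5000))
  a <- p1 + o$par[1] * d1
  b <- p2 + o$par[2] * d2
  list(mid = (a + b) / 2, miss = sqrt(sum((a - b)^2)),
       s = o$par[1], u = o$par[2])
}

# random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

dist_to_box <- function(p, box) {
  d <- pmax(box[1, ] - p, 0, p - box[2, ])
  sqrt(sum(d^2))
}
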