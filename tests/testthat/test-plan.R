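test_that("end range in uniform water equals the Bragg-Kleeman range", {
  ph <- make_phantom(body_size = c(100, 100, 200), body_origin = c(-50, -50, 0))
  E <- energy_for_range(80)           # R(E) = 80 mm
  plan <- plan_table(1L, 0, 0, E, 1000)
  er <- compute_end_range(plan, ph, range_shifter_wet = 0)
  expect_equal(er$z, 80, tolerance = 1)     # within one marching step
  expect_equal(er$wepl, 80, tolerance = 1e-6)

  ph2 <- make_phantom(body_size = c(100, 100, 400),
                      body_origin = c(-50, -50, 0), base_density = 0.5)
  er2 <- compute_end_range(plan, ph2, range_shifter_wet = 0)
  expect_equal(er2$z, 160, tolerance = 1)   # geometric depth doubles
})

test_that("layered phantom end range matches a fine-step integration oracle", {
  # 30 mm at rho = 1 then rho = 0.2; R(E) = 40 mm -> 30 + 10/0.2 = 80 mm
  ph <- make_phantom(body_size = c(100, 100, 200), body_origin = c(-50, -50, 0),
                     base_density = 0.2)
  n <- dim(ph$density)
  ph$density[, , 1:15] <- 1            # first 30 mm (2 mm voxels)
  E <- energy_for_range(40)
  er <- compute_end_range(plan_table(1L, 0, 0, E, 10), ph,
                          range_shifter_wet = 0)
  # independent fine-step oracle
  zg <- seq(0.005, 200, by = 0.01)
  dens <- ifelse(zg < 30, 1, 0.2)
  z_orc <- zg[which(cumsum(dens * 0.01) >= 40)[1]]
  expect_equal(z_orc, 80, tolerance = 0.1)
  expect_equal(er$z, z_orc, tolerance = 1.1)
})

test_that("range shifter consumes range upstream and short ranges stop at entry", {
  ph <- make_phantom(body_size = c(100, 100, 200), body_origin = c(-50, -50, 0))
  E <- energy_for_range(50)
  er <- compute_end_range(plan_table(1L, 0, 0, E, 10), ph,
                          range_shifter_wet = 30)
  expect_equal(er$z, 20, tolerance = 1)
  # range exhausted inside the shifter
  er0 <- compute_end_range(plan_table(1L, 0, 0, energy_for_range(25), 10),
                           ph, range_shifter_wet = 30)
  expect_equal(er0$z, 0)
  expect_equal(er0$wepl, 0)
  expect_error(compute_end_range(plan_table(1L, 0, 0, 400, 10), ph, 0),
               "beyond phantom")
})

test_that("SPB aggregation follows the cell rule and the 75-member cap", {
  one <- data.frame(pb_id = 1L, x = 1, y = 2, z = 3, wepl = 3)
  m <- merge_into_spbs(one)
  expect_equal(nrow(m), 1L)

  many <- data.frame(pb_id = 1:150, x = 2, y = 2, z = 3, wepl = 3)
  m <- merge_into_spbs(many)
  sizes <- table(m$spb_id)
  expect_equal(sort(as.integer(sizes)), c(75L, 75L))
  # delivery-order fill: first 75 PBs share the first SPB
  expect_equal(length(unique(m$spb_id[1:75])), 1L)

  expect_equal(nrow(merge_into_spbs(many[0, ])), 0L)
})

test_that("SPB partition matches an independent dictionary oracle", {
  set.seed(3)
  n <- 1000
  er <- data.frame(pb_id = seq_len(n),
                   x = runif(n, -25, 25), y = runif(n, -25, 25),
                   z = runif(n, 40, 90), wepl = 0)
  m <- merge_into_spbs(er, cell = c(10, 10, 6), max_members = 75)

  # oracle: explicit dictionary of cells, chunked in delivery order
  dict <- new.env()
  oracle_spb <- character(n)
  for (i in seq_len(n)) {
    key <- paste(floor(er$x[i] / 10), floor(er$y[i] / 10),
                 floor(er$z[i] / 6))
    members <- if (is.null(dict[[key]])) integer() else dict[[key]]
    members <- c(members, i)
    dict[[key]] <- members
    oracle_spb[i] <- paste(key, ceiling(length(members) / 75))
  }
  # same partition: groups agree as sets
  expect_equal(length(unique(m$spb_id)), length(unique(oracle_spb)))
  cross <- table(m$spb_id, oracle_spb)
  expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))

  # partition properties
  expect_equal(sort(m$pb_id), er$pb_id)               # exhaustive, disjoint
  expect_true(all(table(m$spb_id) <= 75))
  # determinism
  expect_identical(m, merge_into_spbs(er, cell = c(10, 10, 6)))
  # end-range spread within an SPB bounded by the cell diagonal
  sums <- spb_summary(m, er)
  diag_len <- sqrt(sum(c(10, 10, 6)^2))
  for (id in sums$spb_id[sums$n_members > 1]) {
    pts <- er[m$spb_id == id, c("x", "y", "z")]
    expect_lte(max(dist(pts)), diag_len)
  }
})

test_that("plan validation enforces sanity bounds", {
  expect_error(plan_table(c(1, 1), 0, 0, 200, 10), "unique")
  expect_error(plan_table(1, 0, 0, 600, 10), "sanity")
  expect_error(plan_table(1, 0, 0, 200, 0), "n_ions")
})
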