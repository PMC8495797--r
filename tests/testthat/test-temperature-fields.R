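# hand-made climatology on a 2x2 grid with two levels
toy_clim <- function(vals_deep = c(18, NA, 12, 12),
                     vals_shallow = c(20, NA, 12, 12)) {
  lat <- c(38.05, 38.15); lon <- c(-74.15, -74.05)
  levels <- c(0, 5)
  temp <- array(NA_real_, c(12, 2, 2, 2))
  for (m in 1:12) {
    temp[m, 1, , ] <- matrix(vals_shallow, 2, 2)
    temp[m, 2, , ] <- matrix(vals_deep, 2, 2)
  }
  mask <- matrix(!is.na(vals_shallow) | !is.na(vals_deep), 2, 2)
  climatology_field("1985-1994", lat, lon, levels, temp, mask)
}

test_that("bottom extraction takes the deepest valid level, never zero-fills", {
  cb <- climatology_bottom(toy_clim())
  expect_equal(cb$temp[1, 1, 1], 18)          # deepest of {20, 18}
  expect_true(is.na(cb$temp[1, 2, 1]))        # all-missing cell stays missing
  expect_equal(cb$temp[6, 1, 2], 12)          # uniform column -> that value

  # deepest level missing below seafloor: falls back to next valid level up
  cl <- toy_clim()
  cl$temp[, 2, 1, 2] <- NA                    # remove the 5 m level in one cell
  expect_equal(climatology_bottom(cl)$temp[3, 1, 2], 12)
})

test_that("decade assignment follows the climatology coverage rules", {
  expect_identical(assign_decade(1992), "1985-1994")
  expect_identical(assign_decade(1995), "1995-2004")
  expect_identical(assign_decade(2013), "2005-2012")
  expect_identical(assign_decade(2015), "2005-2012")
  expect_error(assign_decade(1984), "coverage")
  expect_error(assign_decade(2016), "coverage")
})

test_that("decadal regrid bin-averages model cells into climatology cells", {
  # two model cells inside one climatology cell, constant in time
  lat_m <- c(38.025, 38.075); lon_m <- -74.05
  time <- data.frame(year = rep(1990:1991, each = 12), month = rep(1:12, 2))
  temp <- array(NA_real_, c(24, 2, 1))
  temp[, 1, 1] <- 8; temp[, 2, 1] <- 12
  model <- grid_field(lat_m, lon_m, time, temp, matrix(TRUE, 2, 1))
  clim_grid <- list(lat = 38.05, lon = -74.05)
  dm <- decadal_monthly_mean_regrid(model, "1985-1994", clim_grid)
  expect_equal(as.vector(dm$temp), rep(10, 12))

  # constant field stays constant
  temp[] <- 10
  model10 <- grid_field(lat_m, lon_m, time, temp, matrix(TRUE, 2, 1))
  expect_equal(as.vector(decadal_monthly_mean_regrid(model10, "1985-1994",
                                                     clim_grid)$temp),
               rep(10, 12))
  expect_error(decadal_monthly_mean_regrid(model, "2005-2012", clim_grid),
               "no years")
})

test_that("bias field is the elementwise model-minus-climatology difference", {
  cb <- climatology_bottom(toy_clim())
  zero <- compute_bias_field(cb, cb)
  expect_equal(max(abs(zero$temp), na.rm = TRUE), 0)

  warm <- cb; warm$temp <- cb$temp + 2
  b <- compute_bias_field(warm, cb)
  expect_equal(range(b$temp, na.rm = TRUE), c(2, 2))
  expect_true(all(is.na(b$temp[, 2, 1])))

  other <- monthly_grid(cb$lat + 1, cb$lon, cb$temp)
  expect_error(compute_bias_field(other, cb), "mismatch")
})

test_that("bias correction round trip recovers the known bias and the climatology", {
  w <- shared_world
  biases <- world_biases(w)
  # recovered bias equals the bin-average of the generating bias function
  for (d in names(biases)) {
    b <- biases[[d]]
    for (m in c(2, 7, 11)) {
      truth_bias <- outer(b$lat, b$lon,
                          function(la, lo) w$bias_fn(la, lo, m))
      diff <- b$temp[m, , ] - truth_bias
      expect_lt(max(abs(diff), na.rm = TRUE), 0.02)  # bin-average vs centre value
    }
  }
  corrected <- apply_bias(w$model, biases)
  # corrected decadal monthly means equal the climatology to ~1e-9
  for (d in names(w$clim)) {
    dm <- decadal_monthly_mean_regrid(corrected, d, w$clim[[d]])
    cb <- climatology_bottom(w$clim[[d]])
    expect_lt(max(abs(dm$temp - cb$temp), na.rm = TRUE), 1e-9)
  }
  # conservation: grid and wet mask unchanged
  expect_identical(corrected$mask, w$model$mask)
  expect_identical(corrected$lat, w$model$lat)
  # model warmer than climatology -> positive bias -> correction cools
  expect_true(all(biases[["1985-1994"]]$temp > 0, na.rm = TRUE))
  expect_true(all(corrected$temp <= w$model$temp, na.rm = TRUE))
})

test_that("zero bias leaves the model unchanged; adding c shifts bias by c", {
  w <- shared_world
  biases <- world_biases(w)
  zero <- lapply(biases, function(b) { b$temp[] <- 0; b })
  corr0 <- apply_bias(w$model, zero)
  expect_equal(corr0$temp, w$model$temp)

  shifted <- w$model; shifted$temp <- shifted$temp + 1.5
  dm0 <- decadal_monthly_mean_regrid(w$model, "1985-1994", w$clim[[1]])
  dm1 <- decadal_monthly_mean_regrid(shifted, "1985-1994", w$clim[[1]])
  cb <- climatology_bottom(w$clim[[1]])
  b0 <- compute_bias_field(dm0, cb); b1 <- compute_bias_field(dm1, cb)
  expect_equal(b1$temp, b0$temp + 1.5)
  # corrected fields are unchanged by the constant shift
  c0 <- apply_bias(w$model, list(`1985-1994` = b0, `1995-2004` = b0,
                                 `2005-2012` = b0))
  c1 <- apply_bias(shifted, list(`1985-1994` = b1, `1995-2004` = b1,
                                 `2005-2012` = b1))
  expect_equal(c1$temp, c0$temp, tolerance = 1e-12)
})

test_that("apply_bias errors when a required decade is absent", {
  w <- shared_world
  biases <- world_biases(w)
  expect_error(apply_bias(w$model, biases[1:2]), "2005-2012")
})

test_that("bias lookup maps each model cell to its nearest climatology cell", {
  # 2x2 climatology cells, 4x4 nested model cells; hand enumeration of the
  # nearest-centre mapping
  lat_c <- c(38.05, 38.15); lon_c <- c(-74.15, -74.05)
  bias <- array(NA_real_, c(12, 2, 2))
  for (m in 1:12) bias[m, , ] <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- monthly_grid(lat_c, lon_c, bias)
  lat_m <- c(38.025, 38.075, 38.125, 38.175)
  lon_m <- c(-74.175, -74.125, -74.075, -74.025)
  time <- data.frame(year = 1990, month = 6)
  temp <- array(10, c(1, 4, 4))
  model <- grid_field(lat_m, lon_m, time, temp, matrix(TRUE, 4, 4))
  corr <- apply_bias(model, list(`1985-1994` = b))
  expected_bias <- rbind(c(1, 1, 3, 3), c(1, 1, 3, 3),
                         c(2, 2, 4, 4), c(2, 2, 4, 4))
  expect_equal(corr$temp[1, , ], 10 - expected_bias)
})

test_that("tow matching picks the nearest wet cell with deterministic ties", {
  w <- shared_world
  biases <- world_biases(w)
  corrected <- apply_bias(w$model, biases)
  nlat <- length(corrected$lat)

  # tow exactly at a wet cell centre gets that cell's value
  wet <- which(corrected$mask)[10]
  il <- (wet - 1) %% nlat + 1; io <- (wet - 1) %/% nlat + 1
  tow <- data.frame(year = 1999, month = 5,
                    lat = corrected$lat[il], lon = corrected$lon[io])
  ti <- which(corrected$time$year == 1999 & corrected$time$month == 5)
  expect_equal(as.numeric(match_trawls(tow, corrected)),
               corrected$temp[ti, il, io])

  # equidistant between two wet cells in the same column: lower flattened
  # index (southern cell) wins
  stopifnot(corrected$mask[il, io], corrected$mask[il + 1, io])
  mid <- data.frame(year = 1999, month = 5,
                    lat = mean(corrected$lat[il + 0:1]), lon = corrected$lon[io])
  expect_equal(as.numeric(match_trawls(mid, corrected)),
               corrected$temp[ti, il, io])

  expect_error(match_trawls(data.frame(year = 1970, month = 1,
                                       lat = 38.5, lon = -74),
                            corrected), "coverage")
})

test_that("tow matching agrees with a brute-force nearest-neighbour scan", {
  w <- shared_world
  corrected <- apply_bias(w$model, world_biases(w))
  nlat <- length(corrected$lat)
  set.seed(77)
  n <- 200
  tows <- data.frame(year = sample(1985:2015, n, TRUE),
                     month = sample(1:12, n, TRUE),
                     lat = runif(n, 38, 40), lon = runif(n, -75, -73))
  got <- suppressMessages(match_trawls(tows, corrected, cutoff_km = 25))
  wet <- which(corrected$mask)
  wet_il <- (wet - 1) %% nlat + 1; wet_io <- (wet - 1) %/% nlat + 1
  for (i in seq_len(n)) {
    d <- geosphere::distHaversine(
      cbind(tows$lon[i], tows$lat[i]),
      cbind(corrected$lon[wet_io], corrected$lat[wet_il])) / 1000
    best <- wet[order(d, wet)][1]
    ti <- which(corrected$time$year == tows$year[i] &
                  corrected$time$month == tows$month[i])
    want <- if (min(d) > 25) NA_real_ else
      corrected$temp[ti, (best - 1) %% nlat + 1, (best - 1) %/% nlat + 1]
    expect_equal(got[i], want, ignore_attr = TRUE)
  }
})
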