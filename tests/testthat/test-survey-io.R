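test_that("read_survey parses well-formed files and collects rejects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "longitude,latitude,year,temperature,depth,transparency,dissolved_oxygen",
    "-81.5,42.1,2001,21.3,12,2.5,8.1",
    "-80.2,42.4,2002,19.8,25,4.0,7.2",
    "-79.9,42.6,2003,18.1,40,5.5,6.9"), f)
  out <- read_survey(f)
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$rejects), 0)
  expect_equal(out$records$depth, c(12, 25, 40))

  # a non-numeric temperature row is rejected with the column as reason
  writeLines(c(
    "longitude,latitude,year,temperature,depth,transparency,dissolved_oxygen",
    "-81.5,42.1,2001,warm,12,2.5,8.1",
    "-80.2,42.4,2002,19.8,25,4.0,7.2"), f)
  out <- read_survey(f)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$rejects$reason, "temperature")

  # tab-delimited autodetection
  writeLines(c(
    paste("longitude", "latitude", "year", "temperature", "depth",
          "transparency", "dissolved_oxygen", sep = "\t"),
    paste(-81.5, 42.1, 2001, 21.3, 12, 2.5, 8.1, sep = "\t")), f)
  expect_equal(nrow(read_survey(f)$records), 1)
})

test_that("read_survey errors name the missing column and reject empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("longitude,latitude,year,temperature,depth,transparency",
               "-81,42,2000,20,10,3"), f)
  expect_error(read_survey(f), "dissolved_oxygen")
  writeLines("longitude,latitude,year,temperature,depth,transparency,dissolved_oxygen",
             f)
  expect_error(read_survey(f), "no data rows")
  # column mapping resolves nonstandard headers
  writeLines(c("LON,LAT,yr,Temp,Dep,Sec,DO",
               "-81,42,2000,20,10,3,8"), f)
  out <- read_survey(f, column_map = c(
    longitude = "LON", latitude = "LAT", year = "yr", temperature = "Temp",
    depth = "Dep", transparency = "Sec", dissolved_oxygen = "DO"))
  expect_equal(out$records$temperature, 20)
})

test_that("clean_survey derives presence by life stage and is idempotent", {
  d <- data.frame(temperature = c(20, 21, NA, 22, 40),
                  depth = c(10, -1, 12, 13, 14),
                  transparency = c(2, 2, 2, 2, 2),
                  dissolved_oxygen = c(8, 8, 8, 8, 8),
                  catch_age0 = c(3, 0, 1, 0, 2),
                  catch_age1 = c(0, 0, 0, 0, 0),
                  catch_age2 = c(5, 1, 2, 0, 1))
  out <- clean_survey(d)
  # rows dropped: NA temperature, depth <= 0, temperature out of range
  expect_equal(out$removed, 3)
  expect_equal(out$data$presence_juvenile, c(1, 0))
  expect_equal(out$data$presence_adult, c(1, 0))
  # idempotent: cleaning a cleaned set removes nothing
  out2 <- clean_survey(out$data)
  expect_equal(out2$removed, 0)
  expect_equal(out2$data$presence_juvenile, out$data$presence_juvenile)
  # missing catch counts as erroneous
  d2 <- d[1:2, ]; d2$depth <- 10; d2$catch_age2[2] <- NA
  expect_equal(clean_survey(d2)$removed, 1)
  # all rows bad -> empty-data error
  d3 <- d[1, ]; d3$depth <- -5
  expect_error(clean_survey(d3), "all rows removed")
})

test_that("UTM projection: central meridian, round trip, haversine agreement", {
  p <- project_coordinates(-81, 42)
  expect_equal(p$x, 500000, tolerance = 1e-9)

  set.seed(3)
  lon <- runif(50, -83.5, -78.9)
  lat <- runif(50, 41.2, 43.0)
  pr <- project_coordinates(lon, lat)
  rt <- utm_inverse(pr$x, pr$y)
  expect_lt(max(abs(rt$lon - lon)), 1e-6)
  expect_lt(max(abs(rt$lat - lat)), 1e-6)

  # planar vs ellipsoidal geodesic distance within 0.1% at lake scale
  skip_if_not_installed("geosphere")
  pairs <- list(c(-81.000, 42, -80.990, 42),    # 0.01 deg of longitude
                c(-82.5, 41.7, -79.3, 42.6),    # across the whole lake
                c(-80.1, 41.9, -80.1, 42.4))    # due north
  for (q in pairs) {
    a <- project_coordinates(q[1], q[2])
    b <- project_coordinates(q[3], q[4])
    planar <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
    gc <- geosphere::distGeo(q[1:2], q[3:4])
    expect_lt(abs(planar - gc) / gc, 0.001)
  }

  # easting strictly increases with longitude at fixed latitude
  lons <- seq(-83, -79, length.out = 20)
  e <- project_coordinates(lons, rep(42.2, 20))$x
  expect_true(all(diff(e) > 0))

  expect_error(project_coordinates(-70, 42), "zone")
})

test_that("VIF: orthogonal, collinear and corr-0.9 designs; affine invariance", {
  set.seed(4)
  n <- 200
  z1 <- rnorm(n)
  # x2 built to have *exactly* 0.9 sample correlation with x1
  z2 <- residuals(lm(rnorm(n) ~ z1))
  x1 <- scale(z1)[, 1]
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * scale(z2)[, 1]
  v <- compute_vif(cbind(a = x1, b = x2))
  expect_equal(v$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
  expect_true(all(v$excluded))  # 5.26 exceeds the threshold of 3

  # orthogonal columns -> VIF exactly 1
  x2o <- scale(z2)[, 1]
  vo <- compute_vif(cbind(x1, x2o))
  expect_equal(vo$vif, c(1, 1), tolerance = 1e-9)

  # exact duplicate -> infinite VIF, excluded, no crash
  vd <- compute_vif(cbind(x1, x1copy = x1))
  expect_true(all(is.infinite(vd$vif)))
  expect_true(all(vd$excluded))

  # affine rescaling of any column leaves VIFs unchanged
  X3 <- cbind(x1, x2, r = rnorm(n))
  v3 <- compute_vif(X3)
  X3s <- X3; X3s[, 2] <- 100 * X3s[, 2] - 7
  expect_equal(compute_vif(X3s)$vif, v3$vif, tolerance = 1e-9)

  # agrees with the standard regression-diagnostic implementation
  skip_if_not_installed("car")
  yy <- rnorm(n)
  ref <- car::vif(lm(yy ~ X3[, 1] + X3[, 2] + X3[, 3]))
  expect_equal(unname(v3$vif), unname(ref), tolerance = 1e-8)
})
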