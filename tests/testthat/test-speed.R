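test_that("haversine distance matches the closed-form equatorial arc and geosphere", {
  expect_identical(haversine_distance(10, 20, 10, 20), 0)
  # one degree of arc on the equator: R * pi/180
  expect_equal(haversine_distance(0, 0, 0, 1), 6371000 * pi / 180,
               tolerance = 1e-12)
  set.seed(3)
  lat1 <- runif(100, -90, 90); lon1 <- runif(100, -180, 180)
  lat2 <- runif(100, -90, 90); lon2 <- runif(100, -180, 180)
  expect_equal(haversine_distance(lat1, lon1, lat2, lon2),
               haversine_distance(lat2, lon2, lat1, lon1))
  skip_if_not_installed("geosphere")
  expect_equal(haversine_distance(lat1, lon1, lat2, lon2),
               geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                        r = 6371000),
               tolerance = 1e-9)
  expect_error(haversine_distance(91, 0, 0, 0), "out of range")
})

test_that("distance matrices are square, symmetric and validated against stations", {
  spa <- as_station_table(data.frame(
    station = c("S01", "S02", "S03"),
    latitude = c(54.40, 54.44, 54.48), longitude = 13.6))
  m <- build_distance_matrix(spa)
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(rownames(m), spa$station)
  expect_identical(m, t(m))
  expect_identical(unname(diag(m)), rep(0, 3))
  expect_true(all(m >= 0))

  expect_error(validate_distance_matrix(m[1:2, 1:2], spa), "missing station")
  m_asym <- m; m_asym[1, 2] <- m_asym[1, 2] + 5
  expect_error(validate_distance_matrix(m_asym, spa), "not symmetric")
  # external matrices are reordered to the station-table order
  perm <- m[c(2, 3, 1), c(3, 1, 2)]
  expect_identical(validate_distance_matrix(perm, spa), m)
})

test_that("the allometric speed law reproduces the worked critical-speed example", {
  m <- speed_model(base = 0.019, factor_column = "TL", exponent = 0.75)
  expect_identical(round(animal_speed(m, 616)), 8457)  # 616 mm fish
  # constant speed defaults to m/h; explicit units convert
  expect_identical(animal_speed(speed_model(3600)), 3600)
  expect_identical(animal_speed(speed_model(1, base_unit = "m/s")), 3600)
  # zero exponent degenerates to the (converted) base
  m0 <- speed_model(0.5, "TL", 0)
  expect_identical(animal_speed(m0, 123), 0.5 * 3600)
  expect_error(speed_model(0.019, factor_column = "TL"), "exponent")
  expect_error(animal_speed(m, NULL), "TL")
})

test_that("effective distance subtracts both footprints and floors at zero", {
  expect_identical(effective_distance(1000, 200, 300), 500)
  expect_identical(effective_distance(400, 200, 300), 0)
  expect_identical(effective_distance(0, 200, 300), 0)
  expect_error(effective_distance(-1, 0, 0), "non-negative")
})

# shared geometry for the filter tests: three stations 4 km apart on a meridian
speed_fixture <- function() {
  spa <- as_station_table(data.frame(
    station = c("S01", "S02", "S03"),
    latitude = 54.40 + (0:2) * 4000 / (pi / 180 * 6371000),
    longitude = 13.6))
  list(spa = spa, m = build_distance_matrix(spa))
}

test_that("an infeasibly fast arrival is removed; quiet data is untouched", {
  g <- speed_fixture()
  model <- speed_model(8457)  # m/h
  rng <- range_spec(0)
  t0 <- utc("2021-06-01 00:00:00")

  # ~8 km in 0.5 h requires ~16,000 m/h > 8457 -> the later detection goes
  pair <- det_table(t0 + c(0, 0.5) * 3600, station = c("S01", "S03"))
  r <- filter_by_speed(pair, g$m, model, rng)
  expect_identical(nrow(r$removed), 1L)
  expect_identical(r$removed$station, "S03")
  expect_identical(r$kept$station, "S01")

  # all at one station: nothing to do, converged on the first sweep
  same <- det_table(t0 + (0:5) * 60, station = "S01")
  r2 <- filter_by_speed(same, g$m, model, rng)
  expect_identical(nrow(r2$removed), 0L)
  expect_identical(r2$iterations, 1L)

  # zero time gap across distinct stations: infinite required speed
  zt <- det_table(c(t0, t0), station = c("S01", "S02"),
                  receiver = c("R01", "R02"))
  r3 <- filter_by_speed(zt, g$m, model, rng)
  expect_identical(r3$removed$station, "S02")  # later in (timestamp, receiver) order

  expect_error(filter_by_speed(det_table(t0, station = "S99"), g$m, model, rng),
               "S99")
})

test_that("removal re-iterates: a flagged row changes its neighbour's adjacency", {
  g <- speed_fixture()
  model <- speed_model(8457)
  rng <- range_spec(0)
  t0 <- utc("2021-06-01 00:00:00")
  # A at S01; ghost at S03 20 min later (infeasible arrival); B back at S01
  # 25 min after the ghost. Sweep 1 flags the ghost AND B (B's arrival is
  # judged against the still-retained ghost); sweep 2 re-checks and finds
  # A -> (nothing), so convergence takes an extra, empty sweep.
  chain <- det_table(t0 + c(0, 1200, 2700), station = c("S01", "S03", "S01"))
  r <- filter_by_speed(chain, g$m, model, rng)
  expect_identical(nrow(r$kept) + nrow(r$removed), 3L)
  expect_identical(r$removed$station[1], "S03")
  expect_gte(r$iterations, 2L)
  # after convergence the kept trajectory holds no violation at all
  sp <- c(F01 = 8457)
  expect_identical(count_speed_violations(r$kept, g$m, sp, 0), 0L)

  # a ghost whose onward leg is feasible costs only itself: A at S01,
  # ghost at S02 2 min later, next genuine at S02 an hour on
  gh <- det_table(t0 + c(0, 120, 3720), station = c("S01", "S02", "S02"))
  r2 <- filter_by_speed(gh, g$m, model, rng)
  expect_identical(nrow(r2$removed), 1L)
  expect_identical(r2$removed$timestamp, t0 + 120)
  expect_identical(r2$iterations, 2L)
})

test_that("kept output never violates the speed rule (independent audit)", {
  g <- speed_fixture()
  rng_m <- 250
  set.seed(21)
  for (i in 1:15) {
    n <- sample(20:150, 1)
    det <- det_table(
      utc("2021-06-01 00:00:00") + sort(runif(n, 0, 96)) * 3600,
      animal = sample(c("F01", "F02"), n, replace = TRUE),
      station = sample(g$spa$station, n, replace = TRUE))
    det[, receiver := sub("S", "R", station)]
    speed_mh <- runif(1, 500, 4000)
    model <- speed_model(speed_mh)
    r <- filter_by_speed(det, g$m, model, range_spec(rng_m))
    expect_identical(nrow(r$kept) + nrow(r$removed), n)
    expect_lte(r$iterations, n)
    sp <- c(F01 = speed_mh, F02 = speed_mh)
    expect_identical(count_speed_violations(r$kept, g$m, sp, rng_m), 0L)
  }
})

test_that("raising the speed threshold never removes more detections", {
  g <- speed_fixture()
  set.seed(8)
  n <- 120
  det <- det_table(
    utc("2021-06-01 00:00:00") + sort(runif(n, 0, 48)) * 3600,
    station = sample(g$spa$station, n, replace = TRUE))
  removed_prev <- Inf
  for (speed_mh in c(500, 1000, 2000, 8000, 1e9)) {
    r <- filter_by_speed(det, g$m, speed_model(speed_mh), range_spec(250))
    expect_lte(nrow(r$removed), removed_prev)
    removed_prev <- nrow(r$removed)
  }
  # practically infinite speed and no max_distance keeps everything
  expect_identical(removed_prev, 0L)
})

test_that("max_distance caps raw station distance inside the same sweep", {
  g <- speed_fixture()
  t0 <- utc("2021-06-01 00:00:00")
  det <- det_table(t0 + c(0, 24, 48) * 3600, station = c("S01", "S03", "S02"))
  free <- filter_by_speed(det, g$m, speed_model(1e9), range_spec(0))
  expect_identical(nrow(free$removed), 0L)
  capped <- filter_by_speed(det, g$m, speed_model(1e9), range_spec(0),
                            max_distance = 5000)
  expect_identical(capped$removed$station, "S03")  # 8 km jump > 5 km cap
  expect_identical(capped$kept$station, c("S01", "S02"))  # re-check passes
})

test_that("time-varying ranges change which detections are flagged", {
  g <- speed_fixture()
  t0 <- utc("2021-06-01 00:00:00")
  # ranges widen mid-study: 100 m before June 3, 1900 m after
  rng <- range_spec(table = data.frame(
    range_category = "std",
    start = c("2021-05-01 00:00:00", "2021-06-03 00:00:01"),
    end = c("2021-06-03 00:00:00", "2021-07-01 00:00:00"),
    range_m = c(100, 1900)))
  model <- speed_model(2000)  # m/h; adjacent stations are 4 km apart
  mk <- function(day) det_table(t0 + (day * 24 + c(0, 1)) * 3600,
                                station = c("S01", "S02"),
                                range_category = "std")
  # before the change: effective 4000 - 200 = 3800 m in 1 h -> removed
  early <- filter_by_speed(mk(0), g$m, model, rng)
  expect_identical(nrow(early$removed), 1L)
  # after: effective 4000 - 3800 = 200 m in 1 h -> kept
  late <- filter_by_speed(mk(5), g$m, model, rng)
  expect_identical(nrow(late$removed), 0L)
  # a detection outside every range interval is an error, not a guess
  out <- det_table(utc("2021-08-01 00:00:00"), station = "S01",
                   range_category = "std")
  expect_error(filter_by_speed(out, g$m, model, rng), "no detection range")
})

test_that("a missing biometric is an error naming the animal", {
  g <- speed_fixture()
  det <- det_table(utc("2021-06-01 00:00:00"), station = "S01",
                   animal = "F07", TL = NA_real_)
  expect_error(
    filter_by_speed(det, g$m, speed_model(0.019, "TL", 0.75), range_spec(0)),
    "F07")
})
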