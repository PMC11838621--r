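test_that("planar projection has meter-true latitude spacing", {
  tr <- gps_trace(tibble::tibble(t = c(0, 60), lat = c(42, 42.001),
                                 lon = -71, accuracy = 10))
  xy <- project_to_plane(tr)
  expect_equal(nrow(xy), 2)
  expect_equal(diff(xy$y), 111.2, tolerance = 0.5 / 111.2)
  # median fix is the origin
  expect_true(any(abs(xy$x) < 1e-9 & abs(xy$y) < 1e-6) ||
                all(abs(xy$y - mean(xy$y)) > 0))
})

test_that("stationary fixes form one pause; straight tracks one flight", {
  set.seed(2)
  fx <- tibble::tibble(t = seq(0, 1200, 60), x = rnorm(21, 0, 3),
                       y = rnorm(21, 0, 3))
  tr <- segment_flights_pauses(fx)
  expect_equal(tr$type, "pause")

  fx2 <- tibble::tibble(t = seq(0, 600, 60), x = seq(0, 5000, 500), y = 0)
  tr2 <- segment_flights_pauses(fx2)
  expect_equal(tr2$type, "flight")
  expect_equal(sqrt((tr2$x1 - tr2$x0)^2 + (tr2$y1 - tr2$y0)^2), 5000)
})

test_that("a turn sharper than the heading threshold splits the flight", {
  # L-shaped track with a 90 degree turn
  fx <- tibble::tibble(
    t = seq(0, 600, 60),
    x = c(seq(0, 2500, 500), rep(2500, 5)),
    y = c(rep(0, 6), seq(500, 2500, 500))
  )
  tr <- segment_flights_pauses(fx)
  expect_equal(sum(tr$type == "flight"), 2)
  lens <- sqrt((tr$x1 - tr$x0)^2 + (tr$y1 - tr$y0)^2)
  expect_equal(sum(lens), 5000)
})

test_that("gap imputation fills by the displacement rule", {
  p <- mobility_params()
  traj <- rbind(
    traj_row("pause", 0, 600, 0, 0, 0, 0),
    traj_row("pause", 1200, 1800, 10, 0, 10, 0),    # 10 m apart: pause fill
    traj_row("pause", 2400, 3000, 1010, 0, 1010, 0) # 1000 m apart: flight
  )
  out <- impute_gaps(traj, p)
  fills <- out[!(out$start_t %in% traj$start_t), ]
  expect_equal(fills$type, c("pause", "flight"))
  expect_equal(fills$x0[1], 5)  # midpoint
  expect_equal(sqrt((fills$x1[2] - fills$x0[2])^2), 1000)
  # span extension fills pauses at nearest observed position
  out2 <- impute_gaps(traj, p, span = c(-600, 3600))
  expect_equal(out2$start_t[1], -600)
  expect_equal(out2$end_t[nrow(out2)], 3600)
  expect_equal(out2$x0[1], 0)
  expect_equal(out2$x0[nrow(out2)], 1010)
})

test_that("significant locations honor the 15-min and 50-m rules", {
  p20 <- 20 * 60
  mk <- function(start, dur, x, y) traj_row("pause", start, start + dur, x, y, x, y)
  # three long pauses pairwise >= 100 m apart
  traj <- rbind(mk(0, p20, 0, 0), mk(2000, p20, 150, 0), mk(4000, p20, 0, 150))
  expect_equal(nrow(significant_locations(traj)$clusters), 3)
  # two long pauses 10 m apart merge
  traj2 <- rbind(mk(0, p20, 0, 0), mk(2000, p20, 10, 0))
  sig2 <- significant_locations(traj2)
  expect_equal(nrow(sig2$clusters), 1)
  # duration-weighted centroid
  expect_equal(sig2$clusters$x, 5)
  # 14-minute pause does not qualify; exactly 900 s does (inclusive)
  expect_equal(nrow(significant_locations(mk(0, 14 * 60, 0, 0))$clusters), 0)
  expect_equal(nrow(significant_locations(mk(0, 900, 0, 0))$clusters), 1)
})

test_that("home is the night-dominant cluster and home time accumulates all day", {
  day <- function(d) d * 86400
  traj <- do.call(rbind, lapply(0:2, function(d) {
    rbind(
      traj_row("pause", day(d), day(d) + 8 * 3600, 0, 0, 0, 0),        # night at home
      traj_row("flight", day(d) + 8 * 3600, day(d) + 9 * 3600, 0, 0, 5000, 0),
      traj_row("pause", day(d) + 9 * 3600, day(d) + 15 * 3600, 5000, 0, 5000, 0),
      traj_row("flight", day(d) + 15 * 3600, day(d) + 16 * 3600, 5000, 0, 0, 0),
      traj_row("pause", day(d) + 16 * 3600, day(d + 1), 0, 0, 0, 0)    # evening at home
    )
  }))
  sig <- significant_locations(traj)
  home <- home_location(sig)
  expect_equal(unname(home), c(0, 0), tolerance = 1e-6)
  # 8 h morning + 8 h evening at home on each date
  ht <- daily_home_time(traj, as.Date("1970-01-02"), home)
  expect_equal(ht, 16)
  expect_equal(daily_distance(traj, as.Date("1970-01-02")), 10)
  expect_equal(n_locations_on_date(sig, as.Date("1970-01-02")), 2)
})

test_that("time is conserved per day after imputation", {
  set.seed(3)
  # duty-cycled fixes of a stationary day
  tt <- gaitmob:::gps_fix_grid(60, 600, 5)
  fx <- tibble::tibble(t = tt, x = rnorm(length(tt), 0, 5),
                       y = rnorm(length(tt), 0, 5))
  traj <- segment_flights_pauses(fx)
  traj <- impute_gaps(traj, span = c(0, 86400))
  b <- c(0, 86400)
  covered <- sum(pmin(traj$end_t, b[2]) - pmax(traj$start_t, b[1]))
  expect_equal(covered, 86400, tolerance = 1 / 86400)
  # a stationary duty-cycled day collapses to one continuous pause
  expect_true(all(traj$type == "pause"))
})

test_that("distance is invariant under rigid rotation and translation", {
  path_x <- c(seq(0, 4000, 100), rep(4000, 20))
  path_y <- c(rep(0, 41), seq(200, 4000, 200))
  t <- seq_along(path_x) * 30
  d0 <- daily_distance(
    impute_gaps(segment_flights_pauses(tibble::tibble(t = t, x = path_x, y = path_y))),
    as.Date("1970-01-01"))
  th <- 0.7
  rx <- cos(th) * path_x - sin(th) * path_y + 12345
  ry <- sin(th) * path_x + cos(th) * path_y - 999
  d1 <- daily_distance(
    impute_gaps(segment_flights_pauses(tibble::tibble(t = t, x = rx, y = ry))),
    as.Date("1970-01-01"))
  expect_equal(d0, d1, tolerance = 1e-9)
  expect_equal(d0, 8, tolerance = 0.01)
})

test_that("location counts are stable under small fix jitter", {
  set.seed(4)
  base <- tibble::tibble(
    t = c(seq(0, 1800, 30), seq(4000, 5800, 30)),
    x = c(rep(0, 61), rep(500, 61)),
    y = 0
  )
  n0 <- nrow(significant_locations(
    segment_flights_pauses(base))$clusters)
  jit <- base
  jit$x <- jit$x + rnorm(nrow(jit), 0, 5)
  jit$y <- jit$y + rnorm(nrow(jit), 0, 5)
  n1 <- nrow(significant_locations(segment_flights_pauses(jit))$clusters)
  expect_equal(n0, 2)
  expect_equal(n1, n0)
})
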