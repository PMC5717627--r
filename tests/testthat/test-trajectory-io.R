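# Reading cursor logs and the preprocessing chain.

make_log_df <- function() {
  rbind(
    data.frame(participant = "a", trial = 1, t = c(0, 0.1, 0.2),
               x = c(400, 500, 700), y = c(600, 400, 100)),
    data.frame(participant = "a", trial = 2, t = c(0, 0.1, 0.2),
               x = c(400, 300, 100), y = c(600, 350, 100)))
}

test_that("reader returns one trajectory per (participant, trial)", {
  path <- write_log(make_log_df())
  trajs <- read_trajectories(path)
  expect_length(trajs, 2)
  expect_s3_class(trajs[[1]], "dl_trajectory")
  expect_setequal(vapply(trajs, function(t) t$trial_id, numeric(1)), c(1, 2))
})

test_that("reader enforces the schema and rejects unusable files", {
  df <- make_log_df()
  bad <- df[, setdiff(names(df), "t")]
  expect_error(read_trajectories(write_log(bad)),
               regexp = "t", class = "dl_format_error")
  empty <- df[0, ]
  expect_error(read_trajectories(write_log(empty)),
               class = "dl_empty_input_error")
  expect_error(read_trajectories(tempfile()), class = "dl_io_error")
})

test_that("reader sorts samples by time and drops non-finite rows", {
  df <- make_log_df()[1:3, ]
  shuffled <- df[c(3, 1, 2), ]
  trajs <- read_trajectories(write_log(shuffled))
  expect_equal(trajs[[1]]$times, sort(df$t))
  expect_equal(trajs[[1]]$xs, df$x[order(df$t)])

  df2 <- make_log_df()
  df2$x[2] <- NA
  trajs2 <- read_trajectories(write_log(df2))
  expect_equal(n_samples(trajs2[[1]]), 2)
})

test_that("tsv dialect is autodetected by extension", {
  path <- write_log(make_log_df(), ext = ".tsv")
  expect_length(read_trajectories(path), 2)
})

test_that("rescale maps the layout anchors to the normalized frame", {
  geom <- default_geom()
  raw <- trajectory(times = c(0, 1, 2, 3),
                    xs = c(400, 550, 700, 700),
                    ys = c(600, 350, 100, 100))
  tr <- rescale(raw, geom)
  expect_equal(c(tr$xs[1], tr$ys[1]), c(0, 0))      # start -> (0, 0)
  expect_equal(c(tr$xs[3], tr$ys[3]), c(1, 1))      # right target -> (1, 1)
  expect_equal(c(tr$xs[2], tr$ys[2]), c(0.5, 0.5))  # midpoint -> (0.5, 0.5)
  expect_identical(tr$choice, 1L)

  raw_left <- trajectory(times = c(0, 1), xs = c(400, 100), ys = c(600, 100))
  tl <- rescale(raw_left, geom)
  expect_equal(c(tl$xs[2], tl$ys[2]), c(-1, 1))     # left target -> (-1, 1)
})

test_that("rescale rejects degenerate geometry and inverts exactly", {
  expect_error(screen_geometry(c(0, 0), c(-1, 1), c(-1, 1)),
               class = "dl_geometry_error")
  expect_error(screen_geometry(c(0, 1), c(-1, 1), c(1, 1)),
               class = "dl_geometry_error")
  geom <- default_geom()
  raw <- trajectory(times = 0:3, xs = c(400, 520, 610, 700),
                    ys = c(600, 420, 230, 100))
  tr <- rescale(raw, geom)
  # invert the affine map by hand: round-trip within 1e-12
  sx <- 300; start <- geom$start
  target_row_y <- 100; sy <- target_row_y - start[2]
  expect_equal(tr$xs * sx + start[1], raw$xs, tolerance = 1e-12)
  expect_equal(tr$ys * sy + start[2], raw$ys, tolerance = 1e-12)
})

test_that("trim removes the static head and tail and resets the clock", {
  # 5 identical leading samples, motion, 4 identical trailing samples
  xs <- c(rep(0, 5), 0.3, 0.6, 1, rep(1, 3))
  ys <- c(rep(0, 5), 0.3, 0.6, 1, rep(1, 3))
  tr <- trajectory(times = seq(0, 1, length.out = 11), xs = xs, ys = ys)
  out <- trim(tr)
  expect_equal(n_samples(out), 11 - 4 - 3)  # first 4 and last 3 removed
  expect_equal(out$times[1], 0)
  expect_equal(out$xs[1], 0)
  expect_equal(out$xs[n_samples(out)], 1)
  expect_identical(out$choice, 1L)

  # no static head or tail: unchanged apart from the time shift
  clean <- trajectory(times = 1 + seq(0, 0.5, length.out = 6),
                      xs = seq(0, 1, length.out = 6),
                      ys = seq(0, 1, length.out = 6))
  out2 <- trim(clean)
  expect_equal(n_samples(out2), 6)
  expect_equal(out2$times, clean$times - 1)
  expect_equal(out2$xs, clean$xs)
})

test_that("trim errors on static or tied trajectories", {
  still <- trajectory(times = 0:5, xs = rep(0.001, 6), ys = rep(0, 6))
  expect_error(trim(still), class = "dl_degenerate_error")
  # ends exactly at x = 0: choice undetermined
  tied <- trajectory(times = 0:3, xs = c(0, 0.5, 0.2, 0), ys = c(0, 0.4, 0.8, 1))
  expect_error(trim(tied), class = "dl_degenerate_error")
})

test_that("trim never increases the sample count", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    tr <- trajectory(times = cumsum(stats::runif(n, 0.01, 0.05)),
                     xs = c(0, cumsum(stats::rnorm(n - 1, 0.03, 0.02))),
                     ys = seq(0, 1, length.out = n))
    out <- tryCatch(trim(tr), dl_degenerate_error = function(e) NULL)
    if (!is.null(out)) expect_lte(n_samples(out), n)
  }
})

test_that("resample produces the requested uniform grid and preserves endpoints", {
  tr <- make_smooth_traj(n = 37, duration = 0.83)
  out <- resample(tr)
  expect_equal(n_samples(out), 101)   # default grid size
  expect_true(all(abs(diff(diff(out$times))) < 1e-12))
  expect_identical(out$xs[1], tr$xs[1])
  expect_identical(out$xs[101], tr$xs[37])
  expect_equal(out$times[101] - out$times[1],
               tr$times[37] - tr$times[1])       # duration preserved

  out9 <- resample(tr, n_points = 9)
  expect_equal(n_samples(out9), 9)
  expect_error(resample(tr, 1), class = "dl_parameter_error")
})

test_that("resampling straight-line data keeps every point on the line", {
  set.seed(5)
  t_irr <- sort(stats::runif(30, 0, 1))
  tr <- trajectory(times = c(0, t_irr, 1), xs = c(0, t_irr, 1) * 0.8,
                   ys = c(0, t_irr, 1))
  out <- resample(tr, 101)
  expect_equal(out$xs, 0.8 * out$ys, tolerance = 1e-12)
})

test_that("resample is idempotent on an already-uniform grid", {
  tr <- make_smooth_traj(n = 101)
  out <- resample(tr, 101)
  expect_equal(out$xs, tr$xs, tolerance = 1e-12)
  expect_equal(out$times, tr$times, tolerance = 1e-12)
})

test_that("velocity estimators are exact on data they should be exact on", {
  n <- 101
  tt <- seq(0, 1, length.out = n)
  lin <- trajectory(times = tt, xs = tt, ys = rep(0.5, n) + 0 * tt)
  for (m in c("savgol", "fd")) {
    v <- estimate_velocity(lin, method = m)
    expect_equal(v$vxs, rep(1, n), tolerance = 1e-10)
    expect_equal(v$vys, rep(0, n), tolerance = 1e-10)
  }
  # constant position
  still <- trajectory(times = tt, xs = rep(0.2, n), ys = rep(0.9, n))
  v0 <- estimate_velocity(still)
  expect_equal(max(abs(v0$vxs)), 0, tolerance = 1e-12)

  # quadratic is differentiated exactly by the order-2 smoother (interior)
  quad <- trajectory(times = tt, xs = tt^2, ys = tt)
  vq <- estimate_velocity(quad, method = "savgol", window = 7, polyorder = 2)
  interior <- 4:(n - 3)
  expect_lt(max(abs(vq$vxs[interior] - 2 * tt[interior])), 1e-9)
})

test_that("polynomial data of degree <= polyorder reproduce analytic derivatives", {
  n <- 101
  tt <- seq(0, 1, length.out = n)
  cub <- trajectory(times = tt, xs = 0.3 * tt^3 - 0.5 * tt, ys = tt^2)
  v <- estimate_velocity(cub, method = "savgol", window = 9, polyorder = 3)
  interior <- 5:(n - 4)
  expect_lt(max(abs(v$vxs[interior] - (0.9 * tt^2 - 0.5)[interior])), 1e-9)
  expect_lt(max(abs(v$vys[interior] - (2 * tt)[interior])), 1e-9)
})

test_that("velocity estimation demands a uniform grid and sane filter settings", {
  irr <- trajectory(times = c(0, 0.1, 0.3, 0.35, 0.7),
                    xs = 1:5 / 5, ys = 1:5 / 5)
  expect_error(estimate_velocity(irr), class = "dl_precondition_error",
               regexp = "resample")
  uni <- make_smooth_traj(n = 21)
  expect_error(estimate_velocity(uni, window = 6), class = "dl_parameter_error")
  expect_error(estimate_velocity(uni, window = 3, polyorder = 4),
               class = "dl_parameter_error")
})

test_that("mirroring is an involution that flips choice and preserves geometry", {
  tr <- make_smooth_traj(choice = -1L)
  expect_identical(mirror_to_canonical(tr, 1), tr)
  m <- mirror_to_canonical(tr, -1)
  expect_identical(m$choice, 1L)
  expect_equal(m$xs, -tr$xs)
  back <- mirror_to_canonical(mirror_to_canonical(tr, -1), -1)
  expect_equal(back$xs, tr$xs)
  expect_identical(back$choice, tr$choice)
  expect_equal(abs(max_deviation(m)), abs(max_deviation(tr)))
})

test_that("write_trajectories round-trips through the reader", {
  trs <- list(make_smooth_traj(trial_id = 1), make_smooth_traj(trial_id = 2,
                                                               choice = -1L))
  path <- tempfile(fileext = ".csv")
  write_trajectories(trs, path)
  back <- read_trajectories(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$xs, trs[[1]]$xs)
  expect_equal(back[[2]]$times, trs[[2]]$times)
})

test_that("full preprocessing meets the endpoint contract", {
  p <- landscape_params(alpha = 2, tau = 0.05)
  for (x0 in c(0.02, -0.015)) {
    tr <- simulate_trajectory(p, x0 = x0, y0 = 0.01)
    out <- preprocess_trajectory(tr)$trajectory
    expect_equal(n_samples(out), 101)
    expect_lt(sqrt(out$xs[1]^2 + out$ys[1]^2), 0.05)
    expect_lt(sqrt((out$xs[101] - out$choice)^2 + (out$ys[101] - 1)^2), 0.2)
    expect_identical(out$choice, as.integer(sign(x0)))
  }
})
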