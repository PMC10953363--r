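test_that("frame-to-frame assignment matches a brute-force enumeration oracle", {
  b <- 50^2
  for (seed in 1:6) {
    set.seed(seed)
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    p1 <- matrix(runif(2 * n1, 0, 100), n1, 2)
    p2 <- matrix(runif(2 * n2, 0, 100), n2, 2)
    d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
    assign <- polarscope:::lap_link(d2, b)
    cost <- sum(d2[cbind(which(!is.na(assign)), assign[!is.na(assign)])]) +
      b * (sum(is.na(assign)) + (n2 - sum(!is.na(assign))))
    expect_equal(cost, brute_force_link_cost(d2, b), tolerance = 1e-9)
  }
})

test_that("track assembly keeps identities and enforces the length rule", {
  # one stationary object across 10 frames: one track of length 10
  obj <- tibble::tibble(frame = 1:10, x = 5, y = 5)
  tr <- link_tracks(obj, min_length = 5)
  expect_equal(dplyr::n_distinct(tr$track_id), 1)
  expect_equal(nrow(tr), 10)
  # two distant objects moving 1 px/frame: two tracks, no identity switches
  obj2 <- dplyr::bind_rows(
    tibble::tibble(frame = 1:8, x = 0 + (0:7), y = 0),
    tibble::tibble(frame = 1:8, x = 200, y = 10 + (0:7)))
  tr2 <- link_tracks(obj2, min_length = 5)
  expect_equal(dplyr::n_distinct(tr2$track_id), 2)
  per <- tr2 |> dplyr::group_by(track_id) |>
    dplyr::summarise(xr = max(x) - min(x), yr = max(y) - min(y))
  expect_true(all(per$xr == 7 & per$yr == 0 | per$xr == 0 & per$yr == 7))
  # a 4-frame observation is discarded, a 5-frame one retained
  obj3 <- dplyr::bind_rows(tibble::tibble(frame = 1:4, x = 0, y = 0),
                           tibble::tibble(frame = 1:5, x = 100, y = 100))
  tr3 <- link_tracks(obj3, min_length = 5)
  expect_equal(dplyr::n_distinct(tr3$track_id), 1)
  expect_equal(unique(tr3$x), 100)
  # links beyond max_link_distance are forbidden: the track breaks
  obj4 <- tibble::tibble(frame = 1:10, x = c(rep(0, 5), rep(300, 5)), y = 0)
  tr4 <- link_tracks(obj4, max_link_distance = 50, min_length = 5)
  expect_equal(dplyr::n_distinct(tr4$track_id), 2)
  # cells and clusters are linked in separate pools
  obj5 <- tibble::tibble(frame = rep(1:5, each = 2),
                         x = rep(c(0, 2), 5), y = 0,
                         class = rep(c("cell", "cluster"), 5))
  tr5 <- link_tracks(obj5, min_length = 5)
  expect_equal(sort(unique(tr5$class)), c("cell", "cluster"))
  expect_equal(dplyr::n_distinct(tr5$track_id), 2)
  # empty input: empty track set
  expect_equal(nrow(link_tracks(tibble::tibble())), 0)
})

test_that("track metrics follow their closed-form values", {
  tr <- tibble::tibble(track_id = 1, frame = 1:3, x = c(0, 0, 0), y = c(0, 3, 6))
  m <- track_metrics(tr, frame_interval = 20)
  expect_equal(m$mean_speed, 3)
  expect_equal(m$euclidean_distance, 6)
  expect_equal(m$path_length, 6)
  expect_equal(m$speed_px_per_min, 3 / 20)
  # stationary: all zero
  m0 <- track_metrics(tibble::tibble(track_id = 1, frame = 1:4, x = 1, y = 1))
  expect_equal(m0$mean_speed, 0)
  expect_equal(m0$euclidean_distance, 0)
  expect_equal(m0$path_length, 0)
  # closed square loop, side 4, back to start over 5 frames
  sq <- tibble::tibble(track_id = 1, frame = 1:5,
                       x = c(0, 4, 4, 0, 0), y = c(0, 0, 4, 4, 0))
  ms <- track_metrics(sq)
  expect_equal(ms$euclidean_distance, 0)
  expect_equal(ms$path_length, 16)
  expect_equal(ms$mean_speed, 4)
  # single-detection tracks are rejected
  expect_error(track_metrics(tibble::tibble(track_id = 1, frame = 1, x = 0, y = 0)),
               class = "polarscope_short_track")
})

test_that("euclidean displacement never exceeds path length", {
  set.seed(4)
  for (k in 1:20) {
    tr <- tibble::tibble(track_id = 1, frame = 1:10,
                         x = cumsum(rnorm(10)), y = cumsum(rnorm(10)))
    m <- track_metrics(tr)
    expect_lte(m$euclidean_distance, m$path_length + 1e-12)
  }
})

test_that("field summaries average per-track metrics and flag empty fields", {
  m <- structure(tibble::tibble(track_id = 1:2, class = "cell", n_frames = 5,
                                mean_speed = c(2, 4), speed_px_per_min = c(0.1, 0.2),
                                euclidean_distance = c(1, 3), path_length = c(5, 9)),
                 class = c("track_metrics", class(tibble::tibble())))
  fs <- field_summary(m)
  expect_equal(fs$mean_speed, 3)
  expect_equal(fs$mean_euclidean_distance, 2)
  # an assigned field with no tracks reports missing values, not zeros
  fields <- tibble::tibble(track_id = c(1, 2, NA), field_id = c("f1", "f1", "f2"))
  fs2 <- field_summary(m, fields = fields)
  expect_true(is.na(fs2$mean_speed[fs2$field_id == "f2"]))
  expect_equal(fs2$n_tracks[fs2$field_id == "f2"], 0)
  # clusters excluded by default, included on request
  mc <- m; mc$class <- c("cell", "cluster")
  expect_equal(field_summary(mc)$mean_speed, 2)
  expect_equal(field_summary(mc, include_clusters = TRUE)$mean_speed, 3)
})

test_that("truth evaluation scores perfect recovery and planted switches", {
  truth <- list(tracks = tidyr::expand_grid(cell_id = 1:2, frame = 1:6) |>
                  dplyr::mutate(x = ifelse(cell_id == 1, frame, 100 + frame), y = 0),
                cell_radius = 5,
                speeds = tibble::tibble(cell_id = 1:2, speed = 1))
  perfect <- truth$tracks |>
    dplyr::rename(track_id = cell_id) |>
    dplyr::mutate(class = "cell")
  ev <- evaluate_against_truth(perfect, truth)
  expect_equal(ev$purity, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$speed_bias, 0)
  # one identity switch in 10 links: purity 0.9
  truth2 <- list(tracks = tidyr::expand_grid(cell_id = 1:2, frame = 1:11) |>
                   dplyr::mutate(x = ifelse(cell_id == 1, 0, 50), y = 0),
                 cell_radius = 3,
                 speeds = tibble::tibble(cell_id = 1:2, speed = 0))
  switched <- tibble::tibble(track_id = 1, class = "cell", frame = 1:11,
                             x = c(rep(0, 10), 50), y = 0)
  ev2 <- evaluate_against_truth(switched, truth2)
  expect_equal(ev2$purity, 0.9)
  expect_error(evaluate_against_truth(perfect, list(cell_radius = 3)),
               class = "polarscope_no_truth")
})

test_that("doubling planted speed doubles recovered speed on jittered detections", {
  make_detections <- function(speed, seed) {
    sim <- simulate_motility_video(n_cells = 8, frames = 12, height = 400,
                                   width = 400, speed = speed,
                                   persistence = 0.8, seed = seed)
    set.seed(seed + 100)
    det <- sim$truth$tracks |>
      dplyr::mutate(x = x + rnorm(dplyr::n(), 0, 0.3),
                    y = y + rnorm(dplyr::n(), 0, 0.3))
    mean(track_metrics(link_tracks(det, min_length = 5))$mean_speed)
  }
  s2 <- make_detections(2, 1)
  s4 <- make_detections(4, 1)
  expect_gt(s4, s2)
  expect_lt(abs(s4 / s2 - 2), 0.3)
})
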