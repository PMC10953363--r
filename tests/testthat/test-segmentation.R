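test_that("variance foreground mask finds textured disks and degrades safely", {
  p <- segmentation_params()
  # constant frame: empty mask with a warning
  expect_warning(mask0 <- foreground_mask(matrix(0.5, 64, 64), p), "Constant")
  expect_false(any(mask0))
  # one speckled disk (texture only, no mean offset): one component of
  # about the disk area
  set.seed(7)
  f <- matrix(rnorm(128 * 128, 0.4, 0.01), 128, 128)
  f <- draw_disk(f, cx = 60, cy = 60, r = 15, level = 0.4, texture_sd = 0.2)
  mask <- foreground_mask(f, p)
  comps <- polarscope:::cpp_label_components(mask, 8L)
  big <- table(comps[comps > 0])
  big <- big[big > 50]  # speckle odd pixels aside
  expect_length(big, 1)
  expect_lt(abs(as.integer(big) - pi * 15^2) / (pi * 15^2), 0.3)
  # two well-separated disks: exactly two sizeable components
  set.seed(8)
  f2 <- matrix(rnorm(160 * 160, 0.4, 0.01), 160, 160)
  f2 <- draw_disk(f2, 40, 40, 12, level = 0.4, texture_sd = 0.2)
  f2 <- draw_disk(f2, 115, 115, 12, level = 0.4, texture_sd = 0.2)
  comps2 <- polarscope:::cpp_label_components(foreground_mask(f2, p), 8L)
  expect_equal(sum(table(comps2[comps2 > 0]) > 50), 2)
})

test_that("difference-of-Gaussian landscape uses the full 8-bit range with minima at cells", {
  p <- segmentation_params()
  expect_warning(l0 <- dog_landscape(matrix(1, 32, 32), p), "flat")
  expect_true(all(l0 == 0))
  set.seed(3)
  f <- matrix(rnorm(128 * 128, 0.4, 0.01), 128, 128)
  f <- draw_disk(f, 64, 64, 12)
  l <- dog_landscape(f, p)
  expect_equal(min(l), 0L)
  expect_equal(max(l), 255L)
  # global minimum inside the bright disk
  idx <- which(l == min(l), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((idx[2] - 1 - 64)^2 + (idx[1] - 1 - 64)^2), 12)
})

test_that("extended minima merge basins shallower than the depth h", {
  p <- segmentation_params(minima_depth_h = 10)
  # strictly monotonic ramp: one marker
  ramp <- matrix(rep(seq(0, 255, length.out = 32), each = 32), 32, 32,
                 byrow = TRUE)
  expect_equal(max(extended_minima_markers(ramp, p)), 1)
  # two basins (depth 40) separated by a ridge: two markers
  deep <- matrix(100, 20, 40)
  deep[10, 10] <- 60; deep[10, 30] <- 60
  expect_equal(max(extended_minima_markers(deep, p)), 2)
  # ridge shallower than h: basins merge into one marker
  shallow <- matrix(100, 20, 40)
  shallow[10, 10] <- 95; shallow[10, 30] <- 95
  expect_equal(max(extended_minima_markers(shallow, p)), 1)
})

test_that("watershed splits small components by markers and spares clusters", {
  p <- segmentation_params()
  # one component, one marker: unchanged
  mask <- matrix(FALSE, 40, 40); mask[10:20, 10:20] <- TRUE
  land <- matrix(100L, 40, 40)
  mk <- matrix(0L, 40, 40); mk[15, 15] <- 1L
  lab <- split_and_label(mask, mk, land, p)
  expect_equal(sum(lab > 0), sum(mask))
  expect_equal(length(unique(lab[lab > 0])), 1)
  # two touching disks with two markers: split into two parts of similar area
  mask2 <- matrix(FALSE, 80, 120)
  for (rr in 1:80) for (cc in 1:120) {
    if ((cc - 45)^2 + (rr - 40)^2 <= 15^2 ||
        (cc - 74)^2 + (rr - 40)^2 <= 15^2) mask2[rr, cc] <- TRUE
  }
  expect_lt(sum(mask2), 2000)
  land2 <- matrix(200L, 80, 120)
  for (rr in 1:80) for (cc in 1:120) {
    d <- min(sqrt((cc - 45)^2 + (rr - 40)^2), sqrt((cc - 74)^2 + (rr - 40)^2))
    land2[rr, cc] <- as.integer(min(200, 10 * d))
  }
  mk2 <- matrix(0L, 80, 120); mk2[40, 45] <- 1L; mk2[40, 74] <- 2L
  lab2 <- split_and_label(mask2, mk2, land2, p)
  areas <- as.integer(table(lab2[lab2 > 0]))
  expect_length(areas, 2)
  one_disk <- pi * 15^2
  expect_true(all(abs(areas - one_disk) / one_disk < 0.25))
  # conservation: children partition the parent exactly
  expect_equal(sum(areas), sum(mask2))
  expect_true(all(xor(lab2 > 0, !mask2)))
  # cluster-sized component with three markers: never split
  mask3 <- matrix(FALSE, 80, 80); mask3[10:59, 10:59] <- TRUE  # 2500 px2
  mk3 <- matrix(0L, 80, 80); mk3[20, 20] <- 1L; mk3[40, 40] <- 2L; mk3[50, 20] <- 3L
  lab3 <- split_and_label(mask3, mk3, matrix(0L, 80, 80), p)
  expect_equal(length(unique(lab3[lab3 > 0])), 1)
  # component with zero markers kept whole
  mk0 <- matrix(0L, 40, 40)
  lab4 <- split_and_label(mask, mk0, land, p)
  expect_equal(sum(lab4 > 0), sum(mask))
})

test_that("object size classes follow the exact px2 boundaries", {
  p <- segmentation_params()
  h <- 120; w <- 260
  m <- label_rectangle(h, w, 5, 5, 10, 15, id = 1L)          # 150 px2: noise
  m[m == 0] <- label_rectangle(h, w, 30, 5, 10, 20, id = 2L)[m == 0]   # 200 px2: cell
  m[m == 0] <- label_rectangle(h, w, 50, 5, 40, 50, id = 3L)[m == 0]   # 2000 px2: cluster
  m[m == 0] <- label_rectangle(h, w, 5, 120, 43, 46, id = 4L)[m == 0]  # 1978 px2: cell
  tab <- classify_objects(m, p)
  expect_false(1 %in% tab$label)
  expect_equal(tab$class[tab$label == 2], "cell")
  expect_equal(tab$area_px2[tab$label == 2], 200)
  expect_equal(tab$class[tab$label == 3], "cluster")
  expect_equal(tab$area_px2[tab$label == 3], 2000)
  expect_equal(tab$class[tab$label == 4], "cell")
  # every retained object has exactly one class
  expect_true(all(tab$class %in% c("cell", "cluster")))
  # centroid of the 200 px2 rectangle: rows 30..39, cols 5..24 (1-based)
  expect_equal(tab$x[tab$label == 2], mean(c(5:24) - 1))
  expect_equal(tab$y[tab$label == 2], mean(c(30:39) - 1))
})

test_that("integer translation shifts centroids equivariantly", {
  set.seed(10)
  f <- matrix(rnorm(128 * 128, 0.4, 0.01), 128, 128)
  f <- draw_disk(f, 50, 60, 12)
  p <- segmentation_params()
  seg1 <- classify_objects(split_and_label(
    foreground_mask(f, p), extended_minima_markers(dog_landscape(f, p), p),
    dog_landscape(f, p), p), p)
  g <- polarscope:::shift_frame(f, 7, -5)
  seg2 <- classify_objects(split_and_label(
    foreground_mask(g, p), extended_minima_markers(dog_landscape(g, p), p),
    dog_landscape(g, p), p), p)
  i1 <- which.max(seg1$area_px2); i2 <- which.max(seg2$area_px2)
  expect_equal(seg2$x[i2] - seg1$x[i1], 7, tolerance = 0.2)
  expect_equal(seg2$y[i2] - seg1$y[i1], -5, tolerance = 0.2)
})

test_that("translation drift is estimated to subpixel accuracy", {
  set.seed(5)
  f0 <- matrix(rnorm(96 * 96), 96, 96)
  # identical frames: zero shift
  d0 <- estimate_drift(list(f0, f0))
  expect_equal(unlist(d0[2, c("dx", "dy")]), c(dx = 0, dy = 0), tolerance = 1e-6)
  # planted (3, -2) shift
  f1 <- polarscope:::fft_translate(f0, 3, -2)
  d1 <- estimate_drift(list(f0, f1))
  expect_lt(abs(d1$dx[2] - 3), 0.5)
  expect_lt(abs(d1$dy[2] - (-2)), 0.5)
  # cumulative (1, 1) per frame over 5 frames
  frames <- lapply(0:4, function(t) polarscope:::fft_translate(f0, t, t))
  d2 <- estimate_drift(frames)
  expect_lt(abs(d2$dx[5] - 4), 0.5)
  expect_lt(abs(d2$dy[5] - 4), 0.5)
  # blank frame: zero with warning
  expect_warning(db <- estimate_drift(list(f0, matrix(0, 96, 96))), "blank")
  expect_equal(unlist(db[2, c("dx", "dy")]), c(dx = 0, dy = 0))
  expect_error(estimate_drift(list(f0)), class = "polarscope_bad_argument")
})

test_that("stack segmentation recovers planted cells, clusters and drift", {
  sim <- simulate_motility_video(n_cells = 10, frames = 8, height = 400,
                                 width = 400, cell_radius = 12, speed = 4,
                                 persistence = 0.8, seed = 31)
  seg <- segment_stack(sim)
  counts <- dplyr::count(dplyr::filter(seg$objects, class == "cell"), frame)
  expect_true(all(abs(counts$n - 10) <= 1))
  expect_equal(sum(seg$objects$class == "cluster"), 0)
  # blank video: empty object table
  blank <- array(0.5, c(64, 64, 5))
  suppressWarnings(seg0 <- segment_stack(blank, correct_drift = FALSE))
  expect_equal(nrow(seg0$objects), 0)
  # three cells placed touching with union >= 2000 px2 count as one cluster
  sim3 <- simulate_motility_video(n_cells = 3, frames = 5, height = 200,
                                  width = 200, cell_radius = 16, speed = 0,
                                  cluster_fraction = 2 / 3, seed = 8)
  seg3 <- segment_stack(sim3, correct_drift = FALSE)
  f1 <- dplyr::filter(seg3$objects, frame == 1)
  expect_equal(sum(f1$class == "cluster"), 1)
})

test_that("stationary cells stay put after correcting planted drift", {
  sim <- simulate_motility_video(n_cells = 5, frames = 6, height = 256,
                                 width = 256, cell_radius = 12, speed = 0,
                                 drift = c(2, 1), seed = 13)
  seg <- segment_stack(sim)
  tracks <- link_tracks(seg$objects, max_link_distance = 6, min_length = 6)
  expect_gt(dplyr::n_distinct(tracks$track_id), 0)
  spread <- tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(sx = stats::sd(x), sy = stats::sd(y))
  expect_true(all(spread$sx < 1 & spread$sy < 1))
})
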