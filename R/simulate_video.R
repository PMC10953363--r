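#' Simulate a phase-contrast-like motility video with ground truth
#'
#' Generates a grayscale time-lapse stack of textured moving disks on a flat
#' noisy background, emulating label-free phase-contrast imaging of cultured
#' macrophages (frames every 20 min over 12 h in the emulated protocol).
#' Cells follow a persistent random walk with exact per-frame step length
#' `speed`, reflect at image borders, and can optionally be placed touching
#' (clusters) or ride a global stage drift. The returned truth tracks are
#' the drift-free (but reflection-aware) positions, so recovered motion can
#' be compared against planted motion after drift correction.
#'
#' Cells are rendered as a radial intensity dome (cell-body thickness
#' profile) with per-pixel Gaussian speckle on top, at positive contrast
#' over the background: the speckle and the dome's internal gradient give
#' the high local variance that variance-based foreground detection relies
#' on, and the dome gives the blob-scale band-pass response that makes one
#' extended minimum per cell.
#'
#' @param n_cells Number of cells (>= 1).
#' @param frames Number of frames (>= 5).
#' @param height,width Image size in px.
#' @param cell_radius Disk radius in px (>= 3). The default 12 px gives an
#'   area of ~452 px², inside the single-cell size band.
#' @param speed Step length in px per frame; a scalar or one value per cell.
#' @param persistence Directional persistence in \[0, 1\]: 0 is an
#'   uncorrelated random walk, values near 1 give nearly straight paths.
#' @param drift Global stage drift `(dx, dy)` in px per frame, added to the
#'   rendered frames only (truth tracks are drift-free).
#' @param cluster_fraction Fraction of cells placed touching another cell,
#'   forming merged blobs (default 0).
#' @param noise_sd Gaussian background noise sd (intensity units in
#'   \[0, 1\]), regenerated every frame.
#' @param bg_texture_sd Amplitude of a faint static background texture
#'   (plate debris / illumination mottle) that rides the stage drift
#'   (default 0.02; set 0 for a featureless background). Translation-based
#'   drift estimation needs some static scene content, exactly as
#'   feature-based registration does on real videos.
#' @param cell_contrast Mean intensity offset of cell pixels over
#'   background.
#' @param texture_sd Relative sd of the per-pixel speckle texture.
#' @param background Background intensity level.
#' @param frame_interval Minutes between frames (metadata; default 20).
#' @param seed Integer seed; identical parameters and seed give an
#'   identical stack.
#'
#' @return A list of class `motility_sim`:
#' \describe{
#'   \item{frames}{numeric array `height x width x frames`, intensities in
#'     \[0, 1\].}
#'   \item{truth}{list with `tracks` (tibble `cell_id`, `frame`, `x`, `y`;
#'     0-based pixel coordinates, x = column, y = row), `speeds` (tibble
#'     `cell_id`, `speed`), `cell_radius`, `drift`, `cluster_ids`.}
#'   \item{frame_interval}{minutes between frames.}
#' }
#' @examples
#' sim <- simulate_motility_video(n_cells = 3, frames = 6, height = 128,
#'                                width = 128, seed = 1)
#' dim(sim$frames)
#' @export
simulate_motility_video <- function(n_cells = 10, frames = 36,
                                    height = 512, width = 512,
                                    cell_radius = 12, speed = 4,
                                    persistence = 0.7, drift = c(0, 0),
                                    cluster_fraction = 0, noise_sd = 0.01,
                                    bg_texture_sd = 0.02,
                                    cell_contrast = 0.3, texture_sd = 0.03,
                                    background = 0.5, frame_interval = 20,
                                    seed = 1) {
  n_cells <- check_count(n_cells, "n_cells")
  frames <- check_count(frames, "frames", min = 5L)
  height <- check_count(height, "height", min = 16L)
  width <- check_count(width, "width", min = 16L)
  cell_radius <- check_scalar(cell_radius, "cell_radius", min = 3)
  persistence <- check_fraction(persistence, "persistence")
  cluster_fraction <- check_fraction(cluster_fraction, "cluster_fraction")
  noise_sd <- check_scalar(noise_sd, "noise_sd", min = 0)
  if (length(speed) == 1) speed <- rep(speed, n_cells)
  if (length(speed) != n_cells || any(speed < 0)) {
    abort("`speed` must be a nonnegative scalar or one value per cell.",
          class = "polarscope_bad_argument")
  }
  if (length(drift) != 2 || !is.numeric(drift)) {
    abort("`drift` must be a numeric (dx, dy) pair.", class = "polarscope_bad_argument")
  }
  r <- cell_radius
  if (width <= 4 * r + 2 || height <= 4 * r + 2) {
    abort("Image too small for the requested cell radius.",
          class = "polarscope_image_too_small")
  }

  with_seed(seed, {
    n_cluster <- round(cluster_fraction * n_cells)
    cluster_ids <- if (n_cluster > 0 && n_cells >= 2) {
      sort(sample.int(n_cells, min(n_cluster, n_cells - 1)))
    } else integer()
    free_ids <- setdiff(seq_len(n_cells), cluster_ids)

    # rejection placement of non-overlapping free cells; the margin keeps
    # initially separate cells resolvable as separate objects
    pos <- matrix(NA_real_, n_cells, 2)  # x, y (0-based, continuous)
    min_sep <- 3 * r
    tries <- 0L
    for (i in free_ids) {
      repeat {
        tries <- tries + 1L
        if (tries > 500L * n_cells) {
          abort("Could not place cells without overlap; reduce n_cells or cell_radius.",
                class = "polarscope_placement_failed")
        }
        cand <- c(stats::runif(1, r, width - 1 - r), stats::runif(1, r, height - 1 - r))
        placed <- pos[free_ids[free_ids < i], , drop = FALSE]
        if (nrow(placed) == 0 ||
            min(sqrt(rowSums((placed - rep(cand, each = nrow(placed)))^2))) >= min_sep) {
          pos[i, ] <- cand
          break
        }
      }
    }
    # cluster members sit touching a randomly chosen placed anchor
    for (i in cluster_ids) {
      anchor <- pos[sample(free_ids, 1), ]
      theta <- stats::runif(1, 0, 2 * pi)
      cand <- anchor + 1.5 * r * c(cos(theta), sin(theta))
      pos[i, ] <- pmin(pmax(cand, r), c(width - 1 - r, height - 1 - r))
    }

    # persistent random walk with exact step length, border reflection and
    # excluded-volume contact avoidance (adherent cells do not interpenetrate;
    # intentionally clustered cells are exempt)
    lim <- c(width - 1 - r, height - 1 - r)
    reflect_step <- function(p, d, s) {
      cand <- p + d * s
      for (ax in 1:2) {
        if (cand[ax] < r) { cand[ax] <- 2 * r - cand[ax]; d[ax] <- -d[ax] }
        if (cand[ax] > lim[ax]) { cand[ax] <- 2 * lim[ax] - cand[ax]; d[ax] <- -d[ax] }
        cand[ax] <- min(max(cand[ax], r), lim[ax])
      }
      list(pos = cand, dir = d)
    }
    theta <- stats::runif(n_cells, 0, 2 * pi)
    dir <- cbind(cos(theta), sin(theta))
    tracks <- array(NA_real_, c(n_cells, frames, 2))
    tracks[, 1, ] <- pos
    for (t in seq_len(frames - 1)) {
      u <- stats::runif(n_cells, 0, 2 * pi)
      mix <- persistence * dir + (1 - persistence) * cbind(cos(u), sin(u))
      len <- sqrt(rowSums(mix^2))
      len[len == 0] <- 1
      dir <- mix / len
      for (i in seq_len(n_cells)) {
        d_i <- dir[i, ]
        for (try in 0:8) {
          step <- reflect_step(pos[i, ], d_i, speed[i])
          clash <- FALSE
          if (!(i %in% cluster_ids) && n_cells > 1 && try < 8) {
            others <- pos[-i, , drop = FALSE]
            clash <- min(sqrt((others[, 1] - step$pos[1])^2 +
                              (others[, 2] - step$pos[2])^2)) < 2 * r
          }
          if (!clash) {
            pos[i, ] <- step$pos
            dir[i, ] <- step$dir
            break
          }
          a <- stats::runif(1, 0, 2 * pi)
          d_i <- c(cos(a), sin(a))
        }
      }
      tracks[, t + 1, ] <- pos
    }

    # static background texture (smoothed, unit-sd), translated with drift
    pattern <- if (bg_texture_sd > 0) {
      p <- gauss_blur(matrix(stats::rnorm(height * width), height, width), 1)
      p / stats::sd(p)
    }

    # render: background noise + speckled disks, shifted by cumulative drift
    stack <- array(0, c(height, width, frames))
    for (t in seq_len(frames)) {
      frame <- matrix(stats::rnorm(height * width, background, noise_sd),
                      height, width)
      shift <- (t - 1) * drift
      if (!is.null(pattern)) {
        frame <- frame + bg_texture_sd * fft_translate(pattern, shift[1], shift[2])
      }
      for (i in seq_len(n_cells)) {
        cx <- tracks[i, t, 1] + shift[1]
        cy <- tracks[i, t, 2] + shift[2]
        cols <- max(1, floor(cx - r) + 1):min(width, ceiling(cx + r) + 1)
        rows <- max(1, floor(cy - r) + 1):min(height, ceiling(cy + r) + 1)
        if (length(cols) == 0 || length(rows) == 0) next
        dx <- (cols - 1) - cx
        dy <- (rows - 1) - cy
        d2 <- outer(dy^2, dx^2, "+")
        inside <- d2 <= r^2
        npix <- sum(inside)
        if (npix > 0) {
          # radial dome (cell-body thickness) + per-pixel Gaussian speckle
          dome <- sqrt(pmax(1 - d2 / r^2, 0))
          sub <- frame[rows, cols]
          sub[inside] <- background + cell_contrast *
            (dome[inside] + texture_sd * stats::rnorm(npix))
          frame[rows, cols] <- sub
        }
      }
      stack[, , t] <- pmin(pmax(frame, 0), 1)
    }

    truth_tracks <- tidyr::expand_grid(cell_id = seq_len(n_cells),
                                       frame = seq_len(frames)) |>
      dplyr::mutate(x = tracks[cbind(.data$cell_id, .data$frame, 1)],
                    y = tracks[cbind(.data$cell_id, .data$frame, 2)])

    structure(list(
      frames = stack,
      truth = list(tracks = truth_tracks,
                   speeds = tibble(cell_id = seq_len(n_cells), speed = speed),
                   cell_radius = r,
                   drift = drift,
                   cluster_ids = cluster_ids),
      frame_interval = frame_interval
    ), class = "motility_sim")
  })
}

#' @export
print.motility_sim <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<motility_sim> %d frames of %dx%d px, %d cells (%d clustered)\n",
              d[3], d[1], d[2], max(x$truth$tracks$cell_id),
              length(x$truth$cluster_ids)))
  invisible(x)
}
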