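#' Segmentation parameters
#'
#' Bundle of tunable parameters for the per-frame detection chain. Defaults
#' follow the published operator settings where stated (local variance
#' sigma = 5 px, difference-of-Gaussian sigma = 7 px, size bands 200 and
#' 2000 px²); the extended-minima depth and connectivity are exposed because
#' they are not fixed by the protocol.
#'
#' @param variance_sigma Gaussian window sigma (px) of the local variance
#'   filter (default 5).
#' @param dog_sigma Large Gaussian sigma (px) of the difference-of-Gaussian
#'   band-pass (default 7).
#' @param dog_sigma_low Small Gaussian sigma (px), must be below
#'   `dog_sigma` (default 1).
#' @param minima_depth_h Extended-minima depth on the 8-bit landscape,
#'   in (0, 255] (default 10).
#' @param connectivity Pixel connectivity for components and flooding,
#'   4 or 8 (default 8).
#' @param min_area Objects below this area (px²) are discarded as noise
#'   (default 200).
#' @param cluster_area Objects at/above this area (px²) are cell clusters
#'   and are never watershed-split (default 2000).
#' @param variance_window `"gaussian"` (sigma-weighted window, default) or
#'   `"box"` (uniform window of half-width `variance_sigma`).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(variance_sigma = 5, dog_sigma = 7,
                                dog_sigma_low = 1, minima_depth_h = 10,
                                connectivity = 8, min_area = 200,
                                cluster_area = 2000,
                                variance_window = c("gaussian", "box")) {
  variance_window <- match.arg(variance_window)
  if (!(dog_sigma_low > 0 && dog_sigma_low < dog_sigma)) {
    abort("Need 0 < dog_sigma_low < dog_sigma.", class = "polarscope_bad_argument")
  }
  if (!(min_area < cluster_area)) {
    abort("Need min_area < cluster_area.", class = "polarscope_bad_argument")
  }
  if (!(minima_depth_h > 0 && minima_depth_h <= 255)) {
    abort("`minima_depth_h` must lie in (0, 255].", class = "polarscope_bad_argument")
  }
  if (!connectivity %in% c(4, 8)) {
    abort("`connectivity` must be 4 or 8.", class = "polarscope_bad_argument")
  }
  structure(list(variance_sigma = variance_sigma, dog_sigma = dog_sigma,
                 dog_sigma_low = dog_sigma_low, minima_depth_h = minima_depth_h,
                 connectivity = as.integer(connectivity),
                 min_area = min_area, cluster_area = cluster_area,
                 variance_window = variance_window),
            class = "segmentation_params")
}

as_frame_list <- function(stack) {
  if (inherits(stack, "motility_sim")) stack <- stack$frames
  if (is.list(stack)) return(stack)
  if (is.matrix(stack)) return(list(stack))
  if (is.array(stack) && length(dim(stack)) == 3) {
    return(lapply(seq_len(dim(stack)[3]), function(t) stack[, , t]))
  }
  abort("`stack` must be a matrix, H x W x T array, list of matrices, or motility_sim.",
        class = "polarscope_bad_argument")
}

gauss_blur <- function(x, sigma) {
  EBImage::imageData(EBImage::gblur(x, sigma = sigma))
}

#' Estimate per-frame translation drift
#'
#' Estimates the translation of every frame relative to the first frame by
#' phase correlation with parabolic subpixel refinement — a translation-only
#' registration honoring the same contract as feature-based drift
#' correction. Blank (zero-variance) frames are reported as zero shift with
#' a warning.
#'
#' @param stack An `H x W x T` array, list of frames, or `motility_sim`.
#' @return Tibble (`frame`, `dx`, `dy`): the shift in px that maps frame 1
#'   onto each frame (apply the negated shifts to align the stack).
#' @export
estimate_drift <- function(stack) {
  frames <- as_frame_list(stack)
  if (length(frames) < 2) {
    abort("Drift estimation needs >= 2 frames.", class = "polarscope_bad_argument")
  }
  ref <- frames[[1]]
  f_ref <- stats::fft(ref)
  shifts <- purrr::map(seq_along(frames), function(t) {
    if (t == 1) return(c(dx = 0, dy = 0))
    fr <- frames[[t]]
    if (stats::sd(fr) == 0 || stats::sd(ref) == 0) {
      warn(sprintf("Frame %d is blank; reporting zero drift.", t))
      return(c(dx = 0, dy = 0))
    }
    cross <- f_ref * Conj(stats::fft(fr))
    mag <- Mod(cross)
    mag[mag == 0] <- 1
    r <- Re(stats::fft(cross / mag, inverse = TRUE))
    peak <- unname(which(r == max(r), arr.ind = TRUE)[1, ])
    sub <- function(axis_len, idx, get) {
      rm1 <- get((idx - 2) %% axis_len + 1)
      r0 <- get((idx - 1) %% axis_len + 1)
      rp1 <- get(idx %% axis_len + 1)
      den <- rm1 - 2 * r0 + rp1
      d <- if (abs(den) > 1e-12) 0.5 * (rm1 - rp1) / den else 0
      shift <- (idx - 1) + max(min(d, 0.5), -0.5)
      if (shift > axis_len / 2) shift <- shift - axis_len
      shift
    }
    dy <- sub(nrow(r), peak[1], function(i) r[i, peak[2]])
    dx <- sub(ncol(r), peak[2], function(j) r[peak[1], j])
    c(dx = -dx, dy = -dy)
  })
  tibble(frame = seq_along(frames),
         dx = vapply(shifts, `[[`, numeric(1), "dx"),
         dy = vapply(shifts, `[[`, numeric(1), "dy"))
}

#' @rdname estimate_drift
#' @param drift Tibble from `estimate_drift()`.
#' @return `apply_drift_correction()` returns the stack as a list of frames
#'   with each frame shifted by the negated, rounded drift (vacated pixels
#'   filled with the frame median).
#' @export
apply_drift_correction <- function(stack, drift) {
  frames <- as_frame_list(stack)
  purrr::map(seq_along(frames), function(t) {
    shift_frame(frames[[t]], -round(drift$dx[t]), -round(drift$dy[t]))
  })
}

# Periodic subpixel translation via a Fourier phase ramp: content moves by
# (+dx, +dy) px with wrap-around.
fft_translate <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  ky <- c(seq(0, floor(h / 2)), seq(-(ceiling(h / 2) - 1), -1))
  kx <- c(seq(0, floor(w / 2)), seq(-(ceiling(w / 2) - 1), -1))
  phase <- exp(-2i * pi * (outer(ky * dy / h, kx * dx / w, "+")))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (h * w)
}

shift_frame <- function(frame, dx, dy) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(stats::median(frame), h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Variance-based foreground mask
#'
#' Enhances textured cells against a homogeneous background with a local
#' variance filter (Gaussian-weighted window by default), binarizes with
#' Otsu's threshold and fills holes. Variance is computed on the raw
#' intensity scale (no rescaling before filtering). A constant frame yields
#' an empty mask with a warning.
#'
#' @param frame Numeric matrix of finite intensities.
#' @param params A [segmentation_params()] list.
#' @return Logical matrix: TRUE = foreground.
#' @export
foreground_mask <- function(frame, params = segmentation_params()) {
  if (!all(is.finite(frame))) {
    abort("`frame` contains non-finite intensities.", class = "polarscope_bad_argument")
  }
  if (max(frame) - min(frame) < .Machine$double.eps) {
    warn("Constant frame: Otsu threshold undefined, returning an empty mask.")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  if (params$variance_window == "gaussian") {
    m1 <- gauss_blur(frame, params$variance_sigma)
    m2 <- gauss_blur(frame^2, params$variance_sigma)
  } else {
    k <- 2 * ceiling(params$variance_sigma) + 1
    kern <- matrix(1 / k^2, k, k)
    m1 <- EBImage::imageData(EBImage::filter2(frame, kern))
    m2 <- EBImage::imageData(EBImage::filter2(frame^2, kern))
  }
  v <- pmax(m2 - m1^2, 0)
  if (max(v) - min(v) < .Machine$double.eps) {
    warn("Constant frame: Otsu threshold undefined, returning an empty mask.")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  thr <- EBImage::otsu(EBImage::Image(v), range = range(v))
  mask <- v > thr
  filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  matrix(as.logical(filled), nrow(frame), ncol(frame))
}

#' Inverted difference-of-Gaussian landscape
#'
#' Band-pass filters the raw frame (small minus large Gaussian blur),
#' inverts the result and rescales it to the full 8-bit range, so that cell
#' centers become intensity minima — the relief flooded by the
#' marker-controlled watershed.
#'
#' @inheritParams foreground_mask
#' @return Integer matrix with values in 0..255 (constant 0 with a warning
#'   for a constant frame; any non-constant frame spans the full range).
#' @export
dog_landscape <- function(frame, params = segmentation_params()) {
  if (!all(is.finite(frame))) {
    abort("`frame` contains non-finite intensities.", class = "polarscope_bad_argument")
  }
  if (max(frame) - min(frame) < .Machine$double.eps) {
    warn("Constant frame: difference-of-Gaussian landscape is flat.")
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  dog <- gauss_blur(frame, params$dog_sigma_low) - gauss_blur(frame, params$dog_sigma)
  inv <- -dog
  rng <- max(inv) - min(inv)
  if (rng < .Machine$double.eps) {
    warn("Degenerate frame: difference-of-Gaussian landscape is flat.")
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  matrix(as.integer(round(255 * (inv - min(inv)) / rng)), nrow(frame), ncol(frame))
}

#' Extended-minima watershed markers
#'
#' Labels the extended (h-)minima of an 8-bit landscape: connected regions
#' whose depth below the surrounding ridges exceeds `minima_depth_h`,
#' computed via grayscale reconstruction. Each labeled region seeds one
#' watershed basin.
#'
#' @param landscape Integer/numeric matrix, typically from
#'   [dog_landscape()].
#' @inheritParams foreground_mask
#' @return Integer matrix of marker labels (0 = none).
#' @export
extended_minima_markers <- function(landscape, params = segmentation_params()) {
  l <- -as.numeric(landscape)
  dim(l) <- dim(landscape)
  hmax <- cpp_reconstruct_dilation(l - params$minima_depth_h, l,
                                   params$connectivity)
  cpp_regional_minima(-hmax, params$connectivity)
}

#' Area-restricted marker-controlled watershed labeling
#'
#' Splits touching cells: each connected foreground component smaller than
#' `cluster_area` px² that contains more than one marker is divided by
#' flooding the landscape from its markers (flooding restricted to the
#' component); components at/above `cluster_area` px² — presumed cell
#' clusters, for which watershed is unreliable — and components without
#' markers pass through unsplit.
#'
#' @param mask Logical foreground matrix.
#' @param markers Integer marker matrix from [extended_minima_markers()].
#' @param landscape Matrix relief from [dog_landscape()].
#' @inheritParams foreground_mask
#' @return Integer label matrix (0 = background), labels contiguous from 1.
#' @export
split_and_label <- function(mask, markers, landscape,
                            params = segmentation_params()) {
  stopifnot(all(dim(mask) == dim(markers)), all(dim(mask) == dim(landscape)))
  comps <- cpp_label_components(mask, params$connectivity)
  n_comp <- max(comps)
  out <- matrix(0L, nrow(mask), ncol(mask))
  next_label <- 0L
  marker_sizes <- tabulate(markers[markers > 0])
  for (cid in seq_len(n_comp)) {
    in_comp <- comps == cid
    area <- sum(in_comp)
    # a marker seeds this component only if most of its basin lies inside;
    # background minima clipping the mask edge must not split objects
    inside <- markers[in_comp & markers > 0]
    inside_counts <- tabulate(inside, nbins = length(marker_sizes))
    comp_markers <- which(inside_counts > 0 &
                            inside_counts > marker_sizes / 2)
    if (area >= params$cluster_area || length(comp_markers) <= 1) {
      next_label <- next_label + 1L
      out[in_comp] <- next_label
    } else {
      seeds <- matrix(0L, nrow(mask), ncol(mask))
      seeds[in_comp] <- match(markers[in_comp], comp_markers, nomatch = 0L)
      ws <- cpp_marker_watershed(landscape + 0, seeds, in_comp,
                                 params$connectivity)
      for (child in seq_along(comp_markers)) {
        next_label <- next_label + 1L
        out[in_comp & ws == child] <- next_label
      }
      # a connected component is fully reachable, but guard any leftovers
      leftover <- in_comp & out == 0L
      if (any(leftover)) out[leftover] <- next_label
    }
  }
  out
}

#' Object table with size-class labels
#'
#' Measures every labeled object and applies the size rules: objects below
#' `min_area` px² are discarded as noise, objects in
#' `[min_area, cluster_area)` px² are individual cells, and objects at or
#' above `cluster_area` px² are cell clusters. Centroids are mean pixel
#' coordinates (0-based, x = column, y = row).
#'
#' @param labels Integer label matrix.
#' @inheritParams foreground_mask
#' @return Tibble (`label`, `area_px2`, `x`, `y`, `class`).
#' @export
classify_objects <- function(labels, params = segmentation_params()) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(tibble(label = integer(), area_px2 = integer(),
                  x = numeric(), y = numeric(), class = character()))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1) %% nrow(labels)       # 0-based y
  cols <- (idx - 1) %/% nrow(labels)      # 0-based x
  tab <- tibble(label = lab, x = cols, y = rows) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(area_px2 = dplyr::n(), x = mean(.data$x),
                     y = mean(.data$y), .groups = "drop") |>
    dplyr::filter(.data$area_px2 >= params$min_area) |>
    dplyr::mutate(class = ifelse(.data$area_px2 >= params$cluster_area,
                                 "cluster", "cell")) |>
    dplyr::select("label", "area_px2", "x", "y", "class")
  tab
}

#' Segment a full time-lapse stack
#'
#' Runs the complete per-frame detection chain: translation drift
#' correction (when `correct_drift = TRUE` and more than one frame), local
#' variance foreground mask, difference-of-Gaussian landscape,
#' extended-minima markers, area-restricted marker-controlled watershed,
#' connected components and size classification. Noise-sized objects are
#' removed from both the object table and the label maps.
#'
#' @param stack An `H x W x T` array, list of frames, or `motility_sim`.
#' @inheritParams foreground_mask
#' @param correct_drift Estimate and remove global translation first
#'   (default TRUE).
#' @return A list of class `segmentation_result`: `labels` (list of integer
#'   label matrices), `objects` (tibble `frame`, `label`, `area_px2`, `x`,
#'   `y`, `class`), `drift` (tibble or NULL) and `params`.
#' @examples
#' sim <- simulate_motility_video(n_cells = 3, frames = 6, height = 128,
#'                                width = 128, seed = 1)
#' seg <- segment_stack(sim)
#' dplyr::count(seg$objects, frame)
#' @export
segment_stack <- function(stack, params = segmentation_params(),
                          correct_drift = TRUE) {
  frames <- as_frame_list(stack)
  drift <- NULL
  if (correct_drift && length(frames) >= 2) {
    drift <- estimate_drift(frames)
    frames <- apply_drift_correction(frames, drift)
  }
  per_frame <- purrr::map(seq_along(frames), function(t) {
    frame <- frames[[t]]
    mask <- foreground_mask(frame, params)
    if (!any(mask)) {
      return(list(labels = matrix(0L, nrow(frame), ncol(frame)),
                  objects = classify_objects(matrix(0L, 1, 1), params)))
    }
    landscape <- dog_landscape(frame, params)
    markers <- extended_minima_markers(landscape, params)
    labels <- split_and_label(mask, markers, landscape, params)
    objects <- classify_objects(labels, params)
    labels[!labels %in% objects$label] <- 0L
    list(labels = labels, objects = objects)
  })
  objects <- purrr::list_rbind(purrr::imap(per_frame, function(pf, t) {
    dplyr::mutate(pf$objects, frame = t, .before = 1)
  }))
  structure(list(labels = purrr::map(per_frame, "labels"),
                 objects = objects, drift = drift, params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  counts <- dplyr::count(x$objects, .data$frame)
  cat(sprintf("<segmentation_result> %d frames, %d objects (median %s per frame)\n",
              length(x$labels), nrow(x$objects),
              if (nrow(counts)) stats::median(counts$n) else 0))
  invisible(x)
}
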