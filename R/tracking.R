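#' Link per-frame detections into tracks
#'
#' Frame-to-frame centroid linking in the Jaqaman/LAP style: for every pair
#' of consecutive frames, detections are matched one-to-one by solving a
#' linear assignment problem that minimizes total squared centroid distance,
#' with links beyond `max_link_distance` forbidden (the alternative cost for
#' starting or ending a track is `max_link_distance^2`). Cells and clusters
#' are linked in separate pools and never linked to each other. Tracks
#' observed in fewer than `min_length` frames are discarded. No gap closing
#' by default; `max_gap = 1` allows a track to bridge a single missed frame.
#'
#' @param objects Data frame of detections with columns `frame`, `x`, `y`
#'   and optionally `class` (default `"cell"`), e.g.
#'   `segment_stack()$objects`.
#' @param max_link_distance Maximum frame-to-frame displacement in px
#'   (default 50).
#' @param min_length Minimum detections per retained track (default 5).
#' @param max_gap Maximum allowed frame gap within a track: 0 (default,
#'   strict frame-to-frame) or 1.
#' @param frame_interval Minutes between frames, carried as metadata
#'   (default 20).
#' @return Tibble (`track_id`, `class`, `frame`, `x`, `y`) of class
#'   `track_set`; linking parameters are stored as attributes. Empty input
#'   gives an empty track set.
#' @examples
#' obj <- tibble::tibble(frame = rep(1:6, each = 1), x = 1:6, y = 0)
#' link_tracks(obj, min_length = 5)
#' @export
link_tracks <- function(objects, max_link_distance = 50, min_length = 5,
                        max_gap = 0, frame_interval = 20) {
  max_link_distance <- check_scalar(max_link_distance, "max_link_distance",
                                    min = 0, strict = TRUE)
  min_length <- check_count(min_length, "min_length")
  if (!max_gap %in% c(0, 1)) {
    abort("`max_gap` must be 0 or 1.", class = "polarscope_bad_argument")
  }
  if (!is.data.frame(objects)) {
    abort("`objects` must be a data frame.", class = "polarscope_bad_argument")
  }
  if (!"class" %in% names(objects)) objects$class <- "cell"
  empty <- tibble(track_id = integer(), class = character(),
                  frame = integer(), x = numeric(), y = numeric())
  if (nrow(objects) == 0) {
    return(new_track_set(empty, max_link_distance, min_length, frame_interval))
  }
  miss <- setdiff(c("frame", "x", "y"), names(objects))
  if (length(miss) > 0) {
    abort(paste0("`objects` is missing column(s): ", toString(miss), "."),
          class = "polarscope_bad_argument")
  }

  pools <- split(objects, objects$class)
  all_tracks <- list()
  next_id <- 0L
  for (cls in names(pools)) {
    pool <- dplyr::arrange(pools[[cls]], .data$frame)
    frames <- sort(unique(pool$frame))
    by_frame <- split(pool, pool$frame)
    # active tracks: list of (id, last_frame, x, y, rows = list of detections)
    active <- list()
    finished <- list()
    for (f in frames) {
      det <- by_frame[[as.character(f)]]
      last_ok <- vapply(active, function(a) f - a$last_frame <= 1 + max_gap,
                        logical(1))
      if (length(active) > 0 && any(!last_ok)) {
        finished <- c(finished, active[!last_ok])
        active <- active[last_ok]
      }
      src <- active
      n1 <- length(src); n2 <- nrow(det)
      linked_to <- rep(NA_integer_, n2)
      if (n1 > 0 && n2 > 0) {
        sx <- vapply(src, `[[`, numeric(1), "x")
        sy <- vapply(src, `[[`, numeric(1), "y")
        d2 <- outer(sx, det$x, "-")^2 + outer(sy, det$y, "-")^2
        assign <- lap_link(d2, max_link_distance^2)
        for (i in seq_len(n1)) {
          j <- assign[i]
          if (!is.na(j)) linked_to[j] <- i
        }
      }
      new_active <- list()
      used_src <- integer()
      for (j in seq_len(n2)) {
        i <- linked_to[j]
        if (!is.na(i)) {
          a <- src[[i]]
          used_src <- c(used_src, i)
          a$last_frame <- f
          a$x <- det$x[j]; a$y <- det$y[j]
          a$rows[[length(a$rows) + 1L]] <- det[j, c("frame", "x", "y")]
          new_active[[length(new_active) + 1L]] <- a
        } else {
          next_id <- next_id + 1L
          new_active[[length(new_active) + 1L]] <-
            list(id = next_id, class = cls, last_frame = f,
                 x = det$x[j], y = det$y[j],
                 rows = list(det[j, c("frame", "x", "y")]))
        }
      }
      if (n1 > 0) {
        for (i in setdiff(seq_len(n1), used_src)) {
          a <- src[[i]]
          # an unmatched track may stay open through an allowed gap
          if (max_gap > 0 && f - a$last_frame <= max_gap) {
            new_active[[length(new_active) + 1L]] <- a
          } else {
            finished[[length(finished) + 1L]] <- a
          }
        }
      }
      active <- new_active
    }
    finished <- c(finished, active)
    all_tracks <- c(all_tracks, finished)
  }

  kept <- all_tracks[vapply(all_tracks, function(a) length(a$rows) >= min_length,
                            logical(1))]
  if (length(kept) == 0) {
    return(new_track_set(empty, max_link_distance, min_length, frame_interval))
  }
  kept <- kept[order(vapply(kept, `[[`, integer(1), "id"))]
  out <- purrr::list_rbind(purrr::imap(kept, function(a, k) {
    dplyr::mutate(purrr::list_rbind(a$rows), track_id = k, class = a$class,
                  .before = 1)
  }))
  new_track_set(dplyr::arrange(out, .data$track_id, .data$frame),
                max_link_distance, min_length, frame_interval)
}

new_track_set <- function(tbl, max_link_distance, min_length, frame_interval) {
  structure(as_tibble(tbl), max_link_distance = max_link_distance,
            min_length = min_length, frame_interval = frame_interval,
            class = c("track_set", class(tibble())))
}

#' Solve a frame-to-frame linking assignment
#'
#' Augments the squared-distance cost block with birth/death alternatives at
#' cost `b` (Jaqaman-style square LAP) and solves it with the Hungarian
#' algorithm. Returns, for each source, the index of its linked target or
#' NA.
#' @noRd
lap_link <- function(d2, b) {
  BIG <- 1e9
  n1 <- nrow(d2); n2 <- ncol(d2)
  cost <- d2
  cost[cost > b] <- BIG
  m <- matrix(BIG, n1 + n2, n2 + n1)
  m[seq_len(n1), seq_len(n2)] <- cost
  m[cbind(seq_len(n1), n2 + seq_len(n1))] <- b           # deaths
  m[cbind(n1 + seq_len(n2), seq_len(n2))] <- b           # births
  m[n1 + seq_len(n2), n2 + seq_len(n1)] <- t(ifelse(cost < BIG, 0, BIG))
  sol <- clue::solve_LSAP(m)
  out <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- sol[i]
    if (j <= n2 && cost[i, j] < BIG) out[i] <- j
  }
  out
}

#' Per-track motion statistics
#'
#' For every track: step displacements between consecutive detections, mean
#' speed (mean step length, px per frame interval), total path length and
#' the Euclidean start-to-end distance. Euclidean distance never exceeds
#' path length.
#'
#' @param tracks A `track_set` tibble (or data frame with `track_id`,
#'   `frame`, `x`, `y` and optionally `class`).
#' @param frame_interval Minutes between frames; `speed_px_per_min` is
#'   derived from it.
#' @return Tibble (`track_id`, `class`, `n_frames`, `mean_speed`,
#'   `speed_px_per_min`, `euclidean_distance`, `path_length`) of class
#'   `track_metrics`; speeds in px per frame interval.
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 1:3, x = c(0, 0, 0),
#'                      y = c(0, 3, 6))
#' track_metrics(tr)
#' @export
track_metrics <- function(tracks, frame_interval = NULL) {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 20
  if (!"class" %in% names(tracks)) tracks$class <- "cell"
  if (nrow(tracks) == 0) {
    return(structure(tibble(track_id = integer(), class = character(),
                            n_frames = integer(), mean_speed = numeric(),
                            speed_px_per_min = numeric(),
                            euclidean_distance = numeric(),
                            path_length = numeric()),
                     frame_interval = frame_interval,
                     class = c("track_metrics", class(tibble()))))
  }
  short <- dplyr::count(tracks, .data$track_id) |> dplyr::filter(.data$n < 2)
  if (nrow(short) > 0) {
    abort(paste0("Track(s) with < 2 detections: ",
                 toString(short$track_id), "."), class = "polarscope_short_track")
  }
  out <- tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id, .data$class) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      mean_speed = mean(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      euclidean_distance = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                                (dplyr::last(.data$y) - dplyr::first(.data$y))^2),
      path_length = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      .groups = "drop") |>
    dplyr::mutate(speed_px_per_min = .data$mean_speed / frame_interval,
                  .after = "mean_speed")
  structure(out, frame_interval = frame_interval,
            class = c("track_metrics", class(tibble())))
}

#' Per-field motility summary
#'
#' Arithmetic means of per-track mean speed and Euclidean distance within
#' each imaging field — the per-field quantities motility scatter plots
#' report. Fields with no retained tracks are reported with missing means
#' rather than zeros.
#'
#' @param metrics A `track_metrics` tibble (or a `track_set`, which is
#'   summarized first).
#' @param fields Optional tibble (`track_id`, `field_id`) assigning each
#'   track to a field; by default all tracks form one field `"field_1"`.
#' @param include_clusters Include cluster tracks in the means
#'   (default FALSE: cells only).
#' @return Tibble (`field_id`, `n_tracks`, `mean_speed`,
#'   `mean_euclidean_distance`).
#' @export
field_summary <- function(metrics, fields = NULL, include_clusters = FALSE) {
  if (inherits(metrics, "track_set")) metrics <- track_metrics(metrics)
  if (is.null(fields)) {
    fields <- tibble(track_id = metrics$track_id, field_id = "field_1")
  }
  if (!include_clusters) metrics <- dplyr::filter(metrics, .data$class != "cluster")
  joined <- dplyr::left_join(fields, metrics, by = "track_id")
  joined |>
    dplyr::group_by(.data$field_id) |>
    dplyr::summarise(
      n_tracks = sum(!is.na(.data$mean_speed)),
      mean_speed = ifelse(.data$n_tracks > 0,
                          mean(.data$mean_speed, na.rm = TRUE), NA_real_),
      mean_euclidean_distance = ifelse(.data$n_tracks > 0,
                                       mean(.data$euclidean_distance, na.rm = TRUE),
                                       NA_real_),
      .groups = "drop")
}

#' Evaluate recovered tracks against simulated ground truth
#'
#' Matches recovered detections to planted cell positions frame by frame
#' (greedy nearest-pair matching within `match_radius`, one-to-one) and
#' summarizes: link-level track purity (fraction of frame-to-frame links
#' whose both endpoints are attributed to the track's majority true cell),
#' detection recall (fraction of planted detections recovered), and speed
#' bias (relative error of the mean recovered speed against the planted
#' mean speed).
#'
#' @param tracks A `track_set` tibble.
#' @param truth The `truth` component of [simulate_motility_video()]
#'   output (or the whole `motility_sim`).
#' @param match_radius Matching radius in px (default: planted cell
#'   radius).
#' @return List of class `track_evaluation` with `purity`, `recall`,
#'   `speed_bias`, `recovered_speed`, `planted_speed`, `n_tracks`;
#'   `glance()` returns them as a one-row tibble.
#' @export
evaluate_against_truth <- function(tracks, truth, match_radius = NULL) {
  if (inherits(truth, "motility_sim")) truth <- truth$truth
  if (is.null(truth$tracks)) {
    abort("`truth` must contain planted tracks.", class = "polarscope_no_truth")
  }
  match_radius <- match_radius %||% truth$cell_radius
  det <- dplyr::mutate(as_tibble(tracks), .row = dplyr::row_number(),
                       true_cell = NA_integer_)
  truth_tr <- truth$tracks
  matched_truth <- 0L
  for (f in unique(det$frame)) {
    d <- det[det$frame == f, ]
    tt <- truth_tr[truth_tr$frame == f, ]
    if (nrow(d) == 0 || nrow(tt) == 0) next
    dist <- sqrt(outer(d$x, tt$x, "-")^2 + outer(d$y, tt$y, "-")^2)
    pairs <- which(dist <= match_radius, arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    ord <- order(dist[pairs])
    used_d <- logical(nrow(d)); used_t <- logical(nrow(tt))
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE
        det$true_cell[d$.row[i]] <- tt$cell_id[j]
        matched_truth <- matched_truth + 1L
      }
    }
  }
  # link-level purity: both link endpoints attributed to the majority cell
  purity_tbl <- det |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_links = dplyr::n() - 1,
      majority_links = {
        a <- .data$true_cell[-dplyr::n()]
        b <- .data$true_cell[-1]
        same <- !is.na(a) & !is.na(b) & a == b
        if (any(same)) max(table(a[same])) else 0L
      },
      .groups = "drop")
  total_links <- sum(purity_tbl$n_links)
  purity <- if (total_links > 0) sum(purity_tbl$majority_links) / total_links else NA_real_
  recall <- matched_truth / nrow(truth_tr)
  metrics <- track_metrics(tracks)
  recovered_speed <- mean(metrics$mean_speed)
  planted_speed <- mean(truth$speeds$speed)
  structure(list(purity = purity, recall = recall,
                 speed_bias = (recovered_speed - planted_speed) / planted_speed,
                 recovered_speed = recovered_speed,
                 planted_speed = planted_speed,
                 n_tracks = dplyr::n_distinct(tracks$track_id)),
            class = "track_evaluation")
}

#' @export
glance.track_evaluation <- function(x, ...) {
  tibble(purity = x$purity, recall = x$recall, speed_bias = x$speed_bias,
         recovered_speed = x$recovered_speed, planted_speed = x$planted_speed,
         n_tracks = x$n_tracks)
}

#' @export
print.track_evaluation <- function(x, ...) {
  cat(sprintf(
    "<track_evaluation> purity %.3f, recall %.3f, speed bias %+.1f%% (%d tracks)\n",
    x$purity, x$recall, 100 * x$speed_bias, x$n_tracks))
  invisible(x)
}

#' Plot recovered trajectories
#'
#' @param object A `track_set` tibble.
#' @param ... Unused.
#' @return A ggplot of trajectories coloured by track.
#' @export
autoplot.track_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$x, .data$y, group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Recovered cell trajectories") +
    ggplot2::theme_minimal()
}
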