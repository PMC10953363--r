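#' Read and write abundance tables with a sample design sidecar
#'
#' The on-disk schema is a delimited table (tab for `.tsv`/`.txt`, comma for
#' `.csv`) whose first column is `protein_id` followed by one numeric column
#' per sample, plus a design table mapping every sample column to
#' `sample_id`, `subtype`, `donor`, `is_control`. Reading validates the
#' pair: duplicate protein ids, non-numeric cells and unmapped samples are
#' rejected with the offending names.
#'
#' @param path Path to the abundance table.
#' @param design_path Path to the design table.
#' @return `read_abundance()` returns `list(abundance, design)` of tibbles.
#' @export
read_abundance <- function(path, design_path) {
  abundance <- read_delim_auto(path)
  design <- read_delim_auto(design_path)
  if (ncol(abundance) < 2 || names(abundance)[1] != "protein_id") {
    abort(sprintf("Malformed abundance header in '%s': first column must be `protein_id`.",
                  path), class = "polarscope_bad_file")
  }
  for (s in setdiff(names(abundance), "protein_id")) {
    if (!is.numeric(abundance[[s]])) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(abundance[[s]]))))
      abort(sprintf("Non-numeric value(s) in sample column '%s' (row %s).",
                    s, toString(utils::head(bad_rows, 3))),
            class = "polarscope_bad_file")
    }
  }
  if ("is_control" %in% names(design)) {
    design$is_control <- as.logical(design$is_control)
  }
  check_abundance(abundance, design)
  list(abundance = abundance, design = design)
}

#' @rdname read_abundance
#' @param abundance,design Tibbles as returned by [simulate_proteome()].
#' @export
write_abundance <- function(abundance, design, path, design_path) {
  readr::write_tsv(abundance, path)
  readr::write_tsv(design, design_path)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "polarscope_bad_file")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read a surface-protein atlas
#'
#' Plain-text identifier whitelist (one identifier per line; blank lines and
#' `#` comments ignored), e.g. a Cell Surface Protein Atlas-style gene or
#' accession list.
#'
#' @param path Path to the list.
#' @param source_label Free-text provenance label (default: the file name).
#' @return List of class `surface_atlas` with `identifiers` and
#'   `source_label`.
#' @export
read_atlas <- function(path, source_label = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(ids) == 0) {
    abort(sprintf("Atlas '%s' contains no identifiers.", path),
          class = "polarscope_bad_file")
  }
  structure(list(identifiers = unique(ids), source_label = source_label),
            class = "surface_atlas")
}

#' @export
print.surface_atlas <- function(x, ...) {
  cat(sprintf("<surface_atlas> %d identifiers (%s)\n",
              length(x$identifiers), x$source_label))
  invisible(x)
}

#' Read and write multi-frame grayscale TIFF stacks
#'
#' Intensity stacks are stored as multi-frame grayscale TIFF with values in
#' \[0, 1\]; label maps as 16-bit grayscale whose integer labels round-trip
#' losslessly. RGB input and mixed frame shapes are rejected.
#'
#' @param path TIFF path.
#' @return `read_stack()` returns an `H x W x T` numeric array.
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) > 2, logical(1)))) {
    abort("RGB/multi-channel TIFF: convert to single-channel grayscale first.",
          class = "polarscope_rgb_input")
  }
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) {
    abort(paste0("Frames have mixed shapes: ", toString(unique(shapes)), "."),
          class = "polarscope_bad_file")
  }
  array(unlist(frames), c(dim(frames[[1]]), length(frames)))
}

#' @rdname read_stack
#' @param stack `H x W x T` array or list of matrices with values in
#'   \[0, 1\].
#' @param bits Bits per sample (8 or 16; default 16).
#' @export
write_stack <- function(stack, path, bits = 16) {
  frames <- as_frame_list(stack)
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname read_stack
#' @param labels List of integer label matrices (or a
#'   `segmentation_result`). Labels must be < 65536.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "segmentation_result")) labels <- labels$labels
  labels <- as_frame_list(labels)
  if (max(unlist(lapply(labels, max)), 0) > 65535) {
    abort("Label values exceed the 16-bit range.", class = "polarscope_bad_argument")
  }
  tiff::writeTIFF(lapply(labels, function(l) l / 65535), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_stack
#' @export
read_labels <- function(path) {
  stack <- read_stack(path)
  lapply(seq_len(dim(stack)[3]), function(t) {
    matrix(as.integer(round(stack[, , t] * 65535)), dim(stack)[1], dim(stack)[2])
  })
}

#' Read and write object and track tables
#'
#' CSV round-trip for the segmentation object table and the linked track
#' table; column headers carry units (`area_px2`, `x_px`, `y_px`).
#'
#' @param objects Object tibble (`frame`, `label`, `area_px2`, `x`, `y`,
#'   `class`).
#' @param path CSV path.
#' @export
write_objects <- function(objects, path) {
  readr::write_csv(dplyr::rename(objects, x_px = "x", y_px = "y"), path)
  invisible(path)
}

#' @rdname write_objects
#' @export
read_objects <- function(path) {
  dplyr::rename(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
                x = "x_px", y = "y_px")
}

#' @rdname write_objects
#' @param tracks A `track_set` tibble.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(dplyr::rename(as_tibble(tracks), x_px = "x", y_px = "y"), path)
  invisible(path)
}

#' @rdname write_objects
#' @param frame_interval Minutes per frame restored onto the track set
#'   (default 20).
#' @export
read_tracks <- function(path, frame_interval = 20) {
  tbl <- dplyr::rename(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
                       x = "x_px", y = "y_px")
  new_track_set(tbl, max_link_distance = NA_real_, min_length = NA_integer_,
                frame_interval = frame_interval)
}

# -- run configuration ------------------------------------------------------

config_fields <- c("up_threshold", "down_threshold", "boundary_inclusive",
                   "variance_sigma", "dog_sigma", "dog_sigma_low",
                   "minima_depth_h", "connectivity", "min_area",
                   "cluster_area", "max_link_distance", "min_length",
                   "frame_interval", "seed", "out_dir")

#' Run configuration round-trip
#'
#' A run configuration is a flat `key: value` text file covering the
#' thresholds, segmentation and tracking parameters, seed and output
#' directory of a run. Unknown keys are an error (fail-fast); the resolved
#' configuration is written next to every run's outputs so results are
#' reproducible.
#'
#' @param path Config path.
#' @return `read_run_config()` returns a named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(parts, `[[`, character(1), 1))
  unknown <- setdiff(keys, config_fields)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", toString(unknown), "."),
          class = "polarscope_bad_config")
  }
  vals <- lapply(parts, function(p) {
    raw <- trimws(paste(p[-1], collapse = ":"))
    if (raw %in% c("TRUE", "FALSE")) as.logical(raw)
    else if (grepl("^-?[0-9.]+([eE]-?[0-9]+)?$", raw)) as.numeric(raw)
    else raw
  })
  stats::setNames(vals, keys)
}

#' @rdname read_run_config
#' @param config Named list of configuration values (subset of the known
#'   keys).
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), config_fields)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", toString(unknown), "."),
          class = "polarscope_bad_config")
  }
  writeLines(vapply(names(config), function(k) {
    sprintf("%s: %s", k, format(config[[k]], scientific = FALSE))
  }, character(1)), path)
  invisible(path)
}
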