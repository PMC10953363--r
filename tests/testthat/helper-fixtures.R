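# Shared fixtures built in code.

# A small abundance table + design with hand-controllable values.
tiny_abundance <- function() {
  list(
    abundance = tibble::tibble(
      protein_id = c("p1", "p2"),
      c1 = c(1, 3),
      s1 = c(2, 6)),
    design = tibble::tibble(
      sample_id = c("c1", "s1"),
      subtype = c("M0", "M1"),
      donor = c("d1", "d1"),
      is_control = c(TRUE, FALSE))
  )
}

# Literal per-cell recomputation of the processing chain, written
# independently of the package implementation (explicit loops, no reuse).
brute_force_chain <- function(values, design) {
  # values: matrix proteins x samples with dimnames
  totals <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) totals[j] <- sum(values[, j])
  target <- mean(totals)
  norm <- values
  for (j in seq_len(ncol(values))) {
    for (i in seq_len(nrow(values))) norm[i, j] <- values[i, j] * target / totals[j]
  }
  ctrl <- design$sample_id[design$is_control]
  test <- design$sample_id[!design$is_control]
  fc <- matrix(NA_real_, nrow(values), length(test),
               dimnames = list(rownames(values), test))
  for (i in seq_len(nrow(values))) {
    cm <- 0
    for (s in ctrl) cm <- cm + norm[i, s]
    cm <- cm / length(ctrl)
    for (s in test) fc[i, s] <- log2(norm[i, s] / cm)
  }
  for (s in test) fc[, s] <- fc[, s] - stats::median(fc[, s])
  subtypes <- unique(design$subtype[!design$is_control])
  means <- matrix(NA_real_, nrow(values), length(subtypes),
                  dimnames = list(rownames(values), subtypes))
  for (st in subtypes) {
    cols <- design$sample_id[design$subtype == st & !design$is_control]
    for (i in seq_len(nrow(values))) {
      acc <- 0
      for (s in cols) acc <- acc + fc[i, s]
      means[i, st] <- acc / length(cols)
    }
  }
  list(norm = norm, fc = fc, means = means)
}

# Draw a sharp-edged speckled disk into a frame matrix (row = y, col = x,
# 0-based centre coordinates).
draw_disk <- function(frame, cx, cy, r, level = 0.8, texture_sd = 0.15) {
  for (row in seq_len(nrow(frame))) {
    for (col in seq_len(ncol(frame))) {
      if (((col - 1) - cx)^2 + ((row - 1) - cy)^2 <= r^2) {
        frame[row, col] <- level + stats::rnorm(1, 0, texture_sd)
      }
    }
  }
  frame
}

# A filled rectangle label patch of exact area, for boundary-size tests.
label_rectangle <- function(h, w, r0, c0, height, width, id = 1L) {
  m <- matrix(0L, h, w)
  m[r0:(r0 + height - 1), c0:(c0 + width - 1)] <- id
  m
}

# Brute-force minimum-cost frame-to-frame linking by enumeration:
# every subset matching between n1 sources and n2 targets, link cost d2
# (forbidden above b), unmatched objects cost b each.
brute_force_link_cost <- function(d2, b) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  best <- Inf
  # enumerate assignments of each source to a target or 0 (unmatched)
  choices <- rep(list(0:n2), n1)
  grid <- do.call(expand.grid, choices)
  for (k in seq_len(nrow(grid))) {
    a <- as.integer(grid[k, ])
    tgt <- a[a > 0]
    if (anyDuplicated(tgt)) next
    cost <- 0
    ok <- TRUE
    for (i in seq_len(n1)) {
      if (a[i] == 0) cost <- cost + b
      else if (d2[i, a[i]] > b) { ok <- FALSE; break }
      else cost <- cost + d2[i, a[i]]
    }
    if (!ok) next
    cost <- cost + b * (n2 - length(tgt))
    best <- min(best, cost)
  }
  best
}
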