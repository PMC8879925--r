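#' Cut a track into consecutive fixed-length segments
#'
#' Non-overlapping consecutive windows of `window_s` seconds; the trailing
#' partial window is dropped when `drop_partial` (the default), so
#' `segments x window = covered duration`.
#'
#' @param track a track data frame (`time_s`, `x_cm`, `y_cm`).
#' @param window_s window length, s, > 0 (default 30).
#' @param drop_partial drop a trailing window shorter than `window_s`?
#' @return a list of `track_segment` data frames, each with attributes
#'   `start_s`, `end_s`, `window_idx` (plus `fish_id`/`day`/`dose` copied
#'   from the parent track when present).
#' @export
segment_track <- function(track, window_s = 30, drop_partial = TRUE) {
  if (window_s <= 0) stop_invalid("invalid-argument: window_s must be > 0")
  t0 <- track$time_s[1]
  rel <- track$time_s - t0
  total <- rel[length(rel)] + if (length(rel) > 1) stats::median(diff(rel)) else 0
  n_full <- floor(total / window_s + 1e-9)
  n_win <- if (drop_partial) n_full else ceiling(total / window_s - 1e-9)
  if (n_win < 1) return(list())
  lapply(seq_len(n_win), function(k) {
    lo <- (k - 1) * window_s
    hi <- k * window_s
    idx <- which(rel >= lo & rel < hi)
    seg <- track[idx, , drop = FALSE]
    rownames(seg) <- NULL
    for (at in c("fish_id", "day", "dose")) {
      attr(seg, at) <- attr(track, at)
    }
    attr(seg, "start_s") <- t0 + lo
    attr(seg, "end_s") <- t0 + min(hi, total)
    attr(seg, "window_idx") <- k
    class(seg) <- c("track_segment", "data.frame")
    seg
  })
}

#' Rasterize a track segment to a fixed-size grayscale image
#'
#' Positions are affinely mapped from the fixed maze bounding box to a
#' `size x size` pixel grid (aspect preserved, padded), consecutive
#' samples are joined by integer line interpolation (Bresenham-style DDA,
#' no anti-aliasing), and pixel intensity grades linearly with time within
#' the window from 0.2 (oldest) to 1.0 (newest); a revisited pixel keeps
#' the highest (most recent) intensity. The mapping depends only on the
#' maze geometry, so two identical paths give identical images wherever
#' the segment sits in time.
#'
#' @param seg a `track_segment` (>= 1 sample).
#' @param geometry a [maze_geometry()] fixing the bounding box.
#' @param size image side in pixels (default 64).
#' @param binary if `TRUE`, plain occupancy (all drawn pixels = 1) instead
#'   of time-graded intensity.
#' @return a `size x size` numeric matrix in `[0, 1]` (class
#'   `track_image`) with provenance attributes.
#' @export
rasterize_segment <- function(seg, geometry, size = 64, binary = FALSE) {
  if (nrow(seg) < 1) stop_invalid("invalid-argument: empty segment")
  bb <- maze_bbox(geometry)
  scale <- (size - 1) / max(bb$w, bb$h)
  # center the maze in the square canvas
  offx <- (size - 1 - bb$w * scale) / 2
  offy <- (size - 1 - bb$h * scale) / 2
  px <- round((seg$x_cm - bb$xmin) * scale + offx) + 1L
  py <- round((seg$y_cm - bb$ymin) * scale + offy) + 1L
  px <- pmin(pmax(px, 1L), size); py <- pmin(pmax(py, 1L), size)
  n <- length(px)
  inten <- if (n > 1) seq(0.2, 1.0, length.out = n) else 1.0

  img <- matrix(0, size, size)
  if (n == 1) {
    img[py, px] <- 1.0
  } else {
    # vectorized DDA over all consecutive pairs
    dx <- diff(px); dy <- diff(py)
    steps <- pmax(abs(dx), abs(dy), 1L)
    total <- sum(steps + 1L)
    seg_id <- rep.int(seq_len(n - 1L), steps + 1L)
    tt <- sequence(steps + 1L) - 1L
    frac <- tt / steps[seg_id]
    qx <- as.integer(round(px[seg_id] + frac * dx[seg_id]))
    qy <- as.integer(round(py[seg_id] + frac * dy[seg_id]))
    val <- inten[seg_id] + frac * (inten[seg_id + 1L] - inten[seg_id])
    # write in increasing intensity order so the newest visit wins
    o <- order(val)
    img[cbind(qy[o], qx[o])] <- val[o]
  }
  if (binary) img[img > 0] <- 1.0
  structure(img, class = c("track_image", "matrix"),
            fish_id = attr(seg, "fish_id"), day = attr(seg, "day"),
            dose = attr(seg, "dose"), window_idx = attr(seg, "window_idx"))
}

maze_bbox <- function(geometry) {
  pts <- do.call(rbind, c(list(geometry$junction), geometry$arms))
  xmin <- min(pts[, 1]); xmax <- max(pts[, 1])
  ymin <- min(pts[, 2]); ymax <- max(pts[, 2])
  list(xmin = xmin, ymin = ymin, w = xmax - xmin, h = ymax - ymin)
}

#' Rasterize every 30-s segment of a cohort into a labeled image set
#'
#' The class label of an image is `"<day>-<dose>"` — one label per
#' day-by-dose combination.
#'
#' @param study a `study_dataset` (or flat track table with
#'   `fish_id`/`day`/`dose` columns).
#' @param geometry a [maze_geometry()].
#' @param window_s segment window, s (default 30).
#' @param size image side, pixels (default 64).
#' @param binary occupancy-only images?
#' @param drop_partial see [segment_track()].
#' @return an object of class `image_set`: `$images` a
#'   `size x size x N` array, `$meta` a data frame
#'   (`class`, `day`, `dose`, `fish_id`, `window_idx`).
#' @export
rasterize_cohort <- function(study, geometry = NULL, window_s = 30,
                             size = 64, binary = FALSE, drop_partial = TRUE) {
  if (is.null(geometry)) {
    geometry <- if (inherits(study, "study_dataset")) study$geometry
                else maze_geometry()
  }
  tab <- if (inherits(study, "study_dataset")) study$tracks
         else data.table::as.data.table(study)
  keys <- paste(tab$fish_id, tab$day, sep = "|")
  imgs <- list(); meta <- list()
  for (idx in split(seq_len(nrow(tab)), keys)) {
    sub <- tab[idx]
    tr <- data.frame(time_s = sub$time_s, x_cm = sub$x_cm, y_cm = sub$y_cm)
    attr(tr, "fish_id") <- sub$fish_id[1]
    attr(tr, "day") <- sub$day[1]
    attr(tr, "dose") <- sub$dose[1]
    for (seg in segment_track(tr, window_s, drop_partial)) {
      if (nrow(seg) < 2) next
      im <- rasterize_segment(seg, geometry, size, binary)
      imgs[[length(imgs) + 1L]] <- im
      meta[[length(meta) + 1L]] <- data.frame(
        class = paste(attr(seg, "day"), attr(seg, "dose"), sep = "-"),
        day = attr(seg, "day"), dose = attr(seg, "dose"),
        fish_id = attr(seg, "fish_id"),
        window_idx = attr(seg, "window_idx"))
    }
  }
  if (!length(imgs)) stop_invalid("invalid-argument: no rasterizable segments")
  arr <- array(unlist(imgs), dim = c(size, size, length(imgs)))
  structure(list(images = arr, meta = do.call(rbind, meta)),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("image_set: %d images %dx%d, %d classes\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              length(unique(x$meta$class))))
  invisible(x)
}

# Subset an image set by row indices of $meta.
subset_image_set <- function(iset, idx) {
  structure(list(images = iset$images[, , idx, drop = FALSE],
                 meta = iset$meta[idx, , drop = FALSE]),
            class = "image_set")
}

#' Persist an image set as plain-text PGM files plus an index CSV
#'
#' Each image is written as an ASCII PGM (P2) file — a portable grayscale
#' format readable by standard imaging tools — and the index CSV
#' (`image_path,fish_id,day,dose,window_idx`) records provenance.
#'
#' @param iset an `image_set`.
#' @param dir output directory (created if needed).
#' @param levels gray levels for quantization (default 255).
#' @return the index CSV path, invisibly.
#' @export
write_image_set <- function(iset, dir, levels = 255) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(iset$images)[3]
  paths <- character(n)
  for (i in seq_len(n)) {
    m <- iset$images[, , i]
    fname <- sprintf("img_%05d.pgm", i)
    paths[i] <- file.path(dir, fname)
    q <- round(m * levels)
    # PGM raster is row-major top-to-bottom; our matrix rows are y (up)
    lines <- apply(q[rev(seq_len(nrow(q))), , drop = FALSE], 1, paste,
                   collapse = " ")
    writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)),
                 as.character(levels), lines), paths[i])
  }
  idx <- data.frame(image_path = basename(paths), iset$meta)
  idx_path <- file.path(dir, "index.csv")
  utils::write.csv(idx, idx_path, row.names = FALSE)
  invisible(idx_path)
}
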