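# ROI definitions, trace extraction from image stacks, and trace-table I/O.
# Traces are tidy tibbles: one row per (roi, channel, frame) with the mean
# intensity inside the ROI rectangle at that frame. Coordinates are 0-based
# with half-open rectangles [x0, x0 + width) x [y0, y0 + height), so a
# 100x100 ROI at the origin covers pixel columns 0..99 and rows 0..99.

#' Define a set of rectangular ROIs
#'
#' @param label Character vector of unique ROI labels.
#' @param x0,y0 0-based pixel offsets of the top-left corner (column, row).
#' @param width,height Pixel extents (>= 1). Default 100x100, the
#'   conventional explant ROI size.
#' @param color Display color per ROI (recycled).
#' @return Tibble with columns `label`, `color`, `x0`, `y0`, `width`,
#'   `height`.
#' @export
roi_spec <- function(label, x0, y0, width = 100L, height = 100L,
                     color = "grey30") {
  if (anyDuplicated(label)) abort("ROI labels must be unique.")
  spec <- tibble(
    label = as.character(label),
    color = rep_len(as.character(color), length(label)),
    x0 = as.integer(x0), y0 = as.integer(y0),
    width = rep_len(as.integer(width), length(label)),
    height = rep_len(as.integer(height), length(label))
  )
  if (any(spec$x0 < 0L | spec$y0 < 0L)) abort("ROI offsets must be >= 0.")
  if (any(spec$width < 1L | spec$height < 1L)) abort("ROI extents must be >= 1.")
  spec
}

#' Read ROI definitions from a JSON config
#'
#' Expects a JSON array of objects with fields `label`, `x0`, `y0`,
#' `width`, `height` and optionally `color`.
#'
#' @param path Path to the JSON file.
#' @return ROI tibble as from [roi_spec()].
#' @export
read_rois <- function(path) {
  raw <- jsonlite::fromJSON(path)
  need <- c("label", "x0", "y0", "width", "height")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("ROI config missing fields: ", paste(missing, collapse = ", ")))
  }
  roi_spec(
    label = raw$label, x0 = raw$x0, y0 = raw$y0,
    width = raw$width, height = raw$height,
    color = raw$color %||% "grey30"
  )
}

#' Read a multi-frame grayscale TIFF stack
#'
#' @param path Path to a TIFF file, one grayscale image per frame.
#' @return Numeric 3-D array `[frames, rows, cols]`.
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 0L) abort("TIFF stack contains no frames.")
  dims <- dim(frames[[1]])
  if (length(dims) > 2L) abort("Expected grayscale frames (one channel per file).")
  stack <- array(0, dim = c(length(frames), dims[1], dims[2]))
  for (i in seq_along(frames)) stack[i, , ] <- as.numeric(frames[[i]])
  stack
}

#' Extract per-ROI mean-intensity traces from an image stack
#'
#' The trace value at frame `t` is the arithmetic mean of all pixel
#' intensities inside the ROI rectangle at frame `t`. ROIs are static;
#' pixel values of any numeric type are converted to double.
#'
#' @param stack Numeric 3-D array `[frames, rows, cols]` (see
#'   [read_stack()]).
#' @param rois ROI tibble from [roi_spec()]/[read_rois()].
#' @param channel Channel name recorded on every trace (e.g. `"calcium"`).
#' @param frame_interval Seconds per frame, kept as metadata (attribute
#'   `frame_interval`); the conventional acquisition is one frame per
#'   minute.
#' @return Tidy tibble with columns `roi`, `channel`, `frame` (1-based),
#'   `intensity`; traces appear in ROI order.
#' @export
extract_traces <- function(stack, rois, channel = "calcium",
                           frame_interval = 60) {
  if (length(dim(stack)) != 3L) {
    abort("`stack` must be a 3-D array [frames, rows, cols].")
  }
  n_frames <- dim(stack)[1]
  n_rows <- dim(stack)[2]
  n_cols <- dim(stack)[3]
  if (n_frames < 1L) abort("`stack` has no frames.")
  if (anyDuplicated(rois$label)) abort("ROI labels must be unique.")

  traces <- purrr::pmap(rois, function(label, x0, y0, width, height, ...) {
    if (x0 + width > n_cols || y0 + height > n_rows) {
      abort(sprintf(
        "ROI '%s' (x0=%d, y0=%d, %dx%d) exceeds the %dx%d image plane.",
        label, x0, y0, width, height, n_cols, n_rows
      ))
    }
    # 0-based half-open rectangle -> 1-based inclusive array indices
    rows <- (y0 + 1L):(y0 + height)
    cols <- (x0 + 1L):(x0 + width)
    vals <- vapply(
      seq_len(n_frames),
      function(t) mean(stack[t, rows, cols, drop = FALSE]),
      numeric(1)
    )
    tibble(
      roi = label, channel = channel,
      frame = seq_len(n_frames), intensity = vals
    )
  })
  out <- dplyr::bind_rows(traces)
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Read a trace table from CSV
#'
#' Expects a header row; first column the frame index, remaining columns
#' one trace each, named `label` or `label@channel`. Bare labels get the
#' channel given by `default_channel`.
#'
#' @param path CSV path.
#' @param default_channel Channel assigned to columns without an
#'   `@channel` suffix.
#' @return Tidy trace tibble (`roi`, `channel`, `frame`, `intensity`).
#' @export
read_trace_table <- function(path, default_channel = "calcium") {
  wide <- readr::read_csv(
    path,
    show_col_types = FALSE, progress = FALSE, name_repair = "minimal"
  )
  if (ncol(wide) < 2L) abort("Trace table needs a frame column plus >= 1 trace column.")
  trace_cols <- names(wide)[-1]
  if (anyDuplicated(trace_cols)) {
    abort(paste0(
      "Duplicate trace columns: ",
      paste(unique(trace_cols[duplicated(trace_cols)]), collapse = ", ")
    ))
  }
  for (j in seq_along(trace_cols)) {
    col <- wide[[j + 1L]]
    if (!is.numeric(col)) {
      row <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      abort(sprintf(
        "Non-numeric value in column '%s', row %d.", trace_cols[j],
        if (is.na(row)) 1L else row
      ))
    }
  }
  wide |>
    dplyr::rename(frame = 1) |>
    tidyr::pivot_longer(-"frame", names_to = "key", values_to = "intensity") |>
    tidyr::separate_wider_delim(
      "key", delim = "@", names = c("roi", "channel"),
      too_few = "align_start"
    ) |>
    dplyr::mutate(channel = dplyr::coalesce(.data$channel, default_channel)) |>
    dplyr::select("roi", "channel", "frame", "intensity") |>
    dplyr::arrange(match(.data$roi, sub("@.*$", "", trace_cols)), .data$frame)
}

#' Write a trace table to CSV
#'
#' Inverse of [read_trace_table()]: one `label@channel` column per trace,
#' first column the frame index. Also accepts binary tables (column
#' `state` instead of `intensity`).
#'
#' @param traces Tidy trace tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  value_col <- if ("intensity" %in% names(traces)) "intensity" else "state"
  wide <- traces |>
    dplyr::mutate(key = paste0(.data$roi, "@", .data$channel)) |>
    dplyr::select("frame", "key", dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "key", values_from = dplyr::all_of(value_col)) |>
    dplyr::arrange(.data$frame)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Render binary traces into a synthetic TIFF stack
#'
#' Writes each trace as a constant-intensity rectangular block per frame,
#' producing a grayscale stack that exercises the imaging path end-to-end
#' (extraction over the written stack recovers the traces exactly).
#'
#' @param traces Tidy table with `roi`, `frame` and `intensity` or `state`.
#' @param path Output TIFF path.
#' @param block Side length in pixels of each ROI block.
#' @return Tibble of the ROI rectangles written, invisibly.
#' @export
write_synthetic_stack <- function(traces, path, block = 10L) {
  value_col <- if ("intensity" %in% names(traces)) "intensity" else "state"
  labels <- unique(traces$roi)
  n_frames <- max(traces$frame)
  ncol_img <- block * length(labels)
  vals <- traces |>
    dplyr::mutate(v = .data[[value_col]] / max(1, max(abs(.data[[value_col]]))))
  imgs <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    img <- matrix(0, nrow = block, ncol = ncol_img)
    for (j in seq_along(labels)) {
      v <- vals$v[vals$roi == labels[j] & vals$frame == t][1]
      img[, ((j - 1L) * block + 1L):(j * block)] <- v
    }
    imgs[[t]] <- img
  }
  tiff::writeTIFF(imgs, path)
  invisible(roi_spec(
    label = labels, x0 = (seq_along(labels) - 1L) * block, y0 = 0L,
    width = block, height = block
  ))
}
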