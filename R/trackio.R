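#' Describe the column layout of a tracked-trajectory table
#'
#' Manual-tracking plugins export delimited tables whose column names, units
#' and frame numbering vary between versions and configurations. A dialect
#' pins these down; all variation is handled at the I/O boundary, and the
#' in-memory convention is always microns with 0-based frames.
#'
#' @param delimiter Field separator (default comma).
#' @param id_col,frame_col,x_col,y_col Column names for track id, frame
#'   index, x and y. Must be distinct.
#' @param coordinate_unit `"micron"` or `"pixel"`. Pixel coordinates are
#'   multiplied by the acquisition pixel size on read (and divided on write).
#' @param frame_base First frame index in the file, 0 or 1.
#' @return An object of class `track_dialect`.
#' @export
track_dialect <- function(delimiter = ",", id_col = "track",
                          frame_col = "frame", x_col = "x", y_col = "y",
                          coordinate_unit = c("micron", "pixel"),
                          frame_base = 0L) {
  coordinate_unit <- match.arg(coordinate_unit)
  cols <- c(id_col, frame_col, x_col, y_col)
  if (any(!nzchar(cols)) || anyDuplicated(cols)) {
    stop("dialect column names must be non-empty and distinct", call. = FALSE)
  }
  if (!frame_base %in% c(0L, 1L)) stop("`frame_base` must be 0 or 1", call. = FALSE)
  structure(
    list(delimiter = delimiter, id_col = id_col, frame_col = frame_col,
         x_col = x_col, y_col = y_col, coordinate_unit = coordinate_unit,
         frame_base = as.integer(frame_base)),
    class = "track_dialect"
  )
}

#' Read tracked trajectories from a delimited text file
#'
#' Parses a plugin-style track table into a list of [trajectory()] objects,
#' one per distinct track id, with frames sorted ascending. Pixel
#' coordinates are converted to microns with `settings$pixel_size`; times
#' are reconstructed as `(frame - first_frame) * frame_interval`. The reader
#' never silently drops rows: malformed coordinates, duplicate
#' `(track, frame)` records, and frame gaps each raise an error naming the
#' offending rows (gaps are tolerated with `allow_gaps = TRUE`, in which
#' case gap-spanning steps are excluded from step-based descriptors).
#'
#' @param path Path to the delimited file.
#' @param dialect A [track_dialect()].
#' @param settings An [acq_settings()] supplying pixel size and frame
#'   interval.
#' @param allow_gaps Tolerate missing frames within a track.
#' @return List of [trajectory()] objects (possibly empty).
#' @export
read_tracks <- function(path, dialect = track_dialect(),
                        settings = acq_settings(), allow_gaps = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  stopifnot(inherits(dialect, "track_dialect"), is_acq_settings(settings))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  need <- c(dialect$id_col, dialect$frame_col, dialect$x_col, dialect$y_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0) return(list())

  num_col <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at data row(s) %s", what,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    v
  }
  id <- raw[[dialect$id_col]]
  frame <- num_col(dialect$frame_col, "frame index")
  x <- num_col(dialect$x_col, "x coordinate")
  y <- num_col(dialect$y_col, "y coordinate")
  if (any(frame != round(frame))) {
    stop("frame indices must be integers", call. = FALSE)
  }
  dup <- duplicated(paste(id, frame, sep = "\r"))
  if (any(dup)) {
    stop(sprintf("duplicate (track, frame) record(s) at data row(s) %s",
                 paste(utils::head(which(dup), 5), collapse = ", ")), call. = FALSE)
  }
  if (dialect$coordinate_unit == "pixel") {
    x <- x * settings$pixel_size
    y <- y * settings$pixel_size
  }

  trajs <- lapply(split(seq_along(id), factor(id, levels = unique(id))), function(ix) {
    ord <- ix[order(frame[ix])]
    fr <- frame[ord]
    gaps <- which(diff(fr) != 1)
    if (length(gaps) && !allow_gaps) {
      stop(sprintf(
        "track '%s' has frame gap(s) after frame %s; use allow_gaps = TRUE to permit",
        id[ord[1]], paste(utils::head(fr[gaps], 5), collapse = ", ")), call. = FALSE)
    }
    trajectory(id[ord[1]], x[ord], y[ord], settings,
               times = (fr - fr[1]) * settings$frame_interval,
               gapped = length(gaps) > 0)
  })
  names(trajs) <- NULL
  trajs
}

#' Write trajectories to a delimited text file
#'
#' Inverse of [read_tracks()]: rows are ordered by track id then frame, and
#' unit conversion mirrors the reader (micron dialects round-trip exactly;
#' pixel dialects to representation precision). Coordinates are printed with
#' 17 significant digits so doubles survive the text round trip.
#'
#' @param trajs List of [trajectory()] objects sharing acquisition settings.
#' @param path Output path.
#' @param dialect A [track_dialect()].
#' @return Invisibly, the path.
#' @export
write_tracks <- function(trajs, path, dialect = track_dialect()) {
  stopifnot(inherits(dialect, "track_dialect"))
  if (length(trajs)) {
    ok <- vapply(trajs, is_trajectory, logical(1))
    if (!all(ok)) stop("`trajs` must be a list of trajectory objects", call. = FALSE)
    px <- vapply(trajs, function(tr) tr$settings$pixel_size, 0)
    dt <- vapply(trajs, function(tr) tr$settings$frame_interval, 0)
    if (length(unique(px)) > 1 || length(unique(dt)) > 1) {
      stop("all trajectories must share acquisition settings", call. = FALSE)
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- paste(c(dialect$id_col, dialect$frame_col, dialect$x_col, dialect$y_col),
                  collapse = dialect$delimiter)
  writeLines(header, con)
  for (tr in trajs) {
    frames <- round(tr$times / tr$settings$frame_interval) + dialect$frame_base
    xs <- tr$x; ys <- tr$y
    if (dialect$coordinate_unit == "pixel") {
      xs <- xs / tr$settings$pixel_size
      ys <- ys / tr$settings$pixel_size
    }
    writeLines(paste(tr$track_id, format(frames, scientific = FALSE, trim = TRUE),
                     sprintf("%.17g", xs), sprintf("%.17g", ys),
                     sep = dialect$delimiter), con)
  }
  invisible(path)
}
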