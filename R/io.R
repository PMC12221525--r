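# File formats: FIMtrack-style track CSV and thermal-frame directories.
#
# Track tables are held internally in mm and seconds; files store pixels
# (px_per_mm, default 4) and frame indices at the nominal frame rate.
# Every writer has a matching reader and round-trips losslessly.

#' Write a track table as FIMtrack-style CSV
#'
#' Columns `frame, id, mom_x, mom_y, head_x, head_y, bending`, one row per
#' larva-frame, coordinates in px. Values are written with full double
#' precision so that [read_fimtrack_csv()] round-trips exactly.
#'
#' @param tracks track data.frame (`id`, `frame`, `t`, `x`, `y`, `head_x`,
#'   `head_y`, `bend_deg`; mm and seconds).
#' @param path output file.
#' @param px_per_mm camera scale, px per mm.
#' @return `path`, invisibly.
#' @export
write_fimtrack_csv <- function(tracks, path, px_per_mm = 4) {
  header <- "frame,id,mom_x,mom_y,head_x,head_y,bending"
  if (nrow(tracks) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  lines <- sprintf("%d,%d,%.17g,%.17g,%.17g,%.17g,%.17g",
                   as.integer(tracks$frame), as.integer(tracks$id),
                   tracks$x * px_per_mm, tracks$y * px_per_mm,
                   tracks$head_x * px_per_mm, tracks$head_y * px_per_mm,
                   tracks$bend_deg)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a FIMtrack-style CSV into a track table
#'
#' @param path input file written by [write_fimtrack_csv()] (or FIMtrack
#'   output reduced to the same columns).
#' @param px_per_mm camera scale, px per mm.
#' @param frame_rate_hz nominal sampling rate used to derive `t`.
#' @return Track data.frame in mm/seconds, rows ordered by (`id`, `frame`).
#' @export
read_fimtrack_csv <- function(path, px_per_mm = 4, frame_rate_hz = 10) {
  ln <- readLines(path)
  if (length(ln) == 0) stop("empty file: ", path)
  expect <- c("frame", "id", "mom_x", "mom_y", "head_x", "head_y", "bending")
  if (!identical(strsplit(ln[1], ",")[[1]], expect))
    stop("unexpected header in ", path)
  if (length(ln) == 1) {
    return(data.frame(id = integer(0), frame = integer(0), t = numeric(0),
                      x = numeric(0), y = numeric(0), head_x = numeric(0),
                      head_y = numeric(0), bend_deg = numeric(0)))
  }
  parts <- strsplit(ln[-1], ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 7))
    stop("malformed row at line ", which(nfield != 7)[1] + 1, " in ", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop("malformed row at line ",
         which(rowSums(is.na(m)) > 0)[1] + 1, " in ", path)
  out <- data.frame(id = as.integer(m[, 2]), frame = as.integer(m[, 1]),
                    t = m[, 1] * (1 / frame_rate_hz),
                    x = m[, 3] / px_per_mm, y = m[, 4] / px_per_mm,
                    head_x = m[, 5] / px_per_mm, head_y = m[, 6] / px_per_mm,
                    bend_deg = m[, 7])
  out[order(out$id, out$frame), , drop = FALSE]
}

#' Write a thermal frame series to a directory
#'
#' One tab-delimited matrix file per frame plus a JSON manifest
#' `manifest.json` of `[{file, t_seconds}, ...]`.
#'
#' @param series a [thermal_frames()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_thermal_frames <- function(series, dir) {
  stopifnot(inherits(series, "thermal_frames"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("frame_%04d.tsv", seq_along(series$frames) - 1L)
  for (i in seq_along(series$frames)) {
    write.table(series$frames[[i]], file.path(dir, files[i]),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(file = files, t_seconds = series$timestamps)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a thermal frame series from a directory
#'
#' @param dir directory written by [write_thermal_frames()].
#' @param arena_mm arena side lengths in mm.
#' @return A [thermal_frames()] object.
#' @export
read_thermal_frames <- function(dir, arena_mm = c(170, 170)) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  frames <- lapply(manifest$file, function(f)
    as.matrix(read.table(file.path(dir, f), sep = "\t")))
  frames <- lapply(frames, unname)
  thermal_frames(frames, manifest$t_seconds, arena_mm = arena_mm)
}
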