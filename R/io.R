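# Plain-text grid and series formats. All files are CSV with `#` comment
# headers; numbers are written in scientific notation with 9 significant
# digits so identical runs produce byte-identical output.

fmt_num <- function(x) {
  out <- formatC(x, format = "e", digits = 8)
  out[is.na(x)] <- "NA"
  out
}

# FNV-1a 32-bit hash of a string, reported as 8 hex digits; used to stamp
# output files with the configuration they came from.
fnv1a_hash <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(enc2utf8(s)) %% 256) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # h * p mod 2^32 in 16-bit pieces to stay within double precision
    hl <- h %% 65536; hh <- (h - hl) / 65536
    h <- (hl * p + ((hh * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

pkg_version <- function() as.character(utils::packageVersion("pivload"))

header_lines <- function(kind, extra = character()) {
  c(sprintf("# pivload %s v1", kind),
    sprintf("# package: pivload %s", pkg_version()),
    extra)
}

#' Write and read velocity frames
#'
#' One CSV per frame with columns `x, y, u, v, valid` covering a complete
#' regular grid (one row per node), units declared in the header, plus a
#' `manifest.csv` (columns `file, t`) giving frame order and timing.
#'
#' @param frame A `velocity_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_velocity_frame <- function(frame, path) {
  stopifnot(inherits(frame, "velocity_frame"))
  g <- frame$grid
  nd <- grid_nodes(g)
  df <- data.frame(x = fmt_num(as.vector(nd$x)), y = fmt_num(as.vector(nd$y)),
                   u = fmt_num(as.vector(frame$u)), v = fmt_num(as.vector(frame$v)),
                   valid = as.integer(as.vector(frame$valid)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines("velocity-grid",
                          c("# units: x [m], y [m], u [m/s], v [m/s]",
                            sprintf("# t: %s", fmt_num(frame$t)))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_grid_table <- function(path, value_cols) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^#", lines, value = TRUE)
  if (!any(grepl("units:.*\\[m\\]", hdr)))
    stop("file ", path, " has no unit declaration in its header")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("x", "y", value_cols)
  if (!all(need %in% names(df)))
    stop("file ", path, " lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  nx <- length(xs); ny <- length(ys)
  if (nrow(df) != nx * ny)
    stop("file ", path, ": node set is not a complete rectangle (",
         nrow(df), " rows, expected ", nx * ny, ")")
  if (nx > 2 && max(abs(diff(diff(xs)))) > 1e-6 * (xs[2] - xs[1]))
    stop("file ", path, ": x spacing is not uniform")
  if (ny > 2 && max(abs(diff(diff(ys)))) > 1e-6 * (ys[2] - ys[1]))
    stop("file ", path, ": y spacing is not uniform")
  g <- grid_spec(xs[1], ys[1], xs[2] - xs[1], ys[2] - ys[1], nx, ny)
  i <- match(df$x, xs); j <- match(df$y, ys)
  tm <- sub("^# t: *", "", grep("^# t:", hdr, value = TRUE))
  t <- if (length(tm)) as.numeric(tm[1]) else 0
  mats <- lapply(value_cols, function(cc) {
    m <- matrix(NA_real_, nx, ny)
    m[cbind(i, j)] <- df[[cc]]
    m
  })
  names(mats) <- value_cols
  c(list(grid = g, t = t, i = i, j = j, df = df), mats)
}

#' @rdname write_velocity_frame
#' @export
read_velocity_frame <- function(path) {
  r <- read_grid_table(path, c("u", "v"))
  valid <- if ("valid" %in% names(r$df)) {
    m <- matrix(TRUE, r$grid$nx, r$grid$ny)
    m[cbind(r$i, r$j)] <- as.logical(r$df$valid)
    m
  } else NULL
  velocity_frame(r$grid, r$u, r$v, t = r$t, valid = valid)
}

#' Write and read velocity sequences
#'
#' @param seq A `velocity_sequence`.
#' @param dir Output directory (created if needed).
#' @param prefix Frame-file prefix.
#' @return The manifest path, invisibly.
#' @export
write_velocity_sequence <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "velocity_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%04d.csv", prefix, seq_along(seq$frames))
  for (k in seq_along(seq$frames))
    write_velocity_frame(seq$frames[[k]], file.path(dir, files[k]))
  man <- file.path(dir, "manifest.csv")
  con <- file(man, "w")
  on.exit(close(con))
  writeLines(header_lines("velocity-manifest"), con)
  utils::write.csv(data.frame(file = files,
                              t = fmt_num(vapply(seq$frames, `[[`, numeric(1), "t"))),
                   con, row.names = FALSE, quote = FALSE)
  invisible(man)
}

#' @rdname write_velocity_sequence
#' @param manifest Path to a `manifest.csv` written by
#'   [write_velocity_sequence()].
#' @export
read_velocity_sequence <- function(manifest) {
  man <- utils::read.csv(manifest, comment.char = "#")
  if (!all(c("file", "t") %in% names(man))) stop("manifest needs columns file, t")
  dir <- dirname(manifest)
  paths <- file.path(dir, man$file)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("manifest frame missing at index ", which(missing)[1], ": ", paths[which(missing)[1]])
  frames <- lapply(paths, read_velocity_frame)
  for (k in seq_along(frames)) frames[[k]]$t <- man$t[k]
  dts <- diff(man$t)
  if (length(dts)) {
    if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
      stop("manifest timestamps are not uniformly spaced")
    dt <- stats::median(dts)
  } else dt <- 1
  velocity_sequence(frames, dt)
}

#' Write and read pressure frames
#'
#' CSV with columns `x, y, p, defined` on the complete grid; `p` is empty
#' (`NA`) where undefined.
#'
#' @param frame A `pressure_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pressure_frame <- function(frame, path) {
  stopifnot(inherits(frame, "pressure_frame"))
  nd <- grid_nodes(frame$grid)
  df <- data.frame(x = fmt_num(as.vector(nd$x)), y = fmt_num(as.vector(nd$y)),
                   p = fmt_num(as.vector(frame$p)),
                   defined = as.integer(as.vector(frame$defined)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines("pressure-grid",
                          c("# units: x [m], y [m], p [Pa]",
                            sprintf("# t: %s", fmt_num(frame$t)))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pressure_frame
#' @export
read_pressure_frame <- function(path) {
  r <- read_grid_table(path, "p")
  defined <- matrix(FALSE, r$grid$nx, r$grid$ny)
  if ("defined" %in% names(r$df)) defined[cbind(r$i, r$j)] <- as.logical(r$df$defined)
  else defined <- is.finite(r$p)
  pressure_frame(r$grid, r$p, t = r$t, defined = defined & is.finite(r$p))
}

#' Write and read load series
#'
#' CSV with columns `t, Fx, Fy, Tz, Fx_star, Fy_star, Tz_star, theta,
#' provenance`; missing optional quantities are `NA`. The header records
#' the package version, provenance, the motion-cycle period (when known)
#' and an optional configuration hash.
#'
#' @param series A `load_series`.
#' @param path Output file path.
#' @param config_hash Optional configuration hash to stamp in the header.
#' @return `path`, invisibly.
#' @export
write_load_series <- function(series, path, config_hash = NULL) {
  stopifnot(inherits(series, "load_series"))
  cols <- c("t", "Fx", "Fy", "Tz", "Fx_star", "Fy_star", "Tz_star", "theta")
  df <- as.data.frame(series)
  for (cc in cols) if (!cc %in% names(df)) df[[cc]] <- rep(NA_real_, nrow(df))
  out <- as.data.frame(lapply(df[cols], fmt_num))
  out$provenance <- rep(attr(series, "provenance"), max(nrow(df), 0))
  extra <- sprintf("# provenance: %s", attr(series, "provenance"))
  if (!is.null(attr(series, "period")))
    extra <- c(extra, sprintf("# period: %s", fmt_num(attr(series, "period"))))
  if (!is.null(config_hash)) extra <- c(extra, sprintf("# config: %s", config_hash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines("load-series", extra), con)
  if (nrow(out) == 0)
    writeLines(paste(c(cols, "provenance"), collapse = ","), con)
  else utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_load_series
#' @export
read_load_series <- function(path) {
  hdr <- grep("^#", readLines(path, n = 20), value = TRUE)
  df <- tryCatch(utils::read.csv(path, comment.char = "#"),
                 error = function(e) stop("malformed load-series file ", path, ": ",
                                          conditionMessage(e)))
  need <- c("t", "Fx", "Fy", "Tz")
  if (!all(need %in% names(df))) stop("load-series file lacks columns t, Fx, Fy, Tz")
  prov <- if ("provenance" %in% names(df) && nrow(df)) as.character(df$provenance[1])
          else sub("^# provenance: *", "", grep("^# provenance:", hdr, value = TRUE))[1]
  if (is.na(prov) || !length(prov)) prov <- "estimated"
  pm <- sub("^# period: *", "", grep("^# period:", hdr, value = TRUE))
  period <- if (length(pm)) as.numeric(pm[1]) else NULL
  num_cols <- setdiff(names(df), "provenance")
  df <- df[num_cols]
  drop <- vapply(df, function(cc) all(is.na(cc)), logical(1)) &
    names(df) %in% c("Fx_star", "Fy_star", "Tz_star", "theta")
  df <- df[!drop]
  if (nrow(df) == 0) df <- df[c("t", "Fx", "Fy", "Tz")]
  load_series_frame(df, provenance = prov, period = period)
}

#' Write a control-surface loop as CSV
#'
#' Columns `index, x, y, nx, ny, dl, span`.
#'
#' @param surface A `control_surface`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_control_surface <- function(surface, path) {
  stopifnot(inherits(surface, "control_surface"))
  df <- data.frame(index = seq_len(nrow(surface$points)),
                   x = fmt_num(surface$points[, 1]), y = fmt_num(surface$points[, 2]),
                   nx = fmt_num(surface$normals[, 1]), ny = fmt_num(surface$normals[, 2]),
                   dl = fmt_num(surface$dl), span = fmt_num(surface$span))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines("surface-loop",
                          c("# units: x [m], y [m], dl [m], span [m]",
                            sprintf("# reference: %s,%s", fmt_num(surface$r0[1]),
                                    fmt_num(surface$r0[2])))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read midlines
#'
#' CSV with columns `t, index, x, y`; several frames may share one file.
#'
#' @param midlines A `midline` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_midlines <- function(midlines, path) {
  if (inherits(midlines, "midline")) midlines <- list(midlines)
  rows <- do.call(rbind, lapply(midlines, function(m)
    data.frame(t = fmt_num(rep(m$t, nrow(m$points))),
               index = seq_len(nrow(m$points)),
               x = fmt_num(m$points[, 1]), y = fmt_num(m$points[, 2]))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines("midline", "# units: x [m], y [m]"), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_midlines
#' @export
read_midlines <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t", "index", "x", "y") %in% names(df)))
    stop("midline file needs columns t, index, x, y")
  lapply(split(df, df$t), function(dd) {
    dd <- dd[order(dd$index), ]
    midline(cbind(dd$x, dd$y), t = dd$t[1])
  })
}
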