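#' Pressure-tensor time series
#'
#' Container for one trajectory's pressure-tensor components sampled on a
#' uniform time grid, together with the metadata needed for the Green-Kubo
#' integral: box volume and temperature. Units are fixed at the I/O boundary:
#' time in ps, pressure in bar, volume in nm^3, temperature in K. All unit
#' conversion happens exactly once, in [unit_factor()].
#'
#' Component labels follow the tensor index convention: `xx`, `yy`, `zz` for
#' the diagonal and `xy`, `xz`, `yz` (plus optional transposes `yx`, `zx`,
#' `zy`) for the off-diagonal elements. At minimum the three off-diagonal
#' elements (or their transposes) must be present; in an isotropic fluid
#' these fluctuate about zero and carry the shear-stress signal.
#'
#' @param components named list of equal-length numeric vectors \[bar\];
#'   names from `xx, yy, zz, xy, xz, yz, yx, zx, zy`.
#' @param time_step sampling interval \[ps\], > 0.
#' @param volume box volume \[nm^3\], > 0 (constant-volume trajectories).
#' @param temperature temperature \[K\], > 0.
#' @param start_time time of the first sample \[ps\].
#' @param trajectory_id opaque trajectory label.
#' @param set_id opaque label of the repeat set the trajectory belongs to.
#' @return an object of class `pressure_series`.
#' @export
#' @examples
#' ps <- pressure_series(
#'   components = list(xy = rnorm(100), xz = rnorm(100), yz = rnorm(100)),
#'   time_step = 0.004, volume = 1000, temperature = 298
#' )
#' ps
pressure_series <- function(components, time_step, volume, temperature,
                            start_time = 0, trajectory_id = "traj",
                            set_id = "set1") {
  x <- structure(
    list(
      components = components, time_step = time_step,
      start_time = start_time, volume = volume, temperature = temperature,
      trajectory_id = as.character(trajectory_id),
      set_id = as.character(set_id)
    ),
    class = "pressure_series"
  )
  validate_pressure_series(x)
  x
}

.tensor_labels <- c("xx", "yy", "zz", "xy", "xz", "yz", "yx", "zx", "zy")
.transpose_of <- c(xy = "yx", xz = "zx", yz = "zy")

#' Validate a pressure_series object
#'
#' Checks the container invariants: positive time step, volume and
#' temperature; equal-length numeric components of length >= 2; known labels;
#' presence of the three off-diagonal channels (directly or as transposes).
#'
#' @param x a `pressure_series`.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_pressure_series <- function(x) {
  stopifnot(inherits(x, "pressure_series"))
  if (!is.list(x$components) || length(x$components) == 0) {
    stop("pressure_series: 'components' must be a non-empty named list")
  }
  labs <- names(x$components)
  if (is.null(labs) || any(!labs %in% .tensor_labels)) {
    stop(
      "pressure_series: component labels must be among ",
      paste(.tensor_labels, collapse = ", ")
    )
  }
  if (anyDuplicated(labs)) stop("pressure_series: duplicated component labels")
  lens <- vapply(x$components, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("pressure_series: all component sequences must share one length")
  }
  if (lens[1] < 2L) stop("pressure_series: component length must be >= 2")
  if (!all(vapply(x$components, is.numeric, logical(1)))) {
    stop("pressure_series: components must be numeric")
  }
  has_offdiag <- vapply(
    names(.transpose_of),
    function(l) l %in% labs || .transpose_of[[l]] %in% labs, logical(1)
  )
  if (!all(has_offdiag)) {
    stop(
      "pressure_series: off-diagonal components {xy, xz, yz} (or their ",
      "transposes) are required"
    )
  }
  if (!is.numeric(x$time_step) || length(x$time_step) != 1 || x$time_step <= 0) {
    stop("pressure_series: time_step must be a positive scalar [ps]")
  }
  if (!is.numeric(x$volume) || x$volume <= 0) {
    stop("pressure_series: volume must be positive [nm^3]")
  }
  if (!is.numeric(x$temperature) || x$temperature <= 0) {
    stop("pressure_series: temperature must be positive [K]")
  }
  invisible(x)
}

#' @export
print.pressure_series <- function(x, ...) {
  n <- length(x$components[[1]])
  cat("Pressure-tensor series '", x$trajectory_id, "' (set ", x$set_id, ")\n",
    sep = ""
  )
  cat(
    "  ", n, " samples, dt = ", x$time_step, " ps (",
    format((n - 1) * x$time_step, big.mark = ","), " ps span)\n",
    sep = ""
  )
  cat("  components:", paste(names(x$components), collapse = " "), "\n")
  cat(
    "  V = ", x$volume, " nm^3, T = ", x$temperature, " K\n",
    sep = ""
  )
  invisible(x)
}

#' Number of samples in a pressure series
#' @param x a `pressure_series`.
#' @return integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "pressure_series"))
  length(x$components[[1]])
}

#' Ensemble layout: trajectories partitioned into repeat sets
#'
#' Groups trajectories into labelled sets, mirroring an MD design in which
#' several independent repeat simulations each spawn a family of
#' constant-volume production runs (e.g. 3 sets x 21 trajectories = 63).
#' The partition must be disjoint and cover all trajectories.
#'
#' @param trajectories list of [pressure_series()] objects.
#' @param sets optional named list of integer index vectors partitioning
#'   `seq_along(trajectories)`. If `NULL`, sets are derived from each
#'   trajectory's `set_id`.
#' @return an object of class `ensemble_layout`.
#' @export
ensemble_layout <- function(trajectories, sets = NULL) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1)
  lapply(trajectories, validate_pressure_series)
  if (is.null(sets)) {
    ids <- vapply(trajectories, function(s) s$set_id, character(1))
    sets <- split(seq_along(trajectories), ids)
  }
  idx <- sort(unlist(sets, use.names = FALSE))
  if (!identical(as.integer(idx), seq_along(trajectories))) {
    stop("ensemble_layout: sets must disjointly cover all trajectories")
  }
  structure(
    list(trajectories = trajectories, sets = sets),
    class = "ensemble_layout"
  )
}

#' @export
print.ensemble_layout <- function(x, ...) {
  cat(
    "Ensemble layout: ", length(x$trajectories), " trajectories in ",
    length(x$sets), " sets (",
    paste(vapply(x$sets, length, integer(1)), collapse = " + "), ")\n",
    sep = ""
  )
  invisible(x)
}

.parse_numeric_table <- function(lines, path) {
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  if (length(lines) == 0) stop("no data rows in '", path, "'")
  rows <- strsplit(gsub(",", " ", lines), "\\s+")
  ncol <- length(rows[[1]])
  if (any(vapply(rows, length, integer(1)) != ncol)) {
    stop("ragged rows in '", path, "': all data rows must have ", ncol, " fields")
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(
      "non-numeric cell in '", path, "' (row ", (bad - 1) %/% ncol + 1,
      ", field ", (bad - 1) %% ncol + 1, ")"
    )
  }
  matrix(vals, ncol = ncol, byrow = TRUE)
}

.check_uniform_grid <- function(tt, path, rel_tol = 1e-6) {
  dt <- diff(tt)
  if (length(dt) == 0) stop("fewer than 2 data rows in '", path, "'")
  if (any(dt <= 0) || max(abs(dt - dt[1])) > rel_tol * abs(dt[1])) {
    stop(
      "non-uniform time grid in '", path, "': spacings range ",
      signif(min(dt), 6), " .. ", signif(max(dt), 6), " ps"
    )
  }
  dt[1]
}

#' Read a GROMACS-style XVG pressure-tensor file
#'
#' Parses whitespace-delimited numeric rows, skipping `#` comment and `@`
#' directive lines, as produced by standard energy-extraction tools. The
#' first column is time \[ps\]; `column_map` assigns tensor labels to the
#' remaining columns. Box volume and temperature are supplied as metadata
#' (energy files do not reliably carry them; at constant volume they are
#' single numbers per trajectory).
#'
#' The time step is inferred from the first two rows and verified uniform
#' across the file within a relative tolerance of 1e-6.
#'
#' @param path file to read.
#' @param volume box volume \[nm^3\].
#' @param temperature temperature \[K\].
#' @param column_map named integer vector, tensor label -> column index
#'   (1-based, where column 1 is time). Example: `c(xy = 2, xz = 3, yz = 4)`.
#' @param trajectory_id,set_id labels stored in the result; default from the
#'   file name.
#' @return a [pressure_series()].
#' @export
read_xvg <- function(path, volume, temperature, column_map,
                     trajectory_id = NULL, set_id = "set1") {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (is.null(names(column_map)) || any(!names(column_map) %in% .tensor_labels)) {
    stop("column_map must be named with tensor labels")
  }
  m <- .parse_numeric_table(readLines(path, warn = FALSE), path)
  if (any(column_map < 2) || any(column_map > ncol(m))) {
    stop(
      "column_map out of range for '", path, "': file has ", ncol(m),
      " columns"
    )
  }
  dt <- .check_uniform_grid(m[, 1], path)
  comps <- lapply(as.integer(column_map), function(j) m[, j])
  names(comps) <- names(column_map)
  if (is.null(trajectory_id)) {
    trajectory_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pressure_series(comps, dt, volume, temperature,
    start_time = m[1, 1],
    trajectory_id = trajectory_id, set_id = set_id
  )
}

#' Write a pressure series as self-describing delimited text
#'
#' Writes the series as whitespace-delimited numeric rows (time plus one
#' column per component) preceded by `#` comment lines carrying volume,
#' temperature, time step and the component column order. The file
#' round-trips losslessly through [read_pressure_table()] (and its numeric
#' body through [read_xvg()]): values are printed with 17 significant
#' digits, enough to reproduce doubles exactly.
#'
#' @param series a valid [pressure_series()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  validate_pressure_series(series)
  n <- n_samples(series)
  tt <- series$start_time + series$time_step * (seq_len(n) - 1)
  hdr <- c(
    sprintf("# gkvisc pressure_series"),
    sprintf("# trajectory_id= %s", series$trajectory_id),
    sprintf("# set_id= %s", series$set_id),
    sprintf("# volume_nm3= %.17g", series$volume),
    sprintf("# temperature_K= %.17g", series$temperature),
    sprintf("# time_step_ps= %.17g", series$time_step),
    sprintf("# columns: time %s", paste(names(series$components), collapse = " "))
  )
  body <- do.call(cbind, c(list(tt), unname(series$components)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(
    apply(body, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
    con
  )
  invisible(path)
}

#' Read delimited tabular pressure data
#'
#' Reads either the self-describing format written by [write_series()]
#' (metadata in `#` comments) or a plain table whose first non-comment row
#' names the columns. The delimiter is auto-detected among comma, tab and
#' whitespace. Volume and temperature arguments override any values found in
#' the header.
#'
#' @param path file to read.
#' @param volume,temperature metadata \[nm^3, K\]; required if the file
#'   header does not carry them.
#' @param trajectory_id,set_id optional label overrides.
#' @return a [pressure_series()].
#' @export
read_pressure_table <- function(path, volume = NULL, temperature = NULL,
                                trajectory_id = NULL, set_id = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  for (key in c("trajectory_id", "set_id", "volume_nm3", "temperature_K")) {
    hit <- grep(sprintf("^#\\s*%s=", key), lines, value = TRUE)
    if (length(hit)) meta[[key]] <- trimws(sub(".*=", "", hit[1]))
  }
  col_line <- grep("^#\\s*columns:", lines, value = TRUE)
  if (length(col_line)) {
    cols <- strsplit(trimws(sub("^#\\s*columns:", "", col_line[1])), "\\s+")[[1]]
  } else {
    # plain dialect: first non-comment row names the columns
    first <- which(!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines)))[1]
    if (is.na(first)) stop("no content in '", path, "'")
    cand <- strsplit(gsub(",", " ", trimws(lines[first])), "\\s+")[[1]]
    if (anyNA(suppressWarnings(as.numeric(cand)))) {
      cols <- cand
      lines <- lines[-first]
    } else {
      stop("'", path, "' has no column header; use read_xvg() with a column_map")
    }
  }
  if (cols[1] != "time") stop("first column of '", path, "' must be 'time'")
  m <- .parse_numeric_table(lines, path)
  if (ncol(m) != length(cols)) {
    stop("'", path, "': header names ", length(cols), " columns, rows have ", ncol(m))
  }
  dt <- .check_uniform_grid(m[, 1], path)
  comps <- lapply(2:ncol(m), function(j) m[, j])
  names(comps) <- cols[-1]
  vol <- volume %||% as.numeric(meta$volume_nm3)
  tem <- temperature %||% as.numeric(meta$temperature_K)
  if (is.null(vol) || length(vol) == 0 || is.na(vol)) {
    stop("volume not given and not found in header of '", path, "'")
  }
  if (is.null(tem) || length(tem) == 0 || is.na(tem)) {
    stop("temperature not given and not found in header of '", path, "'")
  }
  pressure_series(comps, dt, vol, tem,
    start_time = m[1, 1],
    trajectory_id = trajectory_id %||% meta$trajectory_id %||% basename(path),
    set_id = set_id %||% meta$set_id %||% "set1"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
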