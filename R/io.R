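#' Trajectory, kernel and configuration file I/O
#'
#' Trajectories are exchanged as two-column plain text (time, q) with
#' `# key: value` header metadata, written with 17 significant digits so
#' the round trip is lossless at double precision.  Kernels use a JSON
#' dialect `{gamma: [...], tau: [...], units, provenance}`; configurations
#' are YAML.
#'
#' @name memgle_io
#' @keywords internal
NULL

#' @rdname memgle_io
#' @param traj a [trajectory()].
#' @param path output/input file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# delta: %.17g", traj$delta), con)
  writeLines(sprintf("# dt: %.17g", traj$dt), con)
  writeLines(sprintf("# seed: %s", ifelse(is.na(traj$seed), "NA", traj$seed)), con)
  if (length(traj$meta))
    writeLines(sprintf("# meta: %s",
                       jsonlite::toJSON(traj$meta[!vapply(traj$meta, is.list, TRUE)],
                                        auto_unbox = TRUE, digits = NA)), con)
  t <- (seq_along(traj$q) - 1) * traj$delta
  writeLines(sprintf("%.17g %.17g", t, traj$q), con)
  invisible(path)
}

#' @rdname memgle_io
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list(); delta <- NA_real_; dt <- NA_real_; seed <- NA_integer_
  for (h in lines[hdr]) {
    if (grepl("^# delta:", h)) delta <- as.numeric(sub("^# delta:\\s*", "", h))
    else if (grepl("^# dt:", h)) dt <- as.numeric(sub("^# dt:\\s*", "", h))
    else if (grepl("^# seed:", h)) {
      s <- trimws(sub("^# seed:\\s*", "", h))
      seed <- if (s == "NA") NA_integer_ else as.integer(s)
    } else if (grepl("^# meta:", h))
      meta <- jsonlite::fromJSON(sub("^# meta:\\s*", "", h))
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad))
    stop(sprintf("malformed trajectory line %d: '%s'", bad[1], body[bad[1]]))
  tv <- as.numeric(vapply(parts, `[`, character(1), 1))
  qv <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(tv) || anyNA(qv)) stop("non-numeric field in trajectory file")
  if (length(tv) >= 2) {
    steps <- diff(tv)
    d0 <- stats::median(steps)
    if (any(abs(steps - d0) > 1e-9 * max(abs(tv))))
      stop("non-uniform time column")
    if (is.na(delta)) delta <- d0
  }
  if (is.na(dt)) dt <- delta
  trajectory(qv, delta = delta, dt = dt, seed = seed, meta = as.list(meta))
}

#' @rdname memgle_io
#' @param kernel a [memory_kernel()].
#' @param units,provenance metadata strings stored in the JSON.
#' @export
write_kernel <- function(kernel, path, units = "reduced", provenance = "memgle") {
  stopifnot(inherits(kernel, "memory_kernel"))
  # 17 significant digits so doubles round-trip bit-exactly
  num <- function(x) paste(sprintf("%.17g", x), collapse = ", ")
  writeLines(sprintf(
    '{"gamma": [%s], "tau": [%s], "units": "%s", "provenance": "%s"}',
    num(kernel$gamma), num(kernel$tau), units, provenance), path)
  invisible(path)
}

#' @rdname memgle_io
#' @export
read_kernel <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$gamma) || is.null(x$tau))
    stop("kernel file must contain 'gamma' and 'tau' fields")
  k <- memory_kernel(x$gamma, x$tau)
  attr(k, "units") <- x$units
  attr(k, "provenance") <- x$provenance
  k
}

#' @rdname memgle_io
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as boolean false; restore the intended name
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  cfg
}
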