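#' cnpdist: copy-number profile distances for cancer clone phylogenetics
#'
#' Distances between copy-number profiles (CNPs) under segmental
#' amplification/deletion events that may change copy-numbers by more than
#' one unit at a time, together with a clone-tree simulator and a
#' neighbor-joining evaluation pipeline.
#'
#' A CNP is represented throughout as a plain vector of non-negative
#' integers, one entry per genomic position (gene or segment). Positions are
#' 1-based; virtual boundary values at positions 0 and n+1 are always 0 and
#' are never stored. An event is a triple (s, t, delta): every position in
#' the closed interval \[s, t\] with a positive copy-number is changed by
#' delta, clamped below at 0. A position at 0 is absorbing: it can never be
#' re-amplified.
#'
#' @useDynLib cnpdist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# -- validation helpers -------------------------------------------------------

as_cnp <- function(u, arg = "u") {
  if (!is.numeric(u) || length(u) < 1L)
    stop(sprintf("'%s' must be a numeric vector of length >= 1", arg))
  if (any(is.na(u)) || any(u < 0) || any(u != floor(u)))
    stop(sprintf("'%s' must contain non-negative integers", arg))
  as.integer(u)
}

check_same_length <- function(u, v) {
  if (length(u) != length(v))
    stop("profiles must have the same length")
}

#' Construct a sequence of segmental events
#'
#' Events are stored as a data frame with columns `s`, `t` and `delta`
#' (start, end, signed change). Validation is eager: `1 <= s <= t` and
#' `delta != 0` are required at construction; the upper bound `t <= n` is
#' checked when the event is applied to a profile.
#'
#' @param s,t integer vectors of interval starts and (inclusive) ends.
#' @param delta integer vector of nonzero changes (positive = amplification,
#'   negative = deletion).
#' @return a data frame of class `cnp_events` with one row per event.
#' @examples
#' cnp_events(c(1, 2), c(4, 3), c(-2, 1))
#' @export
cnp_events <- function(s = integer(), t = integer(), delta = integer()) {
  s <- as.integer(s); t <- as.integer(t); delta <- as.integer(delta)
  if (length(s) != length(t) || length(s) != length(delta))
    stop("'s', 't' and 'delta' must have the same length")
  if (any(is.na(s)) || any(is.na(t)) || any(is.na(delta)))
    stop("events must not contain NA")
  if (any(s < 1L) || any(t < s))
    stop("events require 1 <= s <= t")
  if (any(delta == 0L))
    stop("events require delta != 0")
  structure(data.frame(s = s, t = t, delta = delta),
            class = c("cnp_events", "data.frame"))
}

#' Apply one segmental event to a copy-number profile
#'
#' Positions inside `[s, t]` with a positive copy-number become
#' `max(u_i + delta, 0)`; null positions are absorbing and remain 0 even
#' under amplification; positions outside the interval are unchanged.
#'
#' @param u integer vector, the profile.
#' @param s,t event interval, `1 <= s <= t <= length(u)`.
#' @param delta nonzero integer change.
#' @return the resulting profile (integer vector).
#' @examples
#' apply_event(c(4, 8, 15, 23, 14), 1, 5, -3)
#' apply_event(c(13, 0, 13), 1, 3, 1)  # the 0 stays 0
#' @export
apply_event <- function(u, s, t, delta) {
  u <- as_cnp(u)
  e <- cnp_events(s, t, delta)
  if (nrow(e) != 1L) stop("apply_event() takes a single event")
  if (e$t > length(u))
    stop("event interval out of bounds")
  idx <- e$s:e$t
  live <- idx[u[idx] > 0L]
  u[live] <- pmax(u[live] + e$delta, 0L)
  u
}

#' Apply an ordered sequence of events
#'
#' Left-to-right fold of [apply_event()]: `u<E> = u<e1><e2>...<ek>`.
#'
#' @param u integer vector, the starting profile.
#' @param events a `cnp_events` data frame (or anything with columns
#'   `s`, `t`, `delta`).
#' @return the transformed profile.
#' @examples
#' apply_sequence(c(15, 2, 15, 2), cnp_events(c(1, 1), c(4, 4), c(-2, 1)))
#' @export
apply_sequence <- function(u, events) {
  u <- as_cnp(u)
  if (is.null(events) || nrow(events) == 0L) return(u)
  for (i in seq_len(nrow(events)))
    u <- apply_event(u, events$s[i], events$t[i], events$delta[i])
  u
}

#' Difference vector of two profiles
#'
#' `w = u - v`, the quantity that event sequences must drive to all zeros
#' when transforming `u` into `v`. The virtual sentinels `w_0 = w_{n+1} = 0`
#' are implicit and not stored.
#'
#' @param u,v integer vectors of equal length.
#' @return integer vector `u - v`.
#' @examples
#' difference_vector(c(4, 8, 15, 23, 14), rep(1, 5))
#' @export
difference_vector <- function(u, v) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  u - v
}

#' Maximal flat intervals of a difference vector
#'
#' A flat interval is a maximal run of equal values in `w`, including the
#' virtual zero sentinels at positions 0 and n+1. The returned intervals
#' partition `[0, n+1]`; adjacent intervals carry different values and the
#' two extreme intervals always have value 0.
#'
#' @param w integer vector (a difference vector, without sentinels).
#' @return a data frame with columns `start`, `end`, `value`.
#' @examples
#' flat_intervals(c(1, 1, 2, 2, 0))
#' @export
flat_intervals <- function(w) {
  if (!is.numeric(w)) stop("'w' must be numeric")
  wp <- c(0L, as.integer(w), 0L)            # positions 0 .. n+1
  n1 <- length(wp)
  brk <- which(wp[-1L] != wp[-n1])          # boundary after position brk-1
  start <- c(0L, brk)                       # 0-based positions
  end <- c(brk - 1L, n1 - 1L)
  data.frame(start = start, end = end, value = wp[start + 1L])
}

#' Length of the longest staircase in a difference vector
#'
#' A staircase is a contiguous run `0 < w_a < w_{a+1} < ... < w_b` of
#' strictly increasing positive values; its length lower-bounds the
#' segmental event distance for any unit-cost scheme.
#'
#' @param w integer vector (difference vector without sentinels).
#' @return the maximum staircase length, 0 if no entry is positive.
#' @examples
#' longest_staircase(c(3, 7, 14, 22, 13))  # 4, interval [1, 4]
#' @export
longest_staircase <- function(w) {
  if (!is.numeric(w)) stop("'w' must be numeric")
  best <- 0L; cur <- 0L; prev <- 0L
  for (x in w) {
    if (x > 0 && x > prev) cur <- cur + 1L
    else cur <- if (x > 0) 1L else 0L
    if (cur > best) best <- cur
    prev <- x
  }
  best
}

#' Can one profile be transformed into another?
#'
#' Transformability only fails at null positions: once a copy-number hits 0
#' it can never increase again, so `u` can reach `v` only if every null of
#' `u` is also null in `v`.
#'
#' @param u,v integer vectors of equal length.
#' @return `TRUE` iff `u_i = 0` implies `v_i = 0` for every position.
#' @examples
#' is_transformable(c(1, 1), c(0, 0))  # TRUE
#' is_transformable(c(0, 0), c(1, 1))  # FALSE
#' @export
is_transformable <- function(u, v) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  !any(u == 0L & v > 0L)
}

# -- CNP table I/O ------------------------------------------------------------

#' Read a table of copy-number profiles
#'
#' Plain-text delimited format: column 1 is a sample identifier, columns
#' 2..n+1 are non-negative integers. The delimiter is TAB by default with
#' comma accepted, auto-detected from the first line. A header line is
#' optional and detected by a non-integer second field.
#'
#' @param path file path.
#' @return an integer matrix with one row per sample, rownames = sample ids.
#' @export
read_cnp_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty CNP table: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  second <- trimws(fields[[1L]][2L])
  has_header <- is.na(suppressWarnings(as.integer(second))) ||
    second != as.character(suppressWarnings(as.integer(second)))
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) stop("CNP table has a header but no data rows")
  n <- length(fields[[1L]]) - 1L
  if (n < 1L) stop("CNP table rows need an id plus at least one position")
  ids <- character(length(fields))
  m <- matrix(NA_integer_, nrow = length(fields), ncol = n)
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) != n + 1L)
      stop(sprintf("CNP table line %d: expected %d fields, found %d",
                   i + has_header, n + 1L, length(f)))
    ids[i] <- f[1L]
    vals <- suppressWarnings(as.integer(f[-1L]))
    if (any(is.na(vals)) || any(vals < 0L))
      stop(sprintf("CNP table line %d: non-integer or negative copy-number",
                   i + has_header))
    m[i, ] <- vals
  }
  rownames(m) <- ids
  m
}

#' Write a table of copy-number profiles
#'
#' @param profiles integer matrix with rownames (sample ids).
#' @param path output file path.
#' @param sep field delimiter, TAB by default.
#' @return `path`, invisibly.
#' @export
write_cnp_table <- function(profiles, path, sep = "\t") {
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("s", seq_len(nrow(profiles)))
  lines <- vapply(seq_len(nrow(profiles)), function(i)
    paste(c(rownames(profiles)[i], profiles[i, ]), collapse = sep), "")
  writeLines(lines, path)
  invisible(path)
}
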