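# CNP distances: null-position reduction, flat-interval approximation,
# greedy merge-event heuristic, unit-event (MEDICC model) distance,
# Euclidean distance, and symmetrization.

new_distance_result <- function(cost, events, method) {
  structure(list(cost = cost, events = events, method = method),
            class = "cnp_distance")
}

#' @export
print.cnp_distance <- function(x, ...) {
  cat(sprintf("CNP distance (%s): cost = %s, %d event(s) recorded\n",
              x$method, format(x$cost), nrow(x$events)))
  invisible(x)
}

rule_names <- c("shared-null", "adjacent-null", "dominated-null", "source-null")

#' Remove null positions without changing the distance
#'
#' Iterates three distance-preserving rules to a fixed point: (a) drop
#' positions null in both profiles; (b) of two consecutive positions null in
#' the target, drop the one with the smaller source value; (c) drop a target
#' null whose difference-vector value does not strictly dominate both
#' neighbours. Afterwards every remaining null of `v` is "sandwiched":
#' `w_{i-1} < w_i` and `w_{i+1} < w_i`.
#'
#' @param u,v source and target profiles (equal length).
#' @param drop_source_nulls if `TRUE`, positions where `u` is null but `v` is
#'   positive (which make the direction undefined) are dropped instead of
#'   raising an error; used by the pragmatic symmetrized pipeline.
#' @return a list with reduced `u`, `v` and a data frame `removed` holding
#'   the original 1-based `position` and the `rule` that removed it.
#' @examples
#' reduce_null_positions(c(3, 5, 2, 4), c(1, 0, 0, 2))
#' @export
reduce_null_positions <- function(u, v, drop_source_nulls = FALSE) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  res <- reduce_pair_cpp(u, v, drop_source_nulls)
  list(u = res$u, v = res$v,
       removed = data.frame(position = res$positions,
                            rule = rule_names[res$rules]))
}

#' Flat-interval count approximation of the segmental event distance
#'
#' Returns `|F_w| - 2`, the number of non-extreme maximal flat intervals of
#' `w = u - v`: a linear-time factor-2 approximation of the minimum number
#' of unrestricted segmental events transforming `u` into `v`. The realizing
#' solution applies one event per nonzero non-extreme flat interval,
#' amplifications first so that no position dies prematurely; intervals
#' whose `w` value is already 0 need no event, so fewer than `cost` events
#' may be returned.
#'
#' @param u,v source and target profiles.
#' @param reduce apply [reduce_null_positions()] first (default). Events are
#'   reported in the coordinates of the reduced profiles.
#' @return a `cnp_distance` with fields `cost`, `events`, `method`.
#' @examples
#' flat_count_distance(c(4, 8, 15, 23, 14), rep(1, 5))$cost  # 5
#' @export
flat_count_distance <- function(u, v, reduce = TRUE) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  if (reduce) {
    red <- reduce_null_positions(u, v)
    u <- red$u; v <- red$v
  } else if (!is_transformable(u, v)) {
    stop("untransformable pair: source null with positive target")
  }
  if (length(u) == 0L || all(u == v))
    return(new_distance_result(0L, cnp_events(), "flat"))
  fi <- flat_intervals(u - v)
  cost <- max(nrow(fi) - 2L, 0L)
  inner <- fi[fi$value != 0L, , drop = FALSE]
  # amplifications (value < 0, event delta > 0) first: safe ordering
  inner <- inner[order(inner$value >= 0L, inner$start), , drop = FALSE]
  ev <- cnp_events(inner$start, inner$end, -inner$value)
  new_distance_result(cost, ev, "flat")
}

#' Find an event that merges two flat intervals
#'
#' An event `(i, j, delta)` reduces the number of flat intervals of `w` by
#' two exactly when `w_{i-1} - w_i = w_{j+1} - w_j = delta`. The search
#' returns the valid such event with the smallest `i`, then smallest `j`, or
#' `NULL` if none exists. Validity: no frozen null of `u` inside `[i, j]`,
#' no position with `v_p > 0` may reach 0, and no position may go below 0.
#'
#' @param w difference vector; must equal `u - v`.
#' @param u,v the current source and target profiles.
#' @return a one-row `cnp_events`, or `NULL`.
#' @examples
#' find_merge_event(c(1, 2, 1), c(2, 3, 2), c(1, 1, 1))
#' @export
find_merge_event <- function(w, u, v) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  if (!isTRUE(all.equal(as.integer(w), u - v)))
    stop("'w' is not the difference vector of 'u' and 'v'")
  e <- merge_event_cpp(u, v)
  if (length(e) == 0L) return(NULL)
  cnp_events(e[1L], e[2L], e[3L])
}

#' Greedy improvement of the flat-interval approximation
#'
#' As long as `u != v`, apply an event that merges two flat intervals
#' (reducing `|F_w|` by 2) if a valid one exists; otherwise zero out the
#' leftmost non-extreme flat interval with a nonzero value. The cost never
#' exceeds the plain flat-interval count.
#'
#' @inheritParams flat_count_distance
#' @param record_events keep the realizing event sequence (default `TRUE`).
#' @return a `cnp_distance`; `apply_sequence(u_reduced, events) == v_reduced`.
#' @examples
#' heuristic_distance(c(2, 3, 4, 3, 2), rep(1, 5))$cost  # 3
#' @export
heuristic_distance <- function(u, v, reduce = TRUE, record_events = TRUE) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  if (reduce) {
    red <- reduce_null_positions(u, v)
    u <- red$u; v <- red$v
  } else if (!is_transformable(u, v)) {
    stop("untransformable pair: source null with positive target")
  }
  if (length(u) == 0L || all(u == v))
    return(new_distance_result(0L, cnp_events(), "heuristic"))
  res <- heuristic_cpp(u, v, record_events)
  ev <- if (record_events)
    cnp_events(res$events[, 1L], res$events[, 2L], res$events[, 3L])
  else cnp_events()
  new_distance_result(res$cost, ev, "heuristic")
}

#' Unit-event (MEDICC model) distance
#'
#' Minimum number of segmental events with `delta` restricted to +1/-1
#' transforming `u` into `v` — the model solved exactly by the
#' Zeira-Zehavi-Shamir dynamic program. Zero-free inputs use a closed-form
#' "skyline" expression (number of rises of the positive and negative parts
#' of `w`); inputs with isolated sandwiched target nulls use a chain dynamic
#' program over per-position deletion coverages. Both routes agree with
#' brute-force search on exhaustive small instances.
#'
#' @inheritParams flat_count_distance
#' @param fast_path use the closed-form skyline on zero-free inputs
#'   (default); `FALSE` forces the dynamic program (testing hook).
#' @return a `cnp_distance` with the cost; no events are reconstructed.
#' @examples
#' zzs_distance(c(1, 1), c(0, 0))$cost  # 1
#' zzs_distance(c(2, 1, 3), c(1, 1, 1))$cost  # 3
#' @export
zzs_distance <- function(u, v, reduce = TRUE, fast_path = TRUE) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  if (!is_transformable(u, v))
    stop("untransformable pair: source null with positive target")
  if (reduce) {
    red <- reduce_null_positions(u, v)
    u <- red$u; v <- red$v
  }
  cost <- if (length(u) == 0L) 0 else zzs_cpp(u, v, fast_path)
  new_distance_result(cost, cnp_events(), "zzs")
}

#' Euclidean distance between profiles
#'
#' `sqrt(sum((u_i - v_i)^2))`, the classical profile comparison; no
#' null-position reduction is applied.
#'
#' @param u,v profiles of equal length.
#' @return a non-negative number.
#' @examples
#' euclidean_distance(c(1, 1), c(0, 0))  # sqrt(2)
#' @export
euclidean_distance <- function(u, v) {
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  sqrt(sum((u - v)^2))
}

method_codes <- c(flat = 1L, heuristic = 2L, zzs = 3L)

#' Symmetrized CNP distance
#'
#' The event distances are directional (a null can never be re-amplified),
#' so the symmetric distance is the minimum of the two ordered directions,
#' each computed after null-position reduction. A direction whose source has
#' a null where the target is positive is undefined and treated as +Inf;
#' when both directions are undefined, positions null in exactly one profile
#' are dropped from both (the pragmatic filter) and the minimum is taken on
#' the remainder. The Euclidean distance is already symmetric and is
#' returned without reduction.
#'
#' @param u,v profiles of equal length.
#' @param method one of `"flat"`, `"heuristic"`, `"zzs"`, `"euclidean"`.
#' @return a non-negative number, symmetric in `u` and `v`.
#' @examples
#' symmetric_distance(c(1, 1), c(0, 0), "zzs")  # 1
#' @export
symmetric_distance <- function(u, v,
                               method = c("heuristic", "flat", "zzs", "euclidean")) {
  method <- match.arg(method)
  u <- as_cnp(u); v <- as_cnp(v, "v")
  check_same_length(u, v)
  if (method == "euclidean") return(euclidean_distance(u, v))
  sym_pair_cpp(u, v, method_codes[[method]])
}

#' Combinatorial lower bound on the segmental event distance
#'
#' The maximum of the staircase bound (a strictly increasing run of `k`
#' positive values in `w` forces at least `k` events, likewise for `-w` and
#' for the left-right mirrored vectors) and the flat-interval bound
#' `ceil((|F_w| - 1) / 2)`. Valid for any unit-cost scheme on reduced,
#' transformable pairs; verified against the exact oracle in the test suite.
#'
#' @param w difference vector of a reduced pair.
#' @return an integer lower bound on the distance.
#' @examples
#' lower_bound(c(3, 7, 14, 22, 13))  # 4: the staircase beats the flat bound
#' @export
lower_bound <- function(w) {
  if (!is.numeric(w)) stop("'w' must be numeric")
  w <- as.integer(w)
  if (all(w == 0L)) return(0L)
  flat_b <- as.integer(ceiling((nrow(flat_intervals(w)) - 1L) / 2))
  sc <- max(longest_staircase(w), longest_staircase(-w),
            longest_staircase(rev(w)), longest_staircase(rev(-w)))
  max(flat_b, sc)
}
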