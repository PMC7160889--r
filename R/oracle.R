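# Exact distances on small instances by exhaustive breadth-first search over
# the capped profile state graph. Used as the validation oracle for the
# approximation guarantees and the unit-event dynamic program.

the <- new.env(parent = emptyenv())  # adjacency cache

oracle_powers <- function(n, cap) (cap + 1)^(0:(n - 1))

oracle_state_id <- function(u, cap) {
  as.integer(sum(u * oracle_powers(length(u), cap)) + 1)
}

oracle_states <- function(n, cap) {
  # all profiles with entries 0..cap, one per row, row i = state id i
  N <- (cap + 1)^n
  S <- matrix(0L, nrow = N, ncol = n)
  ids <- 0:(N - 1)
  for (j in seq_len(n)) S[, j] <- (ids %/% (cap + 1)^(j - 1)) %% (cap + 1)
  S
}

cost_scheme <- function(cost) match.arg(cost, c("any", "mdc", "dbl"))

# successor matrix: states x events; NA where the event has infinite cost
oracle_adjacency <- function(n, cap, cost, max_states) {
  key <- paste(n, cap, cost, sep = "|")
  if (!is.null(the[[key]])) return(the[[key]])
  N <- (cap + 1)^n
  if (N > max_states)
    stop(sprintf("state space too large for the exact oracle (%d > %d states)",
                 N, max_states))
  S <- oracle_states(n, cap)
  deltas <- if (cost == "mdc") c(-1L, 1L) else setdiff(-cap:cap, 0L)
  ev <- expand.grid(s = seq_len(n), t = seq_len(n), delta = deltas)
  ev <- ev[ev$s <= ev$t, , drop = FALSE]
  pw <- oracle_powers(n, cap)
  succ <- matrix(NA_integer_, nrow = N, ncol = nrow(ev))
  for (k in seq_len(nrow(ev))) {
    s <- ev$s[k]; t <- ev$t[k]; d <- ev$delta[k]
    M <- S
    blk <- M[, s:t, drop = FALSE]
    upd <- pmax(blk + d, 0L)
    upd[blk == 0L] <- 0L             # zero absorption
    ok <- rep(TRUE, N)
    if (cost == "dbl" && d > 0L)     # doubling cap: delta <= min u_i on [s, t]
      ok <- apply(blk, 1L, min) >= d
    ok <- ok & apply(upd <= cap, 1L, all)  # stay inside the capped space
    M[, s:t] <- upd
    id <- as.integer(M %*% pw + 1)
    id[!ok] <- NA_integer_
    succ[, k] <- id
  }
  the[[key]] <- succ
  succ
}

#' Exact distances from one profile to many targets
#'
#' Breadth-first search over all profiles with entries in `0..value_cap`,
#' under segmental events allowed by the chosen unit-cost scheme. Exact by
#' exhaustion on small instances; shares one search across all targets.
#'
#' @param u source profile.
#' @param targets matrix of target profiles (one per row), or a single
#'   profile vector.
#' @param cost `"any"` (unrestricted changes), `"mdc"` (only +1/-1), or
#'   `"dbl"` (amplifications at most doubling, deletions unrestricted).
#' @param value_cap largest copy-number explored; defaults to twice the
#'   largest copy-number in `u` and `targets`, leaving head-room for
#'   transient amplification overshoot (an optimal solution may amplify
#'   above both endpoints before deleting, e.g. (1,4,1) to (4,1,4) in two
#'   events via (4,7,4)). Results are exact only over the capped space; the
#'   test suite checks cap-robustness on exhaustive small families.
#' @param max_states refuse searches beyond this state count.
#' @return numeric vector of distances (`Inf` for unreachable targets).
#' @export
exact_distances_from <- function(u, targets, cost = "any", value_cap = NULL,
                                 max_states = 300000) {
  cost <- cost_scheme(cost)
  u <- as_cnp(u)
  if (is.null(dim(targets))) targets <- matrix(as.integer(targets), nrow = 1L)
  storage.mode(targets) <- "integer"
  if (ncol(targets) != length(u))
    stop("targets must have the same length as 'u'")
  if (is.null(value_cap)) value_cap <- max(2L * max(u, targets), 4L)
  cap <- as.integer(value_cap)
  if (max(u, targets) > cap) stop("'value_cap' below the largest copy-number")
  n <- length(u)
  succ <- oracle_adjacency(n, cap, cost, max_states)
  dist <- rep(Inf, nrow(succ))
  src <- oracle_state_id(u, cap)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0L) {
    nxt <- succ[frontier, , drop = FALSE]
    nxt <- unique(nxt[!is.na(nxt)])
    nxt <- nxt[is.infinite(dist[nxt])]
    d <- d + 1
    dist[nxt] <- d
    frontier <- nxt
  }
  dist[apply(targets, 1L, oracle_state_id, cap = cap)]
}

#' Exact segmental event distance on a small instance
#'
#' Wrapper around [exact_distances_from()] for a single pair; intended for
#' instances of a handful of positions with single-digit copy-numbers.
#'
#' @inheritParams exact_distances_from
#' @param v target profile.
#' @return the exact distance (integer).
#' @examples
#' exact_distance_oracle(c(2, 3, 2), c(1, 1, 1), "any")  # 2
#' @export
exact_distance_oracle <- function(u, v, cost = "any", value_cap = NULL,
                                  max_states = 300000) {
  v <- as_cnp(v, "v")
  check_same_length(as_cnp(u), v)
  d <- exact_distances_from(u, v, cost, value_cap, max_states)
  if (is.infinite(d))
    stop("untransformable pair: target unreachable from source")
  as.integer(d)
}
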