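# Shared fixtures: exhaustive small-instance families and their exact
# distances, computed once per test run and reused across test files.

# all length-n profiles with entries drawn from `values`, one per row
family_profiles <- function(values, n = 3L) {
  m <- as.matrix(expand.grid(rep(list(values), n)))[, n:1, drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# exact distances over the zero-free family {1..4}^3 under both cost schemes
zero_free_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prof <- family_profiles(1:4)
      k <- nrow(prof)
      d_any <- matrix(NA_real_, k, k)
      d_mdc <- matrix(NA_real_, k, k)
      for (i in seq_len(k)) {
        d_any[i, ] <- exact_distances_from(prof[i, ], prof, "any")
        d_mdc[i, ] <- exact_distances_from(prof[i, ], prof, "mdc")
      }
      cache <<- list(profiles = prof, d_any = d_any, d_mdc = d_mdc)
    }
    cache
  }
})

# exact mdc distances from zero-free sources {1..3}^3 to targets {0..3}^3
null_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      src <- family_profiles(1:3)
      tgt <- family_profiles(0:3)
      d_mdc <- matrix(NA_real_, nrow(src), nrow(tgt))
      for (i in seq_len(nrow(src)))
        d_mdc[i, ] <- exact_distances_from(src[i, ], tgt, "mdc")
      cache <<- list(src = src, tgt = tgt, d_mdc = d_mdc)
    }
    cache
  }
})

# random transformable pair (target null wherever source is null)
random_pair <- function(n, max_val = 6L, null_prob = 0.15) {
  u <- sample(0:max_val, n, replace = TRUE)
  v <- sample(0:max_val, n, replace = TRUE)
  v[u == 0L] <- 0L
  v[stats::runif(n) < null_prob] <- 0L
  list(u = u, v = v)
}

# canonical string for a rooted topology (children sorted by smallest label)
canonical_topology <- function(tr) {
  l <- length(tr$tip.label)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  rec <- function(nd) {
    if (nd <= l) return(list(key = tr$tip.label[nd], min = tr$tip.label[nd]))
    ch <- lapply(kids[[as.character(nd)]], rec)
    ord <- order(vapply(ch, `[[`, "", "min"))
    ch <- ch[ord]
    list(key = paste0("(", paste(vapply(ch, `[[`, "", "key"), collapse = ","), ")"),
         min = ch[[1L]]$min)
  }
  rec(l + 1L)$key
}
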