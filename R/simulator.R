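# Simulation of cancer clone phylogenies: chromosome strings evolving along a
# random rooted binary tree by segmental tandem duplications and deletions,
# yielding copy-number profiles at the leaves.

#' Simulation configuration
#'
#' Bundles the generator parameters with their default study conditions.
#'
#' @param l number of leaves (clones) in the tree.
#' @param n number of genes in the root chromosome (= profile length).
#' @param e_min,e_max range of the number of events per branch.
#' @param dup_prob probability that an event is a tandem duplication (the
#'   complement is a deletion).
#' @param r per-step stop probability of the event-length extension loop;
#'   event lengths are geometric with mean about `1/r`.
#' @param q probability that a deletion is allowed to suppress the last copy
#'   of a gene during length extension (the guard modelling resistance to
#'   losing every copy of an essential gene).
#' @param alpha measurement-noise rate: each observed copy-number is redrawn
#'   from `Normal(u_i, alpha * u_i)` and rounded (0 = noise-free).
#' @param seed optional integer seed recorded with the run.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(l = 100L, n = 100L, e_min = 5L, e_max = 10L,
                       dup_prob = 0.5, r = 0.05, q = 0.25, alpha = 0,
                       seed = NULL) {
  stopifnot(l >= 2L, n >= 1L, e_min >= 0L, e_max >= e_min,
            dup_prob >= 0, dup_prob <= 1, r > 0, r <= 1,
            q >= 0, q <= 1, alpha >= 0)
  structure(list(l = as.integer(l), n = as.integer(n),
                 e_min = as.integer(e_min), e_max = as.integer(e_max),
                 dup_prob = dup_prob, r = r, q = q, alpha = alpha,
                 seed = seed),
            class = "sim_config")
}

#' Sample a rooted binary tree uniformly over labeled topologies
#'
#' Stepwise leaf insertion: leaf `k` attaches to a uniformly chosen edge of
#' the current tree, including the virtual edge above the root. Every rooted
#' binary labeled topology on `l` leaves (there are `(2l-3)!!` of them) is
#' produced with equal probability.
#'
#' @param l number of leaves, at least 2.
#' @return an `ape` `phylo` object with tip labels `"1" .. "l"`.
#' @export
sample_tree <- function(l) {
  l <- as.integer(l)
  if (is.na(l) || l < 2L) stop("'l' must be an integer >= 2")
  # temporary node ids: leaves 1..l, internals l+1, l+2, ...
  nxt <- l + 1L
  root <- nxt; nxt <- nxt + 1L
  parent <- c(root, root)   # edge list: parent[i] -> child[i]
  child <- c(1L, 2L)
  for (k in seq_len(l)[-(1:2)]) {
    pick <- sample.int(length(parent) + 1L, 1L)
    newn <- nxt; nxt <- nxt + 1L
    if (pick > length(parent)) {        # above the root
      parent <- c(parent, newn, newn)
      child <- c(child, root, k)
      root <- newn
    } else {                            # split edge 'pick'
      old_child <- child[pick]
      child[pick] <- newn
      parent <- c(parent, newn, newn)
      child <- c(child, old_child, k)
    }
  }
  # renumber to ape convention: tips 1..l, root l+1, internals in preorder
  nn <- l - 1L
  map <- integer(max(c(parent, child)))
  map[1:l] <- 1:l
  counter <- l + 1L
  kids <- split(child, parent)
  stack <- root
  order_edges <- integer(0)
  edge_from <- integer(2L * l - 2L); edge_to <- integer(2L * l - 2L); ei <- 0L
  while (length(stack) > 0L) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    map[nd] <- counter; counter <- counter + 1L
    for (ch in kids[[as.character(nd)]]) {
      ei <- ei + 1L
      edge_from[ei] <- nd; edge_to[ei] <- ch
      if (ch > l) stack <- c(ch, stack)   # depth-first, parents first
    }
  }
  # parents are numbered before children along every path, so edges are valid
  edge <- cbind(ifelse(edge_from > l, map[edge_from], edge_from),
                ifelse(edge_to > l, map[edge_to], edge_to))
  tr <- list(edge = edge, tip.label = as.character(1:l), Nnode = nn)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Draw the number of events on a branch
#'
#' A count uniform on `{e_min, ..., e_max}` multiplied by a rate-heterogeneity
#' factor drawn uniformly on `[1 - sqrt(3), 1 + sqrt(3)]` (the unique uniform
#' distribution with mean 1 and standard deviation 1), clamped below at 0,
#' with the product rounded half-up.
#'
#' @param cfg a [sim_config()].
#' @param multiplier optional fixed multiplier overriding the random draw
#'   (testing hook).
#' @return a non-negative integer event count.
#' @export
sample_branch_event_count <- function(cfg, multiplier = NULL) {
  k <- cfg$e_min + sample.int(cfg$e_max - cfg$e_min + 1L, 1L) - 1L
  m <- if (is.null(multiplier)) stats::runif(1, 1 - sqrt(3), 1 + sqrt(3)) else multiplier
  m <- max(m, 0)
  as.integer(floor(k * m + 0.5))
}

#' Evolve a chromosome string by tandem duplications and deletions
#'
#' Applies `k` events. Each event is a tandem duplication with probability
#' `dup_prob`, else a deletion; its start is uniform on the current string
#' and its length extends one position at a time, stopping with probability
#' `r` per step (and truncated at the end of the string). Deletions are
#' subject to the last-copy guard: whenever the proposed deletion would
#' remove every remaining copy of some gene — at the start position, or at
#' any proposed extension once such a gene is inside the range — the event
#' proceeds only with probability `q` (a start-position block cancels the
#' deletion; an extension block stops the growth). A deletion that would
#' empty the chromosome is truncated so one symbol survives.
#'
#' @param seq integer vector of gene identifiers (a chromosome string).
#' @param k number of events to apply.
#' @param cfg a [sim_config()]; `n` must bound the gene identifiers.
#' @return the evolved chromosome string.
#' @export
evolve_chromosome <- function(seq, k, cfg) {
  if (length(seq) == 0L) stop("'seq' must be non-empty")
  if (k < 0L) stop("'k' must be >= 0")
  for (ev in seq_len(k)) {
    L <- length(seq)
    isdup <- stats::runif(1) < cfg$dup_prob
    p <- sample.int(L, 1L)
    t <- 1L
    if (isdup) {
      while (p + t - 1L < L && stats::runif(1) > cfg$r) t <- t + 1L
      seq <- append(seq, seq[p:(p + t - 1L)], after = p + t - 1L)
    } else {
      tot <- tabulate(seq, nbins = cfg$n)
      if (tot[seq[p]] == 1L && stats::runif(1) >= cfg$q) next  # start guard
      inrange <- integer(cfg$n)
      inrange[seq[p]] <- 1L
      killing <- tot[seq[p]] == 1L
      while (p + t - 1L < L) {
        if (stats::runif(1) <= cfg$r) break
        g <- seq[p + t]
        kills <- inrange[g] + 1L == tot[g]
        if ((kills || killing) && stats::runif(1) >= cfg$q) break
        if (kills) killing <- TRUE
        inrange[g] <- inrange[g] + 1L
        t <- t + 1L
      }
      if (p == 1L && t == L) t <- L - 1L   # keep at least one symbol
      if (t > 0L) seq <- seq[-(p:(p + t - 1L))]
    }
  }
  seq
}

#' Copy-number profile of a chromosome string
#'
#' @param seq integer vector of gene identifiers in `1..n`.
#' @param n number of genes.
#' @return integer vector: entry `i` counts the occurrences of gene `i`.
#' @examples
#' cnp_of(c(1, 2, 2, 4), 4)  # 1 2 0 1
#' @export
cnp_of <- function(seq, n) {
  seq <- as.integer(seq)
  if (length(seq) > 0L && (any(seq < 1L) || any(seq > n)))
    stop("gene identifiers must lie in 1..n")
  tabulate(seq, nbins = n)
}

#' Simulate one clone phylogeny with leaf profiles
#'
#' Samples a uniform rooted binary tree, assigns the exemplar chromosome
#' (each gene once, in order) to the root, evolves every branch top-down
#' with a random number of events, and extracts the copy-number profile of
#' each leaf. Noise is not applied here; see [add_noise()].
#'
#' @param cfg a [sim_config()]. If `cfg$seed` is set, the RNG is seeded for
#'   a fully reproducible instance.
#' @return a list: `tree` (`phylo`, tips `"1".."l"`), `profiles` (integer
#'   matrix `l x n`, rownames = tip labels), `sequences` (leaf chromosome
#'   strings), `event_counts` (per-edge realized event counts, in
#'   `tree$edge` order), and `config`.
#' @export
simulate_instance <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- sample_tree(cfg$l)
  l <- cfg$l
  nnode <- l + tree$Nnode
  seqs <- vector("list", nnode)
  seqs[[l + 1L]] <- seq_len(cfg$n)         # exemplar chromosome at the root
  ecount <- integer(nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {     # cladewise: parents first
    par <- tree$edge[i, 1L]; chd <- tree$edge[i, 2L]
    k <- sample_branch_event_count(cfg)
    ecount[i] <- k
    seqs[[chd]] <- evolve_chromosome(seqs[[par]], k, cfg)
  }
  profiles <- t(vapply(seq_len(l), function(i) cnp_of(seqs[[i]], cfg$n),
                       integer(cfg$n)))
  rownames(profiles) <- tree$tip.label
  list(tree = tree, profiles = profiles,
       sequences = seqs[seq_len(l)], event_counts = ecount, config = cfg)
}

#' Perturb a profile with multiplicative measurement noise
#'
#' Each entry is redrawn from `Normal(u_i, alpha * u_i)`, rounded to the
#' nearest integer and clamped at 0. Null positions have zero standard
#' deviation and stay null.
#'
#' @param u integer profile.
#' @param alpha noise rate, >= 0.
#' @return the noisy profile.
#' @export
add_noise <- function(u, alpha) {
  u <- as_cnp(u)
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (alpha == 0) return(u)
  as.integer(pmax(round(stats::rnorm(length(u), mean = u, sd = alpha * u)), 0))
}
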