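# From leaf profiles to trees: pairwise distance matrices, neighbor-joining,
# and scoring against the true tree with the normalized Robinson-Foulds
# distance.

#' Pairwise symmetrized distance matrix
#'
#' Entry `(i, j)` is [symmetric_distance()] between profiles `i` and `j`;
#' the matrix is symmetric with a zero diagonal.
#'
#' @param profiles integer matrix, one profile per row, rownames = sample
#'   ids (generated if missing).
#' @param method `"heuristic"`, `"flat"`, `"zzs"` or `"euclidean"`.
#' @return a numeric `l x l` matrix with dimnames.
#' @export
distance_matrix <- function(profiles,
                            method = c("heuristic", "flat", "zzs", "euclidean")) {
  method <- match.arg(method)
  if (is.null(dim(profiles))) stop("'profiles' must be a matrix")
  storage.mode(profiles) <- "integer"
  if (any(is.na(profiles)) || any(profiles < 0L))
    stop("profiles must contain non-negative integers")
  if (nrow(profiles) < 2L) stop("need at least two profiles")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("s", seq_len(nrow(profiles)))
  D <- if (method == "euclidean") {
    as.matrix(stats::dist(profiles))
  } else {
    pairwise_cpp(profiles, method_codes[[method]])
  }
  dimnames(D) <- list(rownames(profiles), rownames(profiles))
  D
}

phylip_names <- function(nm) {
  out <- substr(nm, 1L, 10L)
  if (anyDuplicated(out)) {
    for (g in unique(out[duplicated(out)])) {
      idx <- which(out == g)
      suf <- sprintf("_%02d", seq_along(idx))
      out[idx] <- paste0(substr(nm[idx], 1L, 10L - nchar(suf)), suf)
    }
    if (anyDuplicated(out))
      stop("sample names collide after truncation to 10 characters")
  }
  out
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line: the number of samples; then one row per sample with the name
#' padded to 10 characters followed by the distances. Names longer than 10
#' characters are truncated, with uniqueness enforced by numeric suffixes.
#'
#' @param m square numeric matrix with dimnames.
#' @param path output file; if `NULL`, the lines are returned invisibly
#'   instead of written.
#' @return the lines, invisibly.
#' @export
write_phylip <- function(m, path = NULL) {
  if (nrow(m) != ncol(m)) stop("'m' must be square")
  nm <- rownames(m)
  if (is.null(nm) || any(!nzchar(nm))) stop("'m' needs non-empty rownames")
  nm <- phylip_names(nm)
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste0(formatC(nm[i], width = -10),
                      paste(sprintf("%.6f", m[i, ]), collapse = " ")), ""))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a PHYLIP square distance matrix
#'
#' @param x a file path, or a character vector of lines.
#' @return a numeric matrix with dimnames.
#' @export
read_phylip <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  l <- as.integer(trimws(lines[[1L]]))
  if (is.na(l) || length(lines) != l + 1L)
    stop("malformed PHYLIP matrix: bad sample count")
  nm <- character(l)
  m <- matrix(NA_real_, l, l)
  for (i in seq_len(l)) {
    ln <- lines[[i + 1L]]
    nm[i] <- trimws(substr(ln, 1L, 10L))
    vals <- as.numeric(strsplit(trimws(substring(ln, 11L)), "\\s+")[[1L]])
    if (length(vals) != l || any(is.na(vals)))
      stop(sprintf("malformed PHYLIP matrix: row %d", i))
    m[i, ] <- vals
  }
  dimnames(m) <- list(nm, nm)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); the result is an
#' unrooted binary tree. Negative branch lengths are retained — they do not
#' affect topological comparison.
#'
#' @param m symmetric distance matrix with dimnames.
#' @return an unrooted `phylo` object.
#' @export
neighbor_joining <- function(m) {
  if (nrow(m) < 3L) stop("neighbor-joining needs at least 3 samples")
  ape::nj(as.matrix(m))
}

#' Normalized Robinson-Foulds distance between two trees
#'
#' Both trees are unrooted and their bipartitions compared; the symmetric
#' difference count is divided by `2 (l - 3)`, the maximum possible for `l`
#' leaves, giving a value in `[0, 1]`.
#'
#' @param true_tree,inferred `phylo` objects on the same leaf set
#'   (`l >= 4`).
#' @return a number in `[0, 1]`; 0 means identical topologies.
#' @export
normalized_rf <- function(true_tree, inferred) {
  if (!setequal(true_tree$tip.label, inferred$tip.label))
    stop("trees must share the same leaf set")
  l <- length(true_tree$tip.label)
  if (l < 4L) stop("normalized RF needs at least 4 leaves")
  t1 <- ape::unroot(true_tree)
  t2 <- ape::unroot(inferred)
  as.numeric(phangorn::RF.dist(t1, t2, normalize = FALSE)) / (2 * (l - 3))
}

#' Run the simulation / reconstruction / scoring experiment grid
#'
#' For every parameter combination and replicate: simulate an instance, add
#' measurement noise if `alpha > 0`, build the distance matrix for each
#' method, reconstruct a neighbor-joining tree and score it against the true
#' tree with the normalized Robinson-Foulds distance.
#'
#' @param grid a data frame whose columns are [sim_config()] argument names
#'   (missing columns take the defaults); one row per combination.
#' @param replicates number of independent replicates per combination.
#' @param methods distance methods to evaluate.
#' @param seed integer seed for the whole experiment; per-replicate streams
#'   are split from it deterministically, so results do not depend on which
#'   methods are evaluated.
#' @return a list with `records` (one row per combination x replicate x
#'   method: parameters, `replicate`, `method`, `rf`, `note`) and `summary`
#'   (per combination x method: mean and quartiles of the RF distance).
#' @export
run_experiment <- function(grid = data.frame(), replicates = 10L,
                           methods = c("heuristic", "flat", "zzs", "euclidean"),
                           seed = 1L) {
  if (nrow(grid) == 0L) grid <- data.frame(row.names = 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  records <- list()
  for (ci in seq_len(nrow(grid))) {
    args <- as.list(grid[ci, setdiff(colnames(grid), "seed"), drop = FALSE])
    cfg0 <- do.call(sim_config, args)
    for (rep in seq_len(replicates)) {
      sub_seed <- (as.integer(seed) %% 100000L) * 20011L + ci * 4001L + rep
      set.seed(sub_seed)
      inst <- simulate_instance(cfg0)
      prof <- inst$profiles
      if (cfg0$alpha > 0)
        prof <- t(apply(prof, 1L, add_noise, alpha = cfg0$alpha))
      rownames(prof) <- rownames(inst$profiles)
      for (method in methods) {
        rf <- NA_real_; note <- ""
        res <- tryCatch({
          D <- distance_matrix(prof, method)
          if (max(D) == 0) {
            note <- "degenerate: all distances zero"
          } else {
            rf <- normalized_rf(inst$tree, neighbor_joining(D))
          }
          NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(res)) note <- res
        rec <- cbind(as.data.frame(cfg0[c("l", "n", "e_min", "e_max",
                                          "dup_prob", "r", "q", "alpha")]),
                     data.frame(combination = ci, replicate = rep,
                                method = method, rf = rf, note = note,
                                stringsAsFactors = FALSE))
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  summary <- do.call(rbind, lapply(
    split(records, list(records$combination, records$method), drop = TRUE),
    function(g) {
      qs <- stats::quantile(g$rf, c(0.25, 0.5, 0.75), na.rm = TRUE)
      data.frame(combination = g$combination[1L], method = g$method[1L],
                 n_ok = sum(!is.na(g$rf)), mean_rf = mean(g$rf, na.rm = TRUE),
                 q25 = qs[[1L]], median = qs[[2L]], q75 = qs[[3L]])
    }))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
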