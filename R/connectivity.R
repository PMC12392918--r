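## Surrogate-based pairwise spike synchrony, functional connection
## graphs, and normalized connection strength (assembloid region-pair
## summaries).

#' Count synchronous spikes between two trains
#'
#' Number of one-to-one matched cross-train spike pairs with
#' `|dt| <= windowMs`. Matching is the maximum one-to-one matching (see
#' [matchedCoincidences()]), so the count never double-counts a spike
#' and is symmetric in its arguments.
#'
#' @param a,b sorted spike-time vectors (s).
#' @param windowMs synchrony window in ms (default 100).
#' @return Integer count.
#' @export
countSynchronous <- function(a, b, windowMs = 100) {
  matchedCoincidences(sort(a), sort(b), windowMs / 1000, inclusive = TRUE)
}

#' ISI-preserving surrogate spike train
#'
#' Returns `first spike time + cumsum(permuted ISIs)`: same length, same
#' first and last spike time, and exactly the original multiset of
#' inter-spike intervals. Trains with fewer than 2 spikes are returned
#' unchanged. Uses the current RNG state.
#'
#' @param train sorted spike-time vector (s).
#' @return Surrogate spike-time vector.
#' @export
surrogateTrain <- function(train) {
  n <- length(train)
  if (n < 2L) return(train)
  isi <- diff(train)
  train[1L] + c(0, cumsum(isi[sample.int(length(isi))]))
}

#' Surrogate z-score of pairwise synchrony
#'
#' Compares the observed synchronous-spike count of a pair against
#' `nSurr` surrogate datasets in which both trains are ISI-shuffled
#' (the stricter null), and returns
#' `z = (observed - mean_surr) / sd_surr`. When the surrogate SD is 0
#' the z-score is `+Inf` / `0` / `-Inf` for observed greater / equal /
#' smaller, flagged degenerate. The RNG substream is derived from
#' `(seed, idA, idB)` so results do not depend on pair iteration order.
#'
#' @param a,b sorted non-empty spike-time vectors (s).
#' @param nSurr number of surrogate datasets (default 100).
#' @param windowMs synchrony window in ms.
#' @param seed integer base seed.
#' @param idA,idB integer pair identity used to derive the substream
#'   (default 1, 2).
#' @return List with `sync_count`, `surrogate_mean`, `surrogate_sd`,
#'   `z_score`, `degenerate`.
#' @export
pairZscore <- function(a, b, nSurr = 100L, windowMs = 100, seed = 1L,
                       idA = 1L, idB = 2L) {
  if (!length(a) || !length(b))
    stop("pair z-score is undefined for an empty train")
  a <- sort(a); b <- sort(b)
  obs <- countSynchronous(a, b, windowMs)
  set.seed(seedOffset(seed, 1000003 * idA + 7919 * idB))
  cnt <- integer(nSurr)
  for (i in seq_len(nSurr))
    cnt[i] <- countSynchronous(surrogateTrain(a), surrogateTrain(b), windowMs)
  m <- mean(cnt); s <- stats::sd(cnt)
  if (is.na(s) || s == 0) {
    z <- if (obs > m) Inf else if (obs < m) -Inf else 0
    deg <- TRUE
  } else {
    z <- (obs - m) / s
    deg <- FALSE
  }
  list(sync_count = obs, surrogate_mean = m, surrogate_sd = s,
       z_score = z, degenerate = deg)
}

#' Z-scores for all soma pairs
#'
#' Computes [pairZscore()] for every unordered pair of trains (or a
#' random subsample of pairs when `maxPairs` is exceeded, drawn
#' reproducibly from `seed`).
#'
#' @param trains list of sorted spike-time vectors (s); empty trains are
#'   skipped.
#' @param nSurr,windowMs,seed see [pairZscore()].
#' @param zThresh connection threshold on z (default 3).
#' @param maxPairs cap on the number of pairs evaluated.
#' @return data.frame with columns `soma_a`, `soma_b`, `sync_count`,
#'   `surrogate_mean`, `surrogate_sd`, `z_score`, `connected`.
#' @export
allPairZscores <- function(trains, nSurr = 100L, windowMs = 100, seed = 1L,
                           zThresh = 3, maxPairs = 200000L) {
  ids <- which(lengths(trains) > 0L)
  if (length(ids) < 2L)
    return(data.frame(soma_a = integer(), soma_b = integer(),
                      sync_count = integer(), surrogate_mean = numeric(),
                      surrogate_sd = numeric(), z_score = numeric(),
                      connected = logical()))
  pr <- t(utils::combn(ids, 2L))
  if (nrow(pr) > maxPairs) {
    set.seed(seedOffset(seed, 555))
    pr <- pr[sample.int(nrow(pr), maxPairs), , drop = FALSE]
    pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  }
  out <- vector("list", nrow(pr))
  for (k in seq_len(nrow(pr))) {
    zs <- pairZscore(trains[[pr[k, 1]]], trains[[pr[k, 2]]], nSurr, windowMs,
                     seed, idA = pr[k, 1], idB = pr[k, 2])
    out[[k]] <- data.frame(soma_a = pr[k, 1], soma_b = pr[k, 2],
                           sync_count = zs$sync_count,
                           surrogate_mean = zs$surrogate_mean,
                           surrogate_sd = zs$surrogate_sd,
                           z_score = zs$z_score,
                           connected = zs$z_score >= zThresh)
  }
  do.call(rbind, out)
}

#' Build the functional connection graph
#'
#' Undirected graph over somas with edges where `z_score >= zThresh`.
#'
#' @param pairs data.frame from [allPairZscores()] (each unordered pair
#'   at most once).
#' @param zThresh connection threshold on z.
#' @param nNodes number of somas (defaults to the largest id seen).
#' @return List with `graph` (igraph), `degrees` (integer per soma),
#'   `meanDegree`, `nEdges`.
#' @export
buildGraph <- function(pairs, zThresh = 3, nNodes = NULL) {
  if (nrow(pairs)) {
    key <- paste(pmin(pairs$soma_a, pairs$soma_b),
                 pmax(pairs$soma_a, pairs$soma_b))
    if (anyDuplicated(key)) stop("duplicate soma pair in input")
    if (any(pairs$soma_a == pairs$soma_b)) stop("self-pair in input")
  }
  if (is.null(nNodes))
    nNodes <- if (nrow(pairs)) max(pairs$soma_a, pairs$soma_b) else 0L
  sel <- pairs[pairs$z_score >= zThresh, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nNodes, directed = FALSE)
  if (nrow(sel))
    g <- igraph::add_edges(g, rbind(sel$soma_a, sel$soma_b))
  deg <- igraph::degree(g)
  list(graph = g, degrees = as.integer(deg),
       meanDegree = if (nNodes) mean(deg) else NA_real_,
       nEdges = igraph::ecount(g))
}

#' Normalized pairwise connection strength
#'
#' Synchronous-spike count normalized by the mean spike count of the
#' pair: `count / ((nA + nB) / 2)`, in `[0, 2]`.
#'
#' @param a,b spike-time vectors (s); at least one non-empty.
#' @param windowMs synchrony window in ms.
#' @return Numeric strength.
#' @export
connectionStrength <- function(a, b, windowMs = 100) {
  nA <- length(a); nB <- length(b)
  if (nA + nB == 0L) stop("connection strength undefined for two empty trains")
  countSynchronous(a, b, windowMs) / ((nA + nB) / 2)
}

#' Region-pair connection strength summaries
#'
#' Mean pairwise [connectionStrength()] over all unordered pairs within
#' each region and across the two regions. A region with fewer than 2
#' somas yields a missing within-region summary.
#'
#' @param trains list of spike-time vectors (s).
#' @param regions character region label per train.
#' @param windowMs synchrony window in ms.
#' @return data.frame with columns `scope`, `region_a`, `region_b`,
#'   `mean_strength`, `n_pairs`.
#' @export
regionStrengths <- function(trains, regions, windowMs = 100) {
  if (length(trains) != length(regions))
    stop("every train needs a region label")
  keep <- lengths(trains) > 0L
  trains <- trains[keep]; regions <- regions[keep]
  regs <- unique(regions)
  rows <- list()
  pairMean <- function(ia, ib = NULL) {
    s <- numeric(); n <- 0L
    if (is.null(ib)) {
      if (length(ia) < 2L) return(c(NA_real_, 0L))
      pr <- utils::combn(ia, 2L)
      for (k in seq_len(ncol(pr)))
        s <- c(s, connectionStrength(trains[[pr[1, k]]], trains[[pr[2, k]]],
                                     windowMs))
    } else {
      for (i in ia) for (j in ib)
        s <- c(s, connectionStrength(trains[[i]], trains[[j]], windowMs))
    }
    c(mean(s), length(s))
  }
  for (r in regs) {
    v <- pairMean(which(regions == r))
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "within", region_a = r, region_b = r,
      mean_strength = v[1], n_pairs = as.integer(v[2]))
  }
  if (length(regs) >= 2L) {
    cmb <- utils::combn(regs, 2L)
    for (k in seq_len(ncol(cmb))) {
      v <- pairMean(which(regions == cmb[1, k]), which(regions == cmb[2, k]))
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "between", region_a = cmb[1, k], region_b = cmb[2, k],
        mean_strength = v[1], n_pairs = as.integer(v[2]))
    }
  }
  do.call(rbind, rows)
}
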