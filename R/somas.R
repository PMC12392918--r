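## Soma identification: merge electrodes whose spike timing coincidences
## and < 50 um proximity indicate they observe the same neuron.

#' Maximum one-to-one spike-time matching count
#'
#' Counts cross-train spike pairs with `|dt|` within `window` seconds,
#' each spike matched at most once. Both trains are scanned in sorted
#' order with a two-pointer sweep, which attains the maximum possible
#' one-to-one matching for a symmetric window and is symmetric in its
#' arguments.
#'
#' @param a,b sorted spike-time vectors (s).
#' @param window coincidence window (s).
#' @param inclusive TRUE for `|dt| <= window` (synchrony analysis),
#'   FALSE for `|dt| < window` (same-count events).
#' @return Integer matched-pair count.
#' @export
matchedCoincidences <- function(a, b, window, inclusive = TRUE) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  i <- 1L; j <- 1L; cnt <- 0L
  while (i <= na && j <= nb) {
    d <- a[i] - b[j]
    hit <- if (inclusive) abs(d) <= window else abs(d) < window
    if (hit) {
      cnt <- cnt + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  cnt
}

#' Identify somas by merging co-active nearby electrodes
#'
#' For each electrode pair closer than `mergeUm`, the same-count is the
#' number of one-to-one matched cross-electrode spike pairs with
#' inter-spike interval below `isiMs`. A pair qualifies as somatic when
#' `same_count >= minSame` and `same_count / min(nA, nB) >= minFrac`.
#' Qualifying pairs form edges of a merge graph; connected components
#' become somas. Soma position is the spike-count-weighted centroid of
#' member electrodes; the soma spike train is the union of member events
#' with events within 1 ms collapsed to the earliest. Spikes inside
#' `burstWindows` are excluded before pairing (network bursts would
#' otherwise produce spurious coincidences between distinct neurons).
#' Somas arise only from qualifying pairs; when no pair qualifies
#' anywhere in the recording, spiking electrodes with at least
#' `minSpikes` events fall back to singleton somas.
#'
#' @param eventsByElectrode list (length = electrodes) of sorted spike
#'   time vectors (s).
#' @param grid the [ElectrodeGrid-class].
#' @param isiMs same-count window in ms (pairs with `|dt| < isiMs`).
#' @param minSame minimum same-count for a putative somatic pair.
#' @param minFrac minimum `same_count / min(nA, nB)`.
#' @param mergeUm maximum electrode distance for merging (um).
#' @param burstWindows optional data.frame (`start_s`, `end_s`) of
#'   network bursts whose spikes are excluded.
#' @param minSpikes singleton-soma floor (events).
#' @param dedupMs spike-train deduplication window (ms).
#' @return A [SomaSet-class].
#' @export
identifySomas <- function(eventsByElectrode, grid, isiMs = 10, minSame = 5L,
                          minFrac = 0.15, mergeUm = 50, burstWindows = NULL,
                          minSpikes = 5L, dedupMs = 1) {
  nE <- nElectrodes(grid)
  if (length(eventsByElectrode) != nE)
    stop("eventsByElectrode must have one entry per grid electrode")
  ev <- eventsByElectrode
  evAll <- ev                              # full trains (kept for output)
  if (!is.null(burstWindows) && nrow(burstWindows))
    for (e in seq_len(nE))
      if (length(ev[[e]])) ev[[e]] <- ev[[e]][!inWindows(ev[[e]], burstWindows)]
  counts <- lengths(ev)
  active <- which(counts > 0L)
  win <- isiMs / 1000

  ## candidate pairs: active electrodes within mergeUm (grid neighborhood)
  edges <- matrix(integer(), 0L, 2L)
  if (length(active) > 1L) {
    rc <- electrodeRowCol(grid, active)
    span <- floor(mergeUm / grid@pitchUm)
    pairsA <- integer(); pairsB <- integer()
    ord <- order(rc[, "row"], rc[, "col"])
    act <- active[ord]; rca <- rc[ord, , drop = FALSE]
    for (u in seq_along(act)) {
      if (u == length(act)) break
      for (v in seq.int(u + 1L, length(act))) {
        dr <- rca[v, 1] - rca[u, 1]
        if (dr > span) break
        if (abs(rca[v, 2] - rca[u, 2]) > span) next
        if (electrodeDistanceUm(grid, act[u], act[v]) >= mergeUm) next
        pairsA <- c(pairsA, act[u]); pairsB <- c(pairsB, act[v])
      }
    }
    if (length(pairsA)) {
      qual <- logical(length(pairsA))
      for (k in seq_along(pairsA)) {
        a <- ev[[pairsA[k]]]; b <- ev[[pairsB[k]]]
        sc <- matchedCoincidences(a, b, win, inclusive = FALSE)
        qual[k] <- sc >= minSame && sc / min(length(a), length(b)) >= minFrac
      }
      edges <- cbind(pairsA[qual], pairsB[qual])
    }
  }

  ## connected components over qualifying edges
  comp <- seq_len(nE)                      # union-find
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  if (nrow(edges))
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) comp[rb] <- ra
    }
  merged <- unique(as.vector(edges))
  groups <- list()
  if (length(merged)) {
    roots <- vapply(merged, find, integer(1))
    groups <- split(merged, roots)
  } else {
    ## no qualifying pair anywhere: fall back to singleton somas for
    ## spiking electrodes that pass the minimum-spikes floor
    groups <- as.list(active[counts[active] >= minSpikes])
  }

  if (!length(groups)) {
    return(new("SomaSet",
               table = data.frame(soma_id = integer(), x_um = numeric(),
                                  y_um = numeric(), n_spikes = integer(),
                                  n_electrodes = integer(),
                                  member_electrodes = character()),
               trains = list(), members = list(), grid = grid))
  }

  ## order somas by position for stable ids
  cent <- t(vapply(groups, function(g) {
    w <- counts[g]
    if (sum(w) == 0) w <- rep(1, length(g))
    p <- electrodePositions(grid, g)
    c(sum(p[, 1] * w), sum(p[, 2] * w)) / sum(w)
  }, numeric(2)))
  ord <- order(cent[, 2], cent[, 1])
  groups <- groups[ord]; cent <- cent[ord, , drop = FALSE]

  dedup <- dedupMs / 1000
  trains <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    tt <- sort(unlist(evAll[groups[[i]]], use.names = FALSE))
    if (length(tt) > 1L) {
      keep <- c(TRUE, logical(length(tt) - 1L))
      last <- tt[1]
      for (k in 2:length(tt)) {
        if (tt[k] - last >= dedup) { keep[k] <- TRUE; last <- tt[k] }
      }
      tt <- tt[keep]
    }
    trains[[i]] <- tt
  }
  tab <- data.frame(
    soma_id = seq_along(groups),
    x_um = cent[, 1], y_um = cent[, 2],
    n_spikes = lengths(trains),
    n_electrodes = lengths(groups),
    member_electrodes = vapply(groups, function(g)
      paste(sort(g), collapse = ";"), character(1)))
  new("SomaSet", table = tab, trains = trains,
      members = lapply(groups, function(g) sort(as.integer(g))), grid = grid)
}

#' Split a recording-level spike table by electrode
#'
#' @param spikes spike data.frame from [detectSpikesRecording()].
#' @param grid the [ElectrodeGrid-class].
#' @return List of sorted spike-time vectors, one per electrode.
#' @export
spikesByElectrode <- function(spikes, grid) {
  out <- rep(list(numeric()), nElectrodes(grid))
  if (nrow(spikes)) {
    sp <- split(spikes$time_s, spikes$electrode)
    out[as.integer(names(sp))] <- lapply(sp, sort)
  }
  out
}
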