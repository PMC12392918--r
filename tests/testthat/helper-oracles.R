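# Independent oracles and small fixture builders used across tests.

# Maximum bipartite matching count between two spike trains with
# |dt| <= window, via igraph (independent of the package's two-pointer
# matcher).
oracleMatchCount <- function(a, b, window) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  edges <- integer()
  for (i in seq_len(na)) {
    js <- which(abs(b - a[i]) <= window)
    if (length(js)) edges <- c(edges, rbind(i, na + js))
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# Random sorted spike train of n spikes over [0, span] seconds.
randTrain <- function(n, span = 60) sort(stats::runif(n, 0, span))

# Homogeneous Poisson train at rate (Hz) over [0, span].
poissonTrain <- function(rate, span) {
  n <- stats::rpois(1L, rate * span)
  sort(stats::runif(n, 0, span))
}

# Small grid for quick tests.
testGrid <- function(nRows = 8, nCols = 8) ElectrodeGrid(nRows, nCols, 10.52)

# Interval Jaccard for event windows.
intervalJaccard <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  uni <- max(a1, b1) - min(a0, b0)
  inter / uni
}
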