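#' Brute-force centrality oracle for tiny graphs
#'
#' Computes a centrality metric from first principles, independently of the
#' edge-parallel engine: all-pairs hop distances come from powers of the
#' adjacency matrix (the smallest `k` with a nonzero walk count is the
#' distance), and every geodesic of every pair is enumerated explicitly by a
#' depth-limited search that only steps to neighbours strictly closer to the
#' target. Betweenness and stress are then literal sums over enumerated paths.
#' Exponential in the worst case; guarded to `n <= 14`. Intended for validating
#' the fast path in tests, not for analysis.
#'
#' @param graph a [net_graph()] with at most 14 nodes.
#' @param metric one of `"bc"`, `"cc"`, `"ec"`, `"sc"`.
#' @return a `centrality_scores` object (unnormalized).
#' @export
oracle_centrality <- function(graph, metric = c("bc", "cc", "ec", "sc")) {
  stopifnot(inherits(graph, "net_graph"))
  metric <- match.arg(tolower(metric), c("bc", "cc", "ec", "sc"))
  if (graph$n > 14L)
    stop("oracle guard: exhaustive enumeration limited to n <= 14, got n = ",
         graph$n)
  g <- oracle_geodesics(graph)
  values <- switch(metric,
    bc = g$bc,
    sc = g$sc,
    cc = apply(g$D, 1L, function(row) {
      dr <- row[is.finite(row) & row > 0]
      if (length(dr)) length(dr) / sum(dr) else 0
    }),
    ec = apply(g$D, 1L, function(row) {
      dr <- row[is.finite(row) & row > 0]
      if (length(dr)) 1 / max(dr) else 0
    })
  )
  new_centrality_scores(toupper(metric), unname(values), graph$node_labels)
}

# Distances (matrix powers), per-pair geodesic counts, and the pair sums
# behind betweenness/stress, all by exhaustive enumeration.
oracle_geodesics <- function(graph) {
  n <- graph$n
  A <- matrix(0, n, n)
  if (graph$m) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  walk <- diag(n)
  for (k in seq_len(max(n - 1L, 0L))) {
    walk <- walk %*% A
    D[is.infinite(D) & walk > 0] <- k
  }

  adj <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  bc <- numeric(n)
  sc <- numeric(n)
  sig <- matrix(0, n, n)

  # all geodesics s -> t: extend only to neighbours one step closer to t
  enum_paths <- function(cur, t, budget, path) {
    if (cur == t) return(list(path))
    nxt <- adj[[cur]][D[adj[[cur]], t] == budget - 1]
    unlist(lapply(nxt, function(w) enum_paths(w, t, budget - 1, c(path, w))),
           recursive = FALSE)
  }

  if (n >= 2) {
    for (s in seq_len(n - 1L)) {
      for (t in seq.int(s + 1L, n)) {
        if (!is.finite(D[s, t])) next
        paths <- enum_paths(s, t, D[s, t], s)
        cnt <- length(paths)
        sig[s, t] <- sig[t, s] <- cnt
        if (D[s, t] >= 2) {
          interior <- tabulate(unlist(lapply(paths, function(p) p[-c(1L, length(p))])),
                               nbins = n)
          sc <- sc + interior
          bc <- bc + interior / cnt
        }
      }
    }
  }
  list(D = D, sigma = sig, bc = bc, sc = sc)
}
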