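METRICS <- c("bc", "cc", "ec", "sc")

#' Compute shortest-path centrality metrics in one APSP pass
#'
#' Streams one edge-parallel BFS per source and accumulates every requested
#' metric on the fly, so asking for several metrics costs one all-pairs pass.
#' Metrics:
#' \describe{
#'   \item{`bc` betweenness}{`BC(u) = sum over unordered pairs {s, t}, s != u != t,
#'     of sigma_st(u) / sigma_st` — the fraction of geodesics between all other
#'     node pairs that pass through `u`. Pairs with no connecting path
#'     contribute 0. Unnormalized by default; with `normalize = TRUE` scores
#'     are divided by `(n - 1)(n - 2) / 2`, the number of pairs.}
#'   \item{`sc` stress}{`SC(u) = sum over unordered pairs of sigma_st(u)` — the
#'     total count of geodesics through `u`; integer-valued (exact while path
#'     counts stay below 2^53).}
#'   \item{`cc` closeness}{reciprocal of the mean hop distance from `u` to the
#'     nodes reachable from it; 0 for an isolated node.}
#'   \item{`ec` eccentricity}{reciprocal of the maximum hop distance from `u`
#'     to any reachable node; 0 for an isolated node.}
#' }
#' Pair counting is unordered: directed per-source dependencies are summed over
#' all sources and halved, the standard convention for undirected graphs. On
#' disconnected graphs closeness and eccentricity consider reachable nodes
#' only.
#'
#' @param graph a [net_graph()].
#' @param metrics non-empty character subset of `c("bc", "cc", "ec", "sc")`.
#' @param normalize logical; normalize betweenness by the pair count (other
#'   metrics are unaffected).
#' @param engine `"vec"` or `"ref"`, see [bfs_edge_parallel()].
#' @return a named list (one element per requested metric, in `metrics` order)
#'   of `centrality_scores` objects: `metric`, `values` (named numeric in node
#'   order), `normalized`.
#' @examples
#' g <- net_graph(cbind(c("a", "b"), c("b", "c")))
#' compute_all(g, "bc")$bc$values # a=0 b=1 c=0
#' @export
compute_all <- function(graph, metrics = METRICS, normalize = FALSE,
                        engine = c("vec", "ref")) {
  stopifnot(inherits(graph, "net_graph"))
  engine <- match.arg(engine)
  metrics <- tolower(as.character(metrics))
  if (length(metrics) == 0L) stop("`metrics` must name at least one metric")
  bad <- setdiff(metrics, METRICS)
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(METRICS, collapse = ", "), ")")
  metrics <- unique(metrics)

  n <- graph$n
  arrays <- build_edge_arrays(graph)
  need_dep <- any(c("bc", "sc") %in% metrics)

  bc <- numeric(n)
  sc <- numeric(n)
  cc <- numeric(n)
  ec <- numeric(n)

  for (s in seq_len(n)) {
    r <- bfs_edge_parallel(arrays, s, engine = engine)
    if (need_dep) {
      r <- accumulate_dependencies(r, arrays, engine = engine)
      r$delta[s] <- 0   # the source's own accumulator carries no meaning
      r$npaths[s] <- 0
      bc <- bc + r$delta
      sc <- sc + r$sigma * r$npaths
    }
    if (any(c("cc", "ec") %in% metrics)) {
      dr <- r$d[is.finite(r$d) & r$d > 0]
      if (length(dr)) {
        cc[s] <- length(dr) / sum(dr)
        ec[s] <- 1 / max(dr)
      } # else both stay 0: nothing reachable from s
    }
  }
  bc <- bc / 2 # each unordered pair was seen from both endpoints
  sc <- sc / 2
  if (normalize && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)

  vals <- list(bc = bc, cc = cc, ec = ec, sc = sc)
  out <- lapply(metrics, function(mt) {
    new_centrality_scores(toupper(mt), vals[[mt]], graph$node_labels,
                          normalized = (mt == "bc") && normalize)
  })
  names(out) <- metrics
  out
}

new_centrality_scores <- function(metric, values, labels, normalized = FALSE) {
  names(values) <- labels
  structure(list(metric = metric, values = values, normalized = normalized),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("<centrality_scores> %s (%s), %d node(s)\n", x$metric,
              if (x$normalized) "normalized" else "unnormalized",
              length(x$values)))
  if (length(x$values)) print(utils::head(x$values, 10L))
  invisible(x)
}

#' @rdname compute_all
#' @export
betweenness <- function(graph, normalize = FALSE, engine = c("vec", "ref")) {
  compute_all(graph, "bc", normalize = normalize, engine = engine)$bc
}

#' @rdname compute_all
#' @export
closeness <- function(graph, engine = c("vec", "ref")) {
  compute_all(graph, "cc", engine = engine)$cc
}

#' @rdname compute_all
#' @export
eccentricity <- function(graph, engine = c("vec", "ref")) {
  compute_all(graph, "ec", engine = engine)$ec
}

#' @rdname compute_all
#' @export
stress <- function(graph, engine = c("vec", "ref")) {
  compute_all(graph, "sc", engine = engine)$sc
}

#' Write a centrality table as TSV
#'
#' First line is the comment header `# metric=<BC|CC|EC|SC>
#' normalized=<true|false>`, then one `node<TAB>score` row per node in input
#' node order, scores at full double precision.
#'
#' @param scores a `centrality_scores` object from [compute_all()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "centrality_scores"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# metric=%s normalized=%s", scores$metric,
                     if (scores$normalized) "true" else "false"), con)
  if (length(scores$values)) {
    writeLines(sprintf("%s\t%.17g", names(scores$values), scores$values), con)
  }
  invisible(path)
}
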