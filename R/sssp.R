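#' Single-source BFS with the edge-parallel, frontier-synchronous kernel
#'
#' Computes hop distances `d`, shortest-path counts `sigma` and per-edge-slot
#' shortest-path flags from one source, proceeding in synchronized levels: at
#' level `t` every edge slot `(u, v)` with `d[u] == t` and `d[v]` unset settles
#' `v` at `t + 1`; a second sweep over the finished level accumulates
#' `sigma[v] <- sigma[v] + sigma[u]` over all such slots and raises
#' `pred_flag[k]` on every slot `k` with `d[tail[k]] == d[head[k]] + 1`.
#' The loop terminates when a level produces no update. Because a node's
#' distance is set exactly once, the result is independent of the order in
#' which slots are examined — the defining property of the one-work-item-per-
#' edge parallel decomposition this kernel mirrors.
#'
#' Two interchangeable engines implement the same contract: `"vec"`, a
#' compiled whole-array kernel scanning all `l` slots per level, and `"ref"`, a
#' literal per-edge-slot R loop. They are required (and tested) to produce
#' identical output.
#'
#' @param arrays an [build_edge_arrays()] object.
#' @param source node index in `[1, n]`.
#' @param engine `"vec"` (compiled, default) or `"ref"` (reference R loop).
#' @return an object of class `sssp_result`: `source`; `d`, numeric length-`n`
#'   hop distances with `Inf` marking unreachable nodes; `sigma`, numeric
#'   geodesic counts (exact below 2^53); `pred_flag`, logical length-`l`;
#'   `delta`, numeric length-`n`, zero-initialized (see
#'   [accumulate_dependencies()]); `levels`, the number of frontier expansions
#'   performed, which equals the eccentricity of `source` within its component.
#' @examples
#' g <- net_graph(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a"))) # 4-cycle
#' r <- bfs_edge_parallel(build_edge_arrays(g), source = 1)
#' r$d     # 0 1 2 1
#' r$sigma # 1 1 2 1
#' @export
bfs_edge_parallel <- function(arrays, source, engine = c("vec", "ref")) {
  stopifnot(inherits(arrays, "edge_arrays"))
  engine <- match.arg(engine)
  n <- arrays$n
  if (!is.numeric(source) || length(source) != 1L || is.na(source) ||
      source < 1 || source > n || source != floor(source))
    stop("`source` must be a node index in [1, ", n, "]")
  source <- as.integer(source)

  res <- if (engine == "vec") {
    .Call(C_bfs_edge_parallel, arrays$head, arrays$tail, n, source)
  } else {
    ref_bfs(arrays$head, arrays$tail, n, source)
  }
  structure(
    list(source = source, d = res$d, sigma = res$sigma,
         pred_flag = res$pred_flag, delta = numeric(n), levels = res$levels),
    class = "sssp_result"
  )
}

# Reference engine: a literal transliteration of the per-edge kernel, one R
# iteration per edge slot per level. Kept deliberately naive; used to certify
# the compiled engine on small inputs.
ref_bfs <- function(head, tail, n, source) {
  l <- length(head)
  d <- rep(Inf, n)
  sigma <- numeric(n)
  pred <- logical(l)
  d[source] <- 0
  sigma[source] <- 1
  t <- 0
  levels <- 0L
  repeat {
    updated <- FALSE
    for (k in seq_len(l)) {
      u <- head[k]
      v <- tail[k]
      if (d[u] == t && is.infinite(d[v])) {
        d[v] <- t + 1
        updated <- TRUE
      }
    }
    if (!updated) break
    for (k in seq_len(l)) {
      u <- head[k]
      v <- tail[k]
      if (d[u] == t && d[v] == t + 1) {
        sigma[v] <- sigma[v] + sigma[u]
        pred[k] <- TRUE
      }
    }
    levels <- levels + 1L
    t <- t + 1
  }
  list(d = d, sigma = sigma, pred_flag = pred, levels = levels)
}

#' Brandes dependency back-propagation
#'
#' Fills the `delta` field of an [bfs_edge_parallel()] result by processing
#' levels in decreasing distance: for every flagged slot `(u, v)`,
#' `delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])`. On
#' completion `delta[v]` equals the source's betweenness dependency
#' `sum over targets t of sigma_st(v) / sigma_st`; the value accumulated at the
#' source itself is meaningless and ignored by consumers. The same sweep also
#' fills `npaths`, the number of geodesic continuations below each node
#' (`npaths[u] <- npaths[u] + 1 + npaths[v]` per flagged slot), from which the
#' stress contribution of the source is `sigma * npaths`.
#'
#' @param result an `sssp_result` with `delta` still all zero.
#' @param arrays the [build_edge_arrays()] object the result was computed from.
#' @param engine `"vec"` (compiled) or `"ref"` (reference R loop).
#' @return `result` with `delta` and `npaths` filled.
#' @examples
#' g <- net_graph(cbind(c("a", "b"), c("b", "c")))
#' a <- build_edge_arrays(g)
#' r <- accumulate_dependencies(bfs_edge_parallel(a, 1), a)
#' r$delta # 0 1 0 at nodes a, b, c (delta at the source is ignored)
#' @export
accumulate_dependencies <- function(result, arrays, engine = c("vec", "ref")) {
  stopifnot(inherits(result, "sssp_result"), inherits(arrays, "edge_arrays"))
  engine <- match.arg(engine)
  if (!all(result$delta == 0))
    stop("contract violation: `delta` must be zero-initialized")
  acc <- if (engine == "vec") {
    .Call(C_accumulate_dependencies, result$d, result$sigma, result$pred_flag,
          arrays$head, arrays$tail)
  } else {
    ref_accumulate(result$d, result$sigma, result$pred_flag,
                   arrays$head, arrays$tail)
  }
  result$delta <- acc$delta
  result$npaths <- acc$npaths
  result
}

ref_accumulate <- function(d, sigma, pred, head, tail) {
  n <- length(d)
  l <- length(head)
  delta <- numeric(n)
  npaths <- numeric(n)
  finite <- d[is.finite(d)]
  maxd <- if (length(finite)) max(finite) else 0
  t <- maxd
  while (t >= 1) {
    for (k in seq_len(l)) {
      if (pred[k] && d[tail[k]] == t) {
        u <- head[k]
        v <- tail[k]
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
        npaths[u] <- npaths[u] + 1 + npaths[v]
      }
    }
    t <- t - 1
  }
  list(delta = delta, npaths = npaths)
}

#' @export
print.sssp_result <- function(x, ...) {
  nreach <- sum(is.finite(x$d)) - 1L
  cat(sprintf("<sssp_result> source %d: %d reachable node(s), eccentricity %d\n",
              x$source, nreach, x$levels))
  invisible(x)
}

#' All-pairs shortest paths as a per-source stream
#'
#' Runs [bfs_edge_parallel()] from every source in index order and applies
#' `FUN` to each `sssp_result` as it is produced, so only one per-source result
#' (O(n + l) memory) is live at a time. With the default `FUN`, the full list
#' of results is returned — only do that on small graphs.
#'
#' @param arrays an [build_edge_arrays()] object.
#' @param FUN function applied to each per-source `sssp_result`; its return
#'   values are collected in a list. Use a reducing `FUN` (or one returning
#'   `NULL`) to keep memory flat.
#' @param engine `"vec"` or `"ref"`, see [bfs_edge_parallel()].
#' @param sources integer vector of source indices, default all of `1:n`.
#' @return invisibly, the list of `FUN` values in source order.
#' @examples
#' g <- net_graph(cbind(c("a", "b"), c("b", "c")))
#' D <- do.call(rbind, apsp(build_edge_arrays(g), FUN = function(r) r$d))
#' D # symmetric 3 x 3 hop-distance matrix
#' @export
apsp <- function(arrays, FUN = identity, engine = c("vec", "ref"),
                 sources = NULL) {
  stopifnot(inherits(arrays, "edge_arrays"))
  engine <- match.arg(engine)
  if (is.null(sources)) sources <- seq_len(arrays$n)
  out <- vector("list", length(sources))
  for (i in seq_along(sources)) {
    out[[i]] <- FUN(bfs_edge_parallel(arrays, sources[i], engine = engine))
  }
  invisible(out)
}
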