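#' Construct an undirected simple graph from labelled edges
#'
#' A `net_graph` is an undirected, unweighted simple graph: unique string node
#' labels mapped to contiguous 1-based indices, and a set of unordered label
#' pairs as edges. Self-loops are rejected and duplicate edges (in either
#' orientation) collapse to one.
#'
#' @param edges a two-column character matrix or data frame of edge endpoint
#'   labels, or `NULL` for an edgeless graph. Extra columns are ignored.
#' @param nodes character vector of node labels fixing the index order; labels
#'   appearing only in `edges` are appended in first-seen order (first column
#'   before second, row by row).
#' @return an object of class `net_graph` with fields `node_labels` (character,
#'   length `n`), `edges` (`m` x 2 integer matrix of node indices, each row
#'   `i < j`), `n` and `m`.
#' @examples
#' g <- net_graph(cbind(c("a", "b"), c("b", "c")))
#' g$n # 3
#' g$m # 2
#' @export
net_graph <- function(edges = NULL, nodes = character()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  if (is.null(edges) || NROW(edges) == 0L) {
    return(new_net_graph(nodes, matrix(integer(), 0L, 2L)))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("`edges` needs two columns of endpoint labels")
  a <- as.character(edges[, 1L])
  b <- as.character(edges[, 2L])
  if (anyNA(a) || anyNA(b)) stop("edge endpoints must be non-missing labels")
  loop <- a == b
  if (any(loop)) {
    stop("self-loop not allowed: ", a[which(loop)[1L]], "--", b[which(loop)[1L]])
  }
  labels <- unique(c(nodes, as.vector(t(cbind(a, b)))))
  ia <- match(a, labels)
  ib <- match(b, labels)
  em <- cbind(pmin(ia, ib), pmax(ia, ib))
  em <- em[!duplicated(em), , drop = FALSE]
  new_net_graph(labels, em)
}

new_net_graph <- function(labels, edge_matrix) {
  storage.mode(edge_matrix) <- "integer"
  dimnames(edge_matrix) <- NULL
  structure(
    list(node_labels = labels, edges = edge_matrix,
         n = length(labels), m = nrow(edge_matrix)),
    class = "net_graph"
  )
}

#' @export
print.net_graph <- function(x, ...) {
  cat(sprintf("<net_graph> %d nodes, %d undirected edges\n", x$n, x$m))
  invisible(x)
}

#' Read an undirected graph from an edge-list text file
#'
#' Each non-blank, non-comment line names one edge as two whitespace- or
#' tab-separated node labels; extra tokens on a line are ignored with a
#' warning. Duplicate edge lines (in either orientation) collapse silently to
#' one edge. Nodes are indexed in first-seen order. An empty file yields an
#' empty graph; a self-loop line is an error naming the offending line.
#'
#' @param path path to the edge-list file.
#' @param comment_prefix lines starting with this prefix (after leading
#'   whitespace) are skipped. Default `"#"`.
#' @return a [net_graph()].
#' @seealso [write_edgelist()]
#' @export
load_edgelist <- function(path, comment_prefix = "#") {
  if (!file.exists(path))
    stop("cannot open edge-list file '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, comment_prefix)
  lineno <- which(keep)
  if (length(lineno) == 0L) return(net_graph())
  toks <- strsplit(trimmed[keep], "[ \t]+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    stop(sprintf("line %d of '%s': expected two node labels, found %d token(s)",
                 lineno[which(nt < 2L)[1L]], path, min(nt)))
  }
  if (any(nt > 2L)) {
    warning(sprintf("%d line(s) with extra tokens in '%s'; only the first two are used",
                    sum(nt > 2L), path))
  }
  a <- vapply(toks, `[`, character(1), 1L)
  b <- vapply(toks, `[`, character(1), 2L)
  loop <- a == b
  if (any(loop)) {
    stop(sprintf("line %d of '%s': self-loop '%s %s' not allowed",
                 lineno[which(loop)[1L]], path, a[which(loop)[1L]], b[which(loop)[1L]]))
  }
  net_graph(cbind(a, b))
}

#' Write a graph as an edge-list text file
#'
#' One line per undirected edge, the two endpoint labels tab-separated; each
#' unordered pair is written once. Round-tripping through [load_edgelist()]
#' reproduces the node-label set and the edge set exactly.
#'
#' @param graph a [net_graph()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "net_graph"))
  lab <- graph$node_labels
  lines <- if (graph$m > 0L) {
    paste(lab[graph$edges[, 1L]], lab[graph$edges[, 2L]], sep = "\t")
  } else {
    character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert a graph to the two-array edge representation
#'
#' The engine's native format: two parallel integer arrays `head` and `tail`
#' of length `l = 2m`, holding every undirected edge once per direction; slot
#' `k` is the directed slot `(head[k], tail[k])`. Node indices are 1-based.
#'
#' @param graph a [net_graph()].
#' @return an object of class `edge_arrays` with fields `head`, `tail`
#'   (integer, length `l`), `l` and `n`.
#' @examples
#' g <- net_graph(cbind(c("a", "b"), c("b", "c")))
#' build_edge_arrays(g)$l # 4
#' @export
build_edge_arrays <- function(graph) {
  stopifnot(inherits(graph, "net_graph"))
  structure(
    list(head = c(graph$edges[, 1L], graph$edges[, 2L]),
         tail = c(graph$edges[, 2L], graph$edges[, 1L]),
         l = 2L * graph$m, n = graph$n),
    class = "edge_arrays"
  )
}

#' @export
print.edge_arrays <- function(x, ...) {
  cat(sprintf("<edge_arrays> n = %d, l = %d directed edge slots\n", x$n, x$l))
  invisible(x)
}

#' Node degrees
#'
#' @param graph a [net_graph()].
#' @return named integer vector of degrees, in node-index order.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "net_graph"))
  deg <- tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n)
  names(deg) <- graph$node_labels
  deg
}
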