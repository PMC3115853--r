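# Fixture graphs and independent oracles shared across test files.
# Everything here is built in code; no data files.

path3 <- function() net_graph(cbind(c("a", "b"), c("b", "c")))

star4 <- function() net_graph(cbind(rep("c", 3), c("x", "y", "z"))) # center first

cycle_n <- function(n) {
  lab <- sprintf("v%d", seq_len(n))
  net_graph(cbind(lab, lab[c(seq(2, n), 1L)]))
}

complete_n <- function(n) {
  lab <- sprintf("v%d", seq_len(n))
  p <- t(combn(lab, 2L))
  net_graph(p)
}

two_disjoint_edges <- function() net_graph(cbind(c("a", "c"), c("b", "d")))

# Erdos-Renyi G(n, p); independent of the package generator.
random_er <- function(n, p, seed) {
  set.seed(seed)
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pick <- stats::runif(nrow(ij)) < p
  lab <- sprintf("v%d", seq_len(n))
  net_graph(cbind(lab[ij[pick, 1L]], lab[ij[pick, 2L]]), nodes = lab)
}

adjacency_list <- function(graph) {
  a <- build_edge_arrays(graph)
  split(a$tail, factor(a$head, levels = seq_len(graph$n)))
}

# Textbook queue-based serial BFS; the independent distance oracle.
serial_bfs <- function(adj, n, s) {
  d <- rep(Inf, n)
  d[s] <- 0
  q <- integer(n)
  q[1L] <- s
  qh <- 1L
  qt <- 1L
  while (qh <= qt) {
    u <- q[qh]
    qh <- qh + 1L
    nb <- adj[[u]]
    fresh <- nb[is.infinite(d[nb])]
    if (length(fresh)) {
      d[fresh] <- d[u] + 1
      q[qt + seq_along(fresh)] <- fresh
      qt <- qt + length(fresh)
    }
  }
  d
}

is_connected <- function(graph) {
  if (graph$n <= 1L) return(TRUE)
  adj <- adjacency_list(graph)
  all(is.finite(serial_bfs(adj, graph$n, 1L)))
}

edge_key_set <- function(graph) {
  lab <- graph$node_labels
  a <- lab[graph$edges[, 1L]]
  b <- lab[graph$edges[, 2L]]
  sort(paste(pmin(a, b), pmax(a, b)))
}
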