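#' Generate a Barabási–Albert scale-free network
#'
#' Seeded preferential-attachment generator. Growth starts from `beta`
#' isolated seed nodes; the first added node attaches to all of them (resolving
#' the degree-zero bootstrap), and every subsequent node attaches to `beta`
#' distinct existing nodes sampled with probability proportional to current
#' degree. Sampling uses the repeated-endpoints list: each node appears in the
#' pool once per incident edge endpoint, and duplicates drawn for one new node
#' are rejected until `beta` distinct targets are found.
#'
#' Under this convention the edge count is exactly `beta * (n - beta)` and the
#' graph is connected for every seed. The seed fully determines the output;
#' bit-identity with other implementations of the model is not promised, only
#' the structural invariants.
#'
#' @param n number of nodes (>= 2).
#' @param beta number of attachments per new node, `1 <= beta < n`.
#' @param seed integer RNG seed. The caller's RNG state is preserved.
#' @return a [net_graph()] with node labels `"n1" ... "n<n>"` in creation
#'   order.
#' @examples
#' g <- generate_ba(100, 3, seed = 1)
#' g$m # 3 * 97
#' @export
generate_ba <- function(n, beta, seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != floor(n))
    stop("`n` must be an integer >= 2")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 1 || beta != floor(beta))
    stop("`beta` must be an integer >= 1")
  if (beta >= n) stop("`beta` must be smaller than `n`")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number")
  n <- as.integer(n)
  beta <- as.integer(beta)

  m <- beta * (n - beta)
  efrom <- integer(m)
  eto <- integer(m)
  pool <- integer(2L * m) # repeated-endpoints list
  nedge <- 0L
  npool <- 0L

  with_seed(seed, {
    targets <- seq_len(beta) # first added node attaches to all seed nodes
    for (v in seq.int(beta + 1L, n)) {
      idx <- nedge + seq_len(beta)
      efrom[idx] <- v
      eto[idx] <- targets
      nedge <- nedge + beta
      pool[npool + seq_len(beta)] <- targets
      pool[npool + beta + seq_len(beta)] <- v
      npool <- npool + 2L * beta
      if (v < n) {
        picked <- integer(0)
        while (length(picked) < beta) {
          draw <- pool[sample.int(npool, beta - length(picked), replace = TRUE)]
          picked <- unique(c(picked, draw))
        }
        targets <- picked
      }
    }
  })

  labels <- sprintf("n%d", seq_len(n))
  net_graph(cbind(labels[efrom], labels[eto]), nodes = labels)
}
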