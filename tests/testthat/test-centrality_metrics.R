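# Worked examples are hand-derived: on the 3-path only {a,c} has an interior
# node; on the star every leaf pair is mediated by the center; on the 4-cycle
# each opposite pair has two geodesics and a given node lies on one of them.

test_that("worked examples: path, star, 4-cycle, K4", {
  g <- path3()
  expect_equal(betweenness(g)$values, c(a = 0, b = 1, c = 0))
  expect_equal(stress(g)$values, c(a = 0, b = 1, c = 0))
  expect_equal(closeness(g)$values, c(a = 2 / 3, b = 1, c = 2 / 3))
  expect_equal(eccentricity(g)$values, c(a = 1 / 2, b = 1, c = 1 / 2))

  g <- star4() # center "c" + leaves x, y, z
  expect_equal(unname(betweenness(g)$values), c(3, 0, 0, 0))
  expect_equal(unname(stress(g)$values), c(3, 0, 0, 0))
  expect_equal(unname(closeness(g)$values), c(1, 3 / 5, 3 / 5, 3 / 5))
  expect_equal(unname(eccentricity(g)$values), c(1, 1 / 2, 1 / 2, 1 / 2))

  g <- cycle_n(4)
  expect_equal(unname(betweenness(g)$values), rep(0.5, 4))
  expect_equal(unname(stress(g)$values), rep(1, 4))
  expect_equal(unname(closeness(g)$values), rep(3 / 4, 4))
  expect_equal(unname(eccentricity(g)$values), rep(1 / 2, 4))

  g <- complete_n(4) # every pair adjacent: no interior vertices anywhere
  expect_equal(unname(betweenness(g)$values), rep(0, 4))
  expect_equal(unname(stress(g)$values), rep(0, 4))
  expect_equal(unname(closeness(g)$values), rep(1, 4))
  expect_equal(unname(eccentricity(g)$values), rep(1, 4))
})

test_that("compute_all matches single-metric calls and validates metrics", {
  g <- random_er(8, 0.4, seed = 5)
  all4 <- compute_all(g)
  expect_named(all4, c("bc", "cc", "ec", "sc"))
  expect_identical(all4$bc$values, betweenness(g)$values)
  expect_identical(all4$cc$values, closeness(g)$values)
  expect_identical(all4$ec$values, eccentricity(g)$values)
  expect_identical(all4$sc$values, stress(g)$values)

  expect_error(compute_all(g, character()), "at least one")
  expect_error(compute_all(g, c("bc", "bogus")), "unknown metric")

  only_bc <- compute_all(cycle_n(4), "bc")
  expect_named(only_bc, "bc")
  expect_equal(unname(only_bc$bc$values), rep(0.5, 4))
})

test_that("betweenness normalization divides by the pair count", {
  g <- star4()
  raw <- betweenness(g)$values
  nrm <- betweenness(g, normalize = TRUE)$values
  expect_equal(nrm, raw / choose(3, 2))
  expect_true(compute_all(g, "bc", normalize = TRUE)$bc$normalized)
  expect_false(compute_all(g, "bc")$bc$normalized)
})

test_that("disconnected graphs: reachable-only averages, isolated nodes score 0", {
  g <- net_graph(cbind(c("a", "b"), c("b", "c")), nodes = c("a", "b", "c", "iso"))
  cc <- closeness(g)$values
  ec <- eccentricity(g)$values
  expect_equal(unname(cc["iso"]), 0)
  expect_equal(unname(ec["iso"]), 0)
  expect_equal(unname(cc["b"]), 1) # averages ignore the unreachable node
  expect_equal(unname(ec["b"]), 1)

  two <- two_disjoint_edges()
  expect_equal(unname(closeness(two)$values), rep(1, 4))
  expect_equal(unname(betweenness(two)$values), rep(0, 4))
})

test_that("oracle equivalence on seeded random graphs", {
  for (seed in 1:15) {
    g <- random_er(5L + (seed %% 8L), 0.4, seed = 4000 + seed)
    fast <- compute_all(g)
    expect_equal(unname(fast$sc$values), unname(oracle_centrality(g, "sc")$values))
    for (mt in c("bc", "cc", "ec")) {
      expect_equal(unname(fast[[mt]]$values), unname(oracle_centrality(g, mt)$values),
                   tolerance = 1e-9)
    }
  }
})

test_that("betweenness agrees with igraph on connected random graphs", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 8, 21)) {
    g <- random_er(12, 0.3, seed = seed)
    if (!is_connected(g)) next
    ig <- igraph::graph_from_edgelist(
      cbind(g$edges[, 1L], g$edges[, 2L]), directed = FALSE)
    expect_equal(unname(betweenness(g)$values),
                 unname(igraph::betweenness(ig, directed = FALSE)),
                 tolerance = 1e-9)
  }
})

test_that("property: conservation, dominance, bounds, symmetry", {
  for (seed in 1:15) {
    g <- random_er(10, 0.4, seed = 5000 + seed)
    res <- compute_all(g)
    bc <- res$bc$values
    sc <- res$sc$values
    cc <- res$cc$values
    ec <- res$ec$values

    expect_true(all(bc >= 0 & sc >= 0))
    expect_true(all(cc >= 0 & cc <= 1 & ec >= 0 & ec <= 1))
    expect_true(all(sc - bc >= -1e-12)) # each pair contributes sigma >= sigma/sigma_st
    leaves <- degrees(g) <= 1L
    expect_equal(unname(bc[leaves]), rep(0, sum(leaves)))
    expect_equal(unname(sc[leaves]), rep(0, sum(leaves)))

    if (is_connected(g) && g$n > 1) {
      D <- do.call(rbind, apsp(build_edge_arrays(g), FUN = function(r) r$d))
      S <- do.call(rbind, apsp(build_edge_arrays(g), FUN = function(r) r$sigma))
      pairs_d <- D[upper.tri(D)]
      pairs_s <- S[upper.tri(S)]
      expect_equal(sum(bc), sum(pairs_d - 1), tolerance = 1e-12)
      expect_equal(sum(sc), sum(pairs_s * (pairs_d - 1)), tolerance = 1e-12)
      # radius >= diameter / 2
      expect_lte(max(1 / ec), 2 * min(1 / ec))
    }
  }
  # vertex-transitive graphs score uniformly on every metric
  for (g in list(cycle_n(6), complete_n(5))) {
    for (s in compute_all(g)) {
      expect_equal(diff(range(s$values)), 0)
    }
  }
})

test_that("score tables serialize with the documented header", {
  f <- withr::local_tempfile()
  s <- betweenness(path3())
  write_scores(s, f)
  lines <- readLines(f)
  expect_equal(lines[1], "# metric=BC normalized=false")
  expect_equal(lines[-1], c("a\t0", "b\t1", "c\t0"))

  write_scores(compute_all(net_graph(), "cc")$cc, f)
  expect_equal(readLines(f), "# metric=CC normalized=false")
})
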