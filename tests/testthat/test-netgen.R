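test_that("DAG generator yields acyclic networks with binomial edge counts", {
  expect_error(generate_dag(1), "at least 2")
  expect_error(generate_dag(10, edge_density = 0), "edge_density")

  # n=2, density=1: the unique saturated acyclic 2-node graph
  net2 <- generate_dag(2, 1, seed = 4)
  expect_equal(nrow(net2$edges), 1L)

  # acyclicity by construction, cross-checked against igraph
  for (s in c(1, 17, 99)) {
    net <- generate_dag(50, 0.08, seed = s)
    expect_false(is.null(grnbench:::topological_order(net)))
    expect_true(igraph::is_dag(as_igraph(net)))
  }

  # binomial oracle: mean edge count over 100 seeds near 0.1 * C(20,2) = 19
  counts <- vapply(1:100, function(s) nrow(generate_dag(20, 0.1, seed = s)$edges),
                   numeric(1))
  se_mean <- sqrt(190 * 0.1 * 0.9 / 100)
  expect_lt(abs(mean(counts) - 19), 3 * se_mean)

  # bit-reproducible
  expect_identical(generate_dag(20, 0.1, seed = 5), generate_dag(20, 0.1, seed = 5))
})

test_that("scale-free generator grows connected heavy-tailed trees", {
  expect_error(generate_scale_free(3, 3), "exceed")
  expect_error(generate_scale_free(10, 0), "at least 1")

  net3 <- generate_scale_free(3, 1, seed = 1)
  expect_equal(nrow(net3$edges), 2L)

  # m=1: tree with n-1 edges, connected undirected skeleton (all seeds)
  for (s in 1:5) {
    net <- generate_scale_free(10, 1, seed = s)
    expect_equal(nrow(net$edges), 9L)
    g <- as_igraph(net)
    expect_true(igraph::is_connected(g, mode = "weak"))
    expect_true(igraph::is_dag(g))
  }

  # heavy tail: max total degree >= 10 at n=500 in at least 95% of 50 seeds
  maxdeg <- vapply(1:50, function(s) {
    net <- generate_scale_free(500, 1, seed = s)
    max(grnbench:::in_degree(net) + grnbench:::out_degree(net))
  }, numeric(1))
  expect_gte(mean(maxdeg >= 10), 0.95)
})

test_that("random network generator matches its binomial edge model", {
  expect_equal(nrow(generate_random(5, 0, seed = 1)$edges), 0L)
  expect_equal(nrow(generate_random(4, 1, seed = 1)$edges), 6L)
  expect_error(generate_random(4, 1.5), "probability")

  counts <- vapply(1:200, function(s) {
    nrow(generate_random(100, 0.02, seed = s)$edges)
  }, numeric(1))
  se_mean <- sqrt(4950 * 0.02 * 0.98 / 200)
  expect_lt(abs(mean(counts) - 99), 3 * se_mean)
})

test_that("subnetwork sampling returns induced, connected subgraphs", {
  chain <- grn(c("A", "B", "C"),
               data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_error(sample_subnetwork(chain, 4), "between 1")

  # identity and singleton cases
  expect_setequal(sample_subnetwork(chain, 3, seed = 1)$nodes, c("A", "B", "C"))
  expect_equal(nrow(sample_subnetwork(chain, 3, seed = 1)$edges), 2L)
  expect_equal(nrow(sample_subnetwork(chain, 1, seed = 2)$edges), 0L)

  # all connected 2-subsets of a chain are {A,B} and {B,C}; edges induced
  picks <- vapply(1:20, function(s) {
    sub <- sample_subnetwork(chain, 2, seed = s)
    expect_equal(nrow(sub$edges), 1L)
    paste0(sub$edges$from, sub$edges$to)
  }, character(1))
  expect_true(all(picks %in% c("AB", "BC")))
  expect_length(unique(picks), 2L)

  # induced-edge property on random graphs, brute-force cross-check
  for (s in 1:20) {
    set.seed(s)
    src <- random_signed_net(12, p = 0.3)
    sub <- sample_subnetwork(src, 6, seed = s + 100)
    expect_length(sub$nodes, 6L)
    manual <- src$edges[src$edges$from %in% sub$nodes &
                          src$edges$to %in% sub$nodes, ]
    expect_setequal(paste(sub$edges$from, sub$edges$to),
                    paste(manual$from, manual$to))
  }
})

test_that("edge-sign assignment is binomial in the activator probability", {
  net <- generate_dag(40, 0.3, seed = 1)
  expect_true(all(assign_edge_signs(net, 1, seed = 2)$edges$sign == "+"))
  expect_true(all(assign_edge_signs(net, 0, seed = 2)$edges$sign == "-"))

  big <- generate_random(70, 0.42, seed = 3)   # ~1000 edges
  n_act <- vapply(1:30, function(s) {
    sum(assign_edge_signs(big, 0.5, seed = s)$edges$sign == "+")
  }, numeric(1))
  ne <- nrow(big$edges)
  expect_lt(abs(mean(n_act) - ne / 2), 3 * sqrt(ne * 0.25 / 30))

  empty <- grn(c("A", "B"))
  expect_error(assign_edge_signs(empty, 0.5), "no edges")
})

test_that("undirected skeleton collapses directions and deduplicates", {
  bidir <- grn(c("A", "B"), data.frame(from = c("A", "B"), to = c("B", "A")))
  expect_equal(undirected_skeleton(bidir),
               data.frame(a = "A", b = "B", stringsAsFactors = FALSE))
  expect_equal(nrow(undirected_skeleton(grn(c("A", "B")))), 0L)
  chain <- grn(c("A", "B", "C"),
               data.frame(from = c("A", "B"), to = c("B", "C")))
  sk <- undirected_skeleton(chain)
  expect_equal(sk$a, c("A", "B"))
  expect_equal(sk$b, c("B", "C"))
})

test_that("network constructor enforces its invariants", {
  expect_error(grn("A", data.frame(from = "A", to = "A")), "self-loop")
  expect_error(grn(c("A", "B"),
                   data.frame(from = c("A", "A"), to = c("B", "B"))),
               "duplicate")
  expect_error(grn("A", data.frame(from = "A", to = "Z")), "endpoints")
  expect_error(grn(c("A", "B"),
                   data.frame(from = "A", to = "B", sign = "?")),
               "sign")
  cyc <- data.frame(from = c("A", "B"), to = c("B", "A"))
  expect_error(grn(c("A", "B"), cyc, acyclic = TRUE), "cycle")
})
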