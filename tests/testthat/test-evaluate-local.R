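chain_net <- grn(c("A", "B", "C"),
                 data.frame(from = c("A", "B"), to = c("B", "C"),
                            sign = c("+", "-")))

test_that("edge TPR counts unordered recoveries over the ensemble", {
  genes <- c("A", "B", "C")
  runs <- list(toy_inferred(genes, list(c("A", "B"), c("B", "C"))),
               toy_inferred(genes, list(c("B", "A"))),
               toy_inferred(genes, list()))
  tpr <- edge_tpr(chain_net, runs)
  expect_equal(unname(tpr["A->B"]), 2 / 3)
  expect_equal(unname(tpr["B->C"]), 1 / 3)
  expect_error(edge_tpr(chain_net, list()), "nonempty")

  # tpr * ensemble size is an integer; order of runs is irrelevant
  expect_equal(tpr * 3, round(tpr * 3))
  expect_equal(edge_tpr(chain_net, rev(runs)), tpr)
})

test_that("degree-sum covariate counts out-degree of source plus in-degree of target", {
  iso <- grn(c("A", "B"), data.frame(from = "A", to = "B"))
  expect_equal(ds_value(iso, "A", "B"), 2L)

  net <- grn(c("A", "B", "C", "D"),
             data.frame(from = c("A", "A", "D"), to = c("B", "C", "B")))
  expect_equal(ds_value(net, "A", "B"), 4L)   # out(A)=2, in(B)=2
  expect_equal(ds_value(net, "A", "C"), 3L)
  expect_error(ds_value(net, "B", "A"), "not in the true network")

  # adding an out-edge at the source increments Ds by exactly 1
  net2 <- grn(c("A", "B", "C", "D"),
              data.frame(from = c("A", "A", "D", "A"),
                         to = c("B", "C", "B", "D")))
  expect_equal(ds_value(net2, "A", "B"), ds_value(net, "A", "B") + 1L)
})

test_that("KS test on sign classes matches hand-computed ECDF suprema", {
  mk <- function(act, rep_) {
    data.frame(sign = c(rep("+", length(act)), rep("-", length(rep_))),
               tpr = c(act, rep_) / max(c(act, rep_, 1)))
  }
  # identical multisets: D = 0
  same <- edge_sign_ks_test(mk(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  # disjoint supports: D = 1
  disj <- edge_sign_ks_test(mk(c(1, 2), c(3, 4)))
  expect_equal(disj$statistic, 1)
  # {1,2,3} vs {2,3,4}: supremum gap of the ECDFs is 1/3
  third <- edge_sign_ks_test(mk(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(third$statistic, 1 / 3)

  one_class <- data.frame(sign = c("+", "+"), tpr = c(0.1, 0.2))
  expect_error(edge_sign_ks_test(one_class), "repressor")
})

test_that("TPR-by-Ds ANOVA matches the hand-computed F statistic", {
  mk <- function(g1, g2) {
    data.frame(ds = rep(c(2L, 3L), c(length(g1), length(g2))),
               tpr = c(g1, g2))
  }
  # {1,2,3} vs {2,3,4}: SSB = 2 (1 df), SSW = 4 (4 df) -> F = 1.5
  av <- tpr_by_ds_anova(mk(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(av$statistic, 1.5)

  ident <- tpr_by_ds_anova(mk(c(0.2, 0.4), c(0.2, 0.4)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  sep <- tpr_by_ds_anova(mk(c(0, 0), c(1, 1)))
  expect_lt(sep$p.value, 1e-10)

  # singleton levels are dropped from the test but kept in the table
  stats3 <- rbind(mk(c(1, 2, 3), c(2, 3, 4)),
                  data.frame(ds = 9L, tpr = 0.5))
  av3 <- tpr_by_ds_anova(stats3)
  expect_equal(av3$statistic, 1.5)
  expect_true(9L %in% av3$group_means$ds)
  expect_error(tpr_by_ds_anova(data.frame(ds = c(2L, 2L), tpr = c(0, 1))),
               "at least 2 Ds levels")
})

test_that("motif classification matches the four canonical patterns", {
  ed <- function(from, to) data.frame(from = from, to = to,
                                      stringsAsFactors = FALSE)
  nodes <- c("A", "B", "C")
  expect_equal(classify_motif(ed(c("A", "B"), c("B", "C")), nodes), "chain")
  expect_equal(classify_motif(ed(c("A", "C"), c("B", "B")), nodes), "collider")
  expect_equal(classify_motif(ed(c("B", "B"), c("A", "C")), nodes), "fork")
  expect_equal(classify_motif(ed(c("A", "B", "A"), c("B", "C", "C")), nodes),
               "triangle")
  # a lone reciprocal pair matches no pattern
  expect_equal(classify_motif(ed(c("A", "B"), c("B", "A")), nodes), "none")
  expect_equal(classify_motif(ed(character(0), character(0)), nodes), "none")
  expect_error(classify_motif(ed("A", "B"), c("A", "B")), "3 distinct nodes")

  # invariance under all 3! node relabelings
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  base <- ed(c("A", "B"), c("B", "C"))
  for (p in perms) {
    relab <- stats::setNames(nodes[p], nodes)
    edp <- ed(unname(relab[base$from]), unname(relab[base$to]))
    expect_equal(classify_motif(edp, nodes), "chain")
  }
})

test_that("motif enumeration is exhaustive and matches brute force", {
  expect_equal(enumerate_motifs(chain_net)$type, "chain")
  star <- grn(c("A", "B", "C", "D"),
              data.frame(from = rep("B", 3), to = c("A", "C", "D")))
  ms <- enumerate_motifs(star)
  expect_equal(sum(ms$type == "fork"), 3L)
  expect_equal(nrow(enumerate_motifs(grn(c("A", "B", "C")))), 0L)

  set.seed(41)
  for (i in 1:60) {
    net <- random_signed_net(8, 0.3)
    found <- enumerate_motifs(net)
    expected <- oracle_motif_counts(net)
    for (ty in names(expected)) {
      expect_equal(sum(found$type == ty), unname(expected[ty]),
                   info = sprintf("instance %d, type %s", i, ty))
    }
  }
})

test_that("motif true reconstruction rate averages pair TPR and TNR", {
  genes <- c("A", "B", "C")
  # perfect ensemble: TRR = 1 for the chain motif
  perfect <- replicate(4, toy_inferred(genes, list(c("A", "B"), c("B", "C"))),
                       simplify = FALSE)
  tr <- motif_trr(chain_net, perfect)
  expect_equal(tr$motifs$trr, 1)

  # empty ensemble inference: two missed edges, one correct absence -> 1/3
  nothing <- replicate(4, toy_inferred(genes, list()), simplify = FALSE)
  expect_equal(motif_trr(chain_net, nothing)$motifs$trr, 1 / 3)
  # triangle motif under empty inference -> TRR 0
  ffl <- grn(genes, data.frame(from = c("A", "B", "A"), to = c("B", "C", "C")))
  expect_equal(motif_trr(ffl, nothing)$motifs$trr, 0)

  # half-recovered ensemble, hand-computed: (0.5 + 0.5 + 1) / 3 = 2/3
  half <- list(toy_inferred(genes, list(c("A", "B"), c("B", "C"))),
               toy_inferred(genes, list()))
  expect_equal(motif_trr(chain_net, half)$motifs$trr, 2 / 3)

  # summary bookkeeping
  summ <- motif_trr(chain_net, half)$summary
  expect_equal(summ$n_motifs[summ$type == "chain"], 1L)
  expect_true(all(is.na(summ$mean_trr[summ$n_motifs == 0L])))
})

test_that("TPR categories use half-open bins with boundaries in the lower bin", {
  expect_equal(categorize_edges(c(0.8, 0.75, 0.6, 0.5, 0.3, 0.25, 0.1, 0, 1)),
               c("black", "blue", "blue", "green", "green", "red", "red",
                 "red", "black"))
  expect_error(categorize_edges(1.2), "\\[0, 1\\]")
})

test_that("leaf edges are identified by their target's degrees", {
  genes <- c("A", "B", "C")
  runs <- list(toy_inferred(genes, list(c("B", "C"))),
               toy_inferred(genes, list(c("B", "C"))))
  es <- edge_stats(chain_net, runs)
  # chain A->B->C: only B->C is a leaf edge (C: in 1, out 0)
  expect_equal(es$leaf, c(FALSE, TRUE))
  lr <- leaf_edge_report(es)
  expect_equal(lr$leaf_mean, 1)
  expect_equal(lr$internal_mean, 0)

  star <- grn(genes, data.frame(from = c("B", "B"), to = c("A", "C"),
                                sign = c("+", "-")))
  es_star <- edge_stats(star, runs)
  expect_true(all(es_star$leaf))
  expect_equal(leaf_edge_report(es_star)$n_internal, 0L)
})
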