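#' Per-edge true-positive rates over an ensemble
#'
#' For every directed true edge (i, j), the TPR is the fraction of
#' ensemble runs whose inferred network contains the unordered pair
#' \{i, j\}. Both members of a reciprocal true pair map to the same
#' unordered pair and therefore share a TPR.
#'
#' @param truth a [grn] object.
#' @param inferred_list nonempty list of [inferrednet] objects (one per
#'   ensemble dataset).
#' @return Named numeric vector, one entry per true directed edge (names
#'   `"from->to"`), values in \\[0, 1].
#' @export
edge_tpr <- function(truth, inferred_list) {
  stopifnot(inherits(truth, "grn"))
  if (!is.list(inferred_list) || length(inferred_list) == 0L) {
    stop("inferred_list must be a nonempty list of inferred networks")
  }
  for (inf in inferred_list) {
    sdiff <- c(setdiff(inf$genes, truth$nodes),
               setdiff(truth$nodes, inf$genes))
    if (length(sdiff)) {
      stop("gene sets differ between ensemble member and truth: ",
           paste(sdiff, collapse = ", "))
    }
  }
  keys <- pair_keys(truth$edges$from, truth$edges$to)
  counts <- numeric(length(keys))
  for (inf in inferred_list) {
    counts <- counts + (keys %in% inferred_pair_keys(inf))
  }
  stats::setNames(counts / length(inferred_list),
                  paste0(truth$edges$from, "->", truth$edges$to))
}

#' Degree-sum covariate of a directed true edge
#'
#' For the edge i -> j, `Ds = out-degree(i) + in-degree(j)` computed on the
#' true network. The edge itself contributes one to each term, so
#' `Ds >= 2`; larger values indicate a denser local neighbourhood, which
#' degrades maximum-MI edge selection.
#'
#' @param truth a [grn] object.
#' @param from,to endpoints of a directed edge present in `truth`.
#' @return Integer `Ds >= 2`.
#' @export
ds_value <- function(truth, from, to) {
  stopifnot(inherits(truth, "grn"))
  if (!any(truth$edges$from == from & truth$edges$to == to)) {
    stop("edge ", from, "->", to, " is not in the true network")
  }
  sum(truth$edges$from == from) + sum(truth$edges$to == to)
}

#' Per-edge statistics table over an ensemble
#'
#' Assembles one row per directed true edge: endpoints, regulatory sign,
#' ensemble TPR, degree-sum covariate `Ds`, the leaf-edge flag (target has
#' in-degree 1 and out-degree 0) and the TPR colour category of
#' [categorize_edges()].
#'
#' @param truth a signed [grn] object.
#' @param inferred_list nonempty list of [inferrednet] objects.
#' @return Data frame with columns `from`, `to`, `sign`, `tpr`, `ds`,
#'   `leaf`, `category`.
#' @export
edge_stats <- function(truth, inferred_list) {
  tpr <- edge_tpr(truth, inferred_list)
  indeg <- in_degree(truth); outdeg <- out_degree(truth)
  ds <- outdeg[truth$edges$from] + indeg[truth$edges$to]
  leaf <- indeg[truth$edges$to] == 1L & outdeg[truth$edges$to] == 0L
  data.frame(from = truth$edges$from, to = truth$edges$to,
             sign = truth$edges$sign, tpr = unname(tpr),
             ds = as.integer(unname(ds)), leaf = unname(leaf),
             category = categorize_edges(unname(tpr)),
             stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov comparison of activator and repressor edge TPRs
#'
#' Two-sided two-sample KS test of the TPR distributions of activator
#' (`"+"`) versus repressor (`"-"`) edges, asking whether the regulatory
#' sign systematically affects how inferable an edge is.
#'
#' @param stats data frame from [edge_stats()] (columns `sign`, `tpr`).
#' @return List with `statistic` (D), `p.value`, and the two TPR samples
#'   `activator` and `repressor`.
#' @export
edge_sign_ks_test <- function(stats) {
  act <- stats$tpr[stats$sign == "+"]
  rep_ <- stats$tpr[stats$sign == "-"]
  if (length(act) == 0L) stop("no edges in sign class 'activator'")
  if (length(rep_) == 0L) stop("no edges in sign class 'repressor'")
  ks <- suppressWarnings(stats::ks.test(act, rep_, alternative = "two.sided"))
  list(statistic = unname(ks$statistic), p.value = unname(ks$p.value),
       activator = act, repressor = rep_)
}

#' One-way ANOVA of edge TPR by degree-sum level
#'
#' Tests whether mean edge TPR differs across `Ds` levels. Every distinct
#' `Ds` value is one factor level; levels with fewer than two edges carry
#' no within-group information and are dropped from the test (they remain
#' in the group-mean table). At least two retained levels are required.
#'
#' @param stats data frame from [edge_stats()] (columns `ds`, `tpr`).
#' @return List with `statistic` (F), `p.value` and `group_means` (data
#'   frame `ds`, `n`, `mean_tpr` over all levels).
#' @export
tpr_by_ds_anova <- function(stats) {
  counts <- table(stats$ds)
  means <- tapply(stats$tpr, stats$ds, mean)
  group_means <- data.frame(ds = as.integer(names(counts)),
                            n = as.integer(counts),
                            mean_tpr = as.numeric(means))
  keep_levels <- names(counts)[counts >= 2L]
  sub <- stats[as.character(stats$ds) %in% keep_levels, , drop = FALSE]
  if (length(keep_levels) < 2L) {
    stop("ANOVA needs at least 2 Ds levels with at least 2 edges each")
  }
  fit <- stats::aov(tpr ~ factor(ds), data = sub)
  tab <- summary(fit)[[1L]]
  list(statistic = tab[["F value"]][1L], p.value = tab[["Pr(>F)"]][1L],
       group_means = group_means)
}

#' Classify the directed motif on a gene triple
#'
#' The four three-gene motif types: a *chain* (two edges meeting
#' head-to-tail), a *collider* (two edges sharing their target), a *fork*
#' (two edges sharing their source) and a *triangle* (all three unordered
#' pairs connected, any orientation). Triples matching none of the
#' patterns — including a lone reciprocal pair — classify as `"none"`.
#'
#' @param edges data frame with columns `from`, `to`: the induced directed
#'   edge set of the triple.
#' @param nodes character vector of exactly 3 node identifiers.
#' @return One of `"chain"`, `"collider"`, `"fork"`, `"triangle"`,
#'   `"none"`.
#' @export
classify_motif <- function(edges, nodes) {
  if (length(unique(nodes)) != 3L) stop("exactly 3 distinct nodes required")
  if (nrow(edges) == 0L) return("none")
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints outside the node triple")
  }
  pk <- unique(pair_keys(edges$from, edges$to))
  if (length(pk) == 3L) return("triangle")
  if (nrow(edges) != 2L || length(pk) != 2L) return("none")
  # exactly two edges on two distinct pairs
  if (edges$to[1L] == edges$to[2L]) return("collider")
  if (edges$from[1L] == edges$from[2L]) return("fork")
  if (edges$to[1L] == edges$from[2L] || edges$to[2L] == edges$from[1L]) {
    return("chain")
  }
  "none"
}

#' Enumerate all three-gene motifs of a network
#'
#' Scans every 3-node subset, classifies its induced directed edge set and
#' keeps the triples matching a motif type. Counts per type (`#m`) are
#' exhaustive.
#'
#' @param truth a [grn] object.
#' @return Data frame with columns `n1`, `n2`, `n3` (triple, in node
#'   order), `type`, and `pairs_present` (number of connected unordered
#'   pairs, 2 or 3).
#' @export
enumerate_motifs <- function(truth) {
  stopifnot(inherits(truth, "grn"))
  n <- length(truth$nodes)
  empty <- data.frame(n1 = character(0), n2 = character(0),
                      n3 = character(0), type = character(0),
                      pairs_present = integer(0), stringsAsFactors = FALSE)
  if (n < 3L || nrow(truth$edges) == 0L) return(empty)
  # restrict to triples with >= 2 induced edges via adjacency bookkeeping
  idx <- stats::setNames(seq_len(n), truth$nodes)
  ef <- idx[truth$edges$from]; et <- idx[truth$edges$to]
  triples <- utils::combn(n, 3L)
  recs <- vector("list", ncol(triples))
  for (t in seq_len(ncol(triples))) {
    trip <- triples[, t]
    inside <- ef %in% trip & et %in% trip
    if (sum(inside) < 2L) next
    ind <- truth$edges[inside, c("from", "to"), drop = FALSE]
    ty <- classify_motif(ind, truth$nodes[trip])
    if (ty == "none") next
    recs[[t]] <- data.frame(n1 = truth$nodes[trip[1L]],
                            n2 = truth$nodes[trip[2L]],
                            n3 = truth$nodes[trip[3L]],
                            type = ty,
                            pairs_present = length(unique(pair_keys(ind$from, ind$to))),
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' True reconstruction rate of three-gene motifs over an ensemble
#'
#' For each motif, the TRR averages over its three unordered pairs the TPR
#' (fraction of runs inferring the pair) for pairs connected in the truth
#' and the TNR (fraction of runs *not* inferring the pair) for absent
#' pairs. Per motif type, the number of motifs, the mean TRR and its
#' standard deviation are reported.
#'
#' @param truth a [grn] object.
#' @param inferred_list nonempty list of [inferrednet] objects.
#' @param motifs optional precomputed table from [enumerate_motifs()].
#' @return List with `motifs` (per-motif data frame incl. `trr`) and
#'   `summary` (data frame `type`, `n_motifs`, `mean_trr`, `sd_trr` over
#'   the four types).
#' @export
motif_trr <- function(truth, inferred_list, motifs = NULL) {
  if (!is.list(inferred_list) || length(inferred_list) == 0L) {
    stop("inferred_list must be a nonempty list of inferred networks")
  }
  if (is.null(motifs)) motifs <- enumerate_motifs(truth)
  nruns <- length(inferred_list)
  inf_keys <- lapply(inferred_list, inferred_pair_keys)
  skel <- undirected_skeleton(truth)
  true_keys <- pair_keys(skel$a, skel$b)
  # pair recovery frequency across the ensemble
  pair_freq <- function(a, b) {
    k <- pair_keys(a, b)
    vapply(inf_keys, function(keys) k %in% keys, logical(1))
  }
  trr <- numeric(nrow(motifs))
  for (r in seq_len(nrow(motifs))) {
    trip <- c(motifs$n1[r], motifs$n2[r], motifs$n3[r])
    pairs <- utils::combn(trip, 2L)
    rates <- numeric(3L)
    for (p in 1:3) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      freq <- mean(pair_freq(a, b))
      rates[p] <- if (pair_keys(a, b) %in% true_keys) freq else 1 - freq
    }
    trr[r] <- mean(rates)
  }
  motifs$trr <- trr
  types <- c("chain", "collider", "fork", "triangle")
  summ <- data.frame(
    type = types,
    n_motifs = vapply(types, function(ty) sum(motifs$type == ty), integer(1)),
    mean_trr = vapply(types, function(ty) {
      v <- trr[motifs$type == ty]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    sd_trr = vapply(types, function(ty) {
      v <- trr[motifs$type == ty]
      if (length(v) > 1L) stats::sd(v) else if (length(v) == 1L) 0 else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(motifs = motifs, summary = summ)
}

#' TPR colour categories of edges
#'
#' Bins TPR values into the four display categories:
#' black (`tpr > 0.75`), blue (`0.5 < tpr <= 0.75`),
#' green (`0.25 < tpr <= 0.5`) and red (`tpr <= 0.25`). Boundaries belong
#' to the lower bin.
#'
#' @param tpr numeric vector of TPR values in \\[0, 1].
#' @return Character vector of categories.
#' @export
categorize_edges <- function(tpr) {
  if (any(tpr < 0 | tpr > 1, na.rm = TRUE)) {
    stop("tpr values must lie in [0, 1]")
  }
  ifelse(tpr > 0.75, "black",
         ifelse(tpr > 0.5, "blue",
                ifelse(tpr > 0.25, "green", "red")))
}

#' Mean TPR of leaf versus internal edges
#'
#' A leaf edge targets a leaf node: a gene with exactly one incoming and
#' no outgoing edge. Maximum-MI selection recovers such edges especially
#' well, because the leaf's single regulator is almost always its
#' highest-MI partner.
#'
#' @param stats data frame from [edge_stats()] (columns `leaf`, `tpr`).
#' @return List with `leaf_mean`, `internal_mean` (NA when a class is
#'   empty) and the class sizes `n_leaf`, `n_internal`.
#' @export
leaf_edge_report <- function(stats) {
  leaf <- stats$tpr[stats$leaf]
  internal <- stats$tpr[!stats$leaf]
  list(leaf_mean = if (length(leaf)) mean(leaf) else NA_real_,
       internal_mean = if (length(internal)) mean(internal) else NA_real_,
       n_leaf = length(leaf), n_internal = length(internal))
}
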