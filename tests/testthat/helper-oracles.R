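# Independent brute-force reference implementations used as oracles.
# These enumerate the algorithm definitions literally and stay deliberately
# separate from the package's code paths.

# canonical "i|j" labels (i < j) for an edge list of an inferrednet
inferred_pairs <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  g <- net$genes
  i <- match(net$edges$from, g); j <- match(net$edges$to, g)
  sort(paste(pmin(i, j), pmax(i, j), sep = "|"))
}

oracle_rn <- function(mim, I0) {
  out <- character(0)
  n <- nrow(mim)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (mim[i, j] > I0) out <- c(out, paste(i, j, sep = "|"))
  }
  sort(out)
}

oracle_c3net <- function(mim, I0) {
  n <- nrow(mim)
  out <- character(0)
  for (g in seq_len(n)) {
    best <- NA; bestv <- -Inf
    for (j in seq_len(n)) {
      if (j != g && mim[g, j] > I0 && mim[g, j] > bestv) {
        best <- j; bestv <- mim[g, j]
      }
    }
    if (!is.na(best)) {
      out <- c(out, paste(min(g, best), max(g, best), sep = "|"))
    }
  }
  sort(unique(out))
}

oracle_aracne <- function(mim, I0, tol) {
  n <- nrow(mim)
  adj <- mim > I0
  diag(adj) <- FALSE
  marked <- matrix(FALSE, n, n)
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (adj[i, j] && adj[i, k] && adj[j, k]) {
        w <- c(ij = mim[i, j], ik = mim[i, k], jk = mim[j, k])
        weakest <- names(which.min(w))
        if (min(w) < min(w[names(w) != weakest]) - tol) {
          pr <- switch(weakest, ij = c(i, j), ik = c(i, k), jk = c(j, k))
          marked[pr[1], pr[2]] <- TRUE
        }
      }
    }
  }
  out <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (adj[i, j] && !marked[i, j]) out <- c(out, paste(i, j, sep = "|"))
  }
  sort(out)
}

oracle_mrnet <- function(mim, s0) {
  n <- nrow(mim)
  out <- character(0)
  for (y in seq_len(n)) {
    S <- integer(0)
    cand <- setdiff(seq_len(n), y)
    repeat {
      if (!length(cand)) break
      sc <- sapply(cand, function(x) {
        if (!length(S)) mim[x, y] else mim[x, y] - mean(mim[x, S])
      })
      best <- which.max(sc)
      if (sc[best] <= s0) break
      S <- c(S, cand[best]); cand <- cand[-best]
    }
    for (x in S) out <- c(out, paste(min(y, x), max(y, x), sep = "|"))
  }
  sort(unique(out))
}

# symmetric MI-like matrix with distinct positive entries
random_mim <- function(n, genes = sprintf("G%d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  v <- runif(n * (n - 1) / 2, 0.01, 1)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# brute-force motif classification from an adjacency matrix on 3 nodes
oracle_motif_type <- function(adj3) {
  und <- (adj3 + t(adj3)) > 0
  npairs <- sum(und[upper.tri(und)])
  nedges <- sum(adj3)
  if (npairs == 3) return("triangle")
  if (npairs != 2 || nedges != 2) return("none")
  indeg <- colSums(adj3); outdeg <- rowSums(adj3)
  if (any(indeg == 2)) return("collider")
  if (any(outdeg == 2)) return("fork")
  "chain"
}

oracle_motif_counts <- function(net) {
  n <- length(net$nodes)
  adj <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (k in seq_len(nrow(net$edges))) {
    adj[net$edges$from[k], net$edges$to[k]] <- 1L
  }
  counts <- c(chain = 0L, collider = 0L, fork = 0L, triangle = 0L)
  if (n < 3) return(counts)
  trips <- utils::combn(n, 3)
  for (t in seq_len(ncol(trips))) {
    ty <- oracle_motif_type(adj[trips[, t], trips[, t]])
    if (ty != "none") counts[ty] <- counts[ty] + 1L
  }
  counts
}

# random signed directed network on n nodes (may be cyclic)
random_signed_net <- function(n, p = 0.25) {
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  a <- pairs[1, keep]; b <- pairs[2, keep]
  flip <- runif(length(a)) < 0.5
  nodes <- sprintf("N%d", seq_len(n))
  grn(nodes,
      data.frame(from = nodes[ifelse(flip, b, a)],
                 to = nodes[ifelse(flip, a, b)],
                 sign = ifelse(runif(length(a)) < 0.5, "+", "-"),
                 stringsAsFactors = FALSE))
}

# toy inferred network directly from a pair list over a gene universe
toy_inferred <- function(genes, pairs) {
  edges <- if (length(pairs)) {
    do.call(rbind, lapply(pairs, function(p) {
      data.frame(from = min(p), to = max(p), mi = 1, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(from = character(0), to = character(0), mi = numeric(0))
  }
  structure(list(genes = genes, edges = edges, method = "toy", params = list()),
            class = "inferrednet")
}
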