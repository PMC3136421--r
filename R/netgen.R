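#' Generate a random directed acyclic network
#'
#' Draws a uniformly random topological order over the genes and includes
#' each forward pair independently with probability `edge_density`, oriented
#' from the earlier to the later gene in that order. Acyclicity holds by
#' construction; the expected edge count is `edge_density * choose(n, 2)`.
#'
#' @param n_genes number of genes (at least 2).
#' @param edge_density probability in (0, 1] that any forward pair carries an
#'   edge. The default 0.1 gives sparse networks of the kind seen in
#'   transcriptional regulation.
#' @param seed integer seed for reproducibility.
#' @return A [grn] object with `acyclic = TRUE`.
#' @examples
#' net <- generate_dag(20, edge_density = 0.1, seed = 1)
#' summary(net)
#' @export
generate_dag <- function(n_genes, edge_density = 0.1, seed = NULL) {
  if (!is.numeric(n_genes) || n_genes < 2) stop("n_genes must be at least 2")
  n_genes <- as.integer(n_genes)
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must be in (0, 1]")
  }
  check_seed(seed)
  nodes <- gene_names(n_genes)
  ord <- sample.int(n_genes)              # ord[k] = node at position k
  pairs <- utils::combn(n_genes, 2L)      # positions i < j in the order
  keep <- stats::runif(ncol(pairs)) < edge_density
  grn(nodes,
      data.frame(from = nodes[ord[pairs[1L, keep]]],
                 to   = nodes[ord[pairs[2L, keep]]],
                 stringsAsFactors = FALSE),
      acyclic = TRUE)
}

#' Generate a scale-free network by preferential attachment
#'
#' Grows an undirected graph by preferential attachment: each new gene
#' attaches `edges_per_node` edges to existing genes chosen with probability
#' proportional to their current degree (uniformly while all degrees are
#' zero). Edges are then oriented from the older to the newer gene, which
#' makes the result acyclic. With `edges_per_node = 1` the skeleton is a
#' tree with exactly `n_genes - 1` edges.
#'
#' @param n_genes number of genes; must exceed `edges_per_node`.
#' @param edges_per_node number of edges each newly added gene brings.
#' @param seed integer seed.
#' @return A [grn] object with `acyclic = TRUE`.
#' @export
generate_scale_free <- function(n_genes, edges_per_node = 1, seed = NULL) {
  if (!is.numeric(edges_per_node) || edges_per_node < 1) {
    stop("edges_per_node must be at least 1")
  }
  if (!is.numeric(n_genes) || n_genes <= edges_per_node) {
    stop("n_genes must exceed edges_per_node")
  }
  n_genes <- as.integer(n_genes); m <- as.integer(edges_per_node)
  check_seed(seed)
  nodes <- gene_names(n_genes)
  deg <- integer(n_genes)
  from <- integer(0); to <- integer(0)
  for (t in 2:n_genes) {
    k <- min(m, t - 1L)
    existing <- seq_len(t - 1L)
    if (sum(deg[existing]) == 0) {
      targets <- sample(existing, k)
    } else {
      targets <- sample(existing, k, prob = deg[existing])
    }
    from <- c(from, targets)    # older node regulates the newcomer
    to <- c(to, rep.int(t, k))
    deg[targets] <- deg[targets] + 1L
    deg[t] <- deg[t] + k
  }
  grn(nodes, data.frame(from = nodes[from], to = nodes[to],
                        stringsAsFactors = FALSE),
      acyclic = TRUE)
}

#' Generate an Erdos-Renyi random directed network
#'
#' Each unordered gene pair carries an edge independently with probability
#' `p_edge`; the direction of every edge is drawn uniformly at random (the
#' underlying random-graph model is undirected, but directed evaluation
#' metrics need an orientation). The result may contain directed cycles.
#'
#' @param n_genes number of genes (at least 2).
#' @param p_edge edge probability in \\[0, 1].
#' @param seed integer seed.
#' @return A [grn] object (`acyclic = FALSE`).
#' @export
generate_random <- function(n_genes, p_edge, seed = NULL) {
  if (!is.numeric(n_genes) || n_genes < 2) stop("n_genes must be at least 2")
  if (!is.numeric(p_edge) || p_edge < 0 || p_edge > 1) {
    stop("p_edge must be a probability in [0, 1]")
  }
  n_genes <- as.integer(n_genes)
  check_seed(seed)
  nodes <- gene_names(n_genes)
  pairs <- utils::combn(n_genes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  a <- pairs[1L, keep]; b <- pairs[2L, keep]
  flip <- stats::runif(length(a)) < 0.5
  grn(nodes, data.frame(from = nodes[ifelse(flip, b, a)],
                        to   = nodes[ifelse(flip, a, b)],
                        stringsAsFactors = FALSE))
}

#' Sample a connected subnetwork of a larger network
#'
#' Picks a uniform random seed gene and grows the node set by repeatedly
#' adding a uniform random (undirected) neighbour of the current set until
#' the target size is reached, in the style of neighbourhood expansion used
#' when sampling subnetworks of transcriptional regulatory databases. When
#' the reachable component is exhausted before the target size, growth
#' restarts from a uniform random unsampled gene. The returned edge set is
#' exactly the edge set induced by the sampled genes.
#'
#' @param source a [grn] object to sample from.
#' @param size number of genes to sample (at most `length(source$nodes)`).
#' @param seed integer seed.
#' @return A [grn] object on `size` genes; signs are inherited.
#' @export
sample_subnetwork <- function(source, size, seed = NULL) {
  stopifnot(inherits(source, "grn"))
  if (!is.numeric(size) || size < 1 || size > length(source$nodes)) {
    stop("size must be between 1 and the number of source nodes")
  }
  size <- as.integer(size)
  check_seed(seed)
  nbr <- neighbour_list(source)
  sampled <- sample(source$nodes, 1L)
  while (length(sampled) < size) {
    frontier <- setdiff(unique(unlist(nbr[sampled], use.names = FALSE)), sampled)
    if (length(frontier) == 0L) {
      frontier <- setdiff(source$nodes, sampled)   # disconnected source
    }
    sampled <- c(sampled, sample(frontier, 1L))
  }
  keep <- source$edges$from %in% sampled & source$edges$to %in% sampled
  nodes <- source$nodes[source$nodes %in% sampled]  # preserve source order
  grn(nodes, source$edges[keep, , drop = FALSE],
      acyclic = isTRUE(source$acyclic))
}

#' Assign activator/repressor signs to the edges of a network
#'
#' Each edge independently becomes an activator (`"+"`, positive coupling)
#' with probability `p_activator` and a repressor (`"-"`, negative coupling)
#' otherwise. Signs drive the direction of regulation in
#' [simulate_steady_state()] and define the edge classes compared by
#' [edge_sign_ks_test()].
#'
#' @param net a [grn] object with at least one edge.
#' @param p_activator probability an edge is an activator. Default 0.5.
#' @param seed integer seed.
#' @return The network with every edge signed.
#' @export
assign_edge_signs <- function(net, p_activator = 0.5, seed = NULL) {
  stopifnot(inherits(net, "grn"))
  if (nrow(net$edges) == 0L) stop("network has no edges to sign")
  if (p_activator < 0 || p_activator > 1) {
    stop("p_activator must be a probability")
  }
  check_seed(seed)
  net$edges$sign <- ifelse(stats::runif(nrow(net$edges)) < p_activator,
                           "+", "-")
  net
}

#' Undirected skeleton of a directed network
#'
#' Collapses directions: the unordered pair \{i, j\} is present iff the
#' network contains i->j or j->i (or both). This is the object that
#' undirected inference output is scored against.
#'
#' @param net a [grn] object.
#' @return Data frame with columns `a` and `b` (one row per unordered pair,
#'   `a < b` lexicographically), sorted and deduplicated.
#' @export
undirected_skeleton <- function(net) {
  stopifnot(inherits(net, "grn"))
  if (nrow(net$edges) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(net$edges$from, net$edges$to)
  b <- pmax(net$edges$from, net$edges$to)
  key <- paste(a, b, sep = "\t")
  keep <- !duplicated(key)
  out <- data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

# ---- internal ---------------------------------------------------------------

gene_names <- function(n) sprintf("G%d", seq_len(n))

# undirected adjacency as a named list of neighbour character vectors
neighbour_list <- function(net) {
  nbr <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (k in seq_len(nrow(net$edges))) {
    f <- net$edges$from[k]; t <- net$edges$to[k]
    nbr[[f]] <- c(nbr[[f]], t)
    nbr[[t]] <- c(nbr[[t]], f)
  }
  nbr
}
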