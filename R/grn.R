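#' Directed gene regulatory networks
#'
#' A `grn` object is the package's representation of a (true) regulatory
#' network: an ordered set of gene identifiers plus a set of directed edges,
#' each optionally carrying a regulatory sign (`"+"` activator, `"-"`
#' repressor). It is the ground truth against which inferred networks are
#' scored and the structure from which expression data are simulated.
#'
#' @param nodes character vector of unique gene identifiers.
#' @param edges data frame with character columns `from` and `to`, and
#'   optionally `sign` (values `"+"`, `"-"` or `NA`). Zero rows allowed.
#' @param acyclic logical flag asserting the network is a DAG; verified at
#'   construction time by topological sort.
#'
#' @return An object of class `"grn"`: a list with elements `nodes`, `edges`
#'   (data frame `from`/`to`/`sign`) and `acyclic`.
#' @examples
#' net <- grn(c("A", "B", "C"),
#'            data.frame(from = c("A", "B"), to = c("B", "C")))
#' net
#' @export
grn <- function(nodes, edges = NULL, acyclic = FALSE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        sign = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges))) {
      stop("edges must have columns 'from' and 'to'")
    }
    if (is.null(edges$sign)) edges$sign <- NA_character_
    edges <- edges[, c("from", "to", "sign")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$sign <- as.character(edges$sign)
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed: ",
           paste(unique(edges$from[edges$from == edges$to]), collapse = ", "))
    }
    key <- paste(edges$from, edges$to, sep = "\t")
    if (anyDuplicated(key)) stop("duplicate directed edges")
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(missing)) {
      stop("edge endpoints not among nodes: ", paste(missing, collapse = ", "))
    }
    bad <- !(is.na(edges$sign) | edges$sign %in% c("+", "-"))
    if (any(bad)) {
      stop("unknown sign token: ", paste(unique(edges$sign[bad]), collapse = ", "))
    }
    rownames(edges) <- NULL
  }
  net <- structure(list(nodes = nodes, edges = edges, acyclic = acyclic),
                   class = "grn")
  if (acyclic && is.null(topological_order(net))) {
    stop("network flagged acyclic but contains a directed cycle")
  }
  net
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("Directed gene network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (isTRUE(x$acyclic)) " (acyclic)" else ""))
  ns <- n_signed(x)
  if (ns > 0L) {
    cat(sprintf("  signed edges: %d activator (+), %d repressor (-)\n",
                sum(x$edges$sign == "+", na.rm = TRUE),
                sum(x$edges$sign == "-", na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.grn <- function(object, ...) {
  indeg <- in_degree(object)
  outdeg <- out_degree(object)
  res <- list(
    n_nodes = length(object$nodes),
    n_edges = nrow(object$edges),
    acyclic = isTRUE(object$acyclic) || !is.null(topological_order(object)),
    signed = n_signed(object) == nrow(object$edges) && nrow(object$edges) > 0,
    in_degree = summary(indeg),
    out_degree = summary(outdeg),
    n_leaf_nodes = sum(indeg == 1L & outdeg == 0L)
  )
  class(res) <- "summary.grn"
  res
}

#' @export
print.summary.grn <- function(x, ...) {
  cat(sprintf("Directed gene network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  acyclic: %s   fully signed: %s   leaf nodes: %d\n",
              x$acyclic, x$signed, x$n_leaf_nodes))
  cat("  in-degree:\n"); print(x$in_degree)
  cat("  out-degree:\n"); print(x$out_degree)
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param net a [grn] or [inferrednet] object.
#' @return An `igraph` graph (directed for `grn`, undirected for
#'   `inferrednet`), with a `sign` edge attribute when signs are assigned.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "grn")) {
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       directed = TRUE,
                                       vertices = data.frame(name = net$nodes))
    if (n_signed(net) > 0L) {
      g <- igraph::set_edge_attr(g, "sign", value = net$edges$sign)
    }
    g
  } else if (inherits(net, "inferrednet")) {
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = net$genes))
    igraph::set_edge_attr(g, "mi", value = net$edges$mi)
  } else {
    stop("not a grn or inferrednet object")
  }
}

#' @export
plot.grn <- function(x, ...) {
  g <- as_igraph(x)
  ecol <- rep("grey30", nrow(x$edges))
  if (n_signed(x) > 0L) {
    ecol[x$edges$sign == "+"] <- "steelblue"
    ecol[x$edges$sign == "-"] <- "darkorange"
  }
  igraph::plot.igraph(g, edge.color = ecol, vertex.size = 8,
                      vertex.label.cex = 0.7, edge.arrow.size = 0.3, ...)
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

n_signed <- function(net) sum(!is.na(net$edges$sign))

edge_keys <- function(from, to) paste(from, to, sep = "\t")

# unordered pair keys: canonical order by gene id string
pair_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

in_degree <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  t <- table(net$edges$to)
  d[names(t)] <- as.integer(t)
  d
}

out_degree <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  t <- table(net$edges$from)
  d[names(t)] <- as.integer(t)
  d
}

# Kahn's algorithm; NULL if the graph has a directed cycle.
topological_order <- function(net) {
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  indeg <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(net$edges))) {
    i <- idx[[net$edges$from[k]]]; j <- idx[[net$edges$to[k]]]
    adj[[i]] <- c(adj[[i]], j)
    indeg[j] <- indeg[j] + 1L
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) return(NULL)
  net$nodes[out]
}

check_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("seed must be a single finite number")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
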