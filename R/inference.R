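#' Inferred (undirected) networks
#'
#' Every inference algorithm in the package returns an `"inferrednet"`
#' object: the set of unordered gene pairs it declared to be edges, each
#' weighted by the MI value it was selected from, together with the method
#' name and the resolved run parameters. Inference from MI test statistics
#' carries no directional information, so the edge set is undirected.
#'
#' @name inferrednet
#' @keywords internal
NULL

new_inferrednet <- function(genes, i, j, mim, method, params) {
  # i, j: integer indices with i < j, already deduplicated
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  edges <- data.frame(from = genes[i], to = genes[j],
                      mi = mim[cbind(i, j)], stringsAsFactors = FALSE)
  structure(list(genes = genes, edges = edges, method = method,
                 params = params),
            class = "inferrednet")
}

#' @export
print.inferrednet <- function(x, ...) {
  cat(sprintf("Inferred network (%s): %d genes, %d undirected edges\n",
              x$method, length(x$genes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    show <- utils::head(x$edges, 6L)
    show$mi <- signif(show$mi, 4L)
    print(show, row.names = FALSE)
    if (nrow(x$edges) > 6L) cat(sprintf("  ... %d more edges\n",
                                        nrow(x$edges) - 6L))
  }
  invisible(x)
}

#' @export
summary.inferrednet <- function(object, ...) {
  cat(sprintf("Inferred network (%s)\n", object$method))
  cat(sprintf("  genes: %d, edges: %d\n",
              length(object$genes), nrow(object$edges)))
  if (nrow(object$edges) > 0L) {
    cat("  MI weights:\n"); print(summary(object$edges$mi))
  }
  np <- object$params[!vapply(object$params, is.null, logical(1))]
  if (length(np)) {
    cat("  parameters: ",
        paste(names(np), vapply(np, format, character(1)), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' @export
plot.inferrednet <- function(x, ...) {
  igraph::plot.igraph(as_igraph(x), vertex.size = 8, vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' @export
as.matrix.inferrednet <- function(x, ...) {
  n <- length(x$genes)
  adj <- matrix(0, n, n, dimnames = list(x$genes, x$genes))
  if (nrow(x$edges) > 0L) {
    i <- match(x$edges$from, x$genes); j <- match(x$edges$to, x$genes)
    adj[cbind(i, j)] <- x$edges$mi
    adj[cbind(j, i)] <- x$edges$mi
  }
  adj
}

# unordered pair keys of an inferrednet, for set comparisons
inferred_pair_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character(0))
  pair_keys(net$edges$from, net$edges$to)
}

#' C3NET edge selection from an MI matrix and a significance mask
#'
#' The core C3NET step: after non-significant pairs have been eliminated,
#' each gene nominates the single remaining partner with which it shares
#' its maximum MI value, and the union of the nominated unordered pairs is
#' the inferred network. A pair nominated by both of its genes enters only
#' once, and a gene with no significant partner contributes nothing, so the
#' edge count never exceeds the gene count. Ties at a gene's maximum are
#' broken toward the partner earliest in gene order.
#'
#' @param mim symmetric MI matrix from [mi_matrix()].
#' @param mask a `"sigmask"` object from [significance_mask()], or a logical
#'   symmetric matrix of the same shape.
#' @return An [inferrednet] object.
#' @export
infer_c3net <- function(mim, mask) {
  if (inherits(mask, "sigmask")) {
    params <- mask$params; params$method_step1 <- mask$method
    mask <- mask$mask
  } else {
    params <- list()
  }
  if (!is.matrix(mask) || !all(dim(mask) == dim(mim))) {
    stop("mask shape does not match the MI matrix")
  }
  n <- nrow(mim)
  genes <- matrix_genes(mim)
  score <- mim
  score[!mask] <- -Inf
  diag(score) <- -Inf
  ii <- integer(0); jj <- integer(0)
  for (g in seq_len(n)) {
    best <- which.max(score[g, ])       # earliest index on ties
    if (is.finite(score[g, best])) {
      ii <- c(ii, min(g, best)); jj <- c(jj, max(g, best))
    }
  }
  keep <- !duplicated(paste(ii, jj))
  new_inferrednet(genes, ii[keep], jj[keep], mim, "c3net", params)
}

#' Relevance network: threshold the MI matrix
#'
#' Declares an edge for every gene pair whose MI exceeds the threshold
#' `I0`. This is the shared first step of the MI-based inference family.
#'
#' @param mim symmetric MI matrix.
#' @param I0 MI threshold in nats.
#' @return An [inferrednet] object.
#' @export
infer_rn <- function(mim, I0) {
  genes <- matrix_genes(mim)
  sel <- which(upper.tri(mim) & mim > I0, arr.ind = TRUE)
  new_inferrednet(genes, sel[, 1L], sel[, 2L], mim, "rn", list(I0 = I0))
}

#' ARACNE: relevance network plus the data processing inequality
#'
#' Starts from the relevance network at threshold `I0`, then applies the
#' data processing inequality to every fully connected gene triple: the
#' edge with the smallest MI in the triple is marked for removal when it is
#' smaller than both other edges minus `tolerance` (additive convention).
#' All marked edges are removed simultaneously, so the result does not
#' depend on triple order. Output is always a subset of the relevance
#' network.
#'
#' @param mim symmetric MI matrix.
#' @param I0 MI threshold in nats.
#' @param tolerance nonnegative DPI tolerance. Default 0.1, the
#'   conventional benchmarking value.
#' @return An [inferrednet] object.
#' @export
infer_aracne <- function(mim, I0, tolerance = 0.1) {
  if (!is.numeric(tolerance) || tolerance < 0) {
    stop("tolerance must be nonnegative")
  }
  genes <- matrix_genes(mim)
  n <- nrow(mim)
  adj <- mim > I0
  diag(adj) <- FALSE
  drop <- matrix(FALSE, n, n)
  if (n >= 3L) {
    triples <- utils::combn(n, 3L)
    for (t in seq_len(ncol(triples))) {
      a <- triples[1L, t]; b <- triples[2L, t]; c_ <- triples[3L, t]
      if (adj[a, b] && adj[a, c_] && adj[b, c_]) {
        w <- c(mim[a, b], mim[a, c_], mim[b, c_])
        k <- which.min(w)
        others <- w[-k]
        if (w[k] < min(others) - tolerance) {
          pr <- rbind(c(a, b), c(a, c_), c(b, c_))[k, ]
          drop[pr[1L], pr[2L]] <- TRUE
        }
      }
    }
  }
  adj[drop] <- FALSE
  adj[t(drop)] <- FALSE
  sel <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  new_inferrednet(genes, sel[, 1L], sel[, 2L], mim, "aracne",
                  list(I0 = I0, tolerance = tolerance))
}

#' MRNET: greedy maximum-relevance minimum-redundancy selection
#'
#' For each target gene Y the algorithm grows a regulator set S greedily:
#' at every step it picks the candidate X maximizing
#' `I(X; Y) - mean_{Z in S} I(X; Z)` — maximal relevance to the target
#' penalized by the mean redundancy with the regulators already selected
#' (the first pick scores by raw MI). Selection stops when the best score
#' drops to `s0` or below; the inferred network is the union over targets
#' of the pairs \{Y, X\}, X in S.
#'
#' @param mim symmetric MI matrix.
#' @param s0 nonnegative score threshold.
#' @return An [inferrednet] object.
#' @export
infer_mrnet <- function(mim, s0) {
  if (!is.numeric(s0) || s0 < 0) stop("s0 must be nonnegative")
  genes <- matrix_genes(mim)
  n <- nrow(mim)
  ii <- integer(0); jj <- integer(0)
  for (y in seq_len(n)) {
    S <- integer(0)
    candidates <- setdiff(seq_len(n), y)
    repeat {
      if (length(candidates) == 0L) break
      if (length(S) == 0L) {
        scores <- mim[candidates, y]
      } else {
        red <- if (length(S) == 1L) mim[candidates, S]
               else rowMeans(mim[candidates, S, drop = FALSE])
        scores <- mim[candidates, y] - red
      }
      k <- which.max(scores)
      if (scores[k] <= s0) break
      S <- c(S, candidates[k])
      candidates <- candidates[-k]
    }
    if (length(S)) {
      ii <- c(ii, pmin(y, S)); jj <- c(jj, pmax(y, S))
    }
  }
  keep <- !duplicated(paste(ii, jj))
  new_inferrednet(genes, ii[keep], jj[keep], mim, "mrnet", list(s0 = s0))
}

#' All-in-one C3NET inference from expression data
#'
#' The compact entry point: estimates the MI matrix (shared copula
#' transform + Gaussian estimator), runs the significance-elimination step
#' in the chosen mode, and applies the C3NET maximum-MI edge selection.
#' Defaults mirror the reference interface:
#' `alpha = 0.01`, `methodstep1 = "cutoff"`, `cutoffMI = 0`,
#' `MTCmethod = "BH"`, `itnum = 5`.
#'
#' @param dataset genes-by-samples numeric expression matrix.
#' @param alpha significance level for the p-value modes.
#' @param methodstep1 elimination mode: `"cutoff"`, `"justp"` or `"MTC"`.
#' @param cutoffMI MI threshold for cutoff mode.
#' @param MTCmethod multiple-testing correction method for MTC mode.
#' @param itnum permutation iterations for the null distribution.
#' @param seed integer seed for the permutation null.
#' @return An [inferrednet] object (method `"c3net"`).
#' @examples
#' net <- assign_edge_signs(generate_dag(10, 0.15, seed = 1), seed = 2)
#' x <- simulate_steady_state(net, n_samples = 100, seed = 3)
#' inferred <- c3net(x)
#' inferred
#' @export
c3net <- function(dataset, alpha = 0.01, methodstep1 = "cutoff",
                  cutoffMI = 0, MTCmethod = "BH", itnum = 5, seed = NULL) {
  mode <- switch(tolower(methodstep1),
                 cutoff = "cutoff", justp = "justp", mtc = "MTC",
                 stop("methodstep1 must be one of 'cutoff', 'justp', 'MTC'"))
  mim <- mi_matrix(dataset)
  mask <- significance_mask(mim, method = mode, data = dataset,
                            alpha = alpha, cutoffMI = cutoffMI,
                            MTCmethod = MTCmethod, itnum = itnum, seed = seed)
  infer_c3net(mim, mask)
}

matrix_genes <- function(mim) {
  if (!is.null(rownames(mim))) rownames(mim) else gene_names(nrow(mim))
}
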