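#' Confusion counts of an inferred network against a reference
#'
#' Compares the inferred undirected edge set against the undirected
#' skeleton of the true network (a bidirectional true pair counts once).
#' TN is defined over unordered gene pairs, `choose(n, 2)`.
#'
#' @param inferred an [inferrednet] object.
#' @param truth a [grn] object over the same genes.
#' @return Named list with integer `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(inferred, truth) {
  stopifnot(inherits(inferred, "inferrednet"), inherits(truth, "grn"))
  sdiff <- c(setdiff(inferred$genes, truth$nodes),
             setdiff(truth$nodes, inferred$genes))
  if (length(sdiff)) {
    stop("gene sets differ between inferred and true network: ",
         paste(sdiff, collapse = ", "))
  }
  skel <- undirected_skeleton(truth)
  true_keys <- pair_keys(skel$a, skel$b)
  inf_keys <- inferred_pair_keys(inferred)
  TP <- sum(inf_keys %in% true_keys)
  FP <- length(inf_keys) - TP
  FN <- length(true_keys) - TP
  n <- length(truth$nodes)
  TN <- choose(n, 2L) - TP - FP - FN
  list(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
       TN = as.integer(TN))
}

#' Precision, recall and F-score from confusion counts
#'
#' `p = TP/(TP+FP)`, `r = TP/(TP+FN)`, `F = 2pr/(p+r)`; any
#' zero-denominator case returns 0 by convention.
#'
#' @param counts list with `TP`, `FP`, `FN` (as from [confusion_counts()]),
#'   or the three counts given separately.
#' @param FP,FN optional counts when `counts` is given as the scalar TP.
#' @return Named numeric vector `c(precision, recall, fscore)`.
#' @examples
#' precision_recall_f(list(TP = 181, FP = 6, FN = 683))
#' @export
precision_recall_f <- function(counts, FP = NULL, FN = NULL) {
  if (is.list(counts)) {
    TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  } else {
    TP <- counts
  }
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, fscore = f)
}

#' Six-value performance report of an inferred network
#'
#' The standard validation report: precision, F-score, recall, TP, FP and
#' FN, in that order. Values are stored at full precision; printing rounds
#' the three scores to 2 decimals.
#'
#' @param inferred an [inferrednet] object.
#' @param truth a [grn] object over the same genes.
#' @return Object of class `"checknet"`: named numeric vector
#'   `(precision, fscore, recall, TP, FP, FN)`.
#' @export
check_network <- function(inferred, truth) {
  cc <- confusion_counts(inferred, truth)
  s <- precision_recall_f(cc)
  structure(c(precision = unname(s["precision"]),
              fscore = unname(s["fscore"]),
              recall = unname(s["recall"]),
              TP = cc$TP, FP = cc$FP, FN = cc$FN),
            class = "checknet")
}

#' @export
print.checknet <- function(x, ...) {
  cat(sprintf(
    "precision = %.2f, F-score = %.2f, recall = %.2f, TP = %d, FP = %d, FN = %d\n",
    x[["precision"]], x[["fscore"]], x[["recall"]],
    as.integer(x[["TP"]]), as.integer(x[["FP"]]), as.integer(x[["FN"]])))
  invisible(x)
}

#' Optimal MI cut-off for an inference method
#'
#' Sweeps the threshold grid, runs the chosen method at every grid point on
#' one shared MI matrix, and returns the threshold maximizing the F-score
#' against the known true network (ties resolve to the smallest
#' threshold). Because the truth is consulted, the resulting F-score is an
#' upper bound that no data-driven threshold choice can exceed.
#'
#' @param data genes-by-samples expression matrix.
#' @param truth a [grn] object over the same genes.
#' @param method one of `"c3net"`, `"rn"`, `"aracne"`, `"mrnet"`.
#' @param grid numeric vector of candidate thresholds; by default 100
#'   equally spaced points from 0 to the maximum observed MI.
#' @param tolerance DPI tolerance forwarded to [infer_aracne()].
#' @return List with `I0` (optimal threshold), `fscore` (its F-score) and
#'   the full sweep as data frame `curve` (columns `I0`, `fscore`).
#' @export
optimal_cutoff <- function(data, truth, method = "c3net", grid = NULL,
                           tolerance = 0.1) {
  optimal_cutoff_mim(mi_matrix(data), truth, method, grid, tolerance)
}

optimal_cutoff_mim <- function(mim, truth, method, grid = NULL,
                               tolerance = 0.1) {
  if (is.null(grid)) grid <- default_grid(mim)
  if (length(grid) == 0L) stop("threshold grid is empty")
  fs <- vapply(grid, function(I0) {
    f_at_cutoff(mim, truth, method, I0, tolerance)
  }, numeric(1))
  best <- which.max(fs)            # earliest (smallest I0) on ties
  list(I0 = grid[best], fscore = fs[best],
       curve = data.frame(I0 = grid, fscore = fs))
}

#' F-score versus MI cut-off for several methods
#'
#' Evaluates each method over the same threshold grid and the same MI
#' matrix, producing the long-format table behind F-vs-threshold curves.
#' C3NET's per-gene maximum selection makes its curve flat over a wide
#' range of low thresholds, in contrast to the relevance network.
#'
#' @param data genes-by-samples expression matrix.
#' @param truth a [grn] object over the same genes.
#' @param methods character vector of method names. Default
#'   `c("c3net", "rn")`.
#' @param grid numeric vector of thresholds; default as in
#'   [optimal_cutoff()].
#' @param tolerance DPI tolerance for `"aracne"`.
#' @return Data frame with columns `I0`, `method`, `fscore`
#'   (`length(grid) * length(methods)` rows).
#' @export
fscore_vs_cutoff <- function(data, truth, methods = c("c3net", "rn"),
                             grid = NULL, tolerance = 0.1) {
  mim <- mi_matrix(data)
  if (is.null(grid)) grid <- default_grid(mim)
  out <- do.call(rbind, lapply(methods, function(mth) {
    data.frame(I0 = grid, method = mth,
               fscore = vapply(grid, function(I0) {
                 f_at_cutoff(mim, truth, mth, I0, tolerance)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- internal ---------------------------------------------------------------

default_grid <- function(mim) {
  seq(0, max(mim), length.out = 100L)
}

infer_at <- function(mim, method, I0, tolerance = 0.1) {
  switch(method,
         c3net = infer_c3net(mim, significance_mask(mim, "cutoff",
                                                    cutoffMI = I0)),
         rn = infer_rn(mim, I0),
         aracne = infer_aracne(mim, I0, tolerance),
         mrnet = infer_mrnet(mim, I0),
         stop("unknown method '", method, "'"))
}

f_at_cutoff <- function(mim, truth, method, I0, tolerance) {
  inf <- infer_at(mim, method, I0, tolerance)
  unname(precision_recall_f(confusion_counts(inf, truth))["fscore"])
}
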