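#' Copula (rank) transform of an expression matrix
#'
#' Replaces each gene's sample values by their ranks divided by `m + 1`
#' (average ranks for ties), mapping every gene into (0, 1). The transform
#' is invariant to any strictly increasing per-gene distortion of the data,
#' which is what makes the downstream Gaussian mutual-information estimator
#' nonparametric with respect to the marginals.
#'
#' @param data genes-by-samples numeric matrix with at least 2 samples.
#' @return Matrix of the same shape with values in (0, 1).
#' @examples
#' copula_transform(rbind(g1 = c(3, 1, 2)))  # 0.75 0.25 0.50
#' @export
copula_transform <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) < 2L) stop("at least 2 samples are required")
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("data must be finite numeric")
  }
  m <- ncol(data)
  out <- t(apply(data, 1L, rank, ties.method = "average")) / (m + 1)
  dimnames(out) <- dimnames(data)
  out
}

#' Gaussian mutual information between two vectors
#'
#' Estimates MI (in nats) as `-0.5 * log(1 - rho^2)` where `rho` is the
#' Pearson correlation of the copula-transformed vectors. The estimator is
#' zero for uncorrelated ranks and grows without bound as |rho| -> 1;
#' |rho| is clipped at `1 - 1e-12`, so perfectly rank-correlated genes get
#' a large finite value rather than infinity (max-selection downstream must
#' be total).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param transformed logical; set `TRUE` when `x` and `y` are already on
#'   the copula scale to skip the rank transform.
#' @return Nonnegative scalar MI in nats.
#' @export
mi_gaussian <- function(x, y, transformed = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("at least 2 observations are required")
  if (!transformed) {
    u <- copula_transform(rbind(x, y))
    x <- u[1L, ]; y <- u[2L, ]
  }
  rho <- suppressWarnings(stats::cor(x, y))
  if (is.na(rho)) rho <- 0      # zero-variance margin (constant gene)
  rho <- clip_rho(rho)
  -0.5 * log(1 - rho^2)
}

#' Pairwise mutual-information matrix
#'
#' Applies one shared copula transform to the whole matrix and estimates
#' all `n(n-1)/2` pairwise MI values with the Gaussian estimator. The
#' result is symmetric, nonnegative, with a zero diagonal; these MI values
#' are the test statistics every inference algorithm in the package
#' operates on.
#'
#' @param data genes-by-samples numeric matrix (>= 2 genes, >= 2 samples).
#' @return Symmetric numeric matrix in nats with gene ids as dimnames.
#' @export
mi_matrix <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("at least 2 genes are required")
  u <- copula_transform(data)
  rho <- suppressWarnings(stats::cor(t(u)))
  rho[is.na(rho)] <- 0
  rho <- clip_rho(rho)
  mim <- -0.5 * log(1 - rho^2)
  diag(mim) <- 0
  if (is.null(rownames(data))) {
    dimnames(mim) <- list(gene_names(nrow(data)), gene_names(nrow(data)))
  }
  mim
}

#' Permutation null distribution of MI values
#'
#' For each of `itnum` iterations every gene's sample values are permuted
#' independently — destroying all between-gene dependence while preserving
#' each gene's margin — the full MI matrix is recomputed and all
#' upper-triangle values pooled. The pooled values form a shared null
#' distribution for all gene pairs.
#'
#' @param data genes-by-samples numeric matrix.
#' @param itnum number of permutation iterations (>= 1). Default 5.
#' @param seed integer seed.
#' @return Object of class `"minull"`: list with sorted `null_values`,
#'   `itnum` and `seed`.
#' @export
build_null <- function(data, itnum = 5, seed = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(itnum) || itnum < 1) stop("itnum must be at least 1")
  itnum <- as.integer(itnum)
  check_seed(seed)
  n <- nrow(data); m <- ncol(data)
  vals <- vector("list", itnum)
  for (it in seq_len(itnum)) {
    perm <- data
    for (i in seq_len(n)) perm[i, ] <- perm[i, sample.int(m)]
    mim <- mi_matrix(perm)
    vals[[it]] <- mim[upper.tri(mim)]
  }
  structure(list(null_values = sort(unlist(vals)), itnum = itnum,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "minull")
}

#' @export
print.minull <- function(x, ...) {
  cat(sprintf("Permutation MI null: %d values from %d iteration(s)\n",
              length(x$null_values), x$itnum))
  invisible(x)
}

#' Empirical p-values of observed MI values against a permutation null
#'
#' Uses the add-one permutation rule `p = (1 + #{null >= MI}) / (N + 1)`,
#' so p-values are always strictly positive and at most 1.
#'
#' @param mim symmetric MI matrix from [mi_matrix()].
#' @param null a `"minull"` object from [build_null()].
#' @return Symmetric matrix of p-values in (0, 1] with unit diagonal.
#' @export
mi_pvalues <- function(mim, null) {
  stopifnot(inherits(null, "minull"))
  nv <- null$null_values
  if (length(nv) == 0L) stop("empty null distribution")
  # #{null >= x} via position in the sorted null
  cnt_ge <- length(nv) - findInterval(mim, nv, left.open = TRUE)
  p <- matrix((1 + cnt_ge) / (length(nv) + 1), nrow(mim), ncol(mim),
              dimnames = dimnames(mim))
  diag(p) <- 1
  p
}

#' Multiple-testing correction of a p-value vector
#'
#' Thin, validating wrapper around [stats::p.adjust()] for the correction
#' methods supported by the significance-elimination step: `"BH"`,
#' `"bonferroni"`, `"BY"`, `"hochberg"`, `"holm"`, `"hommel"`.
#'
#' @param p numeric vector of p-values in \\[0, 1].
#' @param method correction method name (see above).
#' @return Adjusted p-values in input order, clipped to 1.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  methods <- c("BH", "bonferroni", "BY", "hochberg", "holm", "hommel")
  if (!is.character(method) || length(method) != 1L || !(method %in% methods)) {
    stop("unknown MTC method; available options: ",
         paste(methods, collapse = ", "))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Significance elimination mask over gene pairs
#'
#' Implements the first inference step in its three modes:
#' \describe{
#'   \item{cutoff}{keep pairs with `MI > cutoffMI` (default threshold 0
#'     keeps every positive-MI pair);}
#'   \item{justp}{keep pairs whose raw permutation p-value is below `alpha`;}
#'   \item{MTC}{keep pairs whose multiplicity-adjusted p-value is below
#'     `alpha`.}
#' }
#' The p-value modes need the expression data (to build the permutation
#' null) and `itnum`; MTC mode additionally needs `MTCmethod`.
#'
#' @param mim symmetric MI matrix.
#' @param method one of `"cutoff"`, `"justp"`, `"MTC"`.
#' @param data expression matrix; required unless `method = "cutoff"`.
#' @param alpha significance level. Default 0.01.
#' @param cutoffMI MI threshold for cutoff mode. Default 0.
#' @param MTCmethod correction method for MTC mode (see
#'   [adjust_pvalues()]). Default `"BH"`.
#' @param itnum permutation iterations for the null. Default 5.
#' @param seed integer seed for the permutation null.
#' @return Object of class `"sigmask"`: list with logical symmetric `mask`
#'   (false diagonal), `method` and resolved `params`.
#' @export
significance_mask <- function(mim, method = c("cutoff", "justp", "MTC"),
                              data = NULL, alpha = 0.01, cutoffMI = 0,
                              MTCmethod = "BH", itnum = 5, seed = NULL) {
  method <- match.arg(method)
  if (method == "cutoff") {
    if (!is.numeric(cutoffMI) || length(cutoffMI) != 1L) {
      stop("cutoff mode requires its dependent parameter 'cutoffMI'")
    }
    mask <- mim > cutoffMI
  } else {
    if (is.null(data)) {
      stop(method, " mode requires the expression data to build ",
           "a permutation null (parameter 'data')")
    }
    if (method == "MTC" && is.null(MTCmethod)) {
      stop("MTC mode requires its dependent parameter 'MTCmethod'")
    }
    null <- build_null(data, itnum = itnum, seed = seed)
    p <- mi_pvalues(mim, null)
    if (method == "MTC") {
      ut <- upper.tri(p)
      adj <- adjust_pvalues(p[ut], method = MTCmethod)
      p[ut] <- adj
      p[lower.tri(p)] <- t(p)[lower.tri(p)]
    }
    mask <- p < alpha
  }
  diag(mask) <- FALSE
  structure(list(mask = mask, method = method,
                 params = list(alpha = alpha, cutoffMI = cutoffMI,
                               MTCmethod = MTCmethod, itnum = itnum,
                               seed = if (is.null(seed)) NA else seed)),
            class = "sigmask")
}

#' @export
print.sigmask <- function(x, ...) {
  cat(sprintf("Significance mask (%s mode): %d of %d gene pairs retained\n",
              x$method, sum(x$mask[upper.tri(x$mask)]),
              sum(upper.tri(x$mask))))
  invisible(x)
}

clip_rho <- function(rho) pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
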