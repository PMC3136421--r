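#' Generate a small named test fixture on disk
#'
#' Builds one of the package's standard miniature test cases — a signed
#' true network plus a matched expression dataset — and writes both to
#' `dir` as `<name>_network.tsv` and `<name>_expression.tsv`. Fixtures:
#' \describe{
#'   \item{tiny-chain}{3-gene chain A->B->C (one chain motif; B->C is a
#'     leaf edge).}
#'   \item{tiny-star}{3-gene fork B->A, B->C (both edges leaf edges).}
#'   \item{ffl}{3-gene feed-forward loop A->B, B->C, A->C (one triangle
#'     motif).}
#'   \item{separable-mi}{4 genes with edges A->B and C->D and strongly
#'     coupled simulated pairs, so the MI values of true pairs separate
#'     completely from those of false pairs; the returned `threshold`
#'     (midpoint of the separating gap) yields a perfect F-score of 1 for
#'     thresholding methods.}
#' }
#'
#' @param name fixture name (see above).
#' @param seed integer seed; the fixture bytes are a deterministic
#'   function of it.
#' @param dir output directory (created if missing). Default
#'   [tempdir()].
#' @param n_samples samples in the expression dataset. Default 100.
#' @return List with `network` ([grn]), `data` (matrix), file `paths`, and
#'   for `separable-mi` the separating `threshold`.
#' @export
make_fixture <- function(name, seed = 1, dir = tempdir(), n_samples = 100) {
  known <- c("tiny-chain", "tiny-star", "ffl", "separable-mi")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  check_seed(seed)
  threshold <- NULL
  if (name == "separable-mi") {
    # two independent strongly coupled pairs: true-pair MI >> false-pair MI
    a <- stats::runif(n_samples); c_ <- stats::runif(n_samples)
    data <- rbind(A = a,
                  B = a * exp(stats::rnorm(n_samples, 0, 0.05)),
                  C = c_,
                  D = c_ * exp(stats::rnorm(n_samples, 0, 0.05)))
    colnames(data) <- sample_names(n_samples)
    net <- grn(c("A", "B", "C", "D"),
               data.frame(from = c("A", "C"), to = c("B", "D"),
                          sign = c("+", "+"), stringsAsFactors = FALSE))
    mim <- mi_matrix(data)
    skel <- undirected_skeleton(net)
    true_idx <- cbind(match(skel$a, rownames(mim)), match(skel$b, rownames(mim)))
    ut <- which(upper.tri(mim), arr.ind = TRUE)
    is_true <- paste(ut[, 1], ut[, 2]) %in%
      paste(pmin(true_idx[, 1], true_idx[, 2]), pmax(true_idx[, 1], true_idx[, 2]))
    threshold <- (min(mim[ut[is_true, , drop = FALSE]]) +
                    max(mim[ut[!is_true, , drop = FALSE]])) / 2
  } else {
    net <- switch(name,
      "tiny-chain" = grn(c("A", "B", "C"),
                         data.frame(from = c("A", "B"), to = c("B", "C"),
                                    sign = c("+", "+"))),
      "tiny-star" = grn(c("A", "B", "C"),
                        data.frame(from = c("B", "B"), to = c("A", "C"),
                                   sign = c("+", "-"))),
      "ffl" = grn(c("A", "B", "C"),
                  data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                             sign = c("+", "+", "+"))))
    kin <- draw_kinetics(net)
    data <- simulate_steady_state(net, kin, n_samples)
  }
  net_path <- file.path(dir, paste0(name, "_network.tsv"))
  data_path <- file.path(dir, paste0(name, "_expression.tsv"))
  write_network(net, net_path)
  write_expression(data, data_path)
  out <- list(network = net, data = data,
              paths = c(network = net_path, expression = data_path))
  if (!is.null(threshold)) out$threshold <- threshold
  out
}
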