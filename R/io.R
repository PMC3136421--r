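#' Read and write expression matrices as TSV
#'
#' The expression format is a tab-separated table whose first column,
#' `gene`, holds unique gene identifiers and whose remaining columns (at
#' least two) hold numeric sample values. Values are written with 12
#' significant digits, so a write/read round trip preserves them to that
#' precision and identifiers exactly.
#'
#' @param path file path.
#' @return `read_expression()` returns a genes-by-samples numeric matrix
#'   with gene and sample ids as dimnames.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 3L) {
    stop("expression file needs a gene column and at least 2 sample columns")
  }
  m <- length(header) - 1L
  genes <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, length(lines) - 1L, m)
  for (k in 2:length(lines)) {
    row <- fields[[k]]
    if (length(row) != m + 1L) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   k, m + 1L, length(row)))
    }
    genes[k - 1L] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      stop(sprintf("line %d: non-numeric value for gene '%s'", k, row[1L]))
    }
    vals[k - 1L, ] <- v
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop(sprintf("duplicate gene id '%s' (line %d)", dup[1L],
                 1L + which(genes == dup[1L])[2L]))
  }
  dimnames(vals) <- list(genes, header[-1L])
  vals
}

#' @param x genes-by-samples numeric matrix.
#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- gene_names(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- sample_names(ncol(x))
  lines <- c(paste(c("gene", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], fmt_num(x[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write directed networks
#'
#' Two plain-text formats are supported. The edge-list TSV has a header
#' `source<TAB>target<TAB>sign` with sign tokens `+`, `-` or empty. SIF
#' rows are `source<TAB>interaction<TAB>target` with the interaction token
#' carrying the sign (`+`, `-`, or `regulates` for unsigned); a row with a
#' single field declares an isolated node. `write_network()` additionally
#' exports GraphML (via igraph) for network viewers. Reading GraphML is
#' not supported.
#'
#' @param path file path; for reading, a `.sif` suffix selects SIF.
#' @return `read_network()` returns a [grn] object.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  from <- character(0); to <- character(0); sign <- character(0)
  isolated <- character(0)
  if (sif) {
    for (k in seq_along(lines)) {
      row <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
      if (length(row) == 1L) { isolated <- c(isolated, row); next }
      if (length(row) != 3L) {
        stop(sprintf("line %d: SIF rows need 1 or 3 fields", k))
      }
      s <- parse_sign(row[2L], k)
      from <- c(from, row[1L]); to <- c(to, row[3L]); sign <- c(sign, s)
    }
  } else {
    if (length(lines) == 0L) stop("empty network file: ", path)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L || header[1L] != "source" || header[2L] != "target") {
      stop("network TSV needs header 'source<TAB>target[<TAB>sign]'")
    }
    for (k in seq_along(lines)[-1L]) {
      row <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
      if (length(row) < 2L || length(row) > 3L) {
        stop(sprintf("line %d: expected 2 or 3 fields", k))
      }
      s <- if (length(row) == 3L && nzchar(row[3L])) parse_sign(row[3L], k)
           else NA_character_
      from <- c(from, row[1L]); to <- c(to, row[2L]); sign <- c(sign, s)
    }
  }
  if (any(from == to)) {
    stop("self-loop at node ", from[from == to][1L])
  }
  nodes <- unique(c(from, to, isolated))
  grn(nodes, data.frame(from = from, to = to, sign = sign,
                        stringsAsFactors = FALSE))
}

#' @param net a [grn] object.
#' @param format `"tsv"`, `"sif"` or `"graphml"`; inferred from the file
#'   extension when omitted.
#' @rdname read_network
#' @export
write_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "grn"))
  format <- resolve_format(path, format)
  if (format == "tsv") {
    sign <- ifelse(is.na(net$edges$sign), "", net$edges$sign)
    writeLines(c("source\ttarget\tsign",
                 paste(net$edges$from, net$edges$to, sign, sep = "\t")),
               path)
  } else if (format == "sif") {
    inter <- ifelse(is.na(net$edges$sign), "regulates", net$edges$sign)
    connected <- unique(c(net$edges$from, net$edges$to))
    writeLines(c(paste(net$edges$from, inter, net$edges$to, sep = "\t"),
                 setdiff(net$nodes, connected)),
               path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Write an inferred network
#'
#' TSV rows are `geneA<TAB>geneB<TAB>mi` (12 significant digits on the MI
#' weight); SIF uses the interaction token `mi`; GraphML goes through
#' igraph with the MI weight as an edge attribute.
#'
#' @param net an [inferrednet] object.
#' @param path file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`; inferred from the file
#'   extension when omitted.
#' @export
write_inferred <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "inferrednet"))
  format <- resolve_format(path, format)
  if (format == "tsv") {
    writeLines(c("geneA\tgeneB\tmi",
                 paste(net$edges$from, net$edges$to, fmt_num(net$edges$mi),
                       sep = "\t")),
               path)
  } else if (format == "sif") {
    connected <- unique(c(net$edges$from, net$edges$to))
    writeLines(c(paste(net$edges$from, "mi", net$edges$to, sep = "\t"),
                 setdiff(net$genes, connected)),
               path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read and write MI matrices as square TSV
#'
#' Square table with gene ids as both header row and first column, values
#' at 12 significant digits.
#'
#' @param mim symmetric numeric matrix.
#' @param path file path.
#' @export
write_mi_matrix <- function(mim, path) {
  genes <- matrix_genes(mim)
  lines <- c(paste(c("gene", genes), collapse = "\t"),
             vapply(seq_len(nrow(mim)), function(i) {
               paste(c(genes[i], fmt_num(mim[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
read_mi_matrix <- function(path) {
  read_expression(path)
}

#' Write a run-configuration / provenance sidecar as JSON
#'
#' @param config named list of resolved run parameters.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

fmt_num <- function(x) formatC(x, digits = 12L, format = "g")

resolve_format <- function(path, format) {
  if (!is.null(format)) {
    return(match.arg(format, c("tsv", "sif", "graphml")))
  }
  if (grepl("\\.sif$", path, ignore.case = TRUE)) return("sif")
  if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE)) return("graphml")
  "tsv"
}

parse_sign <- function(tok, line) {
  if (tok %in% c("+", "-")) return(tok)
  if (tok %in% c("regulates", "")) return(NA_character_)
  stop(sprintf("line %d: unknown sign token '%s'", line, tok))
}
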