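#' Write an expression cube as long-format TSV
#'
#' Columns: gene, experiment, time_min, value (ratio scale).
#'
#' @param cube expression cube.
#' @param path output file.
#' @export
write_cube_tsv <- function(cube, path) {
  times <- attr(cube, "times")
  df <- expand.grid(gene = dimnames(cube)[[1]],
                    experiment = dimnames(cube)[[2]],
                    time_min = times, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$value <- as.vector(cube)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format expression cube TSV
#'
#' @param path TSV with columns gene, experiment, time_min, value.
#' @param class_map optional named character vector experiment -> class,
#'   attached to the cube.
#' @return expression cube array with `times` (and optionally `class_map`)
#'   attributes.
#' @export
read_cube_tsv <- function(path, class_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genes <- sort(unique(df$gene))
  exps <- sort(unique(df$experiment))
  times <- sort(unique(df$time_min))
  cube <- array(NA_real_, c(length(genes), length(exps), length(times)),
                dimnames = list(genes, exps, paste0("t", times)))
  cube[cbind(match(df$gene, genes), match(df$experiment, exps),
             match(df$time_min, times))] <- df$value
  attr(cube, "times") <- times
  if (!is.null(class_map)) attr(cube, "class_map") <- class_map
  cube
}

#' Write / read a spot-level table
#'
#' Columns: gene, experiment, time_min, spot_index, red, green.
#'
#' @param spots spot table data.frame.
#' @param path file path.
#' @export
write_spots_tsv <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_tsv
#' @export
read_spots_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a network (true or fitted) as an edge-list TSV
#'
#' Columns: regulator, target, alpha, beta; only nonzero edges are written.
#'
#' @param network a `true_network` or `network_model`.
#' @param path file path.
#' @export
write_network_tsv <- function(network, path) {
  nz <- which(network$alpha != 0 | network$beta != 0, arr.ind = TRUE)
  df <- data.frame(
    regulator = colnames(network$alpha)[nz[, 2]],
    target = rownames(network$alpha)[nz[, 1]],
    alpha = network$alpha[nz], beta = network$beta[nz],
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column reference edge list TSV
#'
#' @param path TSV whose first two columns are gene identifiers (header
#'   optional, detected).
#' @return data.frame with columns `a` and `b`.
#' @export
read_edges_tsv <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  has_header <- any(tolower(unlist(first)) %in%
                      c("source", "target", "regulator", "gene1", "a"))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:2], c("a", "b"))
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of gene identifier vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, character(1), 1))
}

#' Write an artifact ledger or processing report as JSON
#'
#' @param x list or data.frame.
#' @param path output file.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted (or true) network edge-list TSV back into matrices
#'
#' @param path TSV with columns regulator, target, alpha, beta.
#' @param genes gene universe defining matrix dimensions (rows and columns).
#' @return list with `alpha` and `beta` (target x regulator matrices) and a
#'   default `config`, usable wherever a fitted network is expected.
#' @export
read_network_tsv <- function(path, genes) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  alpha <- matrix(0, length(genes), length(genes),
                  dimnames = list(genes, genes))
  beta <- alpha
  alpha[cbind(el$target, el$regulator)] <- el$alpha
  beta[cbind(el$target, el$regulator)] <- el$beta
  structure(list(alpha = alpha, beta = beta,
                 lambda = NULL, diagnostics = NULL,
                 config = list(regulators = genes, exclude_self = TRUE,
                               at = "midpoint", exclude_induced = TRUE)),
            class = "network_model")
}
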