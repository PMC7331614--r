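#' Weighted gene-gene functional-linkage networks
#'
#' A `mp_network` is an undirected, weighted gene graph in the style of the
#' STRING functional-linkage network: nodes are gene symbols, edge weights
#' are positive combined-confidence scores (STRING uses integers in
#' 0--1000; no rescaling is applied because the downstream symmetric
#' normalization is invariant to global weight scaling). Edges may carry
#' per-channel evidence sub-scores (e.g. a `binding` column) to support
#' physical-only filtering.
#'
#' @name mp_network
#' @keywords internal
NULL

new_mp_network <- function(edges, nodes) {
  stopifnot(is.data.frame(edges), all(c("gene1", "gene2", "weight") %in% names(edges)))
  structure(list(edges = edges, nodes = nodes), class = "mp_network")
}

#' @export
print.mp_network <- function(x, ...) {
  cat(sprintf("<mp_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-style weighted edge list
#'
#' Parses a whitespace- or tab-delimited edge list with a header row and
#' columns `protein1 protein2 combined_score` followed by optional numeric
#' evidence-channel columns. The result is an undirected, deduplicated
#' network: self-loops are dropped, duplicate A-B / B-A rows are merged
#' keeping the maximum weight, and node order is lexicographic so matrix
#' views are reproducible.
#'
#' @param path Path to the edge-list file.
#' @param min_weight Minimum combined score; edges with `weight <
#'   min_weight` are dropped (the boundary is kept).
#' @param physical_only If `TRUE`, retain only edges whose physical/binding
#'   evidence channel (column named by `physical_channel`) carries a
#'   positive sub-score.
#' @param physical_channel Name of the evidence column flagging physical
#'   (binding) interactions. Default `"binding"`.
#' @param aliases Optional protein-ID to gene-symbol map: a two-column
#'   data frame (id, symbol) or a named character vector. Applied before
#'   deduplication; when two protein IDs collapse onto one symbol pair the
#'   maximum-weight edge is kept.
#' @return A `mp_network` object (list with `edges` data frame and sorted
#'   `nodes` character vector).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein1\tprotein2\tcombined_score",
#'              "A\tB\t700", "B\tA\t700", "B\tC\t150"), f)
#' net <- read_network(f, min_weight = 200)
#' net$edges
#' @export
read_network <- function(path, min_weight = 0, physical_only = FALSE,
                         physical_channel = "binding", aliases = NULL) {
  stopifnot(min_weight >= 0)
  tab <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 3) {
    stop("edge list must have at least 3 columns (gene, gene, weight): ", path)
  }
  g1 <- as.character(tab[[1]])
  g2 <- as.character(tab[[2]])
  w <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- which(!is.finite(w) | is.na(g1) | is.na(g2) | g1 == "" | g2 == "" | w <= 0)
  if (length(bad)) {
    # +1 accounts for the header row
    stop(sprintf("malformed edge row at line %d of '%s'", bad[1] + 1L, path))
  }

  if (!is.null(aliases)) {
    if (is.data.frame(aliases)) {
      amap <- stats::setNames(as.character(aliases[[2]]), as.character(aliases[[1]]))
    } else {
      amap <- aliases
    }
    hit1 <- g1 %in% names(amap)
    hit2 <- g2 %in% names(amap)
    g1[hit1] <- unname(amap[g1[hit1]])
    g2[hit2] <- unname(amap[g2[hit2]])
  }

  channels <- tab[, setdiff(seq_len(ncol(tab)), 1:3), drop = FALSE]
  channels <- channels[, vapply(channels, is.numeric, logical(1)), drop = FALSE]

  keep <- w >= min_weight & g1 != g2
  if (physical_only) {
    if (!physical_channel %in% names(channels)) {
      stop("physical_only = TRUE but no '", physical_channel,
           "' channel column present in ", path)
    }
    keep <- keep & !is.na(channels[[physical_channel]]) &
      channels[[physical_channel]] > 0
  }
  g1 <- g1[keep]; g2 <- g2[keep]; w <- w[keep]
  channels <- channels[keep, , drop = FALSE]

  if (!length(w)) {
    stop("no edges remain after filtering (min_weight = ", min_weight,
         if (physical_only) ", physical_only = TRUE" else "", ")")
  }

  # canonical unordered pair, then keep the max-weight representative
  a <- pmin(g1, g2)
  b <- pmax(g1, g2)
  ord <- order(a, b, -w)
  a <- a[ord]; b <- b[ord]; w <- w[ord]
  channels <- channels[ord, , drop = FALSE]
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(gene1 = a[!dup], gene2 = b[!dup], weight = w[!dup],
                      stringsAsFactors = FALSE)
  if (ncol(channels)) {
    edges <- cbind(edges, channels[!dup, , drop = FALSE])
  }
  rownames(edges) <- NULL
  new_mp_network(edges, nodes = sort(unique(c(edges$gene1, edges$gene2))))
}

#' Write a network back to an edge-list file
#'
#' Serializes a `mp_network` in the same dialect accepted by
#' [read_network()], so that write-then-read is the identity.
#'
#' @param net A `mp_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  out <- net$edges
  names(out)[1:3] <- c("protein1", "protein2", "combined_score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Weighted adjacency matrix of a network
#'
#' @param net A `mp_network`.
#' @return A symmetric sparse `dgCMatrix` with rows/columns in node order.
#' @export
network_adjacency <- function(net) {
  n <- length(net$nodes)
  i <- match(net$edges$gene1, net$nodes)
  j <- match(net$edges$gene2, net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(net$edges$weight, 2), dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}

#' Symmetric normalization of the network
#'
#' Computes the symmetrically normalized edge weights
#' \deqn{w'_{ij} = w_{ij} / \sqrt{d_i d_j}, \quad d_i = \sum_j w_{ij},}
#' i.e. the matrix \eqn{D^{-1/2} W D^{-1/2}} whose spectral radius is at
#' most 1. This is the operator used by the label-propagation update.
#' Isolated nodes keep zero rows/columns.
#'
#' @param net A `mp_network`.
#' @return A `mp_network_norm` object: list with the sparse normalized
#'   matrix `W`, the node vector `nodes` and weighted `degrees`.
#' @export
normalize_network <- function(net) {
  stopifnot(inherits(net, "mp_network"))
  if (!nrow(net$edges)) stop("cannot normalize an empty network")
  W <- network_adjacency(net)
  d <- Matrix::rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Wn <- Matrix::Diagonal(x = inv_sqrt) %*% W %*% Matrix::Diagonal(x = inv_sqrt)
  Wn <- methods::as(Wn, "CsparseMatrix")
  dimnames(Wn) <- list(net$nodes, net$nodes)
  structure(list(W = Wn, nodes = net$nodes, degrees = d),
            class = "mp_network_norm")
}

#' @export
print.mp_network_norm <- function(x, ...) {
  cat(sprintf("<mp_network_norm> %d nodes, %d normalized edges\n",
              length(x$nodes), Matrix::nnzero(x$W) / 2))
  invisible(x)
}
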