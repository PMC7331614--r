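# Shared fixture builders. Everything is generated in code; the only
# on-disk fixtures are the tiny plain-text examples under inst/extdata.

extdata <- function(name) {
  system.file("extdata", name, package = "metaboprop", mustWork = TRUE)
}

# Build an mp_network directly from an edge data frame (gene1, gene2, weight).
mk_net <- function(gene1, gene2, weight) {
  a <- pmin(gene1, gene2)
  b <- pmax(gene1, gene2)
  ord <- order(a, b)
  edges <- data.frame(gene1 = a[ord], gene2 = b[ord], weight = weight[ord],
                      stringsAsFactors = FALSE)
  metaboprop:::new_mp_network(edges, sort(unique(c(a, b))))
}

# Random Erdos-Renyi weighted network with all n nodes present.
rand_net <- function(n, p = 0.05, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  genes <- sprintf("N%03d", seq_len(n))
  net <- mk_net(genes[pairs[, 1]], genes[pairs[, 2]],
                stats::runif(nrow(pairs), 1, 10))
  net$nodes <- genes  # keep isolated nodes
  net
}

# Dense brute-force oracle for symmetric normalization: D^-1/2 W D^-1/2.
norm_oracle_dense <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$gene1[r]; j <- net$edges$gene2[r]
    W[i, j] <- W[i, j] + net$edges$weight[r]
    W[j, i] <- W[j, i] + net$edges$weight[r]
  }
  d <- rowSums(W)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(inv, n) %*% W %*% diag(inv, n)
}

# Build an mp_genemap directly.
mk_map <- function(gene, met, mass = rep(NA_real_, length(met))) {
  metaboprop:::build_genemap(gene, met, mass, provenance = "test")
}

# Write a temp edge-list file from literal rows (character vector of lines).
tmp_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
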