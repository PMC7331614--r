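#' Candidate-gene ranking, permutation evaluation and score fusion
#'
#' Candidate genes are ranked by a per-gene score (seed ME, propagated, or
#' a combined score). Ties take the minimum (competition) rank; the
#' percentile of a candidate is 100 * rank / N, and "top 20th percentile"
#' (percentile <= 20) is the prioritization-success criterion. The
#' permutation protocol embeds the causative gene(s) in repeated random
#' candidate sets and records the median rank. The fusion model combines
#' the propagated score with an external phenotype score (Exomiser-style)
#' using a per-gene prior driven by the gene's metabolically annotated
#' network neighborhood.
#'
#' @name ranking
#' @keywords internal
NULL

#' Rank a candidate gene list by score
#'
#' @param scores Named numeric vector of per-gene scores. Candidates
#'   absent from it receive score 0 (and hence sort last).
#' @param candidates Character vector of gene symbols, or a data frame
#'   with a `gene` column. Genes must be unique.
#' @param method Method tag recorded in the output (e.g. `"ME"`,
#'   `"netprop"`, `"exomiser"`, `"combined"`).
#' @return Data frame `gene`, `score`, `rank`, `percentile`, `method`,
#'   ordered by rank (ties in input order).
#' @export
rank_candidates <- function(scores, candidates, method = "netprop") {
  genes <- if (is.data.frame(candidates)) as.character(candidates$gene)
           else as.character(candidates)
  stopifnot(length(genes) >= 1, !anyDuplicated(genes))
  s <- unname(scores[genes])
  s[is.na(s)] <- 0
  r <- rank_desc_min(s)
  out <- data.frame(gene = genes, score = s, rank = r,
                    percentile = 100 * r / length(genes),
                    method = method, stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}

#' Median-rank evaluation over permuted candidate sets
#'
#' Emulates ranking the causative gene(s) out of repeated random candidate
#' lists: each permutation unions the causative genes with `set_size - n`
#' genes drawn uniformly without replacement from the rest of the
#' universe, ranks the set by score, and records the causative ranks. The
#' protocol is fully determined by `seed` (the caller's RNG state is
#' restored afterwards): after `set.seed(seed)`, permutation j draws
#' `sample(setdiff(universe, causative), set_size - n)`.
#'
#' @param scores Named numeric vector of per-gene scores over the
#'   universe.
#' @param causative Character vector of causative gene(s), subset of
#'   `universe`.
#' @param universe Gene universe to draw from (default: names of
#'   `scores`).
#' @param set_size Candidate-set size (default 300).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed (mandatory).
#' @return List with `median_rank` (named, per causative gene), `ranks`
#'   (n_perm x n matrix), `n_perm`, `set_size`, `seed`, `causative`.
#' @export
permutation_evaluate <- function(scores, causative, universe = names(scores),
                                 set_size = 300, n_perm = 1000, seed) {
  stopifnot(!missing(seed), all(causative %in% universe),
            set_size <= length(universe))
  n <- length(causative)
  if (set_size < n) stop("set_size smaller than the number of causative genes")
  others <- setdiff(universe, causative)
  ranks <- matrix(NA_integer_, nrow = n_perm, ncol = n,
                  dimnames = list(NULL, causative))
  with_seed(seed, {
    for (j in seq_len(n_perm)) {
      cand <- c(causative, sample(others, set_size - n))
      s <- unname(scores[cand])
      s[is.na(s)] <- 0
      r <- rank_desc_min(s)
      ranks[j, ] <- r[seq_len(n)]
    }
  })
  list(median_rank = apply(ranks, 2, stats::median), ranks = ranks,
       n_perm = n_perm, set_size = set_size, seed = seed,
       causative = causative)
}

#' First-degree metabolic-neighbor statistics
#'
#' For every network gene: its degree, the fraction of its first-degree
#' neighbors that carry metabolite annotations, and the decile bin of that
#' fraction (bins \[0,10), \[10,20), ..., \[90,100\] percent; isolated
#' genes fall in the first bin with fraction 0).
#'
#' @param net A `mp_network`.
#' @param map A `mp_genemap`.
#' @return Data frame `gene`, `degree`, `n_annotated_neighbors`,
#'   `frac_annotated`, `bin` (1-10).
#' @export
neighbor_stats <- function(net, map) {
  stopifnot(inherits(net, "mp_network"), inherits(map, "mp_genemap"))
  nodes <- net$nodes
  annotated <- nodes %in% names(map$gene_to_mets)
  names(annotated) <- nodes
  ends <- factor(c(net$edges$gene1, net$edges$gene2), levels = nodes)
  other <- c(net$edges$gene2, net$edges$gene1)
  deg <- as.integer(table(ends))
  ann_cnt <- tapply(as.numeric(annotated[other]), ends, sum, default = 0)
  ann_cnt <- as.integer(ann_cnt)
  frac <- ifelse(deg > 0, ann_cnt / deg, 0)
  data.frame(gene = nodes, degree = deg, n_annotated_neighbors = ann_cnt,
             frac_annotated = frac,
             bin = pmin(floor(frac * 10), 9) + 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine propagated and external phenotype scores
#'
#' Weighted additive fusion C = scaled(p * E) + scaled((1 - p) * M), where
#' E is the external (Exomiser-style) phenotype score, M the propagated
#' score, and p the per-gene prior: the fraction of full-network genes in
#' the gene's metabolic-first-neighbor decile bin that the propagated
#' ranking places in the top `top_fraction` of the whole network. Genes
#' with many metabolically annotated neighbors (high prior of being
#' propagated upward regardless of disease status) thus lean on the
#' phenotype score, and sparsely connected genes lean on the metabolomic
#' evidence. E and M are each min-max scaled over the candidate list
#' before weighting, and the two weighted terms are min-max scaled again
#' before summation.
#'
#' @param prop A `mp_propagation` over the full network (or a named score
#'   vector covering it); bin priors are computed from this full-network
#'   ranking.
#' @param exo Named numeric vector of external phenotype scores. A missing
#'   candidate score is treated as 0 with a warning.
#' @param candidates Character vector or data frame with a `gene` column
#'   (and optionally an `exomiser` column used when `exo` is missing).
#' @param stats Neighborhood table from [neighbor_stats()].
#' @param top_fraction Top fraction defining "prioritized" in the prior
#'   (default 0.20).
#' @return Data frame `gene`, `prior`, `exomiser_scaled`,
#'   `netprop_scaled`, `term_exomiser`, `term_netprop`, `score`, `rank`,
#'   `percentile`, `method = "combined"`, ordered by rank.
#' @export
combine_scores <- function(prop, exo = NULL, candidates, stats,
                           top_fraction = 0.20) {
  scores <- if (inherits(prop, "mp_propagation")) prop$scores else prop
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            top_fraction > 0, top_fraction < 1)
  genes <- if (is.data.frame(candidates)) as.character(candidates$gene)
           else as.character(candidates)
  if (is.null(exo) && is.data.frame(candidates) && "exomiser" %in% names(candidates)) {
    exo <- stats::setNames(candidates$exomiser, genes)
  }
  if (is.null(exo)) stop("no external phenotype scores provided")

  # per-bin prior from the full-network propagated ranking
  net_rank <- rank_desc_min(scores)
  in_top <- 100 * net_rank / length(scores) <= 100 * top_fraction
  stats <- stats[match(names(scores), stats$gene), ]
  p_bin <- tapply(in_top, stats$bin, mean)

  prior <- rep(1, length(genes))  # off-network: full weight on phenotype
  idx <- match(genes, stats$gene)
  on_net <- !is.na(idx)
  prior[on_net] <- unname(p_bin[as.character(stats$bin[idx[on_net]])])

  E <- unname(exo[genes])
  if (anyNA(E)) {
    warning(sum(is.na(E)), " candidate(s) without external score treated as 0")
    E[is.na(E)] <- 0
  }
  M <- unname(scores[genes])
  M[is.na(M)] <- 0

  E_s <- minmax01(E)
  M_s <- minmax01(M)
  t_e <- minmax01(prior * E_s)
  t_m <- minmax01((1 - prior) * M_s)
  C <- t_e + t_m
  r <- rank_desc_min(C)
  out <- data.frame(gene = genes, prior = prior, exomiser_scaled = E_s,
                    netprop_scaled = M_s, term_exomiser = t_e,
                    term_netprop = t_m, score = C, rank = r,
                    percentile = 100 * r / length(genes),
                    method = "combined", stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}
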