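#' Per-gene metabolic enrichment (ME) seed scores
#'
#' For each gene with annotated metabolites among the measured set, a
#' one-sided Fisher's exact test asks whether the patient's differentially
#' abundant metabolites (DAMs) are over-represented among that gene's
#' annotated metabolites. The unadjusted p-value and the gene's
#' largest-magnitude metabolite z-score are combined into the ME score,
#' which -- min-max scaled to the unit interval -- becomes the gene's
#' seed label for network propagation.
#'
#' @name enrichment
#' @keywords internal
NULL

#' One-sided Fisher enrichment of DAMs per gene
#'
#' The metabolite universe is the set of metabolites that are both
#' measured and annotated to at least one gene (unannotated features are
#' filtered upstream). For a gene with `m` annotated measured metabolites
#' of which `k` are DAMs, with `K` DAMs among `M` universe metabolites,
#' the one-sided over-representation p-value is the hypergeometric upper
#' tail P(X >= k). Genes with `m = 0` are reported untested (`NA` p).
#' Benjamini-Hochberg FDR is computed across tested genes and reported
#' alongside; seed scoring itself uses the unadjusted p.
#'
#' @param dams DAM set: data frame from [call_dams()] or a character
#'   vector of metabolite IDs. Must be a subset of the measured set.
#' @param zscores Measured metabolite z-scores: data frame `id`, `z`.
#' @param map A `mp_genemap`.
#' @return Data frame with one row per gene in the map: `gene`, `k`, `m`,
#'   `K`, `M`, `p`, `fdr`, `z_max`, `tested`.
#' @examples
#' map <- metaboprop:::new_mp_genemap(
#'   list(g1 = c("m1", "m2", "m3")),
#'   stats::setNames(rep(NA_real_, 3), c("m1", "m2", "m3")))
#' z <- data.frame(id = c("m1", "m2", "m3"), z = c(3, -2.5, 0.1))
#' fisher_enrichment(call_dams(z), z, map)
#' @export
fisher_enrichment <- function(dams, zscores, map) {
  stopifnot(inherits(map, "mp_genemap"),
            all(c("id", "z") %in% names(zscores)))
  dam_ids <- if (is.data.frame(dams)) dams$id else as.character(dams)
  measured <- unique(zscores$id)
  if (!all(dam_ids %in% measured)) {
    stop("DAM set must be a subset of the measured metabolites")
  }
  z <- stats::setNames(zscores$z, zscores$id)

  universe <- intersect(measured, annotated_metabolites(map))
  M <- length(universe)
  K <- length(intersect(dam_ids, universe))

  genes <- names(map$gene_to_mets)
  res <- data.frame(gene = genes, k = 0L, m = 0L, K = K, M = M,
                    p = NA_real_, fdr = NA_real_, z_max = 0,
                    tested = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    mets <- intersect(map$gene_to_mets[[i]], universe)
    m <- length(mets)
    if (m == 0) next
    k <- length(intersect(mets, dam_ids))
    res$k[i] <- k
    res$m[i] <- m
    res$tested[i] <- TRUE
    # upper hypergeometric tail P(X >= k); k = 0 gives p = 1 exactly
    res$p[i] <- stats::phyper(k - 1, K, M - K, m, lower.tail = FALSE)
    res$z_max[i] <- max(abs(z[mets]))
  }
  res$fdr[res$tested] <- bh_adjust(res$p[res$tested])
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' input order preserved.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the same order; empty in, empty out.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Metabolic enrichment score and seed labels
#'
#' Combines each tested gene's unadjusted enrichment p-value with the
#' largest-magnitude z-score among its annotated metabolites. Two scoring
#' modes are provided:
#' \describe{
#'   \item{`neglog` (default)}{raw ME = -log2(p) * z_max, jointly monotone:
#'     stronger enrichment and larger perturbation both raise the score.}
#'   \item{`eq3_literal`}{raw ME = -log2(2 + p) * z_max, the published
#'     transform, retained for strict reproduction (its negative factor
#'     makes the raw score decrease with z_max).}
#' }
#' Raw scores of genes with at least one annotated DAM (k >= 1) are
#' min-max scaled to \[0, 1\] (all-equal scores map to 1); genes with no
#' annotated DAMs (k = 0, including untested genes) receive exactly 0 and
#' therefore contribute no seed signal.
#'
#' @param enr Enrichment table from [fisher_enrichment()].
#' @param mode `"neglog"` or `"eq3_literal"`.
#' @return Data frame `gene`, `k`, `me_raw`, `me_scaled`, with the mode as
#'   an attribute.
#' @export
me_score <- function(enr, mode = c("neglog", "eq3_literal")) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "k", "p", "z_max", "tested") %in% names(enr)))
  raw <- numeric(nrow(enr))
  live <- enr$tested & enr$k >= 1
  if (any(live)) {
    p <- enr$p[live]
    zmax <- enr$z_max[live]
    raw[live] <- switch(mode,
      neglog = -log2(p) * zmax,
      eq3_literal = -log2(2 + p) * zmax)
  }
  scaled <- numeric(nrow(enr))
  scaled[live] <- minmax01(raw[live])
  out <- data.frame(gene = enr$gene, k = enr$k, me_raw = raw,
                    me_scaled = scaled, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Seed labels as a named vector
#'
#' @param seeds Data frame from [me_score()].
#' @return Named numeric vector of scaled ME scores.
#' @export
seed_vector <- function(seeds) {
  stats::setNames(seeds$me_scaled, seeds$gene)
}
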