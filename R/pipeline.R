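#' End-to-end scoring pipeline
#'
#' Orchestrates annotation, abundance, enrichment, propagation and
#' ranking for a single patient: metabolite z-scores (curated, or derived
#' from a raw feature table) -> DAM calling -> per-gene Fisher enrichment
#' -> ME seed labels -> label propagation over the normalized network ->
#' candidate rankings (seed-only, propagated, and -- when an external
#' phenotype score is available -- the combined model).
#'
#' @name pipeline
#' @keywords internal
NULL

#' Read a candidate-gene list
#'
#' TSV with a `gene` column and optional `exomiser` external phenotype
#' score column.
#'
#' @param path Path to the TSV.
#' @return Data frame with `gene` and, if present, `exomiser`.
#' @export
read_candidates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab)) stop("candidate file needs a 'gene' column: ", path)
  tab
}

#' Read a curated metabolite z-score table
#'
#' TSV with columns `metabolite_id` and `z` (one patient).
#'
#' @param path Path to the TSV.
#' @return Data frame `id`, `z`.
#' @export
read_zscore_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "z") %in% names(tab))) {
    stop("z-score file needs columns 'metabolite_id' and 'z': ", path)
  }
  data.frame(id = as.character(tab$metabolite_id), z = as.numeric(tab$z),
             stringsAsFactors = FALSE)
}

#' Run the scoring pipeline for one patient
#'
#' @param network A `mp_network` or path to an edge-list file.
#' @param genemap A `mp_genemap` or path to an annotation file.
#' @param metabolomics Either a curated z-score table (data frame `id`,
#'   `z`, or a path to one) or a raw input list as produced by
#'   [make_feature_table()]: `features` (feature_id, mz, mode, isotope),
#'   `intensities` (raw matrix), `patient`, `controls`.
#' @param candidates Optional candidate list (data frame with `gene` and
#'   optionally `exomiser`, character vector, or path). Without it only
#'   network-wide scores are returned.
#' @param dam_threshold Absolute z cut-off for DAM calling (default 2).
#' @param scoring_mode ME scoring mode, `"neglog"` or `"eq3_literal"`.
#' @param lambda,tol,max_iter Propagation parameters (see
#'   [propagate_labels()]).
#' @param ppm_tol,adduct_model Feature-annotation parameters for the raw
#'   path (see [match_features()]).
#' @param min_prevalence Prevalence filter for the raw path.
#' @param top_fraction Prior cut-off for the combined model.
#' @param out_dir Optional output directory; rankings and a run manifest
#'   are written as TSV/JSON.
#' @return List with `zscores`, `dams`, `enrichment`, `seeds`,
#'   `propagation`, `rankings` (list of data frames: `ME`, `netprop`, and
#'   `combined` when an external score is present) and `manifest`.
#' @export
run_score <- function(network, genemap, metabolomics, candidates = NULL,
                      dam_threshold = 2, scoring_mode = "neglog",
                      lambda = 0.99, tol = 1e-6, max_iter = 10000,
                      ppm_tol = 15, adduct_model = "protonation",
                      min_prevalence = 0.10, top_fraction = 0.20,
                      out_dir = NULL) {
  if (is.character(network)) network <- read_network(network)
  if (is.character(genemap)) genemap <- read_gene_metabolite_map(genemap)
  if (is.character(candidates)) {
    candidates <- if (length(candidates) == 1 && file.exists(candidates)) {
      read_candidates(candidates)
    } else {
      data.frame(gene = candidates, stringsAsFactors = FALSE)
    }
  }
  if (is.character(metabolomics)) metabolomics <- read_zscore_table(metabolomics)

  if (is.data.frame(metabolomics)) {
    zmet <- metabolomics[, c("id", "z")]
    raw_path <- FALSE
  } else {
    raw_path <- TRUE
    stopifnot(all(c("features", "intensities", "patient") %in% names(metabolomics)))
    mat <- preprocess_features(metabolomics$intensities,
                               min_prevalence = min_prevalence)
    mat <- linear_baseline_normalize(log2(mat))
    fz <- zscore_patient(mat, metabolomics$patient)
    ann <- match_features(metabolomics$features, genemap, ppm_tol = ppm_tol,
                          adduct_model = adduct_model)
    feats <- metabolomics$features[metabolomics$features$feature_id %in% fz$id, ]
    feats <- filter_features(feats, ann)
    fz <- fz[fz$id %in% feats$feature_id, ]
    zmet <- feature_z_to_metabolites(fz, ann)
  }

  dams <- call_dams(zmet, threshold = dam_threshold)
  enr <- fisher_enrichment(dams, zmet, genemap)
  seeds <- me_score(enr, mode = scoring_mode)
  nnet <- normalize_network(network)
  prop <- suppressWarnings(
    propagate_labels(nnet, seeds, lambda = lambda, tol = tol,
                     max_iter = max_iter))

  rankings <- list()
  if (!is.null(candidates)) {
    rankings$ME <- rank_candidates(seed_vector(seeds), candidates,
                                   method = "ME")
    rankings$netprop <- rank_candidates(prop$scores, candidates,
                                        method = "netprop")
    if (is.data.frame(candidates) && "exomiser" %in% names(candidates)) {
      st <- neighbor_stats(network, genemap)
      rankings$combined <- combine_scores(prop, candidates = candidates,
                                          stats = st,
                                          top_fraction = top_fraction)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("metaboprop")),
    input_path = if (raw_path) "raw_features" else "curated_zscores",
    parameters = list(dam_threshold = dam_threshold,
                      scoring_mode = scoring_mode, lambda = lambda,
                      tol = tol, ppm_tol = ppm_tol,
                      adduct_model = adduct_model,
                      top_fraction = top_fraction),
    counts = list(
      network_genes = length(network$nodes),
      network_edges = nrow(network$edges),
      measured_metabolites = nrow(zmet),
      dams = nrow(dams),
      genes_tested = sum(enr$tested),
      seeds_positive = sum(seeds$me_scaled > 0),
      propagation_iterations = prop$iterations,
      candidates = if (is.null(candidates)) 0L
                   else if (is.data.frame(candidates)) nrow(candidates)
                   else length(candidates)))

  result <- list(zscores = zmet, dams = dams, enrichment = enr,
                 seeds = seeds, propagation = prop, rankings = rankings,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = names(prop$scores), f_score = unname(prop$scores)),
      file.path(out_dir, "propagated_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(rankings)) {
      utils::write.table(rankings[[nm]],
                         file.path(out_dir, paste0("ranking_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Run the permutation evaluation protocol
#'
#' Thin driver over [permutation_evaluate()] using a pipeline result (or
#' any named score vector) as the score source and the full network as
#' the sampling universe.
#'
#' @param result A [run_score()] result, `mp_propagation`, or named score
#'   vector.
#' @param causative Causative gene(s).
#' @param set_size,n_perm,seed See [permutation_evaluate()].
#' @param out_file Optional TSV path for the per-permutation ranks.
#' @return The [permutation_evaluate()] summary.
#' @export
run_permutations <- function(result, causative, set_size = 300,
                             n_perm = 1000, seed, out_file = NULL) {
  scores <- if (is.list(result) && !is.null(result$propagation)) {
    result$propagation$scores
  } else if (inherits(result, "mp_propagation")) {
    result$scores
  } else {
    result
  }
  perm <- permutation_evaluate(scores, causative, set_size = set_size,
                               n_perm = n_perm, seed = seed)
  if (!is.null(out_file)) {
    out <- data.frame(permutation = seq_len(perm$n_perm), perm$ranks,
                      check.names = FALSE)
    utils::write.table(out, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  perm
}
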