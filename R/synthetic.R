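#' Synthetic fixtures: networks, annotation maps and patients
#'
#' Fully synthetic inputs with the statistical structure the method
#' assumes, so every pipeline stage is testable without external
#' databases. The generator emulates the shapes of the real inputs: a
#' STRING-like weighted gene graph, an HMDB-like gene-to-metabolite map, a
#' curated per-patient metabolite z-score table (background z standard
#' normal, disease signal as a z-shift on the metabolites of selected
#' genes), and optionally a raw LC-MS style feature table. All generators
#' are bit-reproducible under the configured seed.
#'
#' @name synthetic
#' @keywords internal
NULL

#' Synthetic-fixture configuration
#'
#' @param n_genes Number of network genes (>= 10; default 500).
#' @param edge_model `"scale_free"` (preferential attachment, `pa_m` edges
#'   per new node; the default, matching the heavy-tailed degree
#'   distribution of protein networks) or `"erdos_renyi"` with edge
#'   probability `gnp_p`.
#' @param pa_m Edges per node in scale-free mode (default 3).
#' @param gnp_p Edge probability in Erdos-Renyi mode (default 0.02).
#' @param annotated_frac Fraction of genes carrying metabolite annotations
#'   (default 0.6).
#' @param mets_per_gene Range (min, max) of metabolites per annotated gene
#'   (default 2-6).
#' @param met_pool_factor Metabolite pool size relative to total
#'   assignments; < 1 induces sharing of metabolites between genes
#'   (default 0.8).
#' @param n_controls Control samples for raw feature tables (default 20).
#' @param causative_mode `"direct"` (the causative gene's own metabolites
#'   are shifted), `"neighbor_only"` (the causative gene is unannotated;
#'   metabolites of its annotated first neighbors are shifted) or
#'   `"null"` (an unrelated gene's metabolites are shifted).
#' @param effect_size Mean z-shift applied to perturbed metabolites
#'   (default 3).
#' @param noise_sd Background z-score standard deviation (default 1).
#' @param min_seed_neighbors Minimum annotated first neighbors a
#'   neighbor-only causative gene must have (default 3).
#' @param seed Integer RNG seed (mandatory).
#' @return A `mp_synth_config` list.
#' @export
synth_config <- function(n_genes = 500,
                         edge_model = c("scale_free", "erdos_renyi"),
                         pa_m = 3, gnp_p = 0.02,
                         annotated_frac = 0.6, mets_per_gene = c(2, 6),
                         met_pool_factor = 0.8, n_controls = 20,
                         causative_mode = c("direct", "neighbor_only", "null"),
                         effect_size = 3, noise_sd = 1,
                         min_seed_neighbors = 3, seed) {
  stopifnot(!missing(seed), n_genes >= 10,
            annotated_frac > 0, annotated_frac <= 1,
            length(mets_per_gene) == 2, mets_per_gene[1] >= 1,
            n_controls >= 2, effect_size >= 0, noise_sd > 0)
  structure(list(
    n_genes = n_genes, edge_model = match.arg(edge_model), pa_m = pa_m,
    gnp_p = gnp_p, annotated_frac = annotated_frac,
    mets_per_gene = mets_per_gene, met_pool_factor = met_pool_factor,
    n_controls = n_controls, causative_mode = match.arg(causative_mode),
    effect_size = effect_size, noise_sd = noise_sd,
    min_seed_neighbors = min_seed_neighbors, seed = as.integer(seed)),
    class = "mp_synth_config")
}

#' Generate a synthetic weighted gene network
#'
#' STRING-like integer edge weights in 150-999 on an Erdos-Renyi or
#' scale-free random graph; deterministic under `cfg$seed`.
#'
#' @param cfg A `mp_synth_config`.
#' @return A `mp_network`.
#' @export
make_network <- function(cfg) {
  stopifnot(inherits(cfg, "mp_synth_config"))
  with_seed(cfg$seed, {
    g <- switch(cfg$edge_model,
      erdos_renyi = igraph::sample_gnp(cfg$n_genes, cfg$gnp_p),
      scale_free = igraph::sample_pa(cfg$n_genes, m = cfg$pa_m,
                                     directed = FALSE))
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    w <- sample(150:999, nrow(el), replace = TRUE)
    a <- pmin(genes[el[, 1]], genes[el[, 2]])
    b <- pmax(genes[el[, 1]], genes[el[, 2]])
    ord <- order(a, b)
    edges <- data.frame(gene1 = a[ord], gene2 = b[ord], weight = w[ord],
                        stringsAsFactors = FALSE)
    # every generated gene is a node even if isolated under sparse models
    new_mp_network(edges, nodes = genes)
  })
}

#' Generate a synthetic gene-to-metabolite map
#'
#' A fraction of network genes receive 2-6 metabolites drawn from a
#' shared pool (pool smaller than the total assignment count, so some
#' metabolites are annotated to several genes, as in HMDB). Masses are
#' uniform on 80-900 Da.
#'
#' @param cfg A `mp_synth_config`.
#' @param net The network from [make_network()].
#' @return A `mp_genemap`.
#' @export
make_gene_metabolite_map <- function(cfg, net) {
  stopifnot(inherits(cfg, "mp_synth_config"), inherits(net, "mp_network"))
  with_seed(cfg$seed + 1L, {
    n_ann <- max(1L, round(cfg$annotated_frac * length(net$nodes)))
    ann_genes <- sort(sample(net$nodes, n_ann))
    n_mets <- sample(cfg$mets_per_gene[1]:cfg$mets_per_gene[2], n_ann,
                     replace = TRUE)
    pool_size <- max(max(n_mets), ceiling(sum(n_mets) * cfg$met_pool_factor))
    pool <- sprintf("SMET%05d", seq_len(pool_size))
    masses <- round(stats::runif(pool_size, 80, 900), 4)
    gene <- rep(ann_genes, n_mets)
    met <- unlist(lapply(n_mets, function(k) sample(pool, k)))
    build_genemap(gene, met, masses[match(met, pool)],
                  provenance = "synthetic")
  })
}

#' Generate a synthetic patient z-score table with planted signal
#'
#' Background metabolite z-scores are drawn N(0, `noise_sd`); the planted
#' disease signal adds a (randomly signed) shift of mean `effect_size` to
#' the metabolites of the perturbed gene(s):
#' \describe{
#'   \item{direct}{an annotated causative gene is drawn and its own
#'     metabolites shifted.}
#'   \item{neighbor_only}{the causative gene is drawn among unannotated
#'     genes with at least `min_seed_neighbors` annotated first neighbors;
#'     the metabolites of all its annotated first neighbors are shifted,
#'     while the causative gene itself has none (the configuration where
#'     direct enrichment is blind and only propagation can help).}
#'   \item{null}{the causative gene is drawn at random and the shift
#'     applied to an unrelated (non-adjacent) gene.}
#' }
#'
#' @param cfg A `mp_synth_config`.
#' @param net The network.
#' @param map The gene-metabolite map for `net`.
#' @param index Patient index; patient i uses seed `cfg$seed + 1000 + i`
#'   so cohorts are reproducible patient-by-patient.
#' @return List with `zscores` (data frame `id`, `z`), `causative`,
#'   `truth` (mode, shifted genes/metabolites, seed used).
#' @export
make_patient <- function(cfg, net, map, index = 1L) {
  stopifnot(inherits(cfg, "mp_synth_config"), inherits(map, "mp_genemap"))
  patient_seed <- cfg$seed + 1000L + as.integer(index)
  with_seed(patient_seed, {
    mets <- annotated_metabolites(map)
    z <- stats::rnorm(length(mets), 0, cfg$noise_sd)
    names(z) <- mets
    ann_genes <- names(map$gene_to_mets)

    mode <- cfg$causative_mode
    if (mode == "direct") {
      causative <- sample(intersect(ann_genes, net$nodes), 1)
      shifted_genes <- causative
    } else if (mode == "neighbor_only") {
      st <- neighbor_stats(net, map)
      eligible <- st$gene[!(st$gene %in% ann_genes) &
                            st$n_annotated_neighbors >= cfg$min_seed_neighbors]
      if (!length(eligible)) {
        stop("no unannotated gene with >= ", cfg$min_seed_neighbors,
             " annotated first neighbors; regenerate with a denser or more",
             " annotated network")
      }
      causative <- sample(eligible, 1)
      nb <- unique(c(net$edges$gene2[net$edges$gene1 == causative],
                     net$edges$gene1[net$edges$gene2 == causative]))
      shifted_genes <- intersect(nb, ann_genes)
    } else {
      causative <- sample(net$nodes, 1)
      nb <- unique(c(net$edges$gene2[net$edges$gene1 == causative],
                     net$edges$gene1[net$edges$gene2 == causative]))
      unrelated <- setdiff(ann_genes, c(causative, nb))
      shifted_genes <- sample(unrelated, 1)
    }

    shifted_mets <- unique(unlist(map$gene_to_mets[shifted_genes]))
    sign_shift <- sample(c(-1, 1), length(shifted_mets), replace = TRUE)
    z[shifted_mets] <- z[shifted_mets] + sign_shift * cfg$effect_size

    list(zscores = data.frame(id = mets, z = unname(z),
                              stringsAsFactors = FALSE),
         causative = causative,
         truth = list(mode = mode, causative = causative,
                      shifted_genes = shifted_genes,
                      shifted_metabolites = shifted_mets,
                      effect_size = cfg$effect_size, seed = patient_seed))
  })
}

#' Generate a raw LC-MS style feature table matching the map
#'
#' One feature per metabolite with known mass (observed m/z = protonated
#' mass with up to 5 ppm jitter, positive mode), plus unannotated noise
#' features and non-base isotope features that the pre-enrichment filters
#' must remove. Intensities are log-normal; one patient column plus
#' `cfg$n_controls` controls.
#'
#' @param cfg A `mp_synth_config`.
#' @param map The gene-metabolite map.
#' @param n_noise Unannotated noise features (default 10).
#' @param n_isotope Non-base isotope features (default 5).
#' @param index Patient index (seed offset as in [make_patient()]).
#' @return List with `features` (data frame `feature_id`, `mz`, `mode`,
#'   `isotope`, `metabolite_id`), `intensities` (matrix features x
#'   samples, raw scale), `patient`, `controls`.
#' @export
make_feature_table <- function(cfg, map, n_noise = 10, n_isotope = 5,
                               index = 1L) {
  stopifnot(inherits(cfg, "mp_synth_config"), inherits(map, "mp_genemap"))
  with_seed(cfg$seed + 5000L + as.integer(index), {
    masses <- map$met_masses[!is.na(map$met_masses)]
    n_real <- length(masses)
    jitter <- stats::runif(n_real, -5e-6, 5e-6)
    mz_real <- (masses + PROTON_MASS) * (1 + jitter)
    # noise m/z placed far (>100 ppm) from any annotated protonated mass
    mz_noise <- (stats::runif(n_noise, 80, 900) + PROTON_MASS) * (1 + 5e-4)
    iso_src <- sample(n_real, n_isotope, replace = n_isotope > n_real)
    mz_iso <- mz_real[iso_src] + 1.00336  # 13C spacing

    features <- data.frame(
      feature_id = sprintf("F%04d", seq_len(n_real + n_noise + n_isotope)),
      mz = c(mz_real, mz_noise, mz_iso),
      mode = "positive",
      isotope = c(rep("[M]", n_real), rep("", n_noise),
                  rep("[M+1]", n_isotope)),
      metabolite_id = c(names(masses), rep(NA, n_noise),
                        names(masses)[iso_src]),
      stringsAsFactors = FALSE)

    samples <- c("PATIENT", sprintf("CTRL%02d", seq_len(cfg$n_controls)))
    mu <- stats::runif(nrow(features), 14, 22)   # log2 mean intensity
    logI <- matrix(stats::rnorm(nrow(features) * length(samples),
                                mean = mu, sd = 0.8),
                   nrow = nrow(features),
                   dimnames = list(features$feature_id, samples))
    intensities <- 2^logI
    list(features = features, intensities = intensities,
         patient = "PATIENT", controls = samples[-1])
  })
}

#' Write a complete synthetic fixture directory
#'
#' Emits the four pipeline inputs as plain-text files: `network.tsv`,
#' `genemap.tsv`, `zscores.tsv` (one synthetic patient),
#' `candidates.tsv` (causative gene plus random candidates with synthetic
#' external phenotype scores) and `truth.json`.
#'
#' @param cfg A `mp_synth_config`.
#' @param out_dir Output directory (created if absent).
#' @param n_candidates Candidate-list size (default 300, capped at the
#'   network size).
#' @return Named character vector of written paths, invisibly.
#' @export
simulate_fixture <- function(cfg, out_dir, n_candidates = 300) {
  net <- make_network(cfg)
  map <- make_gene_metabolite_map(cfg, net)
  pat <- make_patient(cfg, net, map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- c(network = file.path(out_dir, "network.tsv"),
             genemap = file.path(out_dir, "genemap.tsv"),
             zscores = file.path(out_dir, "zscores.tsv"),
             candidates = file.path(out_dir, "candidates.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_network(net, paths["network"])

  gm <- data.frame(
    gene = rep(names(map$gene_to_mets),
               lengths(map$gene_to_mets)),
    metabolite_id = unlist(map$gene_to_mets, use.names = FALSE),
    stringsAsFactors = FALSE)
  gm$monoisotopic_mass <- map$met_masses[gm$metabolite_id]
  utils::write.table(gm, paths["genemap"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  z <- pat$zscores
  names(z) <- c("metabolite_id", "z")
  utils::write.table(z, paths["zscores"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  n_candidates <- min(n_candidates, length(net$nodes))
  cand <- with_seed(cfg$seed + 2L, {
    genes <- unique(c(pat$causative,
                      sample(setdiff(net$nodes, pat$causative),
                             n_candidates - 1)))
    data.frame(gene = genes,
               exomiser = round(stats::runif(length(genes)), 4),
               stringsAsFactors = FALSE)
  })
  utils::write.table(cand, paths["candidates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  jsonlite::write_json(pat$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
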