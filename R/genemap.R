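#' Gene-to-metabolite annotation maps
#'
#' A `mp_genemap` holds curated gene-to-metabolite associations of the kind
#' distributed by HMDB: for each gene symbol, the set of metabolite
#' accessions annotated to it, and for each metabolite its monoisotopic
#' mass (Da) where known. The map drives both enrichment testing (which
#' metabolites "belong" to a gene) and exact-mass feature annotation.
#'
#' @name mp_genemap
#' @keywords internal
NULL

new_mp_genemap <- function(gene_to_mets, met_masses, provenance = "") {
  structure(list(gene_to_mets = gene_to_mets, met_masses = met_masses,
                 provenance = provenance), class = "mp_genemap")
}

#' @export
print.mp_genemap <- function(x, ...) {
  cat(sprintf("<mp_genemap> %d genes, %d metabolites (%d with mass)%s\n",
              length(x$gene_to_mets), length(x$met_masses),
              sum(!is.na(x$met_masses)),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' All metabolite IDs annotated to at least one gene
#' @param map A `mp_genemap`.
#' @return Character vector of metabolite IDs.
#' @export
annotated_metabolites <- function(map) {
  sort(unique(unlist(map$gene_to_mets, use.names = FALSE)))
}

#' Read a gene-metabolite annotation map
#'
#' Accepts either a TSV with columns `gene`, `metabolite_id` and optional
#' `monoisotopic_mass`, or a reduced HMDB-style XML export (see
#' [read_hmdb_xml()]); the dialect is chosen from the file extension.
#' Duplicate rows are merged with set semantics. Rows with an empty
#' metabolite field are skipped with a warning; a non-positive mass is an
#' error.
#'
#' @param path Path to the TSV or XML file.
#' @param provenance Free-text source tag stored on the map.
#' @return A `mp_genemap`.
#' @export
read_gene_metabolite_map <- function(path, provenance = basename(path)) {
  if (grepl("\\.xml$", path, ignore.case = TRUE)) {
    return(read_hmdb_xml(path, provenance = provenance))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("gene", "metabolite_id")
  if (!all(need %in% names(tab))) {
    stop("annotation TSV must have columns 'gene' and 'metabolite_id': ", path)
  }
  gene <- as.character(tab$gene)
  met <- as.character(tab$metabolite_id)
  mass <- if ("monoisotopic_mass" %in% names(tab)) {
    as.numeric(tab$monoisotopic_mass)
  } else {
    rep(NA_real_, nrow(tab))
  }
  empty <- is.na(met) | met == ""
  if (any(empty)) {
    warning(sum(empty), " row(s) with empty metabolite field skipped")
    gene <- gene[!empty]; met <- met[!empty]; mass <- mass[!empty]
  }
  if (any(!is.na(mass) & mass <= 0)) {
    stop("non-positive monoisotopic mass in ", path)
  }
  build_genemap(gene, met, mass, provenance)
}

build_genemap <- function(gene, met, mass, provenance) {
  gene_to_mets <- lapply(split(met, gene), function(x) sort(unique(x)))
  mets <- sort(unique(met))
  met_masses <- rep(NA_real_, length(mets))
  names(met_masses) <- mets
  known <- !is.na(mass)
  if (any(known)) {
    # first stated mass wins; duplicates with conflicting masses are rare
    # in curated exports and not re-adjudicated here
    first <- !duplicated(met) & known
    met_masses[met[first]] <- mass[first]
    miss <- is.na(met_masses[met]) & known
    met_masses[met[miss]] <- mass[miss]
  }
  new_mp_genemap(gene_to_mets, met_masses, provenance)
}

#' Read a reduced HMDB metabolite XML export
#'
#' Parses an XML document of `<metabolite>` records carrying an
#' `<accession>`, a monoisotopic mass (either `<monoisotopic_mass>` or
#' HMDB's `<monisotopic_molecular_weight>` tag) and associated
#' `<gene_name>` elements, producing the same map as the equivalent TSV.
#'
#' @param path Path to the XML file.
#' @param provenance Free-text source tag.
#' @return A `mp_genemap`.
#' @export
read_hmdb_xml <- function(path, provenance = basename(path)) {
  doc <- xml2::read_xml(path)
  recs <- xml2::xml_find_all(doc, ".//metabolite")
  if (!length(recs)) stop("no <metabolite> records in ", path)
  gene <- character(0); met <- character(0); mass <- numeric(0)
  for (rec in recs) {
    acc <- xml2::xml_text(xml2::xml_find_first(rec, "./accession"))
    if (is.na(acc) || acc == "") stop("metabolite record without accession in ", path)
    mnode <- xml2::xml_find_first(
      rec, "./monoisotopic_mass | ./monisotopic_molecular_weight")
    m <- suppressWarnings(as.numeric(xml2::xml_text(mnode)))
    if (!is.na(m) && m <= 0) stop("non-positive monoisotopic mass for ", acc)
    genes <- xml2::xml_text(xml2::xml_find_all(rec, ".//gene_name"))
    genes <- genes[genes != ""]
    if (!length(genes)) next
    gene <- c(gene, genes)
    met <- c(met, rep(acc, length(genes)))
    mass <- c(mass, rep(m, length(genes)))
  }
  if (!length(gene)) stop("no gene associations found in ", path)
  build_genemap(gene, met, mass, provenance)
}

PROTON_MASS <- 1.007276

#' Annotate m/z features by exact-mass matching
#'
#' Matches each observed feature m/z against all metabolite monoisotopic
#' masses in the map, retaining every metabolite identity within the ppm
#' tolerance (boundary inclusive). Under `adduct_model = "protonation"` the
#' candidate mass is shifted by +/- one proton (1.007276 Da) according to
#' the feature's ionization mode; under `"neutral"` the observed value is
#' compared to the neutral monoisotopic mass directly. The relative error
#' denominator is the candidate (theoretical) mass.
#'
#' @param features Data frame with columns `feature_id`, `mz` and
#'   optionally `mode` (`"positive"`, `"negative"` or `"neutral"`; default
#'   neutral).
#' @param map A `mp_genemap` providing metabolite masses.
#' @param ppm_tol Mass tolerance in parts per million (default 15).
#' @param adduct_model `"protonation"` or `"neutral"`.
#' @return Data frame with one row per (feature, metabolite) match:
#'   `feature_id`, `metabolite_id`, `ppm_error`.
#' @export
match_features <- function(features, map, ppm_tol = 15,
                           adduct_model = c("protonation", "neutral")) {
  stopifnot(ppm_tol > 0, all(c("feature_id", "mz") %in% names(features)))
  adduct_model <- match.arg(adduct_model)
  mode <- if ("mode" %in% names(features)) as.character(features$mode)
          else rep("neutral", nrow(features))
  ok_modes <- c("positive", "negative", "neutral")
  if (any(!mode %in% ok_modes)) {
    stop("unknown ionization mode: ",
         paste(unique(setdiff(mode, ok_modes)), collapse = ", "))
  }
  shift <- if (adduct_model == "protonation") {
    c(positive = PROTON_MASS, negative = -PROTON_MASS, neutral = 0)[mode]
  } else {
    rep(0, nrow(features))
  }
  masses <- map$met_masses[!is.na(map$met_masses)]
  out <- list()
  if (length(masses) && nrow(features)) {
    # candidate[i, k] = mass of metabolite k under feature i's adduct
    cand <- outer(unname(shift), unname(masses), "+")
    ppm <- abs(features$mz - cand) / cand * 1e6
    # inclusive boundary, guarded against floating-point representation
    # error at the tolerance itself (1e-6 ppm is far below instrument
    # precision)
    hit <- which(ppm <= ppm_tol + 1e-6, arr.ind = TRUE)
    out <- data.frame(
      feature_id = features$feature_id[hit[, 1]],
      metabolite_id = names(masses)[hit[, 2]],
      ppm_error = ppm[hit],
      stringsAsFactors = FALSE)
    out <- out[order(match(out$feature_id, features$feature_id), out$metabolite_id), ]
    rownames(out) <- NULL
    return(out)
  }
  data.frame(feature_id = character(0), metabolite_id = character(0),
             ppm_error = numeric(0), stringsAsFactors = FALSE)
}

#' Filter annotated features
#'
#' Applies the two pre-enrichment feature filters: removal of (1) features
#' not matched to any known metabolite, and (2) features flagged as
#' non-base isotopes by the upstream isotope annotation (any flag string
#' containing a non-zero isotope index, e.g. `"[M+1]"`; `""` and `"[M]"`
#' are base). Row order is otherwise preserved.
#'
#' @param features Feature data frame, optionally with an `isotope` column.
#' @param annotations Match table from [match_features()]; alternatively
#'   `features` may already carry an `n_matches` column.
#' @return The surviving rows of `features`, with `n_matches` attached.
#' @export
filter_features <- function(features, annotations = NULL) {
  if (is.null(annotations) && !"n_matches" %in% names(features)) {
    stop("provide 'annotations' or an 'n_matches' column")
  }
  if (!is.null(annotations)) {
    cnt <- table(annotations$feature_id)
    features$n_matches <- as.integer(cnt[as.character(features$feature_id)])
    features$n_matches[is.na(features$n_matches)] <- 0L
  }
  keep <- features$n_matches > 0
  if ("isotope" %in% names(features)) {
    iso <- as.character(features$isotope)
    iso[is.na(iso)] <- ""
    keep <- keep & !grepl("[1-9]", iso)
  }
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
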