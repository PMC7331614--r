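test_that("TSV annotation maps parse with set semantics", {
  map <- read_gene_metabolite_map(extdata("otc_map.tsv"))
  expect_length(map$gene_to_mets$OTC, 2)
  expect_equal(map$met_masses[["HMDB0000904"]], 175.0957)

  # duplicated rows leave the map unchanged
  tab <- utils::read.table(extdata("otc_map.tsv"), header = TRUE, sep = "\t")
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rbind(tab, tab), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map2 <- read_gene_metabolite_map(f)
  expect_equal(map2$gene_to_mets, map$gene_to_mets)
  expect_equal(map2$met_masses, map$met_masses)
})

test_that("reduced HMDB XML yields the same map as the equivalent TSV", {
  mx <- read_hmdb_xml(extdata("hmdb_subset.xml"))
  mt <- read_gene_metabolite_map(extdata("hmdb_subset.tsv"))
  expect_equal(mx$gene_to_mets, mt$gene_to_mets)
  expect_equal(mx$met_masses, mt$met_masses)
})

test_that("invalid annotation input is rejected or skipped", {
  f <- tmp_tsv(c("gene\tmetabolite_id\tmonoisotopic_mass",
                 "G1\tM1\t-5"))
  expect_error(read_gene_metabolite_map(f), "mass")
  g <- tmp_tsv(c("gene\tmetabolite_id", "G1\tM1", "G2\t"))
  expect_warning(map <- read_gene_metabolite_map(g), "skipped")
  expect_equal(names(map$gene_to_mets), "G1")
})

test_that("ppm matching has an inclusive 15-ppm boundary", {
  map <- mk_map("G1", "M1", 300.0000)
  feats <- data.frame(feature_id = c("f1", "f2"),
                      mz = c(300.0045, 300.0046), mode = "neutral")
  ann <- match_features(feats, map, ppm_tol = 15, adduct_model = "neutral")
  expect_equal(ann$feature_id, "f1")     # 15.0 ppm in, 15.33 ppm out
  expect_equal(ann$ppm_error, 15, tolerance = 1e-9)
  expect_error(match_features(data.frame(feature_id = "f", mz = 1,
                                         mode = "weird"), map),
               "unknown ionization mode")
})

test_that("matching equals the brute-force all-pairs oracle", {
  set.seed(11)
  masses <- round(runif(200, 80, 900), 4)
  map <- mk_map(rep(sprintf("G%02d", 1:20), each = 10),
                sprintf("M%03d", 1:200), masses)
  feats <- data.frame(
    feature_id = sprintf("f%02d", 1:50),
    mz = sample(masses, 50) * (1 + runif(50, -30e-6, 30e-6)) +
      sample(c(0, 1.007276), 50, replace = TRUE),
    mode = sample(c("positive", "negative", "neutral"), 50, replace = TRUE))
  for (model in c("neutral", "protonation")) {
    ann <- match_features(feats, map, ppm_tol = 15, adduct_model = model)
    got <- paste(ann$feature_id, ann$metabolite_id)
    want <- character(0)
    for (i in seq_len(nrow(feats))) {
      for (k in seq_along(masses)) {
        shift <- if (model == "neutral") 0 else
          switch(feats$mode[i], positive = 1.007276,
                 negative = -1.007276, neutral = 0)
        cand <- masses[k] + shift
        if (abs(feats$mz[i] - cand) / cand * 1e6 <= 15) {
          want <- c(want, paste(feats$feature_id[i], sprintf("M%03d", k)))
        }
      }
    }
    expect_setequal(got, want)
  }
})

test_that("shrinking the ppm tolerance never adds matches", {
  set.seed(3)
  map <- mk_map(rep("G1", 100), sprintf("M%03d", 1:100),
                round(runif(100, 80, 900), 4))
  feats <- data.frame(feature_id = sprintf("f%02d", 1:30),
                      mz = runif(30, 80, 900), mode = "neutral")
  tols <- c(50, 25, 15, 5, 1)
  prev <- NULL
  for (tol in tols) {
    ann <- match_features(feats, map, ppm_tol = tol, adduct_model = "neutral")
    cur <- paste(ann$feature_id, ann$metabolite_id)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("protonation matching equals neutral matching on shifted masses", {
  set.seed(5)
  masses <- round(runif(50, 100, 500), 4)
  map <- mk_map(rep("G1", 50), sprintf("M%03d", 1:50), masses)
  shifted <- mk_map(rep("G1", 50), sprintf("M%03d", 1:50),
                    masses + 1.007276)
  feats <- data.frame(feature_id = sprintf("f%02d", 1:20),
                      mz = sample(masses, 20) + 1.007276 +
                        runif(20, -0.002, 0.002),
                      mode = "positive")
  a <- match_features(feats, map, adduct_model = "protonation")
  feats$mode <- "neutral"
  b <- match_features(feats, shifted, adduct_model = "neutral")
  expect_setequal(paste(a$feature_id, a$metabolite_id),
                  paste(b$feature_id, b$metabolite_id))
})

test_that("feature filters drop unannotated and non-base-isotope rows", {
  feats <- data.frame(feature_id = sprintf("f%d", 1:5),
                      n_matches = c(2L, 0L, 1L, 0L, 3L))
  expect_equal(filter_features(feats)$feature_id, c("f1", "f3", "f5"))

  iso <- data.frame(feature_id = c("a", "b"), n_matches = 1L,
                    isotope = c("[M+1]", "[M]"))
  expect_equal(filter_features(iso)$feature_id, "b")

  # mixed 12-feature fixture: survivors = annotated AND base isotope
  mixed <- data.frame(
    feature_id = sprintf("x%02d", 1:12),
    n_matches = c(1, 0, 2, 1, 0, 1, 3, 1, 0, 2, 1, 1),
    isotope = c("[M]", "[M]", "[M+1]", "", "", "[M+2]",
                "[M]", "[M]", "[M+1]", "", "[M+1]", "[M]"))
  manual <- mixed$feature_id[mixed$n_matches > 0 &
                               mixed$isotope %in% c("", "[M]")]
  expect_equal(filter_features(mixed)$feature_id, manual)
  expect_error(filter_features(mixed[, 1, drop = FALSE]), "n_matches")
})
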