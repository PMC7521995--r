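test_that("weight tables read with dialects and reject malformed input", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tchr\tbp\tEA\tOA\tlogOR\tEAF",
               "rs1\t1\t100\tA\tG\t0.05\t0.3",
               "rs2\t2\t200\tC\tT\t-0.02\t0.5"), tf)
  wt <- read_weight_table(tf, dialect = c(variant_id = "SNP", chromosome = "chr",
                                          position = "bp", effect_allele = "EA",
                                          other_allele = "OA", weight = "logOR",
                                          effect_allele_frequency = "EAF"))
  expect_s3_class(wt, "prs_weight_table")
  expect_equal(nrow(wt), 2L)
  expect_equal(wt$weight, c(0.05, -0.02))

  # missing column named in the error
  expect_error(read_weight_table(tf), "variant_id")

  tf2 <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tchromosome\tposition\teffect_allele\tother_allele\tweight",
               "rs1\t1\t100\tN\tG\t0.05"), tf2)
  expect_error(read_weight_table(tf2), "A/C/G/T")

  tf3 <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tchromosome\tposition\teffect_allele\tother_allele\tweight",
               "rs1\t1\t100\tA\tG\t0.05",
               "rs1\t1\t100\tA\tG\t0.02"), tf3)
  expect_error(read_weight_table(tf3), "duplicate")

  tf4 <- tempfile(fileext = ".tsv")
  writeLines("variant_id\tchromosome\tposition\teffect_allele\tother_allele\tweight", tf4)
  expect_error(read_weight_table(tf4), "empty")
})

test_that("bundled synthetic weight tables have the published SNP counts", {
  for (spec in list(c("synthetic_prs_bc_313.tsv", 313),
                    c("synthetic_prs_eoc_30.tsv", 30),
                    c("synthetic_prs_hgs_22.tsv", 22))) {
    path <- system.file("extdata", spec[1], package = "carrierprs")
    expect_true(nzchar(path))
    expect_equal(nrow(read_weight_table(path)), as.integer(spec[2]))
  }
})

test_that("raw PRS is the weighted dosage sum with missing-dosage policies", {
  wt <- toy_weight_table(c(0.1, -0.2, 0.05))
  dm <- dosage_matrix(matrix(c(1, 2, 0), 1), "c1", c("rs1", "rs2", "rs3"))
  expect_equal(compute_prs(wt, dm)$raw, -0.3)

  wt0 <- toy_weight_table(c(0, 0, 0))
  expect_equal(compute_prs(wt0, dm)$raw, 0)

  # missing dosage, freq 0.25 under mean-impute: contribution w * 0.5
  wtm <- toy_weight_table(c(0.1, -0.2, 0.4), freq = c(0.3, 0.5, 0.25))
  dmm <- dosage_matrix(matrix(c(1, 2, NA), 1), "c1", c("rs1", "rs2", "rs3"))
  expect_equal(compute_prs(wtm, dmm)$raw, 0.1 - 0.4 + 0.4 * 0.5)
  expect_error(compute_prs(wtm, dmm, missing_policy = "error"), "rs3")
  expect_warning(out <- compute_prs(wtm, dmm, missing_policy = "drop"),
                 "missing")
  expect_equal(out$raw, -0.3)

  # variant absent from dosages without a frequency cannot be mean-imputed
  wt_nof <- toy_weight_table(c(0.1, -0.2))
  wt_nof$effect_allele_frequency <- NULL
  dm1 <- dosage_matrix(matrix(1, 1), "c1", "rs1")
  expect_error(compute_prs(wt_nof, dm1), "rs2")
})

test_that("PRS is linear in the weight table", {
  set.seed(4)
  w1 <- runif(5, -0.3, 0.3); w2 <- runif(5, -0.3, 0.3)
  g <- matrix(sample(0:2, 50, TRUE), 10, 5,
              dimnames = list(paste0("c", 1:10), paste0("rs", 1:5)))
  dm <- dosage_matrix(g)
  p1 <- compute_prs(toy_weight_table(w1, freq = rep(0.5, 5)), dm)$raw
  p2 <- compute_prs(toy_weight_table(w2, freq = rep(0.5, 5)), dm)$raw
  p12 <- compute_prs(toy_weight_table(w1 + w2, freq = rep(0.5, 5)), dm)$raw
  expect_equal(p12, p1 + p2, tolerance = 1e-12)
})

test_that("Hardy-Weinberg genotypes give the closed-form PRS variance", {
  wt <- toy_weight_table(c(0.2, -0.15, 0.1, 0.25),
                         freq = c(0.1, 0.3, 0.5, 0.8))
  n <- 20000
  dm <- simulate_genotypes(wt, n, seed = 9L)
  expect_true(all(dm$dosages %in% 0:2))
  # dosage means ~ 2f within 3 binomial MC SEs
  for (j in 1:4) {
    f <- wt$effect_allele_frequency[j]
    se <- sqrt(2 * f * (1 - f) / n)
    expect_lt(abs(mean(dm$dosages[, j]) - 2 * f), 3 * se)
  }
  raw <- compute_prs(wt, dm)$raw
  sd_theory <- sqrt(sum(wt$weight^2 * 2 * wt$effect_allele_frequency *
                          (1 - wt$effect_allele_frequency)))
  se_sd <- sd_theory / sqrt(2 * (n - 1))
  expect_lt(abs(sd(raw) - sd_theory), 3 * se_sd)

  # standardizing by the empirical control SD gives unit SD
  prs <- standardize_prs(compute_prs(wt, dm), reference_sd = sd(raw),
                         reference_mean = mean(raw))
  expect_equal(sd(prs$standardized), 1, tolerance = 1e-10)
})

test_that("standardization scales and centres; nonpositive SD rejected", {
  prs <- structure(list(carrier_ids = c("a", "b"), raw = c(2, 4),
                        standardized = c(NA_real_, NA_real_),
                        reference_sd = NA_real_, reference_mean = NA_real_),
                   class = "prs_vector")
  expect_equal(standardize_prs(prs, 1, 0)$standardized, c(2, 4))
  expect_equal(standardize_prs(prs, 2, 0)$standardized, c(1, 2))
  expect_equal(standardize_prs(prs, 2, 2)$standardized, c(0, 1))
  expect_error(standardize_prs(prs, 0), "positive")
  expect_error(standardize_prs(prs, -1), "positive")
})

test_that("allele harmonisation flips swapped strands and flags ambiguity", {
  wt <- validate_weight_table(data.frame(
    variant_id = c("rs1", "rs2", "rs3"), chromosome = "1",
    position = 1:3, effect_allele = c("A", "C", "A"),
    other_allele = c("G", "G", "T"), weight = c(0.1, 0.2, 0.3)))
  dm <- dosage_matrix(matrix(c(2, 2, 2), 1), "c1", c("rs1", "rs2", "rs3"),
                      effect_allele = c("A", "G", "A"),
                      other_allele = c("G", "C", "T"))
  expect_warning(h <- harmonize_dosages(dm, wt), "ambiguous")
  expect_equal(as.numeric(h$dosages), c(2, 0, 2))  # rs2 flipped

  bad <- dosage_matrix(matrix(1, 1), "c1", "rs1",
                       effect_allele = "C", other_allele = "T")
  expect_error(harmonize_dosages(bad, wt), "mismatch")
})

test_that("percentile categories follow the reference distribution", {
  set.seed(2)
  vals <- rnorm(1000)
  prs <- structure(list(carrier_ids = paste0("c", 1:1000), raw = vals,
                        standardized = vals, reference_sd = 1,
                        reference_mean = 0), class = "prs_vector")
  pc <- assign_percentiles(prs, prs$carrier_ids)
  expect_equal(levels(pc$category)[1], "40-60")
  counts <- table(factor(pc$category, levels = pc$scheme$labels))
  widths <- diff(c(0, pc$scheme$bin_edges, 100)) / 100
  # reference-set bin occupancy tracks the bin widths
  expect_true(all(abs(as.numeric(counts) / 1000 - widths) <= 2 / 1000 + 3 *
                    sqrt(widths * (1 - widths) / 1000)))
  # top 5% of a 1000-strong reference holds about 50 carriers
  expect_lt(abs(counts[["95-100"]] - 50), 22)

  # half-open [lower, upper): a value at a threshold joins the upper bin
  prs2 <- prs; prs2$standardized[1] <- pc$scheme$thresholds[8]
  pc2 <- assign_percentiles(prs2, prs2$carrier_ids[-1])
  expect_error(assign_percentiles(prs, character(0)), "empty")

  same <- prs; same$standardized <- rep(1, 1000); same$raw <- rep(1, 1000)
  expect_error(assign_percentiles(same, same$carrier_ids), "degenerate")
  expect_error(assign_percentiles(prs, prs$carrier_ids[1:5]), "smaller")
})

test_that("carriers with higher PRS concentrate above the 80th percentile", {
  set.seed(3)
  ref <- rnorm(2000)
  shifted <- rnorm(500, mean = 0.6)
  vals <- c(ref, shifted)
  ids <- paste0("c", seq_along(vals))
  prs <- structure(list(carrier_ids = ids, raw = vals, standardized = vals,
                        reference_sd = 1, reference_mean = 0),
                   class = "prs_vector")
  pc <- assign_percentiles(prs, ids[seq_along(ref)])
  top <- pc$category[-seq_along(ref)] %in% c("80-90", "90-95", "95-100")
  expect_gt(mean(top), 0.30)  # vs 20% for the reference population
})
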