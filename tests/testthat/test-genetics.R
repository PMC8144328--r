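make_weights <- function(snp_ids, w) {
  tibble::tibble(snp_id = snp_ids, effect_allele = "A", weight = w)
}

test_that("filter_snps is the identity on clean tables", {
  w <- make_weights(paste0("rs", 1:5), seq(0.1, 0.5, by = 0.1))
  out <- filter_snps(w, imputation_r2 = setNames(rep(1, 5), w$snp_id))
  expect_equal(out$snp_id, w$snp_id)
  expect_equal(nrow(attr(out, "filter_log")), 0)
})

test_that("the exclusion list removes the flagged SNP from a 12-SNP score", {
  # mirrors excluding one pleiotropic SNP from a childhood-BMI score
  ids <- c(paste0("rs", 1:11), "rs13387838")
  w <- make_weights(ids, seq(0.01, 0.12, by = 0.01))
  out <- filter_snps(w, exclusion_list = "rs13387838")
  expect_equal(nrow(out), 11)
  expect_false("rs13387838" %in% out$snp_id)
  log <- attr(out, "filter_log")
  expect_equal(log$snp_id, "rs13387838")
  expect_match(log$reason, "exclusion list")
})

test_that("imputation-quality filtering removes poor SNPs and demands coverage", {
  w <- make_weights(c("a", "b", "c"), c(0.1, 0.2, 0.3))
  r2 <- c(a = 0.95, b = 0.1, c = 0.8)
  out <- filter_snps(w, imputation_r2 = r2, r2_min = 0.3)
  expect_equal(out$snp_id, c("a", "c"))
  # a SNP missing from the r2 map is an error, not a silent pass-through
  expect_error(filter_snps(w, imputation_r2 = c(a = 1, b = 1)),
               "no imputation r2 .* c")
})

test_that("greedy LD pruning keeps the higher-weight partner", {
  w <- make_weights(c("a", "b", "c"), c(0.3, 0.2, 0.1))
  ld <- tibble::tibble(snp1 = "a", snp2 = "b", r2 = 0.5)
  out <- filter_snps(w, ld_pairs = ld, ld_max = 0.2)
  expect_setequal(out$snp_id, c("a", "c"))
  # symmetric map, reversed pair: same result
  ld2 <- tibble::tibble(snp1 = "b", snp2 = "a", r2 = 0.5)
  out2 <- filter_snps(w, ld_pairs = ld2, ld_max = 0.2)
  expect_setequal(out2$snp_id, c("a", "c"))
  # tied weights break lexicographically by SNP id
  w3 <- make_weights(c("b", "a", "c"), c(0.2, 0.2, 0.1))
  out3 <- filter_snps(w3, ld_pairs = ld, ld_max = 0.2)
  expect_setequal(out3$snp_id, c("a", "c"))
})

test_that("LD can be estimated from sample dosages when no map is given", {
  set.seed(4)
  g1 <- rbinom(500, 2, 0.5)
  flip <- rbinom(500, 1, 0.05)
  g2 <- ifelse(flip == 1, sample(0:2, 500, TRUE), g1)  # near-duplicate SNP
  g3 <- rbinom(500, 2, 0.3)
  dos <- tibble::tibble(id = as.character(1:500), a = g1, b = g2, c = g3)
  w <- make_weights(c("a", "b", "c"), c(0.3, 0.2, 0.1))
  out <- filter_snps(w, dosages = dos, ld_max = 0.2)
  expect_setequal(out$snp_id, c("a", "c"))
  expect_true(any(grepl("estimated from sample",
                        attr(out, "filter_log")$reason)))
})

test_that("compute_score does the weighted-sum arithmetic", {
  g <- tibble::tibble(id = c("i1", "i2"),
                      s1 = c(2, 0), s2 = c(1, 0), s3 = c(0, 0))
  w <- make_weights(c("s1", "s2", "s3"), c(0.1, 0.2, 0.3))
  sc <- compute_score(g, w)
  expect_equal(sc$score, c(0.4, 0))
  expect_equal(sc$n_snps_used, c(3, 3))
  # all-zero dosages give zero scores
  g0 <- tibble::tibble(id = "x", s1 = 0, s2 = 0, s3 = 0)
  expect_equal(compute_score(g0, w)$score, 0)
  # rescaling divides by the weight sum (per-allele scale)
  expect_equal(compute_score(g, w, rescale = TRUE)$score, c(0.4, 0) / 0.6)
})

test_that("compute_score is linear in the dosage matrix", {
  set.seed(9)
  w <- make_weights(paste0("s", 1:4), runif(4, 0.05, 0.3))
  d1 <- matrix(rbinom(40, 1, 0.4), 10, 4)
  d2 <- matrix(rbinom(40, 1, 0.4), 10, 4)
  as_tb <- function(m) {
    out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(out) <- paste0("s", 1:4)
    dplyr::mutate(out, id = as.character(1:10), .before = 1)
  }
  s1 <- compute_score(as_tb(d1), w)$score
  s2 <- compute_score(as_tb(d2), w)$score
  s12 <- compute_score(as_tb(d1 + d2), w)$score
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("filter-then-score equals scoring the retained subset", {
  sim <- quick_sim(n = 300, seed = 12)
  w <- sim_weight_table(sim)
  filt <- filter_snps(w, exclusion_list = w$snp_id[c(3, 17)])
  s_filt <- compute_score(sim$genotypes, filt)
  s_sub <- compute_score(sim$genotypes, w[-c(3, 17), ])
  expect_equal(s_filt$score, s_sub$score)
  expect_lte(nrow(filt), nrow(w))
})

test_that("missing dosages error by default and mean-impute on request", {
  g <- tibble::tibble(id = c("a", "b", "c"),
                      s1 = c(2, NA, 0), s2 = c(1, 1, 1))
  w <- make_weights(c("s1", "s2"), c(0.5, 0.1))
  expect_error(compute_score(g, w), "missing dosages")
  sc <- compute_score(g, w, missing_policy = "mean_impute")
  expect_equal(sc$score[2], 0.5 * mean(c(2, 0)) + 0.1 * 1)
  # a SNP absent from the matrix altogether is always an error
  w2 <- make_weights(c("s1", "s9"), c(0.5, 0.1))
  expect_error(compute_score(g, w2), "absent from genotype matrix")
})

test_that("effect-allele mismatches are reported per SNP", {
  g <- tibble::tibble(id = "a", s1 = 1, s2 = 2)
  w <- tibble::tibble(snp_id = c("s1", "s2"), effect_allele = c("A", "G"),
                      weight = c(0.1, 0.2))
  info <- tibble::tibble(snp_id = c("s1", "s2"), effect_allele = c("A", "T"))
  expect_error(compute_score(g, w, allele_info = info), "mismatch.*s2")
  expect_silent(compute_score(g, w, allele_info = info[1, ]))
})

test_that("score correlations behave at the identities and under independence", {
  sim <- quick_sim(n = 10000, seed = 30)
  w <- sim_weight_table(sim)
  s_all <- compute_score(sim$genotypes, w)
  m_self <- score_correlation(list(s_all, s_all))
  expect_equal(unname(m_self[1, 2]), 1)
  s_neg <- s_all
  s_neg$score <- -s_neg$score
  s_neg$score_name <- "neg"
  expect_equal(unname(score_correlation(list(s_all, s_neg))[1, 2]), -1)
  # disjoint SNP subsets: independent SNPs, near-zero correlation
  s_a <- compute_score(sim$genotypes, w[1:16, ])
  s_b <- compute_score(sim$genotypes, w[17:32, ])
  s_b$score_name <- "b"
  r_ind <- score_correlation(list(s_a, s_b))[1, 2]
  expect_lt(abs(r_ind), 0.05)
  # overlapping subsets: moderately correlated, strictly inside (0, 1)
  s_c <- compute_score(sim$genotypes, w[9:32, ])
  s_c$score_name <- "c"
  r_ov <- score_correlation(list(s_a, s_c))[1, 2]
  expect_gt(r_ov, 0)
  expect_lt(r_ov, 1)
  expect_error(score_correlation(list(s_a, s_b[1:100, ])), "different")
})

test_that("score regression on log BMI recovers unit slope at true weights", {
  sim <- quick_sim(n = 20000, seed = 31, attrition = NULL)
  fr <- quick_frame(sim)
  slope <- coef(fit_ols(fr, "log_bmi", "score"))[["score"]]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("weight tables round-trip through TSV and are validated", {
  w <- make_weights(c("rs1", "rs2"), c(0.2, 0.1))
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(w, tf)
  w2 <- read_weights(tf, score_name = "demo")
  expect_equal(w2$snp_id, w$snp_id)
  expect_equal(w2$score_name, rep("demo", 2))
  bad <- make_weights(c("rs1", "rs1"), c(0.2, 0.1))
  readr::write_tsv(bad, tf)
  expect_error(read_weights(tf), "duplicated")
  neg <- make_weights(c("rs1", "rs2"), c(0.2, -0.1))
  readr::write_tsv(neg, tf)
  expect_error(read_weights(tf), "strictly positive")
})

test_that("VCF dosages are ingested via DS with GT fallback", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT:DS",
          "0/1:1.1", "1/1:1.9", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT:DS",
          "0/0:0.2", "0/1:0.8", sep = "\t")), vcf)
  g <- genotypes_from_vcf(vcf)
  expect_equal(g$id, c("S1", "S2"))
  expect_equal(g$rs1, c(1.1, 1.9))
  expect_equal(g$rs2, c(0.2, 0.8))
  info <- attr(g, "allele_info")
  expect_equal(info$effect_allele, c("G", "T"))

  # GT-only file: count ALT alleles
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0|1", "1|1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "./.", sep = "\t")), vcf2)
  g2 <- genotypes_from_vcf(vcf2)
  expect_equal(g2$rs1, c(1, 2))
  expect_equal(g2$rs2, c(0, NA_real_))
})
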