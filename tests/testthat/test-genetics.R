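panel <- default_snp_panel()

test_that("the weighted GRS lives on [0, 1] with exact endpoints", {
  m <- rbind(rep(0, 12), rep(2, 12))
  rownames(m) <- c("none", "all")
  colnames(m) <- panel$snp_id
  g <- weighted_grs(m, panel)
  expect_equal(g$grs_weighted, c(0, 1))
  expect_equal(g$n_snps_used, c(12, 12))
})

test_that("a single heterozygote contributes its normalised log-OR weight", {
  m <- matrix(0, 1, 12, dimnames = list("h", panel$snp_id))
  m[1, 1] <- 1
  w <- log(panel$odds_ratio)
  expect_equal(weighted_grs(m, panel)$grs_weighted, w[1] / (2 * sum(w)))
})

test_that("adding a risk allele strictly increases the score", {
  set.seed(5)
  m <- matrix(rbinom(10 * 12, 2, 0.5), 10, 12,
              dimnames = list(NULL, panel$snp_id))
  base <- weighted_grs(m, panel)$grs_weighted
  for (j in c(1, 7, 12)) {
    m2 <- m
    room <- which(m2[, j] < 2)
    m2[room, j] <- m2[room, j] + 1
    bumped <- weighted_grs(m2, panel)$grs_weighted
    expect_true(all(bumped[room] > base[room]))
    expect_equal(bumped[-room], base[-room])
  }
})

test_that("the score is invariant to powering all odds ratios", {
  set.seed(6)
  m <- matrix(rbinom(20 * 12, 2, 0.7), 20, 12,
              dimnames = list(NULL, panel$snp_id))
  p2 <- panel
  p2$odds_ratio <- panel$odds_ratio^2.5
  expect_equal(weighted_grs(m, panel)$grs_weighted,
               weighted_grs(m, p2)$grs_weighted)
})

test_that("missing dosages are mean-imputed or dropped with notice", {
  m <- matrix(1, 3, 12, dimnames = list(NULL, panel$snp_id))
  m[2, 4] <- NA
  expect_message(g <- weighted_grs(m, panel), "imputing")
  w <- log(panel$odds_ratio)
  imputed <- (sum(w) - w[4] + w[4] * 2 * panel$risk_allele_freq[4]) / (2 * sum(w))
  expect_equal(g$grs_weighted[2], imputed)
  expect_error(weighted_grs(m, panel, impute_missing = FALSE), "imputation disabled")
  m[, 4] <- NA
  expect_warning(g2 <- weighted_grs(m, panel), "no called dosages")
  expect_equal(g2$n_snps_used, rep(11L, 3))
  expect_error(weighted_grs(m, dplyr::mutate(panel, odds_ratio = -panel$odds_ratio)),
               "positive")
})

test_that("HWE chi-square matches closed forms", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$chisq, 0)
  expect_equal(perfect$p_value, 1)
  expect_false(perfect$flagged)

  worst <- hwe_test(50, 0, 50)   # no heterozygotes at p = 0.5
  expect_equal(worst$chisq, 100)
  expect_true(worst$flagged)

  expect_warning(mono <- hwe_test(80, 0, 0), "monomorphic")
  expect_equal(mono$p_value, 1)
  expect_error(hwe_test(0, 0, 0), "at least one")
})

test_that("the HWE flag rate is about 1 percent under equilibrium", {
  set.seed(8)
  n <- 800
  n_snps <- 1500
  flags <- vapply(seq_len(n_snps), function(i) {
    g <- rbinom(n, 2, 0.75)
    hwe_test(sum(g == 2), sum(g == 1), sum(g == 0))$flagged
  }, logical(1))
  rate <- mean(flags)
  tol <- 3 * sqrt(0.01 * 0.99 / n_snps)
  expect_lt(abs(rate - 0.01), tol + 0.003)  # chi-square approximation slack
})

test_that("genotype QC reports call rate and HWE per SNP", {
  set.seed(9)
  m <- vapply(panel$risk_allele_freq, function(p) rbinom(400, 2, p),
              numeric(400))
  colnames(m) <- panel$snp_id
  m[1:3, 2] <- NA
  qc <- genotype_qc(m, panel)
  expect_equal(nrow(qc), 12)
  expect_true(qc$low_call_rate[2])
  expect_equal(qc$call_rate[2], 397 / 400)
  expect_false(any(qc$low_call_rate[-2]))
  expect_true(all(qc$hwe_p >= 0 & qc$hwe_p <= 1))
})

test_that("the default panel reproduces the published population mean score", {
  w <- log(panel$odds_ratio)
  expect_equal(sum(w * panel$risk_allele_freq) / sum(w), 0.80)
  expect_true(all(panel$risk_allele_freq > 0 & panel$risk_allele_freq < 1))
})

test_that("dosage matrices round-trip through delimited text", {
  m <- matrix(c(0, 1, 2, 2, NA, 1), 2, 3,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(participant_id = rownames(m), m)
  readr::write_csv(df, path)
  back <- read_dosage_matrix(path)
  expect_equal(unname(back), unname(m))
  expect_equal(rownames(back), c("a", "b"))
  df$s1[1] <- 3
  readr::write_csv(df, path)
  expect_error(read_dosage_matrix(path), "0, 1 or 2")
})
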