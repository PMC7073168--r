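test_that("genotype encoding follows the 0/1/2 convention", {
  gt <- load_genotype_fixture()
  mg <- encode_genotypes(gt, c("SNP_IGA_122351", "SNP_IGA_134905"),
                         ref_alleles = c("A", "A"))
  expect_s3_class(mg, "multilocus_genotypes")
  expect_equal(unname(mg$codes["Okubo", ]), c(0L, 0L))      # A/A, A/A
  expect_equal(unname(mg$codes["Okinawa", ]), c(2L, 0L))    # G/G, A/A
  expect_equal(unname(mg$codes["Ruby", 1]), 1L)             # A/G het
  # low CR maps to case, high CR to control
  expect_equal(as.character(mg$group[rownames(mg$codes) == "Okinawa"]),
               "case")
  expect_equal(as.character(mg$group[rownames(mg$codes) == "Okubo"]),
               "control")

  # swapping ref and alt mirrors the code: c -> 2 - c
  swapped <- encode_genotypes(gt, "SNP_IGA_122351", ref_alleles = "G")
  direct <- encode_genotypes(gt, "SNP_IGA_122351", ref_alleles = "A")
  expect_equal(unname(swapped$codes[, 1]), 2L - unname(direct$codes[, 1]))

  # a third allele is reported with marker and cultivar context
  bad <- gt
  bad$genotype[bad$cultivar == "Ruby" &
                 bad$marker == "SNP_IGA_122351"] <- "C/T"
  expect_error(encode_genotypes(bad, "SNP_IGA_122351",
                                ref_alleles = "A"),
               "SNP_IGA_122351.*Ruby")
})

test_that("missing genotypes propagate to missing codes", {
  gt <- load_genotype_fixture()
  gt$genotype[gt$cultivar == "Xiami" & gt$marker == "SNP_IGA_122351"] <-
    NA
  mg <- encode_genotypes(gt, "SNP_IGA_122351")
  expect_true(is.na(mg$codes["Xiami", 1]))
  expect_false(anyNA(mg$codes[rownames(mg$codes) != "Xiami", 1]))
})

test_that("EM resolves fully phased samples immediately", {
  # everyone homozygous ref at both loci: only one haplotype possible
  mg <- multilocus_genotypes(matrix(0L, 10, 2),
                             ref_alleles = c("A", "A"),
                             alt_alleles = c("B", "B"))
  est <- em_haplotype_frequencies(mg)
  expect_equal(unname(est$frequencies["AA"]), 1)
  expect_true(est$converged)
  expect_lte(est$n_iter, 3L)

  # 50/50 double homozygotes: phase known, gamete counting gives 0.5/0.5
  codes <- rbind(matrix(0L, 50, 2), matrix(2L, 50, 2))
  est2 <- em_haplotype_frequencies(multilocus_genotypes(
    codes, ref_alleles = c("A", "A"), alt_alleles = c("B", "B")))
  expect_equal(unname(est2$frequencies[c("AA", "BB")]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(unname(est2$frequencies[c("AB", "BA")]), c(0, 0),
               tolerance = 1e-6)
})

test_that("EM recovers generating haplotype frequencies under HWE", {
  truth <- c(AA = 0.50, AB = 0.30, BA = 0.15, BB = 0.05)
  sim <- simulate_hwe_genotypes(truth, n = 500, seed = 1)
  est <- em_haplotype_frequencies(sim, seed = 1)
  expect_true(est$converged)
  expect_lt(max(abs(est$frequencies[names(truth)] - truth)), 0.03)
})

test_that("EM optimum is not beaten by a dense simplex grid search", {
  truth <- c(AA = 0.45, AB = 0.25, BA = 0.20, BB = 0.10)
  sim <- simulate_hwe_genotypes(truth, n = 30, seed = 61)
  est <- em_haplotype_frequencies(sim, seed = 61)
  grid_best <- hap2_grid_max(sim$codes, step = 0.005)
  expect_gte(est$loglik, grid_best - 1e-4)
  # and the EM frequencies reproduce their own reported likelihood
  f <- est$frequencies[c("AA", "AB", "BA", "BB")]
  expect_equal(hap2_loglik(unname(f), sim$codes), est$loglik,
               tolerance = 1e-8)
})

test_that("pure double heterozygotes sit on a non-identifiable ridge", {
  mg <- multilocus_genotypes(matrix(1L, 20, 2))
  est <- em_haplotype_frequencies(mg, seed = 3)
  expect_false(est$identifiable)
})

test_that("missing codes are marginalized rather than dropped", {
  truth <- c(AA = 0.6, AB = 0.1, BA = 0.1, BB = 0.2)
  sim <- simulate_hwe_genotypes(truth, n = 300, seed = 62)
  holes <- sim$codes
  holes[sample(300, 30), 2] <- NA
  est <- em_haplotype_frequencies(multilocus_genotypes(
    holes, ref_alleles = sim$ref_alleles, alt_alleles = sim$alt_alleles),
    seed = 62)
  expect_lt(max(abs(est$frequencies[names(truth)] - truth)), 0.05)

  all_missing <- matrix(NA_integer_, 5, 2)
  expect_error(em_haplotype_frequencies(multilocus_genotypes(all_missing)),
               "complete codes")
})

test_that("HWE simulation is seeded and matches its frequencies in bulk", {
  f <- c(AA = 1, AB = 0, BA = 0, BB = 0)
  point <- simulate_hwe_genotypes(f, n = 20, seed = 7)
  expect_true(all(point$codes == 0L))

  truth <- c(AA = 0.4, AB = 0.3, BA = 0.2, BB = 0.1)
  a <- simulate_hwe_genotypes(truth, n = 100, seed = 8)
  b <- simulate_hwe_genotypes(truth, n = 100, seed = 8)
  expect_identical(a$codes, b$codes)

  big <- simulate_hwe_genotypes(truth, n = 10000, seed = 9)
  # allele-level empirical frequencies per locus vs the marginals
  emp_l1 <- mean(big$codes[, 1]) / 2
  expect_lt(abs(emp_l1 - (truth["BA"] + truth["BB"])), 0.02)
  emp_l2 <- mean(big$codes[, 2]) / 2
  expect_lt(abs(emp_l2 - (truth["AB"] + truth["BB"])), 0.02)

  expect_error(simulate_hwe_genotypes(c(0.5, 0.4), 10), "sum to 1")
})

test_that("case/control stratification reports all three frequency vectors", {
  gt <- load_genotype_fixture()
  mg <- encode_genotypes(gt, c("SNP_IGA_122351", "SNP_IGA_134905"))
  cc <- case_control_haplotype_freqs(mg, seed = 2)
  expect_equal(sum(cc$freq_overall), 1, tolerance = 1e-9)
  expect_equal(sum(cc$freq_case), 1, tolerance = 1e-9)
  expect_equal(sum(cc$freq_control), 1, tolerance = 1e-9)
  expect_equal(names(cc$freq_case), cc$haplotypes)

  # identical case and control halves estimate identical frequencies
  codes <- rbind(matrix(0L, 10, 2), matrix(2L, 10, 2))
  twin <- multilocus_genotypes(rbind(codes, codes),
                               group = rep(c("case", "control"),
                                           each = 20))
  cc2 <- case_control_haplotype_freqs(twin)
  expect_equal(cc2$freq_case, cc2$freq_control, tolerance = 1e-8)
  expect_equal(cc2$freq_case, cc2$freq_overall, tolerance = 1e-8)

  # groups fixed for different haplotypes separate cleanly
  fixed <- multilocus_genotypes(
    rbind(matrix(0L, 8, 2), matrix(2L, 8, 2)),
    group = rep(c("case", "control"), each = 8),
    ref_alleles = c("A", "A"), alt_alleles = c("B", "B"))
  cc3 <- case_control_haplotype_freqs(fixed)
  expect_equal(unname(cc3$freq_case["AA"]), 1, tolerance = 1e-8)
  expect_equal(unname(cc3$freq_control["BB"]), 1, tolerance = 1e-8)
})

test_that("stratified EM recovers group-specific generating frequencies", {
  f_case <- c(AA = 0.55, AB = 0.25, BA = 0.15, BB = 0.05)
  f_ctrl <- c(AA = 0.15, AB = 0.15, BA = 0.30, BB = 0.40)
  case <- simulate_hwe_genotypes(f_case, n = 300, seed = 71)
  ctrl <- simulate_hwe_genotypes(f_ctrl, n = 300, seed = 72)
  mg <- multilocus_genotypes(rbind(case$codes, ctrl$codes),
                             group = rep(c("case", "control"), each = 300),
                             ref_alleles = case$ref_alleles,
                             alt_alleles = case$alt_alleles)
  cc <- case_control_haplotype_freqs(mg, seed = 71)
  expect_lt(max(abs(cc$freq_case[names(f_case)] - f_case)), 0.04)
  expect_lt(max(abs(cc$freq_control[names(f_ctrl)] - f_ctrl)), 0.04)
})

test_that("more than six loci are refused", {
  expect_error(multilocus_genotypes(matrix(0L, 2, 7)), "at most 6 loci")
})
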