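test_that("pca_embed matches a direct eigen-decomposition oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    ds <- melt_dataset(seq(70, 80, length.out = 30),
                       matrix(runif(30 * n), 30, n,
                              dimnames = list(NULL, paste0("s", 1:n))))
    emb <- pca_embed(ds, k = 3)
    xc <- sweep(ds$fluorescence, 2, colMeans(ds$fluorescence))
    eg <- eigen(crossprod(xc), symmetric = TRUE)
    for (j in seq_len(emb$k)) {
      v <- eg$vectors[, j]
      expect_equal(abs(sum(v * emb$coordinates[, j])), 1,
                   tolerance = 1e-8)          # same direction up to sign
    }
    expect_equal(emb$explained_full,
                 (eg$values / sum(eg$values))[seq_along(emb$explained_full)],
                 tolerance = 1e-10)
  }
})

test_that("pca_embed separates genotype groups and fixes signs", {
  p1 <- simulate_plate(quiet_config(n_per_genotype = c(4, 0, 0),
                                    tm_allele_ref = 78))
  p2 <- simulate_plate(quiet_config(n_per_genotype = c(0, 0, 4),
                                    tm_allele_ref = 78, delta_tm_alt = 0.6))
  ds <- melt_dataset(p1$dataset$temperatures,
                     cbind(p1$dataset$fluorescence,
                           p2$dataset$fluorescence),
                     sample_ids = c(paste0("a", 1:4), paste0("b", 1:4)))
  norm <- minmax_normalize(clip_melt_region(ds, 74, 82.5))
  emb <- suppressWarnings(pca_embed(norm, k = 2))
  co <- emb$coordinates
  d <- as.matrix(dist(co[, 1, drop = FALSE]))
  within <- c(d[1:4, 1:4], d[5:8, 5:8])
  between <- d[1:4, 5:8]
  expect_lt(max(within), min(between))
  # sign convention: the largest-magnitude entry of each PC is positive
  for (j in seq_len(ncol(co)))
    expect_gt(co[which.max(abs(co[, j])), j], 0)
  expect_true(all(diff(emb$explained_full) <= 1e-12))
  expect_lte(sum(emb$explained_full), 1 + 1e-9)
})

test_that("degenerate plates are rejected and k is truncated to rank", {
  flat <- melt_dataset(seq(70, 80, length.out = 20),
                       matrix(rep(seq(2, 1, length.out = 20), 3), ncol = 3,
                              dimnames = list(NULL, c("a", "b", "c"))))
  expect_error(pca_embed(flat), "zero variance")
  two_groups <- flat
  two_groups$fluorescence[, 3] <- two_groups$fluorescence[, 3] + 0.1
  expect_warning(pca_embed(two_groups, k = 3), "exceeds data rank")
})

test_that("choose_k follows the explained-variance rule", {
  fake <- function(fracs) structure(list(explained_full = fracs),
                                    class = "pca_embedding")
  expect_equal(choose_k(fake(c(0.95, 0.04, 0.005, 0.005)), 0.9), 2L)
  expect_equal(choose_k(fake(c(0.5, 0.2, 0.1, 0.2)), 0.9), 3L)
  expect_equal(choose_k(fake(c(0.7, 0.3)), 1.0), 2L)   # rank-2 data
})

test_that("gmm_cluster recovers well-separated clouds deterministically", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(60, sd = 0.5), ncol = 2) +
                 matrix(c(0, 0), 30, 2, byrow = TRUE),
               matrix(rnorm(60, sd = 0.5), ncol = 2) +
                 matrix(c(10, 0), 30, 2, byrow = TRUE),
               matrix(rnorm(60, sd = 0.5), ncol = 2) +
                 matrix(c(0, 10), 30, 2, byrow = TRUE))
  rownames(pts) <- paste0("s", 1:90)
  labels <- rep(1:3, each = 30)

  res <- gmm_cluster(pts, G = 3, seed = 2)
  expect_equal(ari(res$assignments, labels), 1.0)
  expect_equal(unname(rowSums(res$posterior)), rep(1, 90),
               tolerance = 1e-9)
  expect_equal(unname(res$assignments),
               unname(apply(res$posterior, 1, which.max)))
  # relabelling by mean first coordinate: the x = 10 cloud sorts last
  expect_true(all(res$assignments[31:60] == 3))
  expect_true(all(res$assignments[1:30] == 1))

  res2 <- gmm_cluster(pts, G = 3, seed = 2)
  expect_identical(res$assignments, res2$assignments)
  expect_identical(res$loglik, res2$loglik)

  auto <- gmm_cluster(pts, G = "auto", seed = 2)
  expect_equal(auto$G, 3L)

  one <- gmm_cluster(pts, G = 1, seed = 2)
  expect_equal(unname(one$assignments), rep(1L, 90))
  expect_equal(one$weights, 1)
})

test_that("gmm_cluster agrees with mclust on well-separated data", {
  set.seed(32)
  pts <- rbind(matrix(rnorm(40, sd = 0.3), ncol = 2),
               matrix(rnorm(40, sd = 0.3), ncol = 2) + 6)
  rownames(pts) <- paste0("s", 1:40)
  ours <- gmm_cluster(pts, G = 2, seed = 1)
  withr::local_package("mclust")
  mc <- Mclust(pts, G = 2, verbose = FALSE)
  expect_equal(ari(ours$assignments, mc$classification), 1.0)
})

test_that("EM log-likelihood only improves with more iterations", {
  set.seed(33)
  pts <- matrix(rnorm(80), ncol = 2) + rep(c(0, 4), each = 20)
  rownames(pts) <- paste0("s", 1:40)
  short <- gmm_cluster(pts, G = 2, seed = 9, n_restarts = 1, max_iter = 1)
  full <- gmm_cluster(pts, G = 2, seed = 9, n_restarts = 1,
                      max_iter = 500)
  expect_gte(full$loglik, short$loglik - 1e-9)
})

test_that("anchor genotypes label clusters by majority with conflicts flagged", {
  assignments <- setNames(rep(1:3, each = 4), paste0("s", 1:12))
  res <- structure(list(assignments = assignments,
                        posterior = diag(3)[rep(1:3, each = 4), ],
                        G = 3L,
                        genotype = setNames(rep(NA_character_, 12),
                                            names(assignments)),
                        cluster_genotype = rep(NA_character_, 3),
                        conflict_flag = rep(FALSE, 3)),
                   class = "cluster_call_result")

  # one concordant anchor per cluster labels every member
  labelled <- call_variants(res, c(s1 = "A/A", s5 = "A/G", s9 = "G/G"))
  expect_equal(unname(labelled$genotype),
               rep(c("A/A", "A/G", "G/G"), each = 4))
  expect_false(any(labelled$conflict_flag))

  # majority with disagreement: flag raised, majority wins
  maj <- suppressWarnings(call_variants(
    res, c(s1 = "A/A", s2 = "A/A", s3 = "A/G", s5 = "A/G", s9 = "G/G")))
  expect_equal(unname(maj$cluster_genotype[1]), "A/A")
  expect_true(maj$conflict_flag[1])

  # exact tie -> undetermined; anchorless cluster -> undetermined + warning
  expect_warning(tie <- call_variants(
    res, c(s1 = "A/A", s2 = "A/G", s5 = "A/G")), "no anchor")
  expect_true(is.na(tie$cluster_genotype[1]))
  expect_true(tie$conflict_flag[1])
  expect_true(is.na(tie$cluster_genotype[3]))

  expect_error(call_variants(res, c(zz = "A/A")), "not on the plate")
})

test_that("genotyping accuracy reproduces the printed ratio convention", {
  calls <- setNames(rep("A/A", 14), paste0("s", 1:14))
  sanger <- calls
  sanger[14] <- "A/G"
  acc <- genotyping_accuracy(calls, sanger)
  expect_equal(acc$numerator, 13L)
  expect_equal(acc$denominator, 14L)
  expect_equal(acc$percent, 92.9)

  calls9 <- setNames(c(rep("G/G", 6), rep("A/G", 3)), paste0("s", 1:9))
  sanger9 <- setNames(c(rep("G/G", 6), rep("G/A", 3)), paste0("s", 1:9))
  # unordered allele comparison: G/A and A/G match
  expect_equal(genotyping_accuracy(calls9, sanger9)$percent, 100)
  sanger9[7:9] <- "A/A"
  expect_equal(genotyping_accuracy(calls9, sanger9)$percent, 66.7)

  expect_equal(genotyping_accuracy(calls, calls)$percent, 100)
  expect_error(genotyping_accuracy(calls, character(0)), "undefined")
})

test_that("the full pipeline recovers simulated genotypes", {
  cfg <- simulation_config(n_per_genotype = c(8, 8, 8), seed = 41)
  plate <- simulate_plate(cfg)
  anchors <- plate$truth[c("ref_hom_01", "het_01", "alt_hom_01")]
  fit <- run_hrm_pca_pipeline(plate$dataset, anchors = anchors,
                              lower = 74, upper = 82.5, seed = 41)
  expect_equal(genotyping_accuracy(fit$genotype, plate$truth)$percent, 100)

  # anchors withheld: clusters form, genotypes stay undetermined
  bare <- suppressWarnings(run_hrm_pca_pipeline(
    plate$dataset, lower = 74, upper = 82.5, seed = 41))
  expect_equal(bare$result$G, 3L)
  expect_true(all(table(bare$result$assignments) > 0))
  expect_true(all(is.na(bare$genotype)))

  # determinism under a fixed seed
  again <- run_hrm_pca_pipeline(plate$dataset, anchors = anchors,
                                lower = 74, upper = 82.5, seed = 41)
  expect_identical(fit$genotype, again$genotype)
  expect_identical(fit$result$loglik, again$result$loglik)
})

test_that("pipeline accuracy is invariant to sample order", {
  cfg <- simulation_config(n_per_genotype = c(8, 8, 8), seed = 43)
  plate <- simulate_plate(cfg)
  anchors <- plate$truth[c("ref_hom_01", "het_01", "alt_hom_01")]
  ds <- plate$dataset
  set.seed(43)
  perm <- sample(ncol(ds$fluorescence))
  shuffled <- melt_dataset(ds$temperatures, ds$fluorescence[, perm],
                           sample_ids = ds$sample_ids[perm])
  acc1 <- genotyping_accuracy(
    run_hrm_pca_pipeline(ds, anchors = anchors, lower = 74, upper = 82.5,
                         seed = 7)$genotype, plate$truth)
  acc2 <- genotyping_accuracy(
    run_hrm_pca_pipeline(shuffled, anchors = anchors, lower = 74,
                         upper = 82.5, seed = 7)$genotype, plate$truth)
  expect_equal(acc1$percent, acc2$percent)
})
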