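test_that("wilcoxon rank-sum matches enumeration on the worked case", {
  # most extreme split of 3 vs 3: one-sided 1/20, two-sided 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(exact_wilcox_oracle(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), "2 values")
})

test_that("exact path agrees with the enumeration oracle and wilcox.test", {
  set.seed(7)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(seq_len(50), n1 + n2)  # tie-free
    g1 <- v[seq_len(n1)]; g2 <- v[-seq_len(n1)]
    p <- wilcoxon_rank_sum(g1, g2)
    expect_equal(p, exact_wilcox_oracle(g1, g2), tolerance = 1e-12)
    expect_equal(p, stats::wilcox.test(g1, g2, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("approximate path tracks the exact path on tie-free n1=n2=6 inputs", {
  set.seed(8)
  for (i in 1:40) {
    v <- runif(12)
    g1 <- v[1:6]; g2 <- v[7:12]
    exact <- wilcoxon_rank_sum(g1, g2)
    ties <- table(rank(v))
    u <- sum(rank(v)[1:6]) - 6 * 7 / 2
    approx <- mgpredeval:::wilcox_approx_p(u, 6, 6, ties)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("tie-corrected approximation matches wilcox.test with ties", {
  set.seed(9)
  for (i in 1:40) {
    g1 <- sample(0:3, 15, replace = TRUE)
    g2 <- sample(0:3, 12, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                               correct = TRUE))$p.value
    expect_equal(wilcoxon_rank_sum(g1, g2), ref, tolerance = 1e-12)
  }
})

test_that("signed log10 transform implements the stated formula", {
  expect_equal(signed_log10_p(0.1, 2, 5), 1)       # (-1) * (-1)
  expect_equal(signed_log10_p(0.1, 5, 2), -1)
  expect_equal(signed_log10_p(1, 10, 0), 0)        # log10(1) = 0
  expect_equal(signed_log10_p(0.01, 3, 3), 0)      # sign(0) = 0
  grid <- expand.grid(p = c(1e-6, 0.01, 0.5, 1), d = c(-2, 0, 2))
  expect_equal(signed_log10_p(grid$p, grid$d, 0),
               log10(grid$p) * sign(grid$d))
  expect_error(signed_log10_p(0, 1, 2), "p_value")
  expect_error(signed_log10_p(1.5, 1, 2), "p_value")
})

test_that("inference vector combines exact Wilcoxon P with direction", {
  genes <- c("up", "flat")
  samples <- paste0("s", 1:10)
  vals <- rbind(up = c(6, 7, 8, 9, 10, 1, 2, 3, 4, 5),
                flat = rep(2, 10))
  tab <- gene_table(`dimnames<-`(vals, list(genes, samples)))
  md <- tiny_metadata(samples)
  v <- inference_vector(tab, md)
  # all group1 above all group2: exact two-sided P = 2/choose(10,5)
  expect_equal(v$p_value[1], 2 / choose(10, 5))
  expect_equal(v$p_t[1], log10(2 / choose(10, 5)) * 1)
  expect_equal(v$p_t[1], -2.1003, tolerance = 1e-4)
  expect_equal(v$p_value[2], 1)
  expect_equal(v$p_t[2], 0)

  # swapping the declared group order flips every nonzero p_t
  md_rev <- study_metadata(md$assignments, group_labels = c("g2", "g1"))
  v_rev <- inference_vector(tab, md_rev)
  expect_equal(v_rev$p_t, -v$p_t)
  expect_equal(v_rev$p_value, v$p_value)

  expect_error(inference_vector(tab, md, genes = "nope"), "not in table")
})

test_that("matrix fast path equals the scalar operation gene by gene", {
  set.seed(12)
  for (ns in c(8, 30)) {  # exact and approximate regimes
    m <- matrix(sample(0:5, 40 * ns, replace = TRUE) +
                  rlnorm(40 * ns) * rbinom(40 * ns, 1, 0.7),
                40, ns, dimnames = list(paste0("g", 1:40), paste0("s", 1:ns)))
    idx1 <- seq_len(ns / 2); idx2 <- (ns / 2 + 1):ns
    fast <- mgpredeval:::wilcoxon_matrix_p(m, idx1, idx2)
    slow <- apply(m, 1, function(x) wilcoxon_rank_sum(x[idx1], x[idx2]))
    expect_equal(fast, unname(slow), tolerance = 1e-12)
  }
})

test_that("inference correlation recovers identity, antitone and hand cases", {
  md <- tiny_metadata(paste0("s", 1:10))
  mk_v <- function(p_t) {
    structure(data.frame(gene_id = paste0("g", seq_along(p_t)),
                         p_value = 10^(-abs(p_t)), mean_group1 = sign(-p_t),
                         mean_group2 = 0, p_t = p_t),
              class = c("inference_vector", "data.frame"))
  }
  v <- mk_v(c(-3, -1, 0.5, 2, 4, -0.2))
  expect_equal(inference_correlation(v, v)$rho, 1)
  neg <- mk_v(-c(-3, -1, 0.5, 2, 4, -0.2))
  expect_equal(inference_correlation(v, neg)$rho, -1)

  a <- mk_v(c(-2, 1, 0, 3, -1, 2))
  b <- mk_v(c(1, -1, 2, 0, 3, -2))
  expect_equal(inference_correlation(a, b)$rho,
               spearman_rank_formula(a$p_t, b$p_t))
  expect_equal(inference_correlation(a, b)$n_genes, 6L)
  expect_error(inference_correlation(mk_v(1:2), mk_v(1:2)), "3 shared")
})

test_that("exchanging group labels leaves the concordance rho unchanged", {
  st <- generate_paired_study(synthetic_config(n_genes = 300,
                                               n_samples_per_group = 8,
                                               seed = 31))
  pair <- align_pair(st$predicted, st$observed)
  md_rev <- study_metadata(st$metadata$assignments,
                           group_labels = rev(st$metadata$group_labels))
  rho_fwd <- inference_correlation(
    inference_vector(pair$predicted, st$metadata, pair$shared_genes),
    inference_vector(pair$observed, st$metadata, pair$shared_genes))$rho
  rho_rev <- inference_correlation(
    inference_vector(pair$predicted, md_rev, pair$shared_genes),
    inference_vector(pair$observed, md_rev, pair$shared_genes))$rho
  expect_equal(rho_fwd, rho_rev, tolerance = 1e-12)
})

test_that("the permutation null is reproducible and centered near zero", {
  st <- generate_paired_study(synthetic_config(n_genes = 400,
                                               n_samples_per_group = 8,
                                               seed = 13))
  pair <- align_pair(st$predicted, st$observed)
  null1 <- inference_permutation_null(pair, st$metadata, 15, seed = 4)
  null2 <- inference_permutation_null(pair, st$metadata, 15, seed = 4)
  expect_identical(null1$rho, null2$rho)
  se <- sd(null1$rho) / sqrt(nrow(null1))
  expect_lt(abs(mean(null1$rho)), 2 * se + 0.05)
  expect_error(inference_permutation_null(pair, st$metadata, 0), "n_permutations")
})

test_that("degenerate subsampling reproduces the full-data concordance", {
  st <- generate_paired_study(synthetic_config(n_genes = 200,
                                               n_samples_per_group = 6,
                                               seed = 17))
  pair <- align_pair(st$predicted, st$observed)
  full <- inference_correlation(
    inference_vector(pair$predicted, st$metadata, pair$shared_genes),
    inference_vector(pair$observed, st$metadata, pair$shared_genes))
  sub <- subsample_and_recompute(pair, st$metadata, per_group = 6,
                                 n_repeats = 2, seed = 1)
  expect_equal(sub$rho, rep(full$rho, 2), tolerance = 1e-12)
  expect_error(subsample_and_recompute(pair, st$metadata, per_group = 7),
               "fewer")
})

test_that("category stratification scopes, skips and flags correctly", {
  st <- generate_paired_study(synthetic_config(n_genes = 300,
                                               n_samples_per_group = 8,
                                               n_categories = 3, seed = 19))
  pair <- align_pair(st$predicted, st$observed)
  v_pred <- inference_vector(pair$predicted, st$metadata, pair$shared_genes)
  v_obs <- inference_vector(pair$observed, st$metadata, pair$shared_genes)

  # one category covering all genes equals the all-genes rho
  all_cat <- functional_hierarchy(data.frame(gene_id = pair$shared_genes,
                                             level1 = "M", level2 = "everything"))
  one <- category_inference_correlations(v_pred, v_obs, all_cat)
  expect_equal(one$rho, inference_correlation(v_pred, v_obs)$rho)
  expect_equal(one$scope, "everything")

  # a 2-gene category is skipped under min_genes = 10
  small_cat <- functional_hierarchy(data.frame(
    gene_id = pair$shared_genes[1:2], level1 = "M", level2 = "tiny"))
  expect_message(res <- category_inference_correlations(v_pred, v_obs,
                                                        small_cat),
                 "skipping")
  expect_equal(nrow(res), 0L)
  expect_error(category_inference_correlations(v_pred, v_obs, small_cat,
                                               min_genes = 2), "min_genes")

  full <- suppressMessages(category_inference_correlations(
    v_pred, v_obs, st$hierarchy))
  expect_true(all(full$n_genes >= 10))
  expect_equal(full$display, full$rho > 0 & full$p_value < 0.05)
})

test_that("per-gene and concordance TSV writers produce the stated columns", {
  st <- generate_paired_study(synthetic_config(n_genes = 50,
                                               n_samples_per_group = 4,
                                               seed = 23))
  pair <- align_pair(st$predicted, st$observed)
  v_pred <- inference_vector(pair$predicted, st$metadata, pair$shared_genes)
  v_obs <- inference_vector(pair$observed, st$metadata, pair$shared_genes)
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_inference_tsv(v_pred, v_obs, st$hierarchy, gpath)
  df <- read.delim(gpath)
  expect_named(df, c("gene_id", "p_pred", "p_obs", "p_t_pred", "p_t_obs",
                     "level1", "level2"))
  expect_equal(nrow(df), length(pair$shared_genes))

  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_concordance_tsv(inference_correlation(v_pred, v_obs), cpath)
  cdf <- read.delim(cpath)
  expect_named(cdf, c("scope", "source", "rho", "p_value", "n_genes",
                      "display"))
})
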