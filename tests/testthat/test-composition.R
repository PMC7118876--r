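test_that("spearman handles monotone, reversed and hand-derived inputs", {
  expect_equal(spearman(1:4, 1:4)$rho, 1)
  expect_equal(spearman(1:3, 3:1)$rho, -1)
  # rank-difference formula: d^2 = (1,1,1,1,0), rho = 1 - 24/120
  expect_equal(spearman(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_equal(spearman_rank_formula(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_warning(res <- spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman(1:3, 1:4), "length")
  expect_error(spearman(1:2, 1:2), "3")
})

test_that("spearman matches cor.test on random short vectors with ties", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    x <- sample(0:4, n, replace = TRUE) + stats::runif(n) * sample(0:1, 1)
    y <- sample(0:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    ours <- spearman(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

make_pair <- function(pred_vals, obs_vals, genes, samples) {
  align_pair(tiny_table(pred_vals, genes, samples),
             tiny_table(obs_vals, genes, samples))
}

test_that("per-sample composition rho is rank-invariant and hand-checkable", {
  genes <- paste0("K", 1:5)
  vals <- c(5, 1, 4, 2, 3, 5, 1, 3, 2, 4)
  pair <- make_pair(vals, vals, genes, c("s1", "s2"))
  expect_equal(sample_composition_rho(pair, "s1")$rho, 1)

  # strictly monotone transform of the observed values leaves rho = 1
  pair2 <- make_pair(vals, vals^2 + 1, genes, c("s1", "s2"))
  expect_equal(sample_composition_rho(pair2, "s2")$rho, 1)

  # hand-built 5-gene sample: ranks (5,1,4,2,3) vs (1,2,3,4,5) in s1
  mk <- function(s1, s2) {
    gene_table(matrix(c(s1, s2), ncol = 2,
                      dimnames = list(genes, c("s1", "s2"))))
  }
  pair3 <- align_pair(mk(c(5, 1, 4, 2, 3) / 10, rep(0.2, 5)),
                      mk(1:5 / 10, rep(0.2, 5)))
  expect_equal(sample_composition_rho(pair3, "s1")$rho,
               spearman_rank_formula(c(5, 1, 4, 2, 3), 1:5))
  expect_equal(sample_composition_rho(pair3, "s1")$n_genes, 5L)
  expect_error(sample_composition_rho(pair3, "nope"), "not shared")
})

test_that("gene-wise permutation preserves each row's multiset of values", {
  set.seed(5)
  tab <- gene_table(matrix(rlnorm(200), 20, 10,
                           dimnames = list(paste0("g", 1:20), paste0("s", 1:10))))
  for (seed in 1:5) {
    perm <- permute_genes_across_samples(tab, seed = seed)
    for (g in rownames(tab)) {
      expect_equal(unname(sort(unclass(perm)[g, ])),
                   unname(sort(unclass(tab)[g, ])))
    }
  }
  # constant table is a fixed point
  const <- gene_table(matrix(2, 3, 4, dimnames = list(letters[1:3],
                                                      paste0("s", 1:4))))
  expect_equal(unclass(permute_genes_across_samples(const, 1)), unclass(const))
  expect_identical(unclass(permute_genes_across_samples(tab, 99)),
                   unclass(permute_genes_across_samples(tab, 99)))
})

test_that("a 1-gene, 2-sample permutation realizes both outcomes", {
  tab <- tiny_table(c(1, 2), "g1", c("s1", "s2"))
  outcomes <- vapply(1:40, function(seed) {
    unclass(permute_genes_across_samples(tab, seed = seed))[1, 1]
  }, numeric(1))
  expect_setequal(unique(outcomes), c(1, 2))
})

test_that("the permutation control reproduces the low-variance artifact", {
  # near-constant functional profiles: permuting genes across samples
  # barely changes the per-sample correlation
  low <- generate_paired_study(synthetic_config(
    n_genes = 500, n_samples_per_group = 10, between_sample_cv = 0.01,
    seed = 11))
  pair <- align_pair(low$predicted, low$observed)
  res <- composition_with_permutation_control(pair, n_permutations = 20,
                                              seed = 1)
  gap_low <- mean(res$per_sample$rho) - mean(res$permuted$rho)
  expect_lt(abs(gap_low), 0.05)

  # gap grows monotonically with between-sample variance
  gaps <- vapply(c(0.01, 0.5, 2), function(cv) {
    st <- generate_paired_study(synthetic_config(
      n_genes = 500, n_samples_per_group = 10, between_sample_cv = cv,
      seed = 11))
    p <- align_pair(st$predicted, st$observed)
    r <- composition_with_permutation_control(p, n_permutations = 20, seed = 1)
    mean(r$per_sample$rho) - mean(r$permuted$rho)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))

  expect_error(composition_with_permutation_control(pair, 0), "n_permutations")
  again <- composition_with_permutation_control(pair, n_permutations = 20,
                                                seed = 1)
  expect_identical(res$permuted, again$permuted)
})

test_that("composition results serialize with real and permutation scopes", {
  st <- generate_paired_study(synthetic_config(n_genes = 30,
                                               n_samples_per_group = 3,
                                               seed = 2))
  pair <- align_pair(st$predicted, st$observed)
  res <- composition_with_permutation_control(pair, 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_composition_tsv(res, path)
  df <- read.delim(path)
  expect_setequal(unique(df$scope), c("real", paste0("permutation_", 1:3)))
  expect_equal(nrow(df), 6 * 4)  # 6 samples x (1 real + 3 permutations)
})
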