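test_that("the generator is bit-identical under one seed", {
  cfg <- sim_config(seed = 99, n_genes = 40L, n_samples_female = 4L,
                    n_samples_male = 3L)
  d1 <- simulate_xci_dataset(cfg, depth = 100)
  d2 <- simulate_xci_dataset(cfg, depth = 100)
  expect_identical(d1$truth$status, d2$truth$status)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$bisulfite$reads, d2$bisulfite$reads)
  expect_identical(d1$marks$marks, d2$marks$marks)
  expect_identical(d1$genotypes$genotypes, d2$genotypes$genotypes)
})

test_that("constitutive-only configs keep one state per gene", {
  cfg <- sim_config(seed = 2, n_genes = 50L, frac_variable = 0,
                    planted_effects = list())
  truth <- simulate_truth(cfg)
  expect_true(all(apply(truth$status, 1L, function(x)
    length(unique(x)) == 1L)))
})

test_that("a degenerate planted effect forces escape in alt homozygotes", {
  cfg <- sim_config(seed = 3, n_genes = 30L, n_samples_female = 30L,
                    planted_effects = list(
                      list(locus_id = "L1", gene_id = "g0005",
                           probs = c(0, 0.5, 1), maf = 0.5)))
  truth <- simulate_truth(cfg)
  gt <- truth$planted_genotypes[, "L1"]
  st <- truth$status["g0005", names(gt)]
  expect_true(all(st[gt == 2L] == "escape"))
  expect_true(all(st[gt == 0L] == "subject"))
})

test_that("planting on an unknown gene errors", {
  cfg <- sim_config(seed = 1, n_genes = 10L, planted_effects = list(
    list(locus_id = "L1", gene_id = "nope", probs = c(0, 0, 0),
         maf = 0.5)))
  expect_error(simulate_truth(cfg), "unknown gene")
})

test_that("allelic counts concentrate at the configured Xi/Xa ratios", {
  cfg <- sim_config(seed = 5, n_genes = 40L, n_samples_female = 2L,
                    skew_fraction = 1,
                    xi_expr_ratio_subject = c(0, 0),
                    xi_expr_ratio_escape = c(1, 1))
  truth <- simulate_truth(cfg)
  counts <- simulate_allelic_counts(truth, depth = 1e5, seed = 6)
  meta <- stats::setNames(truth$genes$meta_status, truth$genes$gene_id)
  sub <- counts[meta[counts$gene_id] == "subject", ]
  expect_true(all(sub$xi_reads == 0))           # r = 0 silences the Xi
  esc <- counts[meta[counts$gene_id] == "escape", ]
  prop <- esc$xi_reads / (esc$xi_reads + esc$xa_reads)
  expect_true(all(abs(prop - 0.5) < 0.01))      # r = 1 at high depth
})

test_that("unskewed samples lose allelic imbalance in expectation", {
  cfg <- sim_config(seed = 7, n_genes = 60L, n_samples_female = 2L,
                    skew_fraction = 0,
                    xi_expr_ratio_subject = c(0, 0))
  truth <- simulate_truth(cfg)
  counts <- simulate_allelic_counts(truth, depth = 1e5, seed = 8)
  meta <- stats::setNames(truth$genes$meta_status, truth$genes$gene_id)
  sub <- counts[meta[counts$gene_id] == "subject", ]
  prop_a <- sub$allele_a / (sub$allele_a + sub$allele_b)
  expect_lt(abs(mean(prop_a) - 0.5), 0.01)
})

test_that("bisulfite reads follow the allele-state methylation means", {
  cfg <- sim_config(seed = 9, n_genes = 20L, n_samples_female = 2L,
                    frac_escape = 0, frac_variable = 0, frac_subject = 1,
                    skew_fraction = 1, per_cpg_sd = 0,
                    dname_xa_mean = 0, dname_xi_subject_mean = 1,
                    planted_effects = list())
  truth <- simulate_truth(cfg)
  bs <- simulate_bisulfite_reads(truth, seed = 10)
  xi <- bs$reads[bs$reads$from_xi, ]
  xa <- bs$reads[!bs$reads$from_xi, ]
  expect_true(all(xi$n_meth == xi$n_total))
  expect_true(all(xa$n_meth == 0))
})

test_that("per-CpG noise produces adjacent-CpG differences matching a
           Monte-Carlo oracle", {
  cfg <- sim_config(seed = 13, n_genes = 100L, n_samples_female = 1L,
                    frac_escape = 0, frac_variable = 0, frac_subject = 1,
                    per_cpg_sd = 0.2, planted_effects = list())
  truth <- simulate_truth(cfg)
  bs <- simulate_bisulfite_reads(truth, seed = 14)
  got <- mean(tapply(bs$cpg_values$value,
                     bs$cpg_values$gene_id, adjacent_cpg_difference))
  # Independent oracle: E|d| for the mean of two clipped normals around the
  # two allele means, by direct Monte-Carlo.
  set.seed(15)
  clip <- function(x) pmin(pmax(x, 0), 1)
  v1 <- (clip(0.05 + rnorm(2e5, 0, 0.2)) +
           clip(0.75 + rnorm(2e5, 0, 0.2))) / 2
  v2 <- (clip(0.05 + rnorm(2e5, 0, 0.2)) +
           clip(0.75 + rnorm(2e5, 0, 0.2))) / 2
  want <- mean(abs(v1 - v2))
  expect_gt(got, 0)
  expect_equal(got, want, tolerance = 0.05)
})

test_that("mark-matrix group means reproduce the effect table", {
  cfg <- sim_config(seed = 17, n_genes = 200L, n_samples_female = 6L,
                    n_samples_male = 4L)
  truth <- simulate_truth(cfg)
  mm <- simulate_mark_matrix(truth, seed = 18)
  eff <- cfg$mark_effects
  for (i in seq_len(nrow(eff))) {
    mk <- eff$mark[i]
    d <- mm$marks[mm$marks$mark == mk, ]
    males <- d$value[d$sex == "male"]
    exp_male <- if (mk == "DNAme") min(max(eff$xa_mean[i], 0), 1) else
      eff$xa_mean[i]
    se <- eff$sd[i] / sqrt(length(males))
    if (mk != "DNAme") {   # DNAme is clipped at 0, shifting the mean
      expect_lt(abs(mean(males) - exp_male), 3 * se + 0.05)
    }
    st <- truth$status[d$gene_id[d$sex == "female"],
                       , drop = FALSE]
    fsub <- d[d$sex == "female", ]
    fsub$truth <- truth$status[cbind(fsub$gene_id, fsub$sample_id)]
    msub <- mean(fsub$value[fsub$truth == "subject"])
    mesc <- mean(fsub$value[fsub$truth == "escape"])
    if (mk == "DNAme") {
      expect_gt(msub, mesc)   # subject-Xi methylation raises female mean
    } else {
      want_dir <- sign(eff$xi_subject[i] - eff$xi_escape[i])
      expect_equal(sign(msub - mesc), want_dir)
    }
  }
})

test_that("genotypes are Hardy-Weinberg and planted columns match truth", {
  cfg <- sim_config(seed = 19, n_genes = 5L, n_samples_female = 5000L,
                    n_samples_male = 5000L,
                    planted_effects = list(
                      list(locus_id = "L1", gene_id = "g0001",
                           probs = c(0.5, 0.5, 0.5), maf = 0.5)))
  truth <- simulate_truth(cfg)
  g <- simulate_genotypes(truth, seed = 20, n_loci = 5L)
  het <- mean(g$genotypes["loc_null_001", ] == 1L)
  q <- g$loci$maf[g$loci$locus_id == "loc_null_001"]
  expect_lt(abs(het - 2 * q * (1 - q)), 0.02)
  fem <- truth$samples$sample_id[truth$samples$sex == "female"]
  expect_identical(unname(g$genotypes["L1", fem]),
                   unname(truth$planted_genotypes[fem, "L1"]))
  # zero alternate-allele frequency: all reference homozygotes
  cfg0 <- sim_config(seed = 19, n_genes = 5L, n_samples_female = 50L,
                     planted_effects = list(
                       list(locus_id = "L0", gene_id = "g0001",
                            probs = c(0.5, 0.5, 0.5), maf = 0)))
  t0 <- simulate_truth(cfg0)
  g0 <- simulate_genotypes(t0, seed = 21, n_loci = 3L)
  expect_true(all(g0$genotypes["L0", ] == 0L))
})

test_that("escape and subject genes separate at the ratio threshold", {
  cfg <- sim_config(seed = 23, n_genes = 200L, n_samples_female = 1L,
                    skew_fraction = 1, planted_effects = list())
  truth <- simulate_truth(cfg)
  counts <- simulate_allelic_counts(truth, depth = 500, seed = 24)
  meta <- stats::setNames(truth$genes$meta_status, truth$genes$gene_id)
  p <- counts$xi_reads / (counts$xi_reads + counts$xa_reads)
  p_star <- 0.10 / 1.10
  esc <- p[meta[counts$gene_id] == "escape"]
  sub <- p[meta[counts$gene_id] == "subject"]
  expect_true(all(esc > p_star))
  expect_true(all(sub < p_star))
})
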