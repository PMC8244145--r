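test_that("bulk DNAme calls follow the threshold bands", {
  expect_equal(call_from_dname(0.05, 0.02), "escape")
  expect_equal(call_from_dname(0.40, 0.02), "subject")
  expect_equal(call_from_dname(0.12, 0.02), "intermediate")  # 10-15% gap
  expect_equal(call_from_dname(0.60, 0.02), "intermediate")  # boundary
  expect_equal(call_from_dname(0.80, 0.02), "hypermethylated")
  expect_equal(call_from_dname(0.05, 0.30), "uninformative")
  expect_equal(call_from_dname(0.05, NA), "uninformative")
})

test_that("per-read profiles compute mean, decile bin and fractions", {
  r <- function(m, t) tibble::tibble(n_meth = m, n_total = t)
  p <- per_read_profile(r(c(0L, 5L), c(5L, 5L)))
  expect_equal(p$mean_dname, 0.5)
  expect_equal(c(p$frac_low, p$frac_mid, p$frac_high), c(0.5, 0, 0.5))
  p2 <- per_read_profile(r(rep(2L, 4), rep(5L, 4)))
  expect_equal(p2$mean_dname, 0.4)
  expect_equal(p2$frac_mid, 1)
  # bin rule: floor(mean*10), top bin closed
  for (vals in list(c(1L, 10L), c(9L, 10L), c(10L, 10L))) {
    p3 <- per_read_profile(r(vals[1], vals[2]))
    expect_equal(p3$bin, min(floor(vals[1] / vals[2] * 10), 9L))
  }
})

test_that("per-read category fractions are disjoint and bounded", {
  set.seed(1)
  for (i in 1:30) {
    n <- sample(1:50, 1)
    tot <- sample(1:10, n, replace = TRUE)
    reads <- tibble::tibble(n_total = tot,
                            n_meth = vapply(tot, function(t)
                              sample(0:t, 1), 0L))
    p <- per_read_profile(reads)
    expect_lte(p$frac_low + p$frac_mid + p$frac_high, 1 + 1e-12)
    expect_true(all(c(p$frac_low, p$frac_mid, p$frac_high) >= 0))
  }
})

test_that("allelic DNAme calls group by base and apply 0.25/0.75 rules", {
  mk <- function(n_ct, m_ct, n_ga, m_ga) tibble::tibble(
    n_meth = c(round(m_ct * 10) * rep(1L, n_ct),
               round(m_ga * 10) * rep(1L, n_ga)),
    n_total = 10L,
    snp_allele = c(rep("C", n_ct), rep("G", n_ga))
  )
  expect_equal(allelic_dname_call(mk(8, 0.05, 8, 0.95), "C", "G")$status,
               "subject")
  expect_equal(allelic_dname_call(mk(8, 0.10, 8, 0.10), "C", "G")$status,
               "escape")
  expect_equal(allelic_dname_call(mk(8, 0.90, 8, 0.95), "C", "G")$status,
               "hypermethylated")
  expect_equal(allelic_dname_call(mk(8, 0.5, 8, 0.9), "C", "G")$status,
               "uninformative")
  # depth guard: fewer than five reads in one group
  expect_equal(allelic_dname_call(mk(4, 0.05, 8, 0.95), "C", "G")$detail,
               "depth")
  # bisulfite-indistinguishable pairs are excluded
  expect_equal(allelic_dname_call(mk(8, 0.0, 8, 1.0), "C", "T")$detail,
               "bisulfite-indistinguishable")
  expect_equal(allelic_dname_call(mk(8, 0.0, 8, 1.0), "G", "A")$detail,
               "bisulfite-indistinguishable")
})

test_that("allelic bins use the mean of per-allele means", {
  mk <- function(m_ct, m_ga, n_ct = 10, n_ga = 30) tibble::tibble(
    n_meth = c(rep(round(m_ct * 10), n_ct), rep(round(m_ga * 10), n_ga)),
    n_total = 10L,
    snp_allele = c(rep("T", n_ct), rep("A", n_ga))
  )
  b <- allelic_bin_profile(mk(0, 1))
  expect_equal(b$bin, 5L)    # midpoint 0.5 despite 3x more high reads
  expect_equal(c(b$low_mean, b$high_mean), c(0, 1))
  expect_equal(allelic_bin_profile(mk(0.2, 0.4))$bin, 3L)
  tie <- allelic_bin_profile(mk(0.3, 0.3))
  expect_equal(tie$low_group, "CT")
})

test_that("adjacent-CpG differences average |delta| and skip missing", {
  expect_equal(adjacent_cpg_difference(c(0.2, 0.2, 0.2)), 0)
  expect_equal(adjacent_cpg_difference(c(0, 1, 0)), 1)
  expect_equal(adjacent_cpg_difference(c(0.1, 0.4, 0.2)), 0.25)
  expect_equal(adjacent_cpg_difference(c(0.1, NA, 0.2, 0.4)), 0.2)
})

test_that("array-style filters drop methylated-male probes and outliers", {
  probes <- sprintf("p%02d", 1:5)
  male <- matrix(c(0.02, 0.05, 0.20, 0.10, 0.50), 5, 3,
                 dimnames = list(probes, paste0("m", 1:3)))
  fem <- matrix(0.3, 5, 12, dimnames = list(probes, paste0("f", 1:12)))
  out <- filter_450k_style(fem, male)
  expect_equal(out$probes, probes[c(1, 2, 4)])
  expect_equal(out$female_samples, colnames(fem))  # identical: none drop
  # one female far below the cohort is dropped
  set.seed(6)
  fem2 <- fem + matrix(rep(rnorm(12, 0, 0.01), each = 5), 5, 12)
  fem2[, 1] <- 0.0
  out2 <- filter_450k_style(fem2, male)
  expect_false("f1" %in% out2$female_samples)
  expect_true(all(paste0("f", 2:12) %in% out2$female_samples))
  # a sample sitting exactly at mean - 2 SD is retained (strict rule):
  # solve for the sample mean that lands on its own cohort's cutoff
  rest <- c(0.28, 0.3, 0.3, 0.31, 0.33, 0.35)
  f_root <- function(x) {
    v <- c(x, rest); x - (mean(v) - 2 * sd(v))
  }
  x0 <- uniroot(f_root, c(0, 0.28), tol = 1e-12)$root
  if (f_root(x0) < 0) x0 <- x0 + 4 * abs(f_root(x0)) + 1e-12
  femb <- matrix(rep(c(x0, rest), each = 5), 5, 7,
                 dimnames = list(probes, paste0("b", 1:7)))
  expect_true("b1" %in% filter_450k_style(femb, male)$female_samples)
  # and epsilon below the cutoff drops
  femb[, 1] <- x0 - 1e-6
  expect_false("b1" %in% filter_450k_style(femb, male)$female_samples)
})

test_that("DNAme variable-escape uses the 33% rule over informative", {
  d <- calls_of(c(rep("escape", 4), rep("subject", 4),
                  rep("uninformative", 2)), id = "tx1")
  out <- dname_variable_escape(d)
  expect_equal(out$transcript$status, "variable")   # 4/8 each >= 1/3
  d2 <- calls_of(c(rep("subject", 9), "escape"), id = "tx1")
  expect_equal(dname_variable_escape(d2)$transcript$status, "subject")
  # opposite constitutive TSSs flag the gene as variable between TSSs
  d3 <- dplyr::bind_rows(
    calls_of(rep("escape", 6), id = "tx1", gene_id = "g1"),
    calls_of(rep("subject", 6), id = "tx2", gene_id = "g1"))
  g <- dname_variable_escape(d3)$gene
  expect_true(g$between_tss)
  expect_equal(g$status, "variable")
})

test_that("transcript DNAme calls recover simulated constitutive truth", {
  cfg <- sim_config(seed = 21, n_genes = 120L)
  truth <- simulate_truth(cfg)
  mm <- simulate_mark_matrix(truth, seed = 22)
  dn <- mm$marks[mm$marks$mark == "DNAme", ]
  males <- truth$samples$sample_id[truth$samples$sex == "male"]
  mmean <- tapply(dn$value[dn$sample_id %in% males],
                  dn$gene_id[dn$sample_id %in% males], mean)
  fem <- dn[dn$sex == "female", ]
  st <- call_from_dname(fem$value, unname(mmean[fem$gene_id]))
  truth_st <- truth$status[cbind(fem$gene_id, fem$sample_id)]
  meta <- stats::setNames(truth$genes$meta_status, truth$genes$gene_id)
  keep <- meta[fem$gene_id] %in% c("escape", "subject") &
    st %in% c("escape", "subject")
  expect_gt(mean(st[keep] == truth_st[keep]), 0.95)
})
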