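# Seeded generator of gene models, allelic expression counts, bisulfite
# reads, chromatin-mark matrices and genotypes with planted XCI structure.
# All randomness flows through the single seed in the config (or the seed
# argument of the individual generators); identical seeds give identical
# output.

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default chromatin-mark effect table for the generator
#'
#' One row per mark: the active-X (Xa) baseline, the inactive-X (Xi)
#' component added to female signal at escape and at subject genes, the
#' Gaussian noise sd, and the region kind the mark is quantified over.
#' Heterochromatic marks (H3K9me3, H3K27me3) carry a larger Xi component at
#' subject genes; euchromatic marks (H3K4me3, H3K27ac, H3K36me3, H3K4me1)
#' carry a larger Xi component at escape genes; promoter DNAme (proportion
#' scale) has the largest standardized escape-vs-subject separation.
#'
#' @return A tibble with columns `mark`, `region_kind`, `xa_mean`,
#'   `xi_escape`, `xi_subject`, `sd`.
#' @export
default_mark_effects <- function() {
  tibble::tribble(
    ~mark,       ~region_kind, ~xa_mean, ~xi_escape, ~xi_subject, ~sd,
    "H3K4me3",   "promoter",   10,       8,          4,           3,
    "H3K27ac",   "promoter",   8,        6,          3,           2.5,
    "H3K9me3",   "promoter",   2,        3,          4.5,         1.5,
    "H3K27me3",  "promoter",   2,        5,          7,           2,
    "H3K36me3",  "exon_body",  6,        4,          2,           2,
    "H3K4me1",   "enhancer",   5,        3.5,        2.5,         2,
    "DNAme",     "promoter",   0.05,     0.02,       0.35,        0.04
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic XCI dataset. Defaults emulate
#' the statistical structure of a skewed-XCI epigenome cohort: escape genes
#' express their Xi allele at 20-100% of the Xa level, subject genes below
#' 5%; promoter CpG islands are unmethylated on the Xa and on the escape-Xi
#' but heavily (and noisily, CpG to CpG) methylated on the subject-Xi;
#' heterochromatic marks are higher and euchromatic marks lower on the Xi at
#' subject genes.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_genes Number of X-linked genes (one transcript each by default).
#' @param frac_escape,frac_subject,frac_variable Status fractions; the
#'   remainder gets meta-status `unknown` (a hidden constitutive state).
#' @param n_samples_female,n_samples_male Cohort sizes.
#' @param tissues Tissue labels cycled over samples.
#' @param skew_fraction Fraction of female samples with fully skewed XCI.
#' @param xi_expr_ratio_escape,xi_expr_ratio_subject Xi/Xa expression-ratio
#'   ranges (uniform draw per gene) for escape and subject states.
#' @param dname_xa_mean,dname_xi_subject_mean,dname_xi_escape_mean Mean
#'   per-CpG methylation of the Xa allele and of the Xi allele under each
#'   state.
#' @param per_cpg_sd SD of the per-CpG offset added to the allele mean
#'   (creates the intermediate, CpG-inconsistent Xi methylation).
#' @param n_cpgs CpGs per promoter island.
#' @param reads_per_island Mean bisulfite reads per island per sample.
#' @param mark_effects Effect table, see [default_mark_effects()].
#' @param mark_effect_scale Multiplier on every Xi component (1 = default;
#'   0 removes all status signal from the marks).
#' @param n_loci Number of genotyped loci (planted + null).
#' @param planted_effects List of planted genotype effects; each element is
#'   `list(locus_id=, gene_id=, probs=c(p_ref, p_het, p_alt), maf=)` giving
#'   the per-genotype escape probability at that (variable) gene.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 250L,
                       frac_escape = 0.16,
                       frac_subject = 0.64,
                       frac_variable = 0.12,
                       n_samples_female = 8L,
                       n_samples_male = 5L,
                       tissues = c("blood", "brain", "breast"),
                       skew_fraction = 0.75,
                       xi_expr_ratio_escape = c(0.2, 1.0),
                       xi_expr_ratio_subject = c(0.0, 0.05),
                       dname_xa_mean = 0.05,
                       dname_xi_subject_mean = 0.75,
                       dname_xi_escape_mean = 0.05,
                       per_cpg_sd = 0.2,
                       n_cpgs = 12L,
                       reads_per_island = 40L,
                       mark_effects = default_mark_effects(),
                       mark_effect_scale = 1,
                       n_loci = 40L,
                       planted_effects = list(
                         list(locus_id = "loc_planted_1", gene_id = "g0001",
                              probs = c(0.25, 0.5, 0.75), maf = 0.5)
                       )) {
  props <- c(frac_escape, frac_subject, frac_variable, skew_fraction)
  stopifnot(all(props >= 0 & props <= 1),
            frac_escape + frac_subject + frac_variable <= 1,
            n_cpgs >= 5L, n_genes > 0L, n_loci >= length(planted_effects))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the ground truth of an XCI cohort
#'
#' Assigns each gene a meta-status (escape / subject / variable / unknown),
#' each female sample an inactivated haplotype and skewing state, and each
#' (variable gene, female sample) pair a per-sample state. Genes named in
#' `planted_effects` are variable with escape probability set per genotype
#' at the planted locus; other variable genes use base rate 0.5.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List of class `xci_truth`: `genes` (gene-model tibble as from
#'   [read_gene_models()] plus `meta_status`), `samples` (sample sheet),
#'   `status` (gene x female-sample character matrix of escape/subject),
#'   `planted_genotypes` (female-sample x planted-locus dosage matrix),
#'   `planted` (the resolved planted-effect list).
#' @export
simulate_truth <- function(cfg, seed = cfg$seed) {
  with_seed_(seed, {
    n <- cfg$n_genes
    gene_id <- sprintf("g%04d", seq_len(n))
    for (pe in cfg$planted_effects) {
      if (!pe$gene_id %in% gene_id) {
        stop("planted locus ", pe$locus_id, " references unknown gene ",
             pe$gene_id)
      }
    }
    n_esc <- round(cfg$frac_escape * n)
    n_sub <- round(cfg$frac_subject * n)
    n_var <- round(cfg$frac_variable * n)
    planted_genes <- vapply(cfg$planted_effects, `[[`, "", "gene_id")
    status_pool <- c(rep("escape", n_esc), rep("subject", n_sub),
                     rep("variable", max(n_var - length(planted_genes), 0L)),
                     rep("unknown", n - n_esc - n_sub -
                           max(n_var, length(planted_genes))))
    meta <- rep(NA_character_, n)
    meta[match(planted_genes, gene_id)] <- "variable"
    meta[is.na(meta)] <- sample(status_pool)

    # Gene models: one transcript per gene along chrX, alternating strand,
    # CpG island centred on the TSS.
    strand <- rep(c("+", "-"), length.out = n)
    start <- 10000L + (seq_len(n) - 1L) * 10000L
    end <- start + 2000L
    tss <- ifelse(strand == "+", start, end - 1L)
    genes <- tibble::tibble(
      gene_id = gene_id, transcript_id = paste0("t_", gene_id),
      chrom = "chrX", strand = strand, tss = tss, start = start, end = end,
      exons = lapply(seq_len(n), function(i) {
        cbind(c(start[i], start[i] + 1200L), c(start[i] + 600L, end[i]))
      }),
      cpg_start = tss - 250L, cpg_end = tss + 250L,
      is_par = FALSE, meta_status = meta
    )

    nf <- cfg$n_samples_female; nm <- cfg$n_samples_male
    samples <- tibble::tibble(
      sample_id = c(sprintf("F%02d", seq_len(nf)),
                    sprintf("M%02d", seq_len(nm))),
      sex = c(rep("female", nf), rep("male", nm)),
      tissue = rep(cfg$tissues, length.out = nf + nm),
      dataset = "sim",
      skewed_xi = c(seq_len(nf) <= round(cfg$skew_fraction * nf),
                    rep(NA, nm)),
      xi_haplotype = c(sample(c("A", "B"), nf, replace = TRUE),
                       rep(NA_character_, nm))
    )
    females <- samples$sample_id[samples$sex == "female"]

    # Planted genotypes (per female sample) drive escape probability at the
    # planted variable genes.
    planted_gt <- matrix(NA_integer_, nf, length(cfg$planted_effects),
                         dimnames = list(females,
                                         vapply(cfg$planted_effects, `[[`,
                                                "", "locus_id")))
    for (j in seq_along(cfg$planted_effects)) {
      q <- cfg$planted_effects[[j]]$maf
      planted_gt[, j] <- rbinom(nf, 2L, q)
    }

    status <- matrix(NA_character_, n, nf,
                     dimnames = list(gene_id, females))
    const <- meta %in% c("escape", "subject")
    status[const, ] <- meta[const]
    hidden <- meta == "unknown"
    status[hidden, ] <- sample(c("escape", "subject"), sum(hidden),
                               replace = TRUE, prob = c(0.2, 0.8))
    for (i in which(meta == "variable")) {
      pe_idx <- match(gene_id[i], planted_genes)
      p <- if (!is.na(pe_idx)) {
        cfg$planted_effects[[pe_idx]]$probs[planted_gt[, pe_idx] + 1L]
      } else rep(0.5, nf)
      status[i, ] <- ifelse(runif(nf) < p, "escape", "subject")
    }
    structure(list(genes = genes, samples = samples, status = status,
                   planted_genotypes = planted_gt,
                   planted = cfg$planted_effects, cfg = cfg),
              class = "xci_truth")
  })
}

#' Simulate allelic expression read counts
#'
#' Per female sample and gene: total reads ~ Poisson(depth); the Xi-allele
#' read count is Binomial(total, r/(1+r)) with the Xi/Xa ratio r drawn from
#' the status-appropriate range. Unskewed samples are 50:50 mixtures of the
#' two Xi choices, so their allelic imbalance vanishes in expectation.
#'
#' @param truth From [simulate_truth()].
#' @param depth Mean total reads per gene.
#' @param seed Optional seed.
#' @return Tibble: `gene_id`, `sample_id`, `allele_a`, `allele_b` (counts by
#'   haplotype), `xi_reads`, `xa_reads` (counts by chromosome state; for
#'   unskewed samples these are with respect to each cell's own Xi).
#' @export
simulate_allelic_counts <- function(truth, depth = 500, seed = NULL) {
  stopifnot(depth > 0)
  with_seed_(seed, {
    fem <- truth$samples[truth$samples$sex == "female", ]
    cfg <- truth$cfg
    out <- lapply(seq_len(nrow(fem)), function(si) {
      sid <- fem$sample_id[si]
      st <- truth$status[, sid]
      lo <- ifelse(st == "escape", cfg$xi_expr_ratio_escape[1L],
                   cfg$xi_expr_ratio_subject[1L])
      hi <- ifelse(st == "escape", cfg$xi_expr_ratio_escape[2L],
                   cfg$xi_expr_ratio_subject[2L])
      r <- runif(length(st), lo, hi)
      p <- r / (1 + r)
      total <- rpois(length(p), depth)
      if (isTRUE(fem$skewed_xi[si])) {
        xi <- rbinom(length(p), total, p)
        a <- if (fem$xi_haplotype[si] == "A") xi else total - xi
      } else {
        n1 <- rbinom(length(p), total, 0.5)     # cells with Xi = A
        xi1 <- rbinom(length(p), n1, p)         # Xi reads in those cells
        xi2 <- rbinom(length(p), total - n1, p)
        xi <- xi1 + xi2
        a <- xi1 + (total - n1 - xi2)
      }
      tibble::tibble(gene_id = rownames(truth$status), sample_id = sid,
                     allele_a = a, allele_b = total - a,
                     xi_reads = xi, xa_reads = total - xi)
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate per-read bisulfite methylation with SNP allele tags
#'
#' Each promoter island carries `n_cpgs` CpGs; the per-CpG methylation
#' probability is the allele-state mean plus a per-CpG offset
#' Normal(0, per_cpg_sd) clipped to `[0, 1]` (CpG-to-CpG inconsistency on
#' the Xi, not cell-mixture bimodality). Reads cover a contiguous run of
#' CpGs and are tagged with the base of a heterozygous SNP when the island
#' has one; some SNPs are deliberately C/T or G/A to exercise the
#' bisulfite-exclusion rule.
#'
#' @param truth From [simulate_truth()].
#' @param seed Optional seed.
#' @param genes Optional subset of gene ids (default all).
#' @return List: `reads` (read_id, island_id = gene_id, sample_id, n_meth,
#'   n_total, snp_id, snp_allele, from_xi), `snps` (snp_id, gene_id, ref,
#'   alt, xi_allele_base per sample handled via reads), `cpg_values`
#'   (gene_id, sample_id, cpg_index, value: the realized female per-CpG
#'   methylation, mean of the two alleles).
#' @export
simulate_bisulfite_reads <- function(truth, seed = NULL, genes = NULL) {
  cfg <- truth$cfg
  with_seed_(seed, {
    gid <- genes %||% truth$genes$gene_id
    fem <- truth$samples[truth$samples$sex == "female", ]
    # SNP per island: 60% informative pair, 20% C/T, 20% G/A, rest none.
    pairs_inf <- list(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))
    snp_kind <- sample(c("inf", "ct", "ga", "none"), length(gid),
                       replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1))
    alleles <- lapply(seq_along(gid), function(i) {
      switch(snp_kind[i],
             inf = pairs_inf[[sample.int(4L, 1L)]],
             ct = c("C", "T"), ga = c("G", "A"), none = NULL)
    })
    snps <- tibble::tibble(
      snp_id = ifelse(snp_kind == "none", NA_character_,
                      paste0("snp_", gid)),
      gene_id = gid,
      ref = vapply(alleles, function(a) a[1L] %||% NA_character_, ""),
      alt = vapply(alleles, function(a) a[2L] %||% NA_character_, "")
    )
    reads_out <- vector("list", length(gid) * nrow(fem))
    cpg_out <- vector("list", length(gid) * nrow(fem))
    k <- 0L
    for (si in seq_len(nrow(fem))) {
      sid <- fem$sample_id[si]
      skewed <- isTRUE(fem$skewed_xi[si])
      for (i in seq_along(gid)) {
        st <- truth$status[gid[i], sid]
        xi_mean <- if (st == "escape") cfg$dname_xi_escape_mean else
          cfg$dname_xi_subject_mean
        p_xa <- pmin(pmax(cfg$dname_xa_mean +
                            rnorm(cfg$n_cpgs, 0, cfg$per_cpg_sd), 0), 1)
        p_xi <- pmin(pmax(xi_mean +
                            rnorm(cfg$n_cpgs, 0, cfg$per_cpg_sd), 0), 1)
        n_reads <- rpois(1L, cfg$reads_per_island)
        if (n_reads == 0L) next
        from_xi <- runif(n_reads) < 0.5          # one Xi, one Xa per cell
        rstart <- sample.int(cfg$n_cpgs, n_reads, replace = TRUE)
        rlen <- pmin(sample(4:8, n_reads, replace = TRUE),
                     cfg$n_cpgs - rstart + 1L)
        n_meth <- vapply(seq_len(n_reads), function(r) {
          p <- if (from_xi[r]) p_xi else p_xa
          idx <- rstart[r]:(rstart[r] + rlen[r] - 1L)
          sum(runif(length(idx)) < p[idx])
        }, 0L)
        al <- alleles[[i]]
        snp_allele <- rep(NA_character_, n_reads)
        if (!is.null(al)) {
          # Xi haplotype carries one fixed allele; in unskewed samples the
          # Xi choice varies by cell but the haplotype-to-allele link is
          # fixed, so the read's allele follows its chromosome of origin
          # via the sample's (or cell's) Xi haplotype.
          xi_is_ref <- (fem$xi_haplotype[si] == "A")
          if (skewed) {
            snp_allele <- ifelse(from_xi == xi_is_ref, al[1L], al[2L])
          } else {
            cell_xi_a <- runif(n_reads) < 0.5
            snp_allele <- ifelse(from_xi == cell_xi_a, al[1L], al[2L])
          }
        }
        k <- k + 1L
        reads_out[[k]] <- tibble::tibble(
          read_id = sprintf("%s_%s_r%03d", gid[i], sid, seq_len(n_reads)),
          island_id = gid[i], sample_id = sid,
          n_meth = n_meth, n_total = rlen,
          snp_id = if (is.null(al)) NA_character_ else snps$snp_id[i],
          snp_allele = snp_allele, from_xi = from_xi
        )
        cpg_out[[k]] <- tibble::tibble(
          gene_id = gid[i], sample_id = sid, cpg_index = seq_len(cfg$n_cpgs),
          value = (p_xa + p_xi) / 2
        )
      }
    }
    list(reads = dplyr::bind_rows(reads_out[seq_len(k)]),
         snps = snps[snp_kind != "none", ],
         cpg_values = dplyr::bind_rows(cpg_out[seq_len(k)]))
  })
}

#' Simulate the normalized chromatin-mark matrix
#'
#' Female signal at a gene = Xa baseline + Xi component (depending on that
#' sample's state at the gene, scaled by `mark_effect_scale`) + Gaussian
#' noise; male signal = Xa baseline + noise. DNAme rows are averaged over
#' the two alleles and clipped to `[0, 1]`. Also returns per-sample
#' autosomal mark means (with tissue offsets) used for female-male pairing.
#'
#' @param truth From [simulate_truth()].
#' @param seed Optional seed.
#' @return List: `marks` (long tibble transcript_id, gene_id, sample_id,
#'   sex, tissue, mark, region_kind, value), `autosomal` (sample x mark
#'   matrix of autosomal means).
#' @export
simulate_mark_matrix <- function(truth, seed = NULL) {
  cfg <- truth$cfg
  with_seed_(seed, {
    eff <- cfg$mark_effects
    smp <- truth$samples
    genes <- truth$genes
    # tissue offsets give the autosomal clustering structure
    toff <- matrix(rnorm(length(cfg$tissues) * nrow(eff), 0, 1.5),
                   length(cfg$tissues), nrow(eff),
                   dimnames = list(cfg$tissues, eff$mark))
    rows <- vector("list", nrow(eff))
    for (m in seq_len(nrow(eff))) {
      xa <- eff$xa_mean[m]
      is_dname <- eff$mark[m] == "DNAme"
      vals <- matrix(NA_real_, nrow(genes), nrow(smp))
      for (s in seq_len(nrow(smp))) {
        noise <- rnorm(nrow(genes), 0, eff$sd[m])
        if (smp$sex[s] == "female") {
          st <- truth$status[, smp$sample_id[s]]
          xi <- ifelse(st == "escape", eff$xi_escape[m],
                       eff$xi_subject[m]) * cfg$mark_effect_scale
          v <- if (is_dname) (xa + xi) / 2 + noise else xa + xi + noise
        } else {
          v <- if (is_dname) xa + noise else xa + noise
        }
        if (is_dname) v <- pmin(pmax(v, 0), 1) else v <- pmax(v, 0)
        vals[, s] <- v
      }
      rows[[m]] <- tibble::tibble(
        transcript_id = rep(genes$transcript_id, nrow(smp)),
        gene_id = rep(genes$gene_id, nrow(smp)),
        sample_id = rep(smp$sample_id, each = nrow(genes)),
        sex = rep(smp$sex, each = nrow(genes)),
        tissue = rep(smp$tissue, each = nrow(genes)),
        mark = eff$mark[m], region_kind = eff$region_kind[m],
        value = as.vector(vals)
      )
    }
    autosomal <- matrix(NA_real_, nrow(smp), nrow(eff),
                        dimnames = list(smp$sample_id, eff$mark))
    for (s in seq_len(nrow(smp))) {
      autosomal[s, ] <- eff$xa_mean + toff[smp$tissue[s], ] +
        rnorm(nrow(eff), 0, 0.2)
    }
    list(marks = dplyr::bind_rows(rows), autosomal = autosomal)
  })
}

#' Simulate genotypes consistent with the planted effects
#'
#' Planted loci reuse the dosages drawn in [simulate_truth()] (for female
#' samples; males get independent Hardy-Weinberg draws at the same allele
#' frequency). Null loci are Hardy-Weinberg at allele frequencies drawn
#' uniformly in `[0.2, 0.8]`, independent of the truth.
#'
#' @param truth From [simulate_truth()].
#' @param seed Optional seed.
#' @param n_loci Optional override of `cfg$n_loci`.
#' @return List: `genotypes` (locus x sample dosage matrix), `loci`
#'   (tibble locus_id, chrom, pos, maf, planted).
#' @export
simulate_genotypes <- function(truth, seed = NULL, n_loci = NULL) {
  cfg <- truth$cfg
  n_loci <- n_loci %||% cfg$n_loci
  with_seed_(seed, {
    smp <- truth$samples
    planted_ids <- colnames(truth$planted_genotypes)
    n_null <- n_loci - length(planted_ids)
    stopifnot(n_null >= 0L)
    ids <- c(planted_ids, sprintf("loc_null_%03d", seq_len(n_null)))
    maf <- c(vapply(truth$planted, `[[`, 0, "maf"),
             runif(n_null, 0.2, 0.8))
    g <- matrix(NA_integer_, n_loci, nrow(smp),
                dimnames = list(ids, smp$sample_id))
    for (j in seq_len(n_loci)) g[j, ] <- rbinom(nrow(smp), 2L, maf[j])
    fem <- smp$sample_id[smp$sex == "female"]
    if (length(planted_ids)) {
      g[planted_ids, fem] <- t(truth$planted_genotypes[fem, , drop = FALSE])
    }
    list(genotypes = g,
         loci = tibble::tibble(
           locus_id = ids,
           chrom = rep(c("chr4", "chr7", "chrX"), length.out = n_loci),
           pos = 1000L + seq_len(n_loci) * 5000L,
           maf = maf, planted = ids %in% planted_ids
         ))
  })
}

#' Simulate a complete synthetic XCI dataset
#'
#' Runs every generator under the config seed, in a fixed order, so the
#' whole dataset is reproducible from `cfg$seed` alone.
#'
#' @param cfg A [sim_config()].
#' @param depth Mean allelic read depth per gene.
#' @return List: `truth`, `counts`, `bisulfite`, `marks`, `genotypes`.
#' @export
simulate_xci_dataset <- function(cfg, depth = 500) {
  truth <- simulate_truth(cfg)
  list(
    truth = truth,
    counts = simulate_allelic_counts(truth, depth = depth,
                                     seed = cfg$seed + 1L),
    bisulfite = simulate_bisulfite_reads(truth, seed = cfg$seed + 2L),
    marks = simulate_mark_matrix(truth, seed = cfg$seed + 3L),
    genotypes = simulate_genotypes(truth, seed = cfg$seed + 4L)
  )
}

#' Write a simulated dataset to disk in the package's external formats
#'
#' Gene models as BED12, sample sheet / counts / reads / marks as TSV, and
#' genotypes as a minimal VCF, so the file-based readers can consume a full
#' dataset produced by the generator.
#'
#' @param dataset From [simulate_xci_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files are named `genes.bed`, `samples.tsv`,
#'   `allelic_counts.tsv`, `methyl_reads.tsv`, `marks.tsv`,
#'   `genotypes.vcf`.
#' @export
write_xci_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_models(dataset$truth$genes, file.path(dir, "genes.bed"))
  tsv(dataset$truth$samples[, c("sample_id", "sex", "tissue", "dataset",
                                "skewed_xi")], "samples.tsv")
  tsv(dataset$counts, "allelic_counts.tsv")
  tsv(dataset$bisulfite$reads[, c("read_id", "island_id", "sample_id",
                                  "n_meth", "n_total", "snp_id",
                                  "snp_allele")], "methyl_reads.tsv")
  tsv(dataset$marks$marks, "marks.tsv")
  g <- dataset$genotypes
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$genotypes + 1L],
                   nrow(g$genotypes))
  gt_str[is.na(g$genotypes)] <- "./."
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g$genotypes)),
                 collapse = "\t"),
           vapply(seq_len(nrow(g$loci)), function(i) {
             paste(c(g$loci$chrom[i], g$loci$pos[i], g$loci$locus_id[i],
                     "A", "G", ".", "PASS", ".", "GT", gt_str[i, ]),
                   collapse = "\t")
           }, ""))
  writeLines(vcf, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
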