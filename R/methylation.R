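# Promoter DNA-methylation XCI callers at three resolutions: bulk female
# means against fixed thresholds (with a male informativeness filter),
# per-read profiles binned by island mean, and allele-resolved calls from
# SNP-tagged bisulfite reads.

#' Configuration for the DNAme callers
#'
#' Band thresholds on the proportion scale. Female means below `escape_max`
#' are escape; strictly between `subject_min` and `subject_max`, subject;
#' above `hyper_min`, hypermethylated; the deliberate gaps (10-15% and the
#' 60% boundary) are an explicit `intermediate` status. TSSs with male mean
#' at or above `male_informative_max` are uninformative (methylated on the
#' Xa). Allele-resolved calls use `allelic_low`/`allelic_high` with at least
#' `min_reads_per_allele` reads per allele group.
#'
#' @param escape_max,subject_min,subject_max,hyper_min,male_informative_max
#'   Band thresholds (defaults 0.10, 0.15, 0.60, 0.60, 0.15).
#' @param allelic_low,allelic_high Allelic thresholds (0.25, 0.75).
#' @param min_reads_per_allele Minimum reads per allele group (5).
#' @return A `dname_call_config` list.
#' @export
dname_call_config <- function(escape_max = 0.10, subject_min = 0.15,
                              subject_max = 0.60, hyper_min = 0.60,
                              male_informative_max = 0.15,
                              allelic_low = 0.25, allelic_high = 0.75,
                              min_reads_per_allele = 5L) {
  stopifnot(0 < escape_max, escape_max < subject_min,
            subject_min < subject_max, subject_max <= hyper_min,
            hyper_min < 1, allelic_low < allelic_high)
  structure(list(escape_max = escape_max, subject_min = subject_min,
                 subject_max = subject_max, hyper_min = hyper_min,
                 male_informative_max = male_informative_max,
                 allelic_low = allelic_low, allelic_high = allelic_high,
                 min_reads_per_allele = as.integer(min_reads_per_allele)),
            class = "dname_call_config")
}

#' XCI call from bulk promoter DNAme means
#'
#' Vectorized over TSSs/samples. Missing male data is uninformative.
#'
#' @param female_mean,male_mean Proportion-scale methylation means.
#' @param cfg A [dname_call_config()].
#' @return Character vector of statuses (escape / subject / hypermethylated
#'   / intermediate / uninformative).
#' @export
call_from_dname <- function(female_mean, male_mean,
                            cfg = dname_call_config()) {
  n <- max(length(female_mean), length(male_mean))
  f <- rep_len(female_mean, n); m <- rep_len(male_mean, n)
  out <- rep("intermediate", n)
  out[f < cfg$escape_max] <- "escape"
  out[f > cfg$subject_min & f < cfg$subject_max] <- "subject"
  out[f > cfg$hyper_min] <- "hypermethylated"
  out[is.na(m) | m >= cfg$male_informative_max] <- "uninformative"
  out[is.na(f) & !(is.na(m) | m >= cfg$male_informative_max)] <-
    "uninformative"
  out
}

#' Per-read methylation profile of one island in one sample
#'
#' Per-read DNAme is methylated / covered CG dinucleotides on the read; the
#' island mean is the unweighted mean over reads; the decile bin is
#' `floor(mean * 10)` with the top bin closed; the category fractions are
#' the fractions of reads below 25%, in (33%, 66%), and above 75%.
#'
#' @param reads Tibble of reads for one island/sample with `n_meth`,
#'   `n_total`.
#' @return One-row tibble: `mean_dname`, `bin`, `frac_low`, `frac_mid`,
#'   `frac_high`, `n_reads`.
#' @export
per_read_profile <- function(reads) {
  stopifnot(nrow(reads) >= 1L, all(reads$n_total >= 1L),
            all(reads$n_meth >= 0L), all(reads$n_meth <= reads$n_total))
  p <- reads$n_meth / reads$n_total
  m <- mean(p)
  tibble::tibble(
    mean_dname = m, bin = min(floor(m * 10), 9L),
    frac_low = mean(p < 0.25), frac_mid = mean(p > 1 / 3 & p < 2 / 3),
    frac_high = mean(p > 0.75), n_reads = length(p)
  )
}

# Bisulfite conversion collapses C->T (and G->A on the opposite strand), so
# a SNP whose two alleles are both in {C,T} or both in {G,A} cannot be
# phased from bisulfite reads.
snp_bisulfite_excluded <- function(ref, alt) {
  al <- c(ref, alt)
  all(al %in% c("C", "T")) || all(al %in% c("G", "A"))
}

#' Allele-resolved XCI call from SNP-tagged bisulfite reads
#'
#' Reads are grouped by SNP base into a CT group (base C or T) and a GA
#' group (base G or A); SNPs whose allele pair is C/T or G/A are excluded as
#' bisulfite-indistinguishable. With at least `min_reads_per_allele` reads
#' in each group, both group means below `allelic_low` call escape; one
#' below `allelic_low` and the other above `allelic_high`, subject; both
#' above `allelic_high`, hypermethylated; anything else uninformative.
#'
#' @param reads Tibble of SNP-tagged reads for one SNP in one sample:
#'   `n_meth`, `n_total`, `snp_allele`.
#' @param ref,alt The SNP's two alleles.
#' @param cfg A [dname_call_config()].
#' @return One-row tibble: `status`, `mean_ct`, `mean_ga`, `n_ct`, `n_ga`,
#'   `detail`.
#' @export
allelic_dname_call <- function(reads, ref, alt,
                               cfg = dname_call_config()) {
  res <- function(status, mct = NA_real_, mga = NA_real_, nct = 0L,
                  nga = 0L, detail = NA_character_) {
    tibble::tibble(status = status, mean_ct = mct, mean_ga = mga,
                   n_ct = nct, n_ga = nga, detail = detail)
  }
  if (snp_bisulfite_excluded(ref, alt)) {
    return(res("uninformative", detail = "bisulfite-indistinguishable"))
  }
  p <- reads$n_meth / reads$n_total
  ct <- reads$snp_allele %in% c("C", "T")
  ga <- reads$snp_allele %in% c("G", "A")
  n_ct <- sum(ct); n_ga <- sum(ga)
  if (n_ct == 0L && n_ga == 0L) {
    return(res("uninformative", detail = "no tagged reads"))
  }
  if (n_ct < cfg$min_reads_per_allele || n_ga < cfg$min_reads_per_allele) {
    return(res("uninformative", mean(p[ct]), mean(p[ga]), n_ct, n_ga,
               "depth"))
  }
  m_ct <- mean(p[ct]); m_ga <- mean(p[ga])
  lo <- cfg$allelic_low; hi <- cfg$allelic_high
  status <- if (m_ct < lo && m_ga < lo) "escape"
  else if ((m_ct < lo && m_ga > hi) || (m_ga < lo && m_ct > hi)) "subject"
  else if (m_ct > hi && m_ga > hi) "hypermethylated"
  else "uninformative"
  res(status, m_ct, m_ga, n_ct, n_ga,
      sprintf("ct=%.3f ga=%.3f", m_ct, m_ga))
}

#' Binned per-allele read methylation with low/high-allele separation
#'
#' The gene bin uses the mean of the two per-allele means (so the bin is the
#' Xi/Xa midpoint even with unequal read depth); within the bin the allele
#' with the lower mean is reported as the low allele. Equal means tie-break
#' deterministically (CT group = low).
#'
#' @param reads SNP-tagged reads for one SNP/sample (`n_meth`, `n_total`,
#'   `snp_allele`).
#' @return One-row tibble: `bin`, `low_mean`, `high_mean`, `low_group`.
#' @export
allelic_bin_profile <- function(reads) {
  p <- reads$n_meth / reads$n_total
  m_ct <- mean(p[reads$snp_allele %in% c("C", "T")])
  m_ga <- mean(p[reads$snp_allele %in% c("G", "A")])
  mid <- mean(c(m_ct, m_ga))
  low_is_ct <- m_ct <= m_ga
  tibble::tibble(
    bin = min(floor(mid * 10), 9L),
    low_mean = if (low_is_ct) m_ct else m_ga,
    high_mean = if (low_is_ct) m_ga else m_ct,
    low_group = if (low_is_ct) "CT" else "GA"
  )
}

#' Mean absolute difference between adjacent CpGs
#'
#' @param values Per-CpG methylation values in island order; pairs with a
#'   missing member are skipped.
#' @return Mean of `|v[i+1] - v[i]|` over retained adjacent pairs.
#' @export
adjacent_cpg_difference <- function(values) {
  stopifnot(length(values) >= 2L)
  d <- abs(diff(values))
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Array-style probe and sample filters
#'
#' Probes are dropped when their male mean methylation exceeds 0.15 (Xa
#' methylated); female samples are dropped when their across-probe mean lies
#' strictly more than two standard deviations below the female-cohort mean
#' (presumed mislabeled males or Xi loss).
#'
#' @param female,male Probe x sample matrices of methylation proportions.
#' @param cfg A [dname_call_config()] (`male_informative_max` reused as the
#'   probe threshold).
#' @return List: `probes` (retained probe names), `female_samples`
#'   (retained female sample names).
#' @export
filter_450k_style <- function(female, male, cfg = dname_call_config()) {
  male_mean <- rowMeans(male, na.rm = TRUE)
  probes <- rownames(female)[male_mean <= cfg$male_informative_max]
  smean <- colMeans(female, na.rm = TRUE)
  cutoff <- mean(smean) - 2 * stats::sd(smean)
  keep <- if (is.na(cutoff)) rep(TRUE, length(smean)) else smean >= cutoff
  list(probes = probes, female_samples = colnames(female)[keep])
}

#' DNAme-based variable-escape classification per transcript and gene
#'
#' A transcript is variably escaping when at least `frac_each` of its
#' informative samples escape and at least `frac_each` are subject;
#' constitutive when one status reaches `1 - frac_each`; otherwise
#' intermediate. Gene-level: a gene whose transcripts have opposite
#' constitutive statuses is flagged variable (between TSSs); otherwise the
#' gene takes a variable call when any transcript is variable, else the
#' transcripts' common status.
#'
#' @param calls Per-sample transcript call table (`id` = transcript,
#'   `gene_id`, `sample_id`, `status`).
#' @param frac_each Fraction of informative samples per status (1/3).
#' @return List: `transcript` (one call per transcript), `gene` (one call
#'   per gene, with `between_tss` flag).
#' @export
dname_variable_escape <- function(calls, frac_each = 1 / 3) {
  inf <- calls[calls$status %in% c("escape", "subject"), ]
  per_tx <- dplyr::summarise(
    dplyr::group_by(inf, .data$id, .data$gene_id),
    n_escape = sum(.data$status == "escape"),
    n_subject = sum(.data$status == "subject"), .groups = "drop"
  )
  n_inf <- per_tx$n_escape + per_tx$n_subject
  fe <- per_tx$n_escape / n_inf
  fs <- per_tx$n_subject / n_inf
  status <- ifelse(
    n_inf == 0, "uninformative",
    ifelse(fe >= frac_each & fs >= frac_each, "variable",
           ifelse(fe >= 1 - frac_each, "escape",
                  ifelse(fs >= 1 - frac_each, "subject", "intermediate")))
  )
  tx <- tibble::tibble(id = per_tx$id, gene_id = per_tx$gene_id,
                       sample_id = "overall", status = status,
                       method = "dname",
                       detail = sprintf("nE=%d nS=%d", per_tx$n_escape,
                                        per_tx$n_subject))
  gene <- dplyr::summarise(
    dplyr::group_by(tx, .data$gene_id),
    between_tss = any(.data$status == "escape") &
      any(.data$status == "subject"),
    status = dplyr::case_when(
      any(.data$status == "escape") & any(.data$status == "subject") ~
        "variable",
      any(.data$status == "variable") ~ "variable",
      all(.data$status == "uninformative") ~ "uninformative",
      any(.data$status == "escape") ~ "escape",
      any(.data$status == "subject") ~ "subject",
      TRUE ~ "intermediate"
    ),
    .groups = "drop"
  )
  list(transcript = tx, gene = gene)
}
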