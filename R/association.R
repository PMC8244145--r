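# Genotype vs XCI-status association at variable-escape genes, population
# attributable risk, and sex-stratified methylation-QTL linear models with
# status-span classification.

#' Relaxed variable-gene set by absolute sample counts
#'
#' For large cohorts the variable set is defined by absolute counts instead
#' of the fraction rule: genes with strictly more than `min_each` samples of
#' each constitutive status.
#'
#' @param calls Per-sample calls (`id`, `status`).
#' @param min_each Count threshold (100; "over" is strict).
#' @return Character vector of gene ids.
#' @export
relaxed_variable_set <- function(calls, min_each = 100L) {
  d <- calls[calls$status %in% c("escape", "subject"), ]
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$id),
    n_escape = sum(.data$status == "escape"),
    n_subject = sum(.data$status == "subject"), .groups = "drop"
  )
  per$id[per$n_escape > min_each & per$n_subject > min_each]
}

# Pearson chi-square (no continuity correction) on a 2x2 table.
chi2_2x2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  c(chi2 = chi2, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Genotype vs XCI-status association tests
#'
#' For every (gene, locus) pair, heterozygous and missing genotypes are
#' excluded (a cis test cannot orient the het's alleles) and a Pearson
#' chi-square is computed on the 2x2 homozygote x status table. BH
#' correction is applied across all tested pairs in the run (optionally
#' restricted to X-linked loci first).
#'
#' @param status Gene x sample character matrix (or tibble `id`,
#'   `sample_id`, `status`) of per-sample statuses.
#' @param genotypes Locus x sample dosage matrix.
#' @param loci Optional loci tibble (for `x_only`).
#' @param genes Genes to test (default all rows of `status`).
#' @param alpha Adjusted significance level (0.01).
#' @param x_only Restrict to X-linked loci (needs `loci$chrom`).
#' @param min_per_class Minimum samples per homozygote class (5).
#' @return Tibble per tested pair: `gene_id`, `locus_id`, the four cell
#'   counts, `chi2`, `p_raw`, `p_adj`, `significant`, `enrichment_ratio`,
#'   `attributable_risk`.
#' @export
xci_genotype_test <- function(status, genotypes, loci = NULL, genes = NULL,
                              alpha = 0.01, x_only = FALSE,
                              min_per_class = 5L) {
  if (!is.matrix(status)) {
    status <- tapply(status$status, list(status$id, status$sample_id),
                     `[`, 1L)
  }
  genes <- genes %||% rownames(status)
  loc_ids <- rownames(genotypes)
  if (x_only) {
    stopifnot(!is.null(loci))
    loc_ids <- loci$locus_id[loci$chrom %in% c("chrX", "X")]
  }
  samples <- intersect(colnames(status), colnames(genotypes))
  rows <- list(); k <- 0L
  for (g in genes) {
    st <- status[g, samples]
    for (l in loc_ids) {
      gt <- genotypes[l, samples]
      keep <- !is.na(gt) & gt != 1L & st %in% c("escape", "subject")
      if (!sum(keep)) next
      tab <- table(factor(gt[keep], levels = c(0L, 2L)),
                   factor(st[keep], levels = c("escape", "subject")))
      if (min(rowSums(tab)) < min_per_class) next
      if (any(colSums(tab) == 0L)) next
      x2 <- chi2_2x2(tab)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        gene_id = g, locus_id = l,
        ref_escape = tab[1L, 1L], ref_subject = tab[1L, 2L],
        alt_escape = tab[2L, 1L], alt_subject = tab[2L, 2L],
        chi2 = x2[["chi2"]], p_raw = x2[["p"]],
        attributable_risk = attributable_risk(tab)
      )
    }
  }
  if (!k) {
    return(tibble::tibble(gene_id = character(), locus_id = character(),
                          ref_escape = integer(), ref_subject = integer(),
                          alt_escape = integer(), alt_subject = integer(),
                          chi2 = numeric(), p_raw = numeric(),
                          attributable_risk = numeric(), p_adj = numeric(),
                          significant = logical(),
                          enrichment_ratio = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p_raw, "BH")
  out$significant <- out$p_adj < alpha
  r_ref <- out$ref_escape / pmax(out$ref_subject, 1L)
  r_alt <- out$alt_escape / pmax(out$alt_subject, 1L)
  er <- r_ref / r_alt
  out$enrichment_ratio <- ifelse(!is.finite(er) | er == 0, NA_real_,
                                 pmax(er, 1 / er))
  out
}

#' Population attributable risk of escape for the higher-risk genotype
#'
#' `AR = (P(escape) - P(escape | non-carrier)) / P(escape)` over the two
#' homozygote classes, taking the genotype with the higher escape rate as
#' the carrier; clipped to `[0, 1]`.
#'
#' @param tab 2x2 genotype (rows) x status (columns escape, subject) table.
#' @return Attributable-risk proportion.
#' @export
attributable_risk <- function(tab) {
  tab <- as.matrix(tab)
  rates <- tab[, 1L] / rowSums(tab)
  p_all <- sum(tab[, 1L]) / sum(tab)
  if (p_all == 0) return(0)
  p_noncarrier <- min(rates)
  max(min((p_all - p_noncarrier) / p_all, 1), 0)
}

#' Sex-stratified methylation QTL linear models
#'
#' For each (locus, island) pair and each sex separately, ordinary least
#' squares of island methylation on genotype dosage (0/1/2), BH-corrected
#' within sex across tested pairs. Per-allele medians are over the two
#' homozygote classes, and `spans_status_change` flags pairs whose two
#' homozygote medians fall one in the escape band and one in the subject
#' band.
#'
#' @param dname Island x sample methylation matrix (or tibble `island_id`,
#'   `sample_id`, `value`).
#' @param genotypes Locus x sample dosage matrix.
#' @param sex Named vector sample_id -> female/male.
#' @param pairs Tibble `locus_id`, `island_id` of pairs to test (default:
#'   all combinations).
#' @param alpha Adjusted significance level (0.01).
#' @param min_n Minimum samples per sex (10).
#' @param cfg A [dname_call_config()] for the status bands.
#' @return Tibble per pair per sex: `locus_id`, `island_id`, `sex`, `slope`,
#'   `intercept`, `p_raw`, `p_adj`, `significant`, `median_ref`,
#'   `median_alt`, `spans_status_change`, `n`.
#' @export
dname_qtl <- function(dname, genotypes, sex, pairs = NULL, alpha = 0.01,
                      min_n = 10L, cfg = dname_call_config()) {
  if (!is.matrix(dname)) {
    dname <- tapply(dname$value, list(dname$island_id, dname$sample_id),
                    mean)
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(locus_id = rownames(genotypes),
                         island_id = rownames(dname),
                         stringsAsFactors = FALSE)
  }
  samples <- intersect(colnames(dname), colnames(genotypes))
  sex <- sex[samples]
  rows <- list(); k <- 0L
  for (sx in c("female", "male")) {
    sm <- samples[sex == sx]
    for (i in seq_len(nrow(pairs))) {
      l <- pairs$locus_id[i]; is <- pairs$island_id[i]
      y <- dname[is, sm]; g <- genotypes[l, sm]
      keep <- !is.na(y) & !is.na(g)
      if (sum(keep) < min_n || stats::sd(g[keep]) == 0) next
      fit <- stats::lm(y[keep] ~ g[keep])
      cf <- summary(fit)$coefficients
      p <- if (nrow(cf) < 2L) NA_real_ else cf[2L, 4L]
      med_ref <- stats::median(y[keep & g == 0L], na.rm = TRUE)
      med_alt <- stats::median(y[keep & g == 2L], na.rm = TRUE)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        locus_id = l, island_id = is, sex = sx,
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        p_raw = p, median_ref = med_ref, median_alt = med_alt,
        n = sum(keep)
      )
    }
  }
  if (!k) {
    return(tibble::tibble(locus_id = character(), island_id = character(),
                          sex = character(), slope = numeric(),
                          intercept = numeric(), p_raw = numeric(),
                          median_ref = numeric(), median_alt = numeric(),
                          n = integer(), p_adj = numeric(),
                          significant = logical(),
                          spans_status_change = logical()))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(dplyr::group_by(out, .data$sex),
                       p_adj = stats::p.adjust(.data$p_raw, "BH"))
  out <- dplyr::ungroup(out)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$spans_status_change <- status_span(out$median_ref, out$median_alt,
                                         cfg)
  out
}

#' Does a QTL span an XCI status change?
#'
#' TRUE when one homozygote-class median lies in the escape band
#' `[0, escape_max)` and the other strictly inside the subject band
#' `(subject_min, subject_max)`.
#'
#' @param median_ref,median_alt Per-allele methylation medians.
#' @param cfg A [dname_call_config()].
#' @return Logical vector.
#' @export
status_span <- function(median_ref, median_alt,
                        cfg = dname_call_config()) {
  esc <- function(x) !is.na(x) & x < cfg$escape_max
  sub <- function(x) !is.na(x) & x > cfg$subject_min & x < cfg$subject_max
  (esc(median_ref) & sub(median_alt)) | (esc(median_alt) & sub(median_ref))
}
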