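# XCI status calls from Xi/Xa allelic read counts: Wald binomial confidence
# interval on the Xi read proportion against the 10% Xi/Xa ratio threshold,
# skew filtering, and the expression-based variable-escape rule.

#' Configuration for the allelic-expression caller
#'
#' @param z Normal quantile for the confidence interval (1.96 = 95% CI).
#' @param ratio_threshold Xi/Xa expression ratio separating escape from
#'   subject (0.10). Internally converted to the proportion scale
#'   `p* = ratio/(1+ratio)`.
#' @param min_total_reads Minimum informative depth per gene per sample.
#' @return An `allelic_call_config` list.
#' @export
allelic_call_config <- function(z = 1.96, ratio_threshold = 0.10,
                                min_total_reads = 10L) {
  stopifnot(z > 0, ratio_threshold > 0, ratio_threshold < 1)
  structure(list(z = z, ratio_threshold = ratio_threshold,
                 min_total_reads = as.integer(min_total_reads)),
            class = "allelic_call_config")
}

#' Wald binomial confidence interval on the Xi read proportion
#'
#' `p_hat = xi/(xi+xa)` with half-width `z * sqrt(p_hat (1-p_hat)/(xi+xa))`,
#' bounds clipped to `[0, 1]`. At `p_hat` of 0 or 1 the Wald half-width is
#' zero by construction. Vectorized.
#'
#' @param xi,xa Non-negative read counts per allele (Xi, Xa).
#' @param z Normal quantile (default 1.96).
#' @return Tibble with `p_hat`, `lower`, `upper`.
#' @export
wald_interval <- function(xi, xa, z = 1.96) {
  n <- xi + xa
  stopifnot(all(n >= 1), all(xi >= 0), all(xa >= 0))
  p <- xi / n
  hw <- z * sqrt(p * (1 - p) / n)
  tibble::tibble(p_hat = p, lower = pmax(p - hw, 0), upper = pmin(p + hw, 1))
}

#' Call XCI status from allelic read counts
#'
#' A gene escapes in a sample when the whole 95% CI on the Xi proportion
#' lies above `p* = ratio/(1+ratio)`, is subject when the CI lies below, and
#' is uninformative when the CI straddles the threshold or depth is below
#' `min_total_reads`.
#'
#' @param counts Tibble with `gene_id`, `sample_id`, `xi_reads`, `xa_reads`.
#' @param cfg An [allelic_call_config()].
#' @return Call table (`id` = gene, `sample_id`, `status`, `method`,
#'   `detail` records the CI or the uninformative reason).
#' @export
call_from_allelic <- function(counts, cfg = allelic_call_config()) {
  n <- counts$xi_reads + counts$xa_reads
  p_star <- cfg$ratio_threshold / (1 + cfg$ratio_threshold)
  status <- rep("uninformative", nrow(counts))
  detail <- rep("depth", nrow(counts))
  ok <- n >= cfg$min_total_reads & n > 0
  ci <- wald_interval(pmax(counts$xi_reads, 0)[ok],
                      pmax(counts$xa_reads, 0)[ok], cfg$z)
  st <- rep("uninformative", sum(ok))
  st[ci$lower > p_star] <- "escape"
  st[ci$upper < p_star] <- "subject"
  status[ok] <- st
  detail[ok] <- sprintf("p=%.4f CI[%.4f,%.4f]", ci$p_hat, ci$lower, ci$upper)
  tibble::tibble(id = counts$gene_id, sample_id = counts$sample_id,
                 status = status, method = "allelic_expression",
                 detail = detail)
}

#' Orient allelic counts by inferring each sample's inactive haplotype
#'
#' At genes with a meta-status of subject to XCI the silenced (minor) allele
#' marks the inactive X. The haplotype silenced at the majority of
#' informative meta-subject genes is labeled Xi; exact ties leave the sample
#' unoriented (NA).
#'
#' @param counts Tibble with `gene_id`, `sample_id`, `allele_a`, `allele_b`.
#' @param meta_status Named character vector gene_id -> meta status.
#' @param min_total Minimum reads for a gene to vote.
#' @return Tibble `sample_id`, `xi_haplotype` ("A"/"B"/NA), `n_votes_a`,
#'   `n_votes_b`.
#' @export
infer_xi_haplotype <- function(counts, meta_status, min_total = 10L) {
  sub_genes <- names(meta_status)[meta_status == "subject"]
  d <- counts[counts$gene_id %in% sub_genes &
                counts$allele_a + counts$allele_b >= min_total &
                counts$allele_a != counts$allele_b, ]
  votes <- dplyr::summarise(
    dplyr::group_by(d, .data$sample_id),
    n_votes_a = sum(.data$allele_a < .data$allele_b),
    n_votes_b = sum(.data$allele_b < .data$allele_a),
    .groups = "drop"
  )
  votes$xi_haplotype <- ifelse(votes$n_votes_a > votes$n_votes_b, "A",
                               ifelse(votes$n_votes_b > votes$n_votes_a,
                                      "B", NA_character_))
  votes[, c("sample_id", "xi_haplotype", "n_votes_a", "n_votes_b")]
}

#' Orient allele counts into Xi/Xa counts
#'
#' Assigns each sample's inferred inactive haplotype's reads to `xi_reads`.
#' Unoriented samples (no haplotype call) are dropped.
#'
#' @param counts Tibble with `gene_id`, `sample_id`, `allele_a`,
#'   `allele_b`.
#' @param haplotypes From [infer_xi_haplotype()].
#' @return `counts` with `xi_reads`/`xa_reads` set from the orientation.
#' @export
orient_counts <- function(counts, haplotypes) {
  hap <- stats::setNames(haplotypes$xi_haplotype, haplotypes$sample_id)
  h <- unname(hap[counts$sample_id])
  out <- counts[!is.na(h), c("gene_id", "sample_id", "allele_a",
                             "allele_b")]
  h <- h[!is.na(h)]
  out$xi_reads <- ifelse(h == "A", out$allele_a, out$allele_b)
  out$xa_reads <- ifelse(h == "A", out$allele_b, out$allele_a)
  out
}

#' Drop samples without skewed XCI
#'
#' A sample is removed when more than `max_escape_frac` of its informative
#' meta-subject genes are called escaping (the signature of unskewed Xi
#' choice, where allelic balance mimics escape). Exactly at the threshold is
#' retained ("more than" is strict).
#'
#' @param calls Per-sample call table from [call_from_allelic()].
#' @param meta_status Named character vector gene_id -> meta status.
#' @param max_escape_frac Threshold fraction (default 0.25).
#' @return Tibble `sample_id`, `escape_frac`, `n_informative`, `retained`.
#' @export
filter_unskewed <- function(calls, meta_status, max_escape_frac = 0.25) {
  d <- calls[calls$id %in% names(meta_status)[meta_status == "subject"] &
               calls$status %in% c("escape", "subject"), ]
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$sample_id),
    escape_frac = mean(.data$status == "escape"),
    n_informative = dplyr::n(), .groups = "drop"
  )
  all_samples <- unique(calls$sample_id)
  missing <- setdiff(all_samples, out$sample_id)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      sample_id = missing, escape_frac = NA_real_, n_informative = 0L))
  }
  out$retained <- !is.na(out$escape_frac) &
    out$escape_frac <= max_escape_frac
  out[match(all_samples, out$sample_id), ]
}

#' Expression-based variable-escape classification per gene
#'
#' A gene is variably escaping when at least `min_each` samples escape and
#' at least `min_each` are subject; otherwise it takes the constitutive
#' status when all informative samples agree on one side after the minority
#' (fewer than `min_each` samples) is discounted; genes with fewer than
#' `min_each` informative samples are uninformative.
#'
#' @param calls Per-sample call table (columns `id`, `sample_id`, `status`).
#' @param min_each Minimum samples per status for a variable call (2).
#' @return One overall call per gene.
#' @export
variable_by_expression <- function(calls, min_each = 2L) {
  d <- calls[calls$status %in% c("escape", "subject"), ]
  per_gene <- dplyr::summarise(
    dplyr::group_by(d, .data$id),
    n_escape = sum(.data$status == "escape"),
    n_subject = sum(.data$status == "subject"), .groups = "drop"
  )
  all_genes <- unique(calls$id)
  per_gene <- per_gene[match(all_genes, per_gene$id), ]
  per_gene$id <- all_genes
  per_gene$n_escape[is.na(per_gene$n_escape)] <- 0L
  per_gene$n_subject[is.na(per_gene$n_subject)] <- 0L
  n_inf <- per_gene$n_escape + per_gene$n_subject
  status <- ifelse(
    per_gene$n_escape >= min_each & per_gene$n_subject >= min_each,
    "variable",
    ifelse(n_inf < min_each, "uninformative",
           ifelse(per_gene$n_escape > per_gene$n_subject,
                  "escape", "subject"))
  )
  tibble::tibble(id = per_gene$id, sample_id = "overall", status = status,
                 method = "allelic_expression",
                 detail = sprintf("nE=%d nS=%d", per_gene$n_escape,
                                  per_gene$n_subject))
}
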