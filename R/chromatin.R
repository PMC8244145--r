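# Normalized chromatin-mark quantification over promoters / exon bodies /
# enhancers, the female-vs-male (Xi:Xa) fold change, group-comparison
# statistics, and strand-aware metagene profiles.

#' Depth-normalization scale factors
#'
#' Samples are scaled to the same total signal (the maximum sample total),
#' the multiplicative analogue of sequencing-depth normalization.
#'
#' @param totals Named numeric vector of per-sample signal totals.
#' @return Named vector of scale factors (`max(totals)/totals`).
#' @export
normalize_depth <- function(totals) {
  if (any(totals <= 0)) stop("zero or negative sample total")
  max(totals) / totals
}

#' Length-weighted mean signal over a region set
#'
#' Promoter and enhancer regions are quantified directly; `exon_body`
#' regions aggregate all of a transcript's exons length-weighted.
#'
#' @param track A `signal_track` ([read_signal()]).
#' @param regions Region tibble (`chrom`, `start`, `end`, `linked_id`,
#'   `kind`).
#' @return Tibble `linked_id`, `value` (NA where the region is uncovered).
#' @export
quantify_regions <- function(track, regions) {
  if (all(regions$kind != "exon_body")) {
    v <- signal_mean(track, regions$chrom, regions$start, regions$end)
    return(tibble::tibble(linked_id = regions$linked_id, value = v))
  }
  # aggregate per linked_id, length-weighted across intervals
  sp <- split(regions, regions$linked_id)
  out <- lapply(names(sp), function(id) {
    r <- sp[[id]]
    v <- signal_mean(track, r$chrom, r$start, r$end, min_covered = 0.5)
    w <- (r$end - r$start)[!is.na(v)]
    vv <- v[!is.na(v)]
    tibble::tibble(linked_id = id,
                   value = if (!length(vv)) NA_real_ else
                     sum(vv * w) / sum(w))
  })
  dplyr::bind_rows(out)
}

#' Exon regions for gene-body marks
#'
#' @param genes Gene-model tibble.
#' @return Region tibble of kind `exon_body`, one row per exon, linked to
#'   the transcript.
#' @export
exon_regions <- function(genes) {
  dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    tibble::tibble(chrom = genes$chrom[i], start = ex[, 1L], end = ex[, 2L],
                   strand = genes$strand[i],
                   linked_id = genes$transcript_id[i], kind = "exon_body",
                   clipped = FALSE)
  }))
}

#' Female-vs-male (Xi:Xa) fold change
#'
#' `(female - male)/male`: the male value proxies the Xa contribution and
#' the female-male difference the Xi contribution, so a ratio of 1 means the
#' Xi carries as much signal as the Xa, and 0 means the Xi carries none.
#' The log2 ratio is defined only for `female > male`; other rows keep the
#' linear value with `log2_xi_xa` NA and a `negative_delta` flag.
#'
#' @param female,male Numeric vectors of paired normalized signal (male
#'   typically a group mean).
#' @param region_id Optional region/transcript identifiers.
#' @return Tibble `region_id`, `female_value`, `male_value`, `xi_xa`,
#'   `log2_xi_xa`, `negative_delta`.
#' @export
xi_xa_fold_change <- function(female, male, region_id = NULL) {
  xi_xa <- ifelse(male > 0, (female - male) / male, NA_real_)
  l2 <- rep(NA_real_, length(xi_xa))
  pos <- !is.na(xi_xa) & xi_xa > 0
  l2[pos] <- log2(xi_xa[pos])
  tibble::tibble(
    region_id = region_id %||% seq_along(female),
    female_value = female, male_value = male, xi_xa = xi_xa,
    log2_xi_xa = l2,
    negative_delta = !is.na(xi_xa) & xi_xa < 0
  )
}

#' Per-feature two-group comparison with BH correction
#'
#' Welch two-sample t-test per feature; Benjamini-Hochberg adjustment within
#' the supplied family. The uncorrected 0.05 mode serves the small
#' expression-based variable-gene analysis.
#'
#' @param values Feature x sample numeric matrix.
#' @param groups Character/factor vector over columns (exactly 2 levels
#'   used).
#' @param alpha Significance level (default 0.01).
#' @param correct `"BH"` or `"none"`.
#' @return Tibble `feature`, `mean_diff` (group1 - group2 in level order),
#'   `p_raw`, `p_adj`, `significant`, `skipped` (groups with < 2 values).
#' @export
group_compare <- function(values, groups, alpha = 0.01, correct = "BH") {
  lv <- unique(as.character(groups))
  stopifnot(length(lv) == 2L)
  g1 <- values[, groups == lv[1L], drop = FALSE]
  g2 <- values[, groups == lv[2L], drop = FALSE]
  res <- lapply(seq_len(nrow(values)), function(i) {
    x <- g1[i, ][!is.na(g1[i, ])]
    y <- g2[i, ][!is.na(g2[i, ])]
    if (length(x) < 2L || length(y) < 2L) {
      return(c(NA_real_, NA_real_, 1))
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(c(mean(x) - mean(y),
               if (mean(x) == mean(y)) 1 else 0, 0))
    }
    tt <- stats::t.test(x, y)
    c(mean(x) - mean(y), tt$p.value, 0)
  })
  m <- do.call(rbind, res)
  p_adj <- if (correct == "BH") stats::p.adjust(m[, 2L], "BH") else m[, 2L]
  tibble::tibble(
    feature = rownames(values) %||% as.character(seq_len(nrow(values))),
    mean_diff = m[, 1L], p_raw = m[, 2L], p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha,
    skipped = m[, 3L] == 1
  )
}

#' Fraction of significant transcripts per XCI meta-status
#'
#' @param tests Output of [group_compare()] with a `feature` column of
#'   transcript ids.
#' @param meta_status Named vector transcript id -> status.
#' @return Tibble `meta_status`, `n_significant`, `n_informative`,
#'   `fraction`.
#' @export
sex_significance_fraction <- function(tests, meta_status) {
  d <- tests[!tests$skipped, ]
  d$meta_status <- unname(meta_status[d$feature])
  dplyr::summarise(
    dplyr::group_by(d, .data$meta_status),
    n_significant = sum(.data$significant),
    n_informative = dplyr::n(),
    fraction = mean(.data$significant), .groups = "drop"
  )
}

#' Strand-aware metagene profile
#'
#' Gene bodies are length-scaled to `body_bins` bins; the up/downstream
#' flanks are binned at fixed width over `flank` bases; minus-strand genes
#' are flipped so the profile reads 5' to 3'. Returns the mean and SD across
#' genes per bin.
#'
#' @param track A `signal_track`.
#' @param genes Gene-model tibble.
#' @param flank Flank size in bases (50000).
#' @param body_bins,flank_bins Bin counts (100 and 50).
#' @return Tibble `bin` (1..flank_bins+body_bins+flank_bins), `zone`
#'   (upstream/body/downstream), `mean`, `sd`, `n`.
#' @export
metagene_profile <- function(track, genes, flank = 50000L,
                             body_bins = 100L, flank_bins = 50L) {
  profile_one <- function(i) {
    g <- genes[i, ]
    up <- seq(g$start - flank, g$start, length.out = flank_bins + 1L)
    body <- seq(g$start, g$end, length.out = body_bins + 1L)
    down <- seq(g$end, g$end + flank, length.out = flank_bins + 1L)
    edges <- c(up[-length(up)], body[-length(body)], down)
    starts <- floor(edges[-length(edges)])
    ends <- ceiling(edges[-1L])
    v <- signal_mean(track, g$chrom, pmax(starts, 0), pmax(ends, 1),
                     min_covered = 1e-9)
    if (g$strand == "-") v <- rev(v)
    v
  }
  mat <- t(vapply(seq_len(nrow(genes)), profile_one,
                  numeric(2L * flank_bins + body_bins)))
  nb <- ncol(mat)
  tibble::tibble(
    bin = seq_len(nb),
    zone = rep(c("upstream", "body", "downstream"),
               c(flank_bins, body_bins, flank_bins)),
    mean = colMeans(mat, na.rm = TRUE),
    sd = apply(mat, 2L, stats::sd, na.rm = TRUE),
    n = colSums(!is.na(mat))
  )
}

#' Pearson chi-square enrichment test on a 2x2 table
#'
#' No continuity correction; intended for testing enrichment of significant
#' mark differences among variably escaping genes, BH-corrected across marks
#' by the caller via [stats::p.adjust()].
#'
#' @param tab 2x2 contingency matrix.
#' @return List `chi2`, `p`.
#' @export
enrichment_chi2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  if (any(e == 0)) return(list(chi2 = NA_real_, p = NA_real_))
  chi2 <- sum((tab - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}
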