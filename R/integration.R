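# Cross-method reconciliation: concordance between call sets,
# variable-escape typing (across the dataset, across tissues, between TSSs,
# within a tissue), differential-mark testing at variable genes, and the
# summary tables.

#' Concordance between two call sets
#'
#' Statuses are collapsed to escape / subject / variable; leaning and
#' uninformative calls leave the denominator. Agreement is computed over
#' genes called constitutively (escape or subject) by both methods.
#'
#' @param a,b Overall call tables (`id`, `status`).
#' @return List: `table` (cross-tabulation over shared informative genes),
#'   `agreement` (fraction agreeing among genes constitutive in both; NA
#'   when the denominator is empty).
#' @export
concordance <- function(a, b) {
  collapse <- function(s) {
    out <- rep(NA_character_, length(s))
    out[s %in% c("escape", "subject", "variable")] <-
      s[s %in% c("escape", "subject", "variable")]
    out
  }
  am <- stats::setNames(collapse(a$status), a$id)
  bm <- stats::setNames(collapse(b$status), b$id)
  shared <- intersect(names(am)[!is.na(am)], names(bm)[!is.na(bm)])
  tab <- table(a = am[shared], b = bm[shared])
  both_const <- shared[am[shared] %in% c("escape", "subject") &
                         bm[shared] %in% c("escape", "subject")]
  agreement <- if (length(both_const)) {
    mean(am[both_const] == bm[both_const])
  } else NA_real_
  list(table = tab, agreement = agreement)
}

#' Classify the type(s) of variable escape per gene
#'
#' Tags (a gene may carry several): `across_dataset` (variable under the
#' fraction rule over all samples); `across_tissues` (constitutive per-
#' tissue consensus statuses that differ between at least two tissues);
#' `between_TSSs` (two transcripts of the gene with opposite constitutive
#' consensus); `within_tissue:<t>` (variable under the fraction rule
#' restricted to one tissue's samples). Per-tissue consensus reuses the
#' aggregation rule and requires at least 2 informative samples.
#'
#' @param calls Per-sample transcript calls: `id` (transcript), `gene_id`,
#'   `sample_id`, `status`, `tissue`.
#' @param cfg A [predictor_config()] (aggregation fractions).
#' @return Tibble `gene_id`, `tags` (list-column), plus logical columns
#'   `across_dataset`, `across_tissues`, `between_tss`, `within_tissue`.
#' @export
classify_variable_type <- function(calls, cfg = predictor_config()) {
  is_variable <- function(st) {
    n <- length(st)
    n >= 2L && sum(st == "escape") / n >= cfg$agg_variable_frac &&
      sum(st == "subject") / n >= cfg$agg_variable_frac
  }
  genes <- unique(calls$gene_id)
  out <- lapply(genes, function(g) {
    d <- calls[calls$gene_id == g, ]
    tags <- character()
    gene_status <- d$status        # across transcripts and samples
    if (is_variable(gene_status)) tags <- c(tags, "across_dataset")
    # per-tissue consensus (constitutive only)
    tis <- split(d$status, d$tissue)
    cons <- vapply(tis, function(st) {
      if (length(st) < 2L) return(NA_character_)
      aggregate_samples(st, cfg)
    }, "")
    const <- cons[cons %in% c("escape", "subject") & !is.na(cons)]
    if (length(unique(const)) >= 2L) tags <- c(tags, "across_tissues")
    for (t in names(tis)) {
      if (is_variable(tis[[t]])) tags <- c(tags, paste0("within_tissue:", t))
    }
    # between TSSs: per-transcript consensus over samples
    txc <- vapply(split(d$status, d$id), aggregate_samples, "", cfg = cfg)
    txc <- txc[txc %in% c("escape", "subject")]
    if (length(unique(txc)) >= 2L) tags <- c(tags, "between_TSSs")
    tag_set <- tags
    tibble::tibble(
      gene_id = g, tags = list(tag_set),
      across_dataset = "across_dataset" %in% tag_set,
      across_tissues = "across_tissues" %in% tag_set,
      between_tss = "between_TSSs" %in% tag_set,
      within_tissue = any(startsWith(tag_set, "within_tissue:"))
    )
  })
  dplyr::bind_rows(out)
}

#' Differential-mark test at variable genes
#'
#' Per gene and mark, a Welch t-test between the samples escaping and the
#' samples subject to XCI. The corrected mode (BH within each mark family,
#' alpha 0.01) serves the DNAme/predictor-based analyses; the uncorrected
#' alpha 0.05 mode serves the small expression-based analysis.
#'
#' @param marks Long tibble `gene_id`, `sample_id`, `mark`, `value`.
#' @param calls Per-sample calls (`id` = gene, `sample_id`, `status`).
#' @param mode `"corrected_0.01"` or `"uncorrected_0.05"`.
#' @return Tibble `gene_id`, `mark`, `mean_diff` (escape minus subject),
#'   `p_raw`, `p_adj`, `significant`, `n_escape`, `n_subject`.
#' @export
variable_gene_mark_test <- function(marks, calls,
                                    mode = c("corrected_0.01",
                                             "uncorrected_0.05")) {
  mode <- match.arg(mode)
  alpha <- if (mode == "corrected_0.01") 0.01 else 0.05
  st <- stats::setNames(calls$status, paste(calls$id, calls$sample_id))
  d <- marks
  d$status <- unname(st[paste(d$gene_id, d$sample_id)])
  d <- d[d$status %in% c("escape", "subject") & !is.na(d$value), ]
  res <- dplyr::summarise(
    dplyr::group_by(d, .data$gene_id, .data$mark),
    n_escape = sum(.data$status == "escape"),
    n_subject = sum(.data$status == "subject"),
    mean_diff = mean(.data$value[.data$status == "escape"]) -
      mean(.data$value[.data$status == "subject"]),
    p_raw = tryCatch(
      stats::t.test(.data$value[.data$status == "escape"],
                    .data$value[.data$status == "subject"])$p.value,
      error = function(e) NA_real_),
    .groups = "drop"
  )
  res <- res[res$n_escape >= 2L & res$n_subject >= 2L, ]
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$mark),
    p_adj = if (mode == "corrected_0.01") stats::p.adjust(.data$p_raw, "BH")
    else .data$p_raw
  )
  res <- dplyr::ungroup(res)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res[, c("gene_id", "mark", "mean_diff", "p_raw", "p_adj", "significant",
          "n_escape", "n_subject")]
}

#' Percent-significant summary by variable-escape category and mark
#'
#' Rows are variable-escape categories, columns marks; a cell is the
#' fraction of that category's genes significant for the mark (genes
#' lacking the mark's data leave the denominator).
#'
#' @param types From [classify_variable_type()].
#' @param tests From [variable_gene_mark_test()].
#' @return Tibble `category`, `mark`, `n_genes`, `n_significant`,
#'   `fraction`.
#' @export
summary_tables <- function(types, tests) {
  cats <- list(
    across_dataset = types$gene_id[types$across_dataset],
    across_tissues = types$gene_id[types$across_tissues],
    between_TSSs = types$gene_id[types$between_tss],
    within_tissue = types$gene_id[types$within_tissue]
  )
  out <- lapply(names(cats), function(cat) {
    g <- cats[[cat]]
    d <- tests[tests$gene_id %in% g, ]
    if (!nrow(d)) {
      return(tibble::tibble(category = cat, mark = character(),
                            n_genes = integer(), n_significant = integer(),
                            fraction = numeric()))
    }
    s <- dplyr::summarise(
      dplyr::group_by(d, .data$mark),
      n_genes = dplyr::n_distinct(.data$gene_id),
      n_significant = dplyr::n_distinct(.data$gene_id[.data$significant]),
      .groups = "drop"
    )
    s$category <- cat
    s$fraction <- s$n_significant / s$n_genes
    s[, c("category", "mark", "n_genes", "n_significant", "fraction")]
  })
  dplyr::bind_rows(out)
}
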