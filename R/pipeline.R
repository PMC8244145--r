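# End-to-end orchestration: a seeded synthetic run from simulation through
# association, each stage writing tidy TSV artifacts plus a manifest, and
# reruns with the same config/seed being bit-identical.

.pipeline_stages <- c("simulate", "call_expression", "call_dname",
                      "predict", "integrate", "associate")

read_tsv_ <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

write_tsv_ <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the synthetic XCI analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (generate and write
#' the dataset), `call_expression` (allelic binomial calls + skew filter +
#' expression-based variable classification), `call_dname` (bulk DNAme
#' calls and DNAme-based variable classification), `predict` (k-means
#' pairing, per-sample ensembles, vote calls, aggregation, importance),
#' `integrate` (method concordance, variable-escape typing,
#' differential-mark tests), `associate` (genotype chi-square association
#' with attributable risk, sex-stratified methylation QTLs). Earlier-stage
#' artifacts are loaded from `outdir` when a stage is re-run in isolation;
#' a missing prerequisite is an error naming the stage to run first.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory.
#' @param stages Subset of stages (default all, in order).
#' @param depth Mean allelic depth per gene.
#' @param pred_cfg A [predictor_config()] (seed defaults to `cfg$seed`).
#' @return Invisibly, a manifest tibble (`stage`, `file`).
#' @export
run_xci_pipeline <- function(cfg = sim_config(), outdir,
                             stages = .pipeline_stages, depth = 500,
                             pred_cfg = predictor_config(seed = cfg$seed)) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(stage = stage,
                                                         file = file)
  }
  env <- new.env(parent = emptyenv())

  # The dataset is rebuilt in memory from the seeded config (deterministic);
  # the simulate stage additionally writes it out.
  env$dataset <- simulate_xci_dataset(cfg, depth = depth)
  truth <- env$dataset$truth
  meta <- stats::setNames(truth$genes$meta_status, truth$genes$gene_id)
  meta_tx <- stats::setNames(truth$genes$meta_status,
                             truth$genes$transcript_id)

  if ("simulate" %in% stages) {
    dir <- file.path(outdir, "simulate")
    write_xci_dataset(env$dataset, dir)
    st <- as.data.frame(truth$status)
    st <- cbind(gene_id = rownames(truth$status), st)
    add("simulate", write_tsv_(st, file.path(dir, "truth_status.tsv")))
    for (f in c("genes.bed", "samples.tsv", "allelic_counts.tsv",
                "methyl_reads.tsv", "marks.tsv", "genotypes.vcf")) {
      add("simulate", file.path(dir, f))
    }
  }

  if ("call_expression" %in% stages) {
    dir <- file.path(outdir, "expression")
    dir.create(dir, showWarnings = FALSE)
    hap <- infer_xi_haplotype(env$dataset$counts, meta)
    oriented <- orient_counts(env$dataset$counts, hap)
    calls <- call_from_allelic(oriented)
    skew <- filter_unskewed(calls, meta)
    kept <- skew$sample_id[skew$retained]
    overall <- variable_by_expression(calls[calls$sample_id %in% kept, ])
    env$expr_calls <- calls; env$expr_overall <- overall
    env$retained_samples <- kept
    add("call_expression",
        write_tsv_(calls, file.path(dir, "calls_per_sample.tsv")))
    add("call_expression",
        write_tsv_(skew, file.path(dir, "skew_filter.tsv")))
    add("call_expression",
        write_tsv_(overall, file.path(dir, "calls_overall.tsv")))
  }

  if (any(c("call_dname", "predict", "integrate", "associate") %in%
          stages)) {
    marks <- env$dataset$marks$marks
    dname <- marks[marks$mark == "DNAme", ]
    males <- truth$samples$sample_id[truth$samples$sex == "male"]
    male_mean <- tapply(dname$value[dname$sample_id %in% males],
                        dname$transcript_id[dname$sample_id %in% males],
                        mean)
    env$dname <- dname; env$male_mean <- male_mean
  }

  if ("call_dname" %in% stages) {
    dir <- file.path(outdir, "dname")
    dir.create(dir, showWarnings = FALSE)
    fem <- env$dname[env$dname$sex == "female", ]
    calls <- tibble::tibble(
      id = fem$transcript_id, gene_id = fem$gene_id,
      sample_id = fem$sample_id,
      status = call_from_dname(fem$value,
                               unname(env$male_mean[fem$transcript_id])),
      method = "dname", detail = sprintf("f=%.3f", fem$value)
    )
    ve <- dname_variable_escape(calls)
    env$dname_calls <- calls
    env$dname_overall <- ve
    add("call_dname",
        write_tsv_(calls, file.path(dir, "calls_per_sample.tsv")))
    add("call_dname",
        write_tsv_(ve$transcript, file.path(dir, "calls_transcript.tsv")))
    add("call_dname",
        write_tsv_(ve$gene, file.path(dir, "calls_gene.tsv")))
  }

  if ("predict" %in% stages) {
    dir <- file.path(outdir, "predictor")
    dir.create(dir, showWarnings = FALSE)
    sexv <- stats::setNames(truth$samples$sex, truth$samples$sample_id)
    pairing <- pair_female_male(env$dataset$marks$autosomal, sexv,
                                k = pred_cfg$k_clusters,
                                seed = pred_cfg$seed)
    marks <- env$dataset$marks$marks
    per_sample <- list(); ens_list <- list()
    for (i in seq_len(nrow(pairing))) {
      fid <- pairing$sample_id[i]
      fv <- build_features(marks, fid, pairing$males[[i]])
      ens <- train_ensemble(fv$features, meta_tx,
                            predictor_config(seed = pred_cfg$seed + i,
                                             n_models = pred_cfg$n_models,
                                             n_trees = pred_cfg$n_trees,
                                             tune_points =
                                               pred_cfg$tune_points))
      pr <- predict_ensemble(ens, fv$features)
      pr$sample_id <- fid
      per_sample[[fid]] <- pr
      ens_list[[fid]] <- ens
    }
    calls <- dplyr::bind_rows(per_sample)
    agg <- aggregate_call_table(
      tibble::tibble(id = calls$transcript_id,
                     sample_id = calls$sample_id, status = calls$status),
      pred_cfg)
    imp <- feature_importance_ranks(ens_list)
    env$pred_calls <- calls; env$pred_overall <- agg
    add("predict",
        write_tsv_(calls, file.path(dir, "votes_per_sample.tsv")))
    add("predict", write_tsv_(agg, file.path(dir, "calls_overall.tsv")))
    add("predict",
        write_tsv_(imp, file.path(dir, "importance_ranks.tsv")))
  }

  if ("integrate" %in% stages) {
    dir <- file.path(outdir, "integrate")
    dir.create(dir, showWarnings = FALSE)
    if (is.null(env$dname_calls) || is.null(env$pred_overall)) {
      stop("'integrate' requires 'call_dname' and 'predict': ",
           "run those stages first")
    }
    tx2gene <- stats::setNames(truth$genes$gene_id,
                               truth$genes$transcript_id)
    pred_gene <- tibble::tibble(id = unname(tx2gene[env$pred_overall$id]),
                                status = env$pred_overall$status)
    conc <- concordance(env$dname_overall$gene[, c("gene_id", "status")] |>
                          stats::setNames(c("id", "status")), pred_gene)
    tissue <- stats::setNames(truth$samples$tissue,
                              truth$samples$sample_id)
    dn <- env$dname_calls
    types <- classify_variable_type(tibble::tibble(
      id = dn$id, gene_id = dn$gene_id, sample_id = dn$sample_id,
      status = dn$status, tissue = unname(tissue[dn$sample_id])
    ))
    marks <- env$dataset$marks$marks
    tests <- variable_gene_mark_test(
      marks[, c("gene_id", "sample_id", "mark", "value")],
      tibble::tibble(id = dn$gene_id, sample_id = dn$sample_id,
                     status = dn$status),
      mode = "corrected_0.01")
    tab <- summary_tables(types, tests)
    env$types <- types
    add("integrate", write_tsv_(
      tibble::tibble(agreement = conc$agreement),
      file.path(dir, "concordance.tsv")))
    add("integrate", write_tsv_(
      types[, c("gene_id", "across_dataset", "across_tissues",
                "between_tss", "within_tissue")],
      file.path(dir, "variable_types.tsv")))
    add("integrate", write_tsv_(tab, file.path(dir, "summary_table.tsv")))
  }

  if ("associate" %in% stages) {
    dir <- file.path(outdir, "associate")
    dir.create(dir, showWarnings = FALSE)
    if (is.null(env$dname_calls)) {
      stop("'associate' requires 'call_dname': run that stage first")
    }
    gt <- env$dataset$genotypes
    dn <- env$dname_calls
    status_m <- tapply(dn$status, list(dn$gene_id, dn$sample_id), `[`, 1L)
    var_genes <- truth$genes$gene_id[truth$genes$meta_status == "variable"]
    assoc <- xci_genotype_test(status_m, gt$genotypes, loci = gt$loci,
                               genes = intersect(var_genes,
                                                 rownames(status_m)),
                               min_per_class = 2L)
    sexv <- stats::setNames(truth$samples$sex, truth$samples$sample_id)
    dname_m <- tapply(env$dname$value,
                      list(env$dname$gene_id, env$dname$sample_id), mean)
    pairs <- expand.grid(locus_id = rownames(gt$genotypes),
                         island_id = intersect(var_genes,
                                               rownames(dname_m)),
                         stringsAsFactors = FALSE)
    qtl <- dname_qtl(dname_m, gt$genotypes, sexv, pairs = pairs,
                     min_n = 4L)
    add("associate", write_tsv_(assoc, file.path(dir, "association.tsv")))
    add("associate", write_tsv_(qtl, file.path(dir, "dname_qtl.tsv")))
  }

  man <- dplyr::bind_rows(manifest)
  writeLines(c(paste0("seed: ", cfg$seed),
               paste0("n_genes: ", cfg$n_genes),
               paste0("stages: ", paste(stages, collapse = ","))),
             file.path(outdir, "run_config.txt"))
  write_tsv_(man, file.path(outdir, "manifest.tsv"))
  invisible(man)
}
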