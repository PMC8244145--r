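# Readers and writers for the external formats used throughout the package.
# All coordinates are 0-based half-open internally (BED convention); GTF
# input (1-based closed) is converted on read.

#' Read gene/transcript models from BED12 or GTF
#'
#' Each record becomes one transcript-level annotation with a strand-aware
#' TSS: the interval start on the plus strand, `end - 1` on the minus strand
#' (0-based half-open coordinates). BED12 block fields give the exons; for
#' GTF, `exon` features are grouped under their `transcript_id`.
#'
#' @param path Path to a BED12 or GTF file. The dialect is chosen from the
#'   file extension (`.gtf`/`.gff` vs anything else) unless `format` is given.
#' @param format `"bed"`, `"gtf"`, or `NULL` to autodetect.
#' @return A tibble with one row per transcript: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `tss`, `start`, `end`, a list-column `exons` of
#'   two-column matrices (start, end), `cpg_start`, `cpg_end` (NA when the
#'   transcript has no CpG island on record), `is_par`, and `meta_status`
#'   (one of escape/subject/variable/unknown; `unknown` when absent).
#'   Malformed lines raise an error naming the line number.
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "gtf") return(read_gene_models_gtf(path))
  read_gene_models_bed(path)
}

read_gene_models_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 6L)) {
    stop("line ", lineno[which(n < 6L)[1L]], ": fewer than 6 BED fields")
  }
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    ln <- lineno[i]
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("line ", ln, ": non-numeric start/end")
    }
    if (end <= start) stop("line ", ln, ": end <= start")
    strand <- f[6L]
    if (!strand %in% c("+", "-")) {
      stop("line ", ln, ": unknown strand symbol '", strand, "'")
    }
    if (length(f) >= 12L) {
      sizes <- as.integer(strsplit(f[11L], ",")[[1L]])
      offs <- as.integer(strsplit(f[12L], ",")[[1L]])
      if (length(sizes) != length(offs)) {
        stop("line ", ln, ": blockSizes/blockStarts length mismatch")
      }
      if (any(sizes <= 0L)) stop("line ", ln, ": zero-length exon")
      ex <- cbind(start + offs, start + offs + sizes)
    } else {
      ex <- cbind(start, end)
    }
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
      stop("line ", ln, ": overlapping exons")
    }
    list(chrom = f[1L], start = start, end = end, name = f[4L],
         strand = strand, exons = ex)
  })
  tibble::tibble(
    gene_id = sub("\\|.*$", "", vapply(recs, `[[`, "", "name")),
    transcript_id = vapply(recs, `[[`, "", "name"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    tss = ifelse(vapply(recs, `[[`, "", "strand") == "+",
                 vapply(recs, function(r) r$start, 0L),
                 vapply(recs, function(r) r$end, 0L) - 1L),
    start = vapply(recs, function(r) r$start, 0L),
    end = vapply(recs, function(r) r$end, 0L),
    exons = lapply(recs, `[[`, "exons"),
    cpg_start = NA_integer_, cpg_end = NA_integer_,
    is_par = FALSE, meta_status = "unknown"
  )
}

read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GTF input requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  df <- as.data.frame(ex)
  sp <- split(df, df$transcript_id)
  recs <- lapply(sp, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    # GTF is 1-based closed; convert to 0-based half-open.
    exm <- cbind(d$start - 1L, d$end)
    strand <- as.character(d$strand[1L])
    start <- min(exm[, 1L]); end <- max(exm[, 2L])
    tibble::tibble(
      gene_id = as.character(d$gene_id[1L]),
      transcript_id = as.character(d$transcript_id[1L]),
      chrom = as.character(d$seqnames[1L]), strand = strand,
      tss = if (strand == "+") start else end - 1L,
      start = start, end = end, exons = list(exm),
      cpg_start = NA_integer_, cpg_end = NA_integer_,
      is_par = FALSE, meta_status = "unknown"
    )
  })
  dplyr::bind_rows(recs)
}

#' Write gene models back to BED12
#'
#' Inverse of [read_gene_models()] for the BED dialect; round-trips content
#' modulo field ordering.
#'
#' @param genes Tibble from [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(
      genes$chrom[i], genes$start[i], genes$end[i], genes$transcript_id[i],
      0, genes$strand[i], genes$start[i], genes$end[i], "0", nrow(ex),
      paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
      paste0(paste(ex[, 1L] - genes$start[i], collapse = ","), ","),
      sep = "\t"
    )
  }, "")
  writeLines(lines, path)
}

#' Promoter windows upstream of TSSs
#'
#' Builds the fixed-width promoter window used for promoter-level mark and
#' methylation quantification: `width` bases immediately upstream of each
#' TSS, strand-aware, clipped at position 0 (clipped regions are flagged and
#' may be shorter than `width`).
#'
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @param width Window width in bases (default 500).
#' @return A tibble region set: `chrom`, `start`, `end`, `strand`,
#'   `linked_id` (transcript), `kind = "promoter"`, `clipped`.
#' @export
promoter_regions <- function(genes, width = 500L) {
  stopifnot(width > 0)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - width, genes$tss + 1L)
  end <- ifelse(plus, genes$tss, genes$tss + 1L + width)
  clipped <- start < 0L
  start <- pmax(start, 0L)
  tibble::tibble(
    chrom = genes$chrom, start = as.integer(start), end = as.integer(end),
    strand = genes$strand, linked_id = genes$transcript_id,
    kind = "promoter", clipped = clipped
  )
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (`chrom start end value`, tab-separated,
#'   sorted within each chromosome, non-overlapping).
#' @return A `signal_track`: list of per-chromosome tibbles with `start`,
#'   `end`, `value`. Unsorted or overlapping intervals, or NaN values, are
#'   errors.
#' @export
read_signal <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  if (any(!is.finite(d$value))) stop("non-finite signal values in ", path)
  if (any(d$end <= d$start)) stop("empty interval in ", path)
  sp <- split(d[c("start", "end", "value")], d$chrom)
  for (chr in names(sp)) {
    s <- sp[[chr]]
    if (is.unsorted(s$start, strictly = TRUE)) {
      stop("unsorted intervals on ", chr, " in ", path)
    }
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
      stop("overlapping intervals on ", chr, " in ", path)
    }
  }
  structure(lapply(sp, tibble::as_tibble), class = "signal_track")
}

#' Length-weighted mean signal over query intervals
#'
#' Positions not covered by the track contribute no weight; a query whose
#' covered fraction is below `min_covered` returns `NA` (absence of signal
#' evidence, never zero).
#'
#' @param track A `signal_track` from [read_signal()].
#' @param chrom,start,end Query interval vectors (0-based half-open).
#' @param min_covered Minimum covered fraction for a non-missing answer
#'   (default 0.5).
#' @return Numeric vector of length-weighted means (NA where uncovered).
#' @export
signal_mean <- function(track, chrom, start, end, min_covered = 0.5) {
  stopifnot(inherits(track, "signal_track"))
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n)
  vapply(seq_len(n), function(i) {
    s <- track[[chrom[i]]]
    if (is.null(s)) return(NA_real_)
    ov_start <- pmax(s$start, start[i])
    ov_end <- pmin(s$end, end[i])
    w <- pmax(ov_end - ov_start, 0L)
    covered <- sum(w)
    if (covered < min_covered * (end[i] - start[i])) return(NA_real_)
    sum(w * s$value) / covered
  }, 0)
}

#' Write a bedGraph signal track
#' @param track A `signal_track`.
#' @param path Output path.
#' @export
write_signal <- function(track, path) {
  d <- dplyr::bind_rows(lapply(names(track), function(chr) {
    cbind(chrom = chr, as.data.frame(track[[chr]]))
  }))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read genotypes from minimal VCF or wide TSV
#'
#' Accepts a minimal VCF (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT +
#' per-sample GT) or a wide TSV (`locus_id` column then one column per
#' sample with dosages 0/1/2 or NA). When several files cover one sample the
#' per-locus consensus is taken: all non-missing values agree, that value;
#' any disagreement, missing.
#'
#' @param paths Character vector of one or more files.
#' @return List with `genotypes` (locus x sample integer matrix of 0/1/2/NA)
#'   and `loci` (tibble `locus_id`, `chrom`, `pos`, `ref`, `alt`; NA-filled
#'   for TSV input).
#' @export
read_genotypes <- function(paths) {
  parts <- lapply(paths, read_genotypes_one)
  loci <- unique(dplyr::bind_rows(lapply(parts, `[[`, "loci")))
  if (anyDuplicated(loci$locus_id)) {
    stop("conflicting locus definitions across files")
  }
  samples <- unique(unlist(lapply(parts, function(p) colnames(p$genotypes))))
  out <- matrix(NA_integer_, nrow(loci), length(samples),
                dimnames = list(loci$locus_id, samples))
  seen <- matrix(FALSE, nrow(loci), length(samples),
                 dimnames = dimnames(out))
  conflict <- matrix(FALSE, nrow(loci), length(samples),
                     dimnames = dimnames(out))
  for (p in parts) {
    g <- p$genotypes
    for (s in colnames(g)) {
      v <- g[, s]
      ok <- !is.na(v)
      rows <- rownames(g)[ok]
      clash <- seen[rows, s] & !is.na(out[rows, s]) &
        out[rows, s] != v[ok]
      conflict[rows, s] <- conflict[rows, s] | clash
      new <- !seen[rows, s]
      out[rows[new], s] <- v[ok][new]
      seen[rows, s] <- TRUE
    }
  }
  out[conflict] <- NA_integer_
  list(genotypes = out, loci = loci)
}

read_genotypes_one <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("^#?CHROM\t", first)) {
    return(read_genotypes_vcf(path))
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(!is.na(m) & !(m %in% 0:2))) stop("dosages must be 0/1/2/NA")
  rownames(m) <- d[[1L]]
  list(genotypes = m,
       loci = tibble::tibble(locus_id = d[[1L]], chrom = NA_character_,
                             pos = NA_integer_, ref = NA_character_,
                             alt = NA_character_))
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("missing #CHROM header in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1L]]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  f <- strsplit(body, "\t", fixed = TRUE)
  samples <- cols[-(1:9)]
  alt <- vapply(f, `[[`, "", 5L)
  if (any(grepl(",", alt))) stop("triallelic locus in ", path)
  ids <- vapply(f, `[[`, "", 3L)
  gts <- t(vapply(f, function(x) {
    gt <- sub(":.*$", "", x[10:length(x)])
    a <- strsplit(gt, "[/|]")
    vapply(a, function(al) {
      if (any(al == ".")) return(NA_integer_)
      sum(as.integer(al))
    }, 0L)
  }, integer(length(samples))))
  if (length(samples) == 1L) gts <- matrix(gts, ncol = 1L)
  dimnames(gts) <- list(ids, samples)
  list(genotypes = gts,
       loci = tibble::tibble(
         locus_id = ids, chrom = vapply(f, `[[`, "", 1L),
         pos = as.integer(vapply(f, `[[`, "", 2L)),
         ref = vapply(f, `[[`, "", 4L), alt = alt
       ))
}

#' Read a sample sheet
#'
#' @param path TSV with header `sample_id, sex, tissue, dataset, skewed_xi`.
#' @return Tibble with those columns; `sex` checked against female/male.
#' @export
read_sample_sheet <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           stringsAsFactors = FALSE))
  need <- c("sample_id", "sex", "tissue", "dataset")
  if (!all(need %in% names(d))) {
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(d$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  if (!"skewed_xi" %in% names(d)) d$skewed_xi <- NA
  d$skewed_xi <- as.logical(d$skewed_xi)
  d
}
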