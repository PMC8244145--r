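# Shared fixture builders: everything is generated in code at test time.

write_bed12 <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

bed12_line <- function(chrom, start, end, name, strand,
                       sizes = end - start, offsets = 0L) {
  paste(chrom, start, end, name, 0, strand, start, end, "0",
        length(sizes), paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(offsets, collapse = ","), ","), sep = "\t")
}

write_bedgraph <- function(df, path = tempfile(fileext = ".bedGraph")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Brute-force per-base signal oracle for length-weighted means.
per_base_mean <- function(df, chrom, start, end) {
  d <- df[df[[1]] == chrom, ]
  vals <- rep(NA_real_, end - start)
  for (i in seq_len(nrow(d))) {
    lo <- max(d[i, 2], start); hi <- min(d[i, 3], end)
    if (hi > lo) vals[(lo - start + 1):(hi - start)] <- d[i, 4]
  }
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

# Small call table builder: statuses per sample for one gene.
calls_of <- function(statuses, id = "g1", gene_id = id) {
  tibble::tibble(id = id, gene_id = gene_id,
                 sample_id = paste0("s", seq_along(statuses)),
                 status = statuses)
}

# Independent oracle for the allelic status rule.
allelic_status_oracle <- function(xi, xa, z = 1.96, ratio = 0.10) {
  n <- xi + xa
  p <- xi / n
  hw <- z * sqrt(p * (1 - p) / n)
  p_star <- ratio / (1 + ratio)
  if (max(p - hw, 0) > p_star) "escape"
  else if (min(p + hw, 1) < p_star) "subject"
  else "uninformative"
}

# Independent oracle for the bulk DNAme rule bands.
dname_status_oracle <- function(f, m) {
  if (is.na(m) || m >= 0.15) return("uninformative")
  if (is.na(f)) return("uninformative")
  if (f < 0.10) return("escape")
  if (f > 0.60) return("hypermethylated")
  if (f > 0.15 && f < 0.60) return("subject")
  "intermediate"
}

# Independent oracle for the vote rule on 0..20 escape votes.
vote_oracle <- function(v, n = 20L) {
  s <- n - v
  if (v >= 15L) return("escape")
  if (s >= 15L) return("subject")
  if (v >= 12L && v > s) return("leaning_escape")
  if (s >= 12L && s > v) return("leaning_subject")
  "uninformative"
}

# Independent oracle for the cross-sample aggregation rule.
aggregate_oracle <- function(nE, nS, nLE, nLS, nI) {
  n <- nE + nS + nLE + nLS + nI
  if (n == 0) return("uninformative")
  if (nE / n >= 0.66) return("escape")
  if (nS / n >= 0.66) return("subject")
  if (nE / n >= 1 / 3 && nS / n >= 1 / 3) return("variable")
  if ((nE + nLE) / n >= 0.66) return("leaning_escape")
  if ((nS + nLS) / n >= 0.66) return("leaning_subject")
  "uninformative"
}
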