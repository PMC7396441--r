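# Shared fixture builders for the test suite. Everything is generated in
# code; the only stored fixtures are the two small printed tables under
# inst/extdata.

rpkm_fixture <- function() {
  read_expression_table(
    system.file("extdata", "candidate_genes_rpkm.tsv", package = "ctstab"))
}

efficiency_fixture <- function() {
  utils::read.delim(
    system.file("extdata", "primer_efficiency.tsv", package = "ctstab"))
}

# minimal long-format Ct data frame: all (sample, gene, replicate) cells
toy_ct_df <- function(genes = c("ACT", "TBP", "EIF"),
                      samples = c("S1", "S2", "S3", "S4"),
                      n_rep = 3, base = 25, seed = 1) {
  set.seed(seed)
  df <- expand.grid(replicate = seq_len(n_rep), gene = genes,
                    sample_id = samples, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$ct <- base + stats::rnorm(nrow(df), sd = 0.5)
  df[, c("sample_id", "gene", "replicate", "ct")]
}

# positive quantity matrix for algorithm-level tests
random_q <- function(n_genes = 5, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(2^stats::rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}

# independent brute-force oracle for the geNorm M-value: explicit double
# loop over partner genes, no shared code with m_value()
brute_force_m <- function(q, gene_j, subset = rownames(q)) {
  others <- setdiff(subset, gene_j)
  acc <- 0
  for (k in others) {
    ratios <- numeric(ncol(q))
    for (s in seq_len(ncol(q))) ratios[s] <- log2(q[gene_j, s] / q[k, s])
    acc <- acc + stats::sd(ratios)
  }
  acc / length(others)
}

# direct Pearson correlation from the textbook formula
direct_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a validation experiment: time course, a target with well-separated
# true expression levels, two stable references (sd 0.1) and one
# unstable reference whose Ct noise (sd 1.5) rivals the target signal
validation_ct <- function(seed = 84) {
  set.seed(seed)
  times <- c(0, 2, 6, 12, 24)
  target_dct <- c(0, -3.5, -1.2, -2.4, -4.6)  # >= 1.1 cycles apart
  n_rep <- 3
  rows <- do.call(rbind, lapply(seq_along(times), function(i) {
    smp <- sprintf("t%gh", times[i])
    loading <- stats::rnorm(1, 0, 0.4)
    data.frame(
      sample_id = smp, tissue = "root", group = "stress",
      time_h = times[i],
      gene = rep(c("tgt", "ref1", "ref2", "bad"), each = n_rep),
      replicate = rep(1:n_rep, 4),
      ct = c(28 + target_dct[i] + loading + rnorm(n_rep, 0, 0.05),
             24 + loading + rnorm(1, 0, 0.1) + rnorm(n_rep, 0, 0.05),
             26 + loading + rnorm(1, 0, 0.1) + rnorm(n_rep, 0, 0.05),
             25 + loading + rnorm(1, 0, 1.5) + rnorm(n_rep, 0, 0.05)),
      stringsAsFactors = FALSE)
  }))
  ct_table(rows)
}
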