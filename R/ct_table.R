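#' @keywords internal
ct_stop <- function(message, class) {
  stop(structure(
    class = c(paste0("ctstab_", class), "ctstab_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @keywords internal
ct_warn <- function(message, class) {
  warning(structure(
    class = c(paste0("ctstab_", class), "ctstab_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Construct a replicate-level Ct table
#'
#' A `ct_table` is a long (tidy) data frame of cycle-threshold observations,
#' one row per (sample, gene, replicate), with optional tissue, condition
#' group and time metadata. It is the canonical input of every stability
#' analysis in the package; wide gene-by-sample matrices are derived views
#' (see [average_replicates()]).
#'
#' @param data A data frame with columns `sample_id`, `gene`, `replicate`,
#'   `ct` and optionally `tissue`, `group`, `time_h`.
#' @param complete If `TRUE` (default) every (sample, gene) pair must be
#'   observed at least once; the stability algorithms assume complete
#'   matrices. If `FALSE`, samples with missing cells are dropped with a
#'   warning (listwise deletion).
#'
#' @return An object of class `ct_table`: the validated data frame with
#'   attributes `genes` and `samples` (ordered, duplicate-free, in order of
#'   first appearance).
#'
#' @details Invariants enforced: `ct` finite and positive, `replicate` a
#'   positive integer, `(sample_id, gene, replicate)` unique, and (unless
#'   `complete = FALSE`) no missing (sample, gene) cell.
#'
#' @examples
#' df <- expand.grid(sample_id = c("S1", "S2"), gene = c("ACT", "TBP"),
#'                   replicate = 1:3, KEEP.OUT.ATTRS = FALSE,
#'                   stringsAsFactors = FALSE)
#' df$ct <- 25 + rnorm(nrow(df), sd = 0.1)
#' ct <- ct_table(df)
#' genes(ct)
#' @export
ct_table <- function(data, complete = TRUE) {
  required <- c("sample_id", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    ct_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "schema_error")
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$sample_id <- as.character(data$sample_id)
  data$gene <- as.character(data$gene)

  if (!is.numeric(data$ct)) {
    ct_stop("column 'ct' must be numeric", "parse_error")
  }
  bad_ct <- which(!is.finite(data$ct) | data$ct <= 0)
  if (length(bad_ct)) {
    ct_stop(sprintf("ct must be finite and > 0; first offending row: %d",
                    bad_ct[1]), "validation_error")
  }
  rep_num <- suppressWarnings(as.numeric(data$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num))) {
    ct_stop("replicate must be a positive integer", "validation_error")
  }
  data$replicate <- as.integer(rep_num)

  key <- paste(data$sample_id, data$gene, data$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    ct_stop(sprintf(
      "duplicate (sample_id, gene, replicate): (%s, %s, %d) at row %d",
      data$sample_id[dup[1]], data$gene[dup[1]], data$replicate[dup[1]],
      dup[1]), "integrity_error")
  }

  if ("time_h" %in% names(data)) {
    th <- suppressWarnings(as.numeric(data$time_h))
    if (any(is.finite(th) & th < 0)) {
      ct_stop("time_h must be non-negative", "validation_error")
    }
    data$time_h <- th
  }

  gene_levels <- unique(data$gene)
  sample_levels <- unique(data$sample_id)

  # completeness of the gene-by-sample grid
  cell <- unique(paste(data$sample_id, data$gene, sep = "\r"))
  n_expected <- length(gene_levels) * length(sample_levels)
  if (length(cell) < n_expected) {
    grid <- expand.grid(sample_id = sample_levels, gene = gene_levels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gkey <- paste(grid$sample_id, grid$gene, sep = "\r")
    absent <- grid[!(gkey %in% cell), , drop = FALSE]
    if (complete) {
      ct_stop(sprintf(
        "missing (sample, gene) cell(s), e.g. (%s, %s); %d cell(s) absent",
        absent$sample_id[1], absent$gene[1], nrow(absent)),
        "integrity_error")
    }
    drop_samples <- unique(absent$sample_id)
    ct_warn(sprintf(
      "dropping %d sample(s) with incomplete gene coverage: %s",
      length(drop_samples), paste(drop_samples, collapse = ", ")),
      "incomplete_cells")
    data <- data[!(data$sample_id %in% drop_samples), , drop = FALSE]
    sample_levels <- setdiff(sample_levels, drop_samples)
    if (!length(sample_levels)) {
      ct_stop("no complete samples remain after listwise deletion",
              "integrity_error")
    }
  }

  rownames(data) <- NULL
  structure(data,
            genes = gene_levels,
            samples = sample_levels,
            class = c("ct_table", "data.frame"))
}

#' Genes and samples of a Ct table
#'
#' @param x A [ct_table()].
#' @return Character vector of gene symbols / sample identifiers in order of
#'   first appearance.
#' @export
genes <- function(x) attr(x, "genes")

#' @rdname genes
#' @export
samples <- function(x) attr(x, "samples")

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("Ct table: %d genes x %d samples, %d observations\n",
              length(genes(x)), length(samples(x)), nrow(x)))
  cat("  genes:", paste(utils::head(genes(x), 8), collapse = ", "),
      if (length(genes(x)) > 8) "..." else "", "\n")
  reps <- table(paste(x$sample_id, x$gene))
  cat(sprintf("  replicates per cell: %s\n",
              paste(sort(unique(as.integer(reps))), collapse = ", ")))
  cat(sprintf("  Ct range: %.2f - %.2f cycles\n", min(x$ct), max(x$ct)))
  invisible(x)
}

#' Read a replicate-level Ct table from CSV
#'
#' Reads a long-format CSV (header row; columns `sample_id`, `gene`,
#' `replicate`, `ct`, optional `tissue`, `group`, `time_h`) and validates it
#' into a [ct_table()]. Parsing is locale-independent; qPCR exports that use
#' a decimal comma are handled via `dec = ","`.
#'
#' @param path Path to a CSV file.
#' @param sep Field separator (default `","`; use `"\t"` for TSV).
#' @param dec Decimal mark in numeric fields, `"."` (default) or `","`.
#' @param complete Passed to [ct_table()]; `FALSE` downgrades missing
#'   (sample, gene) cells to a warning plus listwise deletion.
#' @return A validated [ct_table()], rows in file order.
#' @export
read_ct_table <- function(path, sep = ",", dec = ".", complete = TRUE) {
  if (!file.exists(path)) ct_stop(sprintf("file not found: %s", path),
                                  "io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  required <- c("sample_id", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    ct_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")), "schema_error")
  }
  parse_num <- function(x, col) {
    if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(bad)) {
      ct_stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                      x[bad[1]], col, bad[1]), "parse_error")
    }
    out
  }
  df$ct <- parse_num(df$ct, "ct")
  df$replicate <- parse_num(df$replicate, "replicate")
  if ("time_h" %in% names(df)) df$time_h <- parse_num(df$time_h, "time_h")
  ct_table(df, complete = complete)
}

#' Write a Ct table to CSV
#'
#' Inverse of [read_ct_table()]: writing then re-reading reproduces the
#' table (text fields exactly, numerics to full double precision).
#'
#' @param x A [ct_table()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_ct_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "ct_table"))
  df <- as.data.frame(x)
  num_cols <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num_cols]) {
    df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Subset a Ct table by metadata
#'
#' Declarative filter over the (tissue, group, time) metadata, used to build
#' the per-condition analysis subsets (e.g. "NaCl leaves and roots").
#'
#' @param x A [ct_table()].
#' @param tissue,group,time_h Optional vectors of values to keep; `NULL`
#'   keeps all.
#' @param samples Optional vector of sample ids to keep.
#' @param complete Passed to [ct_table()] when revalidating the subset.
#' @return A [ct_table()] restricted to matching rows.
#' @export
ct_subset <- function(x, tissue = NULL, group = NULL, time_h = NULL,
                      samples = NULL, complete = TRUE) {
  stopifnot(inherits(x, "ct_table"))
  keep <- rep(TRUE, nrow(x))
  if (!is.null(tissue) && "tissue" %in% names(x)) {
    keep <- keep & x$tissue %in% tissue
  }
  if (!is.null(group) && "group" %in% names(x)) {
    keep <- keep & x$group %in% group
  }
  if (!is.null(time_h) && "time_h" %in% names(x)) {
    keep <- keep & x$time_h %in% time_h
  }
  if (!is.null(samples)) keep <- keep & x$sample_id %in% samples
  out <- as.data.frame(x)[keep, , drop = FALSE]
  if (!nrow(out)) ct_stop("subset selects no observations", "subset_error")
  ct_table(out, complete = complete)
}
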