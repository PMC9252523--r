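## Readers, writers and validated containers for every external format the
## pipeline touches. All writers emit canonical column order and %.17g
## decimals so that write -> read -> write is byte-identical.

COHORT_LEVELS <- c("ref_normal", "adj_normal", "tumor")
SEX_LEVELS <- c("male", "female", "unknown")
BASES <- c("A", "C", "G", "T")

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == round(x) & abs(x) < 1e15] <- sprintf("%.0f", x[x == round(x) & abs(x) < 1e15])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated expression cohort
#'
#' An expression cohort is a non-negative gene-by-sample matrix together with
#' a per-sample cohort label (`ref_normal`, `adj_normal` or `tumor`) and a
#' per-sample sex label (`male`, `female` or `unknown`). The constructor
#' enforces the type invariants: unique gene and sample identifiers, matching
#' dimensions, and finite non-negative values. No invalid object can be
#' constructed.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). TPM-like linear-scale units.
#' @param cohort character vector, one label per sample, each one of
#'   `ref_normal`, `adj_normal`, `tumor`.
#' @param sex optional character vector, one of `male`, `female`, `unknown`
#'   per sample; defaults to `unknown`.
#' @return an object of class `expression_cohort`: a list with elements
#'   `values`, `cohort` (factor) and `sex` (factor).
#' @export
expression_cohort <- function(values, cohort, sex = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  gene_ids <- trimws(gene_ids)
  sample_ids <- trimws(sample_ids)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite or negative expression at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  if (length(cohort) == 1L) cohort <- rep(cohort, ncol(values))
  if (length(cohort) != ncol(values))
    stop("`cohort` must supply one label per sample")
  if (!all(cohort %in% COHORT_LEVELS))
    stop("cohort labels must be in {", paste(COHORT_LEVELS, collapse = ", "), "}")
  if (is.null(sex)) sex <- rep("unknown", ncol(values))
  if (length(sex) == 1L) sex <- rep(sex, ncol(values))
  if (length(sex) != ncol(values)) stop("`sex` must supply one label per sample")
  if (!all(sex %in% SEX_LEVELS))
    stop("sex labels must be in {", paste(SEX_LEVELS, collapse = ", "), "}")
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(list(values = values,
                 cohort = factor(cohort, levels = COHORT_LEVELS),
                 sex = factor(sex, levels = SEX_LEVELS)),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(cohort = x$cohort, sex = x$sex))
  invisible(x)
}

#' Subset an expression cohort by genes and/or samples
#' @param x an `expression_cohort`
#' @param i gene index (ids, logical or integer)
#' @param j sample index
#' @param ... ignored
#' @export
`[.expression_cohort` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_cohort(x$values[i, j, drop = FALSE],
                    as.character(x$cohort[j]), as.character(x$sex[j]))
}

read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character")
  for (col in c("sample_id", "cohort"))
    if (!col %in% names(md)) stop("metadata is missing required column '", col, "'")
  if (!"sex" %in% names(md)) md$sex <- "unknown"
  md
}

#' Read a gene-by-sample expression table
#'
#' Supported formats: plain TSV whose first column header is literally
#' `gene_id`, and GCT 1.2. Cohort (and optionally sex) labels come from a
#' metadata sidecar TSV with columns `sample_id`, `cohort` and optionally
#' `sex`, or can be passed directly; cohort labels are required, sex defaults
#' to `unknown`.
#'
#' @param path path to the expression file
#' @param format `"auto"` (default; decided by the `#1.2` magic line),
#'   `"tsv"` or `"gct"`
#' @param metadata path to a metadata sidecar TSV, or a data.frame with the
#'   sidecar columns
#' @param cohort,sex per-sample labels, used when `metadata` is `NULL`;
#'   vectors aligned with the file's sample columns, or a single label
#' @return an [expression_cohort()]
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            metadata = NULL, cohort = NULL, sex = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "#1.2")) "gct" else "tsv"
  }
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2"))
      stop("not a GCT 1.2 file (missing '#1.2' version line): ", path)
    dims <- as.integer(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]])
    if (length(dims) < 2L || anyNA(dims))
      stop("malformed GCT dimensions line")
    header <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 3L || header[[1L]] != "Name")
      stop("malformed GCT header (expected 'Name\\tDescription\\t<samples>')")
    sample_ids <- header[-(1:2)]
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != dims[[1L]] || length(sample_ids) != dims[[2L]])
      stop(sprintf("GCT declared dimensions (%d x %d) do not match body (%d x %d)",
                   dims[[1L]], dims[[2L]], length(body), length(sample_ids)))
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(header)))
      stop("GCT body row ", which(nf != length(header))[1L], " has wrong field count")
    gene_ids <- vapply(fields, `[[`, "", 1L)
    mat <- parse_expr_cells(fields, first_data_col = 3L, gene_ids, sample_ids)
  } else {
    lines <- readLines(path)
    if (!length(lines)) stop("empty expression file: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (header[[1L]] != "gene_id")
      stop("expression TSV must have 'gene_id' as its first column header, found '",
           header[[1L]], "'")
    sample_ids <- header[-1L]
    body <- lines[-1L]
    body <- body[nzchar(body)]
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(header)))
      stop("TSV row ", which(nf != length(header))[1L], " has wrong field count")
    gene_ids <- vapply(fields, `[[`, "", 1L)
    mat <- parse_expr_cells(fields, first_data_col = 2L, gene_ids, sample_ids)
  }
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) read_metadata_tsv(metadata) else metadata
    idx <- match(trimws(sample_ids), trimws(md$sample_id))
    if (anyNA(idx))
      stop("metadata is missing sample(s): ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    cohort <- md$cohort[idx]
    sex <- md$sex[idx] %||% rep("unknown", length(idx))
    sex[is.na(sex) | sex == ""] <- "unknown"
  }
  if (is.null(cohort))
    stop("cohort labels are required: supply `metadata` or `cohort`")
  expression_cohort(mat, cohort, sex)
}

parse_expr_cells <- function(fields, first_data_col, gene_ids, sample_ids) {
  gene_ids <- trimws(gene_ids)
  n_samp <- length(sample_ids)
  mat <- matrix(NA_real_, length(fields), n_samp,
                dimnames = list(gene_ids, trimws(sample_ids)))
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][first_data_col:(first_data_col + n_samp - 1L)]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                   gene_ids[[i]], sample_ids[[bad[1L]]]))
    bad <- which(v < 0)
    if (length(bad))
      stop(sprintf("negative expression value at gene '%s', sample '%s'",
                   gene_ids[[i]], sample_ids[[bad[1L]]]))
    mat[i, ] <- v
  }
  mat
}

#' Write an expression cohort to TSV or GCT 1.2
#'
#' @param x an [expression_cohort()]
#' @param path output path for the expression matrix
#' @param format `"tsv"` (first column `gene_id`) or `"gct"`
#' @param metadata_path optional path for the sample metadata sidecar TSV
#'   (`sample_id`, `cohort`, `sex`)
#' @return `path`, invisibly
#' @export
write_expression <- function(x, path, format = c("tsv", "gct"),
                             metadata_path = NULL) {
  stopifnot(inherits(x, "expression_cohort"))
  format <- match.arg(format)
  rows <- apply(x$values, 1L, function(v) paste(fmt_num(v), collapse = "\t"))
  if (format == "tsv") {
    lines <- c(paste(c("gene_id", colnames(x$values)), collapse = "\t"),
               paste(rownames(x$values), rows, sep = "\t"))
  } else {
    lines <- c("#1.2",
               paste(nrow(x$values), ncol(x$values), sep = "\t"),
               paste(c("Name", "Description", colnames(x$values)), collapse = "\t"),
               paste(rownames(x$values), "na", rows, sep = "\t"))
  }
  writeLines(lines, path)
  if (!is.null(metadata_path)) {
    md <- c("sample_id\tcohort\tsex",
            paste(colnames(x$values), as.character(x$cohort), as.character(x$sex),
                  sep = "\t"))
    writeLines(md, metadata_path)
  }
  invisible(path)
}

#' Construct a gene set
#'
#' @param name set name (non-empty)
#' @param genes character vector of gene identifiers; whitespace-stripped,
#'   must be non-empty after de-duplication
#' @param description free-text description
#' @return object of class `gene_set` with elements `name`, `genes`,
#'   `description`
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set `name` must be a non-empty string")
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) genes <- unique(genes)
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%d genes): %s%s\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 8L), collapse = ", "),
              if (length(x$genes) > 8L) ", ..." else ""))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `name <TAB> description <TAB> gene1 <TAB> gene2 ...`, one
#' set per line. Duplicate genes within a line are collapsed with a warning.
#'
#' @param path path to a GMT file
#' @return a list of [gene_set()] objects (empty list for an empty file)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields (name, description, genes...)")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes))
      warning("GMT set '", f[[1L]], "': ",
              sum(duplicated(genes)), " duplicate gene(s) collapsed")
    out[[i]] <- gene_set(f[[1L]], unique(genes), f[[2L]])
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets a `gene_set` or list of them
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' The packaged 14-gene obesity signature
#' @return a [gene_set()] with the 14 obesity-associated genes
#' @export
obesity_signature <- function() {
  read_gmt(system.file("extdata", "obesity_14.gmt", package = "adipohep"))[[1L]]
}

#' Construct a validated survival table
#'
#' @param sample_id unique sample identifiers
#' @param time_days positive follow-up times in days
#' @param event 0 = censored, 1 = death
#' @param sex optional per-sample sex label
#' @param covariates optional data.frame of named numeric covariate columns
#' @return data.frame of class `survival_table`
#' @export
survival_table <- function(sample_id, time_days, event, sex = NULL,
                           covariates = NULL) {
  sample_id <- trimws(as.character(sample_id))
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s) in survival table: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  time_days <- as.numeric(time_days)
  if (any(!is.finite(time_days) | time_days <= 0))
    stop("survival times must be finite and > 0")
  if (!all(event %in% c(0, 1)))
    stop("`event` must be 0 (censored) or 1 (death); found: ",
         paste(unique(setdiff(event, c(0, 1))), collapse = ", "))
  if (is.null(sex)) sex <- rep("unknown", length(sample_id))
  if (!all(sex %in% SEX_LEVELS)) stop("invalid sex label in survival table")
  df <- data.frame(sample_id = sample_id, time_days = time_days,
                   event = as.integer(event), sex = as.character(sex),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read a survival TSV (sample_id, time_days, event, sex)
#'
#' Rows with non-positive or missing time are dropped with a logged count;
#' an event code outside \{0,1\} is a fatal validation error, as is a missing
#' required column.
#'
#' @param path path to the TSV
#' @return a [survival_table()]; attribute `n_dropped` carries the number of
#'   dropped rows
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("sample_id", "time_days", "event"))
    if (!col %in% names(df)) stop("survival table is missing required column '", col, "'")
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  ev <- suppressWarnings(as.numeric(df$event))
  if (any(is.na(ev)) || !all(ev %in% c(0, 1)))
    stop("invalid `event` value(s) (must be 0 or 1): ",
         paste(unique(df$event[is.na(ev) | !ev %in% c(0, 1)]), collapse = ", "))
  tm <- suppressWarnings(as.numeric(df$time_days))
  keep <- !is.na(tm) & is.finite(tm) & tm > 0
  n_dropped <- sum(!keep)
  if (n_dropped) message("read_survival: dropped ", n_dropped,
                         " row(s) with non-positive or missing time")
  extra <- setdiff(names(df), c("sample_id", "time_days", "event", "sex"))
  out <- survival_table(df$sample_id[keep], tm[keep], ev[keep], df$sex[keep],
                        if (length(extra)) df[keep, extra, drop = FALSE])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a survival table (canonical column order)
#' @param x a [survival_table()]
#' @param path output path
#' @export
write_survival <- function(x, path) {
  stopifnot(inherits(x, "survival_table"))
  extra <- setdiff(names(x), c("sample_id", "time_days", "event", "sex"))
  header <- paste(c("sample_id", "time_days", "event", "sex", extra), collapse = "\t")
  rows <- paste(x$sample_id, fmt_num(x$time_days), x$event, x$sex, sep = "\t")
  for (col in extra) rows <- paste(rows, fmt_num(x[[col]]), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Construct a validated GWAS summary-statistics table
#'
#' Required fields: `snp_id`, `effect_allele`, `other_allele` (single,
#' distinct A/C/G/T bases), `beta`, `se > 0`, `pval` in (0, 1]; `eaf` in
#' (0, 1) or `NA`; `n` a positive count or `NA`.
#'
#' @param df data.frame with the columns above
#' @return data.frame of class `gwas_summary`
#' @export
gwas_summary <- function(df) {
  req <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
           "pval", "n")
  for (col in req)
    if (!col %in% names(df)) stop("GWAS table is missing required column '", col, "'")
  df <- df[, req]
  df$effect_allele <- toupper(trimws(df$effect_allele))
  df$other_allele <- toupper(trimws(df$other_allele))
  ok <- df$effect_allele %in% BASES & df$other_allele %in% BASES &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)) &
    (is.na(df$n) | df$n > 0)
  if (any(!ok)) stop("invalid GWAS row(s); use read_gwas() to drop them")
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Read a GWAS summary TSV
#'
#' Columns: snp_id, effect_allele, other_allele, eaf, beta, se, pval, n.
#' Rows violating the invariants (se <= 0, invalid alleles, p outside
#' (0, 1], eaf outside (0, 1)) are dropped with a logged count; a missing
#' column is fatal.
#'
#' @param path path to the TSV
#' @return a [gwas_summary()] table; attribute `n_dropped` counts dropped rows
#' @export
read_gwas <- function(path) {
  # read everything as character: allele "T" must not become logical TRUE
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character")
  req <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
           "pval", "n")
  for (col in req)
    if (!col %in% names(df)) stop("GWAS table is missing required column '", col, "'")
  for (col in c("eaf", "beta", "se", "pval", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$effect_allele <- toupper(trimws(df$effect_allele))
  df$other_allele <- toupper(trimws(df$other_allele))
  ok <- df$effect_allele %in% BASES & df$other_allele %in% BASES &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)) &
    (is.na(df$n) | df$n > 0)
  n_dropped <- sum(!ok)
  if (n_dropped) message("read_gwas: dropped ", n_dropped, " invalid row(s)")
  out <- gwas_summary(df[ok, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a GWAS summary table (canonical column order)
#' @param x a [gwas_summary()]
#' @param path output path
#' @export
write_gwas <- function(x, path) {
  stopifnot(inherits(x, "gwas_summary"))
  header <- "snp_id\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn"
  num <- function(v) ifelse(is.na(v), "NA", fmt_num(v))
  rows <- paste(x$snp_id, x$effect_allele, x$other_allele, num(x$eaf),
                num(x$beta), num(x$se), num(x$pval), num(x$n), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}
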