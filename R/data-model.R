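#' @keywords internal
"_PACKAGE"

# ---- expression matrices ----------------------------------------------------

#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique, non-empty gene
#' identifiers as rownames and unique sample identifiers as colnames. Values
#' are assumed log-scale and already normalized upstream; the pipeline never
#' re-normalizes across samples.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers in expression matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (!all(is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample identifiers and
#' gene identifiers in the first column. Duplicate gene identifiers are
#' collapsed by their mean; rows containing any missing value are dropped;
#' genes with variance at or below `min_variance` are removed. A load report
#' with the dropped counts is attached as attribute `"load_report"` and
#' emitted as a message.
#'
#' @param path path to the TSV file.
#' @param min_variance genes with across-sample variance `<= min_variance`
#'   are removed (default 0: constant genes go).
#' @return numeric matrix passing [validate_expression()].
#' @export
read_expression <- function(path, min_variance = 0) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L)
    stop("malformed header in ", path, ": need a gene column plus >=2 samples")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) != length(header))
    stop("malformed expression file ", path, ": ragged rows")
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, colnames(vals))))
  bad <- which(is.na(num) & !(vals %in% c("NA", "", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    # +1 for the header line
    stop("non-numeric cell in ", path, " at data row ", bad[1, 1],
         " (file line ", bad[1, 1] + 1L, "), column '",
         colnames(vals)[bad[1, 2]], "'")
  }
  n_na_rows <- sum(!stats::complete.cases(num))
  keep <- stats::complete.cases(num)
  num <- num[keep, , drop = FALSE]
  genes <- genes[keep]
  if (nrow(num) == 0L) stop("empty expression matrix after dropping NA rows")
  n_dup <- sum(duplicated(genes))
  if (n_dup > 0L) {
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(num) <- genes
  v <- rowVars(num)
  n_lowvar <- sum(v <= min_variance)
  num <- num[v > min_variance, , drop = FALSE]
  if (nrow(num) == 0L) stop("empty expression matrix after variance filter")
  report <- list(n_na_rows = n_na_rows, n_duplicate_rows = n_dup,
                 n_low_variance = n_lowvar,
                 n_genes = nrow(num), n_samples = ncol(num))
  message(sprintf(
    "read_expression: %d genes x %d samples (%d NA rows, %d duplicate rows collapsed, %d low-variance genes dropped)",
    nrow(num), ncol(num), n_na_rows, n_dup, n_lowvar))
  validate_expression(num)
  attr(num, "load_report") <- report
  num
}

#' Write an expression matrix to TSV
#'
#' Values are written with 10 significant digits so that a write/read
#' round-trip reproduces the matrix to within 1e-9.
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(row)
    paste(sprintf("%.10g", row), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# ---- signature sets ---------------------------------------------------------

#' Construct a signature set
#'
#' A signature set is a named list of character vectors (gene identifiers per
#' signature) with an optional per-signature category label, e.g. the
#' pro-tumor / anti-tumor immune-cell grouping.
#'
#' @param sets named list of non-empty character vectors.
#' @param category optional character vector, one label per set (recycled
#'   names taken from `sets`).
#' @param name optional collection name.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(sets, category = NULL, name = "signatures") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list of gene id vectors")
  if (anyDuplicated(names(sets))) stop("duplicate signature names")
  if (any(lengths(sets) == 0L)) stop("empty signature set")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (!is.null(category)) {
    if (length(category) != length(sets))
      stop("category must have one label per signature")
    category <- stats::setNames(as.character(category), names(sets))
  }
  structure(list(name = name, sets = sets, category = category),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set '%s': %d sets (sizes %s)\n", x$name,
              length(x$sets), paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then gene identifiers. Duplicate genes within a set are de-duplicated.
#'
#' @param path path to the GMT file.
#' @param category optional category label(s) applied to all sets.
#' @return a [signature_set()].
#' @export
read_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no signatures in GMT file ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    stop("GMT line ", short[1], " in ", path, " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name in ", path, ": ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (!is.null(category) && length(category) == 1L)
    category <- rep(category, length(sets))
  signature_set(sets, category = category,
                name = sub("\\.gmt$", "", basename(path)))
}

#' Write a signature set to GMT
#'
#' @param sigs a [signature_set()].
#' @param path output path; the description field carries the category label
#'   (or `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  desc <- if (is.null(sigs$category)) rep("na", length(sigs$sets))
          else unname(sigs$category)
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sigs$sets), desc, sigs$sets)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict signatures to the genes of an expression matrix
#'
#' Genes absent from the matrix are dropped (reported per set); sets left
#' empty are removed with a warning.
#'
#' @param sigs a [signature_set()].
#' @param expr expression matrix.
#' @return restricted `signature_set` with attribute `"dropped"` (named list
#'   of removed genes per set).
#' @export
restrict_signatures <- function(sigs, expr) {
  stopifnot(inherits(sigs, "signature_set"))
  universe <- rownames(expr)
  kept <- lapply(sigs$sets, function(g) g[g %in% universe])
  dropped <- mapply(function(all, k) setdiff(all, k), sigs$sets, kept,
                    SIMPLIFY = FALSE)
  empty <- lengths(kept) == 0L
  if (any(empty))
    warning("dropping ", sum(empty), " signature(s) with no gene in the matrix: ",
            paste(names(kept)[empty], collapse = ", "))
  if (all(empty)) stop("no signature retains any gene in the expression matrix")
  out <- signature_set(kept[!empty],
                       category = if (!is.null(sigs$category))
                         sigs$category[!empty] else NULL,
                       name = sigs$name)
  attr(out, "dropped") <- dropped
  out
}

# ---- clinical / survival tables --------------------------------------------

#' Construct a survival table
#'
#' @param sample_id character sample identifiers (unique).
#' @param time strictly positive follow-up times (single consistent unit).
#' @param event 0/1 event indicator (1 = death/progression observed).
#' @param ... additional per-sample covariates (numeric or categorical).
#' @return a `data.frame` of class `survival_table`.
#' @export
survival_table <- function(sample_id, time, event, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample identifiers")
  if (!all(is.finite(time)) || any(time <= 0))
    stop("times must be finite and strictly positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  df <- data.frame(sample_id = sample_id, time = as.numeric(time),
                   event = as.integer(event), ...,
                   stringsAsFactors = FALSE, check.names = FALSE)
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read a clinical table from TSV
#'
#' Columns `sample_id`, `time`, `event`, then covariates.
#'
#' @param path path to the TSV file.
#' @return a [survival_table()].
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "")
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("clinical file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  do.call(survival_table, c(list(sample_id = df$sample_id, time = df$time,
                                 event = df$event),
                            df[setdiff(names(df), need)]))
}

#' Write a clinical table to TSV
#' @param surv a [survival_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix and a survival table on shared samples
#'
#' Both are restricted to the intersection of sample identifiers and put in
#' the same (expression-matrix) order. Idempotent.
#'
#' @param expr expression matrix.
#' @param surv a [survival_table()].
#' @return list with elements `expr` and `surv`.
#' @export
align_samples <- function(expr, surv) {
  common <- intersect(colnames(expr), surv$sample_id)
  if (length(common) == 0L)
    stop("no overlap between expression samples and clinical samples")
  expr2 <- expr[, common, drop = FALSE]
  surv2 <- surv[match(common, surv$sample_id), , drop = FALSE]
  rownames(surv2) <- NULL
  message("align_samples: ", length(common), " shared samples")
  list(expr = expr2, surv = surv2)
}

# ---- group assignments ------------------------------------------------------

#' Construct a group assignment
#'
#' @param sample_id character sample identifiers.
#' @param label one categorical label per sample.
#' @return data.frame of class `group_assignment`.
#' @export
group_assignment <- function(sample_id, label) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample identifiers")
  if (length(label) != length(sample_id))
    stop("one label per sample required")
  df <- data.frame(sample_id = sample_id, label = as.character(label),
                   stringsAsFactors = FALSE)
  class(df) <- c("group_assignment", "data.frame")
  df
}

# match a group assignment against a set of sample ids, returning labels
group_labels_for <- function(groups, sample_ids) {
  stopifnot(inherits(groups, "group_assignment"))
  idx <- match(sample_ids, groups$sample_id)
  if (anyNA(idx))
    stop("samples without group label: ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
  groups$label[idx]
}
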