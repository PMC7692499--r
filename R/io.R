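#' Read a gene-by-sample expression matrix from delimited text
#'
#' The file must have gene identifiers in the first column and sample
#' identifiers in the header row. Duplicated gene or sample identifiers and
#' non-numeric or missing cells are rejected with informative errors rather
#' than silently propagated: downstream clustering assumes a complete,
#' uniquely-keyed matrix.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return A numeric matrix (genes in rows, samples in columns) with a
#'   `standardized` attribute set to `FALSE`.
#' @seealso [standardize()], [write_expression()]
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene-id column plus at least one sample column")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g)) {
    stop("duplicate gene identifiers: ", paste(head(dup_g, 10L), collapse = ", "))
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ", paste(head(dup_s, 10L), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "non-numeric or missing value at gene '%s', sample '%s' (value '%s'); %d offending cell(s) in total",
      genes[i], samples[j], vals[i, j], nrow(bad)))
  }
  dimnames(num) <- list(genes, samples)
  attr(num, "standardized") <- FALSE
  num
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: gene ids in the first column (`gene_id`),
#' sample ids in the header. Values are written at full double precision so a
#' read/write round trip is exact to the printed 15 significant digits.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @export
write_expression <- function(expr, path, delimiter = "\t") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample table (clinical, purity, labels) keyed by sample id
#'
#' @param path Path to TSV/CSV with a `sample_id` column.
#' @param delimiter Field delimiter.
#' @return A data.frame; `sample_id` is checked for uniqueness.
#' @export
read_sample_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("sample table must have a 'sample_id' column")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample_id values: ", paste(head(dup, 10L), collapse = ", "))
  df
}

#' Validate a clinical table (survival time, event, optional label columns)
#'
#' @param clinical data.frame with columns `sample_id`, `survival_time`,
#'   `event`.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_clinical <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  need <- c("sample_id", "survival_time", "event")
  miss <- setdiff(need, colnames(clinical))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(clinical$sample_id)) stop("clinical sample_id not unique")
  if (any(!clinical$event %in% c(0, 1))) stop("event must be 0/1")
  if (any(clinical$survival_time < 0, na.rm = TRUE) || anyNA(clinical$survival_time)) {
    stop("survival_time must be nonnegative and complete")
  }
  clinical
}

#' Collapse a probe-level matrix to gene level
#'
#' For genes measured by several probes, only the probe with the highest mean
#' intensity across samples is retained; all other probes for that gene are
#' discarded. Probes absent from the map are dropped (a message reports how
#' many).
#'
#' @param expr Probe-by-sample numeric matrix (probe ids as rownames).
#' @param probe_map data.frame with columns `probe_id` and `gene_id`; each
#'   probe maps to exactly one gene.
#' @return Gene-by-sample matrix, one row per distinct mapped gene.
#' @export
collapse_probes <- function(expr, probe_map) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            is.data.frame(probe_map),
            all(c("probe_id", "gene_id") %in% colnames(probe_map)))
  if (anyDuplicated(probe_map$probe_id)) stop("a probe maps to more than one gene")
  keep <- rownames(expr) %in% probe_map$probe_id
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " unmapped probe(s) dropped")
  if (!any(keep)) stop("no probes left after mapping")
  expr <- expr[keep, , drop = FALSE]
  gene <- probe_map$gene_id[match(rownames(expr), probe_map$probe_id)]
  means <- rowMeans(expr)
  # per gene, index of the probe with maximal row mean (first wins on ties)
  ord <- order(gene, -means)
  first <- ord[!duplicated(gene[ord])]
  out <- expr[first, , drop = FALSE]
  rownames(out) <- gene[first]
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "standardized") <- isTRUE(attr(expr, "standardized"))
  out
}

#' Standardize an expression matrix gene-wise (z-score within dataset)
#'
#' Each gene row is centered to mean 0 and scaled to sample standard
#' deviation 1 (n - 1 denominator). Zero-variance genes become all-zero rows
#' (and are reported) rather than dropped, so gene indices remain aligned
#' with signature lists. Standardizing an already standardized matrix is an
#' error: double scaling is a silent bug in cross-dataset work, where each
#' dataset must be standardized once, within itself.
#'
#' @param expr Numeric gene-by-sample matrix, `standardized` attribute FALSE
#'   or unset.
#' @return The standardized matrix with `standardized = TRUE`.
#' @export
standardize <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (isTRUE(attr(expr, "standardized"))) {
    stop("matrix is already standardized; refusing to scale twice")
  }
  if (anyNA(expr)) stop("expression matrix contains missing values")
  mu <- rowMeans(expr)
  s <- matrixStats::rowSds(expr)
  zero <- s < .Machine$double.eps^0.5
  if (any(zero)) {
    message(sum(zero), " zero-variance gene(s) set to all-zero rows")
  }
  s[zero] <- 1
  out <- (expr - mu) / s
  out[zero, ] <- 0
  attr(out, "standardized") <- TRUE
  out
}
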