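#' Construct a log2 expression matrix
#'
#' The central container of the pipeline: a numeric matrix of log2-scale
#' expression values (as produced upstream by RMA-style normalisation) with
#' transcripts in rows and samples in columns, tagged with the platform it
#' was measured on.
#'
#' @param values Numeric matrix; rownames are transcript identifiers and
#'   colnames are sample identifiers. No missing values are allowed.
#' @param platform Either `"mirna"` or `"mrna"`.
#' @return An object of class `expr_matrix` (a numeric matrix with a
#'   `platform` attribute).
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2,
#'             dimnames = list(paste0("t", 1:3), paste0("s", 1:2)))
#' x <- expr_matrix(m, "mrna")
#' platform(x)
#' @export
expr_matrix <- function(values, platform = c("mirna", "mrna")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have transcript rownames and sample colnames",
         call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate transcript id: ", dup[1L], call. = FALSE)
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id: ", dup[1L], call. = FALSE)
  structure(values, platform = platform, class = c("expr_matrix", "matrix"))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
platform <- function(x) attr(x, "platform")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d transcripts x %d samples (log2 scale)\n",
              platform(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Read a transcripts-by-samples expression TSV
#'
#' Expects a header row of sample identifiers, a first column of transcript
#' identifiers, and a numeric body. Malformed input (duplicate identifiers,
#' non-numeric cells) is rejected with an error naming the offending entry;
#' nothing is silently repaired.
#'
#' @param path Path to a tab-separated file.
#' @param platform `"mirna"` or `"mrna"`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, platform = c("mirna", "mrna")) {
  platform <- match.arg(platform)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file needs >= 1 sample column: ", path, call. = FALSE)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate transcript id in ", path, ": ", dup[1L], call. = FALSE)
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row %d (%s), column %s of %s",
                 bad[1L], ids[bad[1L]], colnames(body)[bad[2L]], path),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(body))
  expr_matrix(num, platform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips are value-identical to
#' the printed precision (values are written with full double precision).
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(transcript_id = rownames(x),
                   as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write the sample metadata table
#'
#' Columns: `sample_id`, `cell_type` (raw label, e.g. CD4 / CD8 before
#' merging), `donor_pool`, `cohort`, `scan_batch`.
#'
#' @param path TSV path.
#' @return A data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "cell_type", "donor_pool", "cohort", "scan_batch")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in metadata: ", dup[1L], call. = FALSE)
  df
}

#' @rdname read_sample_metadata
#' @param meta Metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_metadata <- function(x, meta) {
  miss <- setdiff(colnames(x), meta$sample_id)
  if (length(miss))
    stop("sample without metadata row: ", miss[1L], call. = FALSE)
  meta[match(colnames(x), meta$sample_id), , drop = FALSE]
}

#' Cell-type scheme: raw labels, analysis groups and lineages
#'
#' Maps raw sorted-cell labels to analysis groups (CD4 and CD8 T cells are
#' analysed as a single "T" group) and each analysis group to its
#' hematopoietic lineage. `merge_map` must cover every raw label that can
#' appear in metadata; `lineage_map` must cover every analysis label.
#'
#' @param cell_types Ordered character vector of analysis labels.
#' @param merge_map Named character vector raw label -> analysis label.
#' @param lineage_map Named character vector analysis label -> lineage
#'   (`"myeloid"` or `"lymphoid"`).
#' @return A `cell_scheme` list.
#' @export
cell_scheme <- function(cell_types, merge_map, lineage_map) {
  if (!all(merge_map %in% cell_types))
    stop("merge_map targets must be analysis cell types", call. = FALSE)
  if (!all(cell_types %in% names(lineage_map)))
    stop("lineage_map must cover every analysis cell type", call. = FALSE)
  structure(list(cell_types = cell_types, merge_map = merge_map,
                 lineage_map = lineage_map),
            class = "cell_scheme")
}

#' Default immune-cell scheme
#'
#' The eight analysis groups of the sorted-blood design: neutrophils,
#' eosinophils, monocytes and mDCs (myeloid) plus T, B, NK cells and pDCs
#' (lymphoid), with CD4/CD8 raw labels merged into "T".
#'
#' @return A [cell_scheme()].
#' @export
default_cell_scheme <- function() {
  ana <- c("Neutrophils", "Eosinophils", "Monocytes", "mDC",
           "T", "B", "NK", "pDC")
  merge <- c(stats::setNames(ana, ana), CD4 = "T", CD8 = "T")
  lin <- stats::setNames(c(rep("myeloid", 4), rep("lymphoid", 4)), ana)
  cell_scheme(ana, merge, lin)
}

analysis_labels <- function(meta, scheme) {
  raw <- meta$cell_type
  unknown <- setdiff(unique(raw), names(scheme$merge_map))
  if (length(unknown))
    stop("cell type not in merge_map: ", unknown[1L], call. = FALSE)
  unname(scheme$merge_map[raw])
}

#' Read a target-prediction table
#'
#' TSV columns `mirna_family`, `gene`, `chrom`, `start`, `end`, `sources`
#' (semicolon-separated labels such as targetscan;mirdb). Seed-site
#' intervals are 0-based half-open; rows with `start >= end` are rejected.
#'
#' @param path TSV path.
#' @return A data.frame of class `prediction_table` with `sources` kept as
#'   the semicolon-joined string (use [prediction_sources()] for the parsed
#'   sets).
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("mirna_family", "gene", "chrom", "start", "end", "sources")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("prediction table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  prediction_table(df)
}

#' @rdname read_prediction_table
#' @param df Data.frame with the prediction-table columns.
#' @export
prediction_table <- function(df) {
  if (any(df$start >= df$end))
    stop("seed-site interval with start >= end (0-based half-open required)",
         call. = FALSE)
  key <- with(df, paste(mirna_family, gene, chrom, start, end))
  if (anyDuplicated(key))
    stop("duplicate prediction row: ", key[duplicated(key)][1L],
         call. = FALSE)
  class(df) <- c("prediction_table", "data.frame")
  df
}

#' @rdname read_prediction_table
#' @export
prediction_sources <- function(df) strsplit(df$sources, ";", fixed = TRUE)

#' @rdname read_prediction_table
#' @export
write_prediction_table <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep predictions confirmed by at least one other database
#'
#' Retains rows whose source set contains `targetscan` plus at least one
#' additional source (computational: miranda, mirdb; experimental:
#' mir2disease, tarbase). Row order is preserved.
#'
#' @param df A `prediction_table`.
#' @return The filtered `prediction_table`.
#' @export
filter_confirmed_predictions <- function(df) {
  src <- prediction_sources(df)
  keep <- vapply(src, function(s) "targetscan" %in% s && length(s) >= 2L,
                 logical(1L))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Export seed-site intervals as BED
#'
#' Writes the 0-based half-open seed-site intervals of a prediction table in
#' BED format (name = mirna_family|gene).
#'
#' @param df A `prediction_table`.
#' @param path Output path.
#' @export
write_seed_sites_bed <- function(df, path) {
  bed <- data.frame(df$chrom, df$start, df$end,
                    paste(df$mirna_family, df$gene, sep = "|"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a knockout fold-change table
#'
#' Two TSV columns: `gene` and `linear_fc` (linear-scale treatment/control
#' ratio, strictly positive).
#'
#' @param path TSV path.
#' @return Data.frame with columns `gene`, `linear_fc`.
#' @export
read_fold_changes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "linear_fc") %in% names(df)))
    stop("fold-change table needs columns gene, linear_fc", call. = FALSE)
  df$linear_fc <- as.numeric(df$linear_fc)
  if (anyNA(df$linear_fc) || any(df$linear_fc <= 0))
    stop("linear_fc must be positive and numeric", call. = FALSE)
  df
}
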