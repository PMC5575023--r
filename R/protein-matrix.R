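#' Protein abundance matrix with site and bridge annotations
#'
#' Container for log2 relative protein abundances from a (possibly) two-site
#' design. Columns are measurement records: a bridge sample measured at both
#' sites contributes two records with the same `sample_id` and different
#' `site`, which is why `sample_ids` may repeat until
#' [batch_correct_bridge()] merges them.
#'
#' @param values Numeric matrix, proteins in rows, records in columns. May
#'   contain `NA` (removed by [drop_missing()]).
#' @param protein_ids Unique protein identifiers (default: rownames).
#' @param sample_ids Per-record sample identifiers (default: colnames);
#'   repeats are only allowed for bridge samples across the two sites.
#' @param site Per-record site label, `"A"` or `"B"`; defaults to all `"A"`.
#' @param bridge_ids Identifiers of samples measured at both sites.
#' @return An object of class `"protein_matrix"`.
#' @export
protein_matrix <- function(values, protein_ids = rownames(values),
                           sample_ids = colnames(values), site = NULL,
                           bridge_ids = character()) {
  values <- as.matrix(values)
  if (!nrow(values) || !ncol(values)) stop("empty protein matrix")
  if (is.null(protein_ids) || length(protein_ids) != nrow(values)) {
    stop("`protein_ids` must name every row")
  }
  if (anyDuplicated(protein_ids)) stop("`protein_ids` must be unique")
  if (is.null(sample_ids) || length(sample_ids) != ncol(values)) {
    stop("`sample_ids` must name every column (record)")
  }
  if (is.null(site)) site <- rep("A", ncol(values))
  site <- as.character(site)
  if (length(site) != ncol(values) || !all(site %in% c("A", "B"))) {
    stop("`site` must be an 'A'/'B' label per record")
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(setdiff(dup, bridge_ids))) {
    stop("duplicated sample_ids are only allowed for bridge samples")
  }
  rownames(values) <- protein_ids
  structure(list(values = values, protein_ids = protein_ids,
                 sample_ids = sample_ids, site = site,
                 bridge_ids = as.character(bridge_ids)),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d records (%d unique samples)\n",
              nrow(x$values), ncol(x$values), length(unique(x$sample_ids))))
  cat(sprintf("  sites: A = %d, B = %d; bridge samples: %d; missing values: %d\n",
              sum(x$site == "A"), sum(x$site == "B"),
              length(x$bridge_ids), sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.matrix.protein_matrix <- function(x, ...) x$values

#' Model design matrix from a protein matrix
#'
#' Transposes a (merged, one record per sample) [protein_matrix()] into the
#' samples x proteins orientation used by [sogl_cox()] and the evaluation
#' functions.
#'
#' @param m A `"protein_matrix"` with unique sample identifiers.
#' @return Numeric matrix, samples in rows (named by sample), proteins in
#'   columns.
#' @export
design_matrix <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  if (anyDuplicated(m$sample_ids)) {
    stop("bridge records must be merged first (see batch_correct_bridge)")
  }
  t(structure(m$values, dimnames = list(m$protein_ids, m$sample_ids)))
}

#' Write / read a protein matrix as TSV
#'
#' The expression file has proteins in rows with a leading `protein_id`
#' column; expression columns are record identifiers `<sample>_<site>`. The
#' companion sample-annotation file has one row per record with columns
#' `record_id`, `sample_id`, `site`, `is_bridge`.
#'
#' @param m A `"protein_matrix"`.
#' @param expr_path,samples_path Output (or input) file paths.
#' @return `write_protein_matrix()` returns the paths invisibly;
#'   `read_protein_matrix()` returns a `"protein_matrix"`.
#' @export
write_protein_matrix <- function(m, expr_path, samples_path) {
  stopifnot(inherits(m, "protein_matrix"))
  rec <- paste(m$sample_ids, m$site, sep = "_")
  df <- data.frame(protein_id = m$protein_ids,
                   .fmt_num_df(as.data.frame(m$values)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("protein_id", rec)
  .write_tsv(df, expr_path)
  ann <- data.frame(record_id = rec, sample_id = m$sample_ids, site = m$site,
                    is_bridge = as.integer(m$sample_ids %in% m$bridge_ids),
                    stringsAsFactors = FALSE)
  .write_tsv(ann, samples_path)
  invisible(c(expr_path, samples_path))
}

#' @rdname write_protein_matrix
#' @export
read_protein_matrix <- function(expr_path, samples_path) {
  expr <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- read.delim(samples_path, stringsAsFactors = FALSE)
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!identical(colnames(vals), ann$record_id)) {
    stop("sample annotation does not match the expression columns")
  }
  protein_matrix(vals, protein_ids = expr$protein_id,
                 sample_ids = ann$sample_id, site = ann$site,
                 bridge_ids = unique(ann$sample_id[ann$is_bridge == 1]))
}

# TSV writers with a fixed numeric rendering so identical analyses produce
# byte-identical artifacts.
.fmt_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
  }
  df
}

.write_tsv <- function(df, path) {
  write.table(.fmt_num_df(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
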