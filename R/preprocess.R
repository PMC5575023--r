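# Data-preparation steps for two-site proteomics: per-sample median
# re-centering, bridge-sample batch correction, missing-protein exclusion and
# one-protein-per-gene deduplication. Applied in that order by preprocess();
# every step is idempotent.

#' Re-centre every sample to median zero
#'
#' Shifts each record (column) by a constant so that its median over
#' non-missing proteins is exactly zero, removing per-sample loading and
#' laboratory-condition offsets on the log2 scale.
#'
#' @param m A [protein_matrix()].
#' @return The re-centred `"protein_matrix"`.
#' @export
median_recenter <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  med <- apply(m$values, 2, median, na.rm = TRUE)
  if (any(is.na(med))) stop("every sample needs at least one non-missing value")
  m$values <- sweep(m$values, 2, med)
  m
}

#' Bridge-sample batch correction between two sites
#'
#' For every protein, shifts all site-B records by
#' \eqn{\Delta_p = \mathrm{median}_A(\mathrm{bridge}) -
#' \mathrm{median}_B(\mathrm{bridge})}, the difference of the protein's
#' medians over the bridge samples measured at both sites, so that the two
#' per-protein bridge medians are equalized. Site-A values are untouched.
#' The bridge duplicates are then merged to one record per sample, keeping
#' the site-A record.
#'
#' @param m A [protein_matrix()] with non-empty `bridge_ids`, each bridge
#'   sample having a record at both sites.
#' @return A `"protein_matrix"` with unique sample identifiers and the
#'   per-protein site shift removed.
#' @export
batch_correct_bridge <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  if (!length(m$bridge_ids)) {
    stop("no bridge samples: batch correction is impossible; ",
         "skip this step explicitly for single-site data")
  }
  ba <- m$sample_ids %in% m$bridge_ids & m$site == "A"
  bb <- m$sample_ids %in% m$bridge_ids & m$site == "B"
  if (!any(bb) && !anyDuplicated(m$sample_ids)) {
    return(m)  # already corrected and merged; the step is idempotent
  }
  has_a <- unique(m$sample_ids[ba])
  has_b <- unique(m$sample_ids[bb])
  if (!setequal(has_a, m$bridge_ids) || !setequal(has_b, m$bridge_ids)) {
    stop("every bridge sample must have a record at both sites")
  }
  med_a <- apply(m$values[, ba, drop = FALSE], 1, median, na.rm = TRUE)
  med_b <- apply(m$values[, bb, drop = FALSE], 1, median, na.rm = TRUE)
  delta <- med_a - med_b
  isb <- m$site == "B"
  m$values[, isb] <- m$values[, isb, drop = FALSE] + delta
  drop_cols <- bb  # keep the site-A record of every bridge sample
  protein_matrix(m$values[, !drop_cols, drop = FALSE],
                 protein_ids = m$protein_ids,
                 sample_ids = m$sample_ids[!drop_cols],
                 site = m$site[!drop_cols],
                 bridge_ids = m$bridge_ids)
}

#' Exclude proteins with missing values
#'
#' Keeps only proteins quantified in every record, avoiding imputation.
#' Row order is preserved.
#'
#' @param m A [protein_matrix()].
#' @return A `"protein_matrix"` without missing entries.
#' @export
drop_missing <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  keep <- rowSums(is.na(m$values)) == 0
  if (!any(keep)) stop("every protein has missing values; nothing left")
  protein_matrix(m$values[keep, , drop = FALSE],
                 protein_ids = m$protein_ids[keep],
                 sample_ids = m$sample_ids, site = m$site,
                 bridge_ids = m$bridge_ids)
}

# Numeric part of an accession such as "NP_002737" or "NP_002737.2";
# non-conforming accessions fall back to lexicographic comparison only.
.accession_number <- function(acc) {
  core <- sub("\\..*$", "", acc)
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z_]+", "", core)))
  ifelse(is.na(num), Inf, num)
}

#' Keep one representative protein per gene
#'
#' When several proteins map to the same gene, keeps the one with the
#' minimum accession: accessions are compared by their numeric part after
#' stripping the letter/underscore prefix (so `NP_002737` precedes
#' `NP_620581`), with lexicographic comparison of the full string breaking
#' ties. Row order of the retained proteins is preserved.
#'
#' @param m A [protein_matrix()].
#' @param id_map Data frame with columns `protein_id`, `gene_id` and
#'   `accession`, covering every protein in `m`.
#' @return A deduplicated `"protein_matrix"`.
#' @export
dedup_by_gene <- function(m, id_map) {
  stopifnot(inherits(m, "protein_matrix"))
  need <- c("protein_id", "gene_id", "accession")
  if (!all(need %in% names(id_map))) {
    stop("`id_map` needs columns protein_id, gene_id, accession")
  }
  pos <- match(m$protein_ids, id_map$protein_id)
  if (anyNA(pos)) {
    stop("id map is missing protein(s): ",
         paste(head(m$protein_ids[is.na(pos)], 5L), collapse = ", "))
  }
  gene <- id_map$gene_id[pos]
  acc <- id_map$accession[pos]
  ord <- order(gene, .accession_number(acc), acc)
  keep_ids <- m$protein_ids[ord][!duplicated(gene[ord])]
  keep <- m$protein_ids %in% keep_ids
  protein_matrix(m$values[keep, , drop = FALSE],
                 protein_ids = m$protein_ids[keep],
                 sample_ids = m$sample_ids, site = m$site,
                 bridge_ids = m$bridge_ids)
}

#' Read a protein-to-gene identifier map
#'
#' @param path TSV with columns `protein_id`, `gene_id`, `accession` (the
#'   accession column may be omitted, in which case the protein identifier
#'   doubles as the accession).
#' @return A data frame usable by [dedup_by_gene()].
#' @export
read_id_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$accession)) df$accession <- df$protein_id
  df
}

#' Full data-preparation pipeline
#'
#' Applies, in order: [median_recenter()], [batch_correct_bridge()] (skipped
#' with a message when there are no bridge samples), [drop_missing()] and,
#' when an identifier map is given, [dedup_by_gene()].
#'
#' @param m A [protein_matrix()].
#' @param id_map Optional identifier map for deduplication.
#' @return A preprocessed `"protein_matrix"` with one record per sample.
#' @export
preprocess <- function(m, id_map = NULL) {
  m <- median_recenter(m)
  if (length(m$bridge_ids)) m <- batch_correct_bridge(m)
  m <- drop_missing(m)
  if (!is.null(id_map)) m <- dedup_by_gene(m, id_map)
  m
}
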