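# Pathway collections and enrichment screening: the retained pathways define
# the group structure for the SOGL Cox fit.

#' Pathway collection
#'
#' A named list of (possibly overlapping) protein sets plus the protein
#' universe they live in.
#'
#' @param sets Named list of character vectors (duplicates within a set are
#'   collapsed).
#' @param universe Protein universe; defaults to the union of all members.
#' @return An object of class `"pathway_collection"`.
#' @export
pathway_collection <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must be a non-empty, uniquely named list")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  structure(list(sets = sets, universe = as.character(universe)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("pathway_collection: %d pathways over %d proteins (sizes %d-%d)\n",
              length(x$sets), length(x$universe), min(sz), max(sz)))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' Each GMT line is `name<TAB>description<TAB>member...`; duplicate members
#' within a line are collapsed.
#'
#' @param path File path.
#' @return `read_gmt()` returns a [pathway_collection()] (the description
#'   fields are kept as the `descriptions` attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: expected name, description and >= 1 member",
                 bad[1]))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicated pathway names in GMT file")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  pc <- pathway_collection(sets)
  attr(pc, "descriptions") <- setNames(vapply(parts, `[[`, character(1), 2L), nm)
  pc
}

#' @rdname read_gmt
#' @param pathways A [pathway_collection()].
#' @param descriptions Optional named descriptions; defaults to the pathway id.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  stopifnot(inherits(pathways, "pathway_collection"))
  nm <- names(pathways$sets)
  if (is.null(descriptions)) descriptions <- setNames(nm, nm)
  lines <- vapply(nm, function(id) {
    paste(c(id, descriptions[[id]], pathways$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least the realized overlap between a pathway
#' and a hit set when `|hits|` draws are taken without replacement from a
#' universe containing `|pathway|` successes:
#' \eqn{P(X \ge k)} with \eqn{X \sim
#' \mathrm{Hypergeom}(|U|, |pathway|, |hits|)}.
#'
#' @param pathway,hits Character vectors; members outside `universe` are
#'   ignored.
#' @param universe Non-empty character vector.
#' @return A p-value in \eqn{[0, 1]}.
#' @export
hypergeometric_test <- function(pathway, hits, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  pathway <- intersect(unique(pathway), universe)
  hits <- intersect(unique(hits), universe)
  k <- length(intersect(pathway, hits))
  phyper(k - 1, length(pathway), length(universe) - length(pathway),
         length(hits), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; the order of the input is preserved.
#'
#' @param pvalues Numeric vector in \eqn{[0, 1]}.
#' @return Adjusted values in \eqn{[0, 1]}.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Univariate Cox screen for survival-associated proteins
#'
#' Fits a univariate Cox model (Breslow ties) per protein and returns those
#' with Wald p below the cutoff. This is the default "hit" definition feeding
#' [enrich_pathways()].
#'
#' @param x Samples x proteins matrix with protein column names.
#' @param time,event Survival outcome.
#' @param p_cutoff Wald p-value threshold (default 0.05).
#' @return Character vector of hit proteins, with the full screen table
#'   (protein_id, coef, p_value) as attribute `"table"`.
#' @export
cox_screen <- function(x, time, event, p_cutoff = 0.05) {
  x <- as.matrix(x)
  res <- vapply(seq_len(ncol(x)), function(j) {
    fit <- tryCatch(
      coxph(Surv(time, event) ~ x[, j], ties = "breslow"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit) || anyNA(coef(fit))) return(c(NA_real_, NA_real_))
    s <- summary(fit)$coefficients
    c(s[1, "coef"], s[1, "Pr(>|z|)"])
  }, numeric(2))
  tab <- data.frame(protein_id = colnames(x), coef = res[1, ],
                    p_value = res[2, ], stringsAsFactors = FALSE)
  hits <- tab$protein_id[!is.na(tab$p_value) & tab$p_value < p_cutoff]
  attr(hits, "table") <- tab
  hits
}

#' Pathway enrichment table
#'
#' Tests every pathway for over-representation of the hit set within the
#' universe ([hypergeometric_test()]) and adjusts across pathways with
#' [bh_fdr()]. Pathway membership is restricted to the universe first;
#' pathways with no member in the universe are dropped.
#'
#' @param pathways A [pathway_collection()].
#' @param hits Character vector of hit proteins.
#' @param universe Character vector, the analysis universe (e.g. proteins
#'   surviving preprocessing that map to at least one pathway).
#' @return Data frame with columns `pathway_id`, `size` (members in the
#'   universe), `hits` (overlap), `p_value`, `fdr`.
#' @export
enrich_pathways <- function(pathways, hits, universe) {
  stopifnot(inherits(pathways, "pathway_collection"))
  sets <- lapply(pathways$sets, intersect, y = universe)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("no pathway has members in the universe")
  p <- vapply(sets, hypergeometric_test, numeric(1),
              hits = hits, universe = universe)
  data.frame(
    pathway_id = names(sets),
    size = lengths(sets),
    hits = vapply(sets, function(s) length(intersect(s, hits)), integer(1)),
    p_value = unname(p),
    fdr = unname(bh_fdr(p)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Retain enriched pathways
#'
#' Keeps pathways with `fdr < threshold`, members restricted to the
#' universe. Proteins in no retained pathway drop out of the downstream
#' design by construction.
#'
#' @param pathways A [pathway_collection()].
#' @param table Enrichment table from [enrich_pathways()].
#' @param universe The analysis universe used for the table.
#' @param threshold FDR threshold in (0, 1), default 0.05.
#' @return A [pathway_collection()] of the retained pathways.
#' @export
select_enriched <- function(pathways, table, universe, threshold = 0.05) {
  stopifnot(inherits(pathways, "pathway_collection"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  keep <- table$pathway_id[table$fdr < threshold]
  if (!length(keep)) {
    stop(sprintf("no pathway enriched at fdr < %g: the grouped model is undefined",
                 threshold))
  }
  sets <- lapply(pathways$sets[keep], intersect, y = universe)
  pathway_collection(sets, universe = sort(unique(unlist(sets))))
}
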