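#' Expand a protein design matrix over overlapping pathway groups
#'
#' Builds the duplicated design used by the overlapping group lasso: one
#' column per (protein, pathway) membership, values copied from the protein's
#' column of `x`. A protein shared by k pathways therefore appears as k
#' latent copies, each belonging to exactly one group, which reduces the
#' overlapping-group penalty to an ordinary (non-overlapping) sparse group
#' lasso on the expanded matrix.
#'
#' @param x Numeric matrix, samples in rows, proteins in columns (column
#'   names are the protein identifiers).
#' @param pathways A [pathway_collection] or a named list of character
#'   vectors of protein identifiers. Every member must be a column of `x`.
#' @param group_weight Either `"sqrt_size"` (default; \eqn{d_g =
#'   \sqrt{|g|}}, the conventional group-lasso weight) or `"size"`
#'   (\eqn{d_g = |g|}).
#' @return A list with elements `xtilde` (the n x sum(|g|) duplicated
#'   matrix), `groups` (list of column-index vectors, one per pathway),
#'   `d_g` (group weights), `map` (data frame with one row per duplicated
#'   column: `column`, `protein_id`, `pathway_id`), `pathway_ids`, and
#'   `protein_ids` (unique proteins entering the design, in first-appearance
#'   order).
#' @examples
#' x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
#' ex <- expand_design(x, list(p1 = c("a", "b"), p2 = c("b", "c")))
#' ncol(ex$xtilde)  # 4: protein "b" is duplicated
#' @export
expand_design <- function(x, pathways, group_weight = c("sqrt_size", "size")) {
  group_weight <- match.arg(group_weight)
  x <- as.matrix(x)
  sets <- if (inherits(pathways, "pathway_collection")) pathways$sets else pathways
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("pathways must be uniquely named")
  }
  if (is.null(colnames(x))) stop("`x` must have protein identifiers as column names")
  sets <- lapply(sets, unique)
  missing <- setdiff(unique(unlist(sets)), colnames(x))
  if (length(missing)) {
    stop("pathway members absent from the expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  sizes <- lengths(sets)
  if (any(sizes == 0L)) stop("empty pathways cannot form penalty groups")
  map <- data.frame(
    column = seq_len(sum(sizes)),
    protein_id = unlist(sets, use.names = FALSE),
    pathway_id = rep(names(sets), sizes),
    stringsAsFactors = FALSE
  )
  xt <- x[, map$protein_id, drop = FALSE]
  colnames(xt) <- paste(map$protein_id, map$pathway_id, sep = "@")
  groups <- split(map$column, factor(map$pathway_id, levels = names(sets)))
  d_g <- switch(group_weight, sqrt_size = sqrt(sizes), size = as.numeric(sizes))
  list(
    xtilde = xt, groups = groups, d_g = unname(d_g), map = map,
    pathway_ids = names(sets), protein_ids = unique(map$protein_id),
    group_weight = group_weight
  )
}
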