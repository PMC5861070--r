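# Column filtering.  Two distinct rules are applied at different pipeline
# stages: complete deletion before tree building, modal-gap deletion before
# conservation profiling.

#' Remove every column containing a gap or missing symbol
#'
#' Complete deletion keeps exactly the columns where no sequence has `'-'`,
#' `'X'` or `'N'`.  The retained 1-based column indices are attached as
#' attribute `"retained"` for provenance.
#'
#' @param aln an [msa].
#' @return a filtered [msa] with attribute `retained`.
#' @export
complete_deletion <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  if (ncol(aln) == 0L) stop("empty alignment")
  keep <- which(colSums(matrix(.is_gap(aln), nrow = nrow(aln))) == 0L)
  if (length(keep) == 0L)
    stop("empty-after-filter: no columns survive complete deletion")
  out <- msa(unclass(aln)[, keep, drop = FALSE], type = attr(aln, "type"))
  attr(out, "retained") <- keep
  out
}

#' Remove columns whose modal symbol is a gap
#'
#' A column is dropped only when the gap/missing class (`'-'`, `'X'`, `'N'`,
#' pooled) is strictly the most frequent symbol.  Ties between the gap class
#' and a residue keep the column, so conservation analysis retains the
#' maximal set of usable sites.
#'
#' @inheritParams complete_deletion
#' @return a filtered [msa] with attribute `retained`.
#' @export
modal_gap_deletion <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  if (ncol(aln) == 0L) stop("empty alignment")
  gap_mat <- matrix(.is_gap(aln), nrow = nrow(aln))
  n_gap <- colSums(gap_mat)
  max_res <- vapply(seq_len(ncol(aln)), function(j) {
    res <- aln[!gap_mat[, j], j]
    if (length(res) == 0L) 0L else max(tabulate(factor(res)))
  }, 0L)
  keep <- which(n_gap <= max_res)
  if (length(keep) == 0L)
    stop("empty-after-filter: no columns survive modal-gap deletion")
  out <- msa(unclass(aln)[, keep, drop = FALSE], type = attr(aln, "type"))
  attr(out, "retained") <- keep
  out
}

#' Write retained-column provenance to TSV
#' @param aln a filtered [msa] carrying a `retained` attribute.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_retained_columns <- function(aln, path) {
  ret <- attr(aln, "retained")
  if (is.null(ret)) stop("alignment carries no 'retained' attribute")
  utils::write.table(
    data.frame(filtered_column = seq_along(ret), source_column = ret),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
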