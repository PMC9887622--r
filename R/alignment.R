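#' Construct a protein alignment with column maps
#'
#' Wraps a set of equal-length gapped sequences together with, per row, the
#' bidirectional map between alignment columns and ungapped residue indices
#' (both 1-based). The map is the backbone of intron projection: a residue's
#' column is where its intron evidence lands, and only non-gap cells can
#' carry intron presence.
#'
#' @param seqs Named character vector of aligned sequences (gap `-`).
#' @return An object of class `protein_alignment` with elements `ids`,
#'   `seqs`, `width`, `res2col` (per row: column of residue k) and `col2res`
#'   (per row: residue index at column c, `NA` at gaps).
#' @export
protein_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("rows have unequal lengths: ", paste(unique(widths), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  res2col <- vector("list", length(seqs))
  col2res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    is_res <- chars != "-"
    res2col[[i]] <- which(is_res)
    cr <- rep(NA_integer_, length(chars))
    cr[is_res] <- seq_len(sum(is_res))
    col2res[[i]] <- cr
  }
  names(res2col) <- names(seqs)
  names(col2res) <- names(seqs)
  structure(
    list(ids = names(seqs), seqs = seqs, width = widths[[1]],
         res2col = res2col, col2res = col2res),
    class = "protein_alignment"
  )
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> ", length(x$ids), " sequences x ", x$width,
      " columns\n", sep = "")
  invisible(x)
}

## alignment column of residue k in a row; errors if k out of range
column_of_residue <- function(aln, id, residue_index) {
  map <- aln$res2col[[id]]
  if (is.null(map)) stop("sequence '", id, "' not in alignment")
  if (any(residue_index < 1 | residue_index > length(map))) {
    stop("residue index out of range for '", id, "' (length ", length(map), ")")
  }
  map[residue_index]
}

## residue index at an alignment column in a row; NA if gapped there
residue_at_column <- function(aln, id, column) {
  map <- aln$col2res[[id]]
  if (is.null(map)) stop("sequence '", id, "' not in alignment")
  if (any(column < 1 | column > aln$width)) stop("column out of range")
  map[column]
}

## residue character at a column, "-" if gapped
char_at_column <- function(aln, id, column) {
  substr(aln$seqs[[id]], column, column)
}

#' Remove gap-rich columns from an alignment
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are removed (a
#' fraction exactly equal to the threshold is kept). Trimming is intended for
#' tree-inference inputs only; intron mapping always operates on the
#' untrimmed alignment, and the returned column map re-expresses trimmed
#' columns in original coordinates.
#'
#' @param aln A [protein_alignment()].
#' @param max_gap_fraction Maximum tolerated gap fraction per column, in
#'   (0, 1].
#' @return List with `alignment` (trimmed [protein_alignment()]) and
#'   `column_map` (integer vector: original column of each kept column).
#' @export
trim_alignment <- function(aln, max_gap_fraction) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (!(max_gap_fraction > 0 && max_gap_fraction <= 1)) {
    stop("max_gap_fraction must be in (0, 1]")
  }
  mat <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0) {
    stop("all ", aln$width, " columns exceed the gap threshold ", max_gap_fraction)
  }
  trimmed <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(trimmed) <- aln$ids
  list(alignment = protein_alignment(trimmed), column_map = keep)
}
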