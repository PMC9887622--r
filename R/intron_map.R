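#' Derive protein-coordinate intron positions from a gene model
#'
#' Each junction between consecutive CDS segments is an intron. With `n` the
#' number of coding nucleotides 5' of the junction (counted on the mRNA, so
#' minus-strand genes are read right to left), the intron is assigned
#' `residue_index = floor(n/3) + 1` and `phase = n mod 3`. Phase-0 introns
#' are therefore anchored to the residue immediately following the intron.
#' Terminal introns are impossible by construction (`0 < n < ` CDS length).
#'
#' @param gene A [gene_model()].
#' @return Data frame with columns `protein_id`, `residue_index`, `phase`;
#'   zero rows for a single-segment (intronless) gene.
#' @export
gene_to_protein_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  seg <- gene$cds_segments
  lens <- seg[, "end"] - seg[, "start"] + 1L
  if (gene$strand == "-") lens <- rev(lens)  # mRNA order is reversed genomic
  m <- length(lens)
  if (m == 1) {
    return(data.frame(protein_id = character(0), residue_index = integer(0),
                      phase = integer(0)))
  }
  n <- cumsum(lens)[-m]  # coding nt 5' of each junction
  data.frame(
    protein_id = rep(gene$protein_id, m - 1L),
    residue_index = as.integer(n %/% 3L + 1L),
    phase = as.integer(n %% 3L)
  )
}

## canonical site id for a (column, phase) pair
site_id <- function(column, phase) paste0(column, ".", phase)

#' Project protein introns onto an alignment
#'
#' Maps each intron's residue index to its alignment column through the
#' alignment's column map and merges identical (column, phase) pairs across
#' rows into one homologous intron site. Introns occurring at the same
#' column but a different phase remain distinct sites.
#'
#' @param aln A [protein_alignment()].
#' @param introns Data frame with columns `protein_id`, `residue_index`,
#'   `phase` (e.g. row-bound outputs of [gene_to_protein_introns()]). Every
#'   `protein_id` must be a row of `aln`.
#' @return An object of class `intron_matrix`: list with `presence` (binary
#'   matrix, rows = alignment ids, columns = sites ordered by (column,
#'   phase), column names `"<column>.<phase>"`), `sites` (data frame
#'   `site`, `column`, `phase`) and `alignment`.
#' @export
project_introns <- function(aln, introns) {
  stopifnot(inherits(aln, "protein_alignment"))
  req <- c("protein_id", "residue_index", "phase")
  if (!all(req %in% colnames(introns))) {
    stop("introns must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(introns)) {
    missing <- setdiff(unique(introns$protein_id), aln$ids)
    if (length(missing)) {
      stop("protein(s) with introns absent from alignment: ",
           paste(missing, collapse = ", "))
    }
    if (any(!introns$phase %in% 0:2)) stop("phase must be 0, 1 or 2")
  }
  cols <- integer(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    id <- introns$protein_id[i]
    k <- introns$residue_index[i]
    nres <- length(aln$res2col[[id]])
    if (k < 1 || k > nres) {
      stop("intron residue index ", k, " out of range for protein '", id,
           "' (", nres, " residues)")
    }
    cols[i] <- aln$res2col[[id]][k]
  }
  sites <- unique(data.frame(column = cols, phase = introns$phase))
  sites <- sites[order(sites$column, sites$phase), , drop = FALSE]
  rownames(sites) <- NULL
  ids <- if (nrow(sites)) site_id(sites$column, sites$phase) else character(0)
  sites <- cbind(site = ids, sites)

  mat <- matrix(0L, nrow = length(aln$ids), ncol = nrow(sites),
                dimnames = list(aln$ids, ids))
  if (nrow(introns)) {
    key <- site_id(cols, introns$phase)
    for (i in seq_len(nrow(introns))) {
      mat[introns$protein_id[i], key[i]] <- 1L
    }
  }
  structure(list(presence = mat, sites = sites, alignment = aln),
            class = "intron_matrix")
}

#' @export
print.intron_matrix <- function(x, ...) {
  cat("<intron_matrix> ", nrow(x$presence), " sequences x ",
      ncol(x$presence), " intron sites\n", sep = "")
  invisible(x)
}

#' Back-project an intron site into one protein's coordinates
#'
#' Inverse of [project_introns()] for a single row: returns the protein
#' intron where the row carries a residue at the site's column, or `NULL`
#' when the row is gapped there.
#'
#' @param im An `intron_matrix` from [project_introns()].
#' @param site Site id (`"<column>.<phase>"`) or site row index.
#' @param row Alignment row id.
#' @return List with `protein_id`, `residue_index`, `phase`, or `NULL`.
#' @export
back_project <- function(im, site, row) {
  stopifnot(inherits(im, "intron_matrix"))
  s <- if (is.numeric(site)) im$sites[site, ] else im$sites[im$sites$site == site, ]
  if (nrow(s) != 1) stop("unknown site: ", site)
  res <- residue_at_column(im$alignment, row, s$column)
  if (is.na(res)) return(NULL)
  list(protein_id = row, residue_index = as.integer(res), phase = as.integer(s$phase))
}

#' Write / read an intron presence matrix as TSV
#'
#' The serialization has one row per sequence and one `"<column>.<phase>"`
#' header per homologous intron site.
#'
#' @param im An `intron_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_matrix <- function(im, path) {
  df <- data.frame(id = rownames(im$presence), im$presence,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_intron_matrix
#' @return For `read_intron_matrix`: a binary matrix with site-id columns.
#' @export
read_intron_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  mat
}
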