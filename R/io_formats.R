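#' Read a FASTA file
#'
#' Reads aligned or unaligned FASTA. Sequences are uppercased and the
#' alternative gap character `.` is normalized to `-`; gaps are retained so
#' alignments round-trip. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()] for uppercase sequences with `-` gaps.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model is one protein-coding gene: its ordered coding-exon (CDS)
#' segments in genomic coordinates (1-based, inclusive), the strand, and ids.
#' It is the carrier from which intron positions in protein coordinates are
#' derived.
#'
#' @param gene_id Gene identifier.
#' @param seq_region Sequence region (contig/chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments Two-column matrix or data frame of (start, end)
#'   nucleotide coordinates in genomic order.
#' @param protein_id Protein identifier; defaults to `gene_id`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_region, strand, cds_segments,
                       protein_id = gene_id) {
  seg <- as.matrix(cds_segments)
  storage.mode(seg) <- "integer"
  colnames(seg) <- c("start", "end")
  if (nrow(seg) < 1) stop("gene ", gene_id, ": at least one CDS segment required")
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": strand must be '+' or '-'")
  if (any(seg[, "end"] < seg[, "start"])) {
    stop("gene ", gene_id, ": segment end before start")
  }
  seg <- seg[order(seg[, "start"]), , drop = FALSE]
  if (nrow(seg) > 1 && any(seg[-1, "start"] <= seg[-nrow(seg), "end"])) {
    stop("gene ", gene_id, ": overlapping CDS segments")
  }
  total <- sum(seg[, "end"] - seg[, "start"] + 1L)
  if (total %% 3L != 0L) {
    stop("gene ", gene_id, ": total CDS length ", total, " not divisible by 3")
  }
  structure(
    list(gene_id = gene_id, seq_region = seq_region, strand = strand,
         cds_segments = seg, protein_id = protein_id),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " (", x$strand, ") ",
      nrow(x$cds_segments), " CDS segment(s), ",
      sum(x$cds_segments[, "end"] - x$cds_segments[, "start"] + 1L),
      " coding nt\n", sep = "")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses CDS features and groups them by a parent attribute into one
#' [gene_model()] per gene. Segments are sorted by genomic coordinate; the
#' strand is recorded so downstream nucleotide counting is 5'->3' on the
#' mRNA.
#'
#' @param gff_path Path to a GFF3 file.
#' @param feature_type Feature type to collect (default `"CDS"`).
#' @param id_attribute Attribute naming the parent gene (default `"Parent"`).
#' @return List of `gene_model` objects, ordered by first appearance.
#' @export
read_gff_genes <- function(gff_path, feature_type = "CDS",
                           id_attribute = "Parent") {
  if (!file.exists(gff_path)) stop("GFF file does not exist: ", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  gr <- gr[as.character(mc$type) == feature_type]
  if (length(gr) == 0) stop("no '", feature_type, "' features in ", gff_path)
  mc <- S4Vectors::mcols(gr)
  if (!id_attribute %in% colnames(mc)) {
    stop("attribute '", id_attribute, "' absent from ", feature_type,
         " features in ", gff_path)
  }
  pid <- mc[[id_attribute]]
  # Parent-style attributes come back as a CharacterList
  if (methods::is(pid, "List")) {
    lens <- lengths(pid)
    if (any(lens != 1L)) {
      stop("feature with ", ifelse(any(lens == 0), "missing", "multiple"),
           " '", id_attribute, "' value(s) in ", gff_path)
    }
    pid <- unlist(pid)
  }
  pid <- as.character(pid)
  prot <- if ("protein_id" %in% colnames(mc)) as.character(mc$protein_id) else pid
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  seqs <- as.character(GenomicRanges::seqnames(gr))

  out <- list()
  for (g in unique(pid)) {
    sel <- which(pid == g)
    st <- unique(strands[sel])
    if (length(st) != 1 || !st %in% c("+", "-")) {
      stop("gene ", g, ": CDS segments on mixed or missing strands")
    }
    if (length(unique(seqs[sel])) != 1) {
      stop("gene ", g, ": CDS segments on multiple sequence regions")
    }
    out[[g]] <- gene_model(
      gene_id = g, seq_region = seqs[sel][1], strand = st,
      cds_segments = cbind(start = starts[sel], end = ends[sel]),
      protein_id = prot[sel][1]
    )
  }
  out
}

#' Read a rooted Newick tree
#'
#' @param path Path to a Newick file holding a single rooted tree. Missing
#'   branch lengths default to 0.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file does not exist: ", path)
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    stop("file contains ", length(tree), " trees; a single rooted tree is required: ", path)
  }
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (!ape::is.rooted(tree)) {
    stop("tree in ", path, " is unrooted (trifurcating root); ",
         "root it before use, e.g. with an outgroup")
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in ", path)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in ", path)
  tree
}

#' Write a tree to Newick
#'
#' Round-trips topology, branch lengths (to printed precision) and labels
#' with [read_newick()].
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a tab-separated table with a required schema
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"numeric"`, `"logical"`), or a bare
#'   character vector of required column names. Columns not in the schema are
#'   kept as character.
#' @return A data frame (possibly zero rows).
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("table does not exist: ", path)
  if (is.null(names(schema))) schema <- setNames(rep("character", length(schema)), schema)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), colnames(df))
  if (length(missing)) {
    stop("required column(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(
      schema[[col]],
      character = df[[col]],
      integer = as.integer(df[[col]]),
      numeric = as.numeric(df[[col]]),
      logical = as.logical(df[[col]]),
      stop("unknown schema type '", schema[[col]], "' for column ", col)
    )
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
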