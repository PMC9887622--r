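#' Detect gene duplications by species overlap
#'
#' A node of a rooted gene tree is flagged as a duplication when the
#' species sets of its two children intersect (the species-overlap
#' criterion of gene-tree/species-tree reconciliation).
#'
#' @param gene_tree Rooted, binary `phylo` gene tree.
#' @param species_map Named character vector tip -> species.
#' @return Object of class `duplication_set`: list of records, each with
#'   `node` (key), `tips_a`, `tips_b` (tip labels of the two child clades)
#'   and `shared_species`.
#' @export
find_duplications <- function(gene_tree, species_map) {
  tips <- gene_tree$tip.label
  missing <- setdiff(tips, names(species_map))
  if (length(missing)) {
    stop("tip(s) without species mapping: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tips)
  ch <- children_list(gene_tree)
  dtips <- descendant_tips(gene_tree)
  keys <- node_keys(gene_tree)
  out <- list()
  for (v in (ntip + 1L):n_nodes_total(gene_tree)) {
    kids <- ch[[v]]
    if (length(kids) != 2) {
      stop("node ", keys[v], " is multifurcating; resolve the tree first")
    }
    sp_a <- unique(species_map[tips[dtips[[kids[1]]]]])
    sp_b <- unique(species_map[tips[dtips[[kids[2]]]]])
    shared <- intersect(sp_a, sp_b)
    if (length(shared)) {
      out[[length(out) + 1L]] <- list(
        node = keys[v],
        tips_a = tips[dtips[[kids[1]]]],
        tips_b = tips[dtips[[kids[2]]]],
        shared_species = shared
      )
    }
  }
  structure(out, class = "duplication_set")
}

#' @export
print.duplication_set <- function(x, ...) {
  cat("<duplication_set> ", length(x), " duplication node(s): ",
      paste(vapply(x, `[[`, character(1), "node"), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

## per-duplication, per-column side residue: the unique residue shared by
## all non-gap tips of the side, else NA
side_residues <- function(aln, side_tips_list) {
  width <- aln$width
  k <- length(side_tips_list)
  out <- matrix(NA_character_, nrow = k, ncol = width)
  for (d in seq_len(k)) {
    tips <- side_tips_list[[d]]
    chars <- do.call(rbind, strsplit(unname(aln$seqs[tips]), "", fixed = TRUE))
    for (c in seq_len(width)) {
      v <- chars[, c]
      v <- v[v != "-"]
      if (length(v) && all(v == v[1])) out[d, c] <- v[1]
    }
  }
  out
}

## score one fate assignment; z[d] = TRUE means side B of duplication d is
## fate 1. Returns list(score, columns).
score_fate_assignment <- function(z, A, B, differ, req) {
  width <- ncol(A)
  support <- integer(0)
  cand <- which(colSums(differ) >= pmax(req, 2L))
  for (c in cand) {
    contributing <- which(differ[, c])
    if (length(contributing) < max(req[c], 2L)) next
    f1 <- ifelse(z[contributing], B[contributing, c], A[contributing, c])
    f2 <- ifelse(z[contributing], A[contributing, c], B[contributing, c])
    if (all(f1 == f1[1]) && all(f2 == f2[1])) support <- c(support, c)
  }
  list(score = length(support), columns = support)
}

#' Partition paralogs of independent duplications into recurrent fates
#'
#' Searches over fate assignments (one binary side choice per duplication,
#' with the global fate1/fate2 flip removed) for the assignment maximizing
#' the recurrence score: the number of alignment columns at which at least
#' `min_events` duplications have both paralog sides non-gap with differing
#' residues, all fate-1 sides share one residue and all fate-2 sides share
#' a different one. The search is exhaustive up to 12 duplications; beyond
#' that, assignments proposed by each two-state column seed a greedy
#' single-flip refinement (the all-or-nothing column score offers no
#' gradient to unseeded hill climbing).
#'
#' @param aln A [protein_alignment()] (or named character vector) of the
#'   aligned paralogs.
#' @param duplications A [find_duplications()] result (or list of records
#'   with `tips_a`, `tips_b`); at least two duplications.
#' @param min_events Minimum number of contributing duplications per
#'   supporting column. Default: every duplication with data at the column
#'   (and never fewer than 2).
#' @return Object of class `fate_analysis`: list with `score`,
#'   `supporting_columns`, `assignment` (data frame `node`, `fate1_side` in
#'   `"A"`/`"B"`), `paralog_fates` (named character per tip:
#'   `fate1`/`fate2`/`unassigned`) and `n_duplications`.
#' @export
fate_partition <- function(aln, duplications, min_events = NULL) {
  if (!inherits(aln, "protein_alignment")) aln <- protein_alignment(aln)
  k <- length(duplications)
  if (k < 2) {
    stop("recurrence is undefined for a single duplication; at least two ",
         "independent duplications are required")
  }
  A <- side_residues(aln, lapply(duplications, `[[`, "tips_a"))
  B <- side_residues(aln, lapply(duplications, `[[`, "tips_b"))
  has_data <- !is.na(A) & !is.na(B)
  differ <- has_data & (A != B)
  differ[is.na(differ)] <- FALSE
  req <- if (is.null(min_events)) {
    pmax(colSums(has_data), 2L)
  } else {
    rep(max(as.integer(min_events), 2L), ncol(A))
  }

  best <- list(score = -1L, columns = integer(0))
  best_z <- rep(FALSE, k)
  consider <- function(z) {
    s <- score_fate_assignment(z, A, B, differ, req)
    if (s$score > best$score) {
      best <<- s
      best_z <<- z
    }
  }
  if (k <= 12) {
    for (bits in 0:(2^(k - 1L) - 1L)) {
      z <- c(FALSE, as.logical(bitwAnd(bits %/% 2^(0:(k - 2L)), 1L)))
      consider(z)
    }
  } else {
    consider(rep(FALSE, k))
    # seed from each column where every data-bearing duplication differs
    # over exactly two residues
    seeds <- which(colSums(differ) >= pmax(req, 2L))
    for (c in seeds) {
      contributing <- which(differ[, c])
      ref <- A[contributing[1], c]
      z <- rep(FALSE, k)
      z[contributing] <- A[contributing, c] != ref
      consider(z)
    }
    # greedy single-flip refinement
    repeat {
      improved <- FALSE
      for (d in seq_len(k)) {
        z <- best_z
        z[d] <- !z[d]
        s <- score_fate_assignment(z, A, B, differ, req)
        if (s$score > best$score) {
          best <- s
          best_z <- z
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }

  nodes <- vapply(duplications, function(r) {
    if (is.null(r$node)) NA_character_ else r$node
  }, character(1))
  assignment <- data.frame(node = nodes,
                           fate1_side = ifelse(best_z, "B", "A"))
  paralog_fates <- character(0)
  for (d in seq_len(k)) {
    a <- duplications[[d]]$tips_a
    b <- duplications[[d]]$tips_b
    if (best$score > 0) {
      fa <- if (best_z[d]) "fate2" else "fate1"
      fb <- if (best_z[d]) "fate1" else "fate2"
    } else {
      fa <- fb <- "unassigned"
    }
    paralog_fates[a] <- fa
    paralog_fates[b] <- fb
  }
  structure(
    list(score = best$score, supporting_columns = best$columns,
         assignment = assignment, paralog_fates = paralog_fates,
         n_duplications = k),
    class = "fate_analysis"
  )
}

#' @export
print.fate_analysis <- function(x, ...) {
  cat("<fate_analysis> ", x$n_duplications, " duplications, score ",
      x$score, " (", length(x$supporting_columns), " supporting columns)\n",
      sep = "")
  invisible(x)
}

#' Count independent domain losses per paralog fate
#'
#' Dollo loss counting (as in [count_losses()]) restricted to the tips of
#' each fate: the gene tree is pruned to one fate's tips and each maximal
#' domain-free clade counts as one loss event. Partial domain presence is
#' treated as presence.
#'
#' @param gene_tree Rooted `phylo` gene tree.
#' @param domain_presence Named vector per tip: logical, or character with
#'   values `"present"`, `"partial"`, `"absent"`.
#' @param fate_assignment Named character per tip (`fate1`/`fate2`/other);
#'   tips with other values are ignored.
#' @return Named integer vector of loss-event counts per fate.
#' @export
domain_loss_events <- function(gene_tree, domain_presence, fate_assignment) {
  if (is.character(domain_presence)) {
    domain_presence <- setNames(domain_presence != "absent",
                                names(domain_presence))
  }
  fates <- intersect(c("fate1", "fate2"), unique(fate_assignment))
  out <- setNames(integer(length(fates)), fates)
  for (f in fates) {
    tips <- names(fate_assignment)[fate_assignment == f]
    if (length(tips) == 0) {
      warning("fate ", f, " has no tips; zero loss events")
      out[f] <- 0L
      next
    }
    pres <- domain_presence[tips]
    if (length(tips) == 1) {
      out[f] <- as.integer(!pres)
      next
    }
    sub <- ape::keep.tip(gene_tree, tips)
    out[f] <- if (!any(pres)) {
      stop("domain absent from every fate-", f, " tip: no evidence of ",
           "ancestral presence")
    } else {
      count_losses(sub, pres)
    }
  }
  out
}
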