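#' Call ancestral (LECA) presence for an orthogroup
#'
#' An orthogroup is called present in the last eukaryotic common ancestor
#' when its members span a diverse set of eukaryotes: at least two Opimoda
#' and at least two Diphoda species.
#'
#' @param species Character vector of member species.
#' @param clade_map Named character vector mapping species to clade
#'   (`"Opimoda"`, `"Diphoda"`, `"Discoba"`, `"Metamonada"`).
#' @return `"LECA"` or `"not-LECA"`.
#' @export
infer_leca_og <- function(species, clade_map) {
  species <- unique(species)
  missing <- setdiff(species, names(clade_map))
  if (length(missing)) {
    stop("species missing from clade map: ", paste(missing, collapse = ", "))
  }
  clades <- clade_map[species]
  if (sum(clades == "Opimoda") >= 2 && sum(clades == "Diphoda") >= 2) {
    "LECA"
  } else {
    "not-LECA"
  }
}

## Sankoff small parsimony with unit costs over an arbitrary state set.
## Returns, for each node, the set of states attainable in some
## minimum-cost assignment (most-parsimonious-reconstruction sets).
sankoff_mpr <- function(tree, tip_states) {
  states <- sort(unique(unname(tip_states)))
  k <- length(states)
  nn <- n_nodes_total(tree)
  ntip <- length(tree$tip.label)
  ch <- children_list(tree)
  INF <- 1e9
  # up[v, s]: min cost of subtree below v given v has state s
  up <- matrix(INF, nrow = nn, ncol = k)
  for (v in postorder_simple(tree)) {
    if (v <= ntip) {
      s <- tip_states[[tree$tip.label[v]]]
      up[v, ] <- INF
      up[v, match(s, states)] <- 0
    } else {
      cost <- rep(0, k)
      for (c in ch[[v]]) {
        # min over child state of (up[c, sc] + [sc != sp])
        trans <- vapply(seq_len(k), function(sp) {
          min(up[c, ] + (seq_len(k) != sp))
        }, numeric(1))
        cost <- cost + trans
      }
      up[v, ] <- cost
    }
  }
  root <- root_node(tree)
  # down[v, s]: min cost of the rest of the tree given v has state s
  down <- matrix(0, nrow = nn, ncol = k)
  for (v in preorder_simple(tree)) {
    if (v <= ntip) next
    for (c in ch[[v]]) {
      sib_cost <- rep(0, k)  # indexed by parent state
      for (b in ch[[v]]) {
        if (b == c) next
        sib_cost <- sib_cost + vapply(seq_len(k), function(sp) {
          min(up[b, ] + (seq_len(k) != sp))
        }, numeric(1))
      }
      # for child state sc: min over parent state sp
      down[c, ] <- vapply(seq_len(k), function(sc) {
        min(down[v, ] + sib_cost + (seq_len(k) != sc))
      }, numeric(1))
    }
  }
  total <- up + down
  best <- min(total[root, ])
  mpr <- lapply(seq_len(nn), function(v) states[total[v, ] == min(total[v, ])])
  list(states = states, mpr = mpr, min_cost = best, up = up, down = down)
}

#' Classify the duplication node giving rise to a complex-member orthogroup
#'
#' Implements the five-way classification of the parent node of a
#' spliceosomal orthogroup in a rooted homolog tree whose tips are labelled
#' orthogroups (or prokaryotic clades):
#' * sister group entirely prokaryotic -> `"acquisition"`;
#' * sister group entirely spliceosomal -> `"within"` (within-complex
#'   duplication);
#' * no homolog outside the focal orthogroup -> `"invention"`;
#' * otherwise the ancestral (preduplication) function is reconstructed by
#'   parsimony over the tip labels: a spliceosomal preduplication ancestor
#'   gives `"from"` (the sister left the complex), a non-spliceosomal one
#'   gives `"to"` (the focal orthogroup entered it). A parsimony tie is
#'   reported as `"ambiguous"` rather than forced.
#'
#' @param tree Rooted `phylo` tree whose tips are orthogroup ids.
#' @param focal_og Tip label of the focal (spliceosomal) orthogroup.
#' @param og_labels Named character vector tip -> function label;
#'   `"spliceosomal"` and `"prokaryotic"` are interpreted, any other string
#'   is a non-spliceosomal function.
#' @return One of `"within"`, `"to"`, `"from"`, `"acquisition"`,
#'   `"invention"`, `"ambiguous"`.
#' @export
annotate_duplication <- function(tree, focal_og, og_labels) {
  if (length(tree$tip.label) == 1) {
    if (tree$tip.label != focal_og) stop("focal OG not in tree")
    return("invention")
  }
  if (!focal_og %in% tree$tip.label) stop("focal OG '", focal_og, "' not in tree")
  unlabeled <- setdiff(tree$tip.label, names(og_labels))
  if (length(unlabeled)) {
    stop("unlabeled orthogroup(s): ", paste(unlabeled, collapse = ", "))
  }
  focal <- which(tree$tip.label == focal_og)
  parents <- parent_vector(tree)
  parent <- parents[focal]
  ch <- children_list(tree)
  dtips <- descendant_tips(tree)
  sibs <- setdiff(ch[[parent]], focal)
  sister_tips <- tree$tip.label[unlist(dtips[sibs])]
  sister_labels <- og_labels[sister_tips]
  if (all(sister_labels == "prokaryotic")) return("acquisition")
  if (all(sister_labels == "spliceosomal")) return("within")
  # to/from: parsimony reconstruction of the function at the parent node
  sk <- sankoff_mpr(tree, og_labels)
  anc <- sk$mpr[[parent]]
  if (identical(anc, "spliceosomal")) return("from")
  if (!"spliceosomal" %in% anc) return("to")
  "ambiguous"
}

#' Collapse within-complex duplications into ancestral units
#'
#' Maximal clades whose internal nodes are all within-complex duplications
#' (equivalently, whose tips are all complex members) collapse to a single
#' ancestral unit; complex-member tips outside such clades are units of
#' their own.
#'
#' @param tree Rooted `phylo` tree whose tips are orthogroup ids.
#' @param og_labels Named character vector tip -> label; tips labelled
#'   `"spliceosomal"` are complex members.
#' @return List with `units` (list of character vectors of member
#'   orthogroups), `n_units` and `n_ogs` (number of complex-member tips).
#' @export
collapse_units <- function(tree, og_labels) {
  tips <- tree$tip.label
  unlabeled <- setdiff(tips, names(og_labels))
  if (length(unlabeled)) {
    stop("unlabeled orthogroup(s): ", paste(unlabeled, collapse = ", "))
  }
  is_splice <- og_labels[tips] == "spliceosomal"
  ntip <- length(tips)
  if (ntip == 1) {
    units <- if (is_splice[1]) list(tips) else list()
    return(list(units = units, n_units = length(units), n_ogs = sum(is_splice)))
  }
  parents <- parent_vector(tree)
  dtips <- descendant_tips(tree)
  nn <- n_nodes_total(tree)
  all_splice <- vapply(seq_len(nn), function(v) {
    all(is_splice[dtips[[v]]])
  }, logical(1))
  # maximal all-spliceosomal nodes: all-spliceosomal with a parent that is not
  maximal <- which(all_splice & (is.na(parents) | !all_splice[parents]))
  units <- lapply(maximal, function(v) tips[dtips[[v]]])
  list(units = units, n_units = length(units), n_ogs = sum(is_splice))
}

#' Duplication expansion factor
#'
#' Ratio of orthogroup count to ancestral-unit count, i.e. by what factor
#' within-complex duplications multiplied the complex's proteins. Reported
#' to one decimal.
#'
#' @param n_ogs Number of complex-member orthogroups.
#' @param n_units Number of ancestral units after collapsing.
#' @return Ratio rounded to one decimal.
#' @export
expansion_factor <- function(n_ogs, n_units) {
  if (n_units < 1) stop("n_units must be at least 1")
  round_half_up(n_ogs / n_units, 1)
}

#' Count recurrent losses of a trait on a species tree
#'
#' Dollo parsimony loss count assuming presence at the root (single
#' origin): each maximal clade in which the trait is absent from every tip
#' counts as one loss event.
#'
#' @param species_tree Rooted `phylo` species tree.
#' @param presence Named logical (or 0/1) vector over tips: trait present?
#' @return Integer number of loss events.
#' @export
count_losses <- function(species_tree, presence) {
  tips <- species_tree$tip.label
  missing <- setdiff(tips, names(presence))
  if (length(missing)) {
    stop("tip(s) absent from presence vector: ", paste(missing, collapse = ", "))
  }
  pres <- as.logical(presence[tips])
  if (!any(pres)) {
    stop("trait absent from all tips: no evidence of ancestral presence")
  }
  if (all(pres)) return(0L)
  parents <- parent_vector(species_tree)
  dtips <- descendant_tips(species_tree)
  nn <- n_nodes_total(species_tree)
  all_absent <- vapply(seq_len(nn), function(v) !any(pres[dtips[[v]]]), logical(1))
  maximal <- all_absent & (is.na(parents) | !all_absent[parents])
  sum(maximal)
}

#' Stem-branch asymmetry below a duplication node
#'
#' Sums branch lengths from a duplication node down to each child
#' orthogroup's ancestral (LECA) node and reports the ratio of the longer to
#' the shorter stem. A markedly shorter stem indicates the paralog that
#' diverged less from the preduplication state.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param duplication_node Node key or number; must have exactly two
#'   children.
#' @param leca_nodes Optional length-2 vector (keys or numbers) of the two
#'   child orthogroups' ancestral nodes, one per child clade; default: the
#'   duplication's children themselves.
#' @return List with `lengths` (stem length per child, named by child node
#'   key), `ratio` (longer/shorter; 1 when equal) and `shorter` (key of the
#'   child with the shorter stem).
#' @export
branch_asymmetry <- function(tree, duplication_node, leca_nodes = NULL) {
  d <- resolve_nodes(tree, duplication_node)
  ch <- children_list(tree)[[d]]
  if (length(ch) != 2) {
    stop("duplication node has ", length(ch), " children; an unresolved node ",
         "cannot be analyzed")
  }
  keys <- node_keys(tree)
  if (is.null(leca_nodes)) {
    targets <- ch
  } else {
    targets <- resolve_nodes(tree, leca_nodes)
    if (length(targets) != 2) stop("leca_nodes must identify two nodes")
    # align each target with the child clade it belongs to
    in_first <- targets %in% descendant_nodes(tree, ch[1])
    if (sum(in_first) != 1) stop("leca_nodes must lie one in each child clade")
    targets <- c(targets[in_first], targets[!in_first])
  }
  lens <- c(path_length_down(tree, d, targets[1]),
            path_length_down(tree, d, targets[2]))
  names(lens) <- keys[ch]
  ratio <- if (min(lens) == 0) {
    if (max(lens) == 0) 1 else Inf
  } else {
    max(lens) / min(lens)
  }
  list(lengths = lens, ratio = ratio, shorter = names(lens)[which.min(lens)])
}

#' Select slowly evolving representatives per orthogroup
#'
#' Implements ScrollSaw-style selection of the slowest-evolving sequence
#' per orthogroup per eukaryotic clade, for deep phylogenetic signal.
#' In mode `"shortest"` the tip with the minimal terminal branch length is
#' chosen for each (orthogroup, clade) — skipping clades not represented in
#' the orthogroup — unless it sits on a deviating long branch (longer than
#' `outlier_factor` times the median terminal branch length of all tips of
#' that clade in the tree, a clade-wide norm). In mode `"bbh"` the mutually
#' nearest Opimoda/Diphoda tip pair by patristic distance is chosen per
#' orthogroup.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param og_assignments Named character vector tip -> orthogroup id.
#' @param clade_map Named character vector tip -> eukaryotic clade.
#' @param mode `"shortest"` or `"bbh"`.
#' @param outlier_factor Long-branch exclusion factor (default 5).
#' @return For `"shortest"`: data frame `og`, `clade`, `tip`, `length`.
#'   For `"bbh"`: data frame `og`, `opimoda_tip`, `diphoda_tip`, `distance`.
#' @export
select_slow_representatives <- function(tree, og_assignments, clade_map,
                                        mode = c("shortest", "bbh"),
                                        outlier_factor = 5) {
  mode <- match.arg(mode)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(og_assignments))
  if (length(missing)) stop("tip(s) without orthogroup: ", paste(missing, collapse = ", "))
  missing <- setdiff(tips, names(clade_map))
  if (length(missing)) stop("tip(s) without clade: ", paste(missing, collapse = ", "))
  ogs <- unique(og_assignments[tips])
  if (length(ogs) == 0) stop("empty orthogroup assignment")

  if (mode == "shortest") {
    bl <- branch_above(tree)
    clade_median <- vapply(unique(clade_map[tips]), function(cl) {
      stats::median(bl[match(tips[clade_map[tips] == cl], tips)])
    }, numeric(1))
    out <- list()
    for (og in ogs) {
      og_tips <- tips[og_assignments[tips] == og]
      if (length(og_tips) == 0) stop("empty orthogroup: ", og)
      for (clade in unique(clade_map[og_tips])) {
        ct <- og_tips[clade_map[og_tips] == clade]
        lens <- bl[match(ct, tips)]
        ok <- lens <= outlier_factor * clade_median[[clade]]
        if (!any(ok)) next  # every candidate on a deviating long branch
        best <- ct[ok][which.min(lens[ok])]
        out[[length(out) + 1L]] <- data.frame(
          og = og, clade = clade, tip = best, length = min(lens[ok])
        )
      }
    }
    if (!length(out)) {
      return(data.frame(og = character(0), clade = character(0),
                        tip = character(0), length = numeric(0)))
    }
    return(do.call(rbind, out))
  }

  # bbh: mutually nearest Opimoda/Diphoda pair by patristic distance
  D <- ape::cophenetic.phylo(tree)
  out <- list()
  for (og in ogs) {
    og_tips <- tips[og_assignments[tips] == og]
    opi <- og_tips[clade_map[og_tips] == "Opimoda"]
    dip <- og_tips[clade_map[og_tips] == "Diphoda"]
    if (length(opi) == 0 || length(dip) == 0) next
    sub <- D[opi, dip, drop = FALSE]
    for (o in opi) {
      d_best <- dip[which.min(sub[o, ])]
      o_back <- opi[which.min(sub[, d_best])]
      if (o_back == o) {
        out[[length(out) + 1L]] <- data.frame(
          og = og, opimoda_tip = o, diphoda_tip = d_best,
          distance = sub[o, d_best]
        )
        break
      }
    }
  }
  if (!length(out)) {
    return(data.frame(og = character(0), opimoda_tip = character(0),
                      diphoda_tip = character(0), distance = numeric(0)))
  }
  do.call(rbind, out)
}
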