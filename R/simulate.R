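## Synthetic gene families with known duplication history, sequence
## divergence and intron gain/loss, emulating a eukaryogenesis study design:
## a two-supergroup (Opimoda/Diphoda) species layout plus Discoba and
## Metamonada, pre-LECA stem duplications followed by post-LECA speciations,
## intron gains as a Poisson process over codon-boundary-and-phase positions
## and exponential per-branch losses.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Bundles every parameter of the gene-family generator. All randomness
#' flows from the single mandatory `seed`; two runs with the same
#' configuration are identical.
#'
#' @param n_species_per_clade Named integer vector of species counts for the
#'   clades `Opimoda`, `Diphoda`, `Discoba`, `Metamonada`.
#' @param n_duplications Number of pre-LECA (stem) duplications; each
#'   produces one additional paralog clade containing the full species set.
#' @param protein_length Protein length L in residues.
#' @param gain_rate Expected intron gains per residue per unit branch
#'   length.
#' @param loss_rate Expected losses per intron per unit branch length.
#' @param branch_length_range Range (min, max) for uniform branch lengths,
#'   substitutions/site.
#' @param root_introns Number of intron sites already present in the root
#'   gene, before any duplication (default 10; set 0 for an intronless
#'   root). These are the sites that can be traced to the preduplication
#'   state of every stem duplication.
#' @param duplication_classes Optional planted class label per duplication
#'   (recycled); default alternates `"within"` and `"to"`.
#' @param intron_length Genomic length of every emitted intron, nt.
#' @param fate_signal Optional list injecting a recurrent-fate signal after
#'   one duplication: `duplication` (node key, e.g. `"D1"`), `columns`
#'   (alignment columns), `residues` (length 2: fate1/fate2 residue),
#'   `domain_range` (length 2 columns deleted in fate2),
#'   `loss_probability` (per-tip deletion probability in fate2).
#' @param seed Integer seed (required; no implicit randomness).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species_per_clade = c(Opimoda = 3L, Diphoda = 3L,
                                               Discoba = 2L, Metamonada = 2L),
                       n_duplications = 2L,
                       protein_length = 200L,
                       gain_rate = 0.05,
                       loss_rate = 0.2,
                       branch_length_range = c(0.05, 0.3),
                       root_introns = 10L,
                       duplication_classes = NULL,
                       intron_length = 60L,
                       fate_signal = NULL,
                       seed) {
  if (missing(seed)) stop("seed is required; the generator has no implicit randomness")
  clades <- c("Opimoda", "Diphoda", "Discoba", "Metamonada")
  if (is.null(names(n_species_per_clade)) ||
      !all(names(n_species_per_clade) %in% clades)) {
    stop("n_species_per_clade must be named with clades among: ",
         paste(clades, collapse = ", "))
  }
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be non-negative")
  if (protein_length < 1) stop("protein_length must be positive")
  if (n_duplications < 0) stop("n_duplications must be non-negative")
  if (root_introns < 0 || root_introns >= 3 * protein_length - 1) {
    stop("root_introns must be in [0, 3L - 2)")
  }
  if (length(branch_length_range) != 2 || any(branch_length_range < 0) ||
      branch_length_range[1] > branch_length_range[2]) {
    stop("branch_length_range must be a non-decreasing non-negative pair")
  }
  if (is.null(duplication_classes) && n_duplications > 0) {
    duplication_classes <- rep(c("within", "to"), length.out = n_duplications)
  } else if (n_duplications > 0) {
    duplication_classes <- rep(duplication_classes, length.out = n_duplications)
  }
  structure(
    list(n_species_per_clade = n_species_per_clade,
         n_duplications = as.integer(n_duplications),
         protein_length = as.integer(protein_length),
         gain_rate = gain_rate, loss_rate = loss_rate,
         branch_length_range = branch_length_range,
         root_introns = as.integer(root_introns),
         duplication_classes = duplication_classes,
         intron_length = as.integer(intron_length),
         fate_signal = fate_signal,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

## fold labels into a ladder newick: (((l1,l2),l3),l4)...
ladder_newick <- function(labels) {
  if (length(labels) == 1) return(labels)
  s <- paste0("(", labels[1], ",", labels[2], ")")
  for (l in labels[-(1:2)]) s <- paste0("(", s, ",", l, ")")
  s
}

## species names and clade map from a per-clade count vector
species_layout <- function(n_per_clade) {
  n_per_clade <- n_per_clade[n_per_clade > 0]
  species <- unlist(lapply(names(n_per_clade), function(cl) {
    paste0(substr(cl, 1, 3), seq_len(n_per_clade[[cl]]))
  }))
  clade <- unlist(lapply(names(n_per_clade), function(cl) {
    rep(cl, n_per_clade[[cl]])
  }))
  list(species = species, clade_map = setNames(clade, species))
}

## rooted species topology: (Opimoda, (Diphoda, (Discoba, Metamonada)))
species_topology <- function(n_per_clade, suffix = "") {
  n_per_clade <- n_per_clade[n_per_clade > 0]
  parts <- lapply(names(n_per_clade), function(cl) {
    ladder_newick(paste0(substr(cl, 1, 3), seq_len(n_per_clade[[cl]]), suffix))
  })
  names(parts) <- names(n_per_clade)
  order <- intersect(c("Opimoda", "Diphoda", "Discoba", "Metamonada"),
                     names(parts))
  s <- parts[[order[length(order)]]]
  for (cl in rev(order[-length(order)])) s <- paste0("(", parts[[cl]], ",", s, ")")
  s
}

## uniform branch lengths on every edge (RNG must be seeded by caller)
assign_lengths <- function(tree, range) {
  tree$edge.length <- runif(nrow(tree$edge), range[1], range[2])
  tree
}

## evolve sequences down a tree under a uniform-exchangeability stationary
## process: per site, a substitution occurs on a branch of length t with
## probability 1 - exp(-t), the new residue uniform over the other 19
evolve_sequences <- function(tree, L) {
  nn <- n_nodes_total(tree)
  ntip <- length(tree$tip.label)
  ch <- children_list(tree)
  bl <- branch_above(tree)
  seqs <- matrix(NA_character_, nrow = nn, ncol = L)
  root <- root_node(tree)
  seqs[root, ] <- sample(AA20, L, replace = TRUE)
  for (v in preorder_simple(tree)) {
    for (c in ch[[v]]) {
      s <- seqs[v, ]
      p <- 1 - exp(-bl[c])
      hit <- runif(L) < p
      if (any(hit)) {
        cur <- match(s[hit], AA20)
        off <- sample.int(19L, sum(hit), replace = TRUE)
        s[hit] <- AA20[((cur - 1L + off) %% 20L) + 1L]
      }
      seqs[c, ] <- s
    }
  }
  seqs
}

## (residue, phase) of a coding-nucleotide offset n in 1..3L-1
offset_to_site <- function(n) {
  list(residue = as.integer(n %/% 3L + 1L), phase = as.integer(n %% 3L))
}

#' Simulate intron gain and loss along a tree
#'
#' Gains arrive as a Poisson process with mean `gain_rate * L * t` per
#' branch of length `t`, each gain drawn uniformly from the not-yet-used
#' intra-CDS positions (coding-nucleotide offsets `1 .. 3L-1`, jointly
#' encoding residue and phase; a position never gains twice). An intron
#' present at a branch's parent survives the branch with probability
#' `exp(-loss_rate * t)`.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param protein_length Protein length L.
#' @param gain_rate Gains per residue per unit branch length.
#' @param loss_rate Losses per intron per unit branch length.
#' @param seed Optional seed; omit to draw from the active RNG stream.
#' @param root_sites Optional integer vector of offsets present at the root
#'   (default: the root is intronless).
#' @return List with `sites` (data frame `site`, `offset`, `column`,
#'   `phase`, `gain_node`) and `states` (binary matrix, all nodes x sites,
#'   rows named by node key).
#' @export
simulate_intron_history <- function(tree, protein_length, gain_rate, loss_rate,
                                    seed = NULL, root_sites = NULL) {
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(protein_length)
  npos <- 3L * L - 1L
  nn <- n_nodes_total(tree)
  ch <- children_list(tree)
  bl <- branch_above(tree)
  keys <- node_keys(tree)
  root <- root_node(tree)

  present <- vector("list", nn)
  present[[root]] <- sort(unique(as.integer(root_sites)))
  used <- present[[root]]
  gain_of <- setNames(rep(keys[root], length(used)), used)
  for (v in preorder_simple(tree)) {
    for (c in ch[[v]]) {
      t <- bl[c]
      cur <- present[[v]]
      survived <- cur[runif(length(cur)) < exp(-loss_rate * t)]
      ngain <- rpois(1, gain_rate * L * t)
      avail <- setdiff(seq_len(npos), used)
      if (ngain > length(avail)) ngain <- length(avail)  # saturated
      gained <- if (ngain > 0) sample(avail, ngain) else integer(0)
      used <- c(used, gained)
      if (length(gained)) {
        gain_of[as.character(gained)] <- keys[c]
      }
      present[[c]] <- sort(c(survived, gained))
    }
  }
  offsets <- sort(as.integer(names(gain_of)))
  pos <- offset_to_site(offsets)
  sites <- data.frame(
    site = if (length(offsets)) site_id(pos$residue, pos$phase) else character(0),
    offset = offsets, column = pos$residue, phase = pos$phase,
    gain_node = unname(gain_of[as.character(offsets)])
  )
  states <- matrix(0L, nrow = nn, ncol = nrow(sites),
                   dimnames = list(keys, sites$site))
  for (v in seq_len(nn)) {
    if (length(present[[v]])) {
      states[v, match(present[[v]], offsets)] <- 1L
    }
  }
  list(sites = sites, states = states)
}

#' Simulate one gene family with pre-LECA duplications
#'
#' Builds a species tree over the configured clades, a gene tree in which
#' `n_duplications` serial stem (pre-LECA) duplications each spawn a full
#' paralog copy of the species tree (duplication nodes labelled
#' `"D1" ... "Dk"`), evolves protein sequences under a stationary
#' uniform-exchangeability process, and simulates intron gain/loss over the
#' gene tree. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_bundle`: list with `species_tree`,
#'   `gene_tree`, `alignment` (named character; the true alignment — gaps
#'   arise only from fate-signal domain deletion), `intron_states` (truth,
#'   all nodes x sites), `intron_sites`, `species_map` (data frame `tip`,
#'   `species`, `clade`), `duplications` (data frame `node`, `class`),
#'   `fate_truth` (named character per tip, or `NULL`) and `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- species_layout(config$n_species_per_clade)
  sp_topo <- species_topology(config$n_species_per_clade)
  species_tree <- ape::read.tree(text = paste0(sp_topo, ";"))
  species_tree <- assign_lengths(species_tree, config$branch_length_range)
  species_tree <- label_internal_nodes(species_tree, "S")

  k <- config$n_duplications
  copy_topo <- function(i) species_topology(config$n_species_per_clade,
                                            suffix = paste0("_P", i))
  gene_nwk <- copy_topo(k + 1L)
  if (k > 0) {
    for (i in k:1) {
      gene_nwk <- paste0("(", copy_topo(i), ",", gene_nwk, ")D", i)
    }
  }
  gene_tree <- ape::read.tree(text = paste0(gene_nwk, ";"))
  gene_tree <- assign_lengths(gene_tree, config$branch_length_range)
  gene_tree <- label_internal_nodes(gene_tree, "N")

  L <- config$protein_length
  seqmat <- evolve_sequences(gene_tree, L)
  root_sites <- if (config$root_introns > 0) {
    sample(3L * L - 1L, config$root_introns)
  } else {
    NULL
  }
  hist <- simulate_intron_history(gene_tree, L, config$gain_rate,
                                  config$loss_rate, root_sites = root_sites)

  tips <- gene_tree$tip.label
  species_of <- sub("_P[0-9]+$", "", tips)
  species_map <- data.frame(tip = tips, species = species_of,
                            clade = unname(lay$clade_map[species_of]))
  duplications <- if (k > 0) {
    data.frame(node = paste0("D", seq_len(k)), class = config$duplication_classes)
  } else {
    data.frame(node = character(0), class = character(0))
  }

  fate_truth <- NULL
  ntip <- length(tips)
  if (!is.null(config$fate_signal)) {
    fs <- config$fate_signal
    d <- resolve_nodes(gene_tree, fs$duplication)
    kids <- children_list(gene_tree)[[d]]
    if (length(kids) != 2) stop("fate-signal duplication must be binary")
    dt <- descendant_tips(gene_tree)
    fate_truth <- setNames(rep("none", ntip), tips)
    f1_tips <- dt[[kids[1]]]
    f2_tips <- dt[[kids[2]]]
    fate_truth[f1_tips] <- "fate1"
    fate_truth[f2_tips] <- "fate2"
    for (col in fs$columns) {
      seqmat[f1_tips, col] <- fs$residues[1]
      seqmat[f2_tips, col] <- fs$residues[2]
    }
    if (!is.null(fs$domain_range)) {
      rng <- fs$domain_range[1]:fs$domain_range[2]
      p <- if (is.null(fs$loss_probability)) 1 else fs$loss_probability
      lose <- f2_tips[runif(length(f2_tips)) < p]
      if (length(lose)) {
        seqmat[lose, rng] <- "-"
        # an intron cannot survive inside a deleted block
        in_rng <- hist$sites$column %in% rng
        hist$states[lose, in_rng] <- 0L
      }
    }
  }
  alignment <- setNames(apply(seqmat[seq_len(ntip), , drop = FALSE], 1,
                              paste, collapse = ""), tips)
  structure(
    list(species_tree = species_tree, gene_tree = gene_tree,
         alignment = alignment, intron_states = hist$states,
         intron_sites = hist$sites, species_map = species_map,
         duplications = duplications, fate_truth = fate_truth,
         clade_map = lay$clade_map, config = config),
    class = "sim_bundle"
  )
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle> ", length(x$alignment), " tips, ",
      nrow(x$duplications), " duplications, ",
      nrow(x$intron_sites), " intron sites (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

## genomic CDS layout realizing a set of coding-nt offsets for one protein
## returns data.frame(start, end) in genomic order plus mRNA-order phases
cds_layout <- function(n_coding, offsets, intron_length, strand, origin = 1L) {
  mrna_lens <- diff(c(0L, sort(offsets), n_coding))
  m <- length(mrna_lens)
  phases <- (3L - (cumsum(c(0L, mrna_lens[-m])) %% 3L)) %% 3L
  genomic_lens <- if (strand == "-") rev(mrna_lens) else mrna_lens
  genomic_phases <- if (strand == "-") rev(phases) else phases
  starts <- integer(m)
  ends <- integer(m)
  pos <- origin
  for (i in seq_len(m)) {
    starts[i] <- pos
    ends[i] <- pos + genomic_lens[i] - 1L
    pos <- ends[i] + 1L + intron_length
  }
  data.frame(start = starts, end = ends, phase = genomic_phases)
}

#' Write a simulation bundle to disk as standard-format fixtures
#'
#' Emits an ungapped protein FASTA, the true alignment FASTA, a GFF3 with
#' CDS segments realizing each tip's intron positions and phases (strands
#' alternate so both orientations are exercised), Newick gene and species
#' trees, truth tables (per-node intron states, sites with gain nodes,
#' species map, duplication classes) and a manifest. Re-reading the GFF3
#' and alignment through the mapping stage reproduces the tip intron
#' matrix exactly.
#'
#' @param bundle A [simulate_family()] result.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Overwrite an existing manifest? Default `FALSE`.
#' @return Data frame manifest (`path`, `role`), invisibly.
#' @export
emit_fixture <- function(bundle, out_dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists in ", out_dir, "; set overwrite = TRUE")
  }
  tips <- names(bundle$alignment)
  aln <- protein_alignment(bundle$alignment)
  ungapped <- gsub("-", "", bundle$alignment, fixed = TRUE)

  write_fasta(bundle$alignment, file.path(out_dir, "alignment.faa"))
  write_fasta(ungapped, file.path(out_dir, "proteins.faa"))
  write_newick(bundle$gene_tree, file.path(out_dir, "gene_tree.nwk"))
  write_newick(bundle$species_tree, file.path(out_dir, "species_tree.nwk"))

  states <- bundle$intron_states
  sites <- bundle$intron_sites
  gff <- c("##gff-version 3")
  for (i in seq_along(tips)) {
    tip <- tips[i]
    strand <- if (i %% 2 == 0) "-" else "+"
    pres <- colnames(states)[states[tip, ] == 1L]
    cols <- sites$column[match(pres, sites$site)]
    phases <- sites$phase[match(pres, sites$site)]
    res <- vapply(cols, function(cc) residue_at_column(aln, tip, cc), integer(1))
    if (anyNA(res)) stop("tip ", tip, " carries an intron in a gapped column")
    n_coding <- 3L * nchar(ungapped[[tip]])
    offsets <- (res - 1L) * 3L + phases
    stopifnot(all(offsets > 0L & offsets < n_coding))
    lay <- cds_layout(n_coding, offsets, bundle$config$intron_length, strand)
    contig <- paste0("chr_", tip)
    gff <- c(gff, paste(contig, "spliceotrace", "gene", 1L,
                        max(lay$end) + 10L, ".", strand, ".",
                        paste0("ID=gene:", tip), sep = "\t"))
    for (j in seq_len(nrow(lay))) {
      gff <- c(gff, paste(contig, "spliceotrace", "CDS", lay$start[j],
                          lay$end[j], ".", strand, lay$phase[j],
                          paste0("ID=cds:", tip, ".", j, ";Parent=", tip,
                                 ";protein_id=", tip), sep = "\t"))
    }
  }
  writeLines(gff, file.path(out_dir, "genes.gff3"))

  write_tsv(data.frame(node = rownames(states), states, check.names = FALSE),
            file.path(out_dir, "node_states.tsv"))
  write_tsv(sites, file.path(out_dir, "sites.tsv"))
  write_tsv(bundle$species_map, file.path(out_dir, "species_map.tsv"))
  write_tsv(bundle$duplications, file.path(out_dir, "duplications.tsv"))

  files <- c(alignment = "alignment.faa", proteins = "proteins.faa",
             gene_tree = "gene_tree.nwk", species_tree = "species_tree.nwk",
             genes = "genes.gff3", node_states = "node_states.tsv",
             sites = "sites.tsv", species_map = "species_map.tsv",
             duplications = "duplications.tsv")
  manifest <- data.frame(path = unname(files), role = names(files))
  write_tsv(manifest, manifest_path)
  invisible(manifest)
}

#' Simulate independent post-LECA duplications with recurrent fates
#'
#' Builds a ladder species tree in which the last `n_duplications` species
#' each underwent an independent gene duplication (duplication nodes
#' `"D1" ... "Dk"`, paralog tips `<species>_a` / `<species>_b`), evolves
#' sequences, then injects the recurrent-fate signal: at each signal column
#' every fate-1 paralog receives one residue and every fate-2 paralog a
#' different one, and in a chosen subset of duplications the fate-2 paralog
#' loses a domain block (gapped out), emulating recurrent substitutions in
#' one domain and recurrent loss of another. The planted domain-loss count
#' equals `length(domain_loss_dups)` by construction (validated: the two
#' innermost duplications may not both lose the domain, which would merge
#' two events into one clade).
#'
#' @param n_duplications Number of independent duplications.
#' @param n_single_species Additional species retaining a single copy.
#' @param protein_length Protein length in residues.
#' @param signal_columns Alignment columns carrying the fate signal.
#' @param fate_residues Length-2 residues for fate 1 / fate 2.
#' @param domain_range Length-2 column range of the deletable domain.
#' @param domain_loss_dups Integer indices of duplications whose fate-2
#'   paralog loses the domain.
#' @param branch_length_range Uniform branch-length range.
#' @param seed Integer seed.
#' @return Object of class `fate_bundle`: list with `gene_tree`,
#'   `species_tree`, `alignment`, `species_map` (named tip -> species),
#'   `duplication_nodes`, `fate_truth` (named per tip:
#'   `fate1`/`fate2`/`single`), `domain_presence` (named logical per tip),
#'   `n_domain_losses`, `signal_columns`.
#' @export
simulate_fate_family <- function(n_duplications = 22L, n_single_species = 6L,
                                 protein_length = 160L,
                                 signal_columns = c(20L, 45L, 70L, 95L),
                                 fate_residues = c("D", "E"),
                                 domain_range = c(101L, 160L),
                                 domain_loss_dups = integer(0),
                                 branch_length_range = c(0.05, 0.3),
                                 seed) {
  if (missing(seed)) stop("seed is required")
  if (n_duplications < 1) stop("at least one duplication required")
  if (any(domain_loss_dups < 1 | domain_loss_dups > n_duplications)) {
    stop("domain_loss_dups out of range")
  }
  if (all(c(1, 2) %in% domain_loss_dups)) {
    stop("the two innermost duplications cannot both lose the domain: the ",
         "two planted events would collapse into a single clade loss")
  }
  if (max(signal_columns) > protein_length ||
      (length(domain_loss_dups) && domain_range[2] > protein_length)) {
    stop("signal or domain columns exceed protein length")
  }
  if (any(signal_columns >= domain_range[1] & signal_columns <= domain_range[2])) {
    stop("signal columns must lie outside the deletable domain")
  }
  set.seed(seed)
  n_sp <- n_single_species + n_duplications
  species <- sprintf("S%02d", seq_len(n_sp))
  dup_species <- species[n_single_species + seq_len(n_duplications)]
  tip_of <- function(sp) {
    i <- match(sp, dup_species)
    if (is.na(i)) paste0(sp, "_1")
    else paste0("(", sp, "_a,", sp, "_b)D", i)
  }
  gene_nwk <- ladder_newick(vapply(species, tip_of, character(1)))
  gene_tree <- ape::read.tree(text = paste0(gene_nwk, ";"))
  gene_tree <- assign_lengths(gene_tree, branch_length_range)
  gene_tree <- label_internal_nodes(gene_tree, "N")
  species_tree <- ape::read.tree(text = paste0(ladder_newick(species), ";"))
  species_tree <- assign_lengths(species_tree, branch_length_range)
  species_tree <- label_internal_nodes(species_tree, "S")

  seqmat <- evolve_sequences(gene_tree, protein_length)
  tips <- gene_tree$tip.label
  ntip <- length(tips)
  species_map <- setNames(sub("_(a|b|1)$", "", tips), tips)
  fate_truth <- setNames(ifelse(grepl("_a$", tips), "fate1",
                                ifelse(grepl("_b$", tips), "fate2", "single")),
                         tips)
  f1 <- which(fate_truth == "fate1")
  f2 <- which(fate_truth == "fate2")
  for (col in signal_columns) {
    seqmat[f1, col] <- fate_residues[1]
    seqmat[f2, col] <- fate_residues[2]
  }
  domain_presence <- setNames(rep(TRUE, ntip), tips)
  if (length(domain_loss_dups)) {
    lose_tips <- paste0(dup_species[domain_loss_dups], "_b")
    rng <- domain_range[1]:domain_range[2]
    seqmat[match(lose_tips, tips), rng] <- "-"
    domain_presence[lose_tips] <- FALSE
  }
  alignment <- setNames(apply(seqmat[seq_len(ntip), , drop = FALSE], 1,
                              paste, collapse = ""), tips)
  structure(
    list(gene_tree = gene_tree, species_tree = species_tree,
         alignment = alignment, species_map = species_map,
         duplication_nodes = paste0("D", seq_len(n_duplications)),
         fate_truth = fate_truth, domain_presence = domain_presence,
         n_domain_losses = length(domain_loss_dups),
         signal_columns = signal_columns, seed = seed),
    class = "fate_bundle"
  )
}

#' Plant independent trait losses on a species tree
#'
#' Samples `n_losses` pairwise disjoint clades (size at most
#' `max_clade_size`) to mark as having lost a trait, rejecting any choice
#' that would make a non-chosen node entirely trait-free — so the planted
#' event count is the true minimal loss count by construction, independent
#' of any reconstruction code.
#'
#' @param n_species Number of species in the (random, rooted) survey tree.
#' @param n_losses Number of independent loss events to plant.
#' @param seed Integer seed.
#' @param max_clade_size Largest clade a single loss may remove.
#' @return List with `tree`, `presence` (named logical per tip),
#'   `n_events` and `lost_clades` (node keys of the loss branches).
#' @export
simulate_loss_survey <- function(n_species = 60L, n_losses = 23L, seed,
                                 max_clade_size = 3L) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  tree <- ape::rtree(n_species, rooted = TRUE)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree <- label_internal_nodes(tree, "S")
  ntip <- n_species
  parents <- parent_vector(tree)
  dtips <- descendant_tips(tree)
  nn <- n_nodes_total(tree)
  keys <- node_keys(tree)
  candidates <- sample(which(lengths(dtips) <= max_clade_size &
                               seq_len(nn) != root_node(tree)))
  chosen <- integer(0)
  absent <- logical(ntip)
  for (v in candidates) {
    if (length(chosen) == n_losses) break
    vt <- dtips[[v]]
    if (any(absent[vt])) next
    tentative <- absent
    tentative[vt] <- TRUE
    # every chosen clade (incl. v) must have a parent with a present tip
    ok <- all(vapply(c(chosen, v), function(c) {
      any(!tentative[dtips[[parents[c]]]])
    }, logical(1)))
    if (!ok) next
    chosen <- c(chosen, v)
    absent <- tentative
  }
  if (length(chosen) < n_losses) {
    stop("could not place ", n_losses, " disjoint losses on ", n_species,
         " species; increase n_species")
  }
  list(tree = tree,
       presence = setNames(!absent, tree$tip.label),
       n_events = n_losses,
       lost_clades = keys[chosen])
}
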