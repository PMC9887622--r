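#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end demonstration pipeline
#' with the package-wide defaults. All randomness flows from `seed`.
#'
#' @param out_dir Output directory for fixtures, stage tables and the
#'   report.
#' @param seed Integer seed.
#' @param sim Optional [sim_config()]; default is built from `seed`.
#' @param gap_threshold Maximum gap fraction for [trim_alignment()] of the
#'   tree-inference alignment (default 0.5).
#' @param gain_rate,loss_rate Markov reconstruction rates per site; default
#'   derived from the generating process (`gain_rate * L / (3L - 1)` per
#'   site, and the generator's loss rate).
#' @param posterior_threshold Ancestral presence call threshold (default
#'   0.5).
#' @param outlier_factor Long-branch exclusion factor for representative
#'   selection (default 5).
#' @param min_events Minimum contributing duplications per fate-supporting
#'   column (default: all with data, minimum 2).
#' @param presence_threshold Minimum number of complex-specific orthogroups
#'   for a species to count as retaining the complex (default 1).
#' @param n_complex_losses Planted loss events in the loss-survey stage.
#' @param run_fates Run the recurrent-fate stage? Default `TRUE`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, sim = NULL,
                            gap_threshold = 0.5,
                            gain_rate = NULL, loss_rate = NULL,
                            posterior_threshold = 0.5,
                            outlier_factor = 5,
                            min_events = NULL,
                            presence_threshold = 1L,
                            n_complex_losses = 3L,
                            run_fates = TRUE) {
  if (missing(seed)) stop("seed is required")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         gap_threshold = gap_threshold, gain_rate = gain_rate,
         loss_rate = loss_rate, posterior_threshold = posterior_threshold,
         outlier_factor = outlier_factor, min_events = min_events,
         presence_threshold = presence_threshold,
         n_complex_losses = as.integer(n_complex_losses),
         run_fates = isTRUE(run_fates)),
    class = "pipeline_config"
  )
}

## per-site gain rate of the generating process: gains are spread uniformly
## over the 3L - 1 intra-CDS positions
per_site_gain_rate <- function(sim) {
  L <- sim$protein_length
  sim$gain_rate * L / (3 * L - 1)
}

#' Run the end-to-end demonstration pipeline on a simulated family
#'
#' Simulates a gene family, writes it to standard formats, re-reads it
#' through the I/O layer, maps introns onto the alignment, reconstructs
#' ancestral intron states (Dollo and Markov), summarizes preduplication
#' introns per planted duplication class, counts planted complex losses on
#' a species-tree survey, optionally runs the recurrent-fate stage on an
#' independent-duplication family, and writes a report. Deterministic
#' given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("[simulate] seed ", config$seed)
  bundle <- simulate_family(config$sim)
  fix_dir <- file.path(out_dir, "fixture")
  emit_fixture(bundle, fix_dir, overwrite = TRUE)

  message("[map-introns] ", file.path(fix_dir, "genes.gff3"))
  genes <- read_gff_genes(file.path(fix_dir, "genes.gff3"))
  aln <- protein_alignment(read_fasta(file.path(fix_dir, "alignment.faa")))
  introns <- do.call(rbind, lapply(genes, gene_to_protein_introns))
  im <- project_introns(aln, introns)
  write_intron_matrix(im, file.path(out_dir, "intron_matrix.tsv"))

  message("[ancestral] ", ncol(im$presence), " sites")
  gene_tree <- read_newick(file.path(fix_dir, "gene_tree.nwk"))
  dollo <- dollo_reconstruct(gene_tree, im)
  gain <- if (is.null(config$gain_rate)) per_site_gain_rate(config$sim) else config$gain_rate
  loss <- if (is.null(config$loss_rate)) config$sim$loss_rate else config$loss_rate
  markov <- markov_posterior(gene_tree, im, gain, loss,
                             call_threshold = config$posterior_threshold)
  write_tsv(data.frame(node = rownames(dollo$states), dollo$states,
                       check.names = FALSE),
            file.path(out_dir, "dollo_states.tsv"))

  dup_nodes <- bundle$duplications$node
  records <- NULL
  intron_summary <- NULL
  if (length(dup_nodes)) {
    predup <- preduplication_sites(dollo, dup_nodes)
    records <- data.frame(
      node = dup_nodes, class = bundle$duplications$class,
      n_preduplication = lengths(predup)[dup_nodes]
    )
    intron_summary <- shared_intron_summary(records)
    write_tsv(records, file.path(out_dir, "duplication_records.tsv"))
    write_tsv(intron_summary, file.path(out_dir, "shared_intron_summary.tsv"))
  }

  message("[losses] planting ", config$n_complex_losses, " events")
  survey <- simulate_loss_survey(n_species = 30L,
                                 n_losses = config$n_complex_losses,
                                 seed = config$seed + 1L)
  loss_count <- count_losses(survey$tree, survey$presence)

  fates <- NULL
  if (config$run_fates) {
    message("[fates] independent-duplication family")
    fb <- simulate_fate_family(n_duplications = 6L, n_single_species = 4L,
                               protein_length = 120L,
                               signal_columns = c(20L, 40L, 60L),
                               domain_range = c(81L, 120L),
                               domain_loss_dups = c(3L, 5L),
                               seed = config$seed + 2L)
    dups <- find_duplications(fb$gene_tree, fb$species_map)
    fp <- fate_partition(fb$alignment, dups, min_events = config$min_events)
    dl <- domain_loss_events(fb$gene_tree, fb$domain_presence,
                             fp$paralog_fates)
    fates <- list(n_duplications = length(dups), partition = fp,
                  domain_losses = dl)
    write_tsv(data.frame(tip = names(fp$paralog_fates),
                         fate = unname(fp$paralog_fates)),
              file.path(out_dir, "paralog_fates.tsv"))
  }

  report <- make_report(list(
    intron_summary = intron_summary,
    n_sites = ncol(im$presence),
    loss_count = loss_count,
    fates = fates
  ))
  writeLines(report$text, file.path(out_dir, "report.txt"))
  write_tsv(data.frame(key = names(report$values),
                       value = unlist(lapply(report$values, format))),
            file.path(out_dir, "report.tsv"))
  invisible(list(bundle = bundle, matrix = im, dollo = dollo, markov = markov,
                 records = records, intron_summary = intron_summary,
                 loss_count = loss_count, fates = fates, report = report))
}

#' Assemble a pipeline report
#'
#' Renders the stage outputs as human-readable lines plus a machine-readable
#' key-value list: per-class duplication counts with the fraction and
#' rounded percentage carrying preduplication introns, orthogroup/unit
#' counts with the expansion factor, loss counts, and the fate summary
#' (marked "not run" when absent).
#'
#' @param stages List with any of `intron_summary` (data frame from
#'   [shared_intron_summary()]), `n_sites`, `n_ogs` and `n_units`,
#'   `loss_count`, `fates` (list with `n_duplications`, `partition`,
#'   `domain_losses`).
#' @return List with `text` (character lines) and `values` (named list).
#' @export
make_report <- function(stages) {
  text <- character(0)
  values <- list()
  if (!is.null(stages$n_sites)) {
    text <- c(text, paste0("homologous intron sites: ", stages$n_sites))
    values$n_sites <- stages$n_sites
  }
  if (!is.null(stages$intron_summary)) {
    s <- stages$intron_summary
    for (i in seq_len(nrow(s))) {
      text <- c(text, sprintf(
        "%s duplications: %d/%d with preduplication introns (%d%%)",
        s$class[i], s$n_with_shared[i], s$n_total[i], s$pct_with_shared[i]))
      values[[paste0("pct_shared_", s$class[i])]] <- s$pct_with_shared[i]
      values[[paste0("n_", s$class[i])]] <- s$n_total[i]
    }
  }
  if (!is.null(stages$n_ogs) && !is.null(stages$n_units)) {
    f <- expansion_factor(stages$n_ogs, stages$n_units)
    text <- c(text, sprintf(
      "orthogroups: %d; ancestral units: %d; expansion factor %.1f",
      stages$n_ogs, stages$n_units, f))
    values$n_ogs <- stages$n_ogs
    values$n_units <- stages$n_units
    values$expansion_factor <- f
  }
  if (!is.null(stages$loss_count)) {
    text <- c(text, paste0("recurrent complex losses: ", stages$loss_count))
    values$loss_count <- stages$loss_count
  }
  if (is.null(stages$fates)) {
    text <- c(text, "recurrent fates: not run")
  } else {
    f <- stages$fates
    dl <- f$domain_losses
    text <- c(text, sprintf(
      "recurrent fates: %d duplications, score %d, domain losses %s",
      f$n_duplications, f$partition$score,
      paste(names(dl), dl, sep = "=", collapse = " ")))
    values$n_fate_duplications <- f$n_duplications
    values$fate_score <- f$partition$score
    for (n in names(dl)) values[[paste0("domain_losses_", n)]] <- dl[[n]]
  }
  list(text = text, values = values)
}
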