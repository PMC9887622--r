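test_that("species overlap flags duplication nodes", {
  tr <- ape::read.tree(text = "((X_1,Y_1)a,(X_2,Y_2)b)r;")
  sm <- c(X_1 = "X", Y_1 = "Y", X_2 = "X", Y_2 = "Y")
  dups <- find_duplications(tr, sm)
  expect_length(dups, 1)
  expect_equal(dups[[1]]$node, "r")
  expect_setequal(dups[[1]]$shared_species, c("X", "Y"))

  tr2 <- ape::read.tree(text = "((X_1,Y_1)a,(Z_1,W_1)b)r;")
  sm2 <- c(X_1 = "X", Y_1 = "Y", Z_1 = "Z", W_1 = "W")
  expect_length(find_duplications(tr2, sm2), 0)
  expect_error(find_duplications(tr2, sm2[-1]), "X_1")

  # a duplication-free simulated family yields the empty set
  b <- simulate_family(sim_config(n_duplications = 0, seed = 31))
  sm3 <- setNames(b$species_map$species, b$species_map$tip)
  expect_length(find_duplications(b$gene_tree, sm3), 0)

  # all planted duplications in a fate family are recovered
  fb <- simulate_fate_family(n_duplications = 6, n_single_species = 4,
                             protein_length = 80, seed = 32,
                             domain_range = c(41, 80),
                             signal_columns = c(10, 20, 30))
  dups6 <- find_duplications(fb$gene_tree, fb$species_map)
  expect_setequal(vapply(dups6, `[[`, character(1), "node"),
                  fb$duplication_nodes)
})

make_dups <- function(k) {
  lapply(seq_len(k), function(i) {
    list(node = paste0("d", i), tips_a = paste0("a", i), tips_b = paste0("b", i))
  })
}

test_that("a planted two-column signal is recovered by exhaustive search", {
  # 3 duplications; fate1 carries D and fate2 carries E at columns 5 and 9
  base <- "MKVLWQTRPS"
  seqs <- character(0)
  for (i in 1:3) {
    a <- base; substr(a, 5, 5) <- "D"; substr(a, 9, 9) <- "D"
    b <- base; substr(b, 5, 5) <- "E"; substr(b, 9, 9) <- "E"
    seqs[paste0("a", i)] <- a
    seqs[paste0("b", i)] <- b
  }
  dups <- make_dups(3)
  fp <- fate_partition(seqs, dups)
  expect_equal(fp$score, 2)
  expect_setequal(fp$supporting_columns, c(5, 9))
  expect_true(all(fp$paralog_fates[paste0("a", 1:3)] ==
                    fp$paralog_fates[["a1"]]))
  expect_true(all(fp$paralog_fates[paste0("b", 1:3)] !=
                    fp$paralog_fates[["a1"]]))
  # the oracle confirms this is the maximum over all assignments
  o <- oracle_fate_best(seqs, dups)
  expect_equal(fp$score, o$score)
})

test_that("contradictory signals score zero and leave paralogs unassigned", {
  seqs <- c(a1 = "MDVD", b1 = "MEVE", a2 = "MKVK", b2 = "MRVR")
  fp <- fate_partition(seqs, make_dups(2))
  expect_equal(fp$score, 0)
  expect_true(all(fp$paralog_fates == "unassigned"))
  expect_error(fate_partition(seqs[1:2], make_dups(1)), "single duplication")
})

test_that("the recurrence score is flip-symmetric", {
  set.seed(33)
  fb <- simulate_fate_family(n_duplications = 5, n_single_species = 2,
                             protein_length = 60, seed = 34,
                             signal_columns = c(10, 20),
                             domain_range = c(41, 60))
  dups <- find_duplications(fb$gene_tree, fb$species_map)
  aln <- protein_alignment(fb$alignment)
  A <- spliceotrace:::side_residues(aln, lapply(dups, `[[`, "tips_a"))
  B <- spliceotrace:::side_residues(aln, lapply(dups, `[[`, "tips_b"))
  has_data <- !is.na(A) & !is.na(B)
  differ <- has_data & (A != B)
  differ[is.na(differ)] <- FALSE
  req <- pmax(colSums(has_data), 2L)
  for (i in 1:10) {
    z <- sample(c(TRUE, FALSE), length(dups), replace = TRUE)
    s1 <- spliceotrace:::score_fate_assignment(z, A, B, differ, req)
    s2 <- spliceotrace:::score_fate_assignment(!z, A, B, differ, req)
    expect_equal(s1$score, s2$score)
    expect_equal(s1$columns, s2$columns)
  }
})

test_that("score grows with the number of planted signal columns", {
  all_cols <- c(10, 20, 30, 40)
  scores <- vapply(1:4, function(k) {
    fb <- simulate_fate_family(n_duplications = 5, n_single_species = 2,
                               protein_length = 80, seed = 35,
                               signal_columns = all_cols[1:k],
                               domain_range = c(61, 80))
    dups <- find_duplications(fb$gene_tree, fb$species_map)
    fate_partition(fb$alignment, dups)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_gte(scores[4], 4)
})

test_that("without planted signal the score is null-distribution noise", {
  set.seed(36)
  n_dup <- 5
  width <- 60
  tips <- as.vector(rbind(paste0("a", 1:n_dup), paste0("b", 1:n_dup)))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(sample(aa, length(tips) * width, replace = TRUE),
                nrow = length(tips), dimnames = list(tips, NULL))
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), tips)
  dups <- make_dups(n_dup)
  obs <- fate_partition(seqs, dups)$score
  null_scores <- vapply(1:100, function(i) {
    perm <- apply(mat, 2, sample)
    rownames(perm) <- tips
    fate_partition(setNames(apply(perm, 1, paste, collapse = ""), tips),
                   dups)$score
  }, numeric(1))
  p <- (1 + sum(null_scores >= obs)) / 101
  expect_gt(p, 0.05)
})

test_that("column-seeded search recovers the partition beyond the exhaustive regime", {
  fb <- simulate_fate_family(n_duplications = 14, n_single_species = 3,
                             protein_length = 100, seed = 37,
                             signal_columns = c(15, 35, 55),
                             domain_range = c(71, 100),
                             domain_loss_dups = c(4, 9))
  dups <- find_duplications(fb$gene_tree, fb$species_map)
  fp <- fate_partition(fb$alignment, dups)
  expect_gte(fp$score, 3)
  expect_true(all(c(15, 35, 55) %in% fp$supporting_columns))
  tf <- fb$fate_truth[names(fp$paralog_fates)]
  agree <- mean(fp$paralog_fates == tf)
  expect_true(agree == 1 || mean(fp$paralog_fates == flip_fates(tf)) == 1)
})

test_that("domain losses count once per independent fate clade", {
  # after pruning to fate-2 tips the tree is ((b1,b3),b2); losing the
  # domain in b1 and b2 is two independent events
  tr <- ape::read.tree(text = "(((a1,b1)d1,(a3,b3)d3)x,(a2,b2)d2)r;")
  fates <- c(a1 = "fate1", b1 = "fate2", a2 = "fate1", b2 = "fate2",
             a3 = "fate1", b3 = "fate2")
  pres <- c(a1 = TRUE, b1 = FALSE, a2 = TRUE, b2 = FALSE,
            a3 = TRUE, b3 = TRUE)
  dl <- domain_loss_events(tr, pres, fates)
  expect_equal(unname(dl["fate2"]), 2L)
  expect_equal(unname(dl["fate1"]), 0L)
  # domain present everywhere: zero events
  all_pres <- setNames(rep(TRUE, 6), names(pres))
  expect_equal(sum(domain_loss_events(tr, all_pres, fates)), 0L)
  # partial presence counts as presence
  chr <- c(a1 = "present", b1 = "partial", a2 = "present", b2 = "absent",
           a3 = "present", b3 = "present")
  dl2 <- domain_loss_events(tr, chr, fates)
  expect_equal(unname(dl2["fate2"]), 1L)
  # sister fate-2 tips both losing the domain merge into one clade event
  tr_sis <- ape::read.tree(text = "(((a1,b1)d1,(a2,b2)d2)x,(a3,b3)d3)r;")
  expect_equal(unname(domain_loss_events(tr_sis, pres, fates)["fate2"]), 1L)
})

test_that("planted recurrent domain losses are recovered exactly", {
  fb <- simulate_fate_family(n_duplications = 8, n_single_species = 3,
                             protein_length = 90, seed = 38,
                             signal_columns = c(10, 25, 40),
                             domain_range = c(61, 90),
                             domain_loss_dups = c(3, 5, 7, 8))
  dl <- domain_loss_events(fb$gene_tree, fb$domain_presence, fb$fate_truth)
  expect_equal(unname(dl["fate2"]), 4L)
  expect_equal(unname(dl["fate1"]), 0L)
})
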