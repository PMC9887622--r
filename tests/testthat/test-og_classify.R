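test_that("LECA presence needs two Opimoda and two Diphoda species", {
  cm <- c(h = "Opimoda", y = "Opimoda", f = "Opimoda",
          a = "Diphoda", p = "Diphoda", n = "Discoba")
  expect_equal(infer_leca_og(c("h", "y", "a", "p"), cm), "LECA")
  expect_equal(infer_leca_og(c("h", "y", "f"), cm), "not-LECA")
  expect_equal(infer_leca_og(c("h", "a", "p", "n"), cm), "not-LECA")
  expect_error(infer_leca_og(c("h", "zz"), cm), "zz")
})

test_that("duplication nodes classify by sister composition and ancestry", {
  tr <- ape::read.tree(text = "((focal,sister),(og3,og4))r;")
  lab <- function(s, o3, o4) c(focal = "spliceosomal", sister = s,
                               og3 = o3, og4 = o4)
  expect_equal(annotate_duplication(tr, "focal",
               lab("spliceosomal", "ribosome", "ribosome")), "within")
  expect_equal(annotate_duplication(tr, "focal",
               lab("prokaryotic", "prokaryotic", "prokaryotic")), "acquisition")
  # non-spliceosomal sister, non-spliceosomal deeper homologs: entered
  expect_equal(annotate_duplication(tr, "focal",
               lab("ribosome", "ribosome", "ribosome")), "to")
  # non-spliceosomal sister but spliceosomal ancestry: left
  expect_equal(annotate_duplication(tr, "focal",
               lab("ribosome", "spliceosomal", "spliceosomal")), "from")
  # no homolog outside the orthogroup
  expect_equal(annotate_duplication(ape::read.tree(text = "(focal);"),
                                    "focal", c(focal = "spliceosomal")),
               "invention")
  expect_error(annotate_duplication(tr, "focal",
               c(focal = "spliceosomal", og3 = "x", og4 = "x")), "unlabeled")
})

test_that("to/from parsimony calls agree with exhaustive label enumeration", {
  # enumeration over all ancestral label assignments of a 4-OG tree
  tr <- ape::read.tree(text = "((focal,sister)p,(og3,og4)q)r;")
  states <- c("spliceosomal", "other")
  set.seed(21)
  for (i in 1:20) {
    lab <- c(focal = "spliceosomal",
             sister = sample(states, 1), og3 = sample(states, 1),
             og4 = sample(states, 1))
    if (lab["sister"] == "spliceosomal") next
    got <- annotate_duplication(tr, "focal", lab)
    # brute force: min-change assignments to internal nodes p, q, r
    best <- Inf; anc <- character(0)
    for (sp in states) for (sq in states) for (sr in states) {
      cost <- (lab["focal"] != sp) + (lab["sister"] != sp) +
        (lab["og3"] != sq) + (lab["og4"] != sq) + (sp != sr) + (sq != sr)
      if (cost < best) { best <- cost; anc <- sp }
      else if (cost == best) anc <- union(anc, sp)
    }
    want <- if (identical(anc, "spliceosomal")) "from"
            else if (!"spliceosomal" %in% anc) "to" else "ambiguous"
    expect_equal(got, want, info = paste(lab, collapse = ","))
  }
})

test_that("within-duplication clades collapse into ancestral units", {
  # clade of 3 complex members from 2 within-duplications: one unit
  tr <- ape::read.tree(text = "(((a,b),c),(x,y))r;")
  lab <- c(a = "spliceosomal", b = "spliceosomal", c = "spliceosomal",
           x = "other", y = "other")
  u <- collapse_units(tr, lab)
  expect_equal(u$n_units, 1)
  expect_setequal(u$units[[1]], c("a", "b", "c"))
  expect_equal(u$n_ogs, 3)
  # two unrelated complex members: two units
  tr2 <- ape::read.tree(text = "((a,x),(b,y))r;")
  lab2 <- c(a = "spliceosomal", b = "spliceosomal", x = "other", y = "other")
  expect_equal(collapse_units(tr2, lab2)$n_units, 2)
  # 6 complex members, two within-duplication pairs: 4 units
  tr3 <- ape::read.tree(text = "(((a,b),(c,x)),((d,e),(f,y)))r;")
  lab3 <- c(a = "spliceosomal", b = "spliceosomal", c = "spliceosomal",
            d = "spliceosomal", e = "spliceosomal", f = "spliceosomal",
            x = "other", y = "other")
  u3 <- collapse_units(tr3, lab3)
  expect_equal(u3$n_units, 4)
  expect_equal(u3$n_ogs, 6)
})

test_that("unit counts never exceed orthogroup counts", {
  set.seed(22)
  for (i in 1:15) {
    tr <- rand_tree(sample(4:10, 1))
    lab <- setNames(sample(c("spliceosomal", "other"), length(tr$tip.label),
                           replace = TRUE), tr$tip.label)
    u <- collapse_units(tr, lab)
    expect_lte(u$n_units, u$n_ogs)
    expect_equal(sum(lengths(u$units)), u$n_ogs)
  }
})

test_that("the expansion factor reproduces the printed ratio", {
  expect_equal(expansion_factor(145, 102), 1.4)
  expect_equal(expansion_factor(20, 20), 1.0)
  expect_equal(expansion_factor(30, 20), 1.5)
  expect_error(expansion_factor(10, 0), "n_units")
})

test_that("Dollo loss counting matches examples and the enumeration oracle", {
  st <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(count_losses(st, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  expect_equal(count_losses(st, c(A = 0, B = 0, C = 1, D = 1)), 1L)
  expect_equal(count_losses(st, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_error(count_losses(st, c(A = 0, B = 0, C = 0, D = 0)), "absent")
  set.seed(23)
  for (i in 1:30) {
    tr <- rand_tree(8)
    site <- rand_site(tr)
    expect_equal(count_losses(tr, site), oracle_loss_count(tr, site))
  }
})

test_that("stem-branch asymmetry sums multi-edge paths", {
  tr <- ape::read.tree(text = "((a:0.5,b:1.5)d:1,c:1)r;")
  ba <- branch_asymmetry(tr, "d")
  expect_equal(unname(ba$lengths), c(0.5, 1.5))
  expect_equal(ba$ratio, 3.0)
  expect_equal(ba$shorter, "a")
  tr2 <- ape::read.tree(text = "((a:1,b:1)d:1,c:1)r;")
  expect_equal(branch_asymmetry(tr2, "d")$ratio, 1.0)
  # path through an intermediate node down to the orthogroup ancestors
  tr3 <- ape::read.tree(
    text = "(((a1:1,a2:1)la:0.3,((q1:1,q2:1)lb:0.4)u:0.2)d:1,c:1)r;")
  ba3 <- branch_asymmetry(tr3, "d", leca_nodes = c("la", "lb"))
  expect_equal(sort(unname(ba3$lengths)), c(0.3, 0.6))
  expect_equal(ba3$ratio, 2.0)
  expect_error(branch_asymmetry(ape::read.tree(text = "(a:1,b:1,c:1)m;"), "m"),
               "children")
})

test_that("slow-representative selection picks shortest non-deviating tips", {
  tr <- ape::read.tree(
    text = "(((o1:0.1,o2:0.4)x:0.1,o3:0.2)y:0.1,((d1:0.3,d2:0.2)z:0.1,d3:10)w:0.1)r;")
  og <- setNames(rep("og1", 6), c("o1", "o2", "o3", "d1", "d2", "d3"))
  clades <- c(o1 = "Opimoda", o2 = "Opimoda", o3 = "Opimoda",
              d1 = "Diphoda", d2 = "Diphoda", d3 = "Diphoda")
  sel <- select_slow_representatives(tr, og, clades, mode = "shortest",
                                     outlier_factor = 5)
  expect_equal(sel$tip[sel$clade == "Opimoda"], "o1")
  expect_equal(sel$tip[sel$clade == "Diphoda"], "d2")
  # a tip far beyond the clade median norm is excluded even when shortest
  og2 <- c(o1 = "og1", o2 = "og1", o3 = "og1", d1 = "og1", d2 = "og1",
           d3 = "og2")
  sel2 <- select_slow_representatives(tr, og2, clades, mode = "shortest",
                                      outlier_factor = 5)
  # og2's only Diphoda tip sits at 10 vs clade median 0.3: skipped entirely
  expect_false(any(sel2$og == "og2"))
  # a clade absent from an orthogroup is skipped without error
  og3 <- c(o1 = "og1", o2 = "og1", o3 = "og1", d1 = "og3", d2 = "og3",
           d3 = "og3")
  sel3 <- select_slow_representatives(tr, og3, clades)
  expect_false("Diphoda" %in% sel3$clade[sel3$og == "og1"])
})

test_that("bidirectional-best-hit mode returns mutually nearest pairs", {
  tr <- ape::read.tree(
    text = "((o1:0.1,o2:0.5)x:0.1,(d1:0.1,d2:0.5)y:0.1)r;")
  og <- setNames(rep("og1", 4), c("o1", "o2", "d1", "d2"))
  clades <- c(o1 = "Opimoda", o2 = "Opimoda", d1 = "Diphoda", d2 = "Diphoda")
  sel <- select_slow_representatives(tr, og, clades, mode = "bbh")
  expect_equal(sel$opimoda_tip, "o1")
  expect_equal(sel$diphoda_tip, "d1")
  expect_equal(sel$distance, 0.4)
})
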