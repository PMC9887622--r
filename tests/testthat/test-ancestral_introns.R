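test_that("Dollo places the gain at the MRCA and losses on absent branches", {
  tr <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)r;")
  m <- matrix(c(1, 0, 1, 0,  1, 0, 0, 0), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  d <- dollo_reconstruct(tr, m)
  expect_equal(unname(d$gain_node["s1"]), "r")
  expect_equal(unname(d$states[c("r", "n1", "n2"), "s1"]), c(1L, 1L, 1L))
  expect_setequal(d$losses$child[d$losses$site == "s1"], c("B", "D"))
  # single present tip: gain on the terminal branch, no losses
  expect_equal(unname(d$gain_node["s2"]), "A")
  expect_equal(unname(d$states["r", "s2"]), 0L)
  expect_equal(sum(d$losses$site == "s2"), 0)
  # a site present in no tip cannot exist
  m0 <- cbind(m, s3 = c(0, 0, 0, 0))
  expect_error(dollo_reconstruct(tr, m0), "present in no tip")
})

test_that("Dollo equals the exhaustive single-gain minimum-loss oracle", {
  set.seed(10)
  for (i in 1:40) {
    tr <- rand_tree(sample(3:6, 1))
    site <- rand_site(tr)
    d <- dollo_reconstruct(tr, matrix(site, ncol = 1,
                                      dimnames = list(names(site), "s")))
    o <- oracle_dollo_states(tr, site)
    keys <- spliceotrace:::node_keys(tr)
    expect_identical(unname(d$states[keys, "s"]), o$states)
    expect_equal(sum(d$losses$site == "s"), o$losses)
  }
})

test_that("Markov posteriors match direct enumeration to 1e-9", {
  set.seed(11)
  for (i in 1:30) {
    tr <- rand_tree(sample(2:5, 1), bl = c(0.05, 2))
    site <- rand_site(tr)
    gain <- runif(1, 0.05, 2)
    loss <- runif(1, 0.05, 2)
    prior <- c(loss, gain) / (gain + loss)
    mk <- markov_posterior(tr, matrix(site, ncol = 1,
                                      dimnames = list(names(site), "s")),
                           gain, loss)
    keys <- spliceotrace:::node_keys(tr)
    for (v in seq_along(keys)) {
      expect_equal(unname(mk$posterior[keys[v], "s"]),
                   oracle_markov_posterior(tr, site, gain, loss, prior, v),
                   tolerance = 1e-9)
    }
  }
})

test_that("Markov limits behave: impossible gains, impossible transitions", {
  tr <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)r;")
  m <- matrix(c(1, 0, 1, 0), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), "s"))
  # gains impossible + a present tip: present back to the root
  mk0 <- markov_posterior(tr, m, gain_rate = 0, loss_rate = 1)
  expect_equal(unname(mk0$posterior["r", "s"]), 1)
  # no rates at all with conflicting tips: zero-likelihood data
  expect_error(markov_posterior(tr, m, 0, 0), "zero likelihood")
  # losses impossible: ancestors of absent tips cannot have carried the site
  mk1 <- markov_posterior(tr, m, gain_rate = 0.5, loss_rate = 0)
  expect_equal(unname(mk1$posterior[c("r", "n1", "n2"), "s"]), c(0, 0, 0))
  # two-tip worked case against the independent enumeration oracle
  tr2 <- ape::read.tree(text = "(A:1,B:1)r;")
  m2 <- matrix(c(1, 1), nrow = 2, dimnames = list(c("A", "B"), "s"))
  mk2 <- markov_posterior(tr2, m2, 1, 1, root_prior = c(0.5, 0.5))
  expect_equal(unname(mk2$posterior["r", "s"]),
               oracle_markov_posterior(tr2, c(A = 1, B = 1), 1, 1,
                                       c(0.5, 0.5), 3),
               tolerance = 1e-12)
})

test_that("with vanishing loss rate Markov calls converge to Dollo states", {
  set.seed(12)
  for (i in 1:10) {
    tr <- rand_tree(sample(4:6, 1), bl = c(0.2, 1))
    # loss-free data: one clade carries the site
    dt <- spliceotrace:::descendant_tips(tr)
    v <- sample(seq_along(dt), 1)
    site <- setNames(rep(0L, length(tr$tip.label)), tr$tip.label)
    site[tr$tip.label[dt[[v]]]] <- 1L
    m <- matrix(site, ncol = 1, dimnames = list(names(site), "s"))
    d <- dollo_reconstruct(tr, m)
    # a fixed prior isolates the likelihood limit (the stationary prior
    # itself degenerates to all-present as the loss rate vanishes)
    mk <- markov_posterior(tr, m, gain_rate = 0.05, loss_rate = 1e-9,
                           root_prior = c(0.5, 0.5))
    expect_identical(unname(mk$calls[rownames(d$states), "s"]),
                     unname(d$states[, "s"]))
  }
})

test_that("preduplication sites follow gain-node ancestry, not clade sharing", {
  nwk <- "(((A1:1,B1:1)c1:1,((A2:1,B2:1)c2:1,(A3:1,B3:1)c3:1)D2:1)D1:1,(O1:1,O2:1)og:1)r;"
  tr <- ape::read.tree(text = nwk)
  m <- matrix(0L, nrow = 8, ncol = 3,
              dimnames = list(c("A1", "B1", "A2", "B2", "A3", "B3", "O1", "O2"),
                              c("pre_d1", "between", "inside")))
  m[c("A1", "B1", "A2", "B2", "A3", "B3"), "pre_d1"] <- 1L  # gained at D1
  m[c("A2", "B2", "A3", "B3"), "between"] <- 1L             # gained at D2
  m[c("A2", "B2"), "inside"] <- 1L                          # gained below D2
  d <- dollo_reconstruct(tr, m)
  pre <- preduplication_sites(d, c("D1", "D2"))
  expect_setequal(pre$D1, "pre_d1")
  expect_setequal(pre$D2, c("pre_d1", "between"))
  # outgroup-shared site counts for both duplications
  m2 <- m
  m2[c("O1", "A1"), "pre_d1"] <- c(1L, 1L)
  d2 <- dollo_reconstruct(tr, m2)
  pre2 <- preduplication_sites(d2, c("D1", "D2"))
  expect_true("pre_d1" %in% pre2$D1)
  expect_error(preduplication_sites(d, "A1"), "internal")
  expect_error(preduplication_sites(d, "nope"), "not found")
})

test_that("shared-intron summaries reproduce the printed arithmetic", {
  records <- data.frame(
    class = c(rep("to", 29), rep("within", 39)),
    n_preduplication = c(rep(1, 13), rep(0, 16), rep(2, 18), rep(0, 21))
  )
  s <- shared_intron_summary(records)
  expect_equal(s$pct_with_shared[s$class == "to"], 45)
  expect_equal(s$pct_with_shared[s$class == "within"], 46)
  expect_equal(s$n_with_shared[s$class == "to"], 13)
  zero <- shared_intron_summary(data.frame(class = "to", n_preduplication = 0))
  expect_equal(zero$pct_with_shared, 0)
  expect_error(shared_intron_summary(
    data.frame(class = character(0), n_preduplication = numeric(0))), "empty")
  expect_equal(percent_present(86, 145), 59)
  expect_equal(percent_present(145, 145), 100)
})
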