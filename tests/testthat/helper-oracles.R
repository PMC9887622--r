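## Independent brute-force oracles. These deliberately share no code with
## the package: everything is recomputed from tree$edge by enumeration.

## tips below node v, using only the edge matrix
oracle_desc_tips <- function(tree, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(v)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  unlist(lapply(kids, function(k) oracle_desc_tips(tree, k)))
}

## Enumerate every internal-state assignment for a binary site; keep
## single-gain assignments (exactly one 0->1 transition, counting a present
## root as the gain); return the states of the minimum-loss assignment.
oracle_dollo_states <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  nn <- ntip + nint
  tip_states <- tip_states[tree$tip.label]
  best <- NULL
  best_losses <- Inf
  for (bits in 0:(2^nint - 1)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tip_states
    st[ntip + seq_len(nint)] <- as.integer(bitwAnd(bits %/% 2^(0:(nint - 1)), 1))
    root <- ntip + 1L
    gains <- st[root]
    losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      a <- st[tree$edge[e, 1]]
      b <- st[tree$edge[e, 2]]
      if (a == 0 && b == 1) gains <- gains + 1L
      if (a == 1 && b == 0) losses <- losses + 1L
    }
    if (gains != 1L) next
    if (losses < best_losses) {
      best_losses <- losses
      best <- st
    }
  }
  list(states = best, losses = best_losses)
}

## Minimum loss count with the root forced present and gains forbidden.
oracle_loss_count <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  nn <- ntip + nint
  tip_states <- tip_states[tree$tip.label]
  best <- Inf
  for (bits in 0:(2^nint - 1)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tip_states
    st[ntip + seq_len(nint)] <- as.integer(bitwAnd(bits %/% 2^(0:(nint - 1)), 1))
    if (st[ntip + 1L] != 1L) next  # root present
    losses <- 0L
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      a <- st[tree$edge[e, 1]]
      b <- st[tree$edge[e, 2]]
      if (a == 0 && b == 1) { ok <- FALSE; break }  # no regain
      if (a == 1 && b == 0) losses <- losses + 1L
    }
    if (ok && losses < best) best <- losses
  }
  best
}

## Posterior presence probability at one node by direct summation over all
## internal-state assignments of the two-state gain/loss chain.
oracle_markov_posterior <- function(tree, tip_states, gain, loss, prior, node) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  nn <- ntip + nint
  tip_states <- tip_states[tree$tip.label]
  ptrans <- function(a, b, t) {
    r <- gain + loss
    if (r == 0) return(as.numeric(a == b))
    f <- 1 - exp(-r * t)
    if (a == 0 && b == 1) return(gain / r * f)
    if (a == 1 && b == 0) return(loss / r * f)
    if (a == 0) return(1 - gain / r * f)
    1 - loss / r * f
  }
  total <- 0
  with_node <- 0
  for (bits in 0:(2^nint - 1)) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tip_states
    st[ntip + seq_len(nint)] <- as.integer(bitwAnd(bits %/% 2^(0:(nint - 1)), 1))
    p <- prior[st[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * ptrans(st[tree$edge[e, 1]], st[tree$edge[e, 2]],
                      tree$edge.length[e])
    }
    total <- total + p
    if (st[node] == 1L) with_node <- with_node + p
  }
  with_node / total
}

## Naive recurrence score of a fate assignment, recomputed from raw strings.
## z[d] = TRUE means side B of duplication d is fate 1.
oracle_fate_score <- function(seqs, dups, z, min_events = NULL) {
  width <- nchar(seqs[[1]])
  side_res <- function(tips, c) {
    v <- substr(seqs[tips], c, c)
    v <- v[v != "-"]
    if (length(v) == 0 || length(unique(v)) != 1) return(NA_character_)
    v[[1]]
  }
  score <- 0L
  cols <- integer(0)
  for (c in seq_len(width)) {
    ra <- vapply(dups, function(d) side_res(d$tips_a, c), character(1))
    rb <- vapply(dups, function(d) side_res(d$tips_b, c), character(1))
    data_d <- which(!is.na(ra) & !is.na(rb))
    diff_d <- data_d[ra[data_d] != rb[data_d]]
    req <- if (is.null(min_events)) max(2L, length(data_d)) else max(2L, min_events)
    if (length(diff_d) < req) next
    f1 <- ifelse(z[diff_d], rb[diff_d], ra[diff_d])
    f2 <- ifelse(z[diff_d], ra[diff_d], rb[diff_d])
    if (length(unique(f1)) == 1 && length(unique(f2)) == 1) {
      score <- score + 1L
      cols <- c(cols, c)
    }
  }
  list(score = score, columns = cols)
}

oracle_fate_best <- function(seqs, dups, min_events = NULL) {
  k <- length(dups)
  best <- list(score = -1L)
  for (bits in 0:(2^k - 1)) {
    z <- as.logical(bitwAnd(bits %/% 2^(0:(k - 1)), 1))
    s <- oracle_fate_score(seqs, dups, z, min_events)
    if (s$score > best$score) best <- c(s, list(z = z))
  }
  best
}

## random rooted binary tree with uniform branch lengths
rand_tree <- function(n, bl = NULL) {
  tr <- ape::rtree(n, rooted = TRUE)
  if (!is.null(bl)) tr$edge.length <- runif(nrow(tr$edge), bl[1], bl[2])
  tr
}

## random binary tip-state vector with at least one present tip
rand_site <- function(tree) {
  repeat {
    s <- sample(0:1, length(tree$tip.label), replace = TRUE)
    if (any(s == 1)) break
  }
  setNames(s, tree$tip.label)
}

flip_fates <- function(x) {
  ifelse(x == "fate1", "fate2", ifelse(x == "fate2", "fate1", x))
}
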