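#' Dollo parsimony reconstruction of intron presence
#'
#' Under Dollo parsimony a character can be gained exactly once and lost any
#' number of times. For each intron site the gain node is the most recent
#' common ancestor of the tips carrying it (the terminal branch itself when a
#' single tip carries it); an internal node has state 1 exactly when it lies
#' on a path from the gain node to a present tip, which minimizes the number
#' of losses given the single-gain constraint.
#'
#' @param tree Rooted `phylo` gene tree whose tips are the matrix rows.
#' @param presence Binary matrix (tips x sites) such as the `presence`
#'   element of [project_introns()], or an `intron_matrix`.
#' @return Object of class `dollo_reconstruction`: list with `states`
#'   (binary matrix, all nodes x sites, rows named by node key), `gain_node`
#'   (named character: site -> gain node key), `losses` (data frame `site`,
#'   `parent`, `child` of loss branches, child keys identify the branch) and
#'   `tree`.
#' @export
dollo_reconstruct <- function(tree, presence) {
  if (inherits(presence, "intron_matrix")) presence <- presence$presence
  stopifnot(is.matrix(presence))
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(presence))
  if (length(missing)) {
    stop("tree tip(s) absent from presence matrix: ", paste(missing, collapse = ", "))
  }
  presence <- presence[tips, , drop = FALSE]
  ntip <- length(tips)
  keys <- node_keys(tree)
  parents <- parent_vector(tree)
  dtips <- descendant_tips(tree)
  nn <- n_nodes_total(tree)
  nsite <- ncol(presence)
  sites <- colnames(presence)
  if (is.null(sites)) sites <- as.character(seq_len(nsite))

  states <- matrix(0L, nrow = nn, ncol = nsite, dimnames = list(keys, sites))
  gain <- character(nsite)
  losses <- list()
  for (j in seq_len(nsite)) {
    pres_tips <- which(presence[, j] == 1L)
    if (length(pres_tips) == 0) {
      stop("site '", sites[j], "' is present in no tip; such a site cannot ",
           "exist in a matrix built from observed introns")
    }
    g <- if (length(pres_tips) == 1) pres_tips else ape::getMRCA(tree, tips[pres_tips])
    gain[j] <- keys[g]
    sub <- descendant_nodes(tree, g)
    has_present <- vapply(sub, function(v) any(dtips[[v]] %in% pres_tips), logical(1))
    on_path <- sub[has_present]
    states[on_path, j] <- 1L
    # losses: branches from a state-1 parent to a state-0 child
    st <- states[, j]
    loss_children <- which(st == 0L & !is.na(parents) & st[parents] == 1L)
    if (length(loss_children)) {
      losses[[length(losses) + 1L]] <- data.frame(
        site = sites[j], parent = keys[parents[loss_children]],
        child = keys[loss_children]
      )
    }
  }
  losses <- if (length(losses)) do.call(rbind, losses) else
    data.frame(site = character(0), parent = character(0), child = character(0))
  structure(
    list(states = states, gain_node = setNames(gain, sites), losses = losses,
         tree = tree),
    class = "dollo_reconstruction"
  )
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("<dollo_reconstruction> ", ncol(x$states), " sites on ",
      length(x$tree$tip.label), " tips; ", nrow(x$losses), " losses\n", sep = "")
  invisible(x)
}

## 2x2 transition probability matrix of the gain/loss chain over time t.
## State order: 1 = absent, 2 = present. Rates: gain (0->1), loss (1->0).
gl_transition <- function(gain, loss, t) {
  r <- gain + loss
  if (r == 0 || t == 0) return(diag(2))
  f <- 1 - exp(-r * t)
  p01 <- gain / r * f
  p10 <- loss / r * f
  matrix(c(1 - p01, p10, p01, 1 - p10), nrow = 2)
}

#' Posterior intron presence under a two-state gain/loss Markov model
#'
#' Computes, by Felsenstein pruning (tip-to-root pass) followed by a
#' root-to-tip pass, the marginal posterior probability that each node of
#' the tree carried each intron site. The root prior is the stationary
#' distribution of the chain when both rates are positive; when either rate
#' is zero the stationary distribution is degenerate and a uniform (1/2,
#' 1/2) prior is used instead so the limiting behaviours are well defined
#' (with gains impossible, a present tip forces presence back to the root;
#' with losses impossible, an absent tip below a present site is
#' zero-likelihood data and raises an error).
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param presence Binary tips x sites matrix or `intron_matrix`.
#' @param gain_rate Gain rate (0 -> 1) per unit branch length, per site.
#' @param loss_rate Loss rate (1 -> 0) per unit branch length, per intron.
#' @param root_prior Optional length-2 numeric `(P(absent), P(present))`
#'   overriding the default prior.
#' @param call_threshold Posterior at or above which a node is called
#'   present (default 0.5).
#' @return Object of class `markov_reconstruction`: list with `posterior`
#'   (nodes x sites matrix of presence probabilities; tip rows are their
#'   observed states), `calls` (binary matrix from `call_threshold`),
#'   `root_prior`, and the rates.
#' @export
markov_posterior <- function(tree, presence, gain_rate, loss_rate,
                             root_prior = NULL, call_threshold = 0.5) {
  if (inherits(presence, "intron_matrix")) presence <- presence$presence
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be non-negative")
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(presence))
  if (length(missing)) {
    stop("tree tip(s) absent from presence matrix: ", paste(missing, collapse = ", "))
  }
  presence <- presence[tips, , drop = FALSE]
  if (is.null(root_prior)) {
    root_prior <- if (gain_rate > 0 && loss_rate > 0) {
      c(loss_rate, gain_rate) / (gain_rate + loss_rate)
    } else {
      c(0.5, 0.5)
    }
  }
  stopifnot(length(root_prior) == 2, all(root_prior >= 0),
            abs(sum(root_prior) - 1) < 1e-8)

  ntip <- length(tips)
  nn <- n_nodes_total(tree)
  keys <- node_keys(tree)
  ch <- children_list(tree)
  bl <- branch_above(tree)
  post_order <- postorder_simple(tree)
  pre_order <- preorder_simple(tree)
  root <- root_node(tree)
  # per-node transition matrix for the branch above
  P <- vector("list", nn)
  for (v in seq_len(nn)) {
    if (!is.na(bl[v])) P[[v]] <- gl_transition(gain_rate, loss_rate, bl[v])
  }

  nsite <- ncol(presence)
  sites <- colnames(presence)
  posterior <- matrix(NA_real_, nrow = nn, ncol = nsite,
                      dimnames = list(keys, sites))
  for (j in seq_len(nsite)) {
    up <- matrix(NA_real_, nrow = nn, ncol = 2)
    for (v in post_order) {
      if (v <= ntip) {
        s <- presence[v, j]
        up[v, ] <- if (s == 1L) c(0, 1) else c(1, 0)
      } else {
        lik <- c(1, 1)
        for (c in ch[[v]]) lik <- lik * (P[[c]] %*% up[c, ])[, 1]
        up[v, ] <- lik
      }
    }
    total <- sum(root_prior * up[root, ])
    if (total <= 0) {
      stop("site '", sites[j], "' has zero likelihood under gain_rate = ",
           gain_rate, ", loss_rate = ", loss_rate,
           " (conflicting tip states with an impossible transition)")
    }
    down <- matrix(NA_real_, nrow = nn, ncol = 2)
    down[root, ] <- root_prior
    for (v in pre_order) {
      if (v <= ntip && v != root) next
      for (c in ch[[v]]) {
        # message from above v, combined with v's other children
        msg <- down[v, ]
        for (b in ch[[v]]) {
          if (b != c) msg <- msg * (P[[b]] %*% up[b, ])[, 1]
        }
        down[c, ] <- as.vector(msg %*% P[[c]])
      }
    }
    w <- up * down
    posterior[, j] <- w[, 2] / rowSums(w)
  }
  calls <- (posterior >= call_threshold) * 1L
  structure(
    list(posterior = posterior, calls = calls, root_prior = root_prior,
         gain_rate = gain_rate, loss_rate = loss_rate, tree = tree),
    class = "markov_reconstruction"
  )
}

#' @export
print.markov_reconstruction <- function(x, ...) {
  cat("<markov_reconstruction> ", ncol(x$posterior), " sites, gain ",
      x$gain_rate, ", loss ", x$loss_rate, "\n", sep = "")
  invisible(x)
}

#' Intron sites predating each duplication node
#'
#' A site is preduplication for a duplication node when its Dollo gain node
#' is that node or one of its ancestors — equivalently, under Dollo, when it
#' is present in both child clades of the duplication or shared with the
#' duplication's outgroup.
#'
#' @param dollo A [dollo_reconstruct()] result.
#' @param duplication_nodes Internal nodes (keys or numbers) annotated as
#'   duplications.
#' @return Named list: per duplication node key, the character vector of
#'   preduplication site ids.
#' @export
preduplication_sites <- function(dollo, duplication_nodes) {
  stopifnot(inherits(dollo, "dollo_reconstruction"))
  tree <- dollo$tree
  nodes <- resolve_nodes(tree, duplication_nodes)
  ntip <- length(tree$tip.label)
  if (any(nodes <= ntip)) stop("duplication nodes must be internal nodes")
  keys <- node_keys(tree)
  parents <- parent_vector(tree)
  gain_nodes <- resolve_nodes(tree, unname(dollo$gain_node))
  out <- vector("list", length(nodes))
  names(out) <- keys[nodes]
  for (i in seq_along(nodes)) {
    d <- nodes[i]
    anc <- c(d, ancestor_nodes(tree, d, parents))
    out[[i]] <- names(dollo$gain_node)[gain_nodes %in% anc]
  }
  out
}

## nearest-integer rounding that always rounds halves up
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize shared (preduplication) introns per duplication class
#'
#' For each duplication class, counts how many duplications retained at
#' least one intron traceable to the preduplication state and reports the
#' percentage rounded to the nearest integer.
#'
#' @param records Data frame with one row per duplication, columns `class`
#'   and `n_preduplication` (count of preduplication intron sites).
#' @return Data frame with columns `class`, `n_total`, `n_with_shared`,
#'   `pct_with_shared`.
#' @export
shared_intron_summary <- function(records) {
  req <- c("class", "n_preduplication")
  if (!all(req %in% colnames(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(records) == 0) stop("empty duplication record list")
  classes <- unique(records$class)
  out <- data.frame(
    class = classes,
    n_total = vapply(classes, function(cl) sum(records$class == cl), integer(1)),
    n_with_shared = vapply(classes, function(cl) {
      sum(records$class == cl & records$n_preduplication >= 1)
    }, integer(1))
  )
  out$pct_with_shared <- round_half_up(100 * out$n_with_shared / out$n_total)
  rownames(out) <- NULL
  out
}

#' Percentage of orthogroups retained, nearest integer
#'
#' @param n_present Number of orthogroups present.
#' @param n_total Total number of orthogroups.
#' @return Percentage rounded to the nearest integer.
#' @export
percent_present <- function(n_present, n_total) {
  if (n_total < 1) stop("n_total must be positive")
  round_half_up(100 * n_present / n_total)
}
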