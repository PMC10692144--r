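# Independent oracles used across the suite.  These deliberately avoid the
# package's own shortcuts: reconciliation cost is minimized over all
# explicit embeddings by dynamic programming, Dollo is solved as Sankoff
# small parsimony with a prohibitive gain cost, and the pruning likelihood
# is checked against exhaustive enumeration of internal states.

# random rooted binary tree with unique tip labels and given branch lengths
random_tree <- function(n, lengths = TRUE) {
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  if (!lengths) tr$edge.length <- NULL
  tr
}

tree_children <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

tree_depths <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- rep(NA_integer_, n)
  depth[length(tree$tip.label) + 1L] <- 0L
  for (v in tree$edge[, 2]) depth[v] <- depth[parent[v]] + 1L
  list(parent = parent, depth = depth)
}

descendants_or_self <- function(tree, s) {
  ntip <- length(tree$tip.label)
  kids <- tree_children(tree)
  out <- integer(0)
  stack <- s
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    if (v > ntip) stack <- c(kids[[v]], stack)
  }
  out
}

# Minimum duplication + loss cost over all explicit embeddings of a rooted
# binary gene tree into a rooted species tree.  dp[g][s] = min cost of the
# subtree of g when g is embedded at species node s.  A speciation at s
# sends the two children into two *different* child subtrees of s (each
# strictly below); a duplication keeps both at or below s.  Each level a
# child edge crosses without an observable speciation is one loss.
oracle_dl_cost <- function(gene_tree, species_tree, leaf_species) {
  gntip <- length(gene_tree$tip.label)
  sntip <- length(species_tree$tip.label)
  sn <- sntip + species_tree$Nnode
  gkids <- tree_children(gene_tree)
  skids <- tree_children(species_tree)
  sd <- tree_depths(species_tree)
  below <- lapply(seq_len(sn), function(s) descendants_or_self(species_tree, s))
  dp <- matrix(Inf, gntip + gene_tree$Nnode, sn)
  post <- ape::reorder.phylo(gene_tree, "postorder")
  ord <- c(post$edge[, 2], gntip + 1L)
  for (g in ord) {
    if (g <= gntip) {
      s <- match(leaf_species[[gene_tree$tip.label[g]]],
                 species_tree$tip.label)
      dp[g, s] <- 0
      next
    }
    ab <- gkids[[g]]
    a <- ab[1]; b <- ab[2]
    for (s in seq_len(sn)) {
      best <- Inf
      # duplication at s
      for (sa in below[[s]]) for (sb in below[[s]]) {
        ca <- dp[a, sa]; cb <- dp[b, sb]
        if (!is.finite(ca + cb)) next
        cost <- 1 + ca + cb +
          (sd$depth[sa] - sd$depth[s]) + (sd$depth[sb] - sd$depth[s])
        if (cost < best) best <- cost
      }
      # speciation at s (internal species nodes only)
      if (s > sntip) {
        ch <- skids[[s]]
        for (pick in list(c(1, 2), c(2, 1))) {
          for (sa in below[[ch[pick[1]]]]) for (sb in below[[ch[pick[2]]]]) {
            ca <- dp[a, sa]; cb <- dp[b, sb]
            if (!is.finite(ca + cb)) next
            cost <- ca + cb +
              (sd$depth[sa] - sd$depth[s] - 1) +
              (sd$depth[sb] - sd$depth[s] - 1)
            if (cost < best) best <- cost
          }
        }
      }
      dp[g, s] <- best
    }
  }
  min(dp[gntip + 1L, ])
}

# Sankoff small parsimony for Dollo: binary character, loss cost 1, gain
# cost G chosen larger than any possible loss count, so the optimum has a
# single gain and the loss count is (min cost - G).
oracle_dollo_losses <- function(species_tree, present) {
  G <- 1000
  ntip <- length(species_tree$tip.label)
  kids <- tree_children(species_tree)
  post <- ape::reorder.phylo(species_tree, "postorder")
  ord <- c(post$edge[, 2], ntip + 1L)
  cost <- matrix(Inf, ntip + species_tree$Nnode, 2)  # state 0, state 1
  trans <- matrix(c(0, G, 1, 0), 2, 2, byrow = TRUE)  # trans[from, to]
  for (v in ord) {
    if (v <= ntip) {
      st <- as.integer(species_tree$tip.label[v] %in% present)
      cost[v, st + 1L] <- 0
      next
    }
    for (s in 1:2) {
      tot <- 0
      for (ch in kids[[v]]) {
        tot <- tot + min(cost[ch, 1] + trans[s, 1], cost[ch, 2] + trans[s, 2])
      }
      cost[v, s] <- tot
    }
  }
  root <- ntip + 1L
  total <- min(cost[root, 1], cost[root, 2] + G)
  total - G
}

# Exhaustive-state pruning likelihood for tiny trees (sum over all
# internal-node residue assignments), single rate category.
oracle_loglik_enum <- function(tree, aln_codes, blen_by_node) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- tree_children(tree)
  pi <- unname(lg_frequencies())
  Pmat <- lapply(seq_len(ntip + nnode), function(v) {
    if (is.na(blen_by_node[v])) NULL else lg_transition(blen_by_node[v])
  })
  internals <- (ntip + 1L):(ntip + nnode)
  states <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  total <- 0
  for (site in seq_len(ncol(aln_codes))) {
    lik <- 0
    for (r in seq_len(nrow(states))) {
      assign_ <- states[r, ]
      getstate <- function(v) {
        if (v <= ntip) aln_codes[v, site] else assign_[v - ntip]
      }
      p <- pi[assign_[1]]  # root is first internal node
      for (i in seq_len(nrow(tree$edge))) {
        u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
        p <- p * Pmat[[v]][getstate(u), getstate(v)]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# shared tiny fixture: a taxonomy table written to a temp file
write_tax_file <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
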