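# ---------------------------------------------------------------------------
# Gene-tree / species-tree reconciliation under duplication-loss parsimony.
# Each gene-tree node is mapped to the most recent common ancestor (in the
# species tree) of its descendant species (LCA mapping); a node is a
# duplication when a child maps to the same species node, and losses follow
# the standard depth-difference rule.  Poorly supported gene-tree branches
# can be rearranged to the most parsimonious reconciliation.  Dollo
# parsimony maps gene presence/absence to a single gain plus minimal losses.
# ---------------------------------------------------------------------------

# parent pointer and depth vectors for a rooted phylo
.tree_index <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- length(tree$tip.label) + 1L
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  ord <- c(root, tree$edge[, 2])  # preorder if edges are in cladewise order
  for (v in tree$edge[, 2]) depth[v] <- depth[parent[v]] + 1L
  list(parent = parent, depth = depth, root = root)
}

# MRCA of two species-tree nodes via parent pointers
.node_mrca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] > idx$depth[b]) a <- idx$parent[a] else
      if (idx$depth[b] > idx$depth[a]) b <- idx$parent[b] else {
        a <- idx$parent[a]; b <- idx$parent[b]
      }
  }
  a
}

# postorder node sequence (children before parents)
.postorder_nodes <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  c(tr$edge[, 2][!duplicated(tr$edge[, 2])], length(tree$tip.label) + 1L)
}

#' LCA mapping of gene-tree nodes onto a species tree
#'
#' @param gene_tree Rooted gene tree (`phylo`), tips are sequence ids.
#' @param species_tree Rooted species tree (`phylo`).
#' @param leaf_species Named character vector: gene tip label -> species
#'   (a species-tree tip label).
#' @return Integer vector: for every gene-tree node (ape numbering), the
#'   species-tree node it maps to.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_species) {
  gt <- gene_tree
  ntip <- length(gt$tip.label)
  sp <- leaf_species[gt$tip.label]
  if (anyNA(sp)) {
    stop("no species for gene leaves: ",
         paste(gt$tip.label[is.na(sp)], collapse = ", "))
  }
  stip <- match(sp, species_tree$tip.label)
  if (anyNA(stip)) {
    stop("species not in species tree: ",
         paste(unique(sp[is.na(stip)]), collapse = ", "))
  }
  sidx <- .tree_index(species_tree)
  kids <- .children_list(gt)
  map <- rep(NA_integer_, ntip + gt$Nnode)
  map[seq_len(ntip)] <- stip
  for (v in .postorder_nodes(gt)) {
    if (v <= ntip) next
    ims <- map[unlist(kids[[v]])]
    m <- ims[1]
    for (w in ims[-1]) m <- .node_mrca(sidx, m, w)
    map[v] <- m
  }
  map
}

#' Duplication/loss reconciliation of a rooted binary gene tree
#'
#' Duplication at node g iff some child of g maps to the same species node
#' as g.  Losses follow the depth-difference rule: a child edge whose image
#' lies k levels below its parent's image implies k - 1 losses under a
#' speciation parent and k under a duplication parent.
#'
#' @inheritParams lca_map
#' @return A `reconciliation` list: `mapping`, `events` (per internal gene
#'   node, `"speciation"`/`"duplication"`), `duplications`, `losses`,
#'   `loss_edges` (data.frame of species-tree edges `parent`, `child`).
#' @export
count_dup_loss <- function(gene_tree, species_tree, leaf_species) {
  ntip <- length(gene_tree$tip.label)
  kids <- .children_list(gene_tree)
  deg <- lengths(kids)[(ntip + 1L):(ntip + gene_tree$Nnode)]
  if (any(deg > 2)) {
    stop("gene tree contains polytomies; resolve them first (see rearrange)")
  }
  map <- lca_map(gene_tree, species_tree, leaf_species)
  sidx <- .tree_index(species_tree)
  skids <- .children_list(species_tree)
  events <- rep(NA_character_, gene_tree$Nnode)
  names(events) <- as.character((ntip + 1L):(ntip + gene_tree$Nnode))
  loss_edges <- list()
  for (g in (ntip + 1L):(ntip + gene_tree$Nnode)) {
    ch <- unlist(kids[[g]])
    events[g - ntip] <-
      if (any(map[ch] == map[g])) "duplication" else "speciation"
  }
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1]; v <- gene_tree$edge[i, 2]
    dup <- events[u - ntip] == "duplication"
    # climb the species path from map(v) to map(u); each off-path sibling
    # edge strictly inside the path is a loss; under a duplication parent
    # the sibling at map(u) itself is lost too
    s <- map[v]
    while (s != map[u]) {
      p <- sidx$parent[s]
      if (p != map[u] || dup) {
        sib <- setdiff(unlist(skids[[p]]), s)
        for (w in sib) {
          loss_edges[[length(loss_edges) + 1L]] <- c(p, w)
        }
      }
      s <- p
    }
  }
  loss_edges <- if (length(loss_edges)) {
    as.data.frame(do.call(rbind, loss_edges)) |>
      stats::setNames(c("parent", "child"))
  } else data.frame(parent = integer(), child = integer())
  structure(list(
    mapping = map, events = events,
    duplications = sum(events == "duplication"),
    losses = nrow(loss_edges), loss_edges = loss_edges
  ), class = "reconciliation")
}

#' Root an unrooted gene tree
#'
#' Roots on the edge separating `outgroup` when given (and compatible with
#' some bipartition); otherwise scans every edge and roots where the
#' duplication + loss cost against the species tree is minimal (ties broken
#' by edge order).
#'
#' @param tree Unrooted gene tree.
#' @inheritParams lca_map
#' @param outgroup Optional character vector of tip labels.
#' @return Rooted binary `phylo`.
#' @export
root_gene_tree <- function(tree, species_tree = NULL, leaf_species = NULL,
                           outgroup = NULL) {
  if (!is.null(outgroup)) {
    unknown <- setdiff(outgroup, tree$tip.label)
    if (length(unknown)) stop("unknown outgroup tips: ",
                              paste(unknown, collapse = ", "))
    if (!is_monophyletic(tree, outgroup, rooted = FALSE)) {
      stop("outgroup is not a bipartition side of the tree")
    }
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  if (is.null(species_tree)) {
    stop("need a species tree (or an outgroup) to root")
  }
  best <- NULL; best_cost <- Inf
  for (i in seq_len(nrow(tree$edge))) {
    v <- tree$edge[i, 2]
    side <- clade_leaves(tree, v)
    if (length(side) == length(tree$tip.label)) next
    cand <- tryCatch(
      ape::root(tree, outgroup = side, resolve.root = TRUE),
      error = function(e) NULL
    )
    if (is.null(cand)) next
    rec <- count_dup_loss(cand, species_tree, leaf_species)
    cost <- rec$duplications + rec$losses
    if (cost < best_cost) { best <- cand; best_cost <- cost }
  }
  best
}

# --- nested-list tree helpers for rearrangement -----------------------------

.phylo_to_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- .children_list(tree)
  supp <- tree$support
  rec <- function(v) {
    if (v <= ntip) return(list(label = tree$tip.label[v]))
    s <- if (!is.null(supp)) supp[v - ntip] else NA_real_
    list(children = lapply(kids[[v]], rec), support = s)
  }
  rec(ntip + 1L)
}

.nested_to_newick <- function(n) {
  if (!is.null(n$label)) return(n$label)
  paste0("(", paste(vapply(n$children, .nested_to_newick, character(1)),
                    collapse = ","), ")")
}

.nested_to_phylo <- function(n) {
  parse_newick(paste0(.nested_to_newick(n), ";"))
}

# fast D+L score of a nested tree (no phylo conversion): returns the
# species image and accumulated duplication + loss cost; agrees with
# count_dup_loss on binary trees (checked by tests)
.score_nested <- function(node, stip, sidx) {
  if (!is.null(node$label)) {
    return(list(img = stip[[node$label]], cost = 0))
  }
  ch <- lapply(node$children, .score_nested, stip = stip, sidx = sidx)
  img <- ch[[1]]$img
  for (c2 in ch[-1]) img <- .node_mrca(sidx, img, c2$img)
  dup <- any(vapply(ch, function(c2) c2$img == img, logical(1)))
  cost <- sum(vapply(ch, `[[`, 0, "cost")) + dup
  for (c2 in ch) {
    cost <- cost + sidx$depth[c2$img] - sidx$depth[img] - !dup
  }
  list(img = img, cost = cost)
}

# all rooted binary topologies over a list of subtree units
.enumerate_resolutions <- function(units) {
  if (length(units) == 1L) return(list(units[[1]]))
  if (length(units) == 2L) {
    return(list(list(children = units, support = NA_real_)))
  }
  prev <- .enumerate_resolutions(units[-length(units)])
  x <- units[[length(units)]]
  out <- list()
  for (t in prev) {
    # insert x on every edge, and above the root
    out[[length(out) + 1L]] <-
      list(children = list(t, x), support = NA_real_)
    insert_all <- function(node) {
      # returns list of variants of `node` with x inserted somewhere below
      if (!is.null(node$label)) return(list())
      vars <- list()
      for (i in seq_along(node$children)) {
        child <- node$children[[i]]
        nd <- node
        nd$children[[i]] <- list(children = list(child, x),
                                 support = NA_real_)
        vars[[length(vars) + 1L]] <- nd
        for (sub in insert_all(child)) {
          nd2 <- node
          nd2$children[[i]] <- sub
          vars[[length(vars) + 1L]] <- nd2
        }
      }
      vars
    }
    out <- c(out, insert_all(t))
  }
  out
}

#' Rearrange poorly supported gene-tree branches to minimize D+L
#'
#' Internal edges with support below `support_threshold` are collapsed into
#' polytomies; each polytomy is then re-resolved to minimize the total
#' duplication + loss cost against the species tree (exhaustively for
#' polytomies of degree <= `exhaustive_max`, greedy stepwise insertion
#' above that).  The result never costs more than the input resolution.
#' Branch lengths are dropped: after rearrangement the original estimates
#' no longer apply, and downstream dating re-estimates them.
#'
#' @param gene_tree Rooted binary gene tree with a `support` vector
#'   (supports on \[0, 1\]; `NA` is treated as strong).
#' @inheritParams lca_map
#' @param support_threshold Edges with support below this are rearranged
#'   (default 0.9).
#' @param exhaustive_max Maximum polytomy degree resolved exhaustively
#'   (default 6; 945 candidate resolutions).
#' @return List `tree` (rearranged rooted binary `phylo`) and
#'   `reconciliation` (its [count_dup_loss()] result).
#' @export
rearrange <- function(gene_tree, species_tree, leaf_species,
                      support_threshold = 0.9, exhaustive_max = 6) {
  if (support_threshold < 0 || support_threshold > 1) {
    stop("support_threshold must be in [0, 1]")
  }
  sidx <- .tree_index(species_tree)
  stip <- setNames(
    match(leaf_species, species_tree$tip.label),
    names(leaf_species)
  )
  if (anyNA(stip)) stop("species not in species tree")
  score <- function(nested) .score_nested(nested, stip, sidx)$cost
  weak <- function(node) {
    !is.null(node$children) && !is.na(node$support) &&
      node$support < support_threshold
  }
  # recursively rebuild; at each node, absorb weak-edge children into a
  # polytomy unit list, then resolve that polytomy optimally in context
  current <- .phylo_to_nested(gene_tree)
  rebuild <- function(node, path_set) {
    # path_set: function(replacement_node) -> full nested tree with this
    # position substituted, used for in-context scoring
    if (!is.null(node$label)) return(node)
    units <- list()
    collect <- function(nd) {
      for (ch in nd$children) {
        if (weak(ch)) collect(ch) else units[[length(units) + 1L]] <<- ch
      }
    }
    collect(node)
    # first optimize within each unit (bottom-up)
    for (i in seq_along(units)) {
      ui <- i
      units[[i]] <- rebuild(
        units[[i]],
        function(rep) {
          u2 <- units; u2[[ui]] <- rep
          nd <- list(children = u2, support = node$support)
          path_set(.resolve_arbitrary(nd))
        }
      )
    }
    if (length(units) == length(node$children) &&
        !any(vapply(node$children, weak, logical(1)))) {
      out <- node
      out$children <- units
      return(out)
    }
    # polytomy: choose the resolution minimizing whole-tree D+L
    k <- length(units)
    orig <- node; orig$children <- units  # may still be the original shape
    if (k <= exhaustive_max) {
      cands <- .enumerate_resolutions(units)
    } else {
      cands <- list(.greedy_resolution(units, path_set, score))
    }
    # original (input) arrangement is always a candidate
    orig_resolved <- .original_subtree(node, units)
    cands <- c(cands, list(orig_resolved))
    costs <- vapply(cands, function(cd) score(path_set(cd)), numeric(1))
    best <- cands[[which.min(costs)]]
    best$support <- node$support
    best
  }
  result <- rebuild(current, function(rep) rep)
  out_tree <- .nested_to_phylo(result)
  rec <- count_dup_loss(out_tree, species_tree, leaf_species)
  list(tree = out_tree, reconciliation = rec)
}

# original binary arrangement of a (possibly weakly supported) subtree,
# with its units already optimized: re-attach optimized units in place
.original_subtree <- function(node, units) {
  leafset <- function(n) {
    if (!is.null(n$label)) return(n$label)
    sort(unlist(lapply(n$children, leafset)))
  }
  keys <- vapply(units, function(u) paste(leafset(u), collapse = "\r"),
                 character(1))
  sub <- function(n) {
    key <- paste(leafset(n), collapse = "\r")
    hit <- match(key, keys)
    if (!is.na(hit)) return(units[[hit]])
    n$children <- lapply(n$children, sub)
    n
  }
  sub(node)
}

# stepwise insertion: join largest two units, then insert the rest where
# the whole-tree cost is lowest
.greedy_resolution <- function(units, path_set, score) {
  sizes <- vapply(units, function(u) {
    if (!is.null(u$label)) 1L else length(unlist(u))
  }, integer(1))
  ord <- order(-sizes)
  units <- units[ord]
  cur <- list(children = units[1:2], support = NA_real_)
  for (i in 3:length(units)) {
    x <- units[[i]]
    cands <- .enumerate_insertions(cur, x)
    costs <- vapply(cands, function(cd) score(path_set(cd)), numeric(1))
    cur <- cands[[which.min(costs)]]
  }
  cur
}

.enumerate_insertions <- function(t, x) {
  out <- list(list(children = list(t, x), support = NA_real_))
  rec <- function(node) {
    if (!is.null(node$label)) return(list())
    vars <- list()
    for (i in seq_along(node$children)) {
      child <- node$children[[i]]
      nd <- node
      nd$children[[i]] <- list(children = list(child, x), support = NA_real_)
      vars[[length(vars) + 1L]] <- nd
      for (sub in rec(child)) {
        nd2 <- node; nd2$children[[i]] <- sub
        vars[[length(vars) + 1L]] <- nd2
      }
    }
    vars
  }
  c(out, rec(t))
}

# arbitrary binary resolution (ladder) used only to make a scoreable tree
# while units elsewhere are being optimized
.resolve_arbitrary <- function(node) {
  if (!is.null(node$label)) return(node)
  ch <- lapply(node$children, .resolve_arbitrary)
  while (length(ch) > 2) {
    ch <- c(list(list(children = ch[1:2], support = NA_real_)), ch[-(1:2)])
  }
  node$children <- ch
  node
}

#' Classify duplication events by taxonomic breadth
#'
#' A duplication is `species_specific` when all its descendant leaves come
#' from a single species, otherwise `multi_species` — the distinction drawn
#' between within-species paralog expansions and older duplications.
#'
#' @param rec A [count_dup_loss()] reconciliation.
#' @param gene_tree The reconciled gene tree.
#' @param leaf_species Named character vector, gene tip -> species.
#' @return Named character vector over duplication nodes (ape numbers as
#'   names); empty when there are no duplications.
#' @export
classify_duplications <- function(rec, gene_tree, leaf_species) {
  dups <- as.integer(names(rec$events)[rec$events == "duplication"])
  out <- character(0)
  for (g in dups) {
    sp <- unique(leaf_species[clade_leaves(gene_tree, g)])
    out[as.character(g)] <-
      if (length(sp) == 1L) "species_specific" else "multi_species"
  }
  out
}

#' Test whether a leaf set is monophyletic
#'
#' Rooted test: some node's descendant leaf set equals `leaf_set` exactly.
#' Unrooted test: some bipartition side equals it (i.e. the set or its
#' complement is a rooted clade in the stored representation).
#'
#' @param tree A `phylo`.
#' @param leaf_set Character vector of tip labels.
#' @param rooted Interpret the tree as rooted (default `TRUE`).
#' @return Logical.
#' @export
is_monophyletic <- function(tree, leaf_set, rooted = TRUE) {
  unknown <- setdiff(leaf_set, tree$tip.label)
  if (length(unknown)) stop("unknown leaf: ", paste(unknown, collapse = ", "))
  leaf_set <- unique(leaf_set)
  if (length(leaf_set) == length(tree$tip.label)) return(TRUE)
  is_clade <- function(set) {
    if (length(set) == 1L) return(TRUE)
    m <- .mrca_of(tree, set)
    setequal(clade_leaves(tree, m), set)
  }
  if (is_clade(leaf_set)) return(TRUE)
  if (!rooted) {
    comp <- setdiff(tree$tip.label, leaf_set)
    return(is_clade(comp))
  }
  FALSE
}

#' Dollo-parsimony loss mapping of gene presence/absence
#'
#' Assumes a single origin: the gene is gained once at the MRCA of the taxa
#' that have it, and the minimum number of losses is the number of maximal
#' subtrees below that gain whose leaves all lack the gene.
#'
#' @param species_tree Rooted species tree (`phylo`).
#' @param present_taxa Non-empty character vector of tip labels with the
#'   gene.
#' @return A `dollo_result` list: `gain_node`, `loss_edges` (data.frame
#'   `parent`, `child`, `child_label`), `n_losses`.
#' @export
dollo_losses <- function(species_tree, present_taxa) {
  if (!length(present_taxa)) stop("present_taxa must be non-empty")
  unknown <- setdiff(present_taxa, species_tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  ntip <- length(species_tree$tip.label)
  gain <- .mrca_of(species_tree, unique(present_taxa))
  kids <- .children_list(species_tree)
  absent <- rep(NA, ntip + species_tree$Nnode)
  absent[seq_len(ntip)] <- !(species_tree$tip.label %in% present_taxa)
  for (v in .postorder_nodes(species_tree)) {
    if (v <= ntip) next
    absent[v] <- all(absent[unlist(kids[[v]])])
  }
  loss <- list()
  walk <- function(v) {
    for (ch in unlist(kids[[v]])) {
      if (absent[ch]) {
        lab <- if (ch <= ntip) species_tree$tip.label[ch] else
          paste(clade_leaves(species_tree, ch), collapse = "+")
        loss[[length(loss) + 1L]] <<- data.frame(
          parent = v, child = ch, child_label = lab,
          stringsAsFactors = FALSE
        )
      } else if (ch > ntip) {
        walk(ch)
      }
    }
  }
  if (gain > ntip) walk(gain)
  loss <- if (length(loss)) do.call(rbind, loss) else
    data.frame(parent = integer(), child = integer(),
               child_label = character(), stringsAsFactors = FALSE)
  structure(list(gain_node = gain, loss_edges = loss,
                 n_losses = nrow(loss)),
            class = "dollo_result")
}
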