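sp_AB <- parse_newick("(A,B);")
ls_ab <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")

test_that("LCA mapping sends each gene node to the species MRCA", {
  g <- parse_newick("(a1,b1);")
  m <- lca_map(g, sp_AB, ls_ab)
  expect_equal(m[3], 3)  # root -> species root
  g2 <- parse_newick("((a1,b1),(a2,b2));")
  m2 <- lca_map(g2, sp_AB, ls_ab)
  expect_true(all(m2[5:7] == 3))
  expect_error(lca_map(parse_newick("(a1,x9);"), sp_AB, ls_ab), "x9")
})

test_that("duplication/loss counts match hand-worked cases", {
  r1 <- count_dup_loss(parse_newick("((a1,b1),(a2,b2));"), sp_AB, ls_ab)
  expect_equal(c(r1$duplications, r1$losses), c(1, 0))
  r2 <- count_dup_loss(parse_newick("(a1,(b1,a2));"), sp_AB, ls_ab)
  expect_equal(c(r2$duplications, r2$losses), c(1, 1))
  # congruent gene tree: no events
  sp4 <- parse_newick("((A,B),(C,D));")
  g4 <- parse_newick("((a1,b1),(c1,d1));")
  ls4 <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D")
  r3 <- count_dup_loss(g4, sp4, ls4)
  expect_equal(c(r3$duplications, r3$losses), c(0, 0))
  expect_error(count_dup_loss(parse_newick("(a1,b1,a2);"), sp_AB, ls_ab),
               "polytom")
})

test_that("LCA reconciliation attains the brute-force embedding minimum", {
  for (seed in 1:12) {
    set.seed(seed)
    ns <- sample(3:6, 1)
    sp <- random_tree(ns, lengths = FALSE)
    sp$tip.label <- LETTERS[seq_len(ns)]
    ng <- sample(3:8, 1)
    g <- random_tree(ng, lengths = FALSE)
    g$tip.label <- paste0(letters[seq_len(ng)], "1")
    ls <- setNames(sample(sp$tip.label, ng, TRUE), g$tip.label)
    rec <- count_dup_loss(g, sp, ls)
    expect_equal(rec$duplications + rec$losses,
                 oracle_dl_cost(g, sp, ls),
                 info = sprintf("seed %d", seed))
  }
})

test_that("the fast nested scorer agrees with count_dup_loss", {
  for (seed in 21:26) {
    set.seed(seed)
    sp <- random_tree(5, lengths = FALSE)
    sp$tip.label <- LETTERS[1:5]
    g <- random_tree(7, lengths = FALSE)
    g$tip.label <- paste0(letters[1:7], "1")
    ls <- setNames(sample(sp$tip.label, 7, TRUE), g$tip.label)
    rec <- count_dup_loss(g, sp, ls)
    sidx <- smtphylo:::.tree_index(sp)
    stip <- setNames(match(ls, sp$tip.label), names(ls))
    nested <- smtphylo:::.phylo_to_nested(g)
    expect_equal(smtphylo:::.score_nested(nested, stip, sidx)$cost,
                 rec$duplications + rec$losses)
  }
})

test_that("rooting minimizes D+L over all edges, and honors outgroups", {
  set.seed(5)
  sp <- parse_newick("((A,B),(C,D));")
  ls <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D", f1 = "F")
  g <- ape::unroot(parse_newick("((a1,b1),(c1,d1));"))
  rooted <- root_gene_tree(g, sp, ls)
  best <- count_dup_loss(rooted, sp, ls)
  # oracle: exhaustive scan over every rooting
  costs <- vapply(seq_len(nrow(g$edge)), function(i) {
    side <- clade_leaves(g, g$edge[i, 2])
    if (length(side) == length(g$tip.label)) return(Inf)
    cand <- tryCatch(ape::root(g, outgroup = side, resolve.root = TRUE),
                     error = function(e) NULL)
    if (is.null(cand)) return(Inf)
    oracle_dl_cost(cand, sp, ls)
  }, numeric(1))
  expect_equal(best$duplications + best$losses, min(costs))
  # outgroup rooting
  spF <- parse_newick("(((A,B),(C,D)),F);")
  g2 <- ape::unroot(parse_newick("(((a1,b1),(c1,d1)),f1);"))
  r2 <- root_gene_tree(g2, outgroup = "f1")
  expect_true(is_monophyletic(r2, c("a1", "b1", "c1", "d1")))
  expect_error(root_gene_tree(g2, outgroup = c("f1", "a1")),
               "bipartition")
})

test_that("rearrangement removes spurious events on weak edges only", {
  sp <- parse_newick("(((A,B),C),D);")
  ls <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D")
  # wrong (a1,c1) grouping carried by a weak edge
  g <- parse_newick("(((a1,c1)0.3,b1)0.95,d1);")
  out <- rearrange(g, sp, ls, support_threshold = 0.9)
  expect_equal(out$reconciliation$duplications +
                 out$reconciliation$losses, 0)
  expect_true(is_monophyletic(out$tree, c("a1", "b1")))
  # strong tree is left alone
  g2 <- parse_newick("(((a1,c1)0.99,b1)0.95,d1);")
  out2 <- rearrange(g2, sp, ls, support_threshold = 0.9)
  expect_true(is_monophyletic(out2$tree, c("a1", "c1")))
  expect_error(rearrange(g, sp, ls, support_threshold = 1.5), "threshold")
})

test_that("a fully collapsed quartet resolves congruent with the species tree", {
  sp <- parse_newick("(((A,B),C),D);")
  ls <- c(a1 = "A", b1 = "B", c1 = "C", d1 = "D")
  g <- parse_newick("(((a1,c1)0.1,b1)0.1,d1);")
  out <- rearrange(g, sp, ls, support_threshold = 0.5)
  expect_equal(out$reconciliation$duplications, 0)
  expect_equal(out$reconciliation$losses, 0)
  expect_true(is_monophyletic(out$tree, c("a1", "b1")))
  expect_true(is_monophyletic(out$tree, c("a1", "b1", "c1")))
})

test_that("rearrangement never increases the reconciliation cost", {
  for (seed in 31:40) {
    set.seed(seed)
    ns <- sample(4:6, 1)
    sp <- random_tree(ns, lengths = FALSE)
    sp$tip.label <- LETTERS[seq_len(ns)]
    ng <- sample(5:9, 1)
    g <- random_tree(ng, lengths = FALSE)
    g$tip.label <- paste0(letters[seq_len(ng)], "1")
    g$support <- c(NA, runif(g$Nnode - 1))
    ls <- setNames(sample(sp$tip.label, ng, TRUE), g$tip.label)
    before <- count_dup_loss(g, sp, ls)
    out <- rearrange(g, sp, ls, support_threshold = 0.8)
    expect_lte(out$reconciliation$duplications + out$reconciliation$losses,
               before$duplications + before$losses)
    expect_setequal(out$tree$tip.label, g$tip.label)
  }
})

test_that("duplications are classified by the species they span", {
  sp <- parse_newick("(A,B);")
  g <- parse_newick("((a1,a2),b1);")
  ls <- c(a1 = "A", a2 = "A", b1 = "B")
  rec <- count_dup_loss(g, sp, ls)
  cls <- classify_duplications(rec, g, ls)
  expect_equal(unname(cls), "species_specific")
  g2 <- parse_newick("((a1,b1),(a2,b2));")
  rec2 <- count_dup_loss(g2, sp_AB, ls_ab)
  cls2 <- classify_duplications(rec2, g2, ls_ab)
  expect_equal(unname(cls2), "multi_species")
  # no duplications -> empty classification
  g3 <- parse_newick("(a1,b1);")
  rec3 <- count_dup_loss(g3, sp, c(a1 = "A", b1 = "B"))
  expect_length(classify_duplications(rec3, g3, ls), 0)
})

test_that("monophyly testing covers rooted, unrooted and degenerate cases", {
  tr <- parse_newick("((A,B),C);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(parse_newick("((A,C),B);"), c("A", "B")))
  expect_true(is_monophyletic(tr, c("A", "B", "C")))
  # unrooted: a complement side counts
  tr2 <- parse_newick("((A,B),(C,D));")
  expect_true(is_monophyletic(tr2, c("C", "D"), rooted = FALSE))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown leaf")
})

test_that("Dollo mapping equals Sankoff parsimony on random instances", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    tr <- random_tree(n, lengths = FALSE)
    k <- sample(seq_len(n - 1), 1)
    present <- sample(tr$tip.label, k)
    d <- dollo_losses(tr, present)
    expect_equal(d$n_losses, oracle_dollo_losses(tr, present))
  }
})

test_that("Dollo handles hand-worked cases and the gain placement", {
  tr <- parse_newick("((A,B),(C,D));")
  d <- dollo_losses(tr, c("A", "C"))
  expect_equal(d$n_losses, 2)
  expect_setequal(d$loss_edges$child_label, c("B", "D"))
  expect_equal(d$gain_node, 5)  # root
  d2 <- dollo_losses(tr, c("A", "B"))
  expect_equal(d2$n_losses, 0)
  expect_equal(sort(clade_leaves(tr, d2$gain_node)), c("A", "B"))
  expect_error(dollo_losses(tr, character(0)), "non-empty")
})

test_that("true gene trees reconcile to the simulated event counts", {
  # with no losses, D equals the number of duplication events and L = 0
  set.seed(19)
  for (i in 1:5) {
    sp <- sim_species_tree(8, 1, seed = 100 + i)
    fam <- sim_gene_tree(sp, dup_rate = 0.25, loss_rate = 0,
                         seed = 200 + i)
    if (fam$empty) next
    rec <- count_dup_loss(fam$tree, sp, fam$leaf_species)
    expect_equal(rec$duplications,
                 sum(fam$events$type == "duplication"))
    expect_equal(rec$losses, 0)
  }
  # a hand-built lossy case: one A-copy lost after a root duplication
  sp2 <- parse_newick("(A:1,B:1):0;")
  g <- parse_newick("((a1:1,b1:1):0.5,b2:1.5);")
  rec2 <- count_dup_loss(g, sp2, c(a1 = "A", b1 = "B", b2 = "B"))
  expect_equal(rec2$duplications, 1)
  expect_equal(rec2$losses, 1)
})
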