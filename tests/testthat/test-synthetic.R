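test_that("Yule species trees have exponential root ages and fixed size", {
  lam <- 2
  ages <- vapply(1:4000, function(i) {
    max(node_ages(sim_species_tree(2, lam, seed = i)))
  }, numeric(1))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 1 / lam), 3 * se)
  # determinism and tree arithmetic
  expect_identical(write_newick(sim_species_tree(10, 1, seed = 7)),
                   write_newick(sim_species_tree(10, 1, seed = 7)))
  t50 <- sim_species_tree(50, 1, seed = 3)
  expect_equal(t50$Nnode, 49)
  expect_error(sim_species_tree(1, 1, seed = 1), ">= 2")
})

test_that("taxonomy-structured trees keep genera, phyla and the focal clade monophyletic", {
  cfg <- sim_config(seed = 5)
  tax <- sim_taxonomy(cfg)
  tr <- sim_taxonomy_tree(tax, 1, seed = 5)
  for (g in unique(tax$genus)) {
    expect_true(is_monophyletic(tr, tax$species[tax$genus == g]))
  }
  for (p in unique(tax$phylum)) {
    expect_true(is_monophyletic(tr, tax$species[tax$phylum == p]))
  }
  expect_true(is_monophyletic(tr, tax$species[!tax$is_donor]))
  expect_equal(sort(tr$tip.label), sort(tax$species))
})

test_that("gene families are congruent without duplication or loss", {
  sp <- sim_species_tree(6, 1, seed = 11)
  fam <- sim_gene_tree(sp, 0, 0, seed = 12)
  expect_false(fam$empty)
  expect_equal(nrow(fam$events), 0)
  renamed <- fam$tree
  renamed$tip.label <- unname(fam$leaf_species[renamed$tip.label])
  expect_equal(ape::dist.topo(ape::unroot(renamed), ape::unroot(sp))[1], 0)
  rec <- count_dup_loss(fam$tree, sp, fam$leaf_species)
  expect_equal(c(rec$duplications, rec$losses), c(0, 0))
})

test_that("with no loss, the leaf count follows the duplication log exactly", {
  for (seed in 1:6) {
    sp <- sim_species_tree(6, 1, seed = 20 + seed)
    fam <- sim_gene_tree(sp, 0.3, 0, seed = 30 + seed)
    if (fam$empty) next
    dups <- fam$events[fam$events$type == "duplication", , drop = FALSE]
    extra <- if (!nrow(dups)) 0 else sum(vapply(dups$species_node,
      function(v) length(clade_leaves(sp, v)), numeric(1)))
    expect_equal(length(fam$tree$tip.label),
                 length(sp$tip.label) + extra)
  }
})

test_that("mean copy number per species matches the birth-death expectation", {
  sp <- sim_species_tree(4, 1.5, seed = 99)
  T_ <- max(node_ages(sp))
  dup <- 0.4; loss <- 0.2
  counts <- vapply(1:1000, function(i) {
    fam <- sim_gene_tree(sp, dup, loss, seed = 1000 + i)
    if (fam$empty) return(0)
    length(fam$tree$tip.label) / length(sp$tip.label)
  }, numeric(1))
  want <- exp((dup - loss) * T_)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - want), 3 * se)
})

test_that("contaminant injection obeys its rate and records truth labels", {
  recs <- data.frame(
    id = paste0("r", 1:500), species = paste0("sp", 1:500),
    genus = paste0("g", 1:500), phylum = "Focal",
    residues = "ARND", stringsAsFactors = FALSE
  )
  donors <- data.frame(id = "d1", species = "don", genus = "dg",
                       phylum = "Donor", residues = "WWWW",
                       stringsAsFactors = FALSE)
  none <- inject_contaminants(recs, donors, 0, seed = 1)
  expect_equal(nrow(none$records), 500)
  expect_length(none$contaminant_ids, 0)
  all_in <- inject_contaminants(recs, donors, 1, seed = 1)
  expect_length(all_in$contaminant_ids, 500)
  expect_true(all(all_in$records$residues[
    all_in$records$id %in% all_in$contaminant_ids] == "WWWW"))
  some <- inject_contaminants(recs, donors, 0.1, seed = 2)
  k <- length(some$contaminant_ids)
  bounds <- qbinom(c(0.005, 0.995), 500, 0.1)
  expect_gte(k, bounds[1]); expect_lte(k, bounds[2])
  expect_error(inject_contaminants(recs, donors[0, ], 0.5, seed = 1),
               "empty donor pool")
  recs2 <- recs; recs2$phylum <- "Donor"
  expect_error(inject_contaminants(recs2, donors, 0.5, seed = 1),
               "disjoint")
})

test_that("sequence evolution matches the LG matrix exponential", {
  # 2 taxa at total distance t: P(different) = 1 - sum_i pi_i P(t)_ii
  t_tot <- 0.4
  tr <- parse_newick(sprintf("(A:%f,B:%f);", t_tot / 2, t_tot / 2))
  sim <- sim_rates_and_alignment(tr, 0, 10000, seed = 55)
  p_obs <- mean(sim$alignment["A", ] != sim$alignment["B", ])
  pi <- unname(lg_frequencies())
  p_want <- 1 - sum(pi * diag(lg_transition(t_tot)))
  se <- sqrt(p_want * (1 - p_want) / 10000)
  expect_lt(abs(p_obs - p_want), 3 * se)
  # zero-length tree: identical sequences
  tr0 <- parse_newick("(A:0,B:0);")
  sim0 <- sim_rates_and_alignment(tr0, 0, 200, seed = 56)
  expect_true(all(sim0$alignment["A", ] == sim0$alignment["B", ]))
  # divergence grows with path length under a strict clock
  sp <- sim_species_tree(6, 1, seed = 57)
  simb <- sim_rates_and_alignment(sp, 0, 400, seed = 58)
  D <- distance_matrix(simb$alignment)
  paths <- ape::cophenetic.phylo(sp)[rownames(D), colnames(D)]
  off <- upper.tri(D)
  expect_gt(cor(D[off], paths[off], method = "spearman"), 0.5)
  expect_error(sim_rates_and_alignment(sp, 0, 0, seed = 1), "n_sites")
})

test_that("fixture bundles round-trip through the package readers", {
  dir <- tempfile("fx_")
  fx <- emit_fixture(sim_config(seed = 77, n_sites = 120), dir,
                     n_bootstrap = 20)
  seqs <- read_fasta(fx$paths$fasta_aligned)
  tax <- read_taxonomy(fx$paths$taxonomy)
  hits <- parse_domain_table(fx$paths$domains)
  gt <- parse_newick(paste(readLines(fx$paths$gene_tree_true),
                           collapse = ""))
  nj <- parse_newick(paste(readLines(fx$paths$gene_tree_nj),
                           collapse = ""))
  sp <- parse_newick(paste(readLines(fx$paths$species_tree),
                           collapse = ""))
  cals <- read_calibrations(fx$paths$calibrations)
  expect_setequal(names(seqs), tax$id)
  expect_true(all(gt$tip.label %in% tax$id))
  expect_setequal(nj$tip.label, tax$id)
  expect_true(ape::is.ultrametric(sp, tol = 1e-6))
  expect_length(cals, 2)
  manifest <- jsonlite::read_json(fx$paths$manifest)
  expect_equal(manifest$seed, 77)
  # partial records have exactly one domain hit
  for (id in fx$truth$partial_ids) {
    expect_equal(nrow(hits[hits$seq_id == id, ]), 1)
  }
})

test_that("partial-sequence counts stay inside binomial bounds", {
  cfg <- sim_config(seed = 88, partial_fraction = 0.2)
  fx <- emit_fixture(cfg, tempfile("fxp_"), n_bootstrap = 10)
  n <- length(read_fasta(fx$paths$fasta))
  k <- length(fx$truth$partial_ids)
  bounds <- qbinom(c(0.005, 0.995), n, 0.2)
  expect_gte(k, bounds[1]); expect_lte(k, bounds[2])
})

test_that("fixture emission is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 91, n_sites = 80)
  d1 <- tempfile("fxa_"); d2 <- tempfile("fxb_")
  f1 <- emit_fixture(cfg, d1, n_bootstrap = 10)
  f2 <- emit_fixture(cfg, d2, n_bootstrap = 10)
  for (nm in names(f1$paths)) {
    expect_identical(readLines(f1$paths[[nm]]), readLines(f2$paths[[nm]]),
                     label = nm)
  }
})
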