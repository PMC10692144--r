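# ---------------------------------------------------------------------------
# Synthetic-data generation with known truth for every inference stage:
# dated Yule species trees (optionally structured by a taxonomy plan so
# genera and phyla are monophyletic), gene families evolving inside the
# species tree by duplication and loss, lognormal branch-rate
# heterogeneity with LG-evolved amino-acid alignments, cross-phylum
# contaminant injection, domain tables with partial sequences, and
# calibration sets centred on true node ages.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under:
#' a focal fauna of 3 phyla x 3 genera x 2 species (18 species; small
#' enough for exhaustive oracles, rich enough for the two-genera vetting
#' rule), a donor pool of 2 extra phyla supplying contaminants, a 10%
#' per-species contamination rate, lognormal rate spread 0.3, 200-site
#' proteins and a 20% partial-sequence fraction.
#'
#' @param n_phyla,genera_per_phylum,species_per_genus Focal taxonomy plan.
#' @param donor_phyla,donor_genera_per_phylum,donor_species_per_genus
#'   Donor-pool taxonomy plan (phylum-disjoint from the focal fauna).
#' @param birth_rate Speciation rate of the Yule species tree.
#' @param dup_rate,loss_rate Gene duplication/loss rates per lineage per
#'   unit time.
#' @param contamination_rate Per-species probability of receiving one
#'   mislabeled donor transcript.
#' @param rate_log_sd Lognormal sigma of branch substitution rates.
#' @param n_sites Alignment length (residues).
#' @param partial_fraction Fraction of records truncated to one domain.
#' @param seed Integer seed; every simulator output is deterministic per
#'   seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_phyla = 3, genera_per_phylum = 3,
                       species_per_genus = 2, donor_phyla = 2,
                       donor_genera_per_phylum = 2,
                       donor_species_per_genus = 1,
                       birth_rate = 1, dup_rate = 0.15, loss_rate = 0.1,
                       contamination_rate = 0.1, rate_log_sd = 0.3,
                       n_sites = 200, partial_fraction = 0.2, seed = 1) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, birth_rate > 0,
            contamination_rate >= 0, contamination_rate <= 1,
            partial_fraction >= 0, partial_fraction <= 1, n_sites >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Taxonomy plan as a species table
#' @param config A [sim_config()].
#' @return data.frame `species`, `genus`, `phylum`, `is_donor`.
#' @export
sim_taxonomy <- function(config) {
  block <- function(np, ng, ns, prefix) {
    do.call(rbind, lapply(seq_len(np), function(p) {
      do.call(rbind, lapply(seq_len(ng), function(g) {
        data.frame(
          species = sprintf("%s%dG%dsp%d", prefix, p, g, seq_len(ns)),
          genus = sprintf("%s%dG%d", prefix, p, g),
          phylum = sprintf("%s%d", prefix, p),
          stringsAsFactors = FALSE
        )
      }))
    }))
  }
  focal <- block(config$n_phyla, config$genera_per_phylum,
                 config$species_per_genus, "Phy")
  donor <- block(config$donor_phyla, config$donor_genera_per_phylum,
                 config$donor_species_per_genus, "Don")
  focal$is_donor <- FALSE
  donor$is_donor <- TRUE
  rbind(focal, donor)
}

# backward Yule construction: with k lineages remaining the next merge is
# Exp((k-1) * birth_rate) ago, so the root age is a sum of independent
# exponentials with rates (n-1)b, ..., 1b; the n = 2 root age is Exp(b).
# `prefer` optionally biases which pair merges (taxonomy-structured trees).
.yule_merge <- function(labels, birth_rate, prefer = NULL) {
  n <- length(labels)
  if (n < 2) stop("need at least 2 tips")
  nodes <- lapply(labels, function(l) list(label = l, age = 0))
  groups <- if (is.null(prefer)) NULL else prefer
  age <- 0
  while (length(nodes) > 1) {
    k <- length(nodes)
    age <- age + rexp(1, (k - 1) * birth_rate)
    pair <- if (is.null(groups)) {
      sample.int(k, 2)
    } else {
      cand <- NULL
      for (lvl in seq_len(ncol(groups))) {
        tab <- table(groups[, lvl])
        open <- names(tab)[tab >= 2]
        if (length(open)) {
          grp <- sample(open, 1)
          cand <- sample(which(groups[, lvl] == grp), 2)
          break
        }
      }
      if (is.null(cand)) sample.int(k, 2) else cand
    }
    i <- min(pair); j <- max(pair)
    merged <- list(children = list(nodes[[i]], nodes[[j]]), age = age)
    nodes[[i]] <- merged
    nodes <- nodes[-j]
    if (!is.null(groups)) {
      groups[i, ] <- groups[i, ]  # merged node inherits row i's groups
      groups <- groups[-j, , drop = FALSE]
    }
  }
  .aged_nested_to_phylo(nodes[[1]])
}

.aged_nested_to_newick <- function(n, parent_age) {
  core <- if (!is.null(n$label)) n$label else
    paste0("(", paste(vapply(n$children, .aged_nested_to_newick,
                             character(1), parent_age = n$age),
                      collapse = ","), ")")
  paste0(core, ":", formatC(parent_age - n$age, digits = 10, format = "g"))
}

.aged_nested_to_phylo <- function(n) {
  s <- paste0(
    "(", paste(vapply(n$children, .aged_nested_to_newick, character(1),
                      parent_age = n$age), collapse = ","), ");"
  )
  parse_newick(s)
}

#' Simulate a dated Yule species tree
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @param tip_labels Optional tip labels (default `s1..sn`).
#' @return Ultrametric `phylo`.
#' @export
sim_species_tree <- function(n, birth_rate, seed,
                             tip_labels = paste0("s", seq_len(n))) {
  if (n < 2) stop("n must be >= 2")
  set.seed(seed)
  .yule_merge(tip_labels, birth_rate)
}

#' Simulate a taxonomy-structured dated species tree
#'
#' Same age process as [sim_species_tree()], but lineage pairs merge
#' within genera before genera merge within phyla, so the taxonomy plan's
#' groups come out monophyletic — a clean species phylogeny for the
#' vetting benchmark.
#'
#' @param taxonomy data.frame from [sim_taxonomy()] (or with columns
#'   `species`, `genus`, `phylum`).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @return Ultrametric `phylo` with `taxonomy$species` as tips.
#' @export
sim_taxonomy_tree <- function(taxonomy, birth_rate, seed) {
  set.seed(seed)
  prefer <- cbind(taxonomy$genus, taxonomy$phylum)
  if (!is.null(taxonomy$is_donor)) {
    # donors are an outgroup supergroup, so the focal fauna is a clade
    prefer <- cbind(prefer, ifelse(taxonomy$is_donor, "donor", "focal"))
  }
  .yule_merge(taxonomy$species, birth_rate, prefer = prefer)
}

#' Simulate a gene family inside a dated species tree
#'
#' One gene copy enters at the species root; along every species branch
#' each copy independently duplicates (rate `dup_rate`) or dies (rate
#' `loss_rate`); surviving copies pass into both daughters at speciations.
#' The returned gene tree is pruned of extinct copies (duplication nodes
#' with one surviving child are suppressed).
#'
#' @param species_tree Dated `phylo`.
#' @param dup_rate,loss_rate Event rates per copy per unit time.
#' @param seed Integer seed.
#' @return List: `tree` (dated gene tree, tips `<species>_g<k>`; `NULL` if
#'   the family went extinct), `leaf_species` (named vector tip ->
#'   species), `events` (data.frame `type`, `species_node`, `age`,
#'   `observable`), `empty`.
#' @export
sim_gene_tree <- function(species_tree, dup_rate, loss_rate, seed) {
  set.seed(seed)
  ntip <- length(species_tree$tip.label)
  ages <- node_ages(species_tree)
  kids <- .children_list(species_tree)
  env <- new.env()
  env$events <- list()
  env$counter <- integer(ntip)
  total <- dup_rate + loss_rate
  note <- function(type, node, age, observable = NA) {
    env$events[[length(env$events) + 1L]] <-
      data.frame(type = type, species_node = node, age = age,
                 observable = observable, stringsAsFactors = FALSE)
  }
  at_node <- function(v) {
    # a surviving copy sitting at species node v (tip: becomes a leaf;
    # internal: speciates into both daughters)
    if (v <= ntip) {
      env$counter[v] <- env$counter[v] + 1L
      return(list(label = sprintf("%s_g%d", species_tree$tip.label[v],
                                  env$counter[v]),
                  age = 0))
    }
    ch <- lapply(unlist(kids[[v]]), function(w) {
      along_branch(w, ages[v])
    })
    ch <- ch[!vapply(ch, is.null, logical(1))]
    if (!length(ch)) return(NULL)
    if (length(ch) == 1L) return(ch[[1]])
    list(children = ch, age = ages[v], kind = "speciation")
  }
  along_branch <- function(v, t_top) {
    # one copy entering the species branch above node v at age t_top
    t_bot <- ages[v]
    if (total > 0) {
      dt <- rexp(1, total)
      if (t_top - dt > t_bot) {
        t_ev <- t_top - dt
        if (runif(1) < loss_rate / total) {
          note("loss", v, t_ev)
          return(NULL)
        }
        a <- along_branch(v, t_ev)
        b <- along_branch(v, t_ev)
        note("duplication", v, t_ev,
             observable = !is.null(a) && !is.null(b))
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        return(list(children = list(a, b), age = t_ev,
                    kind = "duplication"))
      }
    }
    at_node(v)
  }
  root_nested <- at_node(ntip + 1L)
  events <- if (length(env$events)) do.call(rbind, env$events) else
    data.frame(type = character(), species_node = integer(),
               age = numeric(), observable = logical())
  if (is.null(root_nested) || !is.null(root_nested$label)) {
    return(list(tree = NULL, leaf_species = character(), events = events,
                empty = TRUE))
  }
  tree <- .aged_nested_to_phylo(root_nested)
  leaf_species <- setNames(sub("_g[0-9]+$", "", tree$tip.label),
                           tree$tip.label)
  list(tree = tree, leaf_species = leaf_species, events = events,
       empty = FALSE)
}

#' Inject cross-phylum contaminant transcripts
#'
#' Each recipient species independently receives, with probability `rate`,
#' a copy of a random donor-pool sequence relabeled into the recipient's
#' id space (the residues stay the donor's — mimicking assembly
#' cross-contamination, and defeating naive identity screens).
#'
#' @param records data.frame `id`, `species`, `genus`, `phylum`,
#'   `residues` of the focal fauna.
#' @param donor_pool data.frame of the same shape; must share no phylum
#'   with `records`.
#' @param rate Per-species contamination probability.
#' @param seed Integer seed.
#' @return List: `records` (with contaminants appended), `contaminant_ids`,
#'   `donor_of` (named vector contaminant id -> donor id).
#' @export
inject_contaminants <- function(records, donor_pool, rate, seed) {
  if (rate > 0 && !nrow(donor_pool)) stop("empty donor pool with rate > 0")
  if (length(intersect(records$phylum, donor_pool$phylum))) {
    stop("donor pool must be phylum-disjoint from the recipients")
  }
  set.seed(seed)
  species <- unique(records$species)
  extra <- list()
  donor_of <- character(0)
  for (sp in species) {
    if (runif(1) >= rate) next
    d <- donor_pool[sample.int(nrow(donor_pool), 1), ]
    row <- records[match(sp, records$species), ]
    cid <- sprintf("%s_contam%d", sp, length(extra) + 1L)
    extra[[length(extra) + 1L]] <- data.frame(
      id = cid, species = sp, genus = row$genus, phylum = row$phylum,
      residues = d$residues, stringsAsFactors = FALSE
    )
    donor_of[cid] <- d$id
  }
  out <- rbind(records, if (length(extra)) do.call(rbind, extra))
  list(records = out, contaminant_ids = names(donor_of),
       donor_of = donor_of)
}

#' Simulate branch rates and an amino-acid alignment along a gene tree
#'
#' Branch rates are independent lognormal draws with expected value 1
#' (`meanlog = -rate_log_sd^2/2`); sequences evolve site-independently
#' under LG (optionally +Gamma) from a root draw at equilibrium.
#'
#' @param gene_tree Dated `phylo`.
#' @param rate_log_sd Lognormal sigma (0 = strict clock).
#' @param n_sites Number of residues (>= 1).
#' @param seed Integer seed.
#' @param gamma_shape Optional gamma shape for among-site heterogeneity.
#' @return List: `rates` (per edge, aligned with `gene_tree$edge`),
#'   `alignment` (tip character matrix).
#' @export
sim_rates_and_alignment <- function(gene_tree, rate_log_sd, n_sites, seed,
                                    gamma_shape = NULL) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  set.seed(seed)
  lg <- lg_eigen()
  nedge <- nrow(gene_tree$edge)
  rates <- if (rate_log_sd > 0) {
    rlnorm(nedge, -rate_log_sd^2 / 2, rate_log_sd)
  } else rep(1, nedge)
  site_scale <- if (is.null(gamma_shape)) rep(1, n_sites) else
    sample(gamma_category_rates(gamma_shape), n_sites, replace = TRUE)
  ntip <- length(gene_tree$tip.label)
  n <- ntip + gene_tree$Nnode
  seqs <- matrix(NA_integer_, n, n_sites)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = lg$pi)
  tr <- ape::reorder.phylo(gene_tree, "cladewise")
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; v <- tr$edge[i, 2]
    ei <- which(gene_tree$edge[, 2] == v)  # rate index in original order
    t_edge <- tr$edge.length[i] * rates[ei]
    for (sc in unique(site_scale)) {
      cols <- which(site_scale == sc)
      P <- lg_transition(t_edge * sc)
      for (s in unique(seqs[p, cols])) {
        at <- cols[seqs[p, cols] == s]
        seqs[v, at] <- sample.int(20L, length(at), replace = TRUE,
                                  prob = P[s, ])
      }
    }
  }
  aln <- matrix(lg$aa[seqs[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(aln) <- gene_tree$tip.label
  list(rates = rates, alignment = aln)
}

# One full in-memory scenario: taxonomy, species tree, gene family,
# alignment, contaminants, partials.  All downstream fixtures and the
# vetting benchmark are built from this.
sim_scenario <- function(config) {
  set.seed(config$seed)
  tax <- sim_taxonomy(config)
  sptree <- sim_taxonomy_tree(tax, config$birth_rate,
                              seed = sample.int(2^31 - 1, 1))
  repeat {
    fam <- sim_gene_tree(sptree, config$dup_rate, config$loss_rate,
                         seed = sample.int(2^31 - 1, 1))
    if (fam$empty) next
    sp <- unique(fam$leaf_species)
    enough_focal <- sum(sp %in% tax$species[!tax$is_donor]) >= 4
    donors_ok <- config$contamination_rate == 0 ||
      any(sp %in% tax$species[tax$is_donor])
    if (enough_focal && donors_ok) break
  }
  sim <- sim_rates_and_alignment(fam$tree, config$rate_log_sd,
                                 config$n_sites,
                                 seed = sample.int(2^31 - 1, 1))
  residues <- apply(sim$alignment, 1, paste, collapse = "")
  recs <- data.frame(id = fam$tree$tip.label,
                     species = fam$leaf_species[fam$tree$tip.label],
                     stringsAsFactors = FALSE)
  recs$genus <- tax$genus[match(recs$species, tax$species)]
  recs$phylum <- tax$phylum[match(recs$species, tax$species)]
  recs$residues <- unname(residues[recs$id])
  focal <- recs[!tax$is_donor[match(recs$species, tax$species)], ]
  donors <- recs[tax$is_donor[match(recs$species, tax$species)], ]
  inj <- inject_contaminants(focal, donors, config$contamination_rate,
                             seed = sample.int(2^31 - 1, 1))
  all_records <- rbind(inj$records, donors)
  list(config = config, taxonomy = tax, species_tree = sptree,
       gene_family = fam, rates = sim$rates, alignment = sim$alignment,
       records = all_records, contaminant_ids = inj$contaminant_ids,
       donor_of = inj$donor_of)
}

# gapped alignment over all records (contaminants copy donor rows;
# partials are masked outside their retained domain)
.records_alignment <- function(scenario, partial_ids = character(0),
                               keep_range = NULL) {
  aln0 <- scenario$alignment
  n_sites <- ncol(aln0)
  rows <- lapply(seq_len(nrow(scenario$records)), function(i) {
    id <- scenario$records$id[i]
    src <- if (id %in% names(scenario$donor_of)) {
      scenario$donor_of[[id]]
    } else id
    aln0[src, ]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- scenario$records$id
  if (length(partial_ids) && !is.null(keep_range)) {
    mask <- setdiff(seq_len(n_sites), keep_range)
    m[partial_ids, mask] <- "-"
  }
  m
}

#' Emit a fixture bundle for the full pipeline
#'
#' Writes, under `dir`: aligned and unaligned FASTA of all records
#' (contaminants included), taxonomy TSV, a pfam_scan-style domain table
#' (the chosen partial fraction of records keeps only the
#' methyltransferase-domain region), the true gene tree, an NJ + bootstrap
#' estimate of the gene tree, the dated species tree, a calibration TSV
#' (lognormal calibrations centred on true node ages: offset 0.9 x true
#' age, log_sd 0.5), and a JSON manifest recording seed, config and truth.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_bootstrap Bootstrap replicates for the estimated gene tree.
#' @return List: `paths` (named file paths), `truth` (contaminant ids,
#'   partial ids, true event counts, true root age, the scenario).
#' @export
emit_fixture <- function(config, dir, n_bootstrap = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- sim_scenario(config)
  n_sites <- config$n_sites
  mt_range <- seq_len(max(2, floor(0.55 * n_sites)))
  ct_range <- seq(min(n_sites - 1, floor(0.65 * n_sites) + 1), n_sites)
  n_rec <- nrow(sc$records)
  is_partial <- runif(n_rec) < config$partial_fraction
  partial_ids <- sc$records$id[is_partial]
  aln <- .records_alignment(sc, partial_ids, mt_range)
  # domain table (pfam_scan dialect: 15 whitespace columns)
  dom <- list()
  for (i in seq_len(n_rec)) {
    id <- sc$records$id[i]
    add <- function(name, range) {
      dom[[length(dom) + 1L]] <<- sprintf(
        "%s %d %d %d %d PF0000%d.1 %s Domain 1 %d %d 100.0 1e-50 1 No_clan",
        id, min(range), max(range), min(range), max(range),
        if (name == "Methyltransf") 1L else 2L, name, length(range),
        length(range)
      )
    }
    add("Methyltransf", mt_range)
    if (!is_partial[i]) add("Sterol_MT_C", ct_range)
  }
  seqs <- apply(aln, 1, paste, collapse = "")
  unaligned <- gsub("-", "", seqs)
  paths <- list(
    fasta = file.path(dir, "records.faa"),
    fasta_aligned = file.path(dir, "records_aligned.faa"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    domains = file.path(dir, "domains.tsv"),
    gene_tree_true = file.path(dir, "gene_tree_true.nwk"),
    gene_tree_nj = file.path(dir, "gene_tree_nj.nwk"),
    species_tree = file.path(dir, "species_tree.nwk"),
    calibrations = file.path(dir, "calibrations.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fasta(unaligned, paths$fasta)
  write_fasta(seqs, paths$fasta_aligned)
  taxo <- sc$records[, c("id", "species", "genus", "phylum")]
  write.table(taxo, paths$taxonomy, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c("# pfam_scan-style domain hits", unlist(dom)), paths$domains)
  write_newick(sc$gene_family$tree, paths$gene_tree_true)
  nj <- bootstrap_support(aln, n_bootstrap,
                          seed = sample.int(2^31 - 1, 1))
  write_newick(nj, paths$gene_tree_nj)
  write_newick(sc$species_tree, paths$species_tree)
  # calibrations: root plus one random internal node of the species tree
  ages <- node_ages(sc$species_tree)
  ntip <- length(sc$species_tree$tip.label)
  root <- ntip + 1L
  others <- setdiff((ntip + 1L):(ntip + sc$species_tree$Nnode), root)
  cal_nodes <- c(root, others[sample.int(length(others), 1)])
  cals <- lapply(cal_nodes, function(v) {
    calibration(clade_leaves(sc$species_tree, v), offset = 0.9 * ages[v],
                log_mean = log(0.1 * ages[v]), log_sd = 0.5)
  })
  write_calibrations(cals, paths$calibrations)
  truth <- list(
    contaminant_ids = sc$contaminant_ids,
    partial_ids = partial_ids,
    n_duplications_observable =
      sum(sc$gene_family$events$type == "duplication" &
            sc$gene_family$events$observable),
    n_losses_raw = sum(sc$gene_family$events$type == "loss"),
    root_age = max(node_ages(sc$species_tree)),
    scenario = sc
  )
  jsonlite::write_json(
    list(seed = config$seed,
         config = unclass(config),
         contaminant_ids = sc$contaminant_ids,
         partial_ids = partial_ids,
         n_duplications_observable = truth$n_duplications_observable,
         n_losses_raw = truth$n_losses_raw,
         root_age = truth$root_age),
    paths$manifest, auto_unbox = TRUE, digits = NA
  )
  list(paths = paths, truth = truth)
}

#' Measure vetting sensitivity and specificity on simulated data
#'
#' For each replicate: simulate a contaminated gene family, estimate the
#' gene tree by neighbor joining, vet it, and score sensitivity (clean
#' focal homologs accepted) and specificity (injected contaminants
#' rejected).
#'
#' @param config A [sim_config()] (its `seed` seeds the whole benchmark).
#' @param n_reps Number of replicates (default 20).
#' @param params [vet_params()] used for vetting.
#' @return data.frame with one row per replicate: `sensitivity`,
#'   `specificity`, `n_clean`, `n_contaminants` (NA-specificity rows mean
#'   no contaminant was injected in that replicate).
#' @export
vet_benchmark <- function(config = sim_config(), n_reps = 20,
                          params = vet_params()) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sc <- sim_scenario(cfg)
    aln <- .records_alignment(sc)
    tree <- neighbor_joining(distance_matrix(aln))
    taxmap <- sc$records[, c("id", "species", "genus", "phylum")]
    taxmap$vetting_ok <- TRUE
    # root as the paper does (outgroups / species-tree information):
    # an arbitrarily rooted NJ tree can split a genuine phylum clade
    # across the root
    ls <- setNames(taxmap$species, taxmap$id)
    tree <- root_gene_tree(ape::unroot(tree), sc$species_tree, ls)
    rep_ <- vet(tree, taxmap, records = sc$records, params = params)
    donor_sp <- sc$taxonomy$species[sc$taxonomy$is_donor]
    clean <- setdiff(
      sc$records$id[!(sc$records$species %in% donor_sp)],
      sc$contaminant_ids
    )
    contam <- sc$contaminant_ids
    out[[r]] <- data.frame(
      sensitivity = mean(clean %in% rep_$accepted$seq_id),
      specificity = if (length(contam)) {
        mean(contam %in% rep_$rejected$seq_id)
      } else NA_real_,
      n_clean = length(clean), n_contaminants = length(contam)
    )
  }
  do.call(rbind, out)
}
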