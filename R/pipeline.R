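# ---------------------------------------------------------------------------
# End-to-end orchestration: domain screen -> gene tree -> vetting ->
# reconciliation (rooting, rearrangement, duplication classification) ->
# Dollo loss mapping -> relaxed-clock dating.  Every stage writes its
# inputs/outputs as plain files under the run directory so any stage can
# be re-run independently, and all randomness flows from the run seed.
# ---------------------------------------------------------------------------

#' Pipeline run configuration
#'
#' @param fasta_aligned Aligned FASTA of candidate homologs (gaps `-`).
#' @param taxonomy Taxonomy TSV (id, species, genus, phylum).
#' @param domains pfam_scan-style domain table.
#' @param species_tree Rooted species tree (Newick).
#' @param gene_tree Optional Newick gene tree with supports; when `NULL`
#'   an NJ + bootstrap tree is estimated from the screened alignment.
#' @param calibrations Optional calibration TSV (species-level clades).
#' @param focal_phyla Optional character vector: the phyla whose joint
#'   monophyly (after rearrangement) the report tests.
#' @param vet VetParams from [vet_params()].
#' @param support_threshold Rearrangement support threshold.
#' @param clock_gens,clock_sample_every MCMC length and sampling interval
#'   (desk-scale defaults; raise for fidelity runs).
#' @param n_bootstrap Bootstrap replicates for the NJ gene tree.
#' @param seed Integer run seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta_aligned, taxonomy, domains, species_tree,
                       gene_tree = NULL, calibrations = NULL,
                       focal_phyla = NULL, vet = vet_params(),
                       support_threshold = 0.9, clock_gens = 200000,
                       clock_sample_every = 100, n_bootstrap = 100,
                       seed = 1, out_dir = tempfile("smtpipe_run_")) {
  cfg <- as.list(environment())
  for (f in c("fasta_aligned", "taxonomy", "domains", "species_tree")) {
    if (!file.exists(cfg[[f]])) stop("input not found: ", cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

# stage 1: domain screen — classify completeness, cut the two conserved
# domain regions out of the alignment, drop all-gap columns, and remove
# same-species redundancy
.stage_screen <- function(cfg, taxmap) {
  seqs <- read_fasta(cfg$fasta_aligned)
  aln <- as_alignment(seqs)
  hits <- parse_domain_table(cfg$domains)
  ids <- rownames(aln)
  cls <- vapply(ids, function(id) {
    classify_completeness(hits[hits$seq_id == id, , drop = FALSE])
  }, character(1))
  keep <- ids[cls != "none"]
  # union of domain spans over full-length records defines the columns of
  # the concatenated domain alignment
  full_hits <- hits[hits$seq_id %in% ids[cls == "full"], , drop = FALSE]
  spans <- sort(unique(unlist(Map(seq, full_hits$start, full_hits$end))))
  spans <- spans[spans <= ncol(aln)]
  sub <- drop_allgap_columns(aln[keep, spans, drop = FALSE])
  recs <- data.frame(id = keep, stringsAsFactors = FALSE)
  recs$species <- taxmap$species[match(keep, taxmap$id)]
  recs$residues <- gsub("-", "", apply(sub$alignment, 1, paste,
                                       collapse = ""))
  removed <- list()
  retained <- character(0)
  for (sp in unique(recs$species)) {
    dd <- dedupe_by_identity(recs[recs$species == sp, , drop = FALSE],
                             cfg$vet$redundancy_threshold)
    retained <- c(retained, dd$retained$id)
    if (nrow(dd$removed)) removed[[length(removed) + 1L]] <- dd$removed
  }
  list(
    alignment = sub$alignment[retained, , drop = FALSE],
    completeness = cls,
    removed = if (length(removed)) do.call(rbind, removed) else NULL
  )
}

#' Run the full analysis pipeline
#'
#' Stages: domain screen, gene-tree estimation (unless provided), vetting,
#' rooting + rearrangement + duplication/loss reconciliation, Dollo loss
#' mapping on the species tree, and relaxed-clock dating of the accepted
#' gene tree.  Stage artifacts are persisted under `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return A `run_report` list with sections `vet`, `monophyly`,
#'   `duplications`, `dollo`, `clock`, plus `seed` and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage_seed <- function() sample.int(2^31 - 1, 1)
  report <- list(seed = cfg$seed, out_dir = cfg$out_dir)
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  taxmap <- tryCatch(read_taxonomy(cfg$taxonomy),
                     error = function(e) fail("inputs", e))
  species_tree <- tryCatch(
    parse_newick(paste(readLines(cfg$species_tree), collapse = "")),
    error = function(e) fail("inputs", e)
  )

  scr <- tryCatch(.stage_screen(cfg, taxmap),
                  error = function(e) fail("screen", e))
  write_fasta(apply(scr$alignment, 1, paste, collapse = ""),
              file.path(cfg$out_dir, "screened_aligned.faa"))

  gtree <- tryCatch({
    if (is.null(cfg$gene_tree)) {
      bootstrap_support(scr$alignment, cfg$n_bootstrap, seed = stage_seed())
    } else {
      parse_newick(paste(readLines(cfg$gene_tree), collapse = ""))
    }
  }, error = function(e) fail("gene_tree", e))
  write_newick(gtree, file.path(cfg$out_dir, "gene_tree_input.nwk"))

  vet_rep <- tryCatch({
    recs <- data.frame(
      id = rownames(scr$alignment),
      species = taxmap$species[match(rownames(scr$alignment), taxmap$id)],
      residues = gsub("-", "", apply(scr$alignment, 1, paste, collapse = "")),
      stringsAsFactors = FALSE
    )
    vet(gtree, taxmap, records = recs, params = cfg$vet)
  }, error = function(e) fail("vet", e))
  write_vet_report(vet_rep,
                   json_path = file.path(cfg$out_dir, "vet_report.json"),
                   tsv_path = file.path(cfg$out_dir, "vet_report.tsv"))
  report$vet <- list(
    n_accepted = nrow(vet_rep$accepted),
    n_rejected = nrow(vet_rep$rejected),
    clades = unique(vet_rep$accepted[, c("clade_id", "phylum")]),
    rejected_by_reason = table(vet_rep$rejected$reason)
  )

  rec_out <- tryCatch({
    acc <- vet_rep$accepted$seq_id
    if (length(acc) < 3) stop("fewer than 3 accepted sequences")
    pruned <- ape::keep.tip(gtree, acc)
    pruned$support <- .labels_to_support(pruned)
    leaf_species <- setNames(taxmap$species[match(acc, taxmap$id)], acc)
    rooted <- root_gene_tree(ape::unroot(pruned), species_tree,
                             leaf_species)
    rooted$support <- .labels_to_support(rooted)
    rr <- rearrange(rooted, species_tree, leaf_species,
                    cfg$support_threshold)
    cls <- classify_duplications(rr$reconciliation, rr$tree, leaf_species)
    list(tree = rr$tree, rec = rr$reconciliation, dup_classes = cls,
         leaf_species = leaf_species)
  }, error = function(e) fail("reconcile", e))
  write_newick(rec_out$tree,
               file.path(cfg$out_dir, "gene_tree_rearranged.nwk"))
  jsonlite::write_json(
    list(duplications = rec_out$rec$duplications,
         losses = rec_out$rec$losses,
         events = as.list(rec_out$rec$events),
         duplication_classes = as.list(rec_out$dup_classes)),
    file.path(cfg$out_dir, "reconciliation.json"),
    auto_unbox = TRUE, digits = NA
  )
  report$duplications <- list(
    total = rec_out$rec$duplications,
    losses = rec_out$rec$losses,
    species_specific = sum(rec_out$dup_classes == "species_specific"),
    multi_species = sum(rec_out$dup_classes == "multi_species")
  )
  report$monophyly <- tryCatch({
    if (is.null(cfg$focal_phyla)) {
      NULL
    } else {
      focal_ids <- vet_rep$accepted$seq_id[
        vet_rep$accepted$phylum %in% cfg$focal_phyla
      ]
      focal_ids <- intersect(focal_ids, rec_out$tree$tip.label)
      list(
        phyla = cfg$focal_phyla,
        monophyletic = is_monophyletic(rec_out$tree, focal_ids),
        n_sequences = length(focal_ids)
      )
    }
  }, error = function(e) fail("monophyly", e))

  dollo <- tryCatch({
    present <- unique(rec_out$leaf_species)
    dollo_losses(species_tree, present)
  }, error = function(e) fail("dollo", e))
  write.table(dollo$loss_edges,
              file.path(cfg$out_dir, "dollo_losses.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$dollo <- list(
    n_losses = dollo$n_losses,
    gain_clade = paste(clade_leaves(species_tree, dollo$gain_node),
                       collapse = "+"),
    loss_clades = dollo$loss_edges$child_label
  )

  report$clock <- tryCatch({
    cals <- if (is.null(cfg$calibrations)) list() else
      .map_calibrations(read_calibrations(cfg$calibrations),
                        rec_out$leaf_species)
    aln <- scr$alignment[rec_out$tree$tip.label, , drop = FALSE]
    model <- clock_model(rec_out$tree, aln, cals)
    trace <- mcmc(model, cfg$clock_gens, cfg$clock_sample_every,
                  seed = stage_seed())
    write.table(trace, file.path(cfg$out_dir, "clock_trace.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_trace(trace)
    dated <- dated_tree_from_summary(model, summ)
    write_newick(dated, file.path(cfg$out_dir, "gene_tree_dated.nwk"))
    list(n_calibrations = length(cals), node_ages = summ,
         root_age_median = summ$median_age[
           summ$node == length(rec_out$tree$tip.label) + 1L],
         acceptance = attr(trace, "acceptance"))
  }, error = function(e) fail("clock", e))

  class(report) <- "run_report"
  report
}

# species-level calibrations -> gene-tree clades: the calibrated node is
# the MRCA of accepted sequences from the calibrated species; calibrations
# hitting fewer than 2 gene leaves are dropped
.map_calibrations <- function(cals, leaf_species) {
  out <- list()
  for (cal in cals) {
    tips <- names(leaf_species)[leaf_species %in% cal$clade]
    if (length(tips) >= 2) {
      out[[length(out) + 1L]] <-
        calibration(tips, cal$offset, cal$log_mean, cal$log_sd)
    }
  }
  out
}

#' Render a pipeline report
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param json_path Optional path for the machine-readable JSON.
#' @return Character vector of human-readable summary lines (invisibly
#'   writes JSON when `json_path` is given).  Skipped or absent stages are
#'   reported as such, never silently omitted.
#' @export
report_render <- function(report, json_path = NULL) {
  lines <- c(sprintf("run seed: %d", report$seed))
  sec <- function(name, body) {
    if (is.null(report[[name]])) {
      c(sprintf("[%s] stage skipped", name))
    } else body
  }
  lines <- c(lines, sec("vet", c(
    sprintf("[vet] accepted: %d, rejected: %d", report$vet$n_accepted,
            report$vet$n_rejected),
    sprintf("[vet] clades: %s",
            paste(apply(report$vet$clades, 1, paste, collapse = ":"),
                  collapse = ", "))
  )))
  lines <- c(lines, sec("monophyly", sprintf(
    "[monophyly] focal phyla (%s) monophyletic: %s (%d sequences)",
    paste(report$monophyly$phyla, collapse = ","),
    report$monophyly$monophyletic, report$monophyly$n_sequences
  )))
  lines <- c(lines, sec("duplications", sprintf(
    "[reconcile] duplications: %d (%d species-specific, %d multi-species), losses: %d",
    report$duplications$total, report$duplications$species_specific,
    report$duplications$multi_species, report$duplications$losses
  )))
  lines <- c(lines, sec("dollo", sprintf(
    "[dollo] independent losses: %d", report$dollo$n_losses
  )))
  lines <- c(lines, sec("clock", sprintf(
    "[clock] posterior median root age: %.4g (%d calibrations)",
    report$clock$root_age_median, report$clock$n_calibrations
  )))
  if (!is.null(json_path)) {
    out <- report
    class(out) <- NULL
    out$vet$rejected_by_reason <- as.list(out$vet$rejected_by_reason)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  lines
}
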