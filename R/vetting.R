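# ---------------------------------------------------------------------------
# Phylogeny-aware contamination vetting.  Transcriptome-derived homolog
# candidates are screened on an annotated gene tree: a sequence survives
# only if it sits in a clade where two or more genera of one phylum group
# together; within such clades, members from a different phylum are flagged
# as probable contaminants and highly similar same-species members as
# redundant.  An optional external-evidence hook (genome confirmation)
# forces rejection of transcripts absent from their species' genome.
# ---------------------------------------------------------------------------

#' Vetting parameters
#'
#' @param min_genera Minimum distinct genera of the majority phylum a clade
#'   must contain (default 2).
#' @param majority_fraction Fraction of clade leaves the majority phylum
#'   must reach for the clade to be assigned that phylum (default 2/3).
#'   A strict 100% rule would be self-defeating: the procedure is designed
#'   to find wrong-phylum members *inside* defined clades and remove them.
#' @param redundancy_threshold Identity threshold for within-clade
#'   same-species redundancy (default 0.90).
#' @return A `vet_params` list.
#' @export
vet_params <- function(min_genera = 2, majority_fraction = 2 / 3,
                       redundancy_threshold = 0.90) {
  if (min_genera < 2) stop("min_genera must be >= 2")
  if (majority_fraction <= 0.5 || majority_fraction > 1) {
    stop("majority_fraction must be in (0.5, 1]")
  }
  if (redundancy_threshold <= 0 || redundancy_threshold > 1) {
    stop("redundancy_threshold must be in (0, 1]")
  }
  structure(list(min_genera = min_genera,
                 majority_fraction = majority_fraction,
                 redundancy_threshold = redundancy_threshold),
            class = "vet_params")
}

#' Attach taxonomy to the leaves of a gene tree
#'
#' @param tree A `phylo` whose tip labels are sequence ids.
#' @param taxmap Taxonomy data.frame from [read_taxonomy()].
#' @return `tree` with a `taxonomy` data.frame (one row per tip, tip order).
#' @export
annotate_tree <- function(tree, taxmap) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) == 0) {
    stop("empty or invalid tree")
  }
  idx <- match(tree$tip.label, taxmap$id)
  if (anyNA(idx)) {
    stop("leaves missing from taxonomy: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  tree$taxonomy <- taxmap[idx, c("species", "genus", "phylum", "vetting_ok")]
  rownames(tree$taxonomy) <- tree$tip.label
  tree
}

#' Find candidate phylum clades on an annotated gene tree
#'
#' Returns the maximal internal nodes whose leaf set has a majority phylum
#' (fraction >= `majority_fraction`) represented by at least `min_genera`
#' distinct genera.  Nested qualifying clades are suppressed in favour of
#' the largest, so each leaf is judged once.
#'
#' @param tree Annotated tree from [annotate_tree()].
#' @param params A [vet_params()] list.
#' @return List of clades, each `list(node, phylum, members)` where
#'   `members` are tip labels.
#' @export
candidate_clades <- function(tree, params = vet_params()) {
  ntip <- length(tree$tip.label)
  tax <- tree$taxonomy
  qualifies <- function(node) {
    tips <- .descendant_tips(tree, node)
    if (length(tips) < 2) return(NULL)
    phyla <- tax$phylum[tips]
    usable <- tax$vetting_ok[tips]
    counts <- table(phyla[usable & nzchar(phyla)])
    if (!length(counts)) return(NULL)
    top <- names(counts)[which.max(counts)]
    frac <- counts[[top]] / length(tips)
    if (frac < params$majority_fraction) return(NULL)
    genera <- unique(tax$genus[tips][usable & phyla == top])
    if (length(genera) < params$min_genera) return(NULL)
    list(node = node, phylum = top, members = tree$tip.label[tips])
  }
  out <- list()
  taken <- rep(FALSE, ntip + tree$Nnode)
  # preorder: root first, so maximal qualifying nodes shadow nested ones
  for (node in c(ntip + 1L, tree$edge[, 2])) {
    if (node <= ntip || taken[node]) next
    cand <- qualifies(node)
    if (!is.null(cand)) {
      out[[length(out) + 1L]] <- cand
      below <- c(.descendant_tips(tree, node), .descendant_internal(tree, node))
      taken[below] <- TRUE
      taken[node] <- TRUE
    }
  }
  out
}

.descendant_internal <- function(tree, node) {
  kids <- .children_list(tree)
  out <- integer(0)
  stack <- kids[[node]]
  ntip <- length(tree$tip.label)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v > ntip) { out <- c(out, v); stack <- c(kids[[v]], stack) }
  }
  out
}

#' Flag removable members of a candidate clade
#'
#' Members whose phylum differs from the clade's majority phylum are
#' probable contaminants (`wrong_phylum`); among members of the same
#' species, near-identical sequences are `redundant` (one representative,
#' the longest, is kept per redundancy cluster).
#'
#' @param clade A clade from [candidate_clades()].
#' @param tree The annotated tree the clade came from.
#' @param records Optional data.frame (`id`, `species`, `residues`) enabling
#'   the redundancy check; without residues only phylum checks run.
#' @param params A [vet_params()] list.
#' @return data.frame `seq_id`, `reason`, `evidence` (possibly empty).
#' @export
flag_members <- function(clade, tree, records = NULL,
                         params = vet_params()) {
  tax <- tree$taxonomy[clade$members, , drop = FALSE]
  out <- list()
  wrong <- clade$members[tax$phylum != clade$phylum]
  for (id in wrong) {
    out[[length(out) + 1L]] <- data.frame(
      seq_id = id, reason = "wrong_phylum",
      evidence = sprintf("phylum '%s' inside %s clade",
                         tax[id, "phylum"], clade$phylum),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(records)) {
    keep <- setdiff(clade$members, wrong)
    keep <- keep[keep %in% records$id]
    by_sp <- split(keep, tax[keep, "species"])
    for (ids in by_sp) {
      if (length(ids) < 2) next
      recs <- records[match(ids, records$id), c("id", "species", "residues")]
      dd <- dedupe_by_identity(recs, params$redundancy_threshold)
      for (i in seq_len(nrow(dd$removed))) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = dd$removed$id[i], reason = "redundant",
          evidence = sprintf("%.1f%% identical to %s",
                             100 * dd$removed$identity[i],
                             dd$removed$representative[i]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(), reason = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Vet homolog candidates on a gene tree
#'
#' Composition of [annotate_tree()], [candidate_clades()] and
#' [flag_members()].  Leaves outside every candidate clade are rejected
#' with reason `no_clade`; every input leaf appears exactly once across
#' the accepted and rejected sets.
#'
#' @param tree Gene tree (`phylo`) over sequence ids.
#' @param taxmap Taxonomy data.frame ([read_taxonomy()]).
#' @param records Optional sequence data.frame for redundancy checks.
#' @param params A [vet_params()] list.
#' @param genome_confirmed Optional named logical: per-sequence external
#'   evidence.  `FALSE` forces rejection with reason `genome_absent`
#'   (transcript not found in its species' genome).
#' @return A `vet_report` list: `accepted` (data.frame `clade_id`, `phylum`,
#'   `seq_id`), `rejected` (data.frame `seq_id`, `reason`, `evidence`),
#'   `params`.
#' @export
vet <- function(tree, taxmap, records = NULL, params = vet_params(),
                genome_confirmed = NULL) {
  tree <- annotate_tree(tree, taxmap)
  clades <- candidate_clades(tree, params)
  rejected <- list()
  accepted <- list()
  claded <- character(0)
  for (k in seq_along(clades)) {
    cl <- clades[[k]]
    claded <- c(claded, cl$members)
    flags <- flag_members(cl, tree, records, params)
    rejected[[length(rejected) + 1L]] <- flags
    ok <- setdiff(cl$members, flags$seq_id)
    if (length(ok)) {
      accepted[[length(accepted) + 1L]] <- data.frame(
        clade_id = sprintf("clade_%02d", k), phylum = cl$phylum,
        seq_id = ok, stringsAsFactors = FALSE
      )
    }
  }
  outside <- setdiff(tree$tip.label, claded)
  if (length(outside)) {
    rejected[[length(rejected) + 1L]] <- data.frame(
      seq_id = outside, reason = "no_clade",
      evidence = "not inside any multi-genus single-phylum clade",
      stringsAsFactors = FALSE
    )
  }
  accepted <- if (length(accepted)) do.call(rbind, accepted) else
    data.frame(clade_id = character(), phylum = character(),
               seq_id = character(), stringsAsFactors = FALSE)
  rejected <- do.call(rbind, c(rejected, list(data.frame(
    seq_id = character(), reason = character(), evidence = character(),
    stringsAsFactors = FALSE
  ))))
  if (!is.null(genome_confirmed)) {
    bad <- names(genome_confirmed)[!genome_confirmed]
    bad <- intersect(bad, accepted$seq_id)
    if (length(bad)) {
      accepted <- accepted[!accepted$seq_id %in% bad, , drop = FALSE]
      rejected <- rbind(rejected, data.frame(
        seq_id = bad, reason = "genome_absent",
        evidence = "transcript not confirmed in species genome",
        stringsAsFactors = FALSE
      ))
    }
  }
  structure(list(accepted = accepted, rejected = rejected, params = params),
            class = "vet_report")
}

#' Write a vetting report to disk
#' @param report A `vet_report`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_vet_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(accepted = report$accepted, rejected = report$rejected,
           params = unclass(report$params)),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(tsv_path)) {
    status_df <- function(df, status, detail) {
      data.frame(seq_id = df$seq_id, status = rep(status, nrow(df)),
                 detail = if (nrow(df)) detail else character(0))
    }
    acc <- status_df(report$accepted, "accepted",
                     paste0(report$accepted$clade_id, ":",
                            report$accepted$phylum))
    rej <- status_df(report$rejected, "rejected",
                     paste0(report$rejected$reason, ": ",
                            report$rejected$evidence))
    write.table(rbind(acc, rej), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(report)
}
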