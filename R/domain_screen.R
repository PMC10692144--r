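# ---------------------------------------------------------------------------
# Conserved-domain screening.  Functional sterol methyltransferases carry two
# conserved regions: the methyltransferase domain (where sterol binding
# occurs) and a C-terminal domain.  Domain hits arrive in a pfam_scan-style
# whitespace table; sequences with both domains are "full", with one
# "partial".  Coordinates are 1-based inclusive throughout.
# ---------------------------------------------------------------------------

#' Parse a pfam_scan-style domain-hit table
#'
#' Whitespace-separated columns: seq id, alignment start, alignment end,
#' envelope start, envelope end, hmm accession, hmm name, type, hmm start,
#' hmm end, hmm length, bit score, E-value (further columns ignored).
#' Lines starting with `#` are comments.
#'
#' @param path Path to the table (or a connection / literal text via
#'   `textConnection`).
#' @return data.frame with columns `seq_id`, `domain_name`, `start`, `end`,
#'   `evalue` (coordinates 1-based inclusive, from the alignment columns).
#' @export
parse_domain_table <- function(path) {
  tab <- tryCatch(
    read.table(path, comment.char = "#", stringsAsFactors = FALSE,
               fill = FALSE, header = FALSE),
    error = function(e) stop("cannot parse domain table: ",
                             conditionMessage(e))
  )
  if (ncol(tab) < 13) stop("domain table has fewer than 13 columns")
  if (!is.numeric(tab[[2]]) || !is.numeric(tab[[3]])) {
    stop("non-numeric domain coordinates")
  }
  hits <- data.frame(
    seq_id = as.character(tab[[1]]),
    domain_name = as.character(tab[[7]]),
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    evalue = as.numeric(tab[[13]]),
    stringsAsFactors = FALSE
  )
  bad <- hits$start > hits$end
  if (any(bad)) {
    stop("domain hit with end < start for: ",
         paste(hits$seq_id[bad], collapse = ", "))
  }
  if (any(hits$start < 1)) stop("domain coordinates must be >= 1")
  if (any(hits$evalue < 0)) stop("negative e-value")
  hits
}

#' Classify a sequence as full-length, partial, or domain-free
#'
#' @param hits Domain hits for one sequence ([parse_domain_table()] rows).
#' @param required Character vector of the two required domain roles
#'   (default the methyltransferase and C-terminal domain names used by the
#'   simulator and fixtures).
#' @return `"full"` if both required domains are hit, `"partial"` if exactly
#'   one, `"none"` otherwise.
#' @export
classify_completeness <- function(hits,
                                  required = c("Methyltransf", "Sterol_MT_C")) {
  stopifnot(length(required) == 2L)
  if (nrow(hits) && length(unique(hits$seq_id)) > 1L) {
    stop("hits must all belong to one sequence")
  }
  n <- sum(required %in% hits$domain_name)
  c("none", "partial", "full")[n + 1L]
}

#' Extract and concatenate the two conserved domains of a full sequence
#'
#' The methyltransferase and C-terminal regions are cut out independently
#' and re-joined in sequence order.  When a role has several hits the one
#' with the lowest e-value is used (ties broken by earliest start).
#'
#' @param residues The full-length residue string.
#' @param hits Domain hits for this sequence.
#' @param required The two domain roles, in concatenation order.
#' @return The concatenated domain residue string.
#' @export
extract_concat_domains <- function(residues, hits,
                                   required = c("Methyltransf", "Sterol_MT_C")) {
  cls <- classify_completeness(hits, required)
  if (cls != "full") {
    stop("cannot extract domains from a '", cls, "' sequence")
  }
  pick <- function(role) {
    h <- hits[hits$domain_name == role, , drop = FALSE]
    h <- h[order(h$evalue, h$start), , drop = FALSE]
    h[1, ]
  }
  chosen <- do.call(rbind, lapply(required, pick))
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  if (any(chosen$end > nchar(residues))) {
    stop("domain hit extends beyond sequence end")
  }
  paste(substring(residues, chosen$start, chosen$end), collapse = "")
}

# Un-gapped best-overlap identity: matches / length of the shorter sequence,
# maximized over all relative offsets of the two (un-gapped) strings.
.pair_identity <- function(a, b) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0
  for (off in 0:(la - lb)) {
    m <- sum(av[(off + 1):(off + lb)] == bv)
    if (m > best) best <- m
  }
  best / lb
}

#' Remove same-species redundant sequences
#'
#' Greedy clustering by decreasing length, in the style of CD-HIT: each
#' record joins the first existing cluster whose representative it matches
#' at `threshold` identity or better, where identity is the exact-match
#' fraction over the shorter sequence at the best un-gapped offset.  The
#' longest record of each cluster is retained.
#'
#' @param records data.frame with columns `id`, `species`, `residues`
#'   (single species).
#' @param threshold Identity threshold (default 0.90, the conventional
#'   redundancy cutoff).
#' @return List with `retained` (data.frame subset) and `removed`
#'   (data.frame `id`, `representative`, `identity`).
#' @export
dedupe_by_identity <- function(records, threshold = 0.90) {
  if (!nrow(records)) stop("no records")
  if (length(unique(records$species)) > 1L) {
    stop("dedupe_by_identity expects records from a single species")
  }
  ord <- order(-nchar(records$residues), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- integer(0)
  removed <- list()
  for (i in seq_len(nrow(records))) {
    placed <- FALSE
    for (r in reps) {
      ident <- .pair_identity(records$residues[r], records$residues[i])
      if (ident >= threshold) {
        removed[[length(removed) + 1L]] <- data.frame(
          id = records$id[i], representative = records$id[r],
          identity = ident, stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) reps <- c(reps, i)
  }
  list(
    retained = records[reps, , drop = FALSE],
    removed = if (length(removed)) do.call(rbind, removed) else
      data.frame(id = character(), representative = character(),
                 identity = numeric(), stringsAsFactors = FALSE)
  )
}

#' Drop alignment columns that are all-gap
#'
#' A minimal cleaning step for concatenated domain alignments; removed
#' column indices are reported so the operation is auditable.
#'
#' @param aln Alignment matrix.
#' @return List with `alignment` and `dropped` (column indices removed).
#' @export
drop_allgap_columns <- function(aln) {
  allgap <- apply(aln == "-", 2, all)
  list(alignment = aln[, !allgap, drop = FALSE], dropped = which(allgap))
}
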