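#' @useDynLib smtphylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rexp rlnorm rgamma rbinom qgamma pgamma dlnorm
#'   dexp median quantile setNames sd
#' @importFrom utils read.delim read.table write.table head tail
NULL

# ---------------------------------------------------------------------------
# Trees are ape "phylo" objects throughout.  Internal-node supports are kept,
# normalized to [0, 1], in a numeric vector `tree$support` of length
# `tree$Nnode` (NA where absent) and mirrored into `tree$node.label` on
# output.  Dated (ultrametric) trees carry ages implicitly in their edge
# lengths; `node_ages()` recovers them.
# ---------------------------------------------------------------------------

#' Parse a Newick string into a phylogenetic tree
#'
#' Internal-node labels that parse as numbers are interpreted as branch
#' supports: values already in \[0, 1\] are kept as-is, values in (1, 100\]
#' (bootstrap percentages) are divided by 100.  Both dialects occur in the
#' wild; supports are normalized to \[0, 1\] internally.
#'
#' @param text A single well-formed Newick statement ending in `;`.
#' @return An [ape::phylo] object with an additional numeric `support`
#'   vector (length `Nnode`, `NA` where no support was present).
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("parse error: `text` must be a single character string")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("parse error at position 1: empty input")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("parse error at position %d: unbalanced ')'", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf(
      "parse error at position %d: %d unclosed '('", nchar(text), depth
    ))
  }
  if (!endsWith(text, ";")) {
    stop(sprintf("parse error at position %d: missing terminal ';'",
                 nchar(text)))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("parse error: not a valid Newick statement")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("parse error: duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  tree$support <- .labels_to_support(tree)
  tree
}

# Dialect rule: numeric internal labels in [0,1] kept, (1,100] divided by 100.
.labels_to_support <- function(tree) {
  supp <- rep(NA_real_, tree$Nnode)
  lab <- tree$node.label
  if (is.null(lab)) return(supp)
  suppressWarnings(num <- as.numeric(lab))
  ok <- !is.na(num) & num >= 0 & num <= 100
  supp[ok & num <= 1] <- num[ok & num <= 1]
  supp[ok & num > 1] <- num[ok & num > 1] / 100
  supp
}

#' Serialize a tree to Newick
#'
#' Supports (if present) are written as internal-node labels on their
#' normalized \[0, 1\] scale, so `parse_newick(write_newick(t))` round-trips
#' topology, labels, branch lengths and supports exactly.  Decimal point is
#' `.`; plain (non-scientific) notation is used for all values >= 1e-6.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @param digits Significant digits for branch lengths (default 12).
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- .children_list(tree)
  elen <- rep(NA_real_, ntip + tree$Nnode)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  supp <- tree$support
  fmt <- function(x) {
    s <- formatC(x, digits = digits, format = "g", flag = "#")
    s <- sub("[.]?0*$", "", s)
    if (grepl("e", s) && abs(x) >= 1e-6) s <- format(x, scientific = FALSE)
    s
  }
  rec <- function(node) {
    if (node <= ntip) {
      out <- tree$tip.label[node]
    } else {
      inner <- vapply(kids[[node]], rec, character(1))
      lab <- ""
      if (!is.null(supp) && !is.na(supp[node - ntip])) {
        lab <- fmt(supp[node - ntip])
      } else if (!is.null(tree$node.label)) {
        nl <- tree$node.label[node - ntip]
        if (!is.na(nl) && nzchar(nl)) lab <- nl
      }
      out <- paste0("(", paste(inner, collapse = ","), ")", lab)
    }
    if (!is.na(elen[node])) out <- paste0(out, ":", fmt(elen[node]))
    out
  }
  s <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# children of every node, indexed by ape node number
.children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

#' Node ages of a dated (ultrametric) tree
#'
#' @param tree An ultrametric `phylo` with branch lengths.
#' @param tol Tolerance for the ultrametricity check.
#' @return Numeric vector of ages for all nodes (tips then internals, ape
#'   numbering); tips are age 0.
#' @export
node_ages <- function(tree, tol = 1e-8) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  h <- max(depth[seq_len(ntip)])
  if (max(abs(depth[seq_len(ntip)] - h)) > tol * max(h, 1)) {
    stop("tree is not ultrametric: leaf depths differ")
  }
  ages <- h - depth
  ages[seq_len(ntip)] <- 0
  ages
}

#' Rebuild the branch lengths of a tree from node ages
#'
#' @param tree A `phylo` giving the topology.
#' @param ages Ages for all nodes (ape numbering, tips first).
#' @return `tree` with `edge.length` set to parent age minus child age.
#' @export
set_node_ages <- function(tree, ages) {
  el <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(el < -1e-9)) stop("ages are not monotone: parent younger than child")
  tree$edge.length <- pmax(el, 0)
  tree
}

#' Read a taxonomy table
#'
#' Expects a TSV with columns `id`, `species`, `genus`, `phylum`.  Rows with
#' an empty phylum (or genus/species) are kept but flagged unusable for
#' phylum-clade vetting via the `vetting_ok` column.
#'
#' @param path Path to the TSV file (or a connection).
#' @return A data.frame with columns `id`, `species`, `genus`, `phylum`,
#'   `vetting_ok`.
#' @export
read_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "species", "genus", "phylum")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup)) {
    stop("duplicate sequence id(s) in taxonomy table: ",
         paste(dup, collapse = ", "))
  }
  tab <- tab[need]
  tab$vetting_ok <- nzchar(tab$species) & nzchar(tab$genus) &
    nzchar(tab$phylum)
  tab
}

#' Read amino-acid FASTA into a named character vector
#' @param path FASTA file path.
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: no '>' header found")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- character(length(ids))
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  if (anyDuplicated(ids)) stop("duplicate FASTA ids")
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Residues per line.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Build an alignment matrix from equal-length sequences
#' @param seqs Named character vector of aligned residue strings.
#' @return Character matrix, rows = sequences, columns = sites.
#' @export
as_alignment <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) {
    stop("sequences have unequal lengths: not an alignment")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Pairwise distance matrix from a protein alignment
#'
#' p-distance is the fraction of differing columns among columns where both
#' sequences have an unambiguous residue (gaps `-` and `X` excluded).  The
#' Poisson correction is d = -ln(1 - p); saturated pairs (p >= 1, impossible
#' for p-distance but guarded) and corrected values above `max_dist` are
#' capped at `max_dist`.
#'
#' @param aln Character matrix from [as_alignment()].
#' @param model `"p-distance"` or `"poisson"`.
#' @param max_dist Cap for saturated corrected distances (default 5).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, model = c("p-distance", "poisson"),
                            max_dist = 5) {
  model <- match.arg(model)
  n <- nrow(aln)
  if (is.null(n) || n < 2) stop("alignment must have at least 2 rows")
  usable <- aln != "-" & aln != "X" & aln != "?"
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- usable[i, ] & usable[j, ]
      if (!any(comp)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     rownames(aln)[i], rownames(aln)[j]))
      }
      p <- mean(aln[i, comp] != aln[j, comp])
      d <- if (model == "p-distance") p
           else if (p >= 1) max_dist else min(-log(1 - p), max_dist)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; negative branch lengths are clamped to zero
#' (a common convention that preserves exactness on additive matrices).
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param labels Optional taxon labels (defaults to `rownames(D)`).
#' @return An unrooted `phylo`.
#' @export
neighbor_joining <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa for neighbor joining")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("distance matrix diagonal is not zero")
  if (!is.null(labels)) rownames(D) <- colnames(D) <- labels
  tree <- ape::nj(D)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap branch supports for a neighbor-joining tree
#'
#' Builds the NJ tree on the full alignment, then resamples alignment
#' columns with replacement `n_reps` times; each internal edge's support is
#' the fraction of replicate trees containing that bipartition.
#'
#' @param aln Alignment matrix.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param model Distance model passed to [distance_matrix()].
#' @return The NJ tree with `support` filled in (root entry `NA`).
#' @export
bootstrap_support <- function(aln, n_reps, seed,
                              model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(ncol(aln)) || ncol(aln) < 1) {
    stop("alignment must have at least 1 column")
  }
  build <- function(x) neighbor_joining(distance_matrix(x, model))
  ref <- build(aln)
  set.seed(seed)
  counts <- ape::boot.phylo(ref, aln, build, B = n_reps,
                            rooted = FALSE, quiet = TRUE)
  supp <- counts / n_reps
  supp[1] <- NA  # root of the unrooted representation: trivial bipartition
  ref$support <- supp
  ref$node.label <- ifelse(is.na(supp), "", formatC(supp, format = "g"))
  ref
}

#' Leaf set of a clade
#' @param tree A `phylo`.
#' @param node Internal (or tip) node number.
#' @return Character vector of tip labels below `node`.
#' @export
clade_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[.descendant_tips(tree, node)]
}

.descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- .children_list(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v) else stack <- c(kids[[v]], stack)
  }
  out
}

# MRCA of a set of tip labels (rooted tree)
.mrca_of <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown leaf: ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}
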