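# ---------------------------------------------------------------------------
# Sterol mass arithmetic.  C-24 sterol methyltransferases add methyl groups
# to carbon 24 of the sterol side chain, taking the C27 skeleton
# (cholesterol, C27H46O) to C28 and C29 sterols.  For GC-MS, sterols are
# derivatized as trimethylsilyl (TMS) ethers (net +C3H8Si, +72 u nominal);
# their electron-impact spectra show the molecular ion plus characteristic
# losses of TMSOH (90 u) and TMSOH+CH3 (105 u).  Nominal (unit-resolution)
# masses only.
# ---------------------------------------------------------------------------

.NOMINAL_MASS <- c(C = 12, H = 1, O = 16, Si = 28)

#' Parse a molecular formula in Hill notation
#'
#' Supports the elements C, H, O and Si.
#'
#' @param formula e.g. `"C27H46O"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != formula) {
    stop("cannot parse formula: ", formula)
  }
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  unknown <- setdiff(elems, names(.NOMINAL_MASS))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, factor(elems, levels = names(.NOMINAL_MASS)), sum)
  out[is.na(out)] <- 0L
  setNames(as.integer(out), names(.NOMINAL_MASS))
}

#' Nominal (integer) mass of a molecular formula
#' @param formula Named count vector from [parse_formula()] or a string.
#' @return Integer nominal mass (C=12, H=1, O=16, Si=28).
#' @export
nominal_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(formula * .NOMINAL_MASS[names(formula)])
}

#' Add C-24 methyl groups to a sterol formula
#'
#' Each methylation adds one CH2 unit (+14 u nominal), so cholesterol
#' (C27H46O) becomes a C28 sterol after one round and a C29 sterol after
#' two — the reactions catalyzed by 24-C sterol methyltransferases.
#'
#' @param base Sterol formula (string or parsed counts).
#' @param k Number of methylations, 0, 1 or 2.
#' @return Named count vector of the methylated sterol.
#' @export
methylate <- function(base, k) {
  if (is.character(base)) base <- parse_formula(base)
  if (!k %in% 0:2) stop("k must be 0, 1 or 2 (C-24 methylation rounds)")
  base[["C"]] <- base[["C"]] + as.integer(k)
  base[["H"]] <- base[["H"]] + 2L * as.integer(k)
  base
}

#' Nominal m/z of the trimethylsilyl ether of a sterol
#'
#' Silylation replaces the hydroxyl H with Si(CH3)3 (net +C3H8Si, +72 u).
#' Assumes a mono-hydroxy sterol.
#'
#' @param sterol Sterol formula (string or parsed counts).
#' @return Integer nominal m/z of the TMS derivative molecular ion.
#' @export
tms_nominal_mz <- function(sterol) {
  if (is.character(sterol)) sterol <- parse_formula(sterol)
  if (sterol[["O"]] < 1L) stop("no hydroxyl oxygen: cannot silylate")
  sterol[["C"]] <- sterol[["C"]] + 3L
  sterol[["H"]] <- sterol[["H"]] + 8L
  sterol[["Si"]] <- sterol[["Si"]] + 1L
  as.integer(nominal_mass(sterol))
}

#' Characteristic TMS-sterol fragment ions
#'
#' Emits the molecular ion and the two canonical neutral losses: TMSOH
#' (90 u) and TMSOH + CH3 (105 u).
#'
#' @param parent_mz Nominal m/z of the TMS molecular ion.
#' @return data.frame with columns `label`, `mz`.
#' @export
fragment_ions <- function(parent_mz) {
  stopifnot(is.numeric(parent_mz), length(parent_mz) == 1L)
  if (parent_mz < 105) stop("parent m/z below 105: fragment ions undefined")
  data.frame(
    label = c("[M]", "[M-TMSOH]", "[M-TMSOH-CH3]"),
    mz = as.integer(c(parent_mz, parent_mz - 90, parent_mz - 105)),
    stringsAsFactors = FALSE
  )
}
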