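# Residue alphabets and conservation groups shared across the package.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Clustal conservation convention: ":" when both residues fall in one
# strong group, "." when both fall in one weak group (and no strong group).
CLUSTAL_STRONG <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV",
                    "MILF", "HY", "FYW")

CLUSTAL_WEAK <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
                  "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")

.group_members <- function(groups) lapply(groups, function(g) strsplit(g, "")[[1]])

.STRONG_SETS <- .group_members(CLUSTAL_STRONG)
.WEAK_SETS <- .group_members(CLUSTAL_WEAK)

# 20 x 20 logical lookup tables; X and gaps are handled by the callers
# (they never count as identical or similar).
.pair_table <- function(sets) {
  m <- matrix(FALSE, 20, 20, dimnames = list(AA_STANDARD, AA_STANDARD))
  for (s in sets) m[s, s] <- TRUE
  m
}

.STRONG_PAIR <- .pair_table(.STRONG_SETS)
.WEAK_PAIR <- .pair_table(.WEAK_SETS)

#' Test whether two residues are conservatively substitutable
#'
#' Two residues are "similar" in the strong sense when they share a Clustal
#' strong conservation group, and in the weak sense when they share a weak
#' group.  `X`, gaps and non-standard characters are never similar.
#'
#' @param a,b Single upper-case amino-acid characters (vectorised).
#' @return Logical vector.
#' @keywords internal
residues_strongly_similar <- function(a, b) {
  ok <- a %in% AA_STANDARD & b %in% AA_STANDARD
  out <- logical(length(ok))
  out[ok] <- .STRONG_PAIR[cbind(a[ok], b[ok])]
  out
}

#' @rdname residues_strongly_similar
#' @keywords internal
residues_weakly_similar <- function(a, b) {
  ok <- a %in% AA_STANDARD & b %in% AA_STANDARD
  out <- logical(length(ok))
  out[ok] <- .WEAK_PAIR[cbind(a[ok], b[ok])]
  out
}

#' Classify a substitution as conservative or not
#'
#' A substitution is conservative when the two residues share any Clustal
#' strong or weak conservation group (e.g. F/Y), and non-conservative
#' otherwise (e.g. L/Q, which share no group).
#'
#' @param expected,observed Amino-acid characters (vectorised).
#' @return Logical vector, `TRUE` for conservative substitutions.
#' @export
is_conservative_substitution <- function(expected, observed) {
  residues_strongly_similar(expected, observed) |
    residues_weakly_similar(expected, observed)
}
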