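# IUPAC degenerate nucleotide alphabet. Each code names a base set; PAM
# patterns are strings over this alphabet. Kept as a package-internal table
# so that matching is a plain logical lookup.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

.IUPAC_CODES <- names(.IUPAC_SETS)
.DNA_BASES <- c("A", "C", "G", "T")

# 15 x 4 logical matrix: does code (row) admit base (column)?
.IUPAC_MATCH <- local({
  m <- matrix(FALSE, nrow = length(.IUPAC_CODES), ncol = 4,
              dimnames = list(.IUPAC_CODES, .DNA_BASES))
  for (code in .IUPAC_CODES) m[code, .IUPAC_SETS[[code]]] <- TRUE
  m
})

# Symbol-wise complement: base sets map onto complemented base sets.
.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

#' Test whether an IUPAC code admits a nucleotide
#'
#' Degenerate PAM patterns are written in the IUPAC one-letter alphabet
#' (N = any base, R = A/G, and so on). `iupac_match()` answers, symbol by
#' symbol, whether a concrete base belongs to the symbol's base set. Both
#' arguments are vectorised and recycled.
#'
#' @param symbol Character vector of single IUPAC codes
#'   (one of A,C,G,T,M,R,W,S,Y,K,V,H,D,B,N).
#' @param base Character vector of unambiguous bases (A, C, G or T).
#' @return Logical vector: `TRUE` where `base` is in `symbol`'s expansion.
#' @examples
#' iupac_match("N", "A")            # TRUE
#' iupac_match("R", c("G", "C"))    # TRUE FALSE
#' @export
iupac_match <- function(symbol, base) {
  symbol <- toupper(as.character(symbol))
  base <- toupper(as.character(base))
  if (!all(symbol %in% .IUPAC_CODES)) {
    bad <- unique(symbol[!symbol %in% .IUPAC_CODES])
    stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ", "))
  }
  if (!all(base %in% .DNA_BASES)) {
    bad <- unique(base[!base %in% .DNA_BASES])
    stop("invalid base(s): ", paste(bad, collapse = ", "))
  }
  n <- max(length(symbol), length(base))
  .IUPAC_MATCH[cbind(rep_len(symbol, n), rep_len(base, n))]
}

#' Validate a PAM pattern string
#'
#' @param pattern A single PAM pattern string over the IUPAC alphabet.
#' @return The pattern, uppercased, invisibly-checked; errors name the first
#'   offending character and its position.
#' @export
check_pam_pattern <- function(pattern) {
  if (length(pattern) != 1L || is.na(pattern) || !nzchar(pattern))
    stop("PAM pattern must be one non-empty string")
  pattern <- toupper(pattern)
  syms <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!syms %in% .IUPAC_CODES)
  if (length(bad))
    stop(sprintf("invalid IUPAC symbol '%s' at position %d in pattern '%s'",
                 syms[bad[1]], bad[1], pattern))
  pattern
}

#' Reverse-complement a degenerate PAM pattern
#'
#' The complement of an IUPAC code is the code naming the complemented base
#' set (A<->T, C<->G, R<->Y, M<->K, B<->V, D<->H; W, S and N are their own
#' complements). Applying the operation twice returns the original pattern.
#'
#' @param pattern PAM pattern string over the IUPAC alphabet.
#' @return The reverse-complemented pattern string.
#' @examples
#' reverse_complement_pattern("NGG")   # "CCN"
#' reverse_complement_pattern("TTTV")  # "BAAA"
#' @export
reverse_complement_pattern <- function(pattern) {
  pattern <- check_pam_pattern(pattern)
  syms <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(rev(unname(.IUPAC_COMPLEMENT[syms])), collapse = "")
}

# Reverse-complement a concrete A/C/G/T sequence (also tolerates IUPAC).
.revcomp_seq <- function(x) {
  vapply(x, reverse_complement_pattern, character(1), USE.NAMES = FALSE)
}

# All start offsets (1-based, relative to `subject`) where `pattern` matches
# `subject` under IUPAC semantics. Positions of `subject` not in A/C/G/T
# never match (callers warn separately). Plain logical-matrix scan.
.match_starts <- function(pattern_syms, subject_chars) {
  L <- length(pattern_syms)
  W <- length(subject_chars)
  if (W < L) return(integer(0))
  ok_base <- subject_chars %in% .DNA_BASES
  starts <- integer(0)
  for (s in seq_len(W - L + 1L)) {
    idx <- s:(s + L - 1L)
    if (!all(ok_base[idx])) next
    if (all(.IUPAC_MATCH[cbind(pattern_syms, subject_chars[idx])]))
      starts <- c(starts, s)
  }
  starts
}
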