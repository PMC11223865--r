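#' Build the mutation-centred search window
#'
#' The window contains the variant base and extends `L` nucleotides up- and
#' downstream, where `L` is the length of the PAM pattern being tested, so
#' every placement of the pattern that overlaps the variant lies fully
#' inside it. At sequence ends the window is clipped, never padded.
#'
#' @param reference Reference sequence: a single string, a named character
#'   vector, or a `DNAStringSet` containing the variant's `sequence_id`.
#' @param v An [variant()] (`snv_variant`).
#' @param L Pattern length (window half-width), `>= 1`.
#' @return List of class `pam_window`: `wt_seq`, `mut_seq` (differing only
#'   at the centre), `centre` (1-based index of the variant inside the
#'   window) and `start` (1-based reference coordinate of the window).
#' @examples
#' w <- build_window("AACTACCAA", variant("ref", 5, "A", "G"), L = 2)
#' w$wt_seq   # "CTACC"
#' w$mut_seq  # "CTGCC"
#' @export
build_window <- function(reference, v, L) {
  stopifnot(inherits(v, "snv_variant"), L >= 1)
  seq <- .resolve_reference(reference, v)
  n <- nchar(seq)
  if (v$position > n)
    stop("variant position ", v$position, " beyond end of sequence '",
         v$sequence_id, "' (length ", n, ")")
  at <- substr(seq, v$position, v$position)
  if (at != v$ref)
    stop("reference mismatch at ", v$sequence_id, ":", v$position,
         ": expected '", v$ref, "', reference has '", at, "'")
  from <- max(1L, v$position - as.integer(L))
  to <- min(n, v$position + as.integer(L))
  wt <- substr(seq, from, to)
  centre <- v$position - from + 1L
  mut <- wt
  substr(mut, centre, centre) <- v$alt
  structure(list(wt_seq = wt, mut_seq = mut, centre = centre,
                 start = from),
            class = "pam_window")
}

#' All placements of a degenerate pattern in a sequence, both orientations
#'
#' A reverse-orientation placement is a forward match of the
#' reverse-complemented pattern against the given (plus) strand; the
#' reported strand is the genomic strand carrying the motif. Positions of
#' the subject outside A/C/G/T never match (a warning is raised once per
#' call when such positions exist, since ambiguity defeats allele
#' exclusivity).
#'
#' @param pattern PAM pattern string (IUPAC).
#' @param sequence Subject sequence string (plus strand).
#' @return data.frame with columns `start` (1-based) and `strand`
#'   (`"+"`/`"-"`), zero rows when nothing matches.
#' @export
pam_placements <- function(pattern, sequence) {
  pattern <- check_pam_pattern(pattern)
  syms_f <- strsplit(pattern, "", fixed = TRUE)[[1]]
  syms_r <- strsplit(reverse_complement_pattern(pattern), "",
                     fixed = TRUE)[[1]]
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (any(!chars %in% .DNA_BASES))
    warning("sequence contains non-A/C/G/T characters; placements ",
            "covering them are disqualified")
  f <- .match_starts(syms_f, chars)
  r <- .match_starts(syms_r, chars)
  out <- data.frame(
    start = c(f, r),
    strand = c(rep("+", length(f)), rep("-", length(r))),
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Does `pattern` (either orientation) match anywhere in `sequence`?
.matches_anywhere <- function(pattern, sequence) {
  nrow(suppressWarnings(pam_placements(pattern, sequence))) > 0L
}

.discriminating_symbol <- function(pattern, strand, align_idx, alt) {
  oriented <- if (strand == "+") pattern
              else reverse_complement_pattern(pattern)
  sym <- substr(oriented, align_idx, align_idx)
  sym %in% .DNA_BASES && sym == alt
}

#' Find SNV-derived PAMs for a variant
#'
#' For each candidate PAM pattern in the registry, scans the
#' mutation-centred window of both alleles in both orientations. A pattern
#' qualifies only when it matches the mutant window somewhere AND matches
#' the wild-type window nowhere (any placement, either orientation): a
#' nearby wild-type match would let the nuclease cut both alleles. Every
#' qualifying mutant placement is emitted as one hit.
#'
#' @param reference Reference sequence (string, named vector or
#'   `DNAStringSet`).
#' @param v An `snv_variant`.
#' @param registry A `cas_registry` (default: packaged registry).
#' @param include_less_preferred Also test the less-preferred alternate
#'   patterns of each enzyme (flagged in the output).
#' @param strict_promiscuity Drop an enzyme's hits when any of its other
#'   annotated patterns (primary or less-preferred) matches the wild-type
#'   window, guarding against promiscuous cleavage of the wild-type allele.
#' @param rank Order hits with [rank_hits()] before returning.
#' @return A `pam_hits` data.frame, one row per qualifying placement:
#'   `enzyme`, `pattern`, `less_preferred`, `strand`, `offset` (placement
#'   start minus variant position), `matched_seq`, `discriminating` (the
#'   "*" flag: the pattern symbol over the variant is a fully specific base
#'   equal to the mutant base) and `score` (pattern selectivity score).
#' @examples
#' ref <- "AACTACCAA"
#' hits <- find_snv_derived_pams(ref, variant("ref", 5, "A", "G"))
#' subset(hits, enzyme == "Cas12c1")
#' @export
find_snv_derived_pams <- function(reference, v, registry = load_registry(),
                                  include_less_preferred = FALSE,
                                  strict_promiscuity = FALSE, rank = TRUE) {
  stopifnot(inherits(v, "snv_variant"), inherits(registry, "cas_registry"))
  pats <- registry_patterns(registry, include_less_preferred)
  all_pats <- registry_patterns(registry, include_less_preferred = TRUE)

  rows <- vector("list", nrow(pats))
  wt_match_cache <- new.env(parent = emptyenv())
  wt_anywhere <- function(pattern) {
    key <- pattern
    if (!is.null(wt_match_cache[[key]])) return(wt_match_cache[[key]])
    w <- build_window(reference, v, nchar(pattern))
    res <- .matches_anywhere(pattern, w$wt_seq)
    wt_match_cache[[key]] <- res
    res
  }

  for (i in seq_len(nrow(pats))) {
    pattern <- pats$pattern[i]
    L <- nchar(pattern)
    w <- build_window(reference, v, L)
    if (wt_anywhere(pattern)) next
    mut_pl <- suppressWarnings(pam_placements(pattern, w$mut_seq))
    if (!nrow(mut_pl)) next
    if (strict_promiscuity) {
      others <- all_pats$pattern[all_pats$enzyme == pats$enzyme[i] &
                                   all_pats$pattern != pattern]
      if (length(others) && any(vapply(others, wt_anywhere, logical(1))))
        next
    }
    align_idx <- w$centre - mut_pl$start + 1L
    rows[[i]] <- data.frame(
      enzyme = pats$enzyme[i],
      pattern = pattern,
      less_preferred = pats$less_preferred[i],
      strand = mut_pl$strand,
      offset = mut_pl$start - w$centre,
      matched_seq = substring(w$mut_seq, mut_pl$start,
                              mut_pl$start + L - 1L),
      discriminating = unname(mapply(.discriminating_symbol, pattern,
                                     mut_pl$strand, align_idx,
                                     MoreArgs = list(alt = v$alt))),
      score = pats$score[i],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                           list(.empty_hits())))
  rownames(hits) <- NULL
  hits <- structure(hits, class = c("pam_hits", "data.frame"))
  attr(hits, "variant") <- v
  if (rank) rank_hits(hits) else hits
}

.empty_hits <- function() {
  data.frame(enzyme = character(0), pattern = character(0),
             less_preferred = logical(0), strand = character(0),
             offset = integer(0), matched_seq = character(0),
             discriminating = logical(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Recompute the specific-discrimination ("*") flag of a hit
#'
#' The flag is set when the pattern symbol aligned to the variant position
#' (in the hit's orientation; for reverse hits the pattern is
#' reverse-complemented onto the plus strand first) is a fully specific
#' base equal to the mutant base. A degenerate symbol such as R or N can
#' admit the mutant base yet also admit others, so it qualifies without
#' discriminating specifically.
#'
#' @param hit One-row `pam_hits` data.frame (or a list with `pattern`,
#'   `strand`, `offset` fields).
#' @param v The `snv_variant` the hit belongs to.
#' @return Logical flag.
#' @export
classify_discrimination <- function(hit, v) {
  L <- nchar(hit$pattern)
  align_idx <- 1L - hit$offset
  if (align_idx < 1L || align_idx > L)
    stop("hit placement does not overlap the variant position")
  .discriminating_symbol(hit$pattern, hit$strand, align_idx, v$alt)
}

#' Order hits by selectivity
#'
#' Descending selectivity score; ties broken by the specific-discrimination
#' flag (flagged hits first), then enzyme name ascending; remaining ties by
#' strand and offset for full determinism.
#'
#' @param hits A `pam_hits` data.frame.
#' @return The same rows, reordered.
#' @export
rank_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(-hits$score, -as.integer(hits$discriminating), hits$enzyme,
             hits$less_preferred, hits$strand, hits$offset)
  out <- hits[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variant") <- attr(hits, "variant")
  class(out) <- class(hits)
  out
}

#' @export
print.pam_hits <- function(x, ...) {
  v <- attr(x, "variant")
  if (!is.null(v))
    cat("SNV-derived PAM hits for", format_hgvs_g(v), "\n")
  if (!nrow(x)) {
    cat("  (no qualifying pattern)\n")
  } else {
    df <- as.data.frame(x)
    df$score <- sprintf("%.2f", df$score)
    df$enzyme <- ifelse(df$discriminating, paste0(df$enzyme, " *"),
                        df$enzyme)
    print(df[, c("enzyme", "pattern", "less_preferred", "strand",
                 "offset", "matched_seq", "score")], row.names = FALSE)
  }
  invisible(x)
}
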