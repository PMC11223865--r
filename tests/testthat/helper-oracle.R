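# Independent brute-force oracles. The matcher expands every IUPAC symbol
# into its base set via Biostrings::IUPAC_CODE_MAP and tests all placements
# by exhaustive set membership; reverse-orientation matching goes through
# Biostrings::reverseComplement of the *subject* with position remapping —
# deliberately a different route than the production code, which
# reverse-complements the pattern.

bf_expand <- function(sym) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[sym]], "", fixed = TRUE)[[1]]
}

bf_match_starts <- function(pattern, subject) {
  syms <- strsplit(pattern, "", fixed = TRUE)[[1]]
  chars <- strsplit(subject, "", fixed = TRUE)[[1]]
  L <- length(syms); W <- length(chars)
  if (W < L) return(integer(0))
  Filter(function(s) {
    all(vapply(seq_len(L), function(k)
      chars[s + k - 1L] %in% bf_expand(syms[k]), logical(1)))
  }, seq_len(W - L + 1L))
}

bf_placements <- function(pattern, subject) {
  W <- nchar(subject); L <- nchar(pattern)
  f <- bf_match_starts(pattern, subject)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(subject)))
  r_rc <- bf_match_starts(pattern, rc)
  r <- vapply(r_rc, function(s) W - s - L + 2L, integer(1))
  out <- data.frame(start = c(unlist(f), r),
                    strand = c(rep("+", length(f)), rep("-", length(r))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# mutant-exclusive qualification by brute force
bf_qualifies <- function(pattern, wt_seq, mut_seq) {
  nrow(bf_placements(pattern, mut_seq)) > 0L &&
    nrow(bf_placements(pattern, wt_seq)) == 0L
}

random_pattern <- function(max_len = 6L) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  codes <- codes[nchar(codes) == 1L & codes %in%
                   c("A","C","G","T","M","R","W","S","Y","K",
                     "V","H","D","B","N")]
  paste(sample(codes, sample(1:max_len, 1), replace = TRUE), collapse = "")
}

random_window_pair <- function(L) {
  W <- sample(seq(max(1, L), 2 * L + 1), 1)
  wt <- paste(sample(c("A","C","G","T"), W, replace = TRUE), collapse = "")
  centre <- sample(seq_len(W), 1)
  ref <- substr(wt, centre, centre)
  alt <- sample(setdiff(c("A","C","G","T"), ref), 1)
  mut <- wt
  substr(mut, centre, centre) <- alt
  list(wt = wt, mut = mut, centre = centre, alt = alt)
}

# naive all-pairs contact oracle on a cas_structure
bf_contacts <- function(structure, pam_chain, pam_resno, threshold) {
  at <- structure$atoms
  heavy <- !(at$element %in% c("H", "D"))
  pam <- at[at$chain == pam_chain & at$resno %in% pam_resno & heavy, ]
  prot_chains <- names(structure$chain_type)[
    structure$chain_type == "protein"]
  prot <- at[at$chain %in% prot_chains & heavy, ]
  res <- unique(prot[, c("chain", "resno", "resid")])
  keep <- vapply(seq_len(nrow(res)), function(i) {
    sub <- prot[prot$chain == res$chain[i] & prot$resno == res$resno[i], ]
    dmin <- Inf
    for (a in seq_len(nrow(sub))) for (b in seq_len(nrow(pam))) {
      d <- sqrt((sub$x[a] - pam$x[b])^2 + (sub$y[a] - pam$y[b])^2 +
                  (sub$z[a] - pam$z[b])^2)
      dmin <- min(dmin, d)
    }
    dmin <= threshold
  }, logical(1))
  res[keep, , drop = FALSE]
}

# registry restricted to a few named enzymes (faster property loops)
small_registry <- function(names) {
  reg <- load_registry()
  reg$enzymes <- reg$enzymes[reg$enzymes$name %in% names, , drop = FALSE]
  reg
}
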