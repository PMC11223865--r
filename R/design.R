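.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
              MSE = "M")
.AA_1TO3 <- stats::setNames(names(.AA_3TO1)[1:20], .AA_3TO1[1:20])

.blosum_env <- new.env(parent = emptyenv())

#' The packaged BLOSUM62 substitution matrix (20 standard amino acids)
#'
#' @return 20x20 integer matrix indexed by one-letter amino-acid codes;
#'   symmetric, with each diagonal entry exceeding every off-diagonal
#'   entry in its row.
#' @export
blosum62 <- function() {
  if (is.null(.blosum_env$B)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$B <- e$BLOSUM62[.AA1, .AA1]
  }
  .blosum_env$B
}

#' Substitution candidates for one residue
#'
#' Proposes every amino acid whose substitution score against the wild-type
#' residue meets the threshold — i.e. exchanges the substitution matrix
#' regards as conservative enough to be worth testing against the PAM.
#' Identity is always excluded.
#'
#' @param wt_aa Wild-type residue, one-letter or three-letter code.
#' @param matrix Substitution matrix (default packaged BLOSUM62).
#' @param threshold Minimum score for a candidate (default 0, i.e.
#'   non-negative BLOSUM62 exchanges).
#' @return Sorted character vector of one-letter candidate codes.
#' @examples
#' candidate_mutations("T")   # A, N, S, V
#' @export
candidate_mutations <- function(wt_aa, matrix = blosum62(), threshold = 0) {
  wt_aa <- toupper(wt_aa)
  if (nchar(wt_aa) == 3L) wt_aa <- unname(.AA_3TO1[wt_aa])
  if (is.na(wt_aa) || !wt_aa %in% rownames(matrix))
    stop("unknown amino-acid code: ", wt_aa)
  row <- matrix[wt_aa, ]
  sort(setdiff(names(row)[row >= threshold], wt_aa))
}

#' Mutation-candidate table for PAM-contacting residues
#'
#' Expands a contact table (from [find_pam_contacts()]) into one row per
#' proposed substitution, optionally annotated with a conservation index.
#' Conservation is advisory only — highly conserved positions hint at
#' catalytic roles and are flagged, never filtered.
#'
#' @param contacts A `pam_contacts` data.frame.
#' @param threshold Minimum substitution score (see
#'   [candidate_mutations()]).
#' @param conservation Optional `conservation_profile` used to annotate
#'   each residue.
#' @param matrix Substitution matrix.
#' @return data.frame: `resno`, `wt_aa`, `proposed_aa`, `blosum_score`,
#'   `conservation` (NA when no profile given), `mutation` (e.g. "T291N").
#' @export
contact_mutation_candidates <- function(contacts, threshold = 0,
                                        conservation = NULL,
                                        matrix = blosum62()) {
  rows <- lapply(seq_len(nrow(contacts)), function(i) {
    wt3 <- contacts$resid[i]
    wt1 <- unname(.AA_3TO1[wt3])
    if (is.na(wt1)) return(NULL)
    props <- candidate_mutations(wt1, matrix, threshold)
    if (!length(props)) return(NULL)
    cons <- NA_real_
    if (!is.null(conservation)) {
      j <- match(contacts$resno[i], conservation$resno)
      if (!is.na(j)) cons <- conservation$conservation[j]
    }
    data.frame(resno = contacts$resno[i], wt_aa = wt1, proposed_aa = props,
               blosum_score = unname(matrix[wt1, props]),
               conservation = cons, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(resno = integer(0), wt_aa = character(0),
                      proposed_aa = character(0), blosum_score = integer(0),
                      conservation = numeric(0), stringsAsFactors = FALSE)
  out$mutation <- paste0(out$wt_aa, out$resno, out$proposed_aa)
  out[order(out$resno, out$proposed_aa), , drop = FALSE]
}

#' Per-residue conservation index from a multiple sequence alignment
#'
#' Scores each alignment column as the mean over all sequence pairs of a
#' min-max-normalised substitution similarity: for residues a and b,
#' `(s(a,b) - min(S)) / (max(s(a,a), s(b,b)) - min(S))`, so identical
#' residues contribute exactly 1 and a pair involving a gap (or a
#' non-standard residue) contributes 0. Columns are mapped back to the
#' ungapped numbering of the query sequence; columns where the query has a
#' gap carry no entry. Values are clamped to [0, 1]: 0 means unconstrained,
#' 1 fully conserved.
#'
#' @param msa Aligned sequences: a named character vector or an
#'   `AAStringSet` (equal lengths required), or a path to an aligned FASTA.
#' @param query_id Name of the query sequence within the alignment.
#' @param matrix Substitution matrix (default packaged BLOSUM62).
#' @param offset Added to the ungapped query index to produce residue
#'   numbers (use the structure's first residue number minus one).
#' @return data.frame of class `conservation_profile`: `resno`, `aa`,
#'   `conservation`; attribute `msa_depth`.
#' @export
conservation_index <- function(msa, query_id, matrix = blosum62(),
                               offset = 0L) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- Biostrings::readAAStringSet(msa)
  if (methods::is(msa, "AAStringSet"))
    msa <- stats::setNames(as.character(msa),
                           sub("\\s.*$", "", names(msa)))
  msa <- toupper(msa)
  if (length(msa) < 2L)
    stop("conservation scoring needs at least 2 aligned sequences")
  if (length(unique(nchar(msa))) != 1L)
    stop("ragged alignment: sequences differ in aligned length")
  if (!query_id %in% names(msa))
    stop("query '", query_id, "' not found in the alignment")

  chars <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  ncol_aln <- ncol(chars)
  smin <- min(matrix)
  diag_s <- diag(matrix)
  pair_idx <- utils::combn(nrow(chars), 2L)

  col_score <- vapply(seq_len(ncol_aln), function(j) {
    col <- chars[, j]
    a <- col[pair_idx[1L, ]]
    b <- col[pair_idx[2L, ]]
    ok <- a %in% .AA1 & b %in% .AA1
    n <- rep(0, length(a))
    if (any(ok)) {
      s <- matrix[cbind(a[ok], b[ok])]
      top <- pmax(diag_s[a[ok]], diag_s[b[ok]])
      n[ok] <- (s - smin) / (top - smin)
    }
    mean(pmin(pmax(n, 0), 1))
  }, numeric(1))

  q <- chars[match(query_id, names(msa)), ]
  keep <- q %in% .AA1
  out <- data.frame(resno = seq_len(sum(keep)) + as.integer(offset),
                    aa = q[keep],
                    conservation = col_score[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  attr(out, "msa_depth") <- length(msa)
  out
}

#' Score mutation candidates with a pluggable energy scorer
#'
#' The scorer contract: a deterministic R function
#' `function(structure, mutation)` returning one finite numeric, the
#' predicted change in Cas-PAM interaction energy for a single substitution
#' written as `"T291N"`. Negative values indicate a more favourable
#' interaction with the PAM. A scorer failure on one candidate leaves that
#' candidate unscored (`ddg = NA`, with a warning) and the run continues.
#'
#' @param structure Structure handle passed through to the scorer.
#' @param candidates Candidate table (see
#'   [contact_mutation_candidates()]); input order is preserved.
#' @param scorer The scoring function.
#' @return `candidates` with a `ddg` column appended.
#' @export
score_candidates <- function(structure, candidates, scorer) {
  stopifnot(is.function(scorer))
  candidates$ddg <- vapply(candidates$mutation, function(m) {
    val <- tryCatch(scorer(structure, m), error = function(e) {
      warning("scorer failed for ", m, ": ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    if (length(val) != 1L || !is.numeric(val)) NA_real_ else as.numeric(val)
  }, numeric(1), USE.NAMES = FALSE)
  candidates
}

#' Iteratively rank candidates by repeated best-mutant extraction
#'
#' Mirrors design engines that only report the single best-scoring mutant
#' per run: every round the scorer is re-invoked on all remaining
#' candidates, the most favourable (most negative) one is extracted and
#' removed, and the pool is re-scored, until the pool is empty. For a
#' scorer whose values do not depend on the pool this reduces to a single
#' sort; for a pool-dependent scorer the extraction order follows the
#' per-round minima. Unscored candidates rank after scored ones. Ties break
#' by residue number, then alphabetically by proposed amino acid.
#'
#' @param candidates Candidate table with a `mutation` column.
#' @param scorer Scorer function (see [score_candidates()]).
#' @param structure Structure handle forwarded to the scorer.
#' @return Candidate rows in extraction order with `rank`, `round` and the
#'   `ddg` observed in the round of extraction.
#' @export
iterative_rank <- function(candidates, scorer, structure = NULL) {
  n <- nrow(candidates)
  if (!n) {
    candidates$ddg <- numeric(0)
    candidates$rank <- integer(0)
    candidates$round <- integer(0)
    return(candidates)
  }
  remaining <- candidates
  picked <- vector("list", n)
  for (round in seq_len(n)) {
    scored <- score_candidates(structure, remaining, scorer)
    o <- order(is.na(scored$ddg), scored$ddg, scored$resno,
               scored$proposed_aa)
    best <- o[1L]
    row <- scored[best, , drop = FALSE]
    row$rank <- round
    row$round <- round
    picked[[round]] <- row
    remaining <- remaining[-best, , drop = FALSE]
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Mock scorers for testing and demonstration
#'
#' `constant_scorer()` returns the same value for every mutation;
#' `table_scorer()` looks mutations up in a named vector, with a default
#' for absent keys. Both satisfy the scorer contract and are useful as
#' deterministic stand-ins when no physics-based engine is wired in.
#'
#' @param value Constant value returned.
#' @return A scorer `function(structure, mutation)`.
#' @export
constant_scorer <- function(value = 0) {
  force(value)
  function(structure, mutation) value
}

#' @rdname constant_scorer
#' @param table Named numeric vector keyed by mutation strings ("T291N").
#' @param default Value for mutations absent from `table`.
#' @export
table_scorer <- function(table, default = 0) {
  force(table); force(default)
  function(structure, mutation) {
    if (mutation %in% names(table)) unname(table[[mutation]]) else default
  }
}

#' Command-line scorer adapter
#'
#' Wraps an external per-mutation design executable as a scorer: the
#' command is run once per mutation with the structure path and mutation
#' string substituted into the argument template, and its standard output
#' must be a single number. Deterministic as long as the executable is.
#'
#' @param command Executable name or path.
#' @param args_template Character vector of arguments; occurrences of
#'   `{structure}` and `{mutation}` are substituted.
#' @return A scorer `function(structure, mutation)` where `structure` is a
#'   file path.
#' @export
subprocess_scorer <- function(command, args_template) {
  force(command); force(args_template)
  function(structure, mutation) {
    args <- gsub("{mutation}", mutation,
                 gsub("{structure}", structure, args_template,
                      fixed = TRUE), fixed = TRUE)
    out <- system2(command, args, stdout = TRUE)
    val <- suppressWarnings(as.numeric(trimws(out[length(out)])))
    if (is.na(val)) stop("scorer subprocess returned non-numeric output")
    val
  }
}

#' Export one structure per proposed mutation
#'
#' Writes a PDB file per candidate with the target residue renamed to the
#' proposed amino acid. Side chains are left as found: rebuilding them is
#' the responsibility of the downstream design engine.
#'
#' @param structure A `cas_structure`.
#' @param candidates Candidate table (`resno`, `proposed_aa`, `mutation`).
#' @param chain Protein chain to mutate.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths written.
#' @export
export_mutant_structures <- function(structure, candidates, chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at <- structure$atoms
  vapply(seq_len(nrow(candidates)), function(i) {
    mut <- at
    sel <- mut$chain == chain & mut$resno == candidates$resno[i]
    if (!any(sel)) stop("residue ", candidates$resno[i],
                        " not found on chain ", chain)
    mut$resid[sel] <- .AA_1TO3[[candidates$proposed_aa[i]]]
    path <- file.path(dir, paste0(candidates$mutation[i], ".pdb"))
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(mut[, c("x", "y", "z")]))),
                     resno = mut$resno, resid = mut$resid,
                     eleno = seq_len(nrow(mut)), elety = mut$elety,
                     chain = mut$chain, o = mut$occupancy,
                     elesy = mut$element)
    path
  }, character(1))
}

#' Write the candidate/score table as TSV
#'
#' @param candidates Scored candidate table.
#' @param destination Output path; conservation and ddg fixed to three
#'   decimals.
#' @export
write_candidates <- function(candidates, destination) {
  df <- as.data.frame(candidates)
  if ("conservation" %in% names(df))
    df$conservation <- ifelse(is.na(df$conservation), "NA",
                              sprintf("%.3f", df$conservation))
  if ("ddg" %in% names(df))
    df$ddg <- ifelse(is.na(df$ddg), "NA", sprintf("%.3f", df$ddg))
  utils::write.table(df, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(destination)
}
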