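# Synthetic fixtures: random references with planted SNVs, and toy
# protein-DNA complexes with atoms at controlled distances from designated
# PAM nucleotides. Both are seeded and fully reproducible.

#' Generate a synthetic reference and variant set
#'
#' Draws a uniform-random A/C/G/T reference and places `n` single-base
#' substitutions at well-separated positions. Optional context rules plant
#' a fixed wild-type motif at each site and force a specific substitution,
#' giving variants with a known ground-truth PAM creation (e.g. planting
#' wild-type `"TA"` and mutating the A to G creates a `"TG"` site private
#' to the mutant allele).
#'
#' @param n Number of variants (>= 1).
#' @param seed Integer seed; fixes the whole stream.
#' @param context_rules Optional list with `wt_context` (short A/C/G/T
#'   string), `mut_index` (1-based position inside the context to mutate)
#'   and `alt` (mutant base, different from the context base).
#' @param spacing Bases between consecutive variant sites (default 30,
#'   enough to keep any PAM window private to one site).
#' @return List: `reference` (named character vector, one contig `synth1`),
#'   `variants` (list of `snv_variant`).
#' @export
generate_fixture_variants <- function(n, seed, context_rules = NULL,
                                      spacing = 30L) {
  stopifnot(n >= 1)
  rng <- .seeded_rng(seed)
  len <- as.integer(n) * spacing + 2L * spacing
  seq_chars <- sample(.DNA_BASES, len, replace = TRUE)
  positions <- spacing + seq_len(n) * spacing

  variants <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- positions[i]
    if (!is.null(context_rules)) {
      ctx <- strsplit(toupper(context_rules$wt_context), "")[[1]]
      mi <- context_rules$mut_index
      stopifnot(mi >= 1, mi <= length(ctx), ctx %in% .DNA_BASES)
      from <- pos - mi + 1L
      seq_chars[from:(from + length(ctx) - 1L)] <- ctx
      ref_base <- ctx[mi]
      alt_base <- toupper(context_rules$alt)
      stopifnot(alt_base %in% .DNA_BASES, alt_base != ref_base)
    } else {
      ref_base <- seq_chars[pos]
      alt_base <- sample(setdiff(.DNA_BASES, ref_base), 1L)
    }
    variants[[i]] <- variant("synth1", pos, ref_base, alt_base)
  }
  rng()  # restore caller RNG state
  list(reference = c(synth1 = paste(seq_chars, collapse = "")),
       variants = variants)
}

# set.seed locally, return a restorer
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' Build a toy Cas-DNA complex with controlled contact geometry
#'
#' Constructs a `cas_structure` in code: a short DNA chain whose designated
#' PAM nucleotides sit near the origin, plus protein residues placed so
#' their closest heavy atom lies at an exact chosen distance from the
#' nearest PAM atom. Used to test contact detection with known ground
#' truth, and to build the packaged synthetic reconstruction of the
#' Cas12c2 PAM-recognition site.
#'
#' @param residues data.frame with columns `resno`, `resid` (three-letter),
#'   `distance` (angstroms from the nearest PAM atom to the residue's
#'   closest heavy atom), and optionally `chain` (default "A").
#' @param pam_resno Residue numbers assigned to the PAM nucleotides
#'   (default 7:8, a TG dinucleotide).
#' @param pam_resid Residue names for the PAM nucleotides (default
#'   c("DT","DG")).
#' @param dna_chain DNA chain id (default "D").
#' @return A `cas_structure`.
#' @export
synthetic_pam_complex <- function(residues, pam_resno = c(7L, 8L),
                                  pam_resid = c("DT", "DG"),
                                  dna_chain = "D") {
  stopifnot(length(pam_resno) == length(pam_resid))
  atoms <- list()
  add <- function(chain, resno, resid, elety, element, x, y, z,
                  occupancy = 1, alt = "") {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = resid,
      elety = elety, element = element, x = x, y = y, z = z,
      occupancy = occupancy, alt = alt, stringsAsFactors = FALSE)
  }

  # DNA: PAM nucleotides stacked along +x near the origin, one flanking
  # nucleotide on each side. Three heavy atoms per nucleotide.
  n_pam <- length(pam_resno)
  flank <- c(min(pam_resno) - 1L, max(pam_resno) + 1L)
  dna_resno <- c(flank[1], pam_resno, flank[2])
  dna_resid <- c("DA", pam_resid, "DC")
  for (k in seq_along(dna_resno)) {
    x0 <- (k - 2) * 4.0  # PAM residues near x = 0 and x = 4
    add(dna_chain, dna_resno[k], dna_resid[k], "P", "P", x0, 0, -2.5)
    add(dna_chain, dna_resno[k], dna_resid[k], "C1'", "C", x0, 0, -1.0)
    add(dna_chain, dna_resno[k], dna_resid[k], "N1", "N", x0, 0, 0)
  }
  pam_anchor <- function(i) c((i - 1) * 4.0, 0, 0)  # N1 of i-th PAM base

  # protein residues: backbone placed 3 A beyond the contact atom so the
  # stated distance is the residue's minimum distance
  if (is.null(residues$chain)) residues$chain <- "A"
  for (i in seq_len(nrow(residues))) {
    anchor <- pam_anchor(1L + (i - 1L) %% length(pam_resno))
    # spread residues on distinct rays in the y>0 half space
    theta <- pi * (0.25 + 0.5 * (i - 1) / max(1, nrow(residues) - 1))
    dirv <- c(cos(theta) * 0.3, sin(theta), 0.4)
    dirv <- dirv / sqrt(sum(dirv^2))
    d <- residues$distance[i]
    tip <- anchor + d * dirv
    ca <- anchor + (d + 3.0) * dirv
    n <- anchor + (d + 4.2) * dirv
    add(residues$chain[i], residues$resno[i], residues$resid[i],
        "N", "N", n[1], n[2], n[3])
    add(residues$chain[i], residues$resno[i], residues$resid[i],
        "CA", "C", ca[1], ca[2], ca[3])
    add(residues$chain[i], residues$resno[i], residues$resid[i],
        "CB", "C", tip[1], tip[2], tip[3])
  }

  at <- do.call(rbind, atoms)
  rownames(at) <- NULL
  chain_type <- vapply(split(at$resid, at$chain), function(res) {
    if (mean(unique(res) %in% .NUCLEIC_RESID) >= 0.5) "nucleic"
    else "protein"
  }, character(1))
  structure(list(atoms = at, chain_type = chain_type,
                 source = "synthetic"), class = "cas_structure")
}

#' Write a `cas_structure` as a PDB file
#'
#' @param structure A `cas_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = at$occupancy,
                   elesy = at$element)
  invisible(path)
}

#' Synthetic reconstruction of the Cas12c2 PAM-recognition site
#'
#' The deposited Cas12c2-DNA complex (PDB 7V94) annotates five protein
#' residues — R137, N289, T291, S294, R351 — in contact (4.0-angstrom
#' threshold) with the two PAM nucleotides. This generator rebuilds that
#' *geometry class* synthetically: the five residues are placed with
#' closest heavy atoms between 2.8 and 3.8 angstroms of the PAM
#' dinucleotide and four decoy residues beyond 4.0. It is a synthetic
#' stand-in with the correct contact topology, not the deposited
#' coordinates; use the real PDB entry for any structural conclusion.
#'
#' @return A `cas_structure`.
#' @export
cas12c2_pam_site_synthetic <- function() {
  synthetic_pam_complex(data.frame(
    resno = c(137L, 289L, 291L, 294L, 351L, 140L, 300L, 352L, 410L),
    resid = c("ARG", "ASN", "THR", "SER", "ARG",
              "LYS", "GLU", "GLY", "TYR"),
    distance = c(2.9, 3.1, 2.8, 3.5, 3.8, 4.6, 5.5, 7.2, 9.0),
    stringsAsFactors = FALSE))
}
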