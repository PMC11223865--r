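# Residue names classified as nucleic for chain typing and PAM selection.
.NUCLEIC_RESID <- c("DA", "DC", "DG", "DT", "DU", "DI",
                    "A", "C", "G", "U", "I")

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

# Guess the element when the file lacks an element column: strip digits and
# leading digit/quote noise from the atom name, take the first letter.
.guess_element <- function(elety) {
  x <- gsub("[0-9'\"*]", "", toupper(elety))
  substr(x, 1L, 1L)
}

#' Load a protein-DNA complex structure
#'
#' Reads PDB or mmCIF coordinates (via bio3d), resolves alternate locations
#' (highest occupancy wins, ties to altloc 'A'/blank) and classifies each
#' chain as protein or nucleic. Hydrogens are retained in the atom table
#' but excluded from contact arithmetic by default.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return Object of class `cas_structure`: list with `atoms` (data.frame:
#'   chain, resno, insert, resid, elety, element, x, y, z, occupancy, alt)
#'   and `chain_type` (named character, `"protein"`/`"nucleic"`/`"other"`).
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                                 verbose = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("cannot parse structure file '", path,
                             "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("structure file '", path, "' contains no atom coordinates")
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = toupper(a$resid),
    elety = a$elety,
    element = if (!is.null(a$elesy) && any(nzchar(a$elesy) & !is.na(a$elesy)))
                toupper(ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                               .guess_element(a$elety), a$elesy))
              else .guess_element(a$elety),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("structure '", path, "' has non-finite coordinates")

  # altloc resolution: one atom per (chain, resno, insert, elety)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               sep = "\r")
  if (anyDuplicated(key)) {
    pref <- order(key, -atoms$occupancy,
                  atoms$alt != "" & atoms$alt != "A", atoms$alt)
    atoms <- atoms[pref, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$elety, sep = "\r")), ,
                   drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  chain_type <- vapply(split(atoms$resid, atoms$chain), function(res) {
    res <- unique(res)
    if (mean(res %in% .NUCLEIC_RESID) >= 0.5) "nucleic"
    else if (mean(res %in% .AA3) >= 0.5) "protein"
    else "other"
  }, character(1))

  structure(list(atoms = atoms, chain_type = chain_type, source = path),
            class = "cas_structure")
}

#' @export
print.cas_structure <- function(x, ...) {
  cat(sprintf("<cas_structure> %d atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(x$chain_type),
              paste(sprintf("%s(%s)", names(x$chain_type), x$chain_type),
                    collapse = ", ")))
  invisible(x)
}

#' Identify PAM-contacting protein residues
#'
#' Returns every protein residue with at least one heavy atom within
#' `threshold` angstroms of any heavy atom of the designated PAM
#' nucleotides. Distance is the minimum Euclidean atom-atom distance;
#' hydrogens/deuteriums, waters and hetero groups outside the selection are
#' ignored. The PAM nucleotides are user-designated by chain and residue
#' number: which bases constitute the PAM is an annotation of the complex,
#' not derivable from coordinates alone.
#'
#' @param structure A `cas_structure`.
#' @param pam_chain Chain identifier carrying the PAM nucleotides.
#' @param pam_resno Integer vector of PAM residue numbers on that chain.
#' @param threshold Contact cutoff in angstroms (default 4.0).
#' @return data.frame of class `pam_contacts`, sorted by residue number:
#'   `chain`, `resno`, `resid`, `min_distance`, `protein_atom`, `pam_atom`,
#'   `pam_resno`.
#' @export
find_pam_contacts <- function(structure, pam_chain, pam_resno,
                              threshold = 4.0) {
  stopifnot(inherits(structure, "cas_structure"), threshold > 0)
  at <- structure$atoms
  heavy <- !(at$element %in% c("H", "D"))

  pam_sel <- at$chain == pam_chain & at$resno %in% pam_resno & heavy
  found <- unique(at$resno[at$chain == pam_chain & at$resno %in% pam_resno])
  missing <- setdiff(pam_resno, found)
  if (length(missing))
    stop("PAM selection refers to residue(s) absent from chain ",
         pam_chain, ": ", paste(missing, collapse = ", "))
  bad <- unique(at$resid[pam_sel][!at$resid[pam_sel] %in% .NUCLEIC_RESID])
  if (length(bad))
    stop("PAM selection includes non-nucleic residue(s): ",
         paste(bad, collapse = ", "))
  pam <- at[pam_sel, , drop = FALSE]

  prot_chains <- names(structure$chain_type)[structure$chain_type ==
                                               "protein"]
  prot <- at[at$chain %in% prot_chains & heavy & at$resid %in% .AA3, ,
             drop = FALSE]
  if (!nrow(prot) || !nrow(pam)) return(.empty_contacts())

  # coarse bounding-box prefilter before the exact all-pairs scan
  keep <- prot$x >= min(pam$x) - threshold & prot$x <= max(pam$x) + threshold &
          prot$y >= min(pam$y) - threshold & prot$y <= max(pam$y) + threshold &
          prot$z >= min(pam$z) - threshold & prot$z <= max(pam$z) + threshold
  prot <- prot[keep, , drop = FALSE]
  if (!nrow(prot)) return(.empty_contacts())

  d2 <- outer(prot$x, pam$x, "-")^2 + outer(prot$y, pam$y, "-")^2 +
        outer(prot$z, pam$z, "-")^2
  res_key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  rows <- lapply(split(seq_len(nrow(prot)), res_key), function(idx) {
    sub <- d2[idx, , drop = FALSE]
    m <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    dmin <- sqrt(sub[m[1], m[2]])
    if (dmin > threshold) return(NULL)
    i <- idx[m[1]]; j <- m[2]
    data.frame(chain = prot$chain[i], resno = prot$resno[i],
               resid = prot$resid[i], min_distance = dmin,
               protein_atom = prot$elety[i], pam_atom = pam$elety[j],
               pam_resno = pam$resno[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(.empty_contacts())))
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pam_contacts", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

.empty_contacts <- function() {
  data.frame(chain = character(0), resno = integer(0), resid = character(0),
             min_distance = numeric(0), protein_atom = character(0),
             pam_atom = character(0), pam_resno = integer(0),
             stringsAsFactors = FALSE)
}

#' Write a contact table as TSV
#'
#' @param contacts A `pam_contacts` data.frame.
#' @param destination Output path; distances are fixed to two decimals.
#' @export
write_contacts <- function(contacts, destination) {
  df <- as.data.frame(contacts)
  df$min_distance <- sprintf("%.2f", df$min_distance)
  utils::write.table(df, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(destination)
}
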