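#' Construct a single-nucleotide variant
#'
#' A variant is a one-base substitution anchored on a named reference
#' sequence. Coordinates are 1-based in all user-facing I/O (VCF, HGVS);
#' conversions to internal offsets happen inside the finder.
#'
#' @param sequence_id Reference sequence name (e.g. an accession or contig).
#' @param position 1-based position on the reference.
#' @param ref,alt Unambiguous bases (A/C/G/T), `ref != alt`. Indels and
#'   multi-nucleotide variants are rejected: allele-selective PAM creation
#'   is defined for single-base substitutions.
#' @return Object of class `snv_variant` (a named list).
#' @export
variant <- function(sequence_id, position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(position) != 1L || is.na(position) || position < 1 ||
      position != as.integer(position))
    stop("position must be a single positive integer (1-based)")
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("only single-nucleotide substitutions are supported ",
         "(got ref='", ref, "', alt='", alt, "')")
  if (!ref %in% .DNA_BASES || !alt %in% .DNA_BASES)
    stop("ref and alt must be unambiguous bases (A/C/G/T)")
  if (ref == alt) stop("ref and alt are identical ('", ref, "')")
  structure(list(sequence_id = as.character(sequence_id),
                 position = as.integer(position), ref = ref, alt = alt),
            class = "snv_variant")
}

#' @export
print.snv_variant <- function(x, ...) {
  cat(format_hgvs_g(x), "\n")
  invisible(x)
}

#' Parse an HGVS genomic substitution string
#'
#' Accepts `[accession:]g.<pos><ref>><alt>`, whitespace-tolerant, e.g.
#' `"NG_008624.1:g.8631A>G"` or `"g.1A>C"`. Non-substitution HGVS
#' (del/ins/dup/delins) is rejected as unsupported.
#'
#' @param text HGVS-g string.
#' @param default_sequence_id Sequence name to use when the accession part
#'   is absent.
#' @return An `snv_variant`.
#' @examples
#' parse_hgvs_g("NG_008624.1:g.8631A>G")
#' @export
parse_hgvs_g <- function(text, default_sequence_id = "ref") {
  raw <- text
  text <- gsub("[[:space:]]+", "", text)
  if (grepl("(del|ins|dup|inv)", text, ignore.case = TRUE))
    stop("unsupported variant type (only g. substitutions are accepted): ",
         raw)
  m <- regexec("^(?:([^:]+):)?g\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) == 0L)
    stop("cannot parse HGVS-g substitution: '", raw, "'")
  seq_id <- if (nzchar(parts[2])) parts[2] else default_sequence_id
  variant(seq_id, as.integer(parts[3]), parts[4], parts[5])
}

#' Format a variant as a canonical HGVS-g string
#'
#' @param v An `snv_variant`.
#' @return String of the form `"<seq>:g.<pos><ref>><alt>"`.
#' @export
format_hgvs_g <- function(v) {
  sprintf("%s:g.%d%s>%s", v$sequence_id, v$position, v$ref, v$alt)
}

#' Read single-nucleotide variants from a minimal VCF
#'
#' Reads the CHROM, POS, REF and ALT columns of VCF-like text; `#` header
#' lines are tolerated and a full column header is not required. Only
#' biallelic single-base substitutions are kept: rows with multi-base REF
#' or ALT, multiple ALT alleles, symbolic alleles or REF==ALT are skipped
#' and counted.
#'
#' @param path Path to the VCF(-like) file.
#' @param verbose Report the number of rows kept and skipped.
#' @return List of `snv_variant`; attribute `skipped` carries the count of
#'   non-SNV rows dropped.
#' @export
read_vcf_snvs <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  out <- list(); skipped <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (length(f) < 5L) { skipped <- skipped + 1L; next }
    chrom <- f[1]; pos <- suppressWarnings(as.integer(f[2]))
    ref <- toupper(f[4]); alt <- toupper(f[5])
    ok <- !is.na(pos) && nchar(ref) == 1L && nchar(alt) == 1L &&
      ref %in% .DNA_BASES && alt %in% .DNA_BASES && ref != alt
    if (!ok) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- variant(chrom, pos, ref, alt)
  }
  if (verbose)
    message(length(out), " SNV(s) read, ", skipped, " row(s) skipped")
  attr(out, "skipped") <- skipped
  out
}

#' Read a reference FASTA into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequences are
#' uppercased and names truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

# Resolve `reference` (named character vector, single string, or
# DNAStringSet) + a variant to one uppercase sequence string.
.resolve_reference <- function(reference, v) {
  if (methods::is(reference, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(reference))
    reference <- stats::setNames(toupper(as.character(reference)), nm)
  }
  if (is.character(reference) && is.null(names(reference)) &&
      length(reference) == 1L)
    return(toupper(reference))
  i <- match(v$sequence_id, names(reference))
  if (is.na(i)) {
    if (length(reference) == 1L) return(toupper(reference[[1]]))
    stop("sequence '", v$sequence_id, "' not found in reference")
  }
  toupper(reference[[i]])
}
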