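# Per-symbol specificity weights used by the selectivity score. A fully
# specific base counts 1.00, a 3-base degeneracy 0.33, a 2-base degeneracy
# 0.50, and N 0.25: longer and more specific patterns score higher.
.PAM_WEIGHTS <- c(
  A = 1.00, C = 1.00, G = 1.00, T = 1.00,
  M = 0.50, R = 0.50, W = 0.50, S = 0.50, Y = 0.50, K = 0.50,
  V = 0.33, H = 0.33, D = 0.33, B = 0.33,
  N = 0.25
)

#' Per-symbol PAM specificity weights
#'
#' @return Named numeric vector over the 15 IUPAC nucleotide codes:
#'   N = 0.25; V, H, D, B = 0.33; M, R, W, S, Y, K = 0.50;
#'   A, C, G, T = 1.00.
#' @export
pam_weights <- function() .PAM_WEIGHTS

#' Selectivity score of a PAM pattern
#'
#' Each pattern symbol contributes its specificity weight and the score is
#' the sum over symbols, so the score grows with both pattern length and
#' base specificity. It is used to order candidate Cas enzymes: a higher
#' score means the enzyme's PAM requirement pins down more sequence, which
#' favours allele-selective targeting.
#'
#' @param pattern PAM pattern string (IUPAC alphabet), or a character vector
#'   of patterns.
#' @param weight_table Named numeric vector of per-symbol weights; defaults
#'   to [pam_weights()].
#' @return Numeric vector of scores, one per pattern.
#' @examples
#' selectivity_score("NGG")     # 2.25
#' selectivity_score("NNGRRT")  # 3.50
#' @export
selectivity_score <- function(pattern, weight_table = pam_weights()) {
  vapply(pattern, function(p) {
    p <- check_pam_pattern(p)
    syms <- strsplit(p, "", fixed = TRUE)[[1]]
    if (!all(syms %in% names(weight_table)))
      stop("weight table does not cover symbol(s): ",
           paste(setdiff(syms, names(weight_table)), collapse = ", "))
    sum(weight_table[syms])
  }, numeric(1), USE.NAMES = FALSE)
}

.split_multi <- function(x) {
  if (is.na(x) || x %in% c("", "-")) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

.registry_columns <- c("name", "organism", "source", "variant", "uniprot_id",
                       "subtype", "primary_pattern", "less_preferred",
                       "structure_ids")

#' Load a Cas/PAM registry
#'
#' With no argument, loads the registry packaged with snvpam: 39 class-2
#' Cas enzymes (22 natural, 17 engineered variants) with their IUPAC PAM
#' patterns, less-preferred alternate patterns, and 39 PDB structure
#' accessions, transcribed from the published enzyme inventory. A custom
#' registry can be supplied as a tab-separated file in the same dialect
#' (columns: name, organism, source, variant, uniprot_id, subtype,
#' primary_pattern, less_preferred, structure_ids; multi-valued cells
#' joined by ';', empty cells '-').
#'
#' @param source Optional path to a registry TSV; `NULL` loads the packaged
#'   default.
#' @return An object of class `cas_registry`: a list with `enzymes`
#'   (data.frame, one row per enzyme) and `weight_table`.
#' @examples
#' reg <- load_registry()
#' nrow(reg$enzymes)                       # 39
#' registry_enzyme(reg, "Cas12c2")$primary_pattern  # "TN"
#' @export
load_registry <- function(source = NULL) {
  path <- if (is.null(source)) {
    system.file("extdata", "cas_registry.tsv", package = "snvpam",
                mustWork = TRUE)
  } else source
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          strip.white = TRUE)
  missing_cols <- setdiff(.registry_columns, names(df))
  if (length(missing_cols))
    stop("malformed registry file '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- df[, .registry_columns]
  df$user_supplied <- FALSE
  reg <- structure(list(enzymes = df, weight_table = pam_weights()),
                   class = "cas_registry")
  validate_registry(reg, path = path)
  reg
}

#' @rdname load_registry
#' @param registry A `cas_registry` object.
#' @param path Internal; file name used in error messages.
#' @export
validate_registry <- function(registry, path = "<registry>") {
  df <- registry$enzymes
  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    stop("duplicate enzyme name(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    pats <- c(df$primary_pattern[i], .split_multi(df$less_preferred[i]))
    for (p in pats) {
      ok <- tryCatch({check_pam_pattern(p); TRUE}, error = function(e) e)
      if (!isTRUE(ok))
        stop("registry ", path, ", line ", i + 1L, ", enzyme '", df$name[i],
             "', field 'pattern': ", conditionMessage(ok))
    }
    if (!df$source[i] %in% c("natural", "engineered"))
      stop("registry ", path, ", line ", i + 1L,
           ", field 'source': must be 'natural' or 'engineered', got '",
           df$source[i], "'")
  }
  invisible(registry)
}

#' Retrieve one registry entry by enzyme name
#'
#' @param registry A `cas_registry`.
#' @param name Enzyme name.
#' @return One-row data.frame for the enzyme.
#' @export
registry_enzyme <- function(registry, name) {
  i <- match(name, registry$enzymes$name)
  if (is.na(i)) stop("enzyme not in registry: ", name)
  registry$enzymes[i, , drop = FALSE]
}

#' Add a user-supplied Cas enzyme to a registry
#'
#' Packaged entries are left untouched; the new entry is flagged
#' user-supplied.
#'
#' @param registry A `cas_registry`.
#' @param name New enzyme name (must not collide with an existing entry).
#' @param pattern_string Primary PAM pattern (IUPAC alphabet).
#' @param structure_id Optional PDB accession (or vector of accessions).
#' @param organism,subtype Optional annotations.
#' @param source `"natural"` or `"engineered"`.
#' @return The extended `cas_registry`.
#' @examples
#' reg <- add_custom_cas(load_registry(), "MyCas", "TTN")
#' @export
add_custom_cas <- function(registry, name, pattern_string,
                           structure_id = NULL, organism = "user",
                           subtype = "-", source = "natural") {
  stopifnot(inherits(registry, "cas_registry"))
  if (name %in% registry$enzymes$name)
    stop("duplicate enzyme name: '", name, "' is already in the registry")
  pattern_string <- check_pam_pattern(pattern_string)
  row <- data.frame(
    name = name, organism = organism, source = source, variant = "-",
    uniprot_id = "-", subtype = subtype, primary_pattern = pattern_string,
    less_preferred = "-",
    structure_ids = if (is.null(structure_id)) "-"
                    else paste(structure_id, collapse = ";"),
    user_supplied = TRUE, stringsAsFactors = FALSE
  )
  registry$enzymes <- rbind(registry$enzymes, row)
  validate_registry(registry)
  registry
}

#' Write a registry to the packaged TSV dialect
#'
#' `write_cas_registry()` followed by `load_registry()` reproduces the
#' registry field by field (the user-supplied flag is not serialised).
#'
#' @param registry A `cas_registry`.
#' @param path Output file path.
#' @export
write_cas_registry <- function(registry, path) {
  utils::write.table(registry$enzymes[, .registry_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' All candidate patterns of a registry, one row per (enzyme, pattern)
#'
#' @param registry A `cas_registry`.
#' @param include_less_preferred Also emit the less-preferred alternate
#'   patterns (flagged).
#' @return data.frame with columns enzyme, pattern, less_preferred, score.
#' @export
registry_patterns <- function(registry, include_less_preferred = FALSE) {
  df <- registry$enzymes
  out <- data.frame(enzyme = df$name, pattern = df$primary_pattern,
                    less_preferred = FALSE, stringsAsFactors = FALSE)
  if (include_less_preferred) {
    for (i in seq_len(nrow(df))) {
      lp <- .split_multi(df$less_preferred[i])
      if (length(lp))
        out <- rbind(out, data.frame(enzyme = df$name[i], pattern = lp,
                                     less_preferred = TRUE,
                                     stringsAsFactors = FALSE))
    }
  }
  out$score <- selectivity_score(out$pattern, registry$weight_table)
  out
}

#' @export
print.cas_registry <- function(x, ...) {
  df <- x$enzymes
  cat(sprintf("<cas_registry> %d enzymes (%d natural, %d engineered)\n",
              nrow(df), sum(df$source == "natural"),
              sum(df$source == "engineered")))
  n_struct <- sum(lengths(lapply(df$structure_ids, .split_multi)))
  cat(sprintf("  structure accessions: %d; user-supplied entries: %d\n",
              n_struct, sum(df$user_supplied)))
  invisible(x)
}

#' Summary counts of a registry
#'
#' @param registry A `cas_registry`.
#' @return Named list: n_enzymes, n_natural, n_engineered, n_structures.
#' @export
registry_counts <- function(registry) {
  df <- registry$enzymes
  list(n_enzymes = nrow(df),
       n_natural = sum(df$source == "natural"),
       n_engineered = sum(df$source == "engineered"),
       n_structures = sum(lengths(lapply(df$structure_ids, .split_multi))))
}
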