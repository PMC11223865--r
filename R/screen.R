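#' Batch screen a variant set for SNV-derived PAMs
#'
#' Runs the finder over every variant and aggregates two summaries: a 4x4
#' targetability matrix (per ref->alt substitution class, the percentage
#' of variants with at least one SNV-derived PAM) and the per-enzyme
#' coverage share of all qualification events. The counting unit for
#' coverage is one (variant, enzyme, pattern) qualification event: several
#' placements of the same pattern at one variant collapse to one event.
#'
#' @param variants List of `snv_variant`.
#' @param reference Reference sequence(s) (string, named vector or
#'   `DNAStringSet`).
#' @param registry A `cas_registry`.
#' @param include_less_preferred Count events from less-preferred patterns
#'   too (excluded by default).
#' @return List of class `pam_screen`:
#'   \describe{
#'     \item{targetability}{data.frame `ref`, `alt`, `n`, `targetable`,
#'       `pct` over the 12 substitution classes.}
#'     \item{coverage}{data.frame `enzyme`, `events`, `share_pct`,
#'       `pattern_length`, `source`, sorted by share.}
#'     \item{n_screened, n_targetable, n_skipped}{totals; skipped variants
#'       are those that could not be resolved on the reference.}
#'   }
#' @export
screen_variants <- function(variants, reference, registry = load_registry(),
                            include_less_preferred = FALSE) {
  classes <- expand.grid(ref = .DNA_BASES, alt = .DNA_BASES,
                         stringsAsFactors = FALSE)
  classes <- classes[classes$ref != classes$alt, ]
  classes <- classes[order(classes$ref, classes$alt), ]
  rownames(classes) <- NULL
  classes$n <- 0L
  classes$targetable <- 0L

  events <- list()
  n_skipped <- 0L
  n_targetable <- 0L
  for (v in variants) {
    hits <- tryCatch(
      find_snv_derived_pams(reference, v, registry,
                            include_less_preferred = include_less_preferred,
                            rank = FALSE),
      error = function(e) NULL)
    if (is.null(hits)) { n_skipped <- n_skipped + 1L; next }
    i <- which(classes$ref == v$ref & classes$alt == v$alt)
    classes$n[i] <- classes$n[i] + 1L
    if (nrow(hits)) {
      n_targetable <- n_targetable + 1L
      classes$targetable[i] <- classes$targetable[i] + 1L
      ev <- unique(hits[, c("enzyme", "pattern")])
      events[[length(events) + 1L]] <- ev
    }
  }
  classes$pct <- ifelse(classes$n > 0, 100 * classes$targetable / classes$n,
                        NA_real_)

  ev <- do.call(rbind, c(events, list(data.frame(enzyme = character(0),
                                                 pattern = character(0)))))
  enz <- registry$enzymes
  cov <- data.frame(enzyme = enz$name,
                    events = vapply(enz$name, function(e)
                      sum(ev$enzyme == e), integer(1)),
                    pattern_length = nchar(enz$primary_pattern),
                    source = enz$source, stringsAsFactors = FALSE)
  total_events <- sum(cov$events)
  cov$share_pct <- if (total_events > 0) 100 * cov$events / total_events
                   else 0
  cov <- cov[order(-cov$events, cov$enzyme), ,
             drop = FALSE]
  rownames(cov) <- NULL

  structure(list(targetability = classes, coverage = cov,
                 n_screened = length(variants) - n_skipped,
                 n_targetable = n_targetable, n_skipped = n_skipped),
            class = "pam_screen")
}

#' @export
print.pam_screen <- function(x, ...) {
  cat(sprintf("<pam_screen> %d variant(s) screened (%d skipped): %d (%.1f%%) targetable\n",
              x$n_screened, x$n_skipped, x$n_targetable,
              if (x$n_screened) 100 * x$n_targetable / x$n_screened else 0))
  top <- utils::head(x$coverage[x$coverage$events > 0, ], 5)
  if (nrow(top)) {
    cat("  top coverage:",
        paste(sprintf("%s (%.1f%%)", top$enzyme, top$share_pct),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Targetability matrix in wide 4x4 form
#'
#' @param screen A `pam_screen`.
#' @param value `"pct"` or `"targetable"` or `"n"`.
#' @return 4x4 matrix (rows = wild-type base, columns = mutant base),
#'   diagonal `NA`.
#' @export
targetability_matrix <- function(screen, value = c("pct", "targetable",
                                                   "n")) {
  value <- match.arg(value)
  t <- screen$targetability
  m <- matrix(NA_real_, 4, 4, dimnames = list(.DNA_BASES, .DNA_BASES))
  m[cbind(t$ref, t$alt)] <- t[[value]]
  m
}

#' Write screen summaries to TSV and JSON
#'
#' @param screen A `pam_screen`.
#' @param prefix Output path prefix; writes `<prefix>_targetability.tsv`,
#'   `<prefix>_coverage.tsv` and `<prefix>_summary.json`.
#' @return Character vector of the three paths.
#' @export
write_screen <- function(screen, prefix) {
  p1 <- paste0(prefix, "_targetability.tsv")
  p2 <- paste0(prefix, "_coverage.tsv")
  p3 <- paste0(prefix, "_summary.json")
  t <- screen$targetability
  t$pct <- ifelse(is.na(t$pct), "NA", sprintf("%.2f", t$pct))
  utils::write.table(t, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- screen$coverage
  cov$share_pct <- sprintf("%.2f", cov$share_pct)
  utils::write.table(cov, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_screened = screen$n_screened,
         n_targetable = screen$n_targetable,
         n_skipped = screen$n_skipped,
         pct_targetable = if (screen$n_screened)
           100 * screen$n_targetable / screen$n_screened else 0),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
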