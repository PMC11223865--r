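test_that("mutation-centred windows are built and clipped correctly", {
  v <- variant("ref", 5, "A", "G")
  w <- build_window("AACTACCAA", v, 2)
  expect_equal(w$wt_seq, "CTACC")
  expect_equal(w$mut_seq, "CTGCC")
  expect_equal(w$centre, 3L)

  # clipping at the 5' end: position 1, L = 2 -> 3 bases, never padded
  w2 <- build_window("AACTACCAA", variant("ref", 1, "A", "G"), 2)
  expect_equal(nchar(w2$wt_seq), 3L)
  expect_equal(w2$centre, 1L)
  # and at the 3' end
  w3 <- build_window("AACTACCAA", variant("ref", 9, "A", "T"), 3)
  expect_equal(w3$wt_seq, "CCAA")
  expect_equal(w3$centre, 4L)

  expect_error(build_window("AACTACCAA", variant("ref", 5, "C", "G"), 2),
               "reference mismatch.*5")
  expect_error(build_window("AAC", variant("ref", 9, "A", "T"), 2),
               "beyond end")
  # wt and mut differ at exactly the centre
  d <- which(strsplit(w$wt_seq, "")[[1]] != strsplit(w$mut_seq, "")[[1]])
  expect_equal(d, w$centre)
})

test_that("a TA>TG substitution creates a Cas12c1-targetable PAM", {
  # wild-type context ...CTACC...; A->G creates TG private to the mutant
  ref <- "AACTACCAA"
  v <- variant("ref", 5, "A", "G")
  hits <- find_snv_derived_pams(ref, v)
  tg <- hits[hits$enzyme == "Cas12c1", ]
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$pattern, "TG")
  expect_equal(tg$strand, "+")
  expect_equal(tg$offset, -1L)
  expect_equal(tg$matched_seq, "TG")
  expect_true(tg$discriminating)
  # Cas12c2's TN matches the wild-type TA dinucleotide: no selectivity
  expect_false("Cas12c2" %in% hits$enzyme)
})

test_that("a wild-type match anywhere in the window disqualifies a pattern", {
  # A->G inside CCAGC: NG would sit on the wild-type A.G dinucleotide
  ref <- "ACCAGCA"
  v <- variant("ref", 4, "A", "G")
  w <- build_window(ref, v, 2)
  expect_equal(w$wt_seq, "CCAGC")
  hits <- find_snv_derived_pams(ref, v)
  expect_false("SpCas9-NG" %in% hits$enzyme)

  # pattern absent from both alleles (either orientation): no hit
  reg1 <- small_registry("Cas12c1")
  h2 <- find_snv_derived_pams("AAAAAGAAA", variant("ref", 5, "A", "C"),
                              reg1)
  expect_equal(nrow(h2), 0L)
  # but both orientations count: an A->C before an A creates a
  # minus-strand TG (plus-strand CA) private to the mutant
  h3 <- find_snv_derived_pams("TTAAAAATT", variant("ref", 5, "A", "C"),
                              reg1)
  expect_equal(h3$strand, "-")
})

test_that("the * flag requires a fully specific symbol equal to the mutant base", {
  reg <- load_registry()
  # C->G: SpCas9's NGG places a specific G over the variant
  ref <- "TTTACGTTT"  # pos 5 C->G gives ..TAGGT..: NGG = AGG over the SNV
  v <- variant("ref", 5, "C", "G")
  hits <- find_snv_derived_pams(ref, v, reg)
  spc <- hits[hits$enzyme == "SpCas9", ]
  expect_equal(nrow(spc), 1L)
  expect_true(spc$discriminating)

  # same kind of mutation under a degenerate R: qualifies, flag stays off
  regR <- add_custom_cas(small_registry(character(0)), "RCas", "CCR")
  hitsR <- find_snv_derived_pams("TTTCCCTTT", variant("ref", 6, "C", "G"),
                                 regR)
  expect_equal(nrow(hitsR), 1L)
  expect_false(hitsR$discriminating)

  # an N over the variant admits the wild-type base too, so a pattern
  # aligning N there can never qualify; as a pure predicate the flag is off
  expect_false(classify_discrimination(
    list(pattern = "CCN", strand = "+", offset = -2L), v))

  # classify_discrimination recomputes the stored flag
  for (i in seq_len(nrow(hits))) {
    expect_equal(classify_discrimination(hits[i, ], v),
                 hits$discriminating[i])
  }
  expect_error(classify_discrimination(
    list(pattern = "TG", strand = "+", offset = 5L), v), "overlap")
})

test_that("hits are ordered by score, then * flag, then enzyme name", {
  ref <- "AACTACCAA"
  v <- variant("ref", 5, "A", "G")
  hits <- find_snv_derived_pams(ref, v)
  expect_true(all(diff(hits$score) <= 0))
  # SaCas9 (NNGRRT, 3.50) outranks Cas12c2 (TN, 1.25) whenever both hit
  reg <- small_registry(c("SaCas9", "Cas12c2"))
  expect_gt(registry_patterns(reg)$score[
    registry_patterns(reg)$enzyme == "SaCas9"], 3.49)
  # tie-break determinism: equal score and flag -> alphabetical enzymes
  regT <- add_custom_cas(add_custom_cas(small_registry(character(0)),
                                        "ZetaCas", "TG"), "AlphaCas", "TG")
  h <- find_snv_derived_pams(ref, v, regT)
  expect_equal(h$enzyme, c("AlphaCas", "ZetaCas"))
  # empty in, empty out
  expect_equal(nrow(rank_hits(h[0, ])), 0L)
})

test_that("production qualification agrees with IUPAC-expansion brute force", {
  set.seed(101)
  reg1 <- small_registry("Cas12c2")  # the TN sanity pattern
  for (i in 1:300) {
    p <- random_pattern(4)
    w <- random_window_pair(nchar(p))
    prod_mut <- pam_placements(p, w$mut)
    prod_wt <- pam_placements(p, w$wt)
    qual_prod <- nrow(prod_mut) > 0 && nrow(prod_wt) == 0
    expect_identical(qual_prod, bf_qualifies(p, w$wt, w$mut),
                     info = paste(p, w$wt, w$mut))
    # registry-wide sanity on the shortest pattern
    expect_identical(
      nrow(pam_placements("TN", w$mut)) > 0 &&
        nrow(pam_placements("TN", w$wt)) == 0,
      bf_qualifies("TN", w$wt, w$mut))
  }
})

test_that("no SNV-derived PAM exists when mutant equals wild-type", {
  set.seed(31)
  for (i in 1:100) {
    p <- random_pattern(4)
    w <- random_window_pair(nchar(p))
    expect_false(bf_qualifies(p, w$wt, w$wt))
  }
})

test_that("every emitted hit placement covers the variant position", {
  set.seed(77)
  reg <- load_registry()
  fx <- generate_fixture_variants(25, seed = 909)
  for (v in fx$variants) {
    hits <- find_snv_derived_pams(fx$reference, v, reg,
                                  include_less_preferred = TRUE)
    if (!nrow(hits)) next
    L <- nchar(hits$pattern)
    expect_true(all(hits$offset <= 0 & hits$offset + L - 1L >= 0))
  }
})

test_that("reverse-complementing the reference flips strands, not patterns", {
  set.seed(13)
  reg <- load_registry()
  for (i in 1:20) {
    fx <- generate_fixture_variants(1, seed = 5000 + i)
    ref <- fx$reference[[1]]
    v <- fx$variants[[1]]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ref)))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    v_rc <- variant("synth1", nchar(ref) - v$position + 1L,
                    comp[[v$ref]], comp[[v$alt]])
    h1 <- find_snv_derived_pams(c(synth1 = ref), v, reg)
    h2 <- find_snv_derived_pams(c(synth1 = rc), v_rc, reg)
    k1 <- unique(paste(h1$enzyme, h1$pattern))
    k2 <- unique(paste(h2$enzyme, h2$pattern))
    expect_setequal(k1, k2)
    if (nrow(h1)) {
      s1 <- sort(paste(h1$enzyme, h1$pattern, h1$strand))
      s2 <- sort(paste(h2$enzyme, h2$pattern,
                       ifelse(h2$strand == "+", "-", "+")))
      expect_identical(s1, s2)
    }
  }
})

test_that("strict promiscuity mode drops enzymes whose alternates cut wild-type", {
  # enzyme with primary TG qualifying, alternate TA matching wild-type
  reg <- small_registry(character(0))
  reg$enzymes <- rbind(reg$enzymes, data.frame(
    name = "PromCas", organism = "x", source = "natural", variant = "-",
    uniprot_id = "-", subtype = "-", primary_pattern = "TG",
    less_preferred = "TA", structure_ids = "-", user_supplied = TRUE))
  ref <- "AACTACCAA"; v <- variant("ref", 5, "A", "G")
  lax <- find_snv_derived_pams(ref, v, reg)
  strict <- find_snv_derived_pams(ref, v, reg, strict_promiscuity = TRUE)
  expect_true("PromCas" %in% lax$enzyme)
  expect_false("PromCas" %in% strict$enzyme)
})
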