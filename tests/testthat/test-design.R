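test_that("substitution matrix satisfies its structural invariants", {
  B <- blosum62()
  expect_true(isSymmetric(B))
  for (a in rownames(B)) {
    expect_gt(B[a, a], max(B[a, setdiff(colnames(B), a)]))
  }
})

test_that("candidate sets follow the substitution-score threshold", {
  # the Thr candidates at threshold 0 include Asn, the substitution that
  # converts the TN-reading pocket into a G-specific one
  expect_equal(candidate_mutations("T"), c("A", "N", "S", "V"))
  expect_equal(candidate_mutations("THR"), c("A", "N", "S", "V"))
  expect_equal(candidate_mutations("G", threshold = 1), character(0))
  expect_equal(candidate_mutations("W", threshold = 12), character(0))
  expect_error(candidate_mutations("X"), "unknown amino-acid")
  expect_error(candidate_mutations("B"), "unknown amino-acid")

  # monotone shrinkage as the threshold rises
  for (aa in rownames(blosum62())) {
    prev <- NULL
    for (thr in c(-4, -1, 0, 1, 2)) {
      cur <- candidate_mutations(aa, threshold = thr)
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
    expect_false(aa %in% candidate_mutations(aa, threshold = -100))
  }
})

test_that("contact tables expand into annotated candidate rows", {
  s <- cas12c2_pam_site_synthetic()
  ct <- find_pam_contacts(s, "D", 7:8, 4.0)
  cands <- contact_mutation_candidates(ct)
  t291 <- cands[cands$resno == 291L, ]
  expect_equal(t291$wt_aa[1], "T")
  expect_true("T291N" %in% t291$mutation)
  expect_true(all(cands$blosum_score >= 0))
  expect_true(all(cands$proposed_aa != cands$wt_aa))
})

test_that("conservation index honours its bounds and gap rules", {
  # identical sequences: every query column exactly 1
  msa <- c(q = "TRAV", s1 = "TRAV", s2 = "TRAV")
  prof <- conservation_index(msa, "q")
  expect_equal(prof$conservation, rep(1, 4))
  expect_equal(prof$resno, 1:4)
  expect_equal(attr(prof, "msa_depth"), 3L)

  # all gaps except the query: every pair touches a gap, score 0
  msa2 <- c(q = "TTTT", s1 = "----", s2 = "----")
  expect_equal(conservation_index(msa2, "q")$conservation, rep(0, 4))

  # query gap columns carry no entry; numbering stays ungapped
  msa3 <- c(q = "T-AV", s1 = "TRAV")
  prof3 <- conservation_index(msa3, "q")
  expect_equal(prof3$resno, 1:3)
  expect_equal(prof3$aa, c("T", "A", "V"))

  expect_error(conservation_index(c(q = "TR"), "q"), "at least 2")
  expect_error(conservation_index(c(q = "TR", s = "TRA"), "q"), "ragged")
  expect_error(conservation_index(c(a = "TR", b = "TR"), "q"), "not found")

  # bounds on random alignments
  set.seed(3)
  aas <- rownames(blosum62())
  for (i in 1:10) {
    n <- sample(2:6, 1); L <- sample(3:10, 1)
    m <- replicate(n, paste(sample(c(aas, "-"), L, replace = TRUE),
                            collapse = ""))
    names(m) <- c("q", paste0("s", seq_len(n - 1)))
    prof <- conservation_index(m, "q")
    expect_true(all(prof$conservation >= 0 & prof$conservation <= 1))
  }
})

test_that("conservation matches a hand-computed 3x4 alignment", {
  # q: T R A V / s1: T R A V / s2: T K A -  (BLOSUM62, min = -4)
  # col1 TTT: all pairs identical -> 1
  # col2 R/R/K: pairs (R,R)=1, (R,K) twice = (2+4)/(5+4) = 6/9
  # col3 AAA: 1
  # col4 V/V/-: (V,V)=1, two gap pairs = 0 -> mean 1/3
  msa <- c(q = "TRAV", s1 = "TRAV", s2 = "TKA-")
  prof <- conservation_index(msa, "q")
  expect_equal(prof$conservation,
               c(1, (1 + 6 / 9 + 6 / 9) / 3, 1, 1 / 3),
               tolerance = 1e-12)
})

test_that("candidate scoring isolates scorer failures", {
  cands <- data.frame(resno = c(291L, 294L), wt_aa = c("T", "S"),
                      proposed_aa = c("N", "A"), blosum_score = c(0L, 1L),
                      conservation = NA_real_,
                      mutation = c("T291N", "S294A"))
  z <- score_candidates(NULL, cands, constant_scorer(0))
  expect_equal(z$ddg, c(0, 0))
  z2 <- score_candidates(NULL, cands, table_scorer(c(T291N = -1)))
  expect_equal(z2$ddg, c(-1, 0))
  expect_equal(z2$mutation, cands$mutation)  # input order preserved

  angry <- function(structure, mutation) {
    if (mutation == "T291N") stop("boom")
    0.5
  }
  expect_warning(z3 <- score_candidates(NULL, cands, angry),
                 "scorer failed for T291N")
  expect_true(is.na(z3$ddg[1]))
  expect_equal(z3$ddg[2], 0.5)
})

test_that("iterative extraction equals sorting for pool-independent scorers", {
  cands <- data.frame(resno = c(1L, 2L, 3L), wt_aa = "T",
                      proposed_aa = c("A", "N", "S"),
                      blosum_score = 0L, conservation = NA_real_,
                      mutation = c("T1A", "T2N", "T3S"))
  r <- iterative_rank(cands, table_scorer(c(T1A = -2, T2N = -1, T3S = 0)))
  expect_equal(r$mutation, c("T1A", "T2N", "T3S"))
  expect_equal(r$rank, 1:3)
  expect_equal(r$ddg, c(-2, -1, 0))

  # property: random pool-independent scorers reduce to a single sort
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:7, 1)
    cd <- data.frame(resno = sample(100:400, n), wt_aa = "A",
                     proposed_aa = sample(LETTERS[1:20], n, replace = TRUE),
                     blosum_score = 0L, conservation = NA_real_)
    cd$mutation <- paste0(cd$wt_aa, cd$resno, cd$proposed_aa)
    tab <- stats::setNames(round(stats::rnorm(n), 3), cd$mutation)
    r <- iterative_rank(cd, table_scorer(tab))
    sorted <- cd[order(tab[cd$mutation], cd$resno, cd$proposed_aa), ]
    expect_equal(r$mutation, sorted$mutation)
  }

  # empty pool: empty result, no error
  r0 <- iterative_rank(cands[0, ], constant_scorer(0))
  expect_equal(nrow(r0), 0L)
})

test_that("pool-dependent scorers are ranked by per-round minima", {
  cands <- data.frame(resno = c(1L, 2L, 3L), wt_aa = "T",
                      proposed_aa = c("A", "N", "S"),
                      blosum_score = 0L, conservation = NA_real_,
                      mutation = c("A", "B", "C"))
  # hand-traced: round 1 scores A=-1 B=-2 C=-3 -> C out;
  # round 2 scores A=-5 B=-4 -> A out; round 3 -> B.
  # a pool-independent reading of round 1 would give C, B, A instead.
  rounds <- list(c(A = -1, B = -2, C = -3), c(A = -5, B = -4), c(B = 0))
  calls <- 0L
  pool_sizes <- c(3L, 2L, 1L)
  scorer <- function(structure, mutation) {
    calls <<- calls + 1L
    round <- findInterval(calls - 1L, cumsum(c(0L, pool_sizes))[1:3])
    rounds[[round]][[mutation]]
  }
  r <- iterative_rank(cands, scorer)
  expect_equal(r$mutation, c("C", "A", "B"))
  expect_equal(r$ddg, c(-3, -5, 0))
  expect_equal(r$round, 1:3)

  # deterministic tie-break: residue number, then amino acid
  cd <- data.frame(resno = c(5L, 5L, 2L), wt_aa = "T",
                   proposed_aa = c("S", "A", "V"), blosum_score = 0L,
                   conservation = NA_real_,
                   mutation = c("T5S", "T5A", "T2V"))
  rt <- iterative_rank(cd, constant_scorer(-1))
  expect_equal(rt$mutation, c("T2V", "T5A", "T5S"))
})

test_that("mutant structures export with the residue renamed", {
  s <- cas12c2_pam_site_synthetic()
  cands <- data.frame(resno = 291L, wt_aa = "T", proposed_aa = "N",
                      blosum_score = 0L, conservation = NA_real_,
                      mutation = "T291N")
  dir <- withr::local_tempdir()
  paths <- export_mutant_structures(s, cands, chain = "A", dir = dir)
  expect_true(file.exists(paths[1]))
  m <- load_structure(paths[1])
  expect_equal(unique(m$atoms$resid[m$atoms$resno == 291 &
                                      m$atoms$chain == "A"]), "ASN")
})
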