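sc <- scoring_scheme()

test_that("self-alignment scores the diagonal sum over the full span", {
  q <- "MKTAYIAKQR"
  al <- local_align(q, q, sc)
  chars <- strsplit(q, "")[[1]]
  expect_equal(al$score, sum(vapply(chars, function(a) sc$matrix[a, a],
                                    numeric(1))))
  expect_equal(c(al$q_start, al$q_end, al$s_start, al$s_end), c(1, 10, 1, 10))
})

test_that("negative-scoring pairs follow the empty-hit convention", {
  al <- local_align("W", "C", sc)
  expect_equal(al$score, 0)
  expect_true(is.na(al$q_start))
})

test_that("local aligner matches the full-DP oracle on random pairs", {
  set.seed(11)
  for (i in 1:60) {
    q <- random_protein_fixture(sample(5:50, 1))
    s <- random_protein_fixture(sample(5:50, 1))
    expect_identical(local_align(q, s, sc)$score, sw_score_oracle(q, s, sc))
  }
})

test_that("E-values follow the closed form and its monotonicities", {
  expect_equal(evalue(0, 10, 100, sc), sc$K * 10 * 100)
  expect_equal(evalue(50, 30, 1000, sc), 2 * evalue(50, 30, 500, sc))
  for (S in c(0, 10, 55, 200)) for (m in c(10, 100)) for (n in c(1e3, 1e6))
    expect_equal(evalue(S, m, n, sc), sc$K * m * n * exp(-sc$lambda * S))
  e <- evalue(0:100, 50, 1e4, sc)
  expect_true(all(diff(e) < 0))
})

test_that("bit scores and E-values are mutually consistent on search hits", {
  set.seed(3)
  subjects <- seq_records(paste0("s", 1:5),
                          replicate(5, random_protein_fixture(80)),
                          "G1", "protein")
  query <- seq_records("q", subjects$residues[2], "G0", "protein")
  hits <- seeded_search(query, subjects, sc)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$bit_score,
               (sc$lambda * hits$raw_score - log(sc$K)) / log(2),
               tolerance = 1e-6)
  n_db <- sum(nchar(subjects$residues))
  expect_equal(hits$evalue, evalue(hits$raw_score, 80, n_db, sc),
               tolerance = 1e-9)
})

test_that("seeding finds identical subjects and skips word-disjoint ones", {
  set.seed(5)
  subjects <- seq_records(paste0("s", 1:10),
                          replicate(10, random_protein_fixture(60)),
                          "G1", "protein")
  query <- seq_records("q", subjects$residues[7], "G0", "protein")
  hits <- seeded_search(query, subjects, sc)
  self <- hits[hits$subject_id == "s7", ]
  expect_equal(self$raw_score, local_align(query$residues, query$residues,
                                           sc)$score)

  # poly-A query shares no 3-mer with a poly-W subject
  query2 <- seq_records("q2", strrep("A", 30), "G0", "protein")
  subjects2 <- seq_records("w1", strrep("W", 30), "G1", "protein")
  expect_equal(nrow(seeded_search(query2, subjects2, sc)), 0)
})

test_that("seeded scores never exceed, and mostly equal, exact SW scores", {
  set.seed(9)
  agree <- 0L
  for (i in 1:50) {
    anc <- random_protein_fixture(sample(80:150, 1))
    a <- evolve_sequence(anc, 0.15)
    b <- evolve_sequence(anc, 0.15)
    hits <- seeded_search(seq_records("q", a, "G0", "protein"),
                          seq_records("s", b, "G1", "protein"), sc)
    exact <- sw_score_oracle(a, b, sc)
    if (nrow(hits) == 1) {
      expect_lte(hits$raw_score, exact)
      if (hits$raw_score == exact) agree <- agree + 1L
    }
  }
  expect_gte(agree / 50, 0.95)
})

test_that("six-frame translation matches an independent codon-table oracle", {
  expect_equal(unname(six_frame_translate("ATGGCC")["+1"]), "MA")
  set.seed(21)
  for (rep in 1:5) {
    dna <- random_dna_fixture(300 + sample(0:2, 1))
    fr <- six_frame_translate(dna)
    rc <- revcomp_fixture(dna)
    expect_equal(unname(fr["+1"]), translate_oracle(dna, 0))
    expect_equal(unname(fr["+2"]), translate_oracle(dna, 1))
    expect_equal(unname(fr["+3"]), translate_oracle(dna, 2))
    expect_equal(unname(fr["-1"]), translate_oracle(rc, 0))
    expect_equal(unname(fr["-2"]), translate_oracle(rc, 1))
    expect_equal(unname(fr["-3"]), translate_oracle(rc, 2))
    # reverse-complement symmetry: frames swap sign
    fr_rc <- six_frame_translate(rc)
    expect_equal(unname(fr_rc[c("-1", "-2", "-3")]),
                 unname(fr[c("+1", "+2", "+3")]))
  }
})

test_that("translation handles N codons, stops, and bad characters", {
  expect_match(six_frame_translate("ATGNNNTAA")["+1"], "^MX\\*$")
  expect_error(six_frame_translate("ATGQCC"), "invalid nucleotide 'Q' at position 4")
  expect_error(six_frame_translate("AT"), "shorter")
})

test_that("translated search finds planted coding sequences on both strands", {
  set.seed(31)
  prot <- random_protein_fixture(100)
  cds <- trgscreen:::reverse_translate(prot)
  scaffold_fwd <- paste0(random_dna_fixture(100), cds, random_dna_fixture(80))
  scaffold_rev <- paste0(random_dna_fixture(77),
                         revcomp_fixture(cds), random_dna_fixture(103))
  q <- seq_records("q", prot, "G0", "protein")
  hf <- translated_search(q, seq_records("scf1", scaffold_fwd, "G1", "dna"),
                          sc, threshold = 1e-7)
  hr <- translated_search(q, seq_records("scf2", scaffold_rev, "G1", "dna"),
                          sc, threshold = 1e-7)
  expect_gte(nrow(hf), 1)
  expect_gte(nrow(hr), 1)
  best_f <- hf[which.min(hf$evalue), ]
  best_r <- hr[which.min(hr$evalue), ]
  expect_equal(best_f$frame, (100 %% 3) + 1)
  expect_true(best_r$frame < 0)
  expect_equal(best_f$raw_score, best_r$raw_score)
  expect_lt(best_f$evalue, 1e-7)
  # DNA coordinates bracket the planted CDS (forward-strand orientation)
  expect_gte(best_f$s_start, 101 - 3)
  expect_lte(best_f$s_end, 100 + nchar(cds) + 3)
})

test_that("translated search stays empty under the null", {
  set.seed(41)
  for (rep in 1:20) {
    q <- seq_records("q", random_protein_fixture(100), "G0", "protein")
    scf <- seq_records("s", random_dna_fixture(600), "G1", "dna")
    expect_equal(nrow(translated_search(q, scf, sc, threshold = 1e-7)), 0)
  }
})

test_that("reverse-complementing scaffolds permutes frames, not scores", {
  set.seed(51)
  prot <- random_protein_fixture(90)
  cds <- trgscreen:::reverse_translate(prot)
  scaffold <- paste0(random_dna_fixture(60), cds, random_dna_fixture(60))
  q <- seq_records("q", prot, "G0", "protein")
  h1 <- translated_search(q, seq_records("s", scaffold, "G1", "dna"), sc)
  h2 <- translated_search(q, seq_records("s", revcomp_fixture(scaffold),
                                         "G1", "dna"), sc)
  expect_equal(sort(h1$raw_score), sort(h2$raw_score))
  expect_equal(sort(h1$frame), sort(-h2$frame))
})
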