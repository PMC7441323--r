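sc <- scoring_scheme()

test_that("center-star alignment of identical sequences is gap-free", {
  rec <- seq_records(c("f", "m"), rep("MKTAYIAKQRLV", 2), "G", "protein")
  al <- star_align(rec, "f", sc)
  expect_equal(unname(al$rows), rep("MKTAYIAKQRLV", 2))
  expect_equal(al$col_to_focal, 1:12)
})

test_that("a deletion in a member becomes one gap column in its row", {
  rec <- seq_records(c("f", "m"), c("MKTAY", "MKAY"), "G", "protein")
  al <- star_align(rec, "f", sc)
  expect_equal(unname(al$rows["f"]), "MKTAY")
  expect_equal(unname(al$rows["m"]), "MK-AY")
  expect_equal(al$col_to_focal, 1:5)  # no focal gaps introduced
})

test_that("ungapping any alignment row reproduces its input sequence", {
  set.seed(23)
  for (rep in 1:5) {
    anc <- random_protein_fixture(sample(60:120, 1))
    seqs <- vapply(1:4, function(i) evolve_sequence(anc, 0.25), character(1))
    # introduce indels by clipping random internal blocks
    seqs[2] <- paste0(substr(seqs[2], 1, 20), substr(seqs[2], 31,
                                                     nchar(seqs[2])))
    seqs[3] <- substr(seqs[3], 10, nchar(seqs[3]))
    rec <- seq_records(paste0("s", 1:4), seqs, "G", "protein")
    al <- star_align(rec, "s1", sc)
    expect_equal(unique(nchar(al$rows)), nchar(al$rows[[1]]))
    for (i in 1:4)
      expect_equal(gsub("-", "", al$rows[paste0("s", i)], fixed = TRUE),
                   setNames(seqs[i], paste0("s", i)))
  }
})

test_that("conservation scores are 1 for identical columns and match a brute-force oracle", {
  rec <- seq_records(c("f", "m1", "m2"), rep("WWAAKKLL", 3), "G", "protein")
  tr <- conservation_profile(star_align(rec, "f", sc), sc, w = 1)
  expect_equal(tr$score, rep(1, 8))

  # dissimilar columns score below identical ones
  rec2 <- seq_records(c("f", "m"), c("WWWW", "WCWW"), "G", "protein")
  tr2 <- conservation_profile(star_align(rec2, "f", sc), sc, w = 1)
  expect_lt(tr2$score[2], tr2$score[1])

  set.seed(33)
  anc <- random_protein_fixture(50)
  rec3 <- seq_records(paste0("s", 1:6),
                      c(anc, vapply(1:5, function(i)
                        evolve_sequence(anc, 0.4), character(1))),
                      "G", "protein")
  al <- star_align(rec3, "s1", sc)
  tr3 <- conservation_profile(al, sc, w = 1)
  # independent double-loop recomputation over the aligned rows
  rows <- lapply(al$rows, function(r) strsplit(r, "")[[1]])
  lo <- min(sc$matrix)
  for (j in seq_along(tr3$score)) {
    res <- vapply(rows, `[[`, "", j)
    res <- res[res != "-"]
    vals <- c()
    if (length(res) >= 2)
      for (a in 1:(length(res) - 1)) for (b in (a + 1):length(res)) {
        hi <- max(sc$matrix[res[a], res[a]], sc$matrix[res[b], res[b]])
        vals <- c(vals, min(1, max(0, (sc$matrix[res[a], res[b]] - lo) /
                                     (hi - lo))))
      }
    if (is.null(vals)) expect_true(is.na(tr3$score[j]))
    else expect_equal(tr3$score[j], mean(vals), tolerance = 1e-12)
  }
})

test_that("conservation profile is invariant under row reordering", {
  set.seed(43)
  anc <- random_protein_fixture(60)
  seqs <- c(anc, vapply(1:4, function(i) evolve_sequence(anc, 0.3),
                        character(1)))
  rec <- seq_records(paste0("s", 1:5), seqs, "G", "protein")
  al1 <- star_align(rec, "s1", sc)
  al2 <- star_align(rec[c(1, 5, 3, 2, 4), ], "s1", sc)
  expect_equal(conservation_profile(al1, sc)$score,
               conservation_profile(al2, sc)$score)
})

test_that("segment detection follows the run rule exactly", {
  mk_track <- function(v) structure(
    list(score = v, smoothed = v, w = 1L,
         col_to_focal = seq_along(v), focal_length = length(v)),
    class = "conservation_track")
  flat <- detect_segments(mk_track(rep(1, 100)), high = 0.7, min_len = 5)
  cons <- flat[flat$label != "unconserved", ]
  expect_equal(c(cons$start, cons$end), c(1, 100))

  v <- rep(0.2, 100); v[60:100] <- 0.9
  segs <- detect_segments(mk_track(v), high = 0.7, min_len = 5)
  cons <- segs[segs$label != "unconserved", ]
  expect_equal(c(cons$start, cons$end), c(60, 100))

  none <- detect_segments(mk_track(rep(0, 80)), high = 0.7, min_len = 5)
  expect_equal(nrow(none[none$label != "unconserved", ]), 0)

  # runs shorter than min_len are not segments
  v2 <- rep(0, 50); v2[10:15] <- 1
  short <- detect_segments(mk_track(v2), high = 0.7, min_len = 10)
  expect_equal(nrow(short[short$label != "unconserved", ]), 0)

  # segments stay in bounds and never overlap
  set.seed(53)
  for (rep in 1:10) {
    v3 <- runif(120)
    s3 <- detect_segments(mk_track(v3), high = 0.6, min_len = 8)
    c3 <- s3[s3$label != "unconserved", ]
    if (nrow(c3) > 1)
      expect_true(all(c3$start[-1] > c3$end[-nrow(c3)]))
    expect_true(all(s3$start >= 1 & s3$end <= 120))
  }
})

test_that("novelty classes follow the domain-overlap rules", {
  mk_segs <- function(df, flen) {
    df$mean_conservation <- 0.9
    attr(df, "focal_length") <- flen
    df
  }
  # chimera pattern: known domain over the N-terminal conserved segment,
  # unannotated conserved C-terminal segment
  segs <- mk_segs(data.frame(
    start = c(1L, 101L, 151L), end = c(100L, 150L, 250L),
    label = c("novel_conserved", "unconserved", "novel_conserved")), 250)
  ann <- data.frame(gene_id = "g", start = 1L, end = 105L,
                    domain_id = "DUF_like", is_extraclade_domain = TRUE)
  out <- classify_novelty(segs, ann)
  expect_equal(out$class, "chimeric")
  expect_equal(out$segments$label[1], "known_domain_overlap")
  expect_equal(out$segments$label[3], "novel_conserved")

  # fully-novel pattern: conserved segments, no known domains at all
  expect_equal(classify_novelty(segs, NULL)$class, "fully_novel")

  # all conserved segments covered by known domains
  ann2 <- rbind(ann, data.frame(gene_id = "g", start = 140L, end = 250L,
                                domain_id = "other",
                                is_extraclade_domain = TRUE))
  expect_equal(classify_novelty(segs, ann2)$class, "known")

  # clade-internal domains never count as "known"
  ann3 <- ann
  ann3$is_extraclade_domain <- FALSE
  expect_equal(classify_novelty(segs, ann3)$class, "fully_novel")

  # degenerate: no conserved segments
  none <- mk_segs(data.frame(start = 1L, end = 250L, label = "unconserved"),
                  250)
  expect_equal(classify_novelty(none, ann)$class, "unclassified")

  expect_error(classify_novelty(segs, data.frame(
    gene_id = "g", start = 0L, end = 10L, domain_id = "d",
    is_extraclade_domain = TRUE)), "out of sequence bounds")
})
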