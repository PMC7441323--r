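cfg <- paper_shaped_config()
INGROUP <- c("cgig", "lgig", "ctel", "hrob", "sman", "smed", "emul", "hmic")

fake_proteome <- function(ids)
  seq_records(ids, vapply(rep(60, length(ids)), random_protein_fixture,
                          character(1)), "cgig", "protein")

test_that("presence cells take the per-genome minimum E-value, strictly below", {
  genes <- fake_proteome(c("g1", "g2", "g3"))
  hits <- rbind(hit_row("g1", "lgig", 1e-8),
                hit_row("g1", "lgig", 1e-4),
                hit_row("g2", "lgig", 1e-7),      # exactly at threshold
                hit_row("g3", "cele", 1e-6),
                hit_row("g1", "cgig", 1e-80))     # self-genome: ignored
  pm <- build_presence_matrix(genes, hits, cfg)
  expect_true(pm$present["g1", "lgig"])
  expect_equal(pm$evalue["g1", "lgig"], 1e-8)
  expect_false(pm$present["g2", "lgig"])          # strict "below"
  expect_true(pm$present["g3", "cele"])           # outgroup role: 1e-6 < 1e-5
  expect_true(all(is.na(pm$evalue[, "cgig"])))    # focal never evidence
  expect_error(build_presence_matrix(genes, hit_row("g1", "nope", 1e-9), cfg),
               "unknown genome")
})

test_that("presence matrix equals a per-cell minimum-and-compare oracle", {
  set.seed(17)
  genes <- fake_proteome(sprintf("g%02d", 1:20))
  genomes <- c(setdiff(INGROUP, "cgig"), cfg$outgroup_genomes)
  hits <- do.call(rbind, lapply(1:300, function(i)
    hit_row(sample(genes$seq_id, 1), sample(genomes, 1),
            10^runif(1, -12, -2))))
  pm <- build_presence_matrix(genes, hits, cfg)
  for (g in genes$seq_id) for (G in genomes) {
    sub <- hits$evalue[hits$query_id == g & hits$subject_genome == G]
    thr <- if (G %in% INGROUP) cfg$e_ingroup else cfg$e_exclusion
    if (length(sub)) {
      expect_equal(pm$evalue[g, G], min(sub))
      expect_equal(pm$present[g, G], min(sub) < thr)
    } else {
      expect_true(is.na(pm$evalue[g, G]))
      expect_false(pm$present[g, G])
    }
  }
})

test_that("ingroup criterion needs one non-focal presence per phylum", {
  row <- setNames(rep(FALSE, 8), INGROUP)
  row[c("lgig", "ctel", "smed")] <- TRUE
  expect_true(ingroup_criterion(row, cfg))

  # both annelids and all flatworms, but no non-focal mollusc
  row2 <- setNames(INGROUP %in% c("cgig", "ctel", "hrob", "sman", "smed",
                                  "emul", "hmic"), INGROUP)
  expect_false(ingroup_criterion(row2, cfg))
  cfg_self <- paper_shaped_config(allow_focal_evidence = TRUE)
  expect_true(ingroup_criterion(row2, cfg_self))
})

test_that("ingroup criterion matches exhaustive enumeration over all patterns", {
  oracle <- function(row) {
    phyla <- list(c("lgig"), c("ctel", "hrob"),
                  c("sman", "smed", "emul", "hmic"))  # focal removed
    all(vapply(phyla, function(m) any(row[m]), logical(1)))
  }
  for (bits in 0:255) {
    row <- setNames(as.logical(bitwAnd(bits, 2^(0:7))), INGROUP)
    expect_identical(ingroup_criterion(row, cfg), oracle(row),
                     info = paste("pattern", bits))
  }
})

test_that("outgroup exclusion applies the strict threshold and taxon filter", {
  out <- outgroup_exclusion("g1", hit_row("g1", "dmel", 1e-6), NULL, cfg)
  expect_true(out$excluded)
  expect_equal(out$offending$source, "dmel")

  expect_false(outgroup_exclusion("g1", hit_row("g1", "dmel", 1e-4),
                                  NULL, cfg)$excluded)
  expect_false(outgroup_exclusion("g1", hit_row("g1", "dmel", 1e-5),
                                  NULL, cfg)$excluded)

  db_in <- hit_row("g1", "nr_like", 1e-30)
  db_in$subject_taxon <- "mollusc"       # clade taxon: never disqualifies
  expect_false(outgroup_exclusion("g1", hit_row("g1", "dmel", 1),
                                  db_in, cfg)$excluded)
  db_out <- db_in
  db_out$subject_taxon <- "ecdysozoa"
  expect_true(outgroup_exclusion("g1", hit_row("g1", "dmel", 1),
                                 db_out, cfg)$excluded)
  db_na <- db_in
  db_na$subject_taxon <- NA_character_
  expect_error(outgroup_exclusion("g1", hit_row("g1", "dmel", 1),
                                  db_na, cfg),
               "without taxon label")
})

test_that("rescue flips only absent ingroup cells and is idempotent", {
  set.seed(61)
  prot <- random_protein_fixture(120)
  genes <- seq_records("g1", prot, "cgig", "protein")
  cds <- trgscreen:::reverse_translate(prot)
  scaffold <- paste0(random_dna_fixture(90), cds, random_dna_fixture(90))
  dna <- list(ctel = seq_records("scf", scaffold, "ctel", "dna"))

  pm <- build_presence_matrix(genes, empty_hits_fixture(), cfg)
  pm2 <- rescue_unannotated(pm, genes, cfg, genome_dna = dna)
  expect_true(pm2$present["g1", "ctel"])
  expect_equal(pm2$evidence["g1", "ctel"], "rescued")
  expect_false(any(pm2$present[, cfg$outgroup_genomes]))

  # already-present cells are untouched; a second round is the identity
  pm3 <- rescue_unannotated(pm2, genes, cfg, genome_dna = dna)
  expect_identical(pm3$present, pm2$present)
  expect_identical(pm3$evidence, pm2$evidence)

  # rescue never removes presence
  expect_true(all(pm2$present >= pm$present))
})

test_that("threshold relaxation is monotone in the expected directions", {
  set.seed(71)
  genes <- fake_proteome(sprintf("g%02d", 1:15))
  genomes <- c(setdiff(INGROUP, "cgig"), cfg$outgroup_genomes)
  hits <- do.call(rbind, lapply(1:250, function(i)
    hit_row(sample(genes$seq_id, 1), sample(genomes, 1),
            10^runif(1, -10, -3))))
  run_with <- function(e_in, e_ex) {
    c2 <- paper_shaped_config(e_ingroup = e_in, e_exclusion = e_ex,
                              engine = "external_hits")
    scr <- run_screen(c2, proteomes = list(cgig = genes), hits = hits)
    scr$candidates
  }
  base <- run_with(1e-7, 1e-5)
  wide_in <- run_with(1e-5, 1e-5)
  pass0 <- base$gene_id[base$passes_ingroup]
  pass1 <- wide_in$gene_id[wide_in$passes_ingroup]
  expect_true(all(pass0 %in% pass1))

  wide_ex <- run_with(1e-7, 1e-3)
  ls0 <- base$gene_id[base$verdict == "lineage_specific"]
  ls1 <- wide_ex$gene_id[wide_ex$verdict == "lineage_specific"]
  expect_true(all(ls1 %in% ls0))
})

test_that("an empty focal proteome yields an empty but valid report", {
  c2 <- paper_shaped_config(engine = "external_hits")
  empty <- seq_records(character(0), character(0), "cgig", "protein")
  scr <- run_screen(c2, proteomes = list(cgig = empty),
                    hits = empty_hits_fixture())
  expect_equal(nrow(scr$candidates), 0)
  expect_equal(nrow(scr$report), 0)
  f <- withr::local_tempfile()
  write_screen_report(scr, f)
  expect_true(file.exists(f))
})

test_that("screen verdicts are invariant to input ordering", {
  set.seed(81)
  sim <- simulate_clade(simulation_config(
    n_pan = 2, n_clade_specific = 3, n_chimera = 1, n_fast = 1, seed = 5))
  scr1 <- run_screen(sim$screen_config, proteomes = sim$proteomes,
                     genome_dna = sim$genome_dna,
                     exclusion_dbs = list(decoy_db = sim$exclusion_db))
  # permute genome order and row order within every proteome
  perm <- rev(names(sim$proteomes))
  prot2 <- lapply(sim$proteomes[perm], function(p)
    p[sample(nrow(p)), , drop = FALSE])
  scr2 <- run_screen(sim$screen_config, proteomes = prot2,
                     genome_dna = rev(sim$genome_dna),
                     exclusion_dbs = list(decoy_db = sim$exclusion_db))
  rownames(scr1$candidates) <- rownames(scr2$candidates) <- NULL
  rownames(scr1$report) <- rownames(scr2$report) <- NULL
  expect_identical(scr1$candidates, scr2$candidates)
  expect_identical(scr1$report, scr2$report)
})
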