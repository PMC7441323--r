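# Independent oracles used across the suite. These re-derive expected
# values by brute force and must stay independent of the package's
# implementation paths.

# Textbook quadratic-space affine-gap Smith-Waterman, score only.
# Same convention as the package: a gap of length L costs gap_open +
# L * gap_extend (both scores <= 0).
sw_score_oracle <- function(q, s, scoring) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  mat <- scoring$matrix
  go <- scoring$gap_open; ge <- scoring$gap_extend
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + go + ge, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go + ge, F[i - 1, j] + ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  as.integer(best)
}

random_protein_fixture <- function(n)
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")

random_dna_fixture <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

revcomp_fixture <- function(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# Independent codon-table translation (manual lookup, standard code).
translate_oracle <- function(dna, offset = 0) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) - offset
  n <- n - n %% 3
  if (n < 3) return("")
  codons <- substring(dna, offset + seq(1, n, 3), offset + seq(3, n, 3))
  aa <- vapply(codons, function(cod) {
    if (grepl("N", cod)) "X" else unname(code[cod])
  }, character(1))
  paste(aa, collapse = "")
}

# Paper-shaped screen configuration: 3 ingroup phyla {2,2,4}, 10 outgroups.
paper_shaped_config <- function(...) {
  screen_config(
    focal_genome = "cgig",
    ingroup_phyla = list(mollusc = c("cgig", "lgig"),
                         annelid = c("ctel", "hrob"),
                         flatworm = c("sman", "smed", "emul", "hmic")),
    outgroup_genomes = c("cele", "dmel", "amel", "mmus", "xlae",
                         "cint", "hmag", "atha", "ddis", "mbre"),
    ...)
}

empty_hits_fixture <- function() trgscreen:::empty_hits()

# one protein hit row in the native layout
hit_row <- function(query, genome, ev, subject = paste0(genome, "_s"),
                    scoring = scoring_scheme()) {
  S <- max(0, round((log(scoring$K * 100 * 1000) - log(ev)) / scoring$lambda))
  data.frame(query_id = query, subject_id = subject, subject_genome = genome,
             raw_score = as.integer(S),
             bit_score = bit_score(S, scoring), evalue = ev,
             q_start = 1L, q_end = 10L, s_start = 1L, s_end = 10L,
             frame = 0L, stringsAsFactors = FALSE)
}
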