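#' Six-frame translation of a nucleotide sequence
#'
#' Frames +1, +2, +3 read the forward strand from offsets 0, 1, 2; frames
#' -1, -2, -3 read the reverse complement the same way. Translation uses the
#' standard genetic code via [Biostrings::translate()]; stop codons become
#' \code{*}, any codon containing \code{N} becomes \code{X}, and a trailing
#' partial codon is dropped.
#'
#' @param dna a nucleotide string over ACGTN (case-insensitive), length >= 3.
#' @return named character vector of the six translated frames, names
#'   \code{"+1" ... "-3"}.
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(dna)
  bad <- regexpr("[^ACGTN]", dna)
  if (bad > 0)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(dna, bad, bad), bad))
  if (nchar(dna) < 3) stop("sequence shorter than one codon")
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3
    if (n < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1, width = n),
      if.fuzzy.codon = "X"))
  }
  out <- c(one(fwd, 0), one(fwd, 1), one(fwd, 2),
           one(rev, 0), one(rev, 1), one(rev, 2))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# Split a translated frame at stop codons; returns data frame of segments
# with their 1-based amino-acid offsets within the frame.
split_at_stops <- function(protein) {
  if (!nzchar(protein))
    return(data.frame(aa_start = integer(), segment = character()))
  parts <- strsplit(protein, "*", fixed = TRUE)[[1]]
  starts <- integer(length(parts))
  pos <- 1L
  for (i in seq_along(parts)) {
    starts[i] <- pos
    pos <- pos + nchar(parts[i]) + 1L
  }
  keep <- nzchar(parts)
  data.frame(aa_start = starts[keep], segment = parts[keep],
             stringsAsFactors = FALSE)
}

# Map an amino-acid interval [p1, p2] in a given frame of a scaffold of
# length L to 1-based forward-strand DNA coordinates.
frame_to_dna <- function(p1, p2, frame, L) {
  f <- abs(frame)
  if (frame > 0) c(f + 3L * (p1 - 1L), f + 3L * (p2 - 1L) + 2L)
  else c(L - f - 3L * (p2 - 1L) - 1L, L - f - 3L * (p1 - 1L) + 1L)
}

#' Translated search of a protein query against genomic scaffolds
#'
#' The tBLASTn-style rescue primitive: every scaffold is translated in six
#' frames, frames are split at stop codons (so no hit crosses a stop), and
#' each open segment is searched with the seeded protein aligner. Subject
#' coordinates are reported on the DNA, 1-based in forward-strand
#' orientation, with the frame recorded. Hits with E-value at or above
#' \code{threshold} are suppressed. The E-value search space is the total
#' number of translated residues across all frames of all scaffolds
#' supplied.
#'
#' @param query single-row protein \code{seq_records}.
#' @param genome_dna nucleotide \code{seq_records} (the scaffolds of one
#'   genome).
#' @param scoring a [scoring_scheme()].
#' @param threshold suppress hits with \code{evalue >= threshold}.
#' @param k seeding word size.
#' @return hit data frame; \code{subject_id} is the scaffold id.
#' @export
translated_search <- function(query, genome_dna, scoring = scoring_scheme(),
                              threshold = 1e-7, k = 3L) {
  if (any(genome_dna$moltype != "dna"))
    stop("translated_search needs nucleotide subjects")
  qseq <- toupper(query$residues[[1]])
  qid <- query$seq_id[[1]]
  qk <- kmer_set(qseq, k)
  # translate everything first so the search space is known up front
  frames <- lapply(seq_len(nrow(genome_dna)), function(i)
    six_frame_translate(genome_dna$residues[i]))
  n_total <- sum(vapply(frames, function(fr) sum(nchar(fr)), numeric(1)))
  if (n_total < 1) return(empty_hits())
  out <- list()
  for (i in seq_len(nrow(genome_dna))) {
    L <- nchar(genome_dna$residues[i])
    for (fname in names(frames[[i]])) {
      fr <- as.integer(fname)
      segs <- split_at_stops(frames[[i]][[fname]])
      for (j in seq_len(nrow(segs))) {
        if (!length(qk) || !any(qk %in% kmer_set(segs$segment[j], k))) next
        al <- local_align(qseq, segs$segment[j], scoring)
        if (al$score <= 0) next
        ev <- evalue(al$score, nchar(qseq), n_total, scoring)
        if (ev >= threshold) next
        p1 <- segs$aa_start[j] + al$s_start - 1L
        p2 <- segs$aa_start[j] + al$s_end - 1L
        dna <- frame_to_dna(p1, p2, fr, L)
        out[[length(out) + 1L]] <- data.frame(
          query_id = qid, subject_id = genome_dna$seq_id[i],
          subject_genome = genome_dna$genome_id[i],
          raw_score = al$score,
          bit_score = bit_score(al$score, scoring),
          evalue = ev,
          q_start = al$q_start, q_end = al$q_end,
          s_start = dna[1], s_end = dna[2],
          frame = fr, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_hits())
  do.call(rbind, out)
}
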