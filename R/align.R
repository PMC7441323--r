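#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman (Gotoh) alignment. A gap of length L scores
#' \code{gap_open + L * gap_extend}. Coordinates are 1-based inclusive. When
#' several alignments share the optimal score, the one with the smallest
#' \code{(q_start, s_start)}, then the shortest span, is reported. A best
#' score of 0 means no positive-scoring local alignment exists (the
#' empty-hit convention): all coordinates are \code{NA}.
#'
#' @param query,subject protein strings (alphabet: 20 residues + X; \code{*}
#'   is additionally allowed so translated frames can be aligned).
#' @param scoring a [scoring_scheme()].
#' @return list with \code{score}, \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end}.
#' @export
local_align <- function(query, subject, scoring = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty")
  alpha <- rownames(scoring$matrix)
  qi <- encode_residues(toupper(query), alpha, "query")
  si <- encode_residues(toupper(subject), alpha, "subject")
  sw_align_idx(qi, si, scoring$matrix, scoring$gap_open, scoring$gap_extend)
}

#' Karlin-Altschul E-value of a raw local-alignment score
#'
#' The expected number of chance local alignments scoring at least S in a
#' search of a length-m query against n database residues, under the
#' ungapped model: \eqn{E = K m n e^{-\lambda S}}. Monotonically decreasing
#' in S and linear in m and n.
#'
#' @param S raw score (non-negative).
#' @param m query length in residues.
#' @param n total residues searched (summed per genome or database).
#' @param scoring a [scoring_scheme()] supplying \eqn{\lambda} and K.
#' @return the E-value.
#' @export
evalue <- function(S, m, n, scoring = scoring_scheme()) {
  stopifnot(all(S >= 0), all(m >= 1), all(n >= 1))
  scoring$K * m * n * exp(-scoring$lambda * S)
}

#' Bit score of a raw score
#'
#' \eqn{S' = (\lambda S - \ln K) / \ln 2}.
#' @inheritParams evalue
#' @export
bit_score <- function(S, scoring = scoring_scheme()) {
  (scoring$lambda * S - log(scoring$K)) / log(2)
}

kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
}

#' Seeded search of one query against a set of protein subjects
#'
#' Word seeding prunes the database: only subjects sharing at least one
#' exact k-mer with the query are aligned. Surviving pairs are scored with
#' the exact affine-gap local aligner ([local_align()]), so an emitted hit's
#' raw score always equals the optimal Smith-Waterman score for that pair;
#' seeding can only lose whole subjects that share no word with the query
#' (which cannot carry a threshold-relevant alignment at desk scale). At
#' most one hit -- the best local alignment -- is emitted per
#' (query, subject) pair.
#'
#' @param query a single-row \code{seq_records} data frame (or a list with
#'   \code{seq_id} and \code{residues}).
#' @param subjects protein \code{seq_records}.
#' @param scoring a [scoring_scheme()].
#' @param k word size for seeding (>= 2).
#' @param n_db residues assumed searched when converting scores to E-values;
#'   defaults to the total length of \code{subjects}.
#' @return a hit data frame (possibly empty) in the 11-column layout.
#' @export
seeded_search <- function(query, subjects, scoring = scoring_scheme(),
                          k = 3L, n_db = NULL) {
  stopifnot(k >= 2)
  if (nrow(subjects) == 0) return(empty_hits())
  if (any(subjects$moltype != "protein"))
    stop("seeded_search subjects must be protein")
  qseq <- toupper(query$residues[[1]])
  qid <- query$seq_id[[1]]
  if (is.null(n_db)) n_db <- sum(nchar(subjects$residues))
  qk <- kmer_set(qseq, k)
  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sk <- kmer_set(subjects$residues[i], k)
    if (!length(qk) || !any(qk %in% sk)) next
    al <- local_align(qseq, subjects$residues[i], scoring)
    if (al$score <= 0) next
    out[[i]] <- data.frame(
      query_id = qid, subject_id = subjects$seq_id[i],
      subject_genome = subjects$genome_id[i],
      raw_score = al$score,
      bit_score = bit_score(al$score, scoring),
      evalue = evalue(al$score, nchar(qseq), n_db, scoring),
      q_start = al$q_start, q_end = al$q_end,
      s_start = al$s_start, s_end = al$s_end,
      frame = 0L, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits)) empty_hits() else hits
}

#' Search every sequence of a proteome against one subject proteome
#'
#' Convenience wrapper around [seeded_search()]: the E-value search space is
#' the subject genome's total residue count, matching per-genome search
#' runs.
#'
#' @param queries,subjects protein \code{seq_records}.
#' @inheritParams seeded_search
#' @return combined hit data frame.
#' @export
search_proteome <- function(queries, subjects, scoring = scoring_scheme(),
                            k = 3L) {
  n_db <- sum(nchar(subjects$residues))
  out <- lapply(seq_len(nrow(queries)), function(i)
    seeded_search(queries[i, ], subjects, scoring, k, n_db = n_db))
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0) empty_hits() else hits
}
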