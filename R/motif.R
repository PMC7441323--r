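#' Center-star multiple alignment of an ortholog set
#'
#' Each member is aligned to the focal (center) sequence with a global,
#' free-end-gap pairwise alignment; the pairwise alignments are merged under
#' the center-star rule ("once a gap, always a gap"), with the focal row
#' defining the column-to-focal-coordinate map.
#'
#' @param members protein \code{seq_records} of the ingroup orthologs,
#'   including the focal sequence (>= 2 rows).
#' @param center seq_id of the focal sequence within \code{members}.
#' @param scoring a [scoring_scheme()].
#' @return object of class \code{ortholog_alignment}: list with
#'   \code{rows} (named equal-length aligned strings), \code{focal_id},
#'   \code{col_to_focal} (per column, the focal residue coordinate or NA at
#'   focal-gap columns) and \code{gene_id}.
#' @export
star_align <- function(members, center, scoring = scoring_scheme()) {
  if (nrow(members) < 2) stop("need at least two member sequences")
  if (!center %in% members$seq_id)
    stop("center sequence ", center, " not among members")
  alpha <- rownames(scoring$matrix)
  cseq <- members$residues[members$seq_id == center][1]
  ci <- encode_residues(toupper(cseq), alpha, center)
  Lc <- length(ci)
  others <- members[members$seq_id != center, , drop = FALSE]

  # per member: insertions (member residues falling in center gaps) keyed by
  # the center position they follow (0 = before the first), plus the member
  # character aligned to each center position ("-" if deleted)
  parses <- lapply(seq_len(nrow(others)), function(i) {
    al <- overlap_align_idx(
      encode_residues(toupper(others$residues[i]), alpha, others$seq_id[i]),
      ci, scoring$matrix, scoring$gap_open, scoring$gap_extend)
    qa <- al$q_aln; sa <- al$s_aln  # q = member, s = center
    ins <- vector("list", Lc + 1)
    aligned <- rep("-", Lc)
    pos <- 0L
    for (col in seq_along(sa)) {
      if (sa[col] >= 0) {
        pos <- pos + 1L
        if (qa[col] >= 0) aligned[pos] <- alpha[qa[col] + 1]
      } else if (qa[col] >= 0) {
        ins[[pos + 1]] <- c(ins[[pos + 1]], alpha[qa[col] + 1])
      }
    }
    list(ins = ins, aligned = aligned)
  })

  ins_len <- vapply(0:Lc, function(p) {
    lens <- vapply(parses, function(pr) length(pr$ins[[p + 1]]), integer(1))
    if (length(lens)) max(lens) else 0L
  }, integer(1))

  build_row <- function(ins, aligned) {
    parts <- character(0)
    for (p in 0:Lc) {
      block <- ins[[p + 1]] %||% character(0)
      pad <- rep("-", ins_len[p + 1] - length(block))
      parts <- c(parts, block, pad,
                 if (p < Lc) aligned[p + 1])
    }
    paste(parts, collapse = "")
  }
  center_chars <- strsplit(toupper(cseq), "")[[1]]
  rows <- c(setNames(list(build_row(vector("list", Lc + 1), center_chars)),
                     center),
            setNames(lapply(parses, function(pr)
              build_row(pr$ins, pr$aligned)), others$seq_id))
  rows <- vapply(rows, identity, character(1))
  col_to_focal <- integer(0)
  pos <- 0L
  for (p in 0:Lc) {
    col_to_focal <- c(col_to_focal, rep(NA_integer_, ins_len[p + 1]),
                      if (p < Lc) p + 1L)
  }
  structure(list(rows = rows, focal_id = center,
                 col_to_focal = col_to_focal,
                 gene_id = center),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf("ortholog_alignment: %d rows x %d columns (focal %s)\n",
              length(x$rows), nchar(x$rows[1]), x$focal_id))
  invisible(x)
}

# normalized score of one residue pair: 1 for an identical pair, 0 at the
# matrix minimum, using the larger of the two self-scores as the ceiling
pair_conservation <- function(a, b, mat) {
  s <- mat[a, b]
  lo <- min(mat)
  hi <- max(mat[a, a], mat[b, b])
  if (hi <= lo) return(0)
  min(1, max(0, (s - lo) / (hi - lo)))
}

#' Per-column conservation profile of an ortholog alignment
#'
#' Each column scores the mean normalized substitution score over all
#' unordered pairs of non-gap residues: an identical-residue column scores
#' exactly 1 whatever the residue, dissimilar columns score towards 0.
#' Columns with fewer than two non-gap residues are masked (NA). A sliding
#' mean of odd width \code{w} (shrinking at the edges, masked columns
#' excluded) gives the smoothed track used for segment detection.
#'
#' @param aln an [star_align()] result.
#' @param scoring a [scoring_scheme()].
#' @param w odd window width >= 1.
#' @return object of class \code{conservation_track}: \code{score} (raw per
#'   column), \code{smoothed}, \code{w}, \code{col_to_focal},
#'   \code{focal_length}.
#' @export
conservation_profile <- function(aln, scoring = scoring_scheme(), w = 11L) {
  stopifnot(w >= 1, w %% 2 == 1)
  mat <- scoring$matrix
  rows <- lapply(aln$rows, function(r) strsplit(r, "")[[1]])
  ncol_aln <- length(rows[[1]])
  raw <- rep(NA_real_, ncol_aln)
  for (j in seq_len(ncol_aln)) {
    res <- vapply(rows, `[[`, "", j)
    res <- res[res != "-"]
    if (length(res) < 2) next
    tot <- 0; np <- 0L
    for (a in seq_along(res)[-length(res)])
      for (b in (a + 1):length(res)) {
        tot <- tot + pair_conservation(res[a], res[b], mat)
        np <- np + 1L
      }
    raw[j] <- tot / np
  }
  half <- (w - 1) / 2
  smoothed <- vapply(seq_len(ncol_aln), function(j) {
    win <- raw[max(1, j - half):min(ncol_aln, j + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  structure(list(score = raw, smoothed = smoothed, w = as.integer(w),
                 col_to_focal = aln$col_to_focal,
                 focal_length = sum(!is.na(aln$col_to_focal))),
            class = "conservation_track")
}

#' Detect conserved segments on a conservation track
#'
#' Maximal runs of at least \code{min_len} consecutive columns whose
#' smoothed score is at or above \code{high} become conserved segments
#' (label \code{"novel_conserved"} until domain annotations say otherwise);
#' the focal positions between them are reported as \code{"unconserved"}
#' segments. Coordinates are 1-based inclusive on the focal sequence;
#' masked (NA) columns break runs.
#'
#' @param track a [conservation_profile()] result.
#' @param high smoothed-score threshold (\eqn{\ge}).
#' @param min_len minimum run length in columns.
#' @return data frame of segments (start, end, mean_conservation, label),
#'   sorted and non-overlapping, with the focal length as attribute
#'   \code{focal_length}.
#' @export
detect_segments <- function(track, high = 0.7, min_len = 20L) {
  ok <- !is.na(track$smoothed) & track$smoothed >= high
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_len) next
    cols <- starts[i]:ends[i]
    fpos <- track$col_to_focal[cols]
    fpos <- fpos[!is.na(fpos)]
    if (!length(fpos)) next
    segs[[length(segs) + 1]] <- data.frame(
      start = min(fpos), end = max(fpos),
      mean_conservation = mean(track$smoothed[cols]),
      label = "novel_conserved", stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, segs)
  if (is.null(segs))
    segs <- data.frame(start = integer(), end = integer(),
                       mean_conservation = numeric(), label = character(),
                       stringsAsFactors = FALSE)
  segs <- segs[order(segs$start), , drop = FALSE]
  # fill the gaps with unconserved segments over focal coordinates
  gaps <- list()
  cursor <- 1L
  for (i in seq_len(nrow(segs))) {
    if (segs$start[i] > cursor)
      gaps[[length(gaps) + 1]] <- c(cursor, segs$start[i] - 1L)
    cursor <- segs$end[i] + 1L
  }
  if (cursor <= track$focal_length)
    gaps[[length(gaps) + 1]] <- c(cursor, track$focal_length)
  if (length(gaps)) {
    gdf <- do.call(rbind, lapply(gaps, function(g)
      data.frame(start = g[1], end = g[2], mean_conservation = NA_real_,
                 label = "unconserved", stringsAsFactors = FALSE)))
    segs <- rbind(segs, gdf)
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  attr(segs, "focal_length") <- track$focal_length
  segs
}

overlap_len <- function(a1, a2, b1, b2)
  max(0L, min(a2, b2) - max(a1, b1) + 1L)

#' Classify a candidate's novelty from its conserved segments
#'
#' Intersects the conserved segments with externally supplied domain
#' annotations (in focal coordinates). A conserved segment "overlaps" a
#' domain when at least half the segment's length is covered by a single
#' extra-clade-known domain. Classes:
#' \describe{
#'   \item{chimeric}{at least one conserved segment overlaps an extra-clade
#'     domain AND at least one conserved segment of length >= min_len has
#'     no such overlap (ancient domain + clade-specific motif).}
#'   \item{fully_novel}{conserved segments exist and none overlaps a known
#'     domain.}
#'   \item{known}{all conserved segments overlap known domains (segments
#'     without overlap shorter than \code{min_len} do not count as novel).}
#'   \item{unclassified}{no conserved segments at all (degenerate input).}
#' }
#'
#' @param segments a [detect_segments()] result.
#' @param domain_annotations data frame with columns \code{start},
#'   \code{end}, \code{domain_id}, \code{is_extraclade_domain}; may have
#'   zero rows. Coordinates outside the focal sequence are an error.
#' @param min_len minimum length for a novel conserved segment.
#' @return list with \code{class} and \code{segments} (labels updated:
#'   overlapping conserved segments become \code{"known_domain_overlap"}).
#' @export
classify_novelty <- function(segments, domain_annotations,
                             min_len = 20L) {
  flen <- attr(segments, "focal_length")
  ann <- domain_annotations
  if (is.null(ann) || nrow(ann) == 0)
    ann <- data.frame(start = integer(), end = integer(),
                      domain_id = character(),
                      is_extraclade_domain = logical())
  if (nrow(ann)) {
    if (any(ann$start > ann$end))
      stop("domain annotation with start > end")
    if (any(ann$start < 1) || (!is.null(flen) && any(ann$end > flen)))
      stop("domain annotation out of sequence bounds")
  }
  ann <- ann[ann$is_extraclade_domain, , drop = FALSE]
  cons <- which(segments$label != "unconserved")
  if (!length(cons))
    return(list(class = "unclassified", segments = segments))
  overlaps <- vapply(cons, function(i) {
    len <- segments$end[i] - segments$start[i] + 1L
    if (nrow(ann) == 0) return(FALSE)
    any(vapply(seq_len(nrow(ann)), function(j)
      overlap_len(segments$start[i], segments$end[i],
                  ann$start[j], ann$end[j]) >= 0.5 * len, logical(1)))
  }, logical(1))
  segments$label[cons[overlaps]] <- "known_domain_overlap"
  novel_long <- !overlaps &
    (segments$end[cons] - segments$start[cons] + 1L) >= min_len
  cls <- if (any(overlaps) && any(novel_long)) "chimeric"
    else if (!any(overlaps)) "fully_novel"
    else "known"
  list(class = cls, segments = segments)
}

#' Classify all lineage-specific candidates of a screen
#'
#' For each candidate with verdict \code{lineage_specific}, the best-hit
#' subject in every ingroup genome with annotated presence is collected as
#' its ortholog set, aligned to the focal sequence by [star_align()],
#' profiled, segmented, and classified against the supplied domain
#' annotations. Candidates whose orthologs are only present as rescued
#' (unannotated) loci have no proteome sequence to align and keep whatever
#' annotated members exist.
#'
#' @param screen a \code{trg_screen} result.
#' @param proteomes named list genome id -> protein \code{seq_records}.
#' @param domain_annotations data frame with columns \code{gene_id},
#'   \code{start}, \code{end}, \code{domain_id},
#'   \code{is_extraclade_domain}.
#' @param scoring a [scoring_scheme()].
#' @param high,min_len,w segment-detection parameters (see
#'   [detect_segments()] and [conservation_profile()]).
#' @return the screen with \code{report$novelty_class} filled and a
#'   \code{novelty} element (per-candidate class and segments).
#' @export
classify_candidates <- function(screen, proteomes, domain_annotations = NULL,
                                scoring = scoring_scheme(),
                                high = 0.7, min_len = 20L, w = 11L) {
  stopifnot(inherits(screen, "trg_screen"))
  cand <- screen$candidates
  ls_genes <- cand$gene_id[cand$verdict == "lineage_specific"]
  focal <- proteomes[[screen$config$focal_genome]]
  res <- list()
  for (g in ls_genes) {
    members <- focal[focal$seq_id == g, , drop = FALSE]
    for (G in names(screen$matrix$role)[screen$matrix$role == "ingroup"]) {
      if (screen$matrix$evidence[g, G] != "annotated") next
      gh <- screen$hits[screen$hits$query_id == g &
                          screen$hits$subject_genome == G, , drop = FALSE]
      if (nrow(gh) == 0) next
      best <- gh$subject_id[which.min(gh$evalue)]
      members <- rbind(members,
                       proteomes[[G]][proteomes[[G]]$seq_id == best, ,
                                      drop = FALSE])
    }
    if (nrow(members) < 2) {
      res[[g]] <- list(class = "unclassified", segments = NULL)
      next
    }
    aln <- star_align(members, g, scoring)
    track <- conservation_profile(aln, scoring, w)
    segs <- detect_segments(track, high, min_len)
    ann <- NULL
    if (!is.null(domain_annotations) && nrow(domain_annotations))
      ann <- domain_annotations[domain_annotations$gene_id == g, ,
                                drop = FALSE]
    res[[g]] <- classify_novelty(segs, ann, min_len)
  }
  cls <- vapply(res, `[[`, "", "class")
  screen$report$novelty_class[match(names(cls), screen$report$gene_id)] <- cls
  screen$novelty <- res
  screen
}
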