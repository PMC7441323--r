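#' Simulate a clade of proteomes with planted ground truth
#'
#' Generates one proteome per tip of the species tree, scaffold DNA
#' carrying the coding sequences of genes dropped from annotation, a decoy
#' exclusion database with per-sequence taxon labels, and a truth table
#' recording the class and fate of every planted family. All randomness is
#' governed by \code{config$seed}; identical configurations give identical
#' output.
#'
#' Construction guarantees: clade-specific families are born at the clade
#' ancestor and never emitted into outgroup proteomes (nor into the decoy
#' database under an extra-clade label); chimera ingroup sequences are
#' domain+linker+motif concatenations whose domain block also evolves into
#' outgroup proteomes as a stand-alone protein; unannotated genes appear
#' only in scaffold DNA, reverse-translated with uniform synonymous codon
#' choice, embedded in random-nucleotide flanks on a random strand, in
#' frame, so the recorded frame translates back to the exact planted
#' protein.
#'
#' @param config a [simulation_config()].
#' @return object of class \code{trg_simulation}: list with
#'   \code{proteomes} (named list of protein \code{seq_records}),
#'   \code{genome_dna} (named list of nucleotide \code{seq_records}),
#'   \code{exclusion_db} (list(records, taxa)), \code{truth} (per-family
#'   data frame), \code{tip_status} (per family x tip), \code{annotations}
#'   (chimera domain annotations in focal coordinates) and
#'   \code{screen_config} (a matching [screen_config()]).
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  tips <- tree$tip.label
  ingroup <- unlist(config$ingroup_phyla, use.names = FALSE)
  mrca <- ape::getMRCA(tree, ingroup)
  root <- length(tips) + 1L
  focal <- config$focal_genome
  unannot_p <- function(tip) {
    p <- config$unannotated_prob
    if (!is.null(names(p))) {
      if (tip %in% names(p)) unname(p[tip]) else 0
    } else p
  }
  rlen <- function(range) sample(range[1]:range[2], 1)

  fam_ids <- c(sprintf("pan%02d", seq_len(config$n_pan)),
               sprintf("cls%02d", seq_len(config$n_clade_specific)),
               sprintf("chi%02d", seq_len(config$n_chimera)),
               sprintf("fst%02d", seq_len(config$n_fast)))
  fam_class <- c(rep("pan", config$n_pan),
                 rep("clade_specific", config$n_clade_specific),
                 rep("chimera", config$n_chimera),
                 rep("fast", config$n_fast))

  proteome_rows <- setNames(lapply(tips, function(x) list()), tips)
  scaffold_rows <- setNames(lapply(tips, function(x) list()), tips)
  decoy_rows <- list()
  truth <- list()
  status_rows <- list()
  ann_rows <- list()

  for (fi in seq_along(fam_ids)) {
    fam <- fam_ids[fi]; cls <- fam_class[fi]
    rho <- if (cls == "fast") config$fast_rho else 1
    lost <- draw_losses(tree, root, config$loss_prob)
    domain_len <- NA_integer_
    if (cls == "chimera") {
      dlen <- rlen(config$domain_len_range)
      llen <- rlen(config$linker_len_range)
      mlen <- rlen(config$motif_len_range)
      domain_root <- random_protein(dlen)
      dom_tips <- evolve_down(tree, root, domain_root, 1, lost)
      # blocks born at the clade ancestor evolve only below it; recover the
      # domain state at the ancestor by replaying the root->ancestor path
      motif_anc <- random_protein(mlen)
      linker_anc <- random_protein(llen)
      motif_tips <- evolve_down(tree, mrca, motif_anc, 1, lost)
      linker_tips <- evolve_down(tree, mrca, linker_anc, config$linker_rho,
                                 lost)
      seqs <- list()
      for (tp in names(dom_tips)) {
        seqs[[tp]] <- if (tp %in% ingroup && !is.null(motif_tips[[tp]]))
          paste0(dom_tips[[tp]], linker_tips[[tp]], motif_tips[[tp]])
        else dom_tips[[tp]]
      }
      domain_len <- dlen
      decoy_rows[[length(decoy_rows) + 1]] <- data.frame(
        seq_id = paste0(fam, "_dbdom"),
        residues = evolve_sequence(domain_root, 0.25, 1),
        taxon = "ecdysozoa", stringsAsFactors = FALSE)
      decoy_rows[[length(decoy_rows) + 1]] <- data.frame(
        seq_id = paste0(fam, "_dbfull"),
        residues = evolve_sequence(
          paste0(dom_tips[[focal]] %||% domain_root, linker_anc, motif_anc),
          0.2, 1),
        taxon = "annelid", stringsAsFactors = FALSE)
    } else {
      len <- rlen(config$len_range)
      founder <- random_protein(len)
      birth <- if (cls == "clade_specific") mrca else root
      seqs <- evolve_down(tree, birth, founder, rho, lost)
      decoy_rows[[length(decoy_rows) + 1]] <- data.frame(
        seq_id = paste0(fam, "_db"),
        residues = evolve_sequence(founder, 0.25, rho),
        taxon = if (cls == "clade_specific") "mollusc" else "ecdysozoa",
        stringsAsFactors = FALSE)
    }

    carried <- names(seqs)
    for (tp in sort(tips)) {
      if (!tp %in% carried) {
        if (tp %in% ingroup || cls != "clade_specific")
          status_rows[[length(status_rows) + 1]] <- data.frame(
            family = fam, tip = tp, status = "lost", scaffold_id = NA,
            frame = NA_integer_, aa_start = NA_integer_,
            stringsAsFactors = FALSE)
        next
      }
      unannotated <- tp %in% ingroup && tp != focal &&
        runif(1) < unannot_p(tp)
      if (unannotated) {
        cds <- reverse_translate(seqs[[tp]])
        flank1 <- rlen(c(150L, 300L))
        flank2 <- rlen(c(150L, 300L))
        fwd <- runif(1) < 0.5
        scaffold <- if (fwd)
          paste0(random_dna(flank1), cds, random_dna(flank2))
        else paste0(random_dna(flank1), revcomp(cds), random_dna(flank2))
        frame <- if (fwd) (flank1 %% 3L) + 1L else -((flank2 %% 3L) + 1L)
        aa_start <- (if (fwd) flank1 else flank2) %/% 3L + 1L
        sid <- paste0("scf_", fam, "_", tp)
        scaffold_rows[[tp]][[length(scaffold_rows[[tp]]) + 1]] <-
          data.frame(seq_id = sid, residues = scaffold,
                     stringsAsFactors = FALSE)
        status_rows[[length(status_rows) + 1]] <- data.frame(
          family = fam, tip = tp, status = "unannotated", scaffold_id = sid,
          frame = frame, aa_start = aa_start, stringsAsFactors = FALSE)
      } else {
        proteome_rows[[tp]][[length(proteome_rows[[tp]]) + 1]] <-
          data.frame(seq_id = paste0(fam, "_", tp),
                     residues = seqs[[tp]], stringsAsFactors = FALSE)
        status_rows[[length(status_rows) + 1]] <- data.frame(
          family = fam, tip = tp, status = "carried", scaffold_id = NA,
          frame = NA_integer_, aa_start = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    truth[[fi]] <- data.frame(family = fam, class = cls,
                              domain_len = domain_len,
                              stringsAsFactors = FALSE)
    if (cls == "chimera" && focal %in% carried)
      ann_rows[[length(ann_rows) + 1]] <- data.frame(
        gene_id = paste0(fam, "_", focal), start = 1L, end = domain_len,
        domain_id = paste0("ancdom_", fam), is_extraclade_domain = TRUE,
        stringsAsFactors = FALSE)
  }

  status <- do.call(rbind, status_rows)
  truth <- do.call(rbind, truth)
  truth <- add_expectations(truth, status, config)

  proteomes <- lapply(sort(tips), function(tp) {
    rows <- do.call(rbind, proteome_rows[[tp]])
    if (is.null(rows))
      rows <- data.frame(seq_id = character(), residues = character())
    seq_records(rows$seq_id, rows$residues, tp, "protein")
  })
  names(proteomes) <- sort(tips)
  genome_dna <- list()
  for (tp in sort(tips)) {
    rows <- do.call(rbind, scaffold_rows[[tp]])
    if (!is.null(rows))
      genome_dna[[tp]] <- seq_records(rows$seq_id, rows$residues, tp, "dna")
  }
  decoy <- do.call(rbind, decoy_rows)
  exclusion_db <- list(
    records = seq_records(decoy$seq_id, decoy$residues, "decoy_db",
                          "protein"),
    taxa = data.frame(seq_id = decoy$seq_id, taxon = decoy$taxon,
                      stringsAsFactors = FALSE))
  scfg <- screen_config(
    focal_genome = focal, ingroup_phyla = config$ingroup_phyla,
    outgroup_genomes = config$outgroup_genomes,
    exclusion_dbs = list(list(name = "decoy_db", path = NA, taxa = NA)),
    clade_taxa = c(names(config$ingroup_phyla), ingroup, "spiralia"))
  structure(list(proteomes = proteomes, genome_dna = genome_dna,
                 exclusion_db = exclusion_db, truth = truth,
                 tip_status = status, annotations = do.call(rbind, ann_rows),
                 screen_config = scfg, sim_config = config),
            class = "trg_simulation")
}

# Structural screen expectations from the planted truth: a family is
# screened when the focal tip carries it annotated; it passes the ingroup
# criterion when every phylum has a non-focal member carrying it (annotated,
# or unannotated -- scaffold DNA is always emitted for those); pan and
# chimera families are disqualified by construction (outgroup carriers
# and/or an extra-clade decoy entry). Fast families evolve too fast for
# their homology to be detectable; their expected outcome is recorded as
# rejected_ingroup but they are scored separately.
add_expectations <- function(truth, status, config) {
  focal <- config$focal_genome
  get_status <- function(fam, tp) {
    s <- status$status[status$family == fam & status$tip == tp]
    if (length(s)) s else "lost"
  }
  truth$screened <- vapply(truth$family, function(f)
    get_status(f, focal) == "carried", logical(1))
  truth$expected_pass_ingroup <- vapply(truth$family, function(f) {
    all(vapply(config$ingroup_phyla, function(members) {
      members <- setdiff(members, focal)
      any(vapply(members, function(tp)
        get_status(f, tp) %in% c("carried", "unannotated"), logical(1)))
    }, logical(1)))
  }, logical(1))
  # stage order matters: a family failing the ingroup criterion is reported
  # as rejected_ingroup even when outgroup evidence would also disqualify it
  truth$expected_verdict <- ifelse(
    !truth$screened, NA_character_,
    ifelse(!truth$expected_pass_ingroup & truth$class != "fast",
           "rejected_ingroup",
           ifelse(truth$class %in% c("pan", "chimera"), "rejected_outgroup",
                  ifelse(truth$class == "fast", "rejected_ingroup",
                         "lineage_specific"))))
  truth$expected_novelty <- ifelse(truth$class == "clade_specific",
                                   "fully_novel",
                                   ifelse(truth$class == "chimera",
                                          "chimeric", NA_character_))
  truth
}

#' Write a simulation to disk as plain-text artifacts
#'
#' Emits one protein FASTA per genome, one scaffold FASTA per genome with
#' unannotated embeddings, the decoy database FASTA plus its taxon-label
#' TSV, the truth and tip-status TSVs, and the domain-annotation TSV.
#'
#' @param sim a [simulate_clade()] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  for (tp in names(sim$proteomes)) {
    if (nrow(sim$proteomes[[tp]]) == 0) next
    f <- file.path(outdir, paste0(tp, ".faa"))
    write_fasta(sim$proteomes[[tp]], f)
    files[paste0("proteome_", tp)] <- f
  }
  for (tp in names(sim$genome_dna)) {
    f <- file.path(outdir, paste0(tp, ".fna"))
    write_fasta(sim$genome_dna[[tp]], f)
    files[paste0("dna_", tp)] <- f
  }
  f <- file.path(outdir, "decoy_db.faa")
  write_fasta(sim$exclusion_db$records, f)
  files["decoy_db"] <- f
  f <- file.path(outdir, "decoy_db_taxa.tsv")
  utils::write.table(sim$exclusion_db$taxa, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files["decoy_taxa"] <- f
  f <- file.path(outdir, "truth.tsv")
  utils::write.table(sim$truth, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["truth"] <- f
  f <- file.path(outdir, "tip_status.tsv")
  utils::write.table(sim$tip_status, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["tip_status"] <- f
  if (!is.null(sim$annotations)) {
    f <- file.path(outdir, "domain_annotations.tsv")
    utils::write.table(sim$annotations, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["annotations"] <- f
  }
  files
}
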