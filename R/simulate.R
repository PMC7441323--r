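#' Default species tree for the simulated clade
#'
#' Eight ingroup tips grouped into three phyla ({mollusc: cgig, lgig},
#' {annelid: ctel, hrob}, {flatworm: sman, smed, emul, hmic}) and ten
#' outgroup tips, with branch lengths in expected substitutions per site.
#' Ingroup branch lengths are set so ortholog divergence stays well inside
#' the screen's detection range at the default protein lengths, while the
#' root-to-outgroup paths leave pan-clade orthologs diverged but still
#' detectable.
#'
#' @return an \code{ape} \code{phylo} tree.
#' @export
default_species_tree <- function() {
  ingroup <- paste0("((cgig:0.10,lgig:0.10):0.08,((ctel:0.10,hrob:0.10):0.08,",
                    "((sman:0.08,smed:0.08):0.05,(emul:0.08,hmic:0.08):0.05)",
                    ":0.08):0.03):0.30")
  outgroup <- paste0("(cele:0.32,(dmel:0.32,(amel:0.32,(mmus:0.32,",
                     "(xlae:0.32,(cint:0.32,(hmag:0.34,(atha:0.36,",
                     "(ddis:0.36,mbre:0.36):0.02):0.02):0.02):0.02):0.02)",
                     ":0.02):0.02):0.02):0.20")
  ape::read.tree(text = sprintf("(%s,%s);", ingroup, outgroup))
}

DEFAULT_PHYLA <- list(mollusc = c("cgig", "lgig"),
                      annelid = c("ctel", "hrob"),
                      flatworm = c("sman", "smed", "emul", "hmic"))
DEFAULT_OUTGROUPS <- c("cele", "dmel", "amel", "mmus", "xlae",
                       "cint", "hmag", "atha", "ddis", "mbre")

#' Configure a clade-proteome simulation
#'
#' Defines the study conditions for the synthetic clade: the species tree,
#' the phylum grouping, and the planted gene families with known ground
#' truth. Family classes: \code{pan} (born at the root, present clade-wide
#' and beyond), \code{clade_specific} (born on the branch leading to the
#' clade ancestor, absent outside), \code{chimera} (an ancient root-born
#' domain fused, in ingroup tips only, to a clade-born motif via a
#' fast-evolving linker), and \code{fast} (root-born but evolving at
#' \code{fast_rho} times the base rate, emulating homology-detection
#' failure).
#'
#' @param tree species tree (\code{phylo}); tips must equal the ingroup plus
#'   outgroup genomes.
#' @param ingroup_phyla named list phylum -> tip labels.
#' @param outgroup_genomes outgroup tip labels.
#' @param focal_genome the screened tip.
#' @param n_pan,n_clade_specific,n_chimera,n_fast family counts.
#' @param fast_rho rate multiplier for \code{fast} families.
#' @param linker_rho rate multiplier for the chimera linker.
#' @param loss_prob per-branch probability that a family is lost in the
#'   subtree below that branch.
#' @param unannotated_prob probability that a carried ingroup (non-focal)
#'   gene is dropped from the proteome but embedded, reverse-translated, in
#'   scaffold DNA.
#' @param len_range protein length range for single-block families.
#' @param domain_len_range,motif_len_range,linker_len_range chimera block
#'   lengths.
#' @param seed integer fixing all randomness end to end.
#' @return object of class \code{sim_config}.
#' @export
simulation_config <- function(tree = default_species_tree(),
                              ingroup_phyla = DEFAULT_PHYLA,
                              outgroup_genomes = DEFAULT_OUTGROUPS,
                              focal_genome = "cgig",
                              n_pan = 5L, n_clade_specific = 5L,
                              n_chimera = 2L, n_fast = 2L,
                              fast_rho = 8, linker_rho = 6,
                              loss_prob = 0.05, unannotated_prob = 0.05,
                              len_range = c(120L, 300L),
                              domain_len_range = c(80L, 140L),
                              motif_len_range = c(60L, 100L),
                              linker_len_range = c(15L, 25L),
                              seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  members <- unlist(ingroup_phyla, use.names = FALSE)
  if (anyDuplicated(members)) stop("phyla must partition the ingroup tips")
  if (!setequal(tips, c(members, outgroup_genomes)))
    stop("tree tips must equal ingroup plus outgroup genomes")
  if (!focal_genome %in% members) stop("focal genome must be an ingroup tip")
  for (p in c(loss_prob, unannotated_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  structure(list(tree = tree, ingroup_phyla = ingroup_phyla,
                 outgroup_genomes = outgroup_genomes,
                 focal_genome = focal_genome,
                 n_pan = n_pan, n_clade_specific = n_clade_specific,
                 n_chimera = n_chimera, n_fast = n_fast,
                 fast_rho = fast_rho, linker_rho = linker_rho,
                 loss_prob = loss_prob, unannotated_prob = unannotated_prob,
                 len_range = len_range,
                 domain_len_range = domain_len_range,
                 motif_len_range = motif_len_range,
                 linker_len_range = linker_len_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_protein <- function(n)
  paste(sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND), collapse = "")

#' Evolve a protein sequence along a branch
#'
#' Per-site substitution under a stationary F81-style exchangeability model
#' over the background amino-acid frequencies: each site experiences an
#' event with probability \eqn{1 - e^{-\rho t}} and then redraws its residue
#' from the background distribution (possibly unchanged). For a parent at
#' the stationary composition the expected fraction of differing sites is
#' \eqn{(1 - e^{-\rho t})(1 - \sum_a f_a^2)}, a monotone function of
#' \eqn{\rho t}; \eqn{t = 0} returns the parent unchanged. Randomness comes
#' from the R session RNG, so a fixed seed fixes the output.
#'
#' @param parent protein string.
#' @param t branch length (expected substitutions per site), >= 0.
#' @param rho rate multiplier, > 0.
#' @return the evolved protein string.
#' @export
evolve_sequence <- function(parent, t, rho = 1) {
  stopifnot(t >= 0, rho > 0)
  if (t == 0) return(parent)
  chars <- strsplit(parent, "")[[1]]
  hit <- runif(length(chars)) < (1 - exp(-rho * t))
  if (any(hit))
    chars[hit] <- sample(AA20, sum(hit), replace = TRUE,
                         prob = AA_BACKGROUND)
  paste(chars, collapse = "")
}

# Evolve a sequence from `node` down to the tips, honoring a per-child-node
# loss map (losses remove whole subtrees). Returns named list tip -> string.
evolve_down <- function(tree, node, seq, rho, lost) {
  ntip <- length(tree$tip.label)
  out <- list()
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (!length(kids)) return(setNames(list(seq), tree$tip.label[node]))
  for (child in kids) {
    if (isTRUE(lost[[as.character(child)]])) next
    bl <- tree$edge.length[tree$edge[, 1] == node & tree$edge[, 2] == child]
    child_seq <- evolve_sequence(seq, bl, rho)
    if (child <= ntip) {
      out[[tree$tip.label[child]]] <- child_seq
    } else {
      out <- c(out, evolve_down(tree, child, child_seq, rho, lost))
    }
  }
  out
}

# Draw per-branch losses below `node` (each descendant branch independently
# kills its subtree with prob loss_prob), as a named logical by child node.
draw_losses <- function(tree, node, loss_prob) {
  below <- function(n) {
    kids <- tree$edge[tree$edge[, 1] == n, 2]
    unlist(lapply(kids, function(k) c(k, below(k))))
  }
  nodes <- below(node)
  setNames(as.list(runif(length(nodes)) < loss_prob), as.character(nodes))
}

reverse_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    codons <- names(code)[code == a]
    codons[sample.int(length(codons), 1)]
  }, character(1)), collapse = "")
}

revcomp <- function(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
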