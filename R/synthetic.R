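# Background amino-acid composition used for decoys and reference
# stand-ins (approximate UniProt/Swiss-Prot frequencies, percent).
AA_BACKGROUND <- c(
  A = 8.26, R = 5.53, N = 4.06, D = 5.46, C = 1.37, Q = 3.93, E = 6.72,
  G = 7.08, H = 2.27, I = 5.93, L = 9.65, K = 5.80, M = 2.41, F = 3.86,
  P = 4.72, S = 6.63, T = 5.35, W = 1.09, Y = 2.92, V = 6.87)

# Aerobic-form residues at the five panel sites (the human states of the
# survey); used as the default VARIANT allele in simulations.
AEROBIC_VARIANTS <- c("COQ2:204" = "F", "COQ2:243" = "A", "MEV1:71" = "I",
                      "TDO2:133" = "A", "ETFDH:437" = "C")

random_protein <- function(n) {
  paste(sample(names(AA_BACKGROUND), n, replace = TRUE,
               prob = AA_BACKGROUND), collapse = "")
}

#' Simulation configuration
#'
#' Controls the synthetic proteomes: background divergence applied to the
#' planted marker homologs, decoy count and sizes, and the protected window
#' around diagnostic sites that indels may not disturb. Identical
#' configurations give byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param substitution_rate per-residue substitution probability applied to
#'   marker homologs outside the protected windows.
#' @param indel_rate per-position indel initiation probability.
#' @param indel_mean_length mean indel length (geometric, minimum 1).
#' @param n_decoys number of unrelated background proteins per proteome.
#' @param decoy_length_range length range (uniform) for decoys.
#' @param protect_window half-width (columns) of the indel-free window
#'   around each diagnostic site; 0 exposes the sites to indels.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, substitution_rate = 0.02, indel_rate = 0,
                       indel_mean_length = 2, n_decoys = 20L,
                       decoy_length_range = c(80L, 400L), protect_window = 2L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, indel_mean_length >= 1,
            n_decoys >= 0, length(decoy_length_range) == 2L,
            protect_window >= 0)
  structure(list(seed = as.integer(seed), substitution_rate = substitution_rate,
                 indel_rate = indel_rate, indel_mean_length = indel_mean_length,
                 n_decoys = as.integer(n_decoys),
                 decoy_length_range = as.integer(decoy_length_range),
                 protect_window = as.integer(protect_window)),
            class = "sim_config")
}

#' Synthetic reference proteins for the marker panel
#'
#' Random proteins long enough to host their diagnostic sites, with the
#' anaerobic residues planted at the exact reference positions — download-free
#' stand-ins for the real C. elegans reference accessions. The stand-ins are
#' synthetic: everything outside the diagnostic positions is background
#' composition, not biological sequence.
#'
#' @param seed integer RNG seed.
#' @param lengths named lengths of the four stand-ins.
#' @return named character vector of protein strings, suitable for
#'   `default_panel(reference_sequences = ...)`.
#' @export
make_reference_set <- function(seed = 1L,
                               lengths = c(COQ2 = 370L, MEV1 = 260L,
                                           TDO2 = 300L, ETFDH = 620L)) {
  panel <- default_panel()
  with_seed(seed, {
    refs <- vapply(names(panel), function(id) {
      s <- strsplit(random_protein(lengths[[id]]), "")[[1]]
      st <- panel[[id]]$sites
      s[st$position] <- st$anaerobic_residue
      paste(s, collapse = "")
    }, "")
    refs
  })
}

#' Genotypes over the five panel sites
#'
#' A genotype is a named character vector giving the residue intended at
#' each panel site. `genotype_anaerobic()` plants the anaerobic residue
#' everywhere; `genotype_aerobic()` plants the aerobic (human-like)
#' variants; `genotype_from_binary()` mixes the two from a logical vector
#' (`TRUE` = anaerobic) in panel site order.
#'
#' @param panel a `"marker_panel"`.
#' @return named character vector (site label -> residue).
#' @export
genotype_anaerobic <- function(panel = default_panel()) {
  setNames(unlist(lapply(panel, function(m) m$sites$anaerobic_residue),
                  use.names = FALSE), panel_site_labels(panel))
}

#' @rdname genotype_anaerobic
#' @export
genotype_aerobic <- function(panel = default_panel()) {
  AEROBIC_VARIANTS[panel_site_labels(panel)]
}

#' @rdname genotype_anaerobic
#' @param bits logical vector of length 5 (`TRUE` = anaerobic residue).
#' @export
genotype_from_binary <- function(bits, panel = default_panel()) {
  stopifnot(length(bits) == length(panel_site_labels(panel)))
  ana <- genotype_anaerobic(panel); aer <- genotype_aerobic(panel)
  setNames(ifelse(bits, ana, aer), names(ana))
}

genotype_states <- function(genotype, panel = default_panel()) {
  ana <- genotype_anaerobic(panel)
  ifelse(genotype[names(ana)] == ana, "ANAEROBIC_MATCH", "VARIANT")
}

# Apply background divergence to a marker homolog: substitutions anywhere
# outside the protected windows, indels likewise (deletions stop at a
# protected window boundary so planted sites survive unless protect_window
# is 0).
mutate_homolog <- function(seqstr, positions, config) {
  ch <- strsplit(seqstr, "")[[1]]
  n <- length(ch)
  protected <- rep(FALSE, n)
  for (p in positions) {
    lo <- max(1L, p - config$protect_window)
    hi <- min(n, p + config$protect_window)
    protected[lo:hi] <- TRUE
  }
  if (config$substitution_rate > 0) {
    hit <- which(runif(n) < config$substitution_rate & !protected)
    for (i in hit) {
      alt <- setdiff(names(AA_BACKGROUND), ch[i])
      ch[i] <- sample(alt, 1L, prob = AA_BACKGROUND[alt])
    }
  }
  if (config$indel_rate > 0) {
    p_geom <- 1 / config$indel_mean_length
    out <- character(0)
    i <- 1L
    while (i <= n) {
      if (!protected[i] && runif(1) < config$indel_rate) {
        len <- 1L + rgeom(1L, p_geom)
        if (runif(1) < 0.5) {  # insertion before position i
          ins <- sample(names(AA_BACKGROUND), len, replace = TRUE,
                        prob = AA_BACKGROUND)
          out <- c(out, ins, ch[i])
          i <- i + 1L
        } else {               # deletion, truncated at protected windows
          stop_at <- i
          while (stop_at < n && stop_at - i + 1L < len &&
                 !protected[stop_at + 1L]) stop_at <- stop_at + 1L
          i <- stop_at + 1L
        }
      } else {
        out <- c(out, ch[i])
        i <- i + 1L
      }
    }
    ch <- out
  }
  paste(ch, collapse = "")
}

#' Synthetic proteome with a planted marker genotype
#'
#' Builds one mutated homolog per marker — the genotype's residues planted
#' at the reference positions, background substitutions and indels applied
#' outside the protected windows — shuffled among unrelated decoy proteins.
#' The truth table records which record carries each marker and the planted
#' per-site states.
#'
#' @param genotype named residue vector, see [genotype_anaerobic()].
#' @param config a [sim_config()].
#' @param references named protein vector from [make_reference_set()] (or
#'   real reference sequences).
#' @param panel a `"marker_panel"`.
#' @return list with `records` (a [read_fasta()]-style data.frame) and
#'   `truth` (data.frame: `marker`, `record_id`, `site`, `planted_residue`,
#'   `planted_state`).
#' @export
make_proteome <- function(genotype, config = sim_config(),
                          references = make_reference_set(),
                          panel = default_panel()) {
  labels <- panel_site_labels(panel)
  stopifnot(all(labels %in% names(genotype)))
  with_seed(config$seed, {
    homologs <- lapply(names(panel), function(id) {
      st <- panel[[id]]$sites
      ch <- strsplit(references[[id]], "")[[1]]
      ch[st$position] <- genotype[paste0(id, ":", st$position)]
      mutate_homolog(paste(ch, collapse = ""), st$position, config)
    })
    names(homologs) <- names(panel)
    decoys <- if (config$n_decoys > 0)
      vapply(seq_len(config$n_decoys), function(i)
        random_protein(sample(config$decoy_length_range[1]:
                              config$decoy_length_range[2], 1L)), "")
      else character(0)
    seqs <- c(unlist(homologs), decoys)
    roles <- c(names(homologs), rep(NA_character_, length(decoys)))
    ord <- sample(seq_along(seqs))
    ids <- sprintf("prot%03d", seq_along(seqs))
    records <- data.frame(id = ids, description = "",
                          sequence = unname(seqs[ord]), stringsAsFactors = FALSE)
    roles <- roles[ord]
    states <- genotype_states(genotype, panel)
    truth <- do.call(rbind, lapply(names(panel), function(id) {
      st <- panel[[id]]$sites
      lab <- paste0(id, ":", st$position)
      data.frame(marker = id, record_id = ids[which(roles == id)],
                 site = lab, planted_residue = unname(genotype[lab]),
                 planted_state = unname(states[lab]), stringsAsFactors = FALSE)
    }))
    list(records = records, truth = truth)
  })
}

#' Reverse-translate a protein into a synthetic nucleotide contig
#'
#' Chooses uniformly among synonymous codons of the standard genetic code,
#' adds random flanking sequence, and places the open reading frame on the
#' requested strand and frame so that [six_frame_translate()] recovers the
#' protein in exactly one frame.
#'
#' @param protein protein string.
#' @param strand `"+"` or `"-"`.
#' @param frame_offset 0, 1 or 2 (frame `+1`/`+2`/`+3` before any strand
#'   flip).
#' @param seed integer RNG seed.
#' @param id record id for the contig.
#' @param flank_range range of random flank lengths.
#' @return a one-row [read_fasta()]-style data.frame.
#' @export
make_contig <- function(protein, strand = c("+", "-"), frame_offset = 0L,
                        seed = 1L, id = "contig", flank_range = c(10L, 60L)) {
  strand <- match.arg(strand)
  stopifnot(frame_offset %in% 0:2)
  protein <- check_protein(protein, "protein", allow_x = FALSE)
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  with_seed(seed, {
    codons <- vapply(strsplit(protein, "")[[1]], function(aa) {
      opts <- by_aa[[aa]]
      opts[sample.int(length(opts), 1L)]
    }, "")
    left_n <- sample(flank_range[1]:flank_range[2], 1L)
    left_n <- left_n - (left_n %% 3L) + frame_offset  # ORF starts in frame
    right_n <- sample(flank_range[1]:flank_range[2], 1L)
    flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
    nt <- paste0(flank(left_n), paste(codons, collapse = ""), flank(right_n))
    if (strand == "-") nt <- reverse_complement(nt)
    data.frame(id = id, description = "", sequence = nt,
               stringsAsFactors = FALSE)
  })
}

#' Evolve marker genotypes along a species tree
#'
#' Starting from a root genotype, each site toggles between its anaerobic
#' and variant residue independently on every branch with probability
#' `flip_prob` — the simplest gain/loss model for the binary presence of
#' the RQ signature. Optionally materializes a proteome per tip.
#'
#' @param tree a rooted bifurcating `"phylo"` tree.
#' @param root_genotype named residue vector at the root.
#' @param flip_prob per-branch, per-site state-flip probability in `[0, 1)`.
#' @param config a [sim_config()]; its seed drives the whole simulation.
#' @param references,panel passed to [make_proteome()] when
#'   `materialize = TRUE`.
#' @param materialize also generate tip proteomes (slower).
#' @return list with `tip_genotypes` (tips x sites residue matrix),
#'   `tip_states` (logical matrix, `TRUE` = anaerobic),
#'   `node_states` (internal nodes x sites, the simulation truth),
#'   and `proteomes` (named list, when materialized).
#' @export
evolve_on_tree <- function(tree, root_genotype = genotype_anaerobic(),
                           flip_prob = 0.05, config = sim_config(),
                           references = make_reference_set(),
                           panel = default_panel(), materialize = FALSE) {
  stopifnot(flip_prob >= 0, flip_prob < 1)
  tree <- prepare_tree(tree)
  labels <- panel_site_labels(panel)
  ana <- genotype_anaerobic(panel)
  variant <- setNames(ifelse(root_genotype[labels] == ana, AEROBIC_VARIANTS[labels],
                             root_genotype[labels]), labels)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  with_seed(config$seed, {
    states <- matrix(NA, nnode, length(labels),
                     dimnames = list(NULL, labels))
    states[root, ] <- root_genotype[labels] == ana
    # reversed postorder = preorder: a parent's state exists when used
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    edges <- edges[rev(seq_len(nrow(edges))), , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1L]; child <- edges[e, 2L]
      flips <- runif(length(labels)) < flip_prob
      states[child, ] <- xor(states[parent, ], flips)
    }
    tip_states <- states[seq_len(ntip), , drop = FALSE]
    rownames(tip_states) <- tree$tip.label
    tip_genotypes <- t(apply(tip_states, 1L, function(b)
      ifelse(b, ana, variant)))
    colnames(tip_genotypes) <- labels
    proteomes <- NULL
    if (materialize) {
      seeds <- sample.int(.Machine$integer.max, ntip)
      proteomes <- lapply(seq_len(ntip), function(i) {
        cfg <- config
        cfg$seed <- seeds[i]
        make_proteome(setNames(tip_genotypes[i, ], labels), cfg,
                      references, panel)
      })
      names(proteomes) <- tree$tip.label
    }
    node_states <- states[(ntip + 1L):nnode, , drop = FALSE]
    rownames(node_states) <- as.character((ntip + 1L):nnode)
    list(tip_genotypes = tip_genotypes, tip_states = tip_states,
         node_states = node_states, proteomes = proteomes)
  })
}
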