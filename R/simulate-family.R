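# Synthetic gene-family generator
#
# Emits a complete, internally consistent bundle -- genome, gene models,
# proteins, true alignment, phylogeny -- with machine-readable planted truth,
# emulating a plant UDP-glycosyltransferase-like family: a duplicated family
# carrying a conserved 44-residue C-terminal motif (PSPG-box-like), planted
# intron-insertion events at known alignment columns and phases, and genes
# distributed over chromosomes on both strands.

# 44-residue PSPG-box-like consensus used as the default query motif
PSPG_MOTIF <- "WAPQVLILSHPSVGGFLTHCGWNSTLESVSAGVPMITWPLFAEQ"

#' Specification for a synthetic gene family
#'
#' Bundles every tunable of [simulate_family()] with validation. Defaults
#' emulate a UGT-like family: 168 members in 16 groups (A-P) on 8
#' chromosomes, a conserved C-terminal 44-residue motif, ten planted
#' intron-insertion events with phase 1 dominant, and 43% intronless members.
#'
#' @param n_family_genes number of family members.
#' @param n_decoy_proteins number of motif-free decoy proteins added to the
#'   emitted proteome.
#' @param group_labels character vector of phylogenetic group labels; genes
#'   are split over the groups as evenly as possible (or per `group_sizes`).
#' @param group_sizes optional integer vector (same length as `group_labels`)
#'   of members per group; must sum to `n_family_genes`.
#' @param protein_length family protein length in residues (pre-indel).
#' @param motif 44-residue consensus motif planted near the C-terminus of
#'   every family protein.
#' @param planted_events tibble/data.frame with columns `column` (1-based
#'   alignment column in the pre-indel coordinate system), `phase` (0/1/2)
#'   and `groups` (list-column of carrier group labels, or the string
#'   `"all"`). Columns must be pairwise >= 3 apart.
#' @param intronless_fraction fraction of family genes forced intronless,
#'   in `[0, 1]`.
#' @param n_chromosomes number of chromosomes genes are distributed over.
#' @param intron_length_range nt interval introns are drawn from (uniform).
#' @param substitution_rate expected substitutions per site per unit branch
#'   length along the family tree.
#' @param indel_mode if `TRUE`, every other group receives a group-specific
#'   5-residue insertion so the true alignment contains gap blocks; stresses
#'   intron-to-alignment projection. Default `FALSE` (true MSA equals the raw
#'   sequences).
#' @param tandem_clusters if `TRUE`, group members are laid down as adjacent
#'   blocks on a chromosome (tandem-duplication-like clustering); default
#'   `FALSE` distributes genes round-robin.
#' @return object of class `family_sim_spec`.
#' @export
family_sim_spec <- function(n_family_genes = 168,
                            n_decoy_proteins = 500,
                            group_labels = LETTERS[1:16],
                            group_sizes = NULL,
                            protein_length = 480,
                            motif = PSPG_MOTIF,
                            planted_events = default_planted_events(group_labels),
                            intronless_fraction = 0.43,
                            n_chromosomes = 8,
                            intron_length_range = c(80, 2000),
                            substitution_rate = 0.3,
                            indel_mode = FALSE,
                            tandem_clusters = FALSE) {
  if (nchar(motif) != 44) {
    abort(sprintf("motif must be exactly 44 residues (got %d)", nchar(motif)))
  }
  if (n_family_genes < 1 || n_decoy_proteins < 0 || n_chromosomes < 1) {
    abort("all counts must be positive")
  }
  if (intronless_fraction < 0 || intronless_fraction > 1) {
    abort("intronless_fraction must lie in [0, 1]")
  }
  if (protein_length < nchar(motif) + 20) {
    abort("protein_length too short to host the motif")
  }
  if (is.null(group_sizes)) {
    base <- n_family_genes %/% length(group_labels)
    extra <- n_family_genes %% length(group_labels)
    group_sizes <- rep(base, length(group_labels)) +
      c(rep(1, extra), rep(0, length(group_labels) - extra))
  }
  if (sum(group_sizes) != n_family_genes) {
    abort("group_sizes must sum to n_family_genes")
  }
  ev <- as_tibble(planted_events)
  if (nrow(ev) > 0) {
    if (any(ev$column > protein_length)) {
      abort("planted event column beyond protein_length")
    }
    if (any(ev$column < 1) || any(ev$column == 1 & ev$phase == 0)) {
      abort("planted event would fall before the first coding base")
    }
    if (!all(ev$phase %in% 0:2)) abort("event phase must be 0, 1 or 2")
    if (nrow(ev) > 1 && min(diff(sort(ev$column))) < 3) {
      abort("planted event columns must be pairwise >= 3 columns apart")
    }
  }
  structure(list(
    n_family_genes = n_family_genes, n_decoy_proteins = n_decoy_proteins,
    group_labels = group_labels, group_sizes = group_sizes,
    protein_length = protein_length, motif = motif,
    planted_events = ev, intronless_fraction = intronless_fraction,
    n_chromosomes = n_chromosomes, intron_length_range = intron_length_range,
    substitution_rate = substitution_rate, indel_mode = indel_mode,
    tandem_clusters = tandem_clusters
  ), class = "family_sim_spec")
}

#' Default planted intron-insertion events
#'
#' Ten events at well-separated alignment columns, phase 1 dominant (as in
#' plant UGT families, where the deepest conserved intron is phase 1), each
#' carried by a subset of groups.
#'
#' @param group_labels group labels the carrier subsets are drawn from.
#' @return tibble with columns `column`, `phase`, `groups` (list-column).
#' @export
default_planted_events <- function(group_labels = LETTERS[1:16]) {
  g <- group_labels
  nthg <- function(idx) list(g[idx[idx <= length(g)]])
  tibble(
    column = c(40L, 75L, 110L, 150L, 190L, 230L, 270L, 310L, 350L, 400L),
    phase  = c(0L, 1L, 1L, 1L, 1L, 0L, 1L, 2L, 1L, 1L),
    groups = c(nthg(1:2), nthg(3:5), nthg(2:4), nthg(5:8), nthg(1:12),
               nthg(9:12), nthg(6:10), nthg(13:14), nthg(11:16), nthg(14:16))
  )
}

# ladder (caterpillar) Newick over labels; tips get `tip_bl`, internals `int_bl`
caterpillar_newick <- function(labels, tip_bl, int_bl) {
  if (length(labels) == 1) {
    return(sprintf("%s:%g", labels, tip_bl))
  }
  out <- sprintf("%s:%g", labels[length(labels)], tip_bl)
  for (i in rev(seq_len(length(labels) - 1))) {
    out <- sprintf("(%s:%g,%s):%g", labels[i], tip_bl, out, int_bl)
  }
  out
}

# mutate a character-vector protein: each site substituted with prob p
mutate_protein <- function(chars, p, site_factor = rep(1, length(chars))) {
  hit <- runif(length(chars)) < p * site_factor
  if (any(hit)) {
    repl <- sample(AA20, sum(hit), replace = TRUE)
    same <- repl == chars[hit]
    while (any(same)) {
      repl[same] <- sample(AA20, sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  chars
}

# evolve sequences along a phylo tree from a root sequence;
# returns matrix tips x sites (character)
evolve_along_tree <- function(tree, root_chars, rate, site_factor) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- root_chars
  # preorder over edges (ape trees from read.tree are in a parent-first order
  # after reorder)
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    p <- min(1, rate * tree$edge.length[k])
    seqs[[child]] <- mutate_protein(seqs[[par]], p, site_factor)
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

# uniform synonymous back-translation of a protein (no stop codon appended,
# so translate(splice(cds)) round-trips exactly)
back_translate <- function(protein_chars) {
  codons <- lapply(protein_chars, function(aa) {
    cs <- CODON_TABLE[[aa]]
    cs[sample.int(length(cs), 1L)]
  })
  paste(unlist(codons), collapse = "")
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a complete synthetic gene family
#'
#' Generates a family of motif-carrying proteins evolved along a known tree,
#' back-translates them to CDS, plants intron-insertion events at known
#' alignment columns and phases, assembles chromosomes with genes on both
#' strands, and returns the genome, GFF3-ready gene models, proteome (family
#' plus motif-free decoys), true protein alignment and a full truth table.
#' Fixing the seed fixes every emitted byte.
#'
#' @param spec a [family_sim_spec()].
#' @param seed integer seed; all randomness flows from it via named
#'   substreams.
#' @return object of class `family_sim`: a list with elements `genome`
#'   (named character, one chromosome per element), `models` (tibble of CDS
#'   segments in transcription order), `proteins` (named character, family +
#'   decoys), `msa` (named character, true family alignment), `tree`
#'   (`phylo`), `truth_genes`, `truth_introns`, `truth_events` (tibbles) and
#'   `spec`.
#' @seealso [write_family_bundle()] to write the bundle to disk,
#'   [parse_gene_models()] to read it back.
#' @export
simulate_family <- function(spec = family_sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "family_sim_spec"))
  n <- spec$n_family_genes
  P <- spec$protein_length
  groups <- rep(spec$group_labels, times = spec$group_sizes)
  gene_ids <- sprintf("g%03d", seq_len(n))

  # --- tree: caterpillar backbone over groups, caterpillar clades within ----
  with_seed(substream_seed(seed, "tree"), {
    sub_news <- vapply(spec$group_labels, function(g) {
      members <- gene_ids[groups == g]
      caterpillar_newick(members, tip_bl = 0.1, int_bl = 0.05)
    }, character(1))
    newick <- if (length(sub_news) == 1) {
      paste0("(", sub_news, ");")
    } else {
      # attach each group clade with a 0.5 stem on a 0.5-branch backbone
      out <- sprintf("(%s):0.5", sub_news[length(sub_news)])
      for (i in rev(seq_len(length(sub_news) - 1))) {
        out <- sprintf("((%s):0.5,%s):0.5", sub_news[i], out)
      }
      paste0(out, ";")
    }
    tree <- ape::read.tree(text = newick)
  })

  # --- sequences: evolve from a motif-bearing root along the tree ----------
  motif_chars <- strsplit(spec$motif, "")[[1]]
  motif_start <- P - 44 - 10 + 1   # motif sits 10 residues before the C-term
  with_seed(substream_seed(seed, "sequences"), {
    root <- sample(AA20, P, replace = TRUE)
    root[motif_start:(motif_start + 43)] <- motif_chars
    site_factor <- rep(1, P)
    site_factor[motif_start:(motif_start + 43)] <- 0.1  # motif conserved
    fam_mat <- evolve_along_tree(tree, root, spec$substitution_rate, site_factor)
    fam_mat <- fam_mat[gene_ids, , drop = FALSE]
  })

  # --- optional indel mode: group-specific insertion blocks ----------------
  # Every other group receives a 5-residue insertion at a group-specific
  # point; in the true MSA all other rows carry a gap block there.
  msa_rows <- fam_mat                       # n x P, no gaps yet
  if (spec$indel_mode) {
    with_seed(substream_seed(seed, "indels"), {
      ins_groups <- spec$group_labels[seq_along(spec$group_labels) %% 2 == 1]
      event_cols <- spec$planted_events$column
      forbidden <- unique(c(outer(event_cols, -3:3, "+"),
                            motif_start:(motif_start + 43)))
      candidates <- setdiff(seq(20, P - 20), forbidden)
      ins_at <- sort(sample(candidates, length(ins_groups)))
      msa_list <- apply(msa_rows, 1, identity, simplify = FALSE)
      for (k in rev(seq_along(ins_groups))) {      # right-to-left keeps coords
        pos <- ins_at[k]
        block_rows <- groups == ins_groups[k]
        msa_list <- lapply(seq_along(msa_list), function(i) {
          row <- msa_list[[i]]
          piece <- if (block_rows[i]) sample(AA20, 5, replace = TRUE) else rep("-", 5)
          append(row, piece, after = pos)
        })
      }
      msa_rows <- do.call(rbind, msa_list)
      rownames(msa_rows) <- gene_ids
    })
  }
  msa <- setNames(apply(msa_rows, 1, paste, collapse = ""), gene_ids)
  proteins_fam <- setNames(gsub("-", "", msa, fixed = TRUE), gene_ids)

  # map pre-indel event columns to final alignment columns: inserted blocks
  # are exactly the columns carrying gaps (only non-carrier rows are gapped
  # there), so the original columns are the gap-free ones, in order
  orig_col_of <- if (spec$indel_mode) {
    which(colSums(msa_rows == "-") == 0)
  } else {
    seq_len(P)
  }

  # --- planted introns ------------------------------------------------------
  ev <- spec$planted_events
  n_events <- nrow(ev)
  with_seed(substream_seed(seed, "introns"), {
    n_intronless <- round(spec$intronless_fraction * n)
    intronless <- if (n_intronless > 0) sample(gene_ids, n_intronless) else character(0)
    truth_introns <- vector("list", n_events)
    for (k in seq_len(n_events)) {
      carrier_groups <- ev$groups[[k]]
      if (identical(carrier_groups, "all")) carrier_groups <- spec$group_labels
      carriers <- setdiff(gene_ids[groups %in% carrier_groups], intronless)
      if (length(carriers) == 0) next
      final_col <- orig_col_of[ev$column[k]]
      # anchor residue index in each carrier's ungapped protein
      r_idx <- vapply(carriers, function(g) {
        sum(msa_rows[g, seq_len(final_col)] != "-")
      }, integer(1))
      truth_introns[[k]] <- tibble(
        gene_id = carriers,
        event_id = sprintf("I-%d", k),    # provisional; renumbered below
        column = final_col,
        phase = ev$phase[k],
        anchor_residue = unname(r_idx),
        cds_offset = 3L * (unname(r_idx) - 1L) + ev$phase[k],
        length = sample(seq(spec$intron_length_range[1],
                            spec$intron_length_range[2]),
                        length(carriers), replace = TRUE)
      )
    }
    truth_introns <- dplyr::bind_rows(truth_introns)
  })
  # serial numbering I-k by alignment column rank
  if (nrow(truth_introns) > 0) {
    col_rank <- rank(sort(unique(truth_introns$column)))
    lut <- setNames(sprintf("I-%d", col_rank), sort(unique(truth_introns$column)))
    truth_introns$event_id <- unname(lut[as.character(truth_introns$column)])
    truth_introns <- dplyr::arrange(truth_introns, .data$gene_id, .data$cds_offset)
    truth_introns <- dplyr::group_by(truth_introns, .data$gene_id)
    truth_introns <- dplyr::mutate(truth_introns, ordinal = dplyr::row_number())
    truth_introns <- dplyr::ungroup(truth_introns)
  } else {
    truth_introns <- tibble(
      gene_id = character(0), event_id = character(0), column = integer(0),
      phase = integer(0), anchor_residue = integer(0), cds_offset = integer(0),
      length = integer(0), ordinal = integer(0))
  }
  truth_events <- truth_introns |>
    dplyr::group_by(.data$event_id, .data$column, .data$phase) |>
    dplyr::summarise(n_carriers = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$column)

  # --- back-translation and gene assembly ----------------------------------
  with_seed(substream_seed(seed, "cds"), {
    cds_seqs <- vapply(gene_ids, function(g) {
      back_translate(strsplit(proteins_fam[[g]], "")[[1]])
    }, character(1))
  })
  with_seed(substream_seed(seed, "assembly"), {
    strands <- sample(c("+", "-"), n, replace = TRUE)
    if (!any(strands == "-")) strands[n] <- "-"
    if (!any(strands == "+")) strands[1] <- "+"
    chrom_names <- sprintf("chr%02d", seq_len(spec$n_chromosomes))
    chrom_of <- if (spec$tandem_clusters) {
      # group blocks laid down consecutively, groups round-robin over chroms
      grp_chr <- setNames(
        chrom_names[(seq_along(spec$group_labels) - 1) %% spec$n_chromosomes + 1],
        spec$group_labels)
      unname(grp_chr[groups])
    } else {
      chrom_names[(seq_len(n) - 1) %% spec$n_chromosomes + 1]
    }

    models <- vector("list", n)
    chrom_seq <- setNames(rep("", spec$n_chromosomes), chrom_names)
    spacer <- 500L
    for (i in seq_len(n)) {
      gid <- gene_ids[i]
      cds <- cds_seqs[[gid]]
      tr_int <- truth_introns[truth_introns$gene_id == gid, , drop = FALSE]
      tr_int <- tr_int[order(tr_int$cds_offset), , drop = FALSE]
      # transcript-side exon bounds on the sense (mRNA) strand
      offsets <- tr_int$cds_offset
      seg_starts_cds <- c(0L, offsets) + 1L            # 1-based CDS coords
      seg_ends_cds <- c(offsets, nchar(cds))
      intron_seqs <- vapply(tr_int$length, function(L) {
        paste0("GT", random_dna(L - 4L), "AG")
      }, character(1))
      pieces <- character(0)
      sense <- ""
      a <- integer(0); b <- integer(0)   # exon bounds on sense gene sequence
      pos <- 0L
      for (k in seq_along(seg_starts_cds)) {
        exon <- substr(cds, seg_starts_cds[k], seg_ends_cds[k])
        a <- c(a, pos + 1L); b <- c(b, pos + nchar(exon))
        sense <- paste0(sense, exon); pos <- pos + nchar(exon)
        if (k <= length(intron_seqs)) {
          sense <- paste0(sense, intron_seqs[k]); pos <- pos + nchar(intron_seqs[k])
        }
      }
      G <- nchar(sense)
      chr <- chrom_of[i]
      o <- nchar(chrom_seq[[chr]]) + spacer + 1L
      placed <- if (strands[i] == "+") sense else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
      chrom_seq[[chr]] <- paste0(chrom_seq[[chr]], random_dna(spacer), placed)
      if (strands[i] == "+") {
        gstart <- o + a - 1L; gend <- o + b - 1L
      } else {
        gstart <- o + (G - b); gend <- o + (G - a)
      }
      models[[i]] <- tibble(
        gene_id = gid, chromosome = chr, strand = strands[i],
        exon = seq_along(a), start = gstart, end = gend
      )
    }
    # terminal spacer on every chromosome
    for (chr in chrom_names) {
      chrom_seq[[chr]] <- paste0(chrom_seq[[chr]], random_dna(spacer))
    }
  })
  models <- dplyr::bind_rows(models)

  # --- decoys ---------------------------------------------------------------
  with_seed(substream_seed(seed, "decoys"), {
    decoys <- if (spec$n_decoy_proteins > 0) {
      setNames(vapply(seq_len(spec$n_decoy_proteins), function(i) {
        paste(sample(AA20, sample(150:616, 1), replace = TRUE), collapse = "")
      }, character(1)), sprintf("decoy%03d", seq_len(spec$n_decoy_proteins)))
    } else character(0)
  })

  n_int <- table(factor(truth_introns$gene_id, levels = gene_ids))
  truth_genes <- tibble(
    gene_id = gene_ids, group = groups,
    chromosome = models$chromosome[match(gene_ids, models$gene_id)],
    strand = models$strand[match(gene_ids, models$gene_id)],
    n_introns = as.integer(n_int),
    protein_length = nchar(proteins_fam)
  )

  structure(list(
    genome = chrom_seq,
    models = models,
    proteins = c(proteins_fam, decoys),
    msa = msa,
    tree = tree,
    truth_genes = truth_genes,
    truth_introns = truth_introns,
    truth_events = truth_events,
    spec = spec,
    seed = seed
  ), class = "family_sim")
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf(
    "<family_sim> %d family genes in %d groups, %d decoys, %d chromosomes\n",
    x$spec$n_family_genes, length(x$spec$group_labels),
    x$spec$n_decoy_proteins, x$spec$n_chromosomes))
  cat(sprintf("  planted events: %d; introns: %d; seed %s\n",
              nrow(x$truth_events), nrow(x$truth_introns), format(x$seed)))
  invisible(x)
}

#' @export
glance.family_sim <- function(x, ...) {
  tibble(
    n_family_genes = x$spec$n_family_genes,
    n_decoys = x$spec$n_decoy_proteins,
    n_groups = length(x$spec$group_labels),
    n_events = nrow(x$truth_events),
    n_introns = nrow(x$truth_introns),
    n_intronless = sum(x$truth_genes$n_introns == 0),
    seed = x$seed
  )
}
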