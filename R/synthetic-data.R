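# Synthetic inputs with planted ground truth for every pipeline stage:
# paired probe kits with a known shared-locus structure, contigs embedding
# probe targets and off-target gene fragments at recorded coordinates,
# locus collections with planted occupancy/long-branch failures, circular
# mitochondrial genomes under arbitrary rotation, and mixed
# bycatch-plus-legacy alignments with known trim boundaries.  Noise is
# substitution-only so planted coordinates stay exact.  Every generator is
# deterministic under its seed and leaves global RNG state untouched.

#' Generate a pair of probe sets with planted homology structure
#'
#' Shared loci are built from a common ancestral region tiled by
#' `probes_per_locus` non-overlapping probes; the spider kit carries the
#' ancestral tiles and the arachnid kit carries copies mutated at rate
#' `divergence`, so paired probes differ by ~`divergence` substitutions
#' and homology is detectable by the default matcher up to divergence
#' ~0.15.  Kit-unique loci are independent random sequences with no
#' ancestry.  Probe ids are namespaced (`uce-*` vs `auce-*`).
#'
#' @param n_shared,n_spider_only,n_arachnid_only locus counts.
#' @param probes_per_locus probes tiling each locus.
#' @param probe_len probe length in bp (>= 20).
#' @param divergence per-site substitution rate between paired probes,
#'   in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list with `spider` and `arachnid` (probe_set tables) and
#'   `truth` (class `synth_truth`) holding `probe_homology_pairs`
#'   (data.frame `spider_probe`, `arachnid_probe`, `locus`),
#'   `locus_regions` (per locus: the plantable target sequence and the
#'   kits that should detect it).
#' @export
gen_probesets <- function(n_shared, n_spider_only, n_arachnid_only,
                          probes_per_locus = 2L, probe_len = 120L,
                          divergence = 0.05, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.5)
  if (probe_len < 20L) stop("probe_len must be >= 20", call. = FALSE)
  with_local_seed(seed, {
    spider <- list(); arachnid <- list()
    regions <- list(); pairs <- list()
    add_probe <- function(store, locus, p, seqs) {
      store[[length(store) + 1L]] <- data.frame(
        probe_id = sprintf("%s_p%d", locus, p), locus_id = locus,
        probe_index = p, sequence = seqs, stringsAsFactors = FALSE)
      store
    }
    for (j in seq_len(n_shared)) {
      s_locus <- sprintf("uce-%d", j)
      a_locus <- sprintf("auce-%d", j)
      tiles <- random_dna(probe_len, probes_per_locus)
      a_tiles <- vapply(tiles, mutate_dna, character(1), rate = divergence,
                        USE.NAMES = FALSE)
      for (p in seq_len(probes_per_locus)) {
        spider <- add_probe(spider, s_locus, p, tiles[p])
        arachnid <- add_probe(arachnid, a_locus, p, a_tiles[p])
      }
      pairs[[j]] <- expand.grid(
        spider_probe = sprintf("%s_p%d", s_locus, seq_len(probes_per_locus)),
        arachnid_probe = sprintf("%s_p%d", a_locus, seq_len(probes_per_locus)),
        stringsAsFactors = FALSE)
      pairs[[j]]$locus <- s_locus
      regions[[s_locus]] <- list(sequence = paste(tiles, collapse = ""),
                                 kits = c("spider", "arachnid"))
    }
    for (j in seq_len(n_spider_only)) {
      locus <- sprintf("uce-%d", n_shared + j)
      tiles <- random_dna(probe_len, probes_per_locus)
      for (p in seq_len(probes_per_locus)) {
        spider <- add_probe(spider, locus, p, tiles[p])
      }
      regions[[locus]] <- list(sequence = paste(tiles, collapse = ""),
                               kits = "spider")
    }
    for (j in seq_len(n_arachnid_only)) {
      locus <- sprintf("auce-%d", n_shared + j)
      tiles <- random_dna(probe_len, probes_per_locus)
      for (p in seq_len(probes_per_locus)) {
        arachnid <- add_probe(arachnid, locus, p, tiles[p])
      }
      regions[[locus]] <- list(sequence = paste(tiles, collapse = ""),
                               kits = "arachnid")
    }
    mk <- function(store, src) {
      df <- do.call(rbind, store)
      df$source_set <- src
      class(df) <- c("probe_set", "data.frame")
      df
    }
    truth <- structure(list(
      probe_homology_pairs = if (length(pairs) > 0L) do.call(rbind, pairs)
                             else data.frame(spider_probe = character(0),
                                             arachnid_probe = character(0),
                                             locus = character(0)),
      locus_regions = regions), class = "synth_truth")
    list(spider = mk(spider, "spider"), arachnid = mk(arachnid, "arachnid"),
         truth = truth)
  })
}

#' Generate per-taxon contigs embedding probe targets and gene fragments
#'
#' For each taxon, every locus region in `truth` is planted on its own
#' contig between random flanks, on a random strand, with substitution
#' noise at `noise_rate`.  Off-target genes are planted split across
#' `fragments_per_gene` contigs: fragments partition the gene contiguously
#' so that noise-free stitching reproduces the gene exactly.  All planted
#' coordinates and strands are recorded.
#'
#' @param taxa character vector of taxon names.
#' @param truth `synth_truth` from [gen_probesets()], or `NULL` if only
#'   off-target content is wanted.
#' @param off_target_genes named character vector of reference gene
#'   sequences (e.g. 28S, 16SND1, COI), or `NULL`.
#' @param noise_rate per-site substitution rate on planted copies.
#' @param seed integer seed.
#' @param flank_len random flank length on each side of a planted feature.
#' @param fragments_per_gene number of contigs each gene is split across.
#' @return list with `contigs` (named list: taxon -> named character vector
#'   of contigs) and `truth` (the input truth with `planted_probe_coords`
#'   and `planted_gene_coords` tables added).
#' @export
gen_contigs <- function(taxa, truth = NULL, off_target_genes = NULL,
                        noise_rate = 0, seed = 1L, flank_len = 60L,
                        fragments_per_gene = 2L) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5, fragments_per_gene >= 1L)
  with_local_seed(seed, {
    if (is.null(truth)) truth <- structure(list(), class = "synth_truth")
    contigs <- list()
    probe_coords <- list(); gene_coords <- list()
    for (tx in taxa) {
      ctg <- character(0)
      ci <- 0L
      for (locus in names(truth$locus_regions %||% list())) {
        ci <- ci + 1L
        region <- mutate_dna(truth$locus_regions[[locus]]$sequence,
                             noise_rate)
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "-") revcomp(region) else region
        cid <- sprintf("%s_node%03d", tx, ci)
        ctg[cid] <- paste0(random_dna(flank_len), ins, random_dna(flank_len))
        probe_coords[[length(probe_coords) + 1L]] <- data.frame(
          taxon = tx, locus = locus, contig = cid,
          start = flank_len + 1L, end = flank_len + nchar(region),
          strand = strand, stringsAsFactors = FALSE)
      }
      for (g in names(off_target_genes %||% character(0))) {
        gseq <- off_target_genes[[g]]
        glen <- nchar(gseq)
        nf <- fragments_per_gene
        cuts <- unique(round(seq(0L, glen, length.out = nf + 1L)))
        for (f in seq_len(length(cuts) - 1L)) {
          ci <- ci + 1L
          qs <- cuts[f] + 1L; qe <- cuts[f + 1L]
          frag <- mutate_dna(substr(gseq, qs, qe), noise_rate)
          strand <- sample(c("+", "-"), 1L)
          ins <- if (strand == "-") revcomp(frag) else frag
          cid <- sprintf("%s_node%03d", tx, ci)
          ctg[cid] <- paste0(random_dna(flank_len), ins, random_dna(flank_len))
          gene_coords[[length(gene_coords) + 1L]] <- data.frame(
            taxon = tx, gene = g, contig = cid,
            q_start = qs, q_end = qe,
            s_start = flank_len + 1L, s_end = flank_len + nchar(frag),
            strand = strand, stringsAsFactors = FALSE)
        }
      }
      contigs[[tx]] <- ctg
    }
    truth$planted_probe_coords <- if (length(probe_coords) > 0L) {
      do.call(rbind, probe_coords)
    } else NULL
    truth$planted_gene_coords <- if (length(gene_coords) > 0L) {
      do.call(rbind, gene_coords)
    } else NULL
    list(contigs = contigs, truth = truth)
  })
}

#' Generate a locus collection with planted filter outcomes
#'
#' Plants exactly `n_fail_occupancy` loci that fail the occupancy rule
#' (fewer than `min_taxa` taxa or fewer than `min_ingroup` ingroup taxa),
#' and among the occupancy passers exactly `n_fail_long_branch` loci whose
#' gene tree longest/second-longest branch ratio is drawn from
#' `[ratio_hi, 2*ratio_hi]`; all other passers get trees with ratio in
#' `(1, ratio_lo]`.  Occupancy-failing loci carry no tree (the cascade
#' never consults it).
#'
#' @param n_loci total loci.
#' @param n_taxa total taxa (ingroup + outgroup).
#' @param n_ingroup number of ingroup taxa among `n_taxa`.
#' @param n_fail_occupancy planted occupancy failures.
#' @param n_fail_long_branch planted long-branch failures among the
#'   occupancy passers.
#' @param ratio_lo ceiling of the branch ratio for passing trees; must be
#'   below `threshold`.
#' @param ratio_hi floor of the branch ratio for long-branch failures.
#' @param threshold the filter threshold the planting must straddle
#'   (default 5).
#' @param min_taxa,min_ingroup the occupancy thresholds being planted
#'   against (defaults 6 and 3).
#' @param aln_len alignment length per locus (bp).
#' @param seed integer seed.
#' @return list with `loci` (list of [locus_record]) and `truth`
#'   (`synth_truth` with `locus_filter_labels`: named vector locus ->
#'   `"pass"`/`"fail_occupancy"`/`"fail_long_branch"`, plus `ingroup_taxa`).
#' @export
gen_locus_set <- function(n_loci, n_taxa, n_ingroup, n_fail_occupancy = 0L,
                          n_fail_long_branch = 0L, ratio_lo = 2,
                          ratio_hi = 5.5, threshold = 5, min_taxa = 6L,
                          min_ingroup = 3L, aln_len = 60L, seed = 1L) {
  stopifnot(n_fail_occupancy + n_fail_long_branch <= n_loci,
            n_ingroup <= n_taxa, n_ingroup >= min_ingroup,
            n_taxa >= min_taxa)
  if (ratio_lo >= threshold) {
    stop("ratio_lo must be below the filter threshold", call. = FALSE)
  }
  if (ratio_hi < threshold) {
    stop("ratio_hi must be at or above the filter threshold", call. = FALSE)
  }
  with_local_seed(seed, {
    ingroup <- sprintf("in%02d", seq_len(n_ingroup))
    outgroup <- sprintf("out%02d", seq_len(n_taxa - n_ingroup))
    labels <- rep("pass", n_loci)
    idx <- sample.int(n_loci)
    labels[idx[seq_len(n_fail_occupancy)]] <- "fail_occupancy"
    labels[idx[n_fail_occupancy + seq_len(n_fail_long_branch)]] <-
      "fail_long_branch"
    rint <- function(lo, hi) {
      if (hi <= lo) return(as.integer(lo))
      as.integer(lo + floor(stats::runif(1) * (hi - lo + 1L)))
    }
    n_out <- length(outgroup)
    pick_taxa <- function(lab) {
      if (lab == "fail_occupancy") {
        # two failure modes: too few taxa total, or enough taxa but too few
        # ingroups (needs enough outgroups to reach min_taxa)
        ni <- rint(0L, min_ingroup - 1L)
        if (n_out >= min_taxa - ni && stats::runif(1) < 0.5) {
          no <- rint(min_taxa - ni, n_out)
        } else {
          tot <- rint(2L, min_taxa - 1L)
          ni <- rint(0L, min(tot, min_ingroup - 1L))
          no <- min(tot - ni, n_out)
        }
      } else {
        ni <- rint(min_ingroup, n_ingroup)
        no <- rint(max(0L, min_taxa - ni), n_out)
      }
      if (ni + no < 2L) ni <- max(ni, 2L - no)
      c(if (ni > 0L) sample(ingroup, ni), if (no > 0L) sample(outgroup, no))
    }
    planted_tree <- function(taxa, ratio) {
      tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
      ne <- nrow(tr$edge)
      lens <- stats::runif(ne, 0.05, 0.1)
      e <- sample.int(ne, 1L)
      l2 <- max(lens[-e])
      lens[e] <- ratio * l2
      tr$edge.length <- lens
      structure(list(tree = tr, edge_lengths = lens,
                     leaf_labels = tr$tip.label,
                     newick = ape::write.tree(tr)), class = "gene_tree")
    }
    loci <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      lab <- labels[i]
      taxa <- pick_taxa(lab)
      row <- random_dna(aln_len)
      aln <- stats::setNames(rep(row, length(taxa)), taxa)
      tree <- if (lab == "fail_occupancy") {
        NULL
      } else if (lab == "fail_long_branch") {
        planted_tree(taxa, stats::runif(1, ratio_hi, 2 * ratio_hi))
      } else {
        planted_tree(taxa, stats::runif(1, 1.05, ratio_lo))
      }
      loci[[i]] <- locus_record(sprintf("uce-%04d", i), aln, tree)
    }
    truth <- structure(list(
      locus_filter_labels = stats::setNames(
        labels, vapply(loci, function(l) l$locus_id, character(1))),
      ingroup_taxa = ingroup), class = "synth_truth")
    list(loci = loci, truth = truth)
  })
}

#' Generate a circular mitochondrial genome under arbitrary rotation
#'
#' A canonical genome of `genome_len` random bases carries three gene
#' intervals (16S, ND1, COI by convention); the emitted genome is the
#' canonical sequence cyclically shifted by `rotation_offset`, emulating
#' the arbitrary starting point of a circular assembly.  The anchor is a
#' window at the start of the 16S interval of the canonical sequence, the
#' conserved region rotation should recover.
#'
#' @param genome_len genome length in bp.
#' @param gene_coords named list of 1-based inclusive `c(start, end)`
#'   intervals on the canonical genome, typically `16S`, `ND1`, `COI`;
#'   must be disjoint and in bounds.
#' @param rotation_offset cyclic shift in `[0, genome_len)`: output starts
#'   at canonical position `rotation_offset + 1`.
#' @param seed integer seed.
#' @param anchor_len anchor window length (bp).
#' @return list with `genome` (rotated), `canonical`, `anchor`, and
#'   `truth` (`synth_truth` with `rotation_offset` and `gene_coords`).
#' @export
gen_mito <- function(genome_len, gene_coords, rotation_offset = 0L,
                     seed = 1L, anchor_len = 40L) {
  stopifnot(rotation_offset >= 0L, rotation_offset < genome_len)
  iv <- do.call(rbind, gene_coords)
  if (any(iv[, 1] < 1L) || any(iv[, 2] > genome_len) ||
      any(iv[, 1] > iv[, 2])) {
    stop("gene intervals out of bounds", call. = FALSE)
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] <= iv[-nrow(iv), 2])) {
    stop("gene intervals must be disjoint", call. = FALSE)
  }
  with_local_seed(seed, {
    canonical <- random_dna(genome_len)
    a0 <- gene_coords[["16S"]][1] %||% 1L
    anchor <- substr(canonical, a0, min(genome_len, a0 + anchor_len - 1L))
    genome <- if (rotation_offset == 0L) canonical else {
      paste0(substr(canonical, rotation_offset + 1L, genome_len),
             substr(canonical, 1L, rotation_offset))
    }
    truth <- structure(list(rotation_offset = rotation_offset,
                            gene_coords = gene_coords),
                       class = "synth_truth")
    list(genome = genome, canonical = canonical, anchor = anchor,
         truth = truth)
  })
}

#' Generate an alignment mixing long bycatch and short legacy rows
#'
#' Long rows span the whole consensus; legacy rows are gap-padded windows
#' of it, with window starts drawn from `legacy_offset_range`.  The range
#' width must be smaller than `legacy_len` so all legacy windows mutually
#' overlap, which makes the true trim boundaries exact order statistics of
#' the planted windows: the k-th smallest start and k-th largest end
#' (k = `k_legacy`).
#'
#' @param n_long,n_legacy row counts.
#' @param long_len,legacy_len row lengths in bp; `legacy_len < long_len`.
#' @param legacy_offset_range `c(lo, hi)` inclusive range of legacy window
#'   start columns; `hi - lo < legacy_len` and windows must fit.
#' @param k_legacy quorum used for the recorded truth boundaries
#'   (default 3).
#' @param seed integer seed.
#' @return list with `alignment` (named character vector; long rows
#'   `long*`, legacy rows `legacy*`), and `truth` (`synth_truth` with
#'   `legacy_ids`, `windows` (data.frame `id`, `start`, `end`) and
#'   `trim_boundaries` = `c(left, right)` or `NA` when `n_legacy <
#'   k_legacy`, in which case a warning is recorded).
#' @export
gen_mixed_alignment <- function(n_long, n_legacy, long_len, legacy_len,
                                legacy_offset_range, k_legacy = 3L,
                                seed = 1L) {
  stopifnot(legacy_len < long_len, length(legacy_offset_range) == 2L)
  lo <- legacy_offset_range[1]; hi <- legacy_offset_range[2]
  stopifnot(lo >= 1L, hi >= lo, hi + legacy_len - 1L <= long_len)
  if (hi - lo >= legacy_len) {
    stop("legacy_offset_range width must be below legacy_len so windows overlap",
         call. = FALSE)
  }
  with_local_seed(seed, {
    consensus <- random_dna(long_len)
    aln <- stats::setNames(
      vapply(seq_len(n_long), function(i) mutate_dna(consensus, 0.02),
             character(1)),
      sprintf("long%02d", seq_len(n_long)))
    starts <- if (n_legacy > 0L) {
      as.integer(lo + sample.int(hi - lo + 1L, n_legacy, replace = TRUE) - 1L)
    } else integer(0)
    for (i in seq_len(n_legacy)) {
      s <- starts[i]; e <- s + legacy_len - 1L
      aln[sprintf("legacy%02d", i)] <- paste0(
        strrep("-", s - 1L), substr(consensus, s, e),
        strrep("-", long_len - e))
    }
    windows <- data.frame(id = sprintf("legacy%02d", seq_len(n_legacy)),
                          start = starts,
                          end = starts + legacy_len - 1L,
                          stringsAsFactors = FALSE)
    note <- NULL
    if (n_legacy < k_legacy) {
      note <- sprintf("only %d legacy rows; %d-row trim rule unsatisfiable",
                      n_legacy, k_legacy)
      warning(note, call. = FALSE)
      tb <- c(NA_integer_, NA_integer_)
    } else {
      tb <- c(sort(windows$start)[k_legacy],
              sort(windows$end, decreasing = TRUE)[k_legacy])
    }
    truth <- structure(list(legacy_ids = windows$id, windows = windows,
                            trim_boundaries = tb, note = note),
                       class = "synth_truth")
    list(alignment = aln, truth = truth)
  })
}

#' Write a truth sidecar as plain tab-separated text
#'
#' Serialises the tabular components of a `synth_truth` (one block per
#' component, introduced by a `## name` line) so fixtures on disk carry
#' their ground truth in a documented plain-text format.
#'
#' @param truth a `synth_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(truth)) {
    x <- truth[[nm]]
    writeLines(sprintf("## %s", nm), con)
    if (is.data.frame(x)) {
      utils::write.table(x, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else if (is.atomic(x) && !is.null(names(x))) {
      utils::write.table(data.frame(key = names(x), value = unname(x)),
                         con, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.atomic(x)) {
      writeLines(paste(x, collapse = "\t"), con)
    } else {
      writeLines(sprintf("# %d entries (non-tabular, omitted)", length(x)),
                 con)
    }
  }
  invisible(path)
}
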