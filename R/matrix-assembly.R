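# Assembly of the analysis supermatrices: rotate circular mitochondrial
# genomes to a shared 16S anchor, trim long bycatch sequences to near-parity
# with short legacy Sanger sequences, apply config-driven manual trims, and
# concatenate blocks with a partition table.

#' Trimming parameters for legacy-parity trimming
#'
#' "Represented" is read column-wise: at the boundary column at least
#' `k_legacy` legacy rows must carry a non-gap character.  Segments
#' (e.g. the mtDNA regions before 16S-ND1, between 16S-ND1 and COI, and
#' after COI) are trimmed independently; interior columns are never
#' removed.
#'
#' @param k_legacy number of legacy rows that must be represented at each
#'   kept boundary column.  Default 3.
#' @param legacy_ids ids of the short legacy (Sanger) rows.
#' @param segments optional data.frame (`name`, `start`, `end`) of 1-based
#'   column intervals tiling the alignment; `NULL` treats the whole
#'   alignment as one segment.
#' @return object of class `trim_params`.
#' @export
trim_params <- function(k_legacy = 3L, legacy_ids = character(0),
                        segments = NULL) {
  stopifnot(k_legacy >= 1L)
  structure(list(k_legacy = as.integer(k_legacy), legacy_ids = legacy_ids,
                 segments = segments),
            class = "trim_params")
}

#' Curation configuration for manual trims and anchors
#'
#' Holds the hand-curation decisions as explicit, reproducible entries:
#' alignment-wide column ranges to delete, per-sequence ranges to blank to
#' gaps (e.g. a suspect terminal stretch of one bycatch sequence), and the
#' conserved anchor sequences used to rotate circular genomes.
#'
#' @param column_trims list of `c(start, end)` 1-based column ranges to
#'   remove matrix-wide.
#' @param sequence_trims named list: sequence id -> list of `c(start, end)`
#'   ranges to replace with gaps in that row only.
#' @param anchors named character vector: genome class -> anchor DNA.
#' @return object of class `curation_config`.
#' @export
curation_config <- function(column_trims = list(), sequence_trims = list(),
                            anchors = character(0)) {
  structure(list(column_trims = column_trims,
                 sequence_trims = sequence_trims, anchors = anchors),
            class = "curation_config")
}

#' Rotate a circular genome so the anchor starts at position 1
#'
#' Whole mitochondrial genomes assemble with arbitrary starting points on
#' the circle; rotating them all to a conserved region (here a 16S
#' fragment) makes a joint alignment possible.  The anchor is located on
#' either strand (a minus-strand genome is reverse-complemented first) via
#' mismatch-tolerant matching over the doubled genome; the best match
#' (fewest mismatches, then leftmost) defines the cut.  Output is a cyclic
#' permutation of the input (or of its reverse complement) and the
#' operation is idempotent.
#'
#' @param genome circular genome as a DNA string.
#' @param anchor anchor DNA string, shorter than the genome.
#' @param min_identity identity floor for the anchor match.  Default 0.8.
#' @return the rotated genome string.
#' @export
rotate_to_anchor <- function(genome, anchor, min_identity = 0.8) {
  n <- nchar(genome)
  stopifnot(nchar(anchor) < n, nchar(anchor) >= 3L)
  max_mm <- floor((1 - min_identity) * nchar(anchor))
  best_for <- function(g) {
    doubled <- paste0(g, g)
    m <- Biostrings::matchPattern(Biostrings::DNAString(anchor),
                                  Biostrings::DNAString(doubled),
                                  max.mismatch = max_mm, fixed = TRUE)
    st <- Biostrings::start(m)
    st <- st[st <= n]
    if (length(st) == 0L) return(NULL)
    mm <- vapply(st, function(s) {
      sum(strsplit(substr(doubled, s, s + nchar(anchor) - 1L), "")[[1]] !=
            strsplit(anchor, "")[[1]])
    }, numeric(1))
    list(start = st[which.min(mm)], mismatches = min(mm))
  }
  fwd <- best_for(genome)
  rc <- revcomp(genome)
  rev <- best_for(rc)
  pick <- if (is.null(fwd) && is.null(rev)) {
    stop(sprintf("anchor not found in genome at identity >= %.2f",
                 min_identity), call. = FALSE)
  } else if (is.null(rev) || (!is.null(fwd) && fwd$mismatches <= rev$mismatches)) {
    list(g = genome, s = fwd$start)
  } else {
    list(g = rc, s = rev$start)
  }
  if (pick$s == 1L) return(pick$g)
  paste0(substr(pick$g, pick$s, n), substr(pick$g, 1L, pick$s - 1L))
}

#' Trim alignment ends to legacy-sequence parity
#'
#' Within each segment, columns are removed from the left end up to the
#' first column at which at least `k_legacy` legacy rows are non-gap, and
#' symmetrically from the right; interior columns and rows are never
#' removed.  A segment in which no column reaches the quorum is dropped
#' entirely (recorded in the boundaries table).  Idempotent.
#'
#' @param alignment named character vector of equal-length rows.
#' @param params a [trim_params]; `legacy_ids` must contain at least
#'   `k_legacy` ids present in the alignment.
#' @return list with `alignment` (trimmed) and `boundaries` (data.frame
#'   `segment`, `start`, `end`, `keep_start`, `keep_end` in original
#'   1-based columns; `NA` for dropped segments).
#' @export
legacy_parity_trim <- function(alignment, params) {
  stopifnot(inherits(params, "trim_params"))
  legacy <- intersect(params$legacy_ids, names(alignment))
  if (length(legacy) < params$k_legacy) {
    stop(sprintf("need >= %d legacy rows in the alignment, have %d",
                 params$k_legacy, length(legacy)), call. = FALSE)
  }
  L <- nchar(alignment[[1]])
  m <- aln_matrix(alignment[legacy])
  cov <- colSums(m != "-" & m != "?")
  segs <- params$segments
  if (is.null(segs)) segs <- data.frame(name = "all", start = 1L, end = L)
  check_partitions(segs, L)
  keep <- integer(0)
  bounds <- list()
  for (i in seq_len(nrow(segs))) {
    a <- segs$start[i]; b <- segs$end[i]
    ok <- which(cov[a:b] >= params$k_legacy)
    if (length(ok) == 0L) {
      bounds[[i]] <- data.frame(segment = segs$name[i], start = a, end = b,
                                keep_start = NA_integer_,
                                keep_end = NA_integer_)
      next
    }
    ks <- a + min(ok) - 1L; ke <- a + max(ok) - 1L
    keep <- c(keep, ks:ke)
    bounds[[i]] <- data.frame(segment = segs$name[i], start = a, end = b,
                              keep_start = ks, keep_end = ke)
  }
  full <- aln_matrix(alignment)
  trimmed <- aln_collapse(full[, keep, drop = FALSE])
  list(alignment = trimmed, boundaries = do.call(rbind, bounds))
}

#' Apply manual curation trims to an alignment
#'
#' Per-sequence trims (gap replacement, coordinate-preserving) are applied
#' first, then matrix-wide column removals; both are specified in the
#' original 1-based coordinates of the input alignment.
#'
#' @param alignment named character vector of equal-length rows.
#' @param config a [curation_config].
#' @return the curated alignment.
#' @export
apply_manual_trims <- function(alignment, config) {
  stopifnot(inherits(config, "curation_config"))
  L <- nchar(alignment[[1]])
  for (sid in names(config$sequence_trims)) {
    if (!sid %in% names(alignment)) {
      stop(sprintf("sequence trim targets unknown id: %s", sid),
           call. = FALSE)
    }
    for (r in config$sequence_trims[[sid]]) {
      if (r[1] < 1L || r[2] > L || r[1] > r[2]) {
        stop(sprintf("sequence trim range out of bounds for %s: %d-%d",
                     sid, r[1], r[2]), call. = FALSE)
      }
      substr(alignment[[sid]], r[1], r[2]) <- strrep("-", r[2] - r[1] + 1L)
    }
  }
  if (length(config$column_trims) > 0L) {
    drop <- unique(unlist(lapply(config$column_trims, function(r) {
      if (r[1] < 1L || r[2] > L || r[1] > r[2]) {
        stop(sprintf("column trim range out of bounds: %d-%d", r[1], r[2]),
             call. = FALSE)
      }
      r[1]:r[2]
    })))
    m <- aln_matrix(alignment)
    alignment <- aln_collapse(m[, -drop, drop = FALSE])
  }
  alignment
}

#' Concatenate alignment blocks into a supermatrix
#'
#' Rows are the union of the blocks' taxa; cells for taxa absent from a
#' block are filled with `missing_fill`.  The partition table follows block
#' order and lengths and tiles the matrix exactly, so each block can be
#' spliced back out of the supermatrix.
#'
#' @param blocks named list of alignments (named character vectors); list
#'   names become partition names.
#' @param missing_fill fill character for absent taxon-by-block cells;
#'   `"?"` is conventional for PHYLIP/NEXUS, `"-"` for FASTA.
#' @param dataset_tag tag recorded on the bundle.
#' @param partitioned logical, see [supermatrix_bundle()].
#' @return a [supermatrix_bundle].
#' @export
concatenate_blocks <- function(blocks, missing_fill = "?",
                               dataset_tag = "custom", partitioned = TRUE) {
  stopifnot(is.list(blocks), length(blocks) > 0L)
  nm <- names(blocks) %||% rep("", length(blocks))
  widths <- integer(length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (anyDuplicated(names(b))) {
      stop(sprintf("duplicate taxon within block %s", nm[i]), call. = FALSE)
    }
    w <- unique(nchar(b))
    if (length(w) != 1L) {
      stop(sprintf("block %s rows have unequal length", nm[i]), call. = FALSE)
    }
    widths[i] <- w
  }
  taxa <- unique(unlist(lapply(blocks, names), use.names = FALSE))
  rows <- vapply(taxa, function(tx) {
    paste(vapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      if (tx %in% names(b)) b[[tx]] else strrep(missing_fill, widths[i])
    }, character(1)), collapse = "")
  }, character(1))
  ends <- cumsum(widths)
  partitions <- data.frame(name = nm,
                           start = c(1L, utils::head(ends, -1L) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  supermatrix_bundle(rows, partitions, dataset_tag = dataset_tag,
                     partitioned = partitioned)
}

#' Splice one partition back out of a supermatrix
#'
#' @param bundle a [supermatrix_bundle].
#' @param name partition name.
#' @return the block as a named character vector.
#' @export
splice_partition <- function(bundle, name) {
  p <- bundle$partitions
  i <- which(p$name == name)
  if (length(i) != 1L) stop(sprintf("no partition named %s", name),
                            call. = FALSE)
  out <- substr(bundle$matrix, p$start[i], p$end[i])
  names(out) <- names(bundle$matrix)
  out
}

#' Assemble the four analysis datasets
#'
#' Produces: #1 "UCEs" — the filtered UCE loci concatenated, analysed
#' unpartitioned; #2 "mtDNA+28S" — 28S and mitochondrial alignments
#' concatenated with two named partitions; #3 "restricted mtDNA+28S" — as
#' #2 after legacy-parity trimming of both alignments (segment-wise for
#' the mtDNA when segments are configured); #4 "UCEs+mtDNA+28S" — #1
#' concatenated to #3, analysed unpartitioned.  Manual curation trims, if
#' configured, are applied to the 28S and mtDNA inputs before any dataset
#' is built.
#'
#' @param uce_loci named list of per-locus alignments (post-filter).
#' @param alignment_28S,alignment_mtDNA named character vectors.
#' @param trim_28S a [trim_params] for the 28S alignment (whole-alignment
#'   segment).
#' @param trim_mtDNA a [trim_params] for the mtDNA alignment (typically
#'   with gene-region segments).
#' @param config optional [curation_config] of manual trims keyed
#'   `"28S"` / `"mtDNA"` in a list: `list(`28S` = cfg, mtDNA = cfg)`.
#' @param missing_fill fill character for absent cells.
#' @return named list of four [supermatrix_bundle]s: `UCEs`, `mtDNA_28S`,
#'   `restricted_mtDNA_28S`, `UCEs_mtDNA_28S`.
#' @export
assemble_datasets <- function(uce_loci, alignment_28S, alignment_mtDNA,
                              trim_28S, trim_mtDNA, config = NULL,
                              missing_fill = "?") {
  if (!is.null(config)) {
    if (!is.null(config[["28S"]])) {
      alignment_28S <- apply_manual_trims(alignment_28S, config[["28S"]])
    }
    if (!is.null(config[["mtDNA"]])) {
      alignment_mtDNA <- apply_manual_trims(alignment_mtDNA, config[["mtDNA"]])
    }
  }
  d1 <- concatenate_blocks(stats::setNames(uce_loci, names(uce_loci)),
                           missing_fill = missing_fill,
                           dataset_tag = "UCEs", partitioned = FALSE)
  d2 <- concatenate_blocks(list(`28S` = alignment_28S,
                                mtDNA = alignment_mtDNA),
                           missing_fill = missing_fill,
                           dataset_tag = "mtDNA_28S", partitioned = TRUE)
  r28 <- legacy_parity_trim(alignment_28S, trim_28S)
  rmt <- legacy_parity_trim(alignment_mtDNA, trim_mtDNA)
  d3 <- concatenate_blocks(list(`28S` = r28$alignment,
                                mtDNA = rmt$alignment),
                           missing_fill = missing_fill,
                           dataset_tag = "restricted_mtDNA_28S",
                           partitioned = TRUE)
  d4 <- concatenate_blocks(list(UCEs = d1$matrix,
                                restricted_mtDNA_28S = d3$matrix),
                           missing_fill = missing_fill,
                           dataset_tag = "UCEs_mtDNA_28S",
                           partitioned = FALSE)
  list(UCEs = d1, mtDNA_28S = d2, restricted_mtDNA_28S = d3,
       UCEs_mtDNA_28S = d4)
}
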