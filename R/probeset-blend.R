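# Blended-probeset construction.  Two bait kits (a spider-specific kit and
# an older pan-arachnid kit) target overlapping but non-identical locus
# sets.  Capture contigs from a diverse taxon panel are matched against both
# kits; any contig matching a probe of each kit witnesses homology between
# those probes.  Arachnid probes with at least one homology edge are
# dropped (duplicate homologs depress recovery, since contigs matching two
# probes are discarded downstream as problematic); the remainder are
# appended to the spider kit to form the blended set.

#' Build a probe-set table from a FASTA file or named sequences
#'
#' @param x path to a probe FASTA file, or a named character vector of probe
#'   sequences whose names follow the `locus_pN` header grammar.
#' @param source_set which kit the probes belong to: `"spider"`,
#'   `"arachnid"` or `"blended"`.
#' @return data.frame of class `probe_set` with columns `probe_id`,
#'   `locus_id`, `probe_index`, `sequence`, `source_set`.
#' @export
read_probe_set <- function(x, source_set = c("spider", "arachnid", "blended")) {
  source_set <- match.arg(source_set)
  seqs <- if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    read_fasta(x)
  } else x
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  if (any(nchar(seqs) == 0L)) stop("empty probe sequence", call. = FALSE)
  hdr <- parse_probe_header(names(seqs))
  ps <- data.frame(probe_id = names(seqs), locus_id = hdr$locus_id,
                   probe_index = hdr$probe_index,
                   sequence = unname(seqs), source_set = source_set,
                   stringsAsFactors = FALSE)
  key <- paste(ps$locus_id, ps$probe_index, ps$source_set)
  if (anyDuplicated(key)) {
    stop("duplicate (locus_id, probe_index) within probe set", call. = FALSE)
  }
  class(ps) <- c("probe_set", "data.frame")
  ps
}

#' Match every probe of a set against a contig collection
#'
#' Both strands are searched; hits shorter than `min_hit_len` or below
#' `min_identity` are dropped by the matcher.
#'
#' @param contigs named character vector of contig sequences (ids unique
#'   across the collection), or a path to a contig FASTA.
#' @param probe_set a `probe_set` table from [read_probe_set()].
#' @param params a [match_params]; defaults stand in for unreported
#'   lastz settings.
#' @return data.frame of hits with columns `probe_id`, `contig_id`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `strand`, `length`,
#'   `identity`, `mismatches`, `score`.
#' @export
match_probes_to_contigs <- function(contigs, probe_set,
                                    params = match_params()) {
  if (is.character(contigs) && length(contigs) == 1L && is.null(names(contigs))) {
    contigs <- read_fasta(contigs)
  }
  stopifnot(length(contigs) > 0L, nrow(probe_set) > 0L)
  k <- params$seed_word_len
  qpre <- lapply(probe_set$sequence, .prep_query, k = k)
  rows <- list()
  for (ci in seq_along(contigs)) {
    spre <- .prep_subject(contigs[[ci]], k)
    cid <- names(contigs)[ci]
    for (pi in seq_len(nrow(probe_set))) {
      h <- .hsps_to_df(.scan_hsps(qpre[[pi]], spre, params))
      if (nrow(h) == 0L) next
      h$probe_id <- probe_set$probe_id[pi]
      h$contig_id <- cid
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(probe_id = character(0), contig_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), mismatches = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[, c("probe_id", "contig_id", "q_start", "q_end", "s_start", "s_end",
         "strand", "length", "identity", "mismatches", "score")]
}

#' Infer probe homology from shared contig matches
#'
#' An edge (spider probe, arachnid probe) exists iff at least one contig has
#' hits to both; each edge records its witness contigs.  A single co-match
#' counts: the removal rule keys on "no hint of homology", so no
#' minimum-witness threshold is applied.
#'
#' @param hits_spider,hits_arachnid hit tables from
#'   [match_probes_to_contigs()], produced from the same contig collection.
#' @return object of class `homology_graph`: list with `edges` (data.frame
#'   `spider_probe`, `arachnid_probe`, `n_witness`) and `witness` (named
#'   list of witness contig ids per edge).
#' @export
infer_probe_homology <- function(hits_spider, hits_arachnid) {
  s <- unique(hits_spider[, c("probe_id", "contig_id")])
  a <- unique(hits_arachnid[, c("probe_id", "contig_id")])
  names(s) <- c("spider_probe", "contig_id")
  names(a) <- c("arachnid_probe", "contig_id")
  j <- merge(s, a, by = "contig_id")
  if (nrow(j) == 0L) {
    edges <- data.frame(spider_probe = character(0),
                        arachnid_probe = character(0),
                        n_witness = integer(0), stringsAsFactors = FALSE)
    return(structure(list(edges = edges, witness = list()),
                     class = "homology_graph"))
  }
  key <- paste(j$spider_probe, j$arachnid_probe, sep = "\r")
  wit <- split(j$contig_id, key)
  ukey <- names(wit)
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  edges <- data.frame(spider_probe = vapply(parts, `[[`, character(1), 1L),
                      arachnid_probe = vapply(parts, `[[`, character(1), 2L),
                      n_witness = vapply(wit, function(x) length(unique(x)),
                                         integer(1)),
                      stringsAsFactors = FALSE)
  ord <- order(edges$spider_probe, edges$arachnid_probe)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  witness <- lapply(wit[ord], unique)
  names(witness) <- paste(edges$spider_probe, edges$arachnid_probe, sep = "|")
  structure(list(edges = edges, witness = witness), class = "homology_graph")
}

#' @export
print.homology_graph <- function(x, ...) {
  cat(sprintf("<homology_graph> %d edges, %d spider probes, %d arachnid probes\n",
              nrow(x$edges), length(unique(x$edges$spider_probe)),
              length(unique(x$edges$arachnid_probe))))
  invisible(x)
}

#' Blend two probe sets using an inferred homology graph
#'
#' Spider probes are always kept.  At `granularity = "probe"` exactly the
#' arachnid probes with at least one homology edge are removed; at
#' `granularity = "locus"` every probe of any arachnid locus with at least
#' one matched probe is removed (the coarser rule matching per-locus
#' duplicate removal downstream).  The locus-level removal set always
#' contains the probe-level one.
#'
#' @param spider_set,arachnid_set `probe_set` tables.
#' @param graph a `homology_graph` over the two sets.
#' @param granularity `"probe"` (default) or `"locus"`.
#' @return list with `blended` (a `probe_set` with `source_set` preserved
#'   per probe) and `report` (class `blend_report`: `n_spider`,
#'   `n_arachnid`, `n_removed`, `n_blended`, `granularity`, `removed_ids`).
#' @export
blend_probesets <- function(spider_set, arachnid_set, graph,
                            granularity = c("probe", "locus")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(graph, "homology_graph"))
  if (length(intersect(spider_set$probe_id, arachnid_set$probe_id)) > 0L) {
    stop("probe id collision between sets; namespace the kits first",
         call. = FALSE)
  }
  bad_s <- setdiff(graph$edges$spider_probe, spider_set$probe_id)
  bad_a <- setdiff(graph$edges$arachnid_probe, arachnid_set$probe_id)
  if (length(bad_s) + length(bad_a) > 0L) {
    stop("homology graph names probes absent from the sets", call. = FALSE)
  }
  matched <- unique(graph$edges$arachnid_probe)
  removed <- if (granularity == "probe") {
    matched
  } else {
    loci <- unique(arachnid_set$locus_id[arachnid_set$probe_id %in% matched])
    arachnid_set$probe_id[arachnid_set$locus_id %in% loci]
  }
  keep_a <- arachnid_set[!arachnid_set$probe_id %in% removed, , drop = FALSE]
  blended <- rbind(spider_set, keep_a)
  rownames(blended) <- NULL
  class(blended) <- c("probe_set", "data.frame")
  report <- structure(list(n_spider = nrow(spider_set),
                           n_arachnid = nrow(arachnid_set),
                           n_removed = length(removed),
                           n_blended = nrow(blended),
                           granularity = granularity,
                           removed_ids = sort(removed)),
                      class = "blend_report")
  list(blended = blended, report = report)
}

#' @export
print.blend_report <- function(x, ...) {
  cat(sprintf(paste0("<blend_report> spider %d + arachnid %d - removed %d",
                     " (granularity %s) = blended %d\n"),
              x$n_spider, x$n_arachnid, x$n_removed, x$granularity,
              x$n_blended))
  invisible(x)
}

#' Summarise per-kit locus recovery by enrichment group
#'
#' Given per-taxon counts of loci recovered by each probe set, computes the
#' arithmetic mean per (enrichment group, probe set), both rounded to the
#' nearest integer and as an exact rational (numerator/denominator).
#'
#' @param loci_per_taxon data.frame with columns `taxon`,
#'   `enrichment_group`, `probeset`, `n_loci`; each (taxon, probeset) pair
#'   at most once.
#' @return data.frame with columns `enrichment_group`, `probeset`,
#'   `n_taxa`, `mean_loci`, `mean_rounded`, `sum_loci` (the exact rational
#'   is `sum_loci / n_taxa`).
#' @export
probeset_efficacy <- function(loci_per_taxon) {
  req <- c("taxon", "enrichment_group", "probeset", "n_loci")
  stopifnot(all(req %in% names(loci_per_taxon)))
  key <- paste(loci_per_taxon$taxon, loci_per_taxon$probeset)
  if (anyDuplicated(key)) {
    stop("each (taxon, probeset) pair must appear once", call. = FALSE)
  }
  agg <- stats::aggregate(n_loci ~ enrichment_group + probeset,
                          data = loci_per_taxon,
                          FUN = function(x) c(n = length(x), sum = sum(x)))
  out <- data.frame(enrichment_group = agg$enrichment_group,
                    probeset = agg$probeset,
                    n_taxa = agg$n_loci[, "n"],
                    sum_loci = agg$n_loci[, "sum"],
                    stringsAsFactors = FALSE)
  out$mean_loci <- out$sum_loci / out$n_taxa
  out$mean_rounded <- as.integer(round(out$mean_loci))
  out[order(out$enrichment_group, out$probeset),
      c("enrichment_group", "probeset", "n_taxa", "mean_loci",
        "mean_rounded", "sum_loci")]
}
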