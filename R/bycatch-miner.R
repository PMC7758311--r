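# Mining of untargeted ("bycatch") loci — 28S rDNA and mitochondrial
# 16S-ND1 and COI — from capture assemblies.  Contigs of each taxon form a
# searchable database queried with reference gene sequences; hits are kept
# when the e-value is below 1e-10 (strict) and the aligned length exceeds
# 200 bp (strict).  When several contigs match disjoint parts of one gene
# they are stitched into a single sequence, interior gaps filled with 'N'.

#' Miner parameters
#'
#' @param evalue_max e-value ceiling; hits are kept iff
#'   `evalue < evalue_max` (strict). Default `1e-10`.
#' @param min_len aligned (HSP) length floor in bp; hits kept iff
#'   `length > min_len` (strict).  The threshold applies to the match, not
#'   the whole contig, since it is the matched gene region being retained.
#'   Default 200.
#' @param stitch_gap_fill character used to fill unmatched interior query
#'   spans when stitching.  Default `"N"`.
#' @return object of class `miner_params`.
#' @export
miner_params <- function(evalue_max = 1e-10, min_len = 200L,
                         stitch_gap_fill = "N") {
  stopifnot(evalue_max > 0, min_len >= 1L, nchar(stitch_gap_fill) == 1L)
  structure(list(evalue_max = evalue_max, min_len = as.integer(min_len),
                 stitch_gap_fill = stitch_gap_fill),
            class = "miner_params")
}

#' Build a searchable database over a taxon's contigs
#'
#' @param contigs named character vector of contig sequences, or a path to
#'   a contig FASTA.
#' @param taxon optional taxon label recorded on the database.
#' @return object of class `contig_db`.
#' @export
build_reference_db <- function(contigs, taxon = NA_character_) {
  if (is.character(contigs) && length(contigs) == 1L && is.null(names(contigs))) {
    contigs <- read_fasta(contigs)
  }
  if (length(contigs) == 0L) stop("empty contig set", call. = FALSE)
  stopifnot(!is.null(names(contigs)))
  check_alphabet(contigs, where = "contigs")
  structure(list(contigs = contigs, taxon = taxon,
                 total_length = sum(nchar(contigs))),
            class = "contig_db")
}

#' @export
print.contig_db <- function(x, ...) {
  cat(sprintf("<contig_db%s> %d contigs, %d bp\n",
              if (is.na(x$taxon)) "" else paste0(" ", x$taxon),
              length(x$contigs), x$total_length))
  invisible(x)
}

#' Search query genes against a contig database
#'
#' The builtin engine runs the gap-free k-mer matcher over both strands and
#' attaches Karlin-Altschul e-values computed from the raw ungapped score
#' (match +1 / mismatch -2; lambda 1.28, K 0.46) scaled by query length and
#' total database length.  The import engine parses a 12-column tabular hit
#' file (BLAST outfmt-6 layout) verbatim, the route to bit-exact parity
#' with an external search tool.
#'
#' @param queries named character vector of query gene sequences.
#' @param db a [build_reference_db()] database.
#' @param engine `"builtin"` or `"import"`.
#' @param params a [match_params] for the builtin engine.
#' @param hits_file path to a tabular hit file, required for
#'   `engine = "import"`.
#' @return a hit table (data.frame) with columns `query_id`, `subject_id`,
#'   `identity`, `length`, `mismatches`, `gapopen`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `strand`, `score`, `bitscore`, `evalue`.
#' @export
search_contigs <- function(queries, db, engine = c("builtin", "import"),
                           params = match_params(), hits_file = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(db, "contig_db"))
  if (engine == "import") {
    if (is.null(hits_file)) stop("import engine needs hits_file", call. = FALSE)
    return(read_hit_table(hits_file))
  }
  stopifnot(length(queries) > 0L, !is.null(names(queries)))
  k <- params$seed_word_len
  spre <- lapply(db$contigs, .prep_subject, k = k)
  rows <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qseq <- queries[[qi]]
    qpre <- .prep_query(qseq, k)
    for (ci in seq_along(db$contigs)) {
      h <- .hsps_to_df(.scan_hsps(qpre, spre[[ci]], params))
      if (nrow(h) == 0L) next
      ka <- .ka_stats(h$score, nchar(qseq), db$total_length)
      h$query_id <- qid
      h$subject_id <- names(db$contigs)[ci]
      h$gapopen <- 0L
      h$bitscore <- ka$bitscore
      h$evalue <- ka$evalue
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (length(rows) == 0L) return(empty_hit_table())
  df <- do.call(rbind, rows)
  df <- df[, c("query_id", "subject_id", "identity", "length", "mismatches",
               "gapopen", "q_start", "q_end", "s_start", "s_end", "strand",
               "score", "bitscore", "evalue")]
  df[order(df$query_id, df$evalue, df$subject_id), , drop = FALSE]
}

#' @noRd
empty_hit_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             identity = numeric(0), length = integer(0),
             mismatches = integer(0), gapopen = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), score = numeric(0),
             bitscore = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Apply the bycatch retention thresholds to a hit table
#'
#' Keeps hits with `evalue < evalue_max` and `length > min_len`, both
#' strict, preserving input order.  Idempotent, and commutes with
#' concatenation of hit tables.
#'
#' @param hits a hit table from [search_contigs()].
#' @param params a [miner_params].
#' @return the filtered hit table.
#' @export
filter_hits <- function(hits, params = miner_params()) {
  stopifnot(inherits(params, "miner_params"))
  keep <- hits$evalue < params$evalue_max & hits$length > params$min_len
  hits[keep, , drop = FALSE]
}

#' Stitch multi-contig hits to one gene into a single sequence
#'
#' All hits must share one query (the reference gene) and come from one
#' taxon's contigs.  Subject segments are orientation-normalised to the
#' query strand and laid out by query coordinate; unmatched interior query
#' spans are filled with runs of `stitch_gap_fill`; where query spans
#' overlap, the higher-bitscore hit's residues win (ties broken
#' deterministically by contig id, with a message).  The result spans from
#' the first kept hit's query start to the last hit's query end.
#'
#' @param hits hit table rows for one (taxon, locus); must be non-empty.
#' @param contigs named character vector holding every subject contig.
#' @param params a [miner_params].
#' @param id id for the output record; defaults to
#'   `<query_id>_stitched`.
#' @return named character vector of length 1 (the stitched sequence).
#' @export
stitch_contigs <- function(hits, contigs, params = miner_params(),
                           id = NULL) {
  stopifnot(nrow(hits) > 0L)
  if (length(unique(hits$query_id)) != 1L) {
    stop("all hits must share one query locus", call. = FALSE)
  }
  missing_sub <- setdiff(hits$subject_id, names(contigs))
  if (length(missing_sub) > 0L) {
    stop(sprintf("contigs missing for subjects: %s",
                 paste(missing_sub, collapse = ", ")), call. = FALSE)
  }
  bs <- if ("bitscore" %in% names(hits)) hits$bitscore else hits$score
  dupspan <- paste(hits$q_start, hits$q_end)
  if (anyDuplicated(dupspan)) {
    for (sp in unique(dupspan[duplicated(dupspan)])) {
      idx <- which(dupspan == sp)
      if (length(unique(bs[idx])) == 1L) {
        message(sprintf("tie on query span %s resolved by contig id (%s)",
                        sp, paste(sort(hits$subject_id[idx]), collapse = " > ")))
      }
    }
  }
  # write lower-priority hits first so better ones overwrite overlaps;
  # priority: bitscore asc, then contig id desc (so smallest id wins ties)
  ord <- order(bs, -xtfrm(hits$subject_id))
  span0 <- min(hits$q_start); span1 <- max(hits$q_end)
  out <- rep(params$stitch_gap_fill, span1 - span0 + 1L)
  for (i in ord) {
    seg <- substr(contigs[[hits$subject_id[i]]], hits$s_start[i], hits$s_end[i])
    if (hits$strand[i] == "-") seg <- revcomp(seg)
    qlen <- hits$q_end[i] - hits$q_start[i] + 1L
    if (nchar(seg) != qlen) {
      # gapped imports may differ; fit to the query span
      seg <- substr(seg, 1L, qlen)
      if (nchar(seg) < qlen) {
        seg <- paste0(seg, strrep(params$stitch_gap_fill, qlen - nchar(seg)))
      }
    }
    pos <- (hits$q_start[i] - span0 + 1L):(hits$q_end[i] - span0 + 1L)
    out[pos] <- strsplit(seg, "", fixed = TRUE)[[1]]
  }
  res <- paste(out, collapse = "")
  names(res) <- id %||% paste0(hits$query_id[1], "_stitched")
  res
}

# -- tabular hit file I/O (12-column, BLAST outfmt-6 layout) ----------------

.HIT_COLS <- c("query_id", "subject_id", "identity", "length", "mismatches",
               "gapopen", "q_start", "q_end", "s_start", "s_end", "evalue",
               "bitscore")

#' Write a hit table as 12-column tabular text
#'
#' Columns follow the tabular BLAST layout (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore); identity is
#' emitted as a percentage and minus-strand hits have `s_start > s_end`.
#'
#' @param hits a hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits
  minus <- out$strand == "-"
  tmp <- out$s_start[minus]
  out$s_start[minus] <- out$s_end[minus]
  out$s_end[minus] <- tmp
  out$identity <- round(100 * out$identity, 3)
  if (!"bitscore" %in% names(out)) out$bitscore <- out$score
  if (!"evalue" %in% names(out)) out$evalue <- NA_real_
  if (!"gapopen" %in% names(out)) out$gapopen <- 0L
  utils::write.table(out[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular hit file
#'
#' Strand is recovered from the subject coordinate order (`s_start >
#' s_end` means minus) and coordinates are normalised to `s_start <=
#' s_end` with an explicit `strand` column.
#'
#' @param path path to the tabular file.
#' @return a hit table as from [search_contigs()].
#' @export
read_hit_table <- function(path) {
  if (file.size(path) == 0L) return(empty_hit_table())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = .HIT_COLS,
                          colClasses = c("character", "character", "numeric",
                                         "integer", "integer", "integer",
                                         "integer", "integer", "integer",
                                         "integer", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  minus <- df$s_start > df$s_end
  tmp <- df$s_start[minus]
  df$s_start[minus] <- df$s_end[minus]
  df$s_end[minus] <- tmp
  df$strand <- ifelse(minus, "-", "+")
  df$identity <- df$identity / 100
  df$score <- (df$bitscore * log(2) + log(.KA_K)) / .KA_LAMBDA
  df[, c("query_id", "subject_id", "identity", "length", "mismatches",
         "gapopen", "q_start", "q_end", "s_start", "s_end", "strand",
         "score", "bitscore", "evalue")]
}
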