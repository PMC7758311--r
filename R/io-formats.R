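# Readers/writers for the external formats the pipeline touches, and the
# probe header grammar.  FASTA parsing is delegated to Biostrings; Newick
# parsing to ape.  Internal coordinates are 0-based half-open only inside
# the matcher; everything stored on objects or emitted to files is 1-based
# inclusive (RAxML/BLAST convention).

#' Parse bait/probe FASTA headers of the form `locus_pN`
#'
#' Probe kits name each bait `<locus>_p<index>`, where the index numbers the
#' tile within the locus (e.g. `uce-503_p1`).  The first
#' whitespace/`|`-delimited token must end in `_p<int>`; anything after the
#' delimiter is free annotation and is ignored.
#'
#' @param headers character vector of FASTA description lines.
#' @return data.frame with columns `locus_id` (character) and
#'   `probe_index` (integer), one row per header.
#' @examples
#' parse_probe_header("uce-503_p12 |design:spider2k")
#' @export
parse_probe_header <- function(headers) {
  stopifnot(is.character(headers), length(headers) > 0L)
  tok <- sub("^>", "", headers)
  tok <- sub("[ \t|].*$", "", tok)
  m <- regmatches(tok, regexec("^(.*)_p([0-9]+)$", tok))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("malformed probe header (no `_p<int>` suffix): %s",
                 paste(utils::head(headers[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  locus <- vapply(m, `[[`, character(1), 2L)
  if (any(locus == "")) {
    stop("malformed probe header: empty locus token", call. = FALSE)
  }
  data.frame(locus_id = locus,
             probe_index = as.integer(vapply(m, `[[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header and
#' must be unique.  Sequences are upper-cased and `?` is normalised to the
#' gap character `-`.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; `character(0)` for an
#'   empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("?", "-", seqs, fixed = TRUE)
  ids <- sub("[ \t].*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence ids in %s: %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  names(seqs) <- ids
  check_alphabet(seqs, where = path)
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (alignment rows may contain `-`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)) && length(seqs) > 0L) {
    stop("sequences must be named", call. = FALSE)
  }
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence ids: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Parse a Newick gene tree, requiring branch lengths
#'
#' The long-branch paralogy filter needs every edge length, so trees without
#' branch lengths are rejected.  Trees are used exactly as given (no
#' re-rooting); the filter treats the edge set as that of the parsed tree.
#'
#' @param text Newick string, or a path to a file containing one tree.
#' @return an object of class `gene_tree`: a list with elements `tree`
#'   (an [ape::read.tree] phylo), `edge_lengths` (numeric vector),
#'   `leaf_labels` (character), `newick` (the input text).
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("could not parse Newick tree", call. = FALSE)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("branch lengths required on every edge", call. = FALSE)
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative", call. = FALSE)
  }
  structure(list(tree = tr,
                 edge_lengths = tr$edge.length,
                 leaf_labels = tr$tip.label,
                 newick = text),
            class = "gene_tree")
}

#' Serialise a gene tree back to Newick
#' @param gt a `gene_tree`.
#' @return Newick string.
#' @export
write_newick <- function(gt) {
  stopifnot(inherits(gt, "gene_tree"))
  ape::write.tree(gt$tree)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d leaves, %d edges, total length %.4g\n",
              length(x$leaf_labels), length(x$edge_lengths),
              sum(x$edge_lengths)))
  invisible(x)
}

# -- partition bookkeeping ---------------------------------------------------

#' Validate that partitions tile [1, L]
#' @noRd
check_partitions <- function(partitions, matrix_length) {
  p <- partitions
  stopifnot(is.data.frame(p), all(c("name", "start", "end") %in% names(p)))
  p <- p[order(p$start), , drop = FALSE]
  if (nrow(p) == 0L) stop("no partitions", call. = FALSE)
  if (p$start[1] != 1L || p$end[nrow(p)] != matrix_length ||
      any(p$end < p$start) ||
      (nrow(p) > 1L && any(p$start[-1] != p$end[-nrow(p)] + 1L))) {
    stop("partitions must tile [1, matrix length] with no gaps or overlaps",
         call. = FALSE)
  }
  p
}

#' Construct a supermatrix bundle
#'
#' A concatenated alignment plus its ordered partition table and a dataset
#' tag recording provenance.  Partitions are 1-based inclusive column ranges
#' that tile the matrix.
#'
#' @param matrix named character vector of equal-length aligned rows.
#' @param partitions data.frame with columns `name`, `start`, `end`.
#' @param dataset_tag one of `"UCEs"`, `"mtDNA_28S"`, `"restricted_mtDNA_28S"`,
#'   `"UCEs_mtDNA_28S"`, or any label.
#' @param partitioned logical; whether downstream analysis should use the
#'   partition table (datasets analysed unpartitioned keep the table for
#'   bookkeeping but no partition file is emitted).
#' @return object of class `supermatrix_bundle`.
#' @export
supermatrix_bundle <- function(matrix, partitions, dataset_tag = "custom",
                               partitioned = TRUE) {
  widths <- unique(nchar(matrix))
  if (length(widths) != 1L) stop("matrix rows must have equal length",
                                 call. = FALSE)
  partitions <- check_partitions(partitions, widths)
  structure(list(matrix = matrix, partitions = partitions,
                 dataset_tag = dataset_tag, partitioned = partitioned),
            class = "supermatrix_bundle")
}

#' @export
print.supermatrix_bundle <- function(x, ...) {
  cat(sprintf("<supermatrix_bundle '%s'> %d taxa x %d sites, %d partition(s)%s\n",
              x$dataset_tag, length(x$matrix), nchar(x$matrix[[1]]),
              nrow(x$partitions),
              if (x$partitioned) "" else " (analysed unpartitioned)"))
  invisible(x)
}

#' Emit a partition table as RAxML or NEXUS sets text
#'
#' Ranges are 1-based inclusive, must tile the matrix, and are emitted in
#' order.  The RAxML dialect writes `DNA, name = a-b` lines; the NEXUS
#' dialect a `sets` block of `charset` commands.
#'
#' @param bundle a [supermatrix_bundle].
#' @param dialect `"raxml"` or `"nexus_sets"`.
#' @param path optional output file.
#' @return the partition text, invisibly if `path` is given.
#' @export
write_partitions <- function(bundle, dialect = c("raxml", "nexus_sets"),
                             path = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(bundle, "supermatrix_bundle"))
  p <- check_partitions(bundle$partitions, nchar(bundle$matrix[[1]]))
  nm <- ifelse(p$name == "", sprintf("part%d", seq_len(nrow(p))), p$name)
  txt <- switch(dialect,
    raxml = paste(sprintf("DNA, %s = %d-%d", nm, p$start, p$end),
                  collapse = "\n"),
    nexus_sets = paste(c("#nexus", "begin sets;",
                         sprintf("  charset %s = %d-%d;", nm, p$start, p$end),
                         "end;"), collapse = "\n"))
  txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' Missing cells are already encoded in the matrix; `?` is conventional in
#' PHYLIP/NEXUS output while FASTA output uses `-`.
#'
#' @param bundle a [supermatrix_bundle].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(bundle, path) {
  stopifnot(inherits(bundle, "supermatrix_bundle"))
  m <- bundle$matrix
  lines <- c(sprintf("%d %d", length(m), nchar(m[[1]])),
             sprintf("%s  %s", names(m), unname(m)))
  writeLines(lines, path)
  invisible(path)
}
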