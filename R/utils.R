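# Internal helpers shared across modules.

# Valid characters in stored sequences: IUPAC nucleotide codes plus the
# alignment gap '-'.  '?' is accepted on ingest and normalised to '-'.
.IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

#' Run code with a local, restorable RNG state
#'
#' All generators take a single integer seed and leave the caller's RNG
#' untouched (no global state leaks between calls).
#' @noRd
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Random DNA string(s)
#' @noRd
random_dna <- function(len, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of plain character DNA
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Point-mutate a DNA string: each site substituted with prob `rate`
#' (substitution-only, so planted coordinates stay exact)
#' @noRd
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars[hit] <- vapply(chars[hit], function(b) {
      a <- alts[[b]]
      if (is.null(a)) b else sample(a, 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Validate a sequence vector against the IUPAC+gap alphabet
#' @noRd
check_alphabet <- function(seqs, where = "sequence") {
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% .IUPAC_CHARS)
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("non-IUPAC characters in %s: %s", where,
                 paste(utils::head(names(seqs)[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seqs)
}

#' Split aligned rows into a character matrix (rows = sequences)
#' @noRd
aln_matrix <- function(alignment) {
  widths <- nchar(alignment)
  if (length(unique(widths)) > 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

#' Collapse a character matrix back to named rows
#' @noRd
aln_collapse <- function(m) {
  out <- apply(m, 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
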