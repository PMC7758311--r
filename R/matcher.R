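# Built-in similarity search: a k-mer-seeded, gap-free extension aligner.
# Seeds are exact k-mer matches; all seeds on one diagonal are merged and the
# highest-scoring contiguous gap-free segment on that diagonal (match +1,
# mismatch -2, Kadane scan) is reported as the HSP.  Both strands of the
# query are searched.  This stands in for lastz-style matching in probe-set
# blending and, with Karlin-Altschul e-values attached, for blastn in
# bycatch mining; externally produced tabular hit files can be imported
# whenever bit-exact parity with the real tools is wanted.

.MATCH_SCORE <- 1
.MISMATCH_SCORE <- -2
# Ungapped Karlin-Altschul parameters for the +1/-2 DNA scoring scheme.
.KA_LAMBDA <- 1.28
.KA_K <- 0.46

#' Matcher parameters
#'
#' @param seed_word_len exact-match seed length (bp); defaults to 11, the
#'   classic blastn word size.
#' @param min_identity minimum fraction of identical sites in a reported hit.
#' @param min_hit_len minimum hit length in bp; must be at least
#'   `seed_word_len`.
#' @return object of class `match_params`.
#' @export
match_params <- function(seed_word_len = 11L, min_identity = 0.80,
                         min_hit_len = 50L) {
  stopifnot(seed_word_len >= 4L, min_identity > 0, min_identity <= 1)
  if (min_hit_len < seed_word_len) {
    stop("min_hit_len must be >= seed_word_len", call. = FALSE)
  }
  structure(list(seed_word_len = as.integer(seed_word_len),
                 min_identity = min_identity,
                 min_hit_len = as.integer(min_hit_len)),
            class = "match_params")
}

#' All k-mers of a character vector of bases, as strings
#' @noRd
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Best gap-free segment on one diagonal (0-based offsets internally;
#' returns 1-based inclusive coordinates).  Ends are anchored: the segment
#' is trimmed to the outermost runs of >= `anchor` consecutive matches, so
#' a lucky short match run in flanking sequence cannot drag the boundary
#' past the true homologous region.
#' @noRd
.diag_hsp <- function(qchars, schars, d, anchor) {
  nq <- length(qchars); ns <- length(schars)
  i0 <- max(1L, 1L - d); i1 <- min(nq, ns - d)
  if (i1 < i0) return(NULL)
  idx <- i0:i1
  is_match <- qchars[idx] == schars[idx + d]
  sc <- ifelse(is_match, .MATCH_SCORE, .MISMATCH_SCORE)
  # Kadane scan with segment tracking
  best <- -Inf; cur <- 0; cs <- 1L; ba <- 1L; bb <- 0L
  for (j in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[j]; cs <- j } else cur <- cur + sc[j]
    if (cur > best) { best <- cur; ba <- cs; bb <- j }
  }
  if (best <= 0) return(NULL)
  # anchor-trim: ends must sit on an exact run of >= anchor matches
  r <- rle(is_match[ba:bb])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= anchor)
  if (length(good) == 0L) return(NULL)
  ba2 <- ba + starts[good[1]] - 1L
  bb2 <- ba + ends[good[length(good)]] - 1L
  ba <- ba2; bb <- bb2
  q_start <- idx[ba]; q_end <- idx[bb]
  nmatch <- sum(is_match[ba:bb])
  len <- q_end - q_start + 1L
  score <- nmatch * .MATCH_SCORE + (len - nmatch) * .MISMATCH_SCORE
  list(q_start = q_start, q_end = q_end,
       s_start = q_start + d, s_end = q_end + d,
       length = len, identity = nmatch / len,
       mismatches = len - nmatch, score = score)
}

#' Precompute a subject's character vector and k-mer position index
#' @noRd
.prep_subject <- function(subject, k) {
  list(chars = strsplit(subject, "", fixed = TRUE)[[1]],
       index = split(seq_len(max(0L, nchar(subject) - k + 1L)),
                     .kmers(subject, k)))
}

#' Precompute both orientations of a query
#' @noRd
.prep_query <- function(query, k) {
  rc <- revcomp(query)
  list(len = nchar(query),
       `+` = list(chars = strsplit(query, "", fixed = TRUE)[[1]],
                  kmers = .kmers(query, k)),
       `-` = list(chars = strsplit(rc, "", fixed = TRUE)[[1]],
                  kmers = .kmers(rc, k)))
}

#' HSP scan against precomputed query/subject structures
#' @noRd
.scan_hsps <- function(qp, sp, params) {
  k <- params$seed_word_len
  out <- list()
  for (strand in c("+", "-")) {
    qo <- qp[[strand]]
    hitidx <- which(qo$kmers %in% names(sp$index))
    if (length(hitidx) == 0L) next
    diags <- unique(unlist(lapply(hitidx,
                                  function(i) sp$index[[qo$kmers[i]]] - i),
                           use.names = FALSE))
    for (d in diags) {
      h <- .diag_hsp(qo$chars, sp$chars, d, anchor = k)
      if (is.null(h)) next
      if (h$length < params$min_hit_len || h$identity < params$min_identity) next
      if (strand == "-") {
        qs <- qp$len - h$q_end + 1L; qe <- qp$len - h$q_start + 1L
        h$q_start <- qs; h$q_end <- qe
      }
      h$strand <- strand
      out[[length(out) + 1L]] <- h
    }
  }
  out
}

#' Gap-free HSPs of one query against one subject, both strands
#'
#' Coordinates are 1-based inclusive on the forward strand of both
#' sequences; `strand == "-"` means the query matches the reverse
#' complement of the subject interval.
#'
#' @param query,subject plain DNA strings.
#' @param params a [match_params].
#' @return data.frame of hits (possibly 0 rows) with columns `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand`, `length`, `identity`,
#'   `mismatches`, `score`.
#' @export
find_hsps <- function(query, subject, params = match_params()) {
  stopifnot(inherits(params, "match_params"))
  k <- params$seed_word_len
  out <- .scan_hsps(.prep_query(query, k), .prep_subject(subject, k), params)
  .hsps_to_df(out)
}

#' @noRd
.hsps_to_df <- function(out) {
  if (length(out) == 0L) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), mismatches = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(out, function(h) {
    data.frame(q_start = h$q_start, q_end = h$q_end, s_start = h$s_start,
               s_end = h$s_end, strand = h$strand, length = h$length,
               identity = h$identity, mismatches = h$mismatches,
               score = h$score, stringsAsFactors = FALSE)
  }))
  # deduplicate identical segments found via multiple seeds
  df <- unique(df)
  df[order(-df$score, df$q_start), , drop = FALSE]
}

#' Karlin-Altschul e-value and bit score for a raw ungapped score
#' @noRd
.ka_stats <- function(score, query_len, db_len) {
  bits <- (.KA_LAMBDA * score - log(.KA_K)) / log(2)
  evalue <- .KA_K * query_len * db_len * exp(-.KA_LAMBDA * score)
  list(bitscore = bits, evalue = evalue)
}
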