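# Shared fixture builders (all fixtures are generated in code).

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# a gene_tree directly from Newick text
gt <- function(newick) read_newick(newick)

# a locus_record with n_in ingroup taxa (in01..) and n_out outgroup taxa
# (out01..), identical 20 bp rows, optional tree
make_locus <- function(id, n_in, n_out, tree = NULL, seqlen = 20L) {
  taxa <- c(sprintf("in%02d", seq_len(n_in)),
            if (n_out > 0) sprintf("out%02d", seq_len(n_out)))
  row <- strrep("ACGT", seqlen / 4L)
  locus_record(id, stats::setNames(rep(row, length(taxa)), taxa), tree)
}

# star-like tree over given taxa with explicit edge lengths
star_tree <- function(taxa, lengths) {
  stopifnot(length(taxa) == length(lengths))
  nwk <- paste0("(", paste(sprintf("%s:%g", taxa, lengths), collapse = ","),
                ");")
  read_newick(nwk)
}

# a minimal one-row hit table for stitch tests
hit_row <- function(query_id, subject_id, q_start, q_end, s_start, s_end,
                    strand = "+", bitscore = 100, identity = 1) {
  len <- q_end - q_start + 1L
  data.frame(query_id = query_id, subject_id = subject_id,
             identity = identity, length = len, mismatches = 0L,
             gapopen = 0L, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, strand = strand,
             score = bitscore, bitscore = bitscore, evalue = 1e-50,
             stringsAsFactors = FALSE)
}
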