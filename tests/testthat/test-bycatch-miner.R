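test_that("contig databases index planted content deterministically", {
  set.seed(51)
  gene <- c(q28S = rand_dna(500))
  contigs <- c(c1 = paste0(rand_dna(100), gene[[1]], rand_dna(100)),
               c2 = rand_dna(400), c3 = rand_dna(350))
  db <- build_reference_db(contigs, taxon = "t1")
  h <- search_contigs(gene, db)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(c(h$q_start, h$q_end), c(1L, 500L))
  expect_equal(c(h$s_start, h$s_end), c(101L, 600L))
  expect_lt(h$evalue, 1e-10)

  expect_error(build_reference_db(character(0)), "empty")
  h2 <- search_contigs(gene, build_reference_db(contigs, taxon = "t1"))
  expect_identical(h, h2)
})

test_that("minus-strand plantings are found with strand '-'", {
  set.seed(52)
  gene <- c(coi = rand_dna(450))
  contigs <- c(c1 = paste0(rand_dna(90), rc(gene[[1]]), rand_dna(90)))
  h <- search_contigs(gene, build_reference_db(contigs))
  expect_equal(h$strand, "-")
  expect_identical(rc(substr(contigs[[1]], h$s_start, h$s_end)), gene[[1]])
})

test_that("shuffled contigs are an empty null at the e-value threshold", {
  set.seed(53)
  gene <- c(g = rand_dna(600))
  for (i in 1:25) {
    shuffled <- c(s = paste(sample(strsplit(gene[[1]], "")[[1]]),
                            collapse = ""))
    h <- search_contigs(gene, build_reference_db(shuffled))
    expect_true(nrow(h) == 0L || all(h$evalue >= 1e-10))
  }
})

test_that("retention thresholds are strict on both e-value and length", {
  base <- hit_row("q", "c1", 1, 250, 1, 250)
  base$evalue <- 1e-11; base$length <- 250L
  kept <- filter_hits(base)
  expect_equal(nrow(kept), 1L)

  at_e <- base; at_e$evalue <- 1e-10
  expect_equal(nrow(filter_hits(at_e)), 0L)   # exactly 1e-10 is removed

  at_len <- base; at_len$length <- 200L
  expect_equal(nrow(filter_hits(at_len)), 0L) # exactly 200 is removed

  # idempotent and commutes with concatenation
  two <- rbind(base, at_e)
  expect_identical(filter_hits(filter_hits(two)), filter_hits(two))
  expect_identical(filter_hits(rbind(base, at_len)),
                   rbind(filter_hits(base), filter_hits(at_len)))
})

test_that("stitching fills interior gaps and keeps best residues in overlaps", {
  set.seed(54)
  gene <- rand_dna(700)
  # hits covering query 1-300 and 401-700 -> length 700 with 100 N fill
  c1 <- substr(gene, 1, 300); c2 <- substr(gene, 401, 700)
  contigs <- c(c1 = c1, c2 = c2)
  hits <- rbind(hit_row("g", "c1", 1, 300, 1, 300),
                hit_row("g", "c2", 401, 700, 1, 300))
  st <- unname(stitch_contigs(hits, contigs))
  expect_equal(nchar(st), 700L)
  expect_identical(substr(st, 301, 400), strrep("N", 100))
  expect_identical(substr(st, 1, 300), c1)
  expect_identical(substr(st, 401, 700), c2)

  # single hit returned as its matching segment unchanged
  single <- stitch_contigs(hit_row("g", "c1", 1, 300, 1, 300), contigs)
  expect_identical(unname(single), c1)

  # overlap: higher bitscore wins the shared span
  cA <- substr(gene, 1, 400)
  cB <- paste0(strrep("T", 50), substr(gene, 351, 700))
  hits2 <- rbind(hit_row("g", "cA", 1, 400, 1, 400, bitscore = 200),
                 hit_row("g", "cB", 301, 700, 1, 400, bitscore = 150))
  st2 <- unname(stitch_contigs(hits2, c(cA = cA, cB = cB)))
  expect_identical(substr(st2, 301, 400), substr(cA, 301, 400))

  # identical spans with equal bitscore: deterministic contig-id tie-break
  hits3 <- rbind(hit_row("g", "cZ", 1, 300, 1, 300, bitscore = 99),
                 hit_row("g", "cY", 1, 300, 1, 300, bitscore = 99))
  expect_message(st3 <- stitch_contigs(hits3, c(cZ = strrep("A", 300),
                                                cY = strrep("G", 300))),
                 "tie")
  expect_identical(unname(st3), strrep("G", 300))  # smallest id wins
})

test_that("noise-free split genes are recovered exactly end to end", {
  genes <- c(g16 = rand_dna(640), coi = rand_dna(660))
  for (s in c(61, 62, 63)) {
    g <- gen_contigs(c("tA", "tB"), NULL, off_target_genes = genes,
                     noise_rate = 0, seed = s)
    for (tx in c("tA", "tB")) {
      db <- build_reference_db(g$contigs[[tx]], taxon = tx)
      hits <- filter_hits(search_contigs(genes, db))
      for (gn in names(genes)) {
        st <- stitch_contigs(hits[hits$query_id == gn, , drop = FALSE],
                             g$contigs[[tx]])
        expect_identical(unname(st), unname(genes[[gn]]))
      }
    }
  }
})

test_that("tabular hit files round-trip and drive identical stitches", {
  set.seed(55)
  gene <- c(gg = rand_dna(620))
  g <- gen_contigs("tX", NULL, off_target_genes = gene, noise_rate = 0,
                   seed = 56)
  db <- build_reference_db(g$contigs$tX)
  hits <- filter_hits(search_contigs(gene, db))
  rownames(hits) <- NULL
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, f)
  imported <- search_contigs(gene, db, engine = "import", hits_file = f)
  expect_identical(imported$strand, hits$strand)
  expect_identical(imported[, c("q_start", "q_end", "s_start", "s_end")],
                   hits[, c("q_start", "q_end", "s_start", "s_end")])
  st1 <- stitch_contigs(hits, g$contigs$tX)
  st2 <- stitch_contigs(imported, g$contigs$tX)
  expect_identical(unname(st1), unname(st2))
  expect_error(search_contigs(gene, db, engine = "import"), "hits_file")
})
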