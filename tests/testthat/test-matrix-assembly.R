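test_that("rotation brings the anchor to position 1", {
  expect_equal(rotate_to_anchor("TTAGGC", "AGG"), "AGGCTT")
  expect_equal(rotate_to_anchor("AGGCTT", "AGG"), "AGGCTT")  # already anchored
  set.seed(71)
  g <- rand_dna(400)
  anchor <- substr(g, 151, 190)
  rot <- rotate_to_anchor(g, anchor)
  expect_equal(substr(rot, 1, 40), anchor)
  expect_error(rotate_to_anchor(g, rand_dna(40)), "anchor not found")
})

test_that("rotation handles minus-strand genomes via reverse complement", {
  set.seed(72)
  g <- rand_dna(500)
  anchor <- substr(g, 101, 140)
  flipped <- rc(g)
  rot <- rotate_to_anchor(flipped, anchor)
  expect_identical(rot, rotate_to_anchor(g, anchor))
  # output is a cyclic permutation of RC(input): substring of doubled RC
  expect_true(grepl(rot, paste0(rc(flipped), rc(flipped)), fixed = TRUE))
})

test_that("legacy-parity trimming follows the column-quorum rule", {
  # legacy non-gap column counts [0,1,2,3,3,3,2,1] -> kept columns 4-6
  legacy <- c(
    legacy1 = "-XXXXX--",
    legacy2 = "--XXXXX-",
    legacy3 = "---XXXXX")
  legacy <- gsub("X", "A", legacy)
  aln <- c(long1 = "GGGGGGGG", long2 = "CCCCCCCC", legacy)
  counts <- colSums(do.call(rbind, strsplit(unname(legacy), "")) != "-")
  expect_equal(counts, c(0, 1, 2, 3, 3, 3, 2, 1))
  tr <- legacy_parity_trim(aln, trim_params(3, names(legacy)))
  expect_equal(tr$boundaries$keep_start, 4L)
  expect_equal(tr$boundaries$keep_end, 6L)
  expect_equal(unique(nchar(tr$alignment)), 3L)
  expect_identical(unname(tr$alignment["long1"]), "GGG")

  # every column already at quorum -> identity
  full <- c(l1 = "AAAA", l2 = "CCCC", l3 = "GGGG", x = "TTTT")
  tr2 <- legacy_parity_trim(full, trim_params(3, c("l1", "l2", "l3")))
  expect_identical(tr2$alignment, full)

  # idempotent
  tr3 <- legacy_parity_trim(tr$alignment, trim_params(3, names(legacy)))
  expect_identical(tr3$alignment, tr$alignment)

  expect_error(legacy_parity_trim(aln, trim_params(5, names(legacy))),
               "legacy rows")
})

test_that("segment-wise trimming never removes interior columns", {
  set.seed(73)
  for (i in 1:10) {
    ma <- gen_mixed_alignment(6, 4, 600, 250, c(50, 250),
                              seed = 7000 + i)
    segs <- data.frame(name = c("pre", "core", "post"),
                       start = c(1L, 201L, 401L), end = c(200L, 400L, 600L))
    tr <- legacy_parity_trim(ma$alignment,
                             trim_params(3, ma$truth$legacy_ids, segs))
    b <- tr$boundaries
    # per segment, boundary columns carry >= 3 legacy non-gaps
    m <- do.call(rbind, strsplit(ma$alignment[ma$truth$legacy_ids], ""))
    cov <- colSums(m != "-")
    for (j in seq_len(nrow(b))) {
      if (!is.na(b$keep_start[j])) {
        expect_gte(cov[b$keep_start[j]], 3)
        expect_gte(cov[b$keep_end[j]], 3)
        # nothing dropped strictly inside the kept span
        inside <- seq(b$keep_start[j], b$keep_end[j])
        expect_equal(b$keep_end[j] - b$keep_start[j] + 1L, length(inside))
      }
    }
  }
})

test_that("manual trims remove columns matrix-wide and blank rows locally", {
  # the 28S arithmetic: 18646 columns minus 1593 leading and 9793 trailing
  wide <- c(r1 = strrep("A", 18646), r2 = strrep("C", 18646))
  cfg <- curation_config(column_trims = list(c(1L, 1593L),
                                             c(8854L, 18646L)))
  out <- apply_manual_trims(wide, cfg)
  expect_equal(unique(nchar(out)), 18646L - 1593L - 9793L)
  expect_equal(unique(nchar(out)), 7260L)

  expect_identical(apply_manual_trims(wide, curation_config()), wide)

  # per-sequence trim: the row gains exactly 183 gap characters
  aln <- c(s1 = strrep("G", 500), s2 = strrep("T", 500))
  cfg2 <- curation_config(sequence_trims = list(s1 = list(c(318L, 500L))))
  out2 <- apply_manual_trims(aln, cfg2)
  expect_equal(sum(strsplit(out2[["s1"]], "")[[1]] == "-"), 183L)
  expect_identical(out2[["s2"]], aln[["s2"]])

  expect_error(apply_manual_trims(aln, curation_config(
    column_trims = list(c(0L, 10L)))), "out of bounds")
  expect_error(apply_manual_trims(aln, curation_config(
    sequence_trims = list(s1 = list(c(400L, 600L))))), "out of bounds")
})

test_that("concatenation conserves cells and partitions splice back", {
  b28 <- c(t1 = strrep("A", 1181), t2 = strrep("C", 1181))
  bmt <- c(t1 = strrep("G", 2211), t3 = strrep("T", 2211))
  b <- concatenate_blocks(list(`28S` = b28, mtDNA = bmt))
  expect_equal(nchar(b$matrix[["t1"]]), 3392L)
  expect_equal(b$partitions$start, c(1L, 1182L))
  expect_equal(b$partitions$end, c(1181L, 3392L))
  # taxon absent from a block gets fill there
  expect_identical(splice_partition(b, "mtDNA")[["t2"]], strrep("?", 2211))
  expect_identical(splice_partition(b, "28S")[["t1"]], b28[["t1"]])

  single <- concatenate_blocks(list(only = b28))
  expect_equal(nrow(single$partitions), 1L)
  expect_equal(single$partitions$end, 1181L)

  expect_error(concatenate_blocks(list(x = c(t1 = "AC", t1 = "GG"))),
               "duplicate taxon")
})

test_that("splice-back equality holds on random block sets", {
  set.seed(74)
  taxa <- sprintf("t%02d", 1:8)
  for (rep in 1:10) {
    nb <- sample(2:4, 1)
    blocks <- list()
    for (j in seq_len(nb)) {
      w <- sample(10:60, 1)
      tx <- sample(taxa, sample(3:8, 1))
      blocks[[sprintf("blk%d", j)]] <-
        stats::setNames(vapply(tx, function(x) rand_dna(w), character(1)), tx)
    }
    b <- concatenate_blocks(blocks, missing_fill = "-")
    expect_equal(nchar(b$matrix[[1]]),
                 sum(vapply(blocks, function(x) nchar(x[[1]]), integer(1))))
    for (j in seq_len(nb)) {
      back <- splice_partition(b, sprintf("blk%d", j))
      orig <- blocks[[j]]
      for (tx in names(orig)) expect_identical(back[[tx]], orig[[tx]])
      absent <- setdiff(names(b$matrix), names(orig))
      for (tx in absent) {
        expect_identical(back[[tx]], strrep("-", nchar(orig[[1]])))
      }
    }
  }
})

test_that("the four datasets carry the stated widths and partition settings", {
  ma28 <- gen_mixed_alignment(6, 4, 500, 220, c(50, 250), seed = 75)
  mamt <- gen_mixed_alignment(6, 4, 800, 320, c(100, 400), seed = 76)
  uce <- list(`uce-1` = c(t1 = rand_dna(30), t2 = rand_dna(30)),
              `uce-2` = c(t1 = rand_dna(40), t3 = rand_dna(40)))
  tp28 <- trim_params(3, ma28$truth$legacy_ids)
  tpmt <- trim_params(3, mamt$truth$legacy_ids)
  ds <- assemble_datasets(uce, ma28$alignment, mamt$alignment, tp28, tpmt)
  w <- vapply(ds, function(d) nchar(d$matrix[[1]]), integer(1))
  expect_equal(unname(w["UCEs"]), 70L)
  expect_equal(unname(w["UCEs_mtDNA_28S"]),
               unname(w["UCEs"] + w["restricted_mtDNA_28S"]))
  expect_equal(ds$mtDNA_28S$partitions$name, c("28S", "mtDNA"))
  expect_true(ds$mtDNA_28S$partitioned)
  expect_true(ds$restricted_mtDNA_28S$partitioned)
  expect_false(ds$UCEs$partitioned)
  expect_false(ds$UCEs_mtDNA_28S$partitioned)
  # restricted widths equal the truth order-statistic spans
  tb28 <- ma28$truth$trim_boundaries
  tbmt <- mamt$truth$trim_boundaries
  expect_equal(unname(w["restricted_mtDNA_28S"]),
               (tb28[2] - tb28[1] + 1L) + (tbmt[2] - tbmt[1] + 1L))
})
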