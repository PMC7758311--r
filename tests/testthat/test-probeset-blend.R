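test_that("matcher finds planted probes exactly, on both strands", {
  set.seed(21)
  probe <- rand_dna(120)
  flank1 <- rand_dna(80); flank2 <- rand_dna(80)
  contig_plus <- paste0(flank1, probe, flank2)
  contig_minus <- paste0(flank1, rc(probe), flank2)

  h <- find_hsps(probe, contig_plus)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$strand, "+")
  expect_equal(c(h$s_start, h$s_end), c(81L, 200L))

  # reverse-complement oracle: minus-strand hit at the same subject interval
  h2 <- find_hsps(probe, contig_minus)
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$s_start, h2$s_end), c(81L, 200L))
  seg <- rc(substr(contig_minus, h2$s_start, h2$s_end))
  expect_identical(seg, substr(probe, h2$q_start, h2$q_end))
})

test_that("unrelated random sequences yield no hits at default settings", {
  set.seed(22)
  for (i in 1:25) {
    contig <- rand_dna(1000)
    probe <- rand_dna(120)
    expect_equal(nrow(find_hsps(probe, contig)), 0L)
  }
})

test_that("probe homology is inferred exactly from contig co-matches", {
  # contig c1 hits s1 and a1 only -> single edge (s1, a1) witnessed by c1
  hs <- data.frame(probe_id = c("s1", "s2"), contig_id = c("c1", "c2"))
  ha <- data.frame(probe_id = "a1", contig_id = "c1")
  g <- infer_probe_homology(hs, ha)
  expect_equal(g$edges$spider_probe, "s1")
  expect_equal(g$edges$arachnid_probe, "a1")
  expect_equal(g$witness[["s1|a1"]], "c1")

  # contig hitting two spider probes but no arachnid probe -> empty graph
  hs2 <- data.frame(probe_id = c("s1", "s2"), contig_id = c("c1", "c1"))
  ha2 <- data.frame(probe_id = character(0), contig_id = character(0))
  expect_equal(nrow(infer_probe_homology(hs2, ha2)$edges), 0L)

  # disjoint contig sets -> empty graph
  ha3 <- data.frame(probe_id = "a1", contig_id = "c9")
  expect_equal(nrow(infer_probe_homology(hs2, ha3)$edges), 0L)
})

test_that("blending follows the removal rule and its set arithmetic", {
  mk <- function(ids, src) {
    df <- data.frame(probe_id = paste0(ids, "_p1"),
                     locus_id = ids, probe_index = 1L,
                     sequence = strrep("A", 30), source_set = src,
                     stringsAsFactors = FALSE)
    class(df) <- c("probe_set", "data.frame")
    df
  }
  spider <- mk(c("s1", "s2", "s3"), "spider")
  arachnid <- mk(c("a1", "a2"), "arachnid")
  g <- structure(list(
    edges = data.frame(spider_probe = "s1_p1", arachnid_probe = "a1_p1",
                       n_witness = 1L),
    witness = list(`s1_p1|a1_p1` = "c1")), class = "homology_graph")

  b <- blend_probesets(spider, arachnid, g, granularity = "probe")
  expect_setequal(b$blended$probe_id, c("s1_p1", "s2_p1", "s3_p1", "a2_p1"))
  expect_equal(b$report$n_blended, 4L)
  # spider never removed; arithmetic identity
  expect_true(all(spider$probe_id %in% b$blended$probe_id))
  expect_equal(b$report$n_blended,
               b$report$n_spider + b$report$n_arachnid - b$report$n_removed)

  empty_g <- infer_probe_homology(
    data.frame(probe_id = character(0), contig_id = character(0)),
    data.frame(probe_id = character(0), contig_id = character(0)))
  b0 <- blend_probesets(spider, arachnid, empty_g)
  expect_equal(b0$report$n_blended, nrow(spider) + nrow(arachnid))

  expect_error(blend_probesets(spider, spider, g), "collision")
})

test_that("locus-level removal contains probe-level removal", {
  ps <- gen_probesets(4, 2, 2, probes_per_locus = 3L, seed = 31)
  gc <- gen_contigs("t1", ps$truth, noise_rate = 0, seed = 32)
  contigs <- unlist(unname(gc$contigs))
  hs <- match_probes_to_contigs(contigs, ps$spider)
  ha <- match_probes_to_contigs(contigs, ps$arachnid)
  g <- infer_probe_homology(hs, ha)
  bp <- blend_probesets(ps$spider, ps$arachnid, g, "probe")
  bl <- blend_probesets(ps$spider, ps$arachnid, g, "locus")
  expect_true(all(bp$report$removed_ids %in% bl$report$removed_ids))
  expect_gte(bl$report$n_removed, bp$report$n_removed)
})

test_that("probeset efficacy means match brute-force recomputation", {
  tbl <- data.frame(
    taxon = c("t1", "t2"),
    enrichment_group = "spider-enriched",
    probeset = "arachnid",
    n_loci = c(100L, 168L))
  e <- probeset_efficacy(tbl)
  expect_equal(e$mean_rounded, 134L)
  expect_equal(e$mean_loci, 134)

  single <- probeset_efficacy(data.frame(taxon = "t1",
                                         enrichment_group = "g",
                                         probeset = "spider", n_loci = 57L))
  expect_equal(single$mean_loci, 57)

  # synthetic 16+4 design vs independent mean oracle
  set.seed(33)
  big <- expand.grid(taxon = sprintf("t%02d", 1:20),
                     probeset = c("spider", "arachnid", "blended"),
                     stringsAsFactors = FALSE)
  big$enrichment_group <- ifelse(big$taxon %in% sprintf("t%02d", 1:16),
                                 "spider-enriched", "arachnid-enriched")
  big$n_loci <- sample(50:1200, nrow(big), replace = TRUE)
  e2 <- probeset_efficacy(big)
  for (i in seq_len(nrow(e2))) {
    sel <- big$enrichment_group == e2$enrichment_group[i] &
      big$probeset == e2$probeset[i]
    expect_equal(e2$mean_loci[i], mean(big$n_loci[sel]))
  }

  dup <- rbind(tbl, tbl[1, ])
  expect_error(probeset_efficacy(dup), "once")
})
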