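test_that("gen_probesets produces the forced counts and homology structure", {
  ps <- gen_probesets(10, 5, 5, probes_per_locus = 2L, probe_len = 120L,
                      divergence = 0.05, seed = 1)
  expect_equal(nrow(ps$spider), 30L)
  expect_equal(nrow(ps$arachnid), 30L)
  expect_equal(length(unique(ps$truth$probe_homology_pairs$locus)), 10L)
  # every homologous pair shares a generating locus
  expect_true(all(ps$truth$probe_homology_pairs$locus %in%
                    ps$spider$locus_id))

  ident <- gen_probesets(3, 0, 0, divergence = 0, seed = 2)
  expect_identical(ident$spider$sequence, ident$arachnid$sequence)

  again <- gen_probesets(10, 5, 5, probes_per_locus = 2L, probe_len = 120L,
                         divergence = 0.05, seed = 1)
  expect_identical(ps$spider, again$spider)
  expect_identical(ps$arachnid, again$arachnid)

  expect_error(gen_probesets(2, 1, 1, probe_len = 10), "probe_len")
})

test_that("gen_contigs plants features at recorded coordinates and strands", {
  gene <- c(g1 = rand_dna(600))
  g <- gen_contigs(c("t1", "t2"), NULL, off_target_genes = gene,
                   noise_rate = 0, seed = 3)
  pg <- g$truth$planted_gene_coords
  expect_true(all(c("t1", "t2") %in% pg$taxon))
  for (i in seq_len(nrow(pg))) {
    ctg <- g$contigs[[pg$taxon[i]]][[pg$contig[i]]]
    seg <- substr(ctg, pg$s_start[i], pg$s_end[i])
    if (pg$strand[i] == "-") seg <- rc(seg)
    expect_identical(seg, substr(gene[[1]], pg$q_start[i], pg$q_end[i]))
  }
  # fragments partition the gene contiguously per taxon
  for (tx in c("t1", "t2")) {
    p <- pg[pg$taxon == tx, ]
    p <- p[order(p$q_start), ]
    expect_equal(p$q_start[1], 1L)
    expect_equal(p$q_end[nrow(p)], 600L)
    if (nrow(p) > 1) expect_equal(p$q_start[-1], p$q_end[-nrow(p)] + 1L)
  }
  g2 <- gen_contigs(c("t1", "t2"), NULL, off_target_genes = gene,
                    noise_rate = 0, seed = 3)
  expect_identical(g$contigs, g2$contigs)
})

test_that("gen_locus_set plants exact filter labels deterministically", {
  ls <- gen_locus_set(40, 12, 8, n_fail_occupancy = 7,
                      n_fail_long_branch = 4, ratio_lo = 2, ratio_hi = 5.5,
                      seed = 5)
  lab <- ls$truth$locus_filter_labels
  expect_equal(sum(lab == "fail_occupancy"), 7L)
  expect_equal(sum(lab == "fail_long_branch"), 4L)
  expect_equal(sum(lab == "pass"), 29L)
  # planted occupancy failures really violate the rule
  for (i in which(lab == "fail_occupancy")) {
    l <- ls$loci[[i]]
    n_in <- sum(l$taxa %in% ls$truth$ingroup_taxa)
    expect_true(length(l$taxa) < 6 || n_in < 3)
  }
  # planted long-branch trees are at or above 5, passers at or below 2
  for (i in which(lab == "fail_long_branch")) {
    expect_gte(branch_ratio(ls$loci[[i]]$tree), 5)
  }
  for (i in which(lab == "pass")) {
    expect_lte(branch_ratio(ls$loci[[i]]$tree), 2 + 1e-9)
  }

  all_pass <- gen_locus_set(10, 12, 8, 0, 0, seed = 6)
  expect_true(all(all_pass$truth$locus_filter_labels == "pass"))

  again <- gen_locus_set(40, 12, 8, 7, 4, ratio_lo = 2, ratio_hi = 5.5,
                         seed = 5)
  expect_identical(ls$truth$locus_filter_labels,
                   again$truth$locus_filter_labels)

  expect_error(gen_locus_set(10, 12, 8, 0, 0, ratio_lo = 5.0, seed = 1),
               "ratio_lo")
})

test_that("gen_mito rotation is a cyclic shift preserving content", {
  coords <- list(`16S` = c(101L, 500L), ND1 = c(601L, 1100L),
                 COI = c(1201L, 1800L))
  m0 <- gen_mito(2000, coords, rotation_offset = 0L, seed = 7)
  expect_identical(m0$genome, m0$canonical)
  mk <- gen_mito(2000, coords, rotation_offset = 700L, seed = 7)
  expect_equal(nchar(mk$genome), 2000L)
  expect_identical(mk$canonical, m0$canonical)
  # rotated genome is a substring of the doubled canonical
  expect_true(grepl(mk$genome, paste0(mk$canonical, mk$canonical),
                    fixed = TRUE))
  # rotate-to-anchor recovers the canonical frame (cyclic-shift oracle)
  expect_identical(rotate_to_anchor(mk$genome, mk$anchor),
                   rotate_to_anchor(m0$genome, m0$anchor))
  expect_error(gen_mito(2000, list(`16S` = c(1L, 500L), ND1 = c(400L, 900L)),
                        0L, seed = 1), "disjoint")
})

test_that("gen_mixed_alignment records order-statistic trim boundaries", {
  # staggered windows: boundary = 3rd-smallest start / 3rd-largest end
  ma <- gen_mixed_alignment(8, 6, 900, 400, c(100, 450), seed = 8)
  w <- ma$truth$windows
  expect_equal(ma$truth$trim_boundaries,
               c(sort(w$start)[3], sort(w$end, decreasing = TRUE)[3]))
  # all legacy windows mutually overlap by construction
  expect_lt(max(w$start), min(w$end))

  # all legacy windows identical -> boundaries are that window's ends
  same <- gen_mixed_alignment(5, 5, 600, 300, c(150, 150), seed = 9)
  expect_equal(same$truth$trim_boundaries, c(150L, 449L))

  # n_legacy = 3 spanning full length -> trim is the identity
  full <- gen_mixed_alignment(4, 3, 500, 499, c(1, 1), seed = 10)
  tr <- legacy_parity_trim(full$alignment,
                           trim_params(3, full$truth$legacy_ids))
  expect_equal(tr$boundaries$keep_start, 1L)
  expect_equal(tr$boundaries$keep_end, 499L)

  expect_warning(gen_mixed_alignment(4, 2, 500, 200, c(1, 100), seed = 11),
                 "unsatisfiable")
})

test_that("truth sidecars serialise tabular components as plain text", {
  ma <- gen_mixed_alignment(4, 3, 500, 200, c(1, 100), seed = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_sidecar(ma$truth, f)
  lines <- readLines(f)
  expect_true("## windows" %in% lines)
  expect_true(any(grepl("legacy01", lines)))
})
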