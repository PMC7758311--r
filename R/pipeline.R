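# Plain sequential orchestration of the curation stages over a workspace
# directory: blend -> capture (external placeholder) -> filter -> mine ->
# assemble.  Each stage writes its outputs plus a manifest entry (inputs,
# parameters, record counts, output digests); deterministic stages are
# byte-identical across reruns with identical config and inputs.  No
# workflow-engine dependency.

.PIPELINE_STAGES <- c("blend", "capture", "filter", "mine", "assemble")

#' Build a demo workspace of synthetic inputs
#'
#' Generates a self-contained workspace every pipeline stage can run on in
#' well under two minutes: two probe kits (8 shared + 4 + 4 loci, 2 probes
#' per locus), per-taxon contigs planting every locus and three split
#' off-target genes (28S, 16SND1, COI), 60 loci with planted filter
#' outcomes over 12 taxa (8 ingroup), per-taxon rotated mitochondrial
#' genomes, and 28S/mtDNA alignments mixing long bycatch rows with short
#' legacy rows.  Identical seeds give identical workspaces.
#'
#' @param dir workspace directory (created if needed).
#' @param seed integer seed.
#' @return the config list for [run_pipeline()], invisibly; the same list
#'   is written to `<dir>/config.json`.
#' @export
make_demo_workspace <- function(dir, seed = 42L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  taxa <- sprintf("taxon%02d", 1:4)

  ps <- gen_probesets(8, 4, 4, probes_per_locus = 2L, probe_len = 120L,
                      divergence = 0.05, seed = seed)
  write_fasta(stats::setNames(ps$spider$sequence, ps$spider$probe_id),
              p("spider_probes.fasta"))
  write_fasta(stats::setNames(ps$arachnid$sequence, ps$arachnid$probe_id),
              p("arachnid_probes.fasta"))

  with_local_seed(seed + 1L, {
    genes <- c(`28S` = random_dna(700), `16SND1` = random_dna(640),
               COI = random_dna(660))
  })
  write_fasta(genes, p("queries.fasta"))
  gc <- gen_contigs(taxa, ps$truth, off_target_genes = genes,
                    noise_rate = 0, seed = seed + 2L)
  dir.create(p("contigs"), showWarnings = FALSE)
  for (tx in taxa) {
    write_fasta(gc$contigs[[tx]], p("contigs", paste0(tx, ".fasta")))
  }
  write_truth_sidecar(gc$truth, p("truth_contigs.tsv"))

  ls <- gen_locus_set(60, n_taxa = 12, n_ingroup = 8, n_fail_occupancy = 10,
                      n_fail_long_branch = 5, ratio_lo = 2, ratio_hi = 5.5,
                      seed = seed + 3L)
  dir.create(p("loci"), showWarnings = FALSE)
  dir.create(p("trees"), showWarnings = FALSE)
  for (l in ls$loci) {
    write_fasta(l$alignment, p("loci", paste0(l$locus_id, ".fasta")))
    if (!is.null(l$tree)) {
      writeLines(write_newick(l$tree), p("trees", paste0(l$locus_id, ".nwk")))
    }
  }
  writeLines(ls$truth$ingroup_taxa, p("ingroup.txt"))
  write_truth_sidecar(ls$truth, p("truth_loci.tsv"))

  dir.create(p("mito"), showWarnings = FALSE)
  anchors <- character(0)
  with_local_seed(seed + 4L, {
    offsets <- sample(0:1999, length(taxa))
  })
  for (i in seq_along(taxa)) {
    mt <- gen_mito(2000, list(`16S` = c(101L, 500L), ND1 = c(601L, 1100L),
                              COI = c(1201L, 1800L)),
                   rotation_offset = offsets[i], seed = seed + 5L)
    write_fasta(stats::setNames(mt$genome, taxa[i]),
                p("mito", paste0(taxa[i], ".fasta")))
    anchors <- mt$anchor
  }
  writeLines(anchors, p("anchor_16S.txt"))

  a28 <- gen_mixed_alignment(6, 5, long_len = 900, legacy_len = 400,
                             legacy_offset_range = c(150, 450),
                             seed = seed + 6L)
  amt <- gen_mixed_alignment(6, 5, long_len = 1200, legacy_len = 500,
                             legacy_offset_range = c(200, 600),
                             seed = seed + 7L)
  write_fasta(a28$alignment, p("align_28S.fasta"))
  write_fasta(amt$alignment, p("align_mtDNA.fasta"))
  writeLines(union(a28$truth$legacy_ids, amt$truth$legacy_ids),
             p("legacy_ids.txt"))

  config <- list(
    workspace = dir, seed = seed, stages = .PIPELINE_STAGES,
    blend = list(spider = p("spider_probes.fasta"),
                 arachnid = p("arachnid_probes.fasta"),
                 contigs_dir = p("contigs"), granularity = "probe"),
    filter = list(loci_dir = p("loci"), trees_dir = p("trees"),
                  ingroup = p("ingroup.txt"), min_taxa = 6L,
                  min_ingroup = 3L, ratio = 5),
    mine = list(contigs_dir = p("contigs"), queries = p("queries.fasta"),
                evalue = 1e-10, min_len = 200L),
    assemble = list(r28s = p("align_28S.fasta"),
                    mtdna = p("align_mtDNA.fasta"),
                    legacy_ids = p("legacy_ids.txt"), k_legacy = 3L,
                    outdir = p("supermatrices")))
  jsonlite::write_json(config, p("config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config)
}

#' Run the curation pipeline over a workspace
#'
#' Stages execute in order; a stage failure halts the run with the failing
#' stage recorded.  The manifest lists, per stage, status, record counts,
#' parameters and md5 digests of every output file, so identical reruns
#' are verifiable byte-for-byte.
#'
#' @param config a config list as produced by [make_demo_workspace()], or
#'   a path to such a config serialised as JSON.
#' @return the run manifest: a list with `stages` (data.frame) and
#'   `outputs` (data.frame `stage`, `file`, `md5`); also written to
#'   `<workspace>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    # read_json simplifies range vectors fine; stages may come back as list
    config$stages <- unlist(config$stages)
  }
  ws <- config$workspace
  stages <- config$stages %||% .PIPELINE_STAGES
  rows <- list(); outputs <- list()
  note_out <- function(stage, files) {
    files <- files[file.exists(files)]
    if (length(files) == 0L) return()
    outputs[[length(outputs) + 1L]] <<- data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  }
  record <- function(stage, status, n_in = NA_integer_, n_out = NA_integer_,
                     note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, status = status, n_in = n_in, n_out = n_out,
      note = note, stringsAsFactors = FALSE)
  }
  finish <- function() {
    manifest <- list(
      stages = do.call(rbind, rows),
      outputs = if (length(outputs) > 0L) do.call(rbind, outputs)
                else data.frame(stage = character(0), file = character(0),
                                md5 = character(0)))
    jsonlite::write_json(manifest, file.path(ws, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
    manifest
  }
  run_stage <- function(stage, fn) {
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      record(stage, "failed", note = conditionMessage(e))
      FALSE
    })
    ok
  }

  for (stage in stages) {
    ok <- switch(stage,
      blend = run_stage("blend", function() {
        cf <- config$blend
        for (f in c(cf$spider, cf$arachnid)) {
          if (!file.exists(f)) stop(sprintf("missing input: %s", f))
        }
        spider <- read_probe_set(cf$spider, "spider")
        arachnid <- read_probe_set(cf$arachnid, "arachnid")
        contigs <- unlist(lapply(list.files(cf$contigs_dir,
                                            pattern = "\\.fasta$",
                                            full.names = TRUE), read_fasta))
        hs <- match_probes_to_contigs(contigs, spider)
        ha <- match_probes_to_contigs(contigs, arachnid)
        g <- infer_probe_homology(hs, ha)
        bl <- blend_probesets(spider, arachnid, g,
                              granularity = cf$granularity %||% "probe")
        out1 <- file.path(ws, "blended_probes.fasta")
        write_fasta(stats::setNames(bl$blended$sequence,
                                    bl$blended$probe_id), out1)
        out2 <- file.path(ws, "blend_report.tsv")
        r <- bl$report
        utils::write.table(
          data.frame(n_spider = r$n_spider, n_arachnid = r$n_arachnid,
                     n_removed = r$n_removed, n_blended = r$n_blended,
                     granularity = r$granularity),
          out2, sep = "\t", quote = FALSE, row.names = FALSE)
        record("blend", "completed", n_in = nrow(spider) + nrow(arachnid),
               n_out = r$n_blended,
               note = sprintf("removed %d arachnid probes", r$n_removed))
        note_out("blend", c(out1, out2))
      }),
      capture = {
        record("capture", "completed", note = paste(
          "external stage (read cleaning, assembly, UCE extraction);",
          "contigs and per-locus alignments are workspace inputs"))
        TRUE
      },
      filter = run_stage("filter", function() {
        cf <- config$filter
        if (!file.exists(cf$ingroup)) {
          stop(sprintf("missing ingroup file: %s", cf$ingroup))
        }
        ingroup <- readLines(cf$ingroup, warn = FALSE)
        files <- list.files(cf$loci_dir, pattern = "\\.fasta$",
                            full.names = TRUE)
        loci <- lapply(files, function(f) {
          id <- tools::file_path_sans_ext(basename(f))
          tf <- file.path(cf$trees_dir, paste0(id, ".nwk"))
          tree <- if (file.exists(tf)) read_newick(tf) else NULL
          locus_record(id, read_fasta(f), tree)
        })
        params <- filter_params(cf$min_taxa %||% 6L, cf$min_ingroup %||% 3L,
                                cf$ratio %||% 5, ingroup_taxa = ingroup)
        res <- suppressWarnings(filter_cascade(loci, params))
        keep_dir <- file.path(ws, "loci_retained")
        dir.create(keep_dir, showWarnings = FALSE)
        for (l in res$retained) {
          write_fasta(l$alignment,
                      file.path(keep_dir, paste0(l$locus_id, ".fasta")))
        }
        out <- file.path(ws, "filter_report.tsv")
        write_filter_report(res$report, out)
        record("filter", "completed", n_in = res$report$n_input,
               n_out = res$report$n_retained,
               note = sprintf("%d fail occupancy, %d fail long-branch",
                              res$report$n_fail_occupancy,
                              res$report$n_fail_long_branch))
        note_out("filter", out)
      }),
      mine = run_stage("mine", function() {
        cf <- config$mine
        queries <- read_fasta(cf$queries)
        mp <- miner_params(cf$evalue %||% 1e-10, cf$min_len %||% 200L)
        files <- list.files(cf$contigs_dir, pattern = "\\.fasta$",
                            full.names = TRUE)
        mined <- list()
        n_hits <- 0L
        for (f in files) {
          tx <- tools::file_path_sans_ext(basename(f))
          contigs <- read_fasta(f)
          db <- build_reference_db(contigs, taxon = tx)
          hits <- filter_hits(search_contigs(queries, db), mp)
          n_hits <- n_hits + nrow(hits)
          for (g in unique(hits$query_id)) {
            seq <- stitch_contigs(hits[hits$query_id == g, , drop = FALSE],
                                  contigs, mp, id = tx)
            mined[[g]] <- c(mined[[g]], seq)
          }
        }
        dir.create(file.path(ws, "mined"), showWarnings = FALSE)
        outs <- character(0)
        for (g in names(mined)) {
          out <- file.path(ws, "mined", paste0(g, ".fasta"))
          write_fasta(mined[[g]], out)
          outs <- c(outs, out)
        }
        record("mine", "completed", n_in = n_hits,
               n_out = sum(lengths(mined)),
               note = sprintf("%d loci mined across %d taxa",
                              length(mined), length(files)))
        note_out("mine", outs)
      }),
      assemble = run_stage("assemble", function() {
        cf <- config$assemble
        a28 <- read_fasta(cf$r28s)
        amt <- read_fasta(cf$mtdna)
        legacy <- readLines(cf$legacy_ids, warn = FALSE)
        keep_dir <- file.path(ws, "loci_retained")
        lfiles <- list.files(keep_dir, pattern = "\\.fasta$",
                             full.names = TRUE)
        uce <- lapply(lfiles, read_fasta)
        names(uce) <- tools::file_path_sans_ext(basename(lfiles))
        tp <- trim_params(cf$k_legacy %||% 3L, legacy_ids = legacy)
        ds <- assemble_datasets(uce, a28, amt, tp, tp)
        outdir <- cf$outdir %||% file.path(ws, "supermatrices")
        dir.create(outdir, showWarnings = FALSE)
        outs <- character(0)
        for (nm in names(ds)) {
          f <- file.path(outdir, paste0(nm, ".phy"))
          write_phylip(ds[[nm]], f)
          outs <- c(outs, f)
          if (ds[[nm]]$partitioned) {
            pf <- file.path(outdir, paste0(nm, ".partitions"))
            write_partitions(ds[[nm]], "raxml", pf)
            outs <- c(outs, pf)
          }
        }
        record("assemble", "completed", n_in = length(uce) + 2L,
               n_out = length(ds),
               note = paste(vapply(ds, function(d)
                 sprintf("%s:%d", d$dataset_tag, nchar(d$matrix[[1]])),
                 character(1)), collapse = " "))
        note_out("assemble", outs)
      }),
      stop(sprintf("unknown stage: %s", stage)))
    if (!isTRUE(ok)) break
  }
  finish()
}
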