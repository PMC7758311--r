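# Two-stage locus filter: (1) occupancy — loci with fewer than `min_taxa`
# taxa total or fewer than `min_ingroup` ingroup taxa are deleted;
# (2) paralogy screen — among occupancy-passers, loci whose gene tree has a
# longest branch at least `branch_ratio_threshold` times the second longest
# are deleted (a very long branch is the signature of paralog capture or
# misassembly).  The cascade report accounts for every input locus.

#' Filter parameters
#'
#' @param min_taxa minimum taxa per locus (strict "fewer than" deletes, so a
#'   locus at exactly `min_taxa` passes).  Default 6.
#' @param min_ingroup minimum ingroup taxa per locus, same comparator.
#'   Default 3.
#' @param branch_ratio_threshold longest/second-longest branch ratio at or
#'   above which a locus fails.  Default 5.
#' @param ingroup_taxa character vector of ingroup taxon names.
#' @param inclusive logical; if `TRUE` (default) a ratio exactly at the
#'   threshold fails ("at least N times longer"); if `FALSE` only ratios
#'   strictly above fail.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(min_taxa = 6L, min_ingroup = 3L,
                          branch_ratio_threshold = 5,
                          ingroup_taxa = character(0), inclusive = TRUE) {
  stopifnot(min_taxa >= min_ingroup, min_ingroup >= 0L,
            branch_ratio_threshold > 1)
  structure(list(min_taxa = as.integer(min_taxa),
                 min_ingroup = as.integer(min_ingroup),
                 branch_ratio_threshold = branch_ratio_threshold,
                 ingroup_taxa = ingroup_taxa,
                 inclusive = isTRUE(inclusive)),
            class = "filter_params")
}

#' Construct a per-locus record
#'
#' @param locus_id locus identifier.
#' @param alignment named character vector of aligned rows; names are taxa.
#' @param tree optional `gene_tree` whose leaves are a subset of the taxa.
#' @return object of class `locus_record`.
#' @export
locus_record <- function(locus_id, alignment, tree = NULL) {
  stopifnot(is.character(alignment), !is.null(names(alignment)))
  if (length(unique(nchar(alignment))) > 1L) {
    stop(sprintf("locus %s: alignment rows have unequal length", locus_id),
         call. = FALSE)
  }
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "gene_tree"))
    extra <- setdiff(tree$leaf_labels, names(alignment))
    if (length(extra) > 0L) {
      stop(sprintf("locus %s: tree leaves not in alignment: %s", locus_id,
                   paste(utils::head(extra, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(locus_id = locus_id, alignment = alignment,
                 taxa = names(alignment), tree = tree),
            class = "locus_record")
}

#' Occupancy decision for one locus
#'
#' Fails iff the locus has fewer than `min_taxa` taxa total or fewer than
#' `min_ingroup` taxa in the ingroup (both comparisons strict, so the
#' boundary counts pass).
#'
#' @param locus a [locus_record].
#' @param params a [filter_params] with `ingroup_taxa` set.
#' @return `"pass"` or `"fail_occupancy"`.
#' @export
occupancy_check <- function(locus, params) {
  n_taxa <- length(locus$taxa)
  n_in <- length(intersect(locus$taxa, params$ingroup_taxa))
  if (n_taxa < params$min_taxa || n_in < params$min_ingroup) {
    "fail_occupancy"
  } else "pass"
}

#' Longest/second-longest branch ratio of a gene tree
#'
#' Edges are taken exactly as parsed from the Newick (no re-rooting, root
#' edge included if present); the tree is treated as unrooted in the sense
#' that all edges, terminal and internal, participate in the ranking.
#' If the second-longest edge has length zero the ratio is `Inf`: a
#' degenerate tree with a single long edge is exactly the paralogy
#' signature the screen targets.
#'
#' @param tree a `gene_tree`.
#' @return the ratio (numeric, possibly `Inf`).
#' @export
branch_ratio <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  len <- tree$edge_lengths
  if (length(len) < 2L) {
    stop("branch ratio needs at least 2 edges", call. = FALSE)
  }
  top2 <- sort(len, decreasing = TRUE)[1:2]
  if (top2[2] == 0) {
    if (top2[1] == 0) return(NaN) else return(Inf)
  }
  top2[1] / top2[2]
}

#' Long-branch decision for one gene tree
#'
#' @param tree a `gene_tree`.
#' @param params a [filter_params].
#' @return `"pass"` or `"fail_long_branch"`.
#' @export
long_branch_check <- function(tree, params) {
  r <- branch_ratio(tree)
  thr <- params$branch_ratio_threshold
  fail <- if (params$inclusive) !is.nan(r) && r >= thr else !is.nan(r) && r > thr
  if (fail) "fail_long_branch" else "pass"
}

#' Run the two-stage filter cascade over a locus collection
#'
#' Occupancy is applied first; the long-branch screen only to occupancy
#' passers.  Loci that pass occupancy but carry no gene tree are retained
#' with a logged warning rather than silently dropped.
#'
#' @param loci list of [locus_record]s.
#' @param params a [filter_params].
#' @return list with `retained` (the surviving locus records) and `report`
#'   (class `filter_report`): counts `n_input`, `n_fail_occupancy`,
#'   `n_fail_long_branch`, `n_retained` and a per-locus `decisions` table
#'   (`locus_id`, `decision`, `n_taxa`, `n_ingroup`, `branch_ratio`,
#'   `note`).
#' @export
filter_cascade <- function(loci, params) {
  stopifnot(inherits(params, "filter_params"))
  n <- length(loci)
  decision <- character(n); note <- character(n)
  n_taxa <- integer(n); n_in <- integer(n); ratio <- rep(NA_real_, n)
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  for (i in seq_len(n)) {
    l <- loci[[i]]
    n_taxa[i] <- length(l$taxa)
    n_in[i] <- length(intersect(l$taxa, params$ingroup_taxa))
    d <- occupancy_check(l, params)
    note[i] <- ""
    if (d == "pass") {
      if (is.null(l$tree)) {
        note[i] <- "no gene tree; long-branch screen skipped"
      } else {
        ratio[i] <- branch_ratio(l$tree)
        d <- long_branch_check(l$tree, params)
      }
    }
    decision[i] <- d
  }
  decisions <- data.frame(locus_id = ids, decision = decision,
                          n_taxa = n_taxa, n_ingroup = n_in,
                          branch_ratio = ratio, note = note,
                          stringsAsFactors = FALSE)
  report <- structure(list(n_input = n,
                           n_fail_occupancy = sum(decision == "fail_occupancy"),
                           n_fail_long_branch = sum(decision == "fail_long_branch"),
                           n_retained = sum(decision == "pass"),
                           decisions = decisions),
                      class = "filter_report")
  if (any(note != "")) {
    warning(sprintf("%d occupancy-passing loci had no gene tree and were retained",
                    sum(note != "")), call. = FALSE)
  }
  list(retained = loci[decision == "pass"], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> input %d loci; %d failed occupancy; ",
                     "%d failed long-branch; %d retained\n"),
              x$n_input, x$n_fail_occupancy, x$n_fail_long_branch,
              x$n_retained))
  invisible(x)
}

#' Write a filter report as tab-separated text
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  hdr <- sprintf("# input=%d fail_occupancy=%d fail_long_branch=%d retained=%d",
                 report$n_input, report$n_fail_occupancy,
                 report$n_fail_long_branch, report$n_retained)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(report$decisions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
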