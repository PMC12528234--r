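#' Per-base coverage profiles from recruited alignments
#'
#' Computes the coverage of every base of each reference genome: depth is
#' incremented over `[start0, start0 + aligned_length)` for each alignment,
#' and summarized as coverage breadth (percent of positions with depth >= 1)
#' and mean depth per covered position (`sum(depth) / n_covered`, the
#' "reads/covered position" statistic).  Coverage is computed on the excised
#' (masked) coordinate system, so breadth denominators exclude masked bases.
#' Genomes without any alignment still receive a profile with breadth 0.
#'
#' @param alignments alignment data frame from [recruit_reads()] or
#'   [import_sam()].
#' @param refs the `reference_set` the alignments refer to.
#' @param total_metagenome_reads total reads in the metagenome (>= number of
#'   alignments); used for the percent-mapped abundance proxy.
#' @param genomes optional character vector restricting which genomes to
#'   profile (default: all genomes in `refs`).
#' @return named list of `coverage_profile` objects, one per genome, each
#'   with fields `genome_id`, `genome_length` (post-excision), `depth`
#'   (integer vector over the genome), `n_mapped_reads`,
#'   `total_metagenome_reads`, `breadth` (percent), `mean_covered_depth`
#'   and `pct_reads_mapped`.
#' @export
compute_coverage <- function(alignments, refs, total_metagenome_reads,
                             genomes = NULL) {
  check_alignments(alignments)
  if (!inherits(refs, "reference_set")) {
    stop("`refs` must be a reference_set", call. = FALSE)
  }
  stopifnot_scalar_number(total_metagenome_reads, "total_metagenome_reads")
  if (total_metagenome_reads < nrow(alignments)) {
    stop("`total_metagenome_reads` must be >= the number of alignments",
         call. = FALSE)
  }
  ids <- genomes %||% refs$offsets$genome_id
  if (!all(ids %in% refs$offsets$genome_id)) {
    stop("unknown genome id in `genomes`", call. = FALSE)
  }
  bad <- !alignments$genome_id %in% refs$offsets$genome_id
  if (any(bad)) {
    stop("alignments reference unknown genome: ",
         paste(unique(alignments$genome_id[bad]), collapse = ", "),
         call. = FALSE)
  }

  b <- match(alignments$contig, refs$blocks$contig)
  if (anyNA(b)) stop("alignment references unknown contig", call. = FALSE)
  if (any(alignments$start0 < 0) ||
      any(alignments$start0 + alignments$aligned_length >
          refs$blocks$len[b])) {
    stop("alignment exceeds genome bounds (coordinate corruption?)",
         call. = FALSE)
  }
  gpos <- refs$blocks$local_start[b] + alignments$start0

  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    G <- refs$offsets$length[refs$offsets$genome_id == id]
    sel <- which(alignments$genome_id == id)
    if (length(sel)) {
      starts <- gpos[sel] + 1L
      ends <- gpos[sel] + alignments$aligned_length[sel] + 1L
      delta <- tabulate(starts, nbins = G + 1L) -
        tabulate(ends, nbins = G + 1L)
      depth <- cumsum(delta)[seq_len(G)]
    } else {
      depth <- integer(G)
    }
    ncov <- sum(depth > 0L)
    out[[id]] <- structure(list(
      genome_id = id,
      genome_length = G,
      depth = depth,
      n_mapped_reads = length(sel),
      total_metagenome_reads = as.integer(total_metagenome_reads),
      breadth = 100 * ncov / G,
      mean_covered_depth = if (ncov > 0L) sum(depth) / ncov else 0,
      pct_reads_mapped = 100 * length(sel) / total_metagenome_reads
    ), class = "coverage_profile")
  }
  out
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: breadth %.1f%%, %.1f reads/covered position\n",
              x$genome_id, x$breadth, x$mean_covered_depth))
  cat(sprintf("  %d mapped read(s) of %d total (%.3f%%), genome %s bp\n",
              x$n_mapped_reads, x$total_metagenome_reads,
              x$pct_reads_mapped,
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Subsample alignments without replacement
#'
#' Draws exactly `floor(fraction * N)` alignments uniformly without
#' replacement.  Sampling is keyed on `read_id` (the table is put into
#' read-id order before drawing), so the result is deterministic for a
#' fixed seed and independent of the input row order.
#'
#' @param alignments alignment data frame.
#' @param fraction fraction to keep, in \[0, 1\].
#' @param seed integer RNG seed.
#' @return subsampled alignment data frame.
#' @export
subsample_alignments <- function(alignments, fraction, seed) {
  check_alignments(alignments)
  stopifnot_scalar_number(fraction, "fraction")
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(alignments)
  keep <- floor(fraction * n)
  if (keep == n) return(alignments)
  if (keep == 0L) return(alignments[integer(), , drop = FALSE])
  o <- order(alignments$read_id, method = "radix")
  idx <- with_seed(seed, sample.int(n, keep))
  out <- alignments[o[sort(idx)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-genome coverage summaries as TSV
#'
#' One row per genome: length, mapped reads, breadth, mean covered depth,
#' percent reads mapped, plus `reads_per_covered` (`n_mapped / n_covered`),
#' the alternative literal reading of "reads/covered position".
#'
#' @param profiles list of `coverage_profile` from [compute_coverage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_summary_tsv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    ncov <- sum(p$depth > 0L)
    data.frame(genome_id = p$genome_id, length = p$genome_length,
               n_mapped = p$n_mapped_reads, breadth_pct = p$breadth,
               mean_covered_depth = p$mean_covered_depth,
               reads_per_covered = if (ncov) p$n_mapped_reads / ncov else 0,
               pct_reads_mapped = p$pct_reads_mapped,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-base depth as 3-column TSV
#'
#' @param profiles list of `coverage_profile`.
#' @param path output path (columns genome_id, pos0, depth).
#' @param nonzero_only write only covered positions (default TRUE).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profiles, path, nonzero_only = TRUE) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    pos <- seq_along(p$depth) - 1L
    d <- p$depth
    if (nonzero_only) {
      keep <- d > 0L
      pos <- pos[keep]
      d <- d[keep]
    }
    if (!length(pos)) return(NULL)
    data.frame(genome_id = p$genome_id, pos0 = pos, depth = d,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(genome_id = character(), pos0 = integer(),
                     depth = integer())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
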