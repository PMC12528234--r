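#' Competitively recruit reads onto a reference set
#'
#' Assigns each read full-length to at most one reference locus.  Candidate
#' loci are found by exact k-mer seeding on both strands and scored by
#' full-length ungapped mismatch count; the best placement (highest
#' identity) is kept iff its identity is at least `min_identity` percent --
#' 95 by default, reflecting the prokaryotic species demarcation threshold.
#' Ties are broken deterministically by (lexicographic genome id, smallest
#' coordinate, then + strand), so runs are reproducible bit for bit.  Reads
#' with no qualifying placement are unassigned and absent from the output.
#'
#' @param reads a `read_set` from [simulate_reads()] / [read_reads_fastq()],
#'   or a named character vector of read sequences.
#' @param refs a `reference_set` from [build_reference_set()].
#' @param min_identity minimum percent identity of the best placement
#'   (default 95).
#' @param seed_stride probe every `seed_stride`-th k-mer of a read when
#'   seeding (default 4).  1 probes every position; larger strides trade a
#'   marginal loss of seeding sensitivity on diverged reads for speed.  The
#'   terminal k-mer is always probed, so error-free reads are unaffected.
#' @return a data frame of read alignments with columns `read_id`,
#'   `genome_id`, `contig`, `start0` (0-based, contig-local, post-excision),
#'   `strand`, `aligned_length`, `mismatches`, `identity`; at most one row
#'   per read.
#' @export
recruit_reads <- function(reads, refs, min_identity = 95, seed_stride = 4L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (!is.character(reads) || is.null(names(reads))) {
    stop("`reads` must be a read_set or a named character vector",
         call. = FALSE)
  }
  if (!inherits(refs, "reference_set")) {
    stop("`refs` must be a reference_set", call. = FALSE)
  }
  if (!length(reads)) return(empty_alignments())
  lens <- nchar(reads)
  n_short <- sum(lens < refs$k)
  if (n_short > 0L) {
    warning(n_short, " read(s) shorter than k = ", refs$k,
            " left unassigned", call. = FALSE)
  }
  res <- cpp_recruit(get_ref_index(refs), unname(reads), min_identity,
                     as.integer(seed_stride))
  hit <- which(res$found)
  if (!length(hit)) return(empty_alignments())
  loc <- global_to_local(refs, res$gstart[hit])
  L <- lens[hit]
  mm <- res$mismatches[hit]
  data.frame(
    read_id = names(reads)[hit],
    genome_id = loc$genome_id,
    contig = loc$contig,
    start0 = loc$start0,
    strand = ifelse(res$strand[hit] == 1L, "-", "+"),
    aligned_length = as.integer(L),
    mismatches = mm,
    identity = 100 * (L - mm) / L,
    stringsAsFactors = FALSE
  )
}

#' Import read alignments from a SAM file
#'
#' Interoperability entry point for alignments produced by an external
#' mapper.  Unmapped, secondary and supplementary records are skipped;
#' identity is computed as `100 * (L - NM) / L` from the edit-distance tag
#' over the query length; records failing `min_identity`, or records whose
#' alignment is not query-full-length (any soft or hard clipping) when
#' `require_full_length` is set, are dropped.  SAM 1-based coordinates are
#' converted to the internal 0-based convention.  Records without an NM tag
#' are skipped with a logged count.
#'
#' @param path SAM file path; header sequence names must be contigs of
#'   `refs`.
#' @param refs a `reference_set`.
#' @param min_identity minimum percent identity (default 95).
#' @param require_full_length drop records with clipped queries
#'   (default TRUE, matching whole-length end-to-end mapping).
#' @return alignment data frame as in [recruit_reads()].
#' @export
import_sam <- function(path, refs, min_identity = 95,
                       require_full_length = TRUE) {
  if (!inherits(refs, "reference_set")) {
    stop("`refs` must be a reference_set", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    tag = "NM"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (!n) return(empty_alignments())

  flag <- x$flag
  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  nm <- x$tag$NM
  n_missing_nm <- sum(keep & is.na(nm))
  if (n_missing_nm > 0L) {
    message(n_missing_nm, " mapped record(s) without NM tag skipped")
  }
  keep <- keep & !is.na(nm)
  if (!any(keep)) return(empty_alignments())

  cigar <- x$cigar[keep]
  qlen <- cigar_query_length(cigar)
  clipped <- grepl("[SH]", cigar)
  rname <- as.character(x$rname[keep])
  unknown <- setdiff(unique(rname), refs$blocks$contig)
  if (length(unknown)) {
    stop("unknown reference name: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nm <- nm[keep]
  identity <- 100 * (qlen - nm) / qlen
  ok <- identity >= min_identity
  if (require_full_length) ok <- ok & !clipped

  data.frame(
    read_id = x$qname[keep][ok],
    genome_id = refs$blocks$genome_id[match(rname[ok], refs$blocks$contig)],
    contig = rname[ok],
    start0 = x$pos[keep][ok] - 1L,
    strand = ifelse(as.character(x$strand[keep][ok]) == "-", "-", "+"),
    aligned_length = as.integer(qlen[ok]),
    mismatches = as.integer(nm[ok]),
    identity = identity[ok],
    stringsAsFactors = FALSE
  )
}

# total query length along a CIGAR string (M/I/S/=/X consume query)
cigar_query_length <- function(cigar) {
  if (requireNamespace("GenomicAlignments", quietly = TRUE)) {
    return(GenomicAlignments::cigarWidthAlongQuerySpace(
      cigar, after.soft.clipping = FALSE))
  }
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]$", "", toks))[
      grepl("[MIS=X]$", toks)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Export alignments as a minimal SAM file
#'
#' Writes an unsorted single-end SAM with `@SQ` lines for every reference
#' contig and an `NM` edit-distance tag per record, sufficient for
#' round-tripping through [import_sam()] or external tooling.
#'
#' @param alignments alignment data frame from [recruit_reads()].
#' @param refs the `reference_set` the alignments refer to.
#' @param path output SAM path.
#' @param reads optional named character vector of read sequences; when
#'   given, SEQ is emitted (reverse-complemented for minus-strand records).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, refs, path, reads = NULL) {
  check_alignments(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refs$blocks$contig, refs$blocks$len))
  if (nrow(alignments)) {
    seq <- rep("*", nrow(alignments))
    if (!is.null(reads)) {
      seq <- unname(reads[alignments$read_id])
      minus <- alignments$strand == "-"
      if (any(minus)) seq[minus] <- cpp_revcomp(seq[minus])
    }
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                   alignments$read_id,
                   ifelse(alignments$strand == "-", 16L, 0L),
                   alignments$contig, alignments$start0 + 1L,
                   alignments$aligned_length, seq, alignments$mismatches)
  } else {
    rec <- character()
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write alignments as TSV
#'
#' @param alignments alignment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  check_alignments(alignments)
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read alignments from TSV
#'
#' @param path TSV written by [write_alignments_tsv()].
#' @return alignment data frame.
#' @export
read_alignments_tsv <- function(path) {
  check_alignments(utils::read.delim(path, stringsAsFactors = FALSE))
}
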