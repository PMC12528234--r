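#' Specify a synthetic community
#'
#' Describes the community a simulated metagenome is drawn from: member
#' genomes with relative abundances, a uniform read length, a substitution
#' error rate and a seed.  Stands in for the filtered, size-fractionated
#' water samples a real survey would sequence.
#'
#' @param members list of [genome_seq] objects.
#' @param abundances numeric vector of relative abundances; must sum to 1
#'   within 1e-9.
#' @param read_length uniform read length in bp (default 150, the common
#'   short-read length).
#' @param error_rate per-base substitution error probability (default 0.001,
#'   a typical modern short-read substitution rate).
#' @param seed integer RNG seed.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(members, abundances, read_length = 150L,
                           error_rate = 0.001, seed = 1L) {
  if (inherits(members, "genome_seq")) members <- list(members)
  if (!length(members) || !all(vapply(members, inherits, TRUE, "genome_seq"))) {
    stop("`members` must be a non-empty list of genome_seq objects",
         call. = FALSE)
  }
  if (length(abundances) != length(members)) {
    stop("`abundances` must match `members` in length", call. = FALSE)
  }
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-9) {
    stop("`abundances` must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  if (read_length < 1L) stop("`read_length` must be >= 1", call. = FALSE)
  for (m in members) {
    if (max(Biostrings::width(m$contigs)) < read_length) {
      stop("read_length longer than every contig of member ", m$id,
           call. = FALSE)
    }
  }
  if (error_rate < 0 || error_rate >= 1) {
    stop("`error_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(members = members, abundances = abundances,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("<community_spec> %d member(s), L = %d bp, error = %g, seed = %d\n",
              length(x$members), x$read_length, x$error_rate, x$seed))
  for (i in seq_along(x$members)) {
    cat(sprintf("  %-20s %8.4f%%\n", x$members[[i]]$id,
                100 * x$abundances[i]))
  }
  invisible(x)
}

#' Simulate a metagenomic read set
#'
#' Each read is drawn by (i) choosing a member genome with probability equal
#' to its relative abundance, (ii) choosing a uniform start position such
#' that the read fits entirely within one contig (reads never span contig
#' junctions), (iii) choosing a strand uniformly, and (iv) applying i.i.d.
#' substitution errors at the community error rate.  The truth table records
#' the source genome, contig, 0-based start and strand of every read.
#' Deterministic for a fixed community seed.
#'
#' @param community a [community_spec].
#' @param n_reads number of reads to draw (>= 0).
#' @return an object of class `read_set`: list with `reads` (named character
#'   vector), `qualities` (constant high quality) and `truth` (data frame
#'   `read_id`, `genome_id`, `contig`, `start0`, `strand`).
#' @export
simulate_reads <- function(community, n_reads) {
  if (!inherits(community, "community_spec")) {
    stop("`community` must be a community_spec", call. = FALSE)
  }
  stopifnot_scalar_number(n_reads, "n_reads")
  if (n_reads < 0) stop("`n_reads` must be >= 0", call. = FALSE)
  n_reads <- as.integer(n_reads)
  L <- community$read_length

  if (n_reads == 0L) {
    return(structure(list(
      reads = stats::setNames(character(), character()),
      qualities = character(),
      truth = data.frame(read_id = character(), genome_id = character(),
                         contig = character(), start0 = integer(),
                         strand = character(), stringsAsFactors = FALSE)
    ), class = "read_set"))
  }

  with_seed(community$seed, {
    k <- length(community$members)
    member <- sample.int(k, n_reads, replace = TRUE,
                         prob = community$abundances)
    strand_minus <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)

    seqs <- character(n_reads)
    genome_id <- character(n_reads)
    contig <- character(n_reads)
    start0 <- integer(n_reads)

    for (i in seq_len(k)) {
      sel <- which(member == i)
      if (!length(sel)) next
      g <- community$members[[i]]
      widths <- Biostrings::width(g$contigs)
      eligible <- which(widths >= L)
      npos <- widths[eligible] - L + 1L
      # uniform over all valid start positions across eligible contigs
      cum <- cumsum(npos)
      u <- sample.int(cum[length(cum)], length(sel), replace = TRUE)
      ci <- findInterval(u - 1L, c(0L, cum), rightmost.closed = FALSE)
      local0 <- u - c(0L, cum)[ci] - 1L
      cseq <- as.character(g$contigs[eligible])
      seqs[sel] <- substring(cseq[ci], local0 + 1L, local0 + L)
      genome_id[sel] <- g$id
      contig[sel] <- names(g$contigs)[eligible][ci]
      start0[sel] <- local0
    }

    seqs <- cpp_finish_reads(seqs, strand_minus, community$error_rate)
    read_id <- sprintf("r%07d", seq_len(n_reads))
    names(seqs) <- read_id

    structure(list(
      reads = seqs,
      qualities = strrep("I", L),
      truth = data.frame(read_id = read_id, genome_id = genome_id,
                         contig = contig, start0 = start0,
                         strand = ifelse(strand_minus, "-", "+"),
                         stringsAsFactors = FALSE)
    ), class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d read(s)%s\n", length(x$reads),
              if (length(x$reads)) sprintf(", %d bp", nchar(x$reads[[1]]))
              else ""))
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' Qualities are emitted as a constant high quality ('I', Phred 40); output
#' is byte-identical for identical inputs.
#'
#' @param read_set a `read_set` from [simulate_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(read_set, path) {
  if (!length(read_set$reads)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(unname(read_set$reads))
  names(x) <- names(read_set$reads)
  qual <- Biostrings::BStringSet(rep(strrep("I", nchar(read_set$reads[[1]])),
                                     length(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file.
#' @return a `read_set` (truth table absent).
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  structure(list(reads = reads, qualities = NULL, truth = NULL),
            class = "read_set")
}

#' Write a simulation truth table as TSV
#'
#' @param read_set a `read_set` with a truth table.
#' @param path output TSV path (columns read_id, genome_id, contig, start0,
#'   strand).
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(read_set, path) {
  if (is.null(read_set$truth)) stop("read set has no truth table")
  utils::write.table(read_set$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
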