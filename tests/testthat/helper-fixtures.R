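# Shared fixture builders.  Everything is generated in code at test time;
# no stored data.

# alignment table taken directly from a simulation truth table (exact,
# error-free placements); the independent route around the recruiter
truth_alignments <- function(read_set, read_length) {
  tr <- read_set$truth
  data.frame(
    read_id = tr$read_id, genome_id = tr$genome_id, contig = tr$contig,
    start0 = tr$start0, strand = tr$strand,
    aligned_length = read_length, mismatches = 0L, identity = 100,
    stringsAsFactors = FALSE
  )
}

# fabricate a coverage_profile with given summary statistics (for decision
# rule and boundary tests that do not need a depth vector)
fake_profile <- function(genome_id = "g", breadth = 0, depth = 0,
                         n_mapped = 0L, total = 1000L, genome_length = 1e5) {
  structure(list(
    genome_id = genome_id, genome_length = genome_length,
    depth = integer(), n_mapped_reads = as.integer(n_mapped),
    total_metagenome_reads = as.integer(total), breadth = breadth,
    mean_covered_depth = depth,
    pct_reads_mapped = 100 * n_mapped / total
  ), class = "coverage_profile")
}

fake_fit <- function(b_max, tau, genome_id = "g") {
  structure(list(genome_id = genome_id, b_max = b_max, tau = tau,
                 rss = 0, n_points = 0L, residuals = NULL),
            class = "saturation_fit")
}

fake_ani <- function(query_id, ref_id, gani, af_avg = 90) {
  structure(list(query_id = query_id, ref_id = ref_id, gani = gani,
                 af_query = af_avg, af_ref = af_avg, af_avg = af_avg,
                 n_fragments = 100L, n_aligned = 90L,
                 defined = !is.na(gani)),
            class = "ani_result")
}

# a diverged relative that retains exact copies of `n_islands` conserved
# segments of the reference (emulating conserved genomic islands shared
# with an ~85%-ANI relative)
relative_with_islands <- function(ref, p, seed, n_islands = 5L,
                                  island_len = 800L, id = "relative") {
  rel <- derive_relative(ref, p, 0, seed = seed, id = id)
  stopifnot(length(ref$contigs) == 1L)
  src <- as.character(ref$contigs[[1]])
  seqs <- as.character(rel$contigs)
  G <- nchar(src)
  gap <- G %/% (n_islands + 1L)
  starts0 <- gap * seq_len(n_islands)  # 0-based island starts
  for (s in starts0) {
    substr(seqs[1], s + 1L, s + island_len) <-
      substr(src, s + 1L, s + island_len)
  }
  names(seqs) <- paste0(id, "_c1")
  ann <- data.frame(contig = names(seqs)[1], start0 = starts0,
                    end0 = starts0 + island_len, role = "conserved-island",
                    stringsAsFactors = FALSE)
  genome_seq(id, seqs, ann)
}

# independent G+C recount by direct base counting
recount_gc <- function(genome) {
  s <- strsplit(paste(as.character(genome$contigs), collapse = ""), "")[[1]]
  sum(s %in% c("G", "C")) / sum(s %in% c("A", "C", "G", "T"))
}

# independent per-position mismatch recount between two equal-length
# single-contig genomes
recount_mismatch_fraction <- function(a, b, end = NULL) {
  sa <- strsplit(as.character(a$contigs[[1]]), "")[[1]]
  sb <- strsplit(as.character(b$contigs[[1]]), "")[[1]]
  if (!is.null(end)) {
    sa <- sa[seq_len(end)]
    sb <- sb[seq_len(end)]
  }
  mean(sa != sb)
}

# exact expected breadth (percent) for N uniform error-free reads of length
# L on a LINEAR genome of length G: unlike the circular-genome form
# 1-(1-L/G)^N, this accounts for the reduced number of read starts covering
# the first and last L-1 positions
expected_breadth_linear <- function(G, L, N) {
  S <- G - L + 1
  p <- 0:(G - 1)
  c_p <- pmin(p + 1, L, S, G - p)
  100 * mean(1 - (1 - c_p / S)^N)
}

# brute-force per-position depth recount over one genome of a reference set
brute_force_depth <- function(alignments, refs, genome_id) {
  G <- refs$offsets$length[refs$offsets$genome_id == genome_id]
  depth <- integer(G)
  aln <- alignments[alignments$genome_id == genome_id, , drop = FALSE]
  for (i in seq_len(nrow(aln))) {
    b <- refs$blocks[refs$blocks$contig == aln$contig[i], ]
    s <- b$local_start + aln$start0[i]
    idx <- seq(s + 1L, s + aln$aligned_length[i])
    depth[idx] <- depth[idx] + 1L
  }
  depth
}
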