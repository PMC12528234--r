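#' Genome summary statistics
#'
#' Total length, contig count and G+C content in mol percent.  G+C is
#' computed as `100 * (G + C) / (A + C + G + T)`: ambiguity codes are
#' excluded from both numerator and denominator, since deposited assemblies
#' may contain N bases.
#'
#' @param genome a [genome_seq] or a FASTA file path (every record becomes
#'   one contig).
#' @return one-row data frame `genome_id`, `total_length`, `n_contigs`,
#'   `gc_mol_percent`.
#' @export
genome_stats <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- read_genome_fasta(genome)
  }
  if (!inherits(genome, "genome_seq")) {
    stop("`genome` must be a genome_seq or FASTA path", call. = FALSE)
  }
  freq <- colSums(Biostrings::letterFrequency(genome$contigs,
                                              c("A", "C", "G", "T")))
  if (sum(freq) == 0) stop("no unambiguous nucleotides in genome",
                           call. = FALSE)
  data.frame(
    genome_id = genome$id,
    total_length = genome_length(genome),
    n_contigs = length(genome$contigs),
    gc_mol_percent = 100 * (freq[["G"]] + freq[["C"]]) / sum(freq),
    stringsAsFactors = FALSE
  )
}

# one direction of a gANI comparison: fragment the query, align each
# fragment to its best reference locus, apply the qualifying rule
gani_direction <- function(query, reference, fragment_length,
                           min_fragment_identity, min_fragment_coverage,
                           k, band, seed_stride) {
  frags <- character()
  for (i in seq_along(query$contigs)) {
    s <- as.character(query$contigs[[i]])
    w <- nchar(s)
    nfrag <- w %/% fragment_length
    if (nfrag > 0) {
      starts <- (seq_len(nfrag) - 1L) * fragment_length + 1L
      frags <- c(frags, substring(s, starts, starts + fragment_length - 1L))
    }
  }
  qlen <- genome_length(query)
  if (!length(frags)) {
    return(list(n_fragments = 0L, n_aligned = 0L, identities = numeric(),
                weights = numeric(), af = 0))
  }
  rblocks <- Biostrings::width(reference$contigs)
  xp <- cpp_index_build(paste(as.character(reference$contigs), collapse = ""),
                        as.integer(cumsum(rblocks) - rblocks),
                        as.integer(cumsum(rblocks)), as.integer(k))
  res <- cpp_fragment_align(xp, frags, as.integer(seed_stride),
                            as.integer(band))
  qualifies <- res$found & !is.na(res$identity) &
    res$identity >= min_fragment_identity &
    res$aligned / fragment_length >= min_fragment_coverage / 100
  list(
    n_fragments = length(frags),
    n_aligned = sum(qualifies),
    identities = res$identity[qualifies],
    weights = rep(fragment_length, sum(qualifies)),
    af = 100 * sum(res$aligned[qualifies]) / qlen
  )
}

#' Whole-genome average nucleotide identity (gANI) with alignment fractions
#'
#' Fragment-based gANI following the established convention: the query is
#' cut into consecutive non-overlapping fragments of `fragment_length` bp
#' (1020 by default; terminal short fragments are discarded, and fragments
#' never span contig junctions); each fragment is aligned to its best
#' reference locus by exact k-mer seeding followed by banded gapped
#' extension; fragments qualify if their identity is at least
#' `min_fragment_identity` percent over at least `min_fragment_coverage`
#' percent of their length (70/70 by default).  gANI is the length-weighted
#' mean identity of qualifying fragments over both directions; each
#' direction's alignment fraction (AF) is the share of that genome covered
#' by qualifying fragment alignments, and `af_avg` is their arithmetic
#' mean, so the result is order-symmetric in `af_avg` by construction.
#'
#' @param query,reference [genome_seq] objects (non-empty).
#' @param fragment_length fragment size in bp (default 1020).
#' @param min_fragment_identity qualifying identity threshold in percent.
#' @param min_fragment_coverage qualifying coverage threshold in percent.
#' @param k seed word length (default 16; must not exceed
#'   `fragment_length`).
#' @param band half-width of the alignment band in bp (default 12).
#' @param seed_stride probe every `seed_stride`-th fragment k-mer when
#'   seeding (default 8).
#' @return object of class `ani_result`: list with `query_id`, `ref_id`,
#'   `gani` (percent; `NA` and `defined = FALSE` when no fragment
#'   qualifies), `af_query`, `af_ref`, `af_avg`, `n_fragments`,
#'   `n_aligned`.
#' @export
compute_gani <- function(query, reference, fragment_length = 1020L,
                         min_fragment_identity = 70,
                         min_fragment_coverage = 70, k = 16L, band = 12L,
                         seed_stride = 8L) {
  if (!inherits(query, "genome_seq") || !inherits(reference, "genome_seq")) {
    stop("`query` and `reference` must be genome_seq objects", call. = FALSE)
  }
  if (fragment_length < k) {
    stop("`fragment_length` must be >= seed word length `k`", call. = FALSE)
  }
  fwd <- gani_direction(query, reference, fragment_length,
                        min_fragment_identity, min_fragment_coverage, k,
                        band, seed_stride)
  rev <- gani_direction(reference, query, fragment_length,
                        min_fragment_identity, min_fragment_coverage, k,
                        band, seed_stride)
  ids <- c(fwd$identities, rev$identities)
  wts <- c(fwd$weights, rev$weights)
  defined <- length(ids) > 0L
  structure(list(
    query_id = query$id,
    ref_id = reference$id,
    gani = if (defined) sum(ids * wts) / sum(wts) else NA_real_,
    af_query = fwd$af,
    af_ref = rev$af,
    af_avg = (fwd$af + rev$af) / 2,
    n_fragments = fwd$n_fragments + rev$n_fragments,
    n_aligned = fwd$n_aligned + rev$n_aligned,
    defined = defined
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<ani_result> %s vs %s: gANI %.2f%%, AF %.2f%%/%.2f%% (avg %.2f%%), %d/%d fragments aligned\n",
                x$query_id, x$ref_id, x$gani, x$af_query, x$af_ref,
                x$af_avg, x$n_aligned, x$n_fragments))
  } else {
    cat(sprintf("<ani_result> %s vs %s: undefined (no qualifying fragments)\n",
                x$query_id, x$ref_id))
  }
  invisible(x)
}

#' Species demarcation from a gANI value
#'
#' Classifies a genome pair against the proposed prokaryotic species
#' threshold of 95 percent gANI; the boundary is inclusive, so a pair at
#' exactly 95.00 is called same-species.
#'
#' @param ani an `ani_result` from [compute_gani()].
#' @param threshold demarcation threshold in percent (default 95).
#' @return `"same-species"` or `"different-species"`.
#' @export
classify_pair <- function(ani, threshold = 95) {
  if (!inherits(ani, "ani_result")) {
    stop("`ani` must be an ani_result", call. = FALSE)
  }
  if (!isTRUE(ani$defined) || is.na(ani$gani)) {
    stop("unclassifiable: gANI undefined (no aligned fragments)",
         call. = FALSE)
  }
  if (ani$gani >= threshold) "same-species" else "different-species"
}

#' Marker-gene identity typing
#'
#' Global alignment of two marker-gene sequences (e.g. partial gyrB) with
#' match +1, mismatch -1, gap -2 scoring; identity is 100 * matches /
#' alignment columns (gap columns included).  An isolate is assigned to a
#' known species when the identity reaches the threshold (97 percent by
#' default, the gyrB species-assignment threshold).
#'
#' @param seq_a,seq_b nucleotide sequences (character or
#'   [Biostrings::DNAString]); non-empty.
#' @param threshold assignment threshold in percent (default 97).
#' @param match,mismatch,gap alignment scores.
#' @return list with `identity` (percent) and `assigned` (logical).
#' @export
marker_identity <- function(seq_a, seq_b, threshold = 97, match = 1,
                            mismatch = -1, gap = -2) {
  seq_a <- as.character(seq_a)
  seq_b <- as.character(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("marker sequences must be non-empty", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat, gapOpening = 0,
    gapExtension = abs(gap)
  )
  columns <- nchar(as.character(Biostrings::alignedPattern(aln)))
  matches <- Biostrings::nmatch(aln)
  identity <- 100 * matches / columns
  list(identity = identity, assigned = identity >= threshold)
}

#' Intra-/inter-species gANI-AF scatter table
#'
#' Turns pairwise ANI results into the records behind an intra- versus
#' inter-species gANI/AF scatter plot: each pair is labelled intra- or
#' inter-species from the supplied species labels and assigned to a branch
#' (or `"cross-branch"` when its species sit on different branches).
#'
#' @param ani_results list of `ani_result` objects.
#' @param species_labels named character vector, genome id -> species.
#' @param branch_labels named character vector, species -> branch.
#' @return data frame `query_id`, `ref_id`, `gani`, `af_avg`, `label`
#'   (`"intra-species"` / `"inter-species"`), `branch`.
#' @export
scatter_table <- function(ani_results, species_labels, branch_labels) {
  if (inherits(ani_results, "ani_result")) ani_results <- list(ani_results)
  rows <- lapply(ani_results, function(a) {
    if (!inherits(a, "ani_result")) {
      stop("`ani_results` must contain ani_result objects", call. = FALSE)
    }
    sp <- species_labels[c(a$query_id, a$ref_id)]
    if (anyNA(sp)) {
      stop("unlabeled genome: ",
           paste(c(a$query_id, a$ref_id)[is.na(sp)], collapse = ", "),
           call. = FALSE)
    }
    br <- branch_labels[sp]
    if (anyNA(br)) {
      stop("species without branch label: ",
           paste(unique(sp[is.na(br)]), collapse = ", "), call. = FALSE)
    }
    data.frame(
      query_id = a$query_id, ref_id = a$ref_id, gani = a$gani,
      af_avg = a$af_avg,
      label = if (sp[1] == sp[2]) "intra-species" else "inter-species",
      branch = if (br[1] == br[2]) unname(br[1]) else "cross-branch",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pairwise ANI results as a matrix TSV
#'
#' @param ani_results list of `ani_result` objects.
#' @param path output path (columns query, ref, gani, af_query, af_ref,
#'   af_avg, n_aligned).
#' @return `path`, invisibly.
#' @export
write_ani_tsv <- function(ani_results, path) {
  if (inherits(ani_results, "ani_result")) ani_results <- list(ani_results)
  df <- do.call(rbind, lapply(ani_results, function(a) {
    data.frame(query = a$query_id, ref = a$ref_id, gani = a$gani,
               af_query = a$af_query, af_ref = a$af_ref, af_avg = a$af_avg,
               n_aligned = a$n_aligned, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
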