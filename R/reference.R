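#' Build a concatenated, masked reference set
#'
#' Prepares the competitive mapping target: ribosomal-operon (or other) mask
#' intervals are excised from each genome -- removed outright, with
#' downstream coordinates shifted -- and the masked genomes are concatenated
#' in lexicographic genome-id order.  Excised intervals are recorded in
#' original coordinates so positions remain recoverable.  All recruitment,
#' coverage and detection coordinates refer to the post-excision sequences.
#'
#' @param genomes a [genome_seq] or list of them; genome ids must be unique.
#' @param masks optional masks to excise: either a named list (one entry per
#'   genome id) of data frames with columns `contig`, `start0`, `end0`
#'   (0-based half-open), or a path to a BED file whose chrom column holds
#'   contig names.
#' @param k seed word length for the recruiter index (default 31, a standard
#'   choice for species-level exact seeding).
#' @return an object of class `reference_set` with elements `genomes`
#'   (post-excision, sorted by id), `offsets` (per-genome global start and
#'   length in the concatenation), `blocks` (per-contig layout), `excised`
#'   (per-genome list of excised intervals in original coordinates), `k` and
#'   `seq` (the concatenated sequence).
#' @export
build_reference_set <- function(genomes, masks = NULL, k = 31L) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  if (!length(genomes) || !all(vapply(genomes, inherits, TRUE, "genome_seq"))) {
    stop("`genomes` must be a non-empty list of genome_seq objects",
         call. = FALSE)
  }
  ids <- vapply(genomes, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome id", call. = FALSE)
  genomes <- genomes[order(ids)]
  ids <- sort(ids)

  if (is.character(masks) && length(masks) == 1L) {
    masks <- read_masks_bed(masks, genomes)
  }
  if (!is.null(masks) && (!is.list(masks) || is.null(names(masks)))) {
    stop("`masks` must be a named list of interval data frames or a BED path",
         call. = FALSE)
  }
  if (!is.null(masks) && !all(names(masks) %in% ids)) {
    stop("mask for unknown genome: ",
         paste(setdiff(names(masks), ids), collapse = ", "), call. = FALSE)
  }

  excised <- stats::setNames(vector("list", length(ids)), ids)
  out_genomes <- vector("list", length(genomes))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    m <- masks[[g$id]]
    if (!is.null(m) && nrow(m)) {
      req <- c("contig", "start0", "end0")
      if (!all(req %in% names(m))) {
        stop("mask intervals need columns contig, start0, end0",
             call. = FALSE)
      }
      widths <- stats::setNames(Biostrings::width(g$contigs),
                                names(g$contigs))
      seqs <- as.character(g$contigs)
      m <- m[order(m$contig, m$start0), req]
      for (ctg in unique(m$contig)) {
        if (!ctg %in% names(widths)) {
          stop("mask references unknown contig: ", ctg, call. = FALSE)
        }
        mi <- m[m$contig == ctg, ]
        if (any(mi$start0 < 0) || any(mi$end0 > widths[[ctg]]) ||
            any(mi$start0 >= mi$end0)) {
          stop("mask outside contig bounds on ", ctg, call. = FALSE)
        }
        if (nrow(mi) > 1L && any(mi$start0[-1L] < mi$end0[-nrow(mi)])) {
          stop("overlapping mask intervals on ", ctg, call. = FALSE)
        }
        # excise from the right so earlier coordinates stay valid
        for (j in rev(seq_len(nrow(mi)))) {
          seqs[[ctg]] <- paste0(substr(seqs[[ctg]], 1L, mi$start0[j]),
                                substr(seqs[[ctg]], mi$end0[j] + 1L,
                                       widths[[ctg]]))
        }
      }
      excised[[g$id]] <- m
      g <- genome_seq(g$id, seqs)
    }
    out_genomes[[i]] <- g
  }

  blocks <- do.call(rbind, lapply(out_genomes, function(g) {
    w <- Biostrings::width(g$contigs)
    data.frame(genome_id = g$id, contig = names(g$contigs), len = w,
               local_start = cumsum(w) - w, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(blocks$contig)) {
    stop("contig names must be unique across the reference set",
         call. = FALSE)
  }
  blocks$gstart <- cumsum(blocks$len) - blocks$len
  if (min(blocks$len) < k) {
    stop("`k` is larger than the shortest contig", call. = FALSE)
  }

  glen <- vapply(out_genomes, genome_length, numeric(1))
  offsets <- data.frame(
    genome_id = ids,
    gstart = blocks$gstart[match(ids, blocks$genome_id)],
    length = as.integer(glen), stringsAsFactors = FALSE
  )
  seq <- paste(unlist(lapply(out_genomes,
                             function(g) as.character(g$contigs))),
               collapse = "")

  structure(list(genomes = stats::setNames(out_genomes, ids),
                 offsets = offsets, blocks = blocks, excised = excised,
                 k = as.integer(k), seq = seq, cache = new.env(parent = emptyenv())),
            class = "reference_set")
}

# lazily built, cached k-mer index (an external pointer; rebuilt
# transparently when absent, e.g. after serialization)
get_ref_index <- function(refs) {
  xp <- refs$cache$index
  if (is.null(xp) || !cpp_index_ok(xp)) {
    xp <- cpp_index_build(refs$seq, refs$blocks$gstart,
                          refs$blocks$gstart + refs$blocks$len, refs$k)
    refs$cache$index <- xp
  }
  xp
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d genome(s), %s bp indexed, k = %d\n",
              length(x$genomes), format(nchar(x$seq), big.mark = ","), x$k))
  for (i in seq_len(nrow(x$offsets))) {
    nexc <- if (is.null(x$excised[[x$offsets$genome_id[i]]])) 0L
            else nrow(x$excised[[x$offsets$genome_id[i]]])
    cat(sprintf("  %-20s global start %10d, length %9d, %d excised interval(s)\n",
                x$offsets$genome_id[i], x$offsets$gstart[i],
                x$offsets$length[i], nexc))
  }
  invisible(x)
}

#' Map a global concatenation position to genome/contig coordinates
#'
#' @param refs a `reference_set`.
#' @param gpos vector of 0-based global positions.
#' @return data frame with `genome_id`, `contig`, `start0` (contig-local,
#'   post-excision) and `genome_pos0` (genome-local, post-excision).
#' @export
global_to_local <- function(refs, gpos) {
  b <- findInterval(gpos, refs$blocks$gstart)
  if (any(b < 1L) || any(gpos >= refs$blocks$gstart[b] + refs$blocks$len[b])) {
    stop("global position outside the concatenation", call. = FALSE)
  }
  data.frame(
    genome_id = refs$blocks$genome_id[b],
    contig = refs$blocks$contig[b],
    start0 = as.integer(gpos - refs$blocks$gstart[b]),
    genome_pos0 = as.integer(gpos - refs$blocks$gstart[b] +
                               refs$blocks$local_start[b]),
    stringsAsFactors = FALSE
  )
}

#' Map contig coordinates back to the global concatenation
#'
#' @param refs a `reference_set`.
#' @param contig contig names.
#' @param start0 0-based contig-local positions (post-excision).
#' @return 0-based global positions.
#' @export
local_to_global <- function(refs, contig, start0) {
  b <- match(contig, refs$blocks$contig)
  if (anyNA(b)) {
    stop("unknown contig: ", paste(unique(contig[is.na(b)]), collapse = ", "),
         call. = FALSE)
  }
  refs$blocks$gstart[b] + start0
}

#' Recover original (pre-excision) coordinates
#'
#' Shifts a post-excision contig coordinate back onto the original contig by
#' re-inserting the widths of all excised intervals at or before it.
#'
#' @param refs a `reference_set`.
#' @param genome_id genome identifier.
#' @param contig contig name (post-excision naming is unchanged).
#' @param start0 0-based post-excision position(s) on that contig.
#' @return 0-based position(s) in original coordinates.
#' @export
restore_coordinates <- function(refs, genome_id, contig, start0) {
  exc <- refs$excised[[genome_id]]
  if (is.null(exc) || !nrow(exc)) return(start0)
  exc <- exc[exc$contig == contig, , drop = FALSE]
  out <- start0
  if (nrow(exc)) {
    exc <- exc[order(exc$start0), ]
    # walk excisions left to right in original coordinates
    for (j in seq_len(nrow(exc))) {
      w <- exc$end0[j] - exc$start0[j]
      out <- ifelse(out >= exc$start0[j], out + w, out)
    }
  }
  out
}

#' Read mask intervals from a BED file
#'
#' BED is 0-based half-open; the chrom column must hold contig names of the
#' supplied genomes.  Requires the `rtracklayer` package.
#'
#' @param path BED file path.
#' @param genomes list of [genome_seq] used to resolve contig -> genome.
#' @return named list (by genome id) of data frames `contig`, `start0`,
#'   `end0`, suitable for [build_reference_set()].
#' @export
read_masks_bed <- function(path, genomes) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading BED masks requires the rtracklayer package",
         call. = FALSE)
  }
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  df <- data.frame(contig = as.character(gr$seqnames),
                   start0 = gr$start - 1L, end0 = gr$end,
                   stringsAsFactors = FALSE)
  contig2genome <- unlist(lapply(genomes, function(g) {
    stats::setNames(rep(g$id, length(g$contigs)), names(g$contigs))
  }))
  gid <- contig2genome[df$contig]
  if (anyNA(gid)) {
    stop("BED contig not found in any genome: ",
         paste(unique(df$contig[is.na(gid)]), collapse = ", "),
         call. = FALSE)
  }
  split(df, unname(gid))
}
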