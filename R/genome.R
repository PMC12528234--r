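#' Genome sequence objects
#'
#' A `genome_seq` is a named, possibly multi-contig nucleotide sequence with
#' optional interval annotations (role tags such as `"core"`, `"accessory"`
#' or `"rRNA-operon"`, as 0-based half-open intervals per contig).  It is the
#' unit handled by the simulator, the reference builder and the genome-index
#' functions.
#'
#' @param id genome identifier.
#' @param contigs named [Biostrings::DNAStringSet] (or named character
#'   vector) of contig sequences.
#' @param annotations optional data frame with columns `contig`, `start0`,
#'   `end0`, `role` (0-based half-open intervals).
#' @return an object of class `genome_seq`: a list with elements `id`,
#'   `contigs` (a `DNAStringSet`) and `annotations`.
#' @export
genome_seq <- function(id, contigs, annotations = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("`id` must be a single non-empty string", call. = FALSE)
  }
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  if (!methods::is(contigs, "DNAStringSet") || length(contigs) == 0L) {
    stop("`contigs` must be a non-empty DNAStringSet", call. = FALSE)
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must have unique names", call. = FALSE)
  }
  if (sum(Biostrings::width(contigs)) == 0L) {
    stop("total genome length must be > 0", call. = FALSE)
  }
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations, contigs)
  }
  structure(list(id = id, contigs = contigs, annotations = annotations),
            class = "genome_seq")
}

validate_annotations <- function(annotations, contigs) {
  req <- c("contig", "start0", "end0", "role")
  if (!is.data.frame(annotations) || !all(req %in% names(annotations))) {
    stop("`annotations` needs columns contig, start0, end0, role",
         call. = FALSE)
  }
  annotations <- annotations[req]
  widths <- stats::setNames(Biostrings::width(contigs), names(contigs))
  for (i in seq_len(nrow(annotations))) {
    ctg <- annotations$contig[i]
    if (!ctg %in% names(widths)) {
      stop("annotation references unknown contig: ", ctg, call. = FALSE)
    }
    if (annotations$start0[i] < 0 || annotations$end0[i] > widths[[ctg]] ||
        annotations$start0[i] >= annotations$end0[i]) {
      stop("annotation interval outside contig bounds on ", ctg,
           call. = FALSE)
    }
  }
  # intervals must not overlap within one role on one contig
  for (key in split(annotations, paste(annotations$contig, annotations$role))) {
    o <- order(key$start0)
    if (nrow(key) > 1L && any(key$start0[o][-1L] < key$end0[o][-nrow(key)])) {
      stop("overlapping annotation intervals within one role", call. = FALSE)
    }
  }
  annotations
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d contig(s), %s bp\n", x$id,
              length(x$contigs),
              format(genome_length(x), big.mark = ",")))
  if (!is.null(x$annotations)) {
    tab <- table(x$annotations$role)
    cat("  annotations:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total length of a genome
#' @param genome a [genome_seq] object.
#' @return total length in bp.
#' @export
genome_length <- function(genome) {
  sum(Biostrings::width(genome$contigs))
}

#' Generate a random genome
#'
#' Draws i.i.d. bases with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`, split into `n_contigs` contigs of
#' as-equal-as-possible length.  Deterministic for a fixed seed.  Emulates
#' small free-living freshwater bacterial genomes (roughly 2.4--3.2 Mbp at
#' 38--42 mol% G+C).
#'
#' @param length total genome length in bp (> 0).
#' @param gc_fraction target G+C fraction in \[0, 1\].
#' @param n_contigs number of contigs (`length >= n_contigs >= 1`).
#' @param seed integer RNG seed.
#' @param id genome identifier (default derived from the seed).
#' @return a [genome_seq] with contigs named `<id>_c1`, `<id>_c2`, ...
#' @export
generate_genome <- function(length, gc_fraction, n_contigs = 1L, seed,
                            id = sprintf("g%d", as.integer(seed))) {
  stopifnot_scalar_number(length, "length")
  stopifnot_scalar_number(gc_fraction, "gc_fraction")
  if (length <= 0) stop("`length` must be positive", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("`gc_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_contigs < 1L || length < n_contigs) {
    stop("need `length` >= `n_contigs` >= 1", call. = FALSE)
  }
  length <- as.integer(length)
  n_contigs <- as.integer(n_contigs)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- with_seed(seed, sample(names(probs), length, replace = TRUE,
                                  prob = probs))
  base_len <- length %/% n_contigs
  extra <- length %% n_contigs
  widths <- rep(base_len, n_contigs) + c(rep(1L, extra),
                                         rep(0L, n_contigs - extra))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  seqs <- vapply(seq_len(n_contigs), function(i) {
    paste(bases[starts[i]:ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s_c%d", id, seq_len(n_contigs))
  genome_seq(id, seqs)
}

#' Derive a conspecific or related strain from a parent genome
#'
#' Reproduces the genomic structure of closely related bacterial strains:
#' a shared core genome in which each position is substituted independently
#' at `substitution_rate` (uniform choice among the three alternative
#' bases), plus a strain-specific accessory region.  The accessory region is
#' a contiguous block at the 3' end of the genome covering
#' `accessory_swap_fraction` of its length, replaced by freshly generated
#' random sequence of equal length and G+C.  Expected core identity to the
#' parent is `100 * (1 - substitution_rate)` percent, so e.g. a rate of 0.02
#' yields conspecific strains at about 98 percent ANI with distinct
#' accessory gene sets.  Core and accessory intervals are recorded in the
#' output annotations.
#'
#' @param parent a [genome_seq].
#' @param substitution_rate per-base substitution probability in \[0, 1).
#' @param accessory_swap_fraction fraction of the genome replaced by new
#'   accessory sequence, in \[0, 1).
#' @param seed integer RNG seed.
#' @param id identifier of the derived genome.
#' @return a [genome_seq] with `"core"` / `"accessory"` annotations.
#' @export
derive_relative <- function(parent, substitution_rate, accessory_swap_fraction,
                            seed, id = paste0(parent$id, "_rel")) {
  if (!inherits(parent, "genome_seq")) stop("`parent` must be a genome_seq")
  stopifnot_scalar_number(substitution_rate, "substitution_rate")
  stopifnot_scalar_number(accessory_swap_fraction, "accessory_swap_fraction")
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop("`substitution_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (accessory_swap_fraction < 0 || accessory_swap_fraction >= 1) {
    stop("`accessory_swap_fraction` must lie in [0, 1)", call. = FALSE)
  }
  widths <- Biostrings::width(parent$contigs)
  total <- sum(widths)
  acc_len <- round(accessory_swap_fraction * total)
  gc <- genome_stats(parent)$gc_mol_percent / 100

  with_seed(seed, {
    seqs <- as.character(parent$contigs)
    ann <- list()
    # accessory block: the trailing `acc_len` bases of the concatenated
    # genome, mapped onto the trailing contigs
    remaining <- acc_len
    for (i in rev(seq_along(seqs))) {
      if (remaining <= 0) break
      w <- widths[i]
      take <- min(w, remaining)
      if (take > 0) {
        probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
        repl <- paste(sample(names(probs), take, replace = TRUE, prob = probs),
                      collapse = "")
        substr(seqs[i], w - take + 1L, w) <- repl
        ann[[length(ann) + 1L]] <- data.frame(
          contig = names(seqs)[i], start0 = w - take, end0 = w,
          role = "accessory", stringsAsFactors = FALSE
        )
        remaining <- remaining - take
      }
    }
    # core: substitutions on everything outside the accessory block
    acc_start_per_contig <- stats::setNames(widths, names(seqs))
    for (a in ann) acc_start_per_contig[[a$contig]] <- a$start0
    for (i in seq_along(seqs)) {
      core_end <- acc_start_per_contig[[names(seqs)[i]]]
      if (core_end > 0) {
        core <- substr(seqs[i], 1L, core_end)
        if (substitution_rate > 0) {
          core <- cpp_finish_reads(core, FALSE, substitution_rate)
        }
        substr(seqs[i], 1L, core_end) <- core
        ann[[length(ann) + 1L]] <- data.frame(
          contig = names(seqs)[i], start0 = 0L, end0 = core_end,
          role = "core", stringsAsFactors = FALSE
        )
      }
    }
    out_names <- sprintf("%s_c%d", id, seq_along(seqs))
    seqs <- stats::setNames(seqs, out_names)
    annotations <- do.call(rbind, ann)
    annotations$contig <- out_names[match(annotations$contig,
                                          names(parent$contigs))]
    genome_seq(id, seqs, annotations)
  })
}

#' Write genomes as FASTA
#'
#' Sequences are wrapped at 80 columns; output is byte-identical for
#' identical inputs.
#'
#' @param genomes a [genome_seq] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  sets <- lapply(genomes, function(g) g$contigs)
  all <- do.call(c, sets)
  Biostrings::writeXStringSet(all, path, width = 80L)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Every record in the file becomes one contig of a single genome.
#'
#' @param path FASTA file.
#' @param id genome identifier (default: file name without extension).
#' @return a [genome_seq].
#' @export
read_genome_fasta <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  contigs <- Biostrings::readDNAStringSet(path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  genome_seq(id, contigs)
}
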