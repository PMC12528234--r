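#' Decide presence or absence of a species in one metagenome
#'
#' Applies the calibrated saturation curve to a mapping result.  Two
#' readings of the detection criterion ("coverage breadth at least tenfold
#' and larger than the calculated coverage breadth") are implemented and
#' selectable:
#'
#' * `min_and_above_curve` (default): detected iff the observed breadth is
#'   at least `b_min` percent AND exceeds the breadth the calibrated curve
#'   predicts for the same mapped-read count.
#' * `fold_above_curve`: detected iff the observed breadth is at least
#'   `fold` times the predicted breadth.
#'
#' The criterion wording is grammatically ambiguous; the default reading is
#' adopted because requiring ten times the predicted breadth rejects
#' genuinely present genomes whose breadth tracks the curve.  The applied
#' rule and its parameters are recorded in every result row.  A result with
#' zero mapped reads is never a detection.
#'
#' @param profile a `coverage_profile`.
#' @param fit the calibrated core-genome `saturation_fit`.
#' @param rule decision rule, `"min_and_above_curve"` or
#'   `"fold_above_curve"`.
#' @param b_min minimum observed breadth in percent (default 10) for the
#'   default rule.
#' @param fold multiple of the predicted breadth (default 10) for the fold
#'   rule.
#' @param metagenome_id identifier recorded in the result.
#' @return one-row data frame (a detection result): `metagenome_id`,
#'   `genome_id`, `n_mapped`, `breadth_obs`, `breadth_pred`,
#'   `pct_reads_mapped`, `detected`, `rule`.
#' @export
decide_detection <- function(profile, fit,
                             rule = c("min_and_above_curve",
                                      "fold_above_curve"),
                             b_min = 10, fold = 10,
                             metagenome_id = "metagenome") {
  if (!inherits(profile, "coverage_profile")) {
    stop("`profile` must be a coverage_profile", call. = FALSE)
  }
  rule <- match.arg(rule)
  n <- profile$n_mapped_reads
  pred <- predict_breadth(fit, n)
  obs <- profile$breadth
  detected <- if (n == 0L) {
    FALSE
  } else if (rule == "min_and_above_curve") {
    obs >= b_min && obs > pred
  } else {
    obs >= fold * pred
  }
  tag <- if (rule == "min_and_above_curve") {
    sprintf("min_and_above_curve(b_min=%g)", b_min)
  } else {
    sprintf("fold_above_curve(fold=%g)", fold)
  }
  data.frame(
    metagenome_id = metagenome_id,
    genome_id = profile$genome_id,
    n_mapped = n,
    breadth_obs = obs,
    breadth_pred = pred,
    pct_reads_mapped = profile$pct_reads_mapped,
    detected = detected,
    rule = tag,
    stringsAsFactors = FALSE
  )
}

#' Survey many metagenomes for the reference species
#'
#' Runs the detection decision for every (metagenome, reference genome)
#' pair and returns one table row per pair, with the percent of metagenomic
#' reads mapping on each genome as the abundance proxy.  Each metagenome is
#' supplied either as a `read_set` (recruited internally against `refs`) or
#' as a list `list(alignments = <data frame>, total_reads = <int>)` with
#' pre-computed alignments.  Detection is evaluated per genome
#' independently, all against the single calibrated core fit.  Reruns with
#' identical inputs are byte-identical.
#'
#' @param metagenomes named list of metagenome inputs (see above).
#' @param refs a `reference_set`.
#' @param fit the calibrated core-genome `saturation_fit`.
#' @param rule,b_min,fold decision-rule parameters, see
#'   [decide_detection()].
#' @param min_identity recruiter identity threshold for `read_set` inputs.
#' @param seed_stride recruiter seeding stride for `read_set` inputs.
#' @return data frame with one row per (metagenome, genome), columns as in
#'   [decide_detection()], in stable (input, genome id) order.
#' @export
survey <- function(metagenomes, refs, fit,
                   rule = c("min_and_above_curve", "fold_above_curve"),
                   b_min = 10, fold = 10, min_identity = 95,
                   seed_stride = 4L) {
  if (!length(metagenomes)) stop("empty metagenome list", call. = FALSE)
  if (is.null(names(metagenomes)) || any(!nzchar(names(metagenomes)))) {
    stop("`metagenomes` must be a named list", call. = FALSE)
  }
  rule <- match.arg(rule)
  rows <- lapply(names(metagenomes), function(mid) {
    mg <- metagenomes[[mid]]
    if (inherits(mg, "read_set")) {
      aln <- recruit_reads(mg, refs, min_identity = min_identity,
                           seed_stride = seed_stride)
      total <- length(mg$reads)
    } else if (is.list(mg) && !is.null(mg$alignments)) {
      aln <- check_alignments(mg$alignments)
      total <- mg$total_reads %||% nrow(aln)
    } else {
      stop("metagenome '", mid, "' must be a read_set or ",
           "list(alignments=, total_reads=)", call. = FALSE)
    }
    profiles <- compute_coverage(aln, refs, total)
    do.call(rbind, lapply(profiles, decide_detection, fit = fit, rule = rule,
                          b_min = b_min, fold = fold, metagenome_id = mid))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a survey: detections per genome
#'
#' @param survey_table data frame from [survey()].
#' @return data frame `genome_id`, `n_metagenomes`, `n_detected`.
#' @export
survey_summary <- function(survey_table) {
  agg <- stats::aggregate(detected ~ genome_id, survey_table,
                          function(d) c(n = length(d), det = sum(d)))
  data.frame(genome_id = agg$genome_id,
             n_metagenomes = agg$detected[, "n"],
             n_detected = agg$detected[, "det"],
             stringsAsFactors = FALSE)
}

#' Collapse genome-level detections to species level
#'
#' A species represented by several conspecific reference genomes counts as
#' detected in a metagenome when any of its genomes is detected.
#'
#' @param survey_table data frame from [survey()].
#' @param species_labels named character vector, genome id -> species.
#' @return data frame `metagenome_id`, `species`, `detected`,
#'   `n_genomes_detected`.
#' @export
species_detection <- function(survey_table, species_labels) {
  sp <- species_labels[survey_table$genome_id]
  if (anyNA(sp)) {
    stop("unlabeled genome: ",
         paste(unique(survey_table$genome_id[is.na(sp)]), collapse = ", "),
         call. = FALSE)
  }
  key <- data.frame(metagenome_id = survey_table$metagenome_id,
                    species = unname(sp),
                    detected = survey_table$detected,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(detected ~ metagenome_id + species, key,
                          function(d) c(any = any(d), n = sum(d)))
  out <- data.frame(metagenome_id = agg$metagenome_id,
                    species = agg$species,
                    detected = as.logical(agg$detected[, "any"]),
                    n_genomes_detected = as.integer(agg$detected[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$metagenome_id, out$species), , drop = FALSE]
}

#' Write a survey table as TSV
#'
#' A header line records the decision rule applied (and flags the ambiguity
#' of the criterion wording), followed by the table.
#'
#' @param survey_table data frame from [survey()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey_tsv <- function(survey_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# detection rule: ",
                    paste(unique(survey_table$rule), collapse = ", "),
                    " (criterion wording ambiguous; see ?decide_detection)"),
             con)
  utils::write.table(survey_table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
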