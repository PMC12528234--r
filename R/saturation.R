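#' Calibration-sample filter
#'
#' A metagenome/genome mapping result qualifies for calibrating the
#' saturation curve only when it is deeply sampled: mean covered depth
#' strictly greater than 100-fold and breadth strictly greater than 70
#' percent.
#'
#' @param profile a `coverage_profile`.
#' @return TRUE iff the profile passes the calibration filter.
#' @export
is_calibration_sample <- function(profile) {
  if (!inherits(profile, "coverage_profile")) {
    stop("`profile` must be a coverage_profile", call. = FALSE)
  }
  profile$mean_covered_depth > 100 && profile$breadth > 70
}

#' Build breadth-saturation points by stepwise read reduction
#'
#' Emulates stepwise reduction of the mapped read count: for each fraction,
#' `replicates` seeded subsamples of the genome's alignments are drawn and
#' their coverage breadth and mean covered depth are averaged, yielding one
#' (mapped-read-count, breadth) point per fraction.
#'
#' @param alignments alignment data frame (the full mapping result).
#' @param refs the `reference_set`.
#' @param genome_id genome to profile.
#' @param fractions ascending subsampling fractions in (0, 1\].  Default
#'   `c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1)`.
#' @param replicates subsamples per fraction (default 3).
#' @param seed integer RNG seed.
#' @param total_metagenome_reads total reads in the metagenome.
#' @return data frame of class `saturation_points` with columns `genome_id`,
#'   `fraction`, `n_reads`, `breadth`, `mean_covered_depth`.
#' @export
build_saturation_points <- function(alignments, refs, genome_id,
                                    fractions = c(0.01, 0.02, 0.05, 0.1,
                                                  0.2, 0.4, 0.6, 0.8, 1),
                                    replicates = 3L, seed = 1L,
                                    total_metagenome_reads = nrow(alignments)) {
  check_alignments(alignments)
  alignments <- alignments[alignments$genome_id == genome_id, , drop = FALSE]
  if (!nrow(alignments)) {
    stop("no alignments for genome ", genome_id, call. = FALSE)
  }
  if (!length(fractions)) stop("`fractions` must be non-empty", call. = FALSE)
  if (any(fractions <= 0) || any(fractions > 1) || is.unsorted(fractions)) {
    stop("`fractions` must be ascending and lie in (0, 1]", call. = FALSE)
  }
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)

  n <- nrow(alignments)
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    br <- numeric(replicates)
    dp <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sub <- subsample_alignments(alignments, f,
                                  derive_seed(seed, i * 1000L + r))
      prof <- compute_coverage(sub, refs, total_metagenome_reads,
                               genomes = genome_id)[[genome_id]]
      br[r] <- prof$breadth
      dp[r] <- prof$mean_covered_depth
    }
    data.frame(genome_id = genome_id, fraction = f,
               n_reads = as.integer(floor(f * n)), breadth = mean(br),
               mean_covered_depth = mean(dp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_points", class(out))
  out
}

#' Fit an asymptotic breadth-saturation curve
#'
#' Least-squares fit of `B(n) = b_max * (1 - exp(-n / tau))`, the
#' Lander-Waterman breadth expectation reparameterized: `b_max` (percent) is
#' the breadth asymptote -- the recruitable fraction of the genome, i.e. the
#' core genome when the metagenome's population differs from the reference
#' in its accessory regions -- and `tau` (reads) is the read count at which
#' `1 - 1/e` of the asymptote is reached.  Fitting is unweighted
#' Gauss-Newton with step halving on the percent scale, initialized at
#' `b_max = max(breadth)` and `tau = n` at half that breadth, iterated until
#' the relative parameter change falls below 1e-8 or 500 iterations.
#'
#' @param points a `saturation_points` data frame (or any data frame with
#'   columns `n_reads`, `breadth`); at least 3 points with at least 2
#'   distinct `n_reads`.
#' @param genome_id genome identifier recorded in the fit.
#' @return object of class `saturation_fit`: list with `genome_id`, `b_max`,
#'   `tau`, `rss`, `n_points`, `residuals`.
#' @export
fit_saturation <- function(points, genome_id = points$genome_id[1]) {
  if (!is.data.frame(points) ||
      !all(c("n_reads", "breadth") %in% names(points))) {
    stop("`points` needs columns n_reads and breadth", call. = FALSE)
  }
  n <- points$n_reads
  b <- points$breadth
  if (length(n) < 3L) stop("need at least 3 saturation points", call. = FALSE)
  if (length(unique(n)) < 2L) {
    stop("need at least 2 distinct n_reads values", call. = FALSE)
  }
  if (all(b <= 0)) stop("all breadth values are zero", call. = FALSE)

  bmax <- max(b)
  half <- which(b >= bmax / 2)
  tau <- max(n[half[1]], 1)
  theta <- c(bmax, tau)
  model <- function(th) th[1] * (1 - exp(-n / th[2]))
  rss <- sum((b - model(theta))^2)
  rel <- Inf

  for (it in seq_len(500L)) {
    e <- exp(-n / theta[2])
    f <- theta[1] * (1 - e)
    r <- b - f
    J <- cbind(1 - e, -theta[1] * e * n / theta[2]^2)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(err) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (h in seq_len(30L)) {
      cand <- theta + lambda * as.numeric(step)
      if (cand[2] > 0 && cand[1] > 0) {
        rss_cand <- sum((b - model(cand))^2)
        if (rss_cand <= rss) {
          rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-12))
          theta <- cand
          rss <- rss_cand
          improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved || rel < 1e-8) break
  }

  structure(list(genome_id = genome_id, b_max = theta[1], tau = theta[2],
                 rss = rss, n_points = length(n),
                 residuals = b - model(theta)),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> %s: b_max = %.2f%%, tau = %.0f reads (rss %.3g, %d points)\n",
              x$genome_id, x$b_max, x$tau, x$rss, x$n_points))
  invisible(x)
}

#' Predicted coverage breadth at a mapped-read count
#'
#' Evaluates the calibrated curve `b_max * (1 - exp(-n / tau))`.
#'
#' @param fit a `saturation_fit`.
#' @param n_reads mapped-read count(s), >= 0.
#' @return predicted breadth in percent.
#' @export
predict_breadth <- function(fit, n_reads) {
  if (!inherits(fit, "saturation_fit")) {
    stop("`fit` must be a saturation_fit", call. = FALSE)
  }
  if (any(n_reads < 0)) stop("`n_reads` must be >= 0", call. = FALSE)
  fit$b_max * (1 - exp(-n_reads / fit$tau))
}

#' Select the core-genome fit
#'
#' Among per-genome saturation fits, returns the one with the smallest
#' asymptote, which reflects the size of the core genome shared by the
#' calibration strains; ties are broken by lexicographic genome id.
#'
#' @param fits list of `saturation_fit` objects (non-empty).
#' @return the selected `saturation_fit`.
#' @export
select_core_fit <- function(fits) {
  if (inherits(fits, "saturation_fit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "saturation_fit"))) {
    stop("`fits` must be a non-empty list of saturation_fit objects",
         call. = FALSE)
  }
  bmax <- vapply(fits, function(f) f$b_max, numeric(1))
  ids <- vapply(fits, function(f) f$genome_id, character(1))
  fits[[order(bmax, ids)[1]]]
}

#' Write saturation fits as JSON
#'
#' @param fits a `saturation_fit` or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  if (inherits(fits, "saturation_fit")) fits <- list(fits)
  x <- lapply(fits, function(f) {
    list(genome_id = f$genome_id, b_max = f$b_max, tau = f$tau, rss = f$rss,
         n_points = f$n_points)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read saturation fits from JSON
#'
#' @param path JSON written by [write_fit_json()].
#' @return list of `saturation_fit` objects.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x, function(f) {
    structure(list(genome_id = f$genome_id, b_max = f$b_max, tau = f$tau,
                   rss = f$rss, n_points = f$n_points, residuals = NULL),
              class = "saturation_fit")
  })
}
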