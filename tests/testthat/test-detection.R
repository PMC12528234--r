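test_that("decide_detection applies both readings of the criterion", {
  fit <- fake_fit(b_max = 80, tau = 5000)
  # high-breadth, low-depth profile above the curve: detected (the survey
  # phenotype of a genuinely present but rare species)
  n <- 20000
  pred <- predict_breadth(fit, n)
  prof <- fake_profile(breadth = 60.3, depth = 3.1, n_mapped = n,
                       total = 1e6)
  res <- decide_detection(prof, fake_fit(55, 5000), metagenome_id = "lake")
  expect_true(res$detected)
  expect_lt(res$breadth_pred, 60.3)
  expect_match(res$rule, "min_and_above_curve\\(b_min=10\\)")

  # below the curve: not detected even with breadth >= 10
  prof2 <- fake_profile(breadth = 40, depth = 30, n_mapped = n)
  expect_false(decide_detection(prof2, fit)$detected)
  expect_gt(predict_breadth(fit, n), 40)

  # below b_min: not detected even above the curve
  prof3 <- fake_profile(breadth = 5, depth = 1.1, n_mapped = 100)
  expect_gt(5, predict_breadth(fit, 100))
  expect_false(decide_detection(prof3, fit)$detected)

  # fold rule: needs fold x predicted
  prof4 <- fake_profile(breadth = 18, depth = 1.2, n_mapped = 100)
  expect_true(decide_detection(prof4, fit, rule = "fold_above_curve")$detected)
  expect_false(decide_detection(prof4, fit, rule = "fold_above_curve",
                                fold = 20)$detected)
  expect_match(decide_detection(prof4, fit, rule = "fold_above_curve")$rule,
               "fold_above_curve\\(fold=10\\)")
})

test_that("zero mapped reads is never a detection", {
  fit <- fake_fit(80, 5000)
  prof <- fake_profile(breadth = 0, depth = 0, n_mapped = 0)
  expect_false(decide_detection(prof, fit)$detected)
  expect_false(decide_detection(prof, fit, rule = "fold_above_curve")$detected)
})

test_that("raising observed breadth never flips a detection off", {
  fit <- fake_fit(75, 4000)
  for (n in c(50, 500, 5000, 50000)) {
    detected <- vapply(seq(0, 100, by = 0.5), function(b) {
      decide_detection(fake_profile(breadth = b, depth = 1 + b,
                                    n_mapped = n), fit)$detected
    }, logical(1))
    expect_true(all(diff(as.integer(detected)) >= 0))
  }
})

# a small end-to-end world: 100 kb reference, calibration from conspecific
# strains, detection of a conspecific target vs an 85%-ANI relative
detection_world <- function() {
  parent <- generate_genome(100000, 0.42, 1, seed = 300, id = "parent")
  ref <- derive_relative(parent, 0.005, 0.2, seed = 301, id = "ref")
  refs <- build_reference_set(list(ref))
  strains <- lapply(1:2, function(i) {
    derive_relative(parent, 0.005, 0.2, seed = 310 + i,
                    id = sprintf("strain%d", i))
  })
  cal_comm <- community_spec(strains, c(0.5, 0.5), error_rate = 0.001,
                             seed = 320)
  cal_rs <- simulate_reads(cal_comm, 70000)
  cal_aln <- recruit_reads(cal_rs, refs)
  cal_prof <- compute_coverage(cal_aln, refs, 70000)[["ref"]]
  pts <- build_saturation_points(cal_aln, refs, "ref", replicates = 2L,
                                 seed = 330, total_metagenome_reads = 70000)
  list(parent = parent, ref = ref, refs = refs, cal_prof = cal_prof,
       fit = fit_saturation(pts, "ref"))
}

test_that("calibrated detection separates a conspecific from an 85%-ANI relative", {
  w <- detection_world()
  expect_true(is_calibration_sample(w$cal_prof))
  # the asymptote reflects the ~80% core of the calibration strains
  expect_lt(abs(w$fit$b_max - 80), 4)

  bg <- generate_genome(100000, 0.45, 1, seed = 340, id = "bg")
  target <- derive_relative(w$ref, 0.02, 0.1, seed = 341, id = "target")
  rel <- relative_with_islands(w$ref, p = 0.15, seed = 342,
                               island_len = 2000)

  present <- vapply(1:3, function(i) {
    comm <- community_spec(list(target, bg), c(0.02, 0.98),
                           error_rate = 0.001, seed = 350 + i)
    rs <- simulate_reads(comm, 100000)
    aln <- recruit_reads(rs, w$refs)
    prof <- compute_coverage(aln, w$refs, 100000)[["ref"]]
    decide_detection(prof, w$fit, metagenome_id = paste0("m", i))$detected
  }, logical(1))
  expect_true(all(present))

  absent <- vapply(1:3, function(i) {
    comm <- community_spec(list(rel, bg), c(0.1, 0.9),
                           error_rate = 0.001, seed = 360 + i)
    rs <- simulate_reads(comm, 100000)
    aln <- recruit_reads(rs, w$refs)
    prof <- compute_coverage(aln, w$refs, 100000)[["ref"]]
    # conserved-island pile-up: observed breadth sits far below the curve
    res <- decide_detection(prof, w$fit, metagenome_id = paste0("a", i))
    expect_lt(res$breadth_obs, res$breadth_pred)
    res$detected
  }, logical(1))
  expect_false(any(absent))
})

test_that("survey emits one stable row per metagenome x genome with rule tags", {
  g1 <- generate_genome(20000, 0.45, 1, seed = 400, id = "g1")
  g2 <- generate_genome(20000, 0.45, 1, seed = 401, id = "g2")
  refs <- build_reference_set(list(g1, g2))
  fit <- fake_fit(80, 500)
  mk <- function(seed) {
    comm <- community_spec(list(g1, g2), c(0.7, 0.3), error_rate = 0,
                           seed = seed)
    simulate_reads(comm, 2000)
  }
  mgs <- list(m1 = mk(1), m2 = mk(2), m3 = mk(3))
  tab <- survey(mgs, refs, fit)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$metagenome_id, rep(c("m1", "m2", "m3"), each = 2))
  expect_equal(tab$genome_id, rep(c("g1", "g2"), 3))
  expect_true(all(nzchar(tab$rule)))
  # reruns are identical
  expect_identical(tab, survey(mgs, refs, fit))
  # summary counts per genome
  s <- survey_summary(tab)
  expect_equal(s$n_metagenomes, c(3L, 3L))
  # pre-computed alignments are accepted too
  aln <- recruit_reads(mgs$m1, refs)
  tab2 <- survey(list(m1 = list(alignments = aln, total_reads = 2000)),
                 refs, fit)
  expect_equal(tab2[, -1], tab[tab$metagenome_id == "m1", -1],
               ignore_attr = TRUE)
  expect_error(survey(list(), refs, fit), "empty")
})

test_that("pct_reads_mapped tracks the true read share of the target", {
  target <- generate_genome(50000, 0.42, 1, seed = 410, id = "target")
  bg <- generate_genome(50000, 0.45, 1, seed = 411, id = "bg")
  refs <- build_reference_set(list(target))
  comm <- community_spec(list(target, bg), c(0.002, 0.998), error_rate = 0,
                         seed = 412)
  rs <- simulate_reads(comm, 200000)
  aln <- recruit_reads(rs, refs, seed_stride = 8L)
  prof <- compute_coverage(aln, refs, 200000)[["target"]]
  expect_lt(abs(prof$pct_reads_mapped - 0.2), 0.05)
})

test_that("species-level detection fires when any conspecific genome fires", {
  tab <- data.frame(
    metagenome_id = rep(c("m1", "m2"), each = 3),
    genome_id = rep(c("gA1", "gA2", "gB"), 2),
    n_mapped = 10L, breadth_obs = 1, breadth_pred = 1,
    pct_reads_mapped = 0.1,
    detected = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    rule = "min_and_above_curve(b_min=10)", stringsAsFactors = FALSE
  )
  labels <- c(gA1 = "spA", gA2 = "spA", gB = "spB")
  out <- species_detection(tab, labels)
  expect_equal(nrow(out), 4L)
  get <- function(m, s) out$detected[out$metagenome_id == m & out$species == s]
  expect_true(get("m1", "spA"))
  expect_false(get("m1", "spB"))
  expect_false(get("m2", "spA"))
  expect_true(get("m2", "spB"))
  expect_equal(out$n_genomes_detected[out$metagenome_id == "m1" &
                                        out$species == "spA"], 1L)
  expect_error(species_detection(tab, labels[-1]), "unlabeled")
})

test_that("survey TSV carries the rule header", {
  tab <- data.frame(metagenome_id = "m", genome_id = "g", n_mapped = 10L,
                    breadth_obs = 12, breadth_pred = 5,
                    pct_reads_mapped = 0.1, detected = TRUE,
                    rule = "min_and_above_curve(b_min=10)")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_survey_tsv(tab, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# detection rule: min_and_above_curve")
  expect_equal(length(lines), 3L)
})
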