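# helper: inject exactly n mismatches into a read at given positions
mutate_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  s[pos] <- rot[s[pos]]
  paste(s, collapse = "")
}

test_that("build_reference_set bookkeeping: offsets tile, lookups round-trip", {
  g1 <- generate_genome(10000, 0.5, 1, seed = 1, id = "alpha")
  g2 <- generate_genome(20000, 0.5, 2, seed = 2, id = "beta")
  refs <- build_reference_set(list(g2, g1))  # input order must not matter
  expect_equal(refs$offsets$genome_id, c("alpha", "beta"))
  expect_equal(refs$offsets$gstart, c(0L, 10000L))
  expect_equal(refs$offsets$length, c(10000L, 20000L))
  expect_equal(nchar(refs$seq), 30000L)
  # boundary positions round-trip
  for (gp in c(0L, 9999L, 10000L, 19999L, 20000L, 29999L)) {
    loc <- global_to_local(refs, gp)
    expect_equal(local_to_global(refs, loc$contig, loc$start0), gp)
  }
  expect_error(global_to_local(refs, 30000L), "outside")
})

test_that("masks are excised and coordinates are recoverable", {
  g <- generate_genome(10000, 0.5, 1, seed = 3, id = "g")
  mask <- list(g = data.frame(contig = names(g$contigs)[1],
                              start0 = 4000L, end0 = 4500L))
  refs <- build_reference_set(list(g), masks = mask)
  expect_equal(refs$offsets$length, 9500L)
  expect_equal(nchar(refs$seq), 9500L)
  # sequence around the excision joins flanks
  orig <- as.character(g$contigs[[1]])
  expect_identical(refs$seq, paste0(substr(orig, 1, 4000),
                                    substr(orig, 4501, 10000)))
  # positions at/after the cut shift back by the excised width
  expect_equal(restore_coordinates(refs, "g", names(g$contigs)[1],
                                   c(0L, 3999L, 4000L, 9000L)),
               c(0L, 3999L, 4500L, 9500L))
})

test_that("build_reference_set rejects bad input", {
  g <- generate_genome(1000, 0.5, 1, seed = 4, id = "dup")
  g2 <- generate_genome(1000, 0.5, 1, seed = 5, id = "dup")
  expect_error(build_reference_set(list(g, g2)), "duplicate")
  m <- list(dup = data.frame(contig = names(g$contigs)[1], start0 = 900L,
                             end0 = 1200L))
  expect_error(build_reference_set(list(g), masks = m), "bounds")
  expect_error(build_reference_set(list(g), k = 1500L), "shortest contig")
})

test_that("recruiter places exact reads at their truth locus with identity 100", {
  g <- generate_genome(10000, 0.5, 1, seed = 6)
  refs <- build_reference_set(list(g))
  read <- substr(as.character(g$contigs[[1]]), 501, 650)
  aln <- recruit_reads(c(r1 = read), refs)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start0, 500L)
  expect_equal(aln$identity, 100)
  expect_equal(aln$strand, "+")
  expect_equal(aln$aligned_length, 150L)
})

test_that("the 95% cutoff brackets 7 vs 8 mismatches on a 150 bp read", {
  g <- generate_genome(10000, 0.5, 1, seed = 7)
  refs <- build_reference_set(list(g))
  base <- substr(as.character(g$contigs[[1]]), 2001, 2150)
  # mismatches confined to the first half so a clean terminal seed remains
  r7 <- mutate_at(base, seq(5, 65, by = 10))
  r8 <- mutate_at(base, seq(5, 75, by = 10))
  a7 <- recruit_reads(c(x = r7), refs)
  a8 <- recruit_reads(c(x = r8), refs)
  expect_equal(nrow(a7), 1L)
  expect_equal(a7$mismatches, 7L)
  expect_equal(a7$identity, 100 * 143 / 150)
  expect_gte(a7$identity, 95)
  expect_equal(nrow(a8), 0L)
  expect_lt(100 * 142 / 150, 95)
})

test_that("error-free simulated reads are recovered >= 99.9% exactly, uniquely", {
  g1 <- generate_genome(50000, 0.45, 1, seed = 8, id = "g1")
  g2 <- generate_genome(50000, 0.45, 2, seed = 9, id = "g2")
  refs <- build_reference_set(list(g1, g2))
  comm <- community_spec(list(g1, g2), c(0.5, 0.5), error_rate = 0,
                         seed = 10)
  rs <- simulate_reads(comm, 20000)
  aln <- recruit_reads(rs, refs)
  expect_equal(anyDuplicated(aln$read_id), 0L)
  m <- merge(aln, rs$truth, by = "read_id")
  exact <- m$contig.x == m$contig.y & m$start0.x == m$start0.y &
    m$strand.x == m$strand.y
  expect_gte(nrow(aln) / 20000, 0.999)
  expect_gte(mean(exact), 0.999)
})

test_that("ties break deterministically: lexicographic genome, coordinate, + strand", {
  g1 <- generate_genome(5000, 0.5, 1, seed = 11, id = "bbb")
  shared <- substr(as.character(g1$contigs[[1]]), 1001, 1300)
  # plant the same segment into a second genome with a lexicographically
  # smaller id, at a later coordinate
  s2 <- as.character(generate_genome(5000, 0.5, 1, seed = 12)$contigs[[1]])
  substr(s2, 3001, 3300) <- shared
  g2 <- genome_seq("aaa", stats::setNames(s2, "aaa_c1"))
  refs <- build_reference_set(list(g1, g2))
  read <- substr(shared, 51, 200)
  aln <- recruit_reads(c(r = read), refs)
  expect_equal(aln$genome_id, "aaa")
  # and within one genome, the smaller coordinate wins
  s3 <- as.character(generate_genome(6000, 0.5, 1, seed = 13)$contigs[[1]])
  substr(s3, 101, 400) <- shared
  substr(s3, 4001, 4300) <- shared
  g3 <- genome_seq("ccc", stats::setNames(s3, "ccc_c1"))
  refs3 <- build_reference_set(list(g3))
  aln3 <- recruit_reads(c(r = read), refs3)
  expect_equal(aln3$start0, 100L + 50L)
  expect_equal(aln3$strand, "+")
})

test_that("reads shorter than k are unassigned with a warning", {
  g <- generate_genome(5000, 0.5, 1, seed = 14)
  refs <- build_reference_set(list(g))
  expect_warning(aln <- recruit_reads(c(tiny = "ACGTACGT"), refs),
                 "shorter than k")
  expect_equal(nrow(aln), 0L)
})

test_that("an 85%-ANI relative recruits < 5% of its reads, onto conserved islands", {
  ref <- generate_genome(100000, 0.42, 1, seed = 15, id = "ref")
  refs <- build_reference_set(list(ref))
  rel <- relative_with_islands(ref, p = 0.15, seed = 16, n_islands = 5,
                               island_len = 800)
  comm <- community_spec(list(rel), 1, error_rate = 0, seed = 17)
  rs <- simulate_reads(comm, 20000)
  aln <- recruit_reads(rs, refs, seed_stride = 1L)
  expect_lt(nrow(aln) / 20000, 0.05)
  # recruited reads overlap the conserved islands
  isl <- rel$annotations[rel$annotations$role == "conserved-island", ]
  in_island <- vapply(seq_len(nrow(aln)), function(i) {
    any(aln$start0[i] < isl$end0 & aln$start0[i] + 150L > isl$start0)
  }, logical(1))
  expect_gt(mean(in_island), 0.95)
})

test_that("SAM round-trip: recruiter and import_sam agree on identity and coordinates", {
  g <- generate_genome(20000, 0.45, 1, seed = 18)
  refs <- build_reference_set(list(g))
  comm <- community_spec(list(g), 1, error_rate = 0.01, seed = 19)
  rs <- simulate_reads(comm, 1000)
  aln <- recruit_reads(rs, refs)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, refs, sam, reads = rs$reads)
  back <- import_sam(sam, refs, min_identity = 95)
  o1 <- aln[order(aln$read_id), ]
  o2 <- back[order(back$read_id), ]
  expect_equal(o1$read_id, o2$read_id)
  expect_equal(o1$identity, o2$identity)
  expect_equal(o1$start0, o2$start0)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$mismatches, o2$mismatches)
})

test_that("import_sam applies flag, NM, clipping and identity rules", {
  g <- generate_genome(2000, 0.5, 1, seed = 20, id = "g")
  refs <- build_reference_set(list(g))
  ctg <- refs$blocks$contig[1]
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:2000", ctg),
    sprintf("ok\t0\t%s\t11\t255\t150M\t*\t0\t0\t*\t*\tNM:i:3", ctg),
    "unmapped\t4\t*\t0\t255\t*\t*\t0\t0\t*\t*",
    sprintf("secondary\t256\t%s\t11\t255\t150M\t*\t0\t0\t*\t*\tNM:i:0", ctg),
    sprintf("lowid\t0\t%s\t21\t255\t150M\t*\t0\t0\t*\t*\tNM:i:10", ctg),
    sprintf("clipped\t16\t%s\t31\t255\t10S140M\t*\t0\t0\t*\t*\tNM:i:0", ctg),
    sprintf("no_nm\t0\t%s\t41\t255\t150M\t*\t0\t0\t*\t*", ctg)
  ), sam)
  expect_message(aln <- import_sam(sam, refs), "without NM tag")
  expect_equal(aln$read_id, "ok")
  expect_equal(aln$identity, 100 * 147 / 150)
  expect_equal(aln$start0, 10L)
  # with clipping allowed, the clipped record passes (identity 100)
  suppressMessages(aln2 <- import_sam(sam, refs, require_full_length = FALSE))
  expect_setequal(aln2$read_id, c("ok", "clipped"))
  expect_equal(aln2$strand[aln2$read_id == "clipped"], "-")
  # unknown reference name errors
  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:other\tLN:500",
               "r\t0\tother\t1\t255\t100M\t*\t0\t0\t*\t*\tNM:i:0"), bad)
  expect_error(import_sam(bad, refs), "unknown reference")
})
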