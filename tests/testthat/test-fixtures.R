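# The synthetic-data generator: determinism, planted-event recovery,
# dialect round-trips.

test_that("make_genome is deterministic with the stated record lengths", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  make_genome(c(1000, 500), f1, seed = 81)
  make_genome(c(1000, 500), f2, seed = 81)
  expect_identical(readLines(f1), readLines(f2))
  kar <- create_karyotype(f1)
  expect_identical(kar$id, c("chr1", "chr2"))
  expect_identical(kar$length, c(1000, 500))
  f3 <- withr::local_tempfile(fileext = ".fasta")
  make_genome(c(1000, 500), f3, seed = 82)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("base composition is uniform within 3 sigma at 50 kb", {
  f <- withr::local_tempfile(fileext = ".fasta")
  make_genome(50000, f, seed = 83)
  seq <- paste(readLines(f)[-1L], collapse = "")
  counts <- table(strsplit(seq, "")[[1L]])
  expect_setequal(names(counts), c("A", "C", "G", "T"))
  # binomial bound: n p +/- 3 sqrt(n p (1 - p))
  expect_true(all(abs(counts - 50000 / 4) <=
                    3 * sqrt(50000 * 0.25 * 0.75)))
})

test_that("without events every pair is concordant and nm_adapt is empty", {
  kar <- toy_karyotype(with_nm = FALSE)
  f <- withr::local_tempfile(fileext = ".sam")
  simulate_pairs(kar, list(), f, n_background = 300, seed = 84)
  expect_identical(nrow(nm_adapt(f)), 0L)
  lines <- readLines(f)
  flags <- as.integer(vapply(strsplit(lines[!startsWith(lines, "@")], "\t"),
                             `[`, character(1), 2L))
  expect_true(all(bitwAnd(flags, 2L) != 0L))   # all proper pairs
})

test_that("foreign insertions plant anchors within one fragment of the site", {
  kar <- toy_karyotype()
  f <- withr::local_tempfile(fileext = ".sam")
  simulate_pairs(kar, list(planted_event("foreign_insertion", chr = "ec",
                                         pos = 5000, n_pairs = 60)),
                 f, n_background = 100, seed = 85)
  anchors <- nm_adapt(f)
  expect_identical(nrow(anchors), 60L)
  expect_true(all(abs(anchors$pos - 5000) <= 330))
})

test_that("coverage conserves every mapped read including event reads", {
  kar <- toy_karyotype(with_nm = FALSE)
  f <- withr::local_tempfile(fileext = ".sam")
  events <- list(
    planted_event("translocation", chr = "ec", pos = 10000,
                  chr2 = "p1", pos2 = 40000, n_pairs = 30),
    planted_event("foreign_insertion", chr = "ec", pos = 90000,
                  n_pairs = 45),
    planted_event("cnv", chr = "ec", start = 120000, end = 150000,
                  n_pairs = 80))
  simulate_pairs(kar, events, f, n_background = 1000, seed = 86)
  cov <- coverage_adapt(f, win = 10000, karyotype = kar)
  # 1000 + 80 concordant pairs (2 reads), 30 discordant pairs (2 reads),
  # 45 half-mapped pairs (1 mapped read)
  expect_identical(sum(cov$value), 2 * 1080 + 2 * 30 + 45)
  expect_identical(sum(cov$value), oracle_counted_alignments(f) + 0)
})

test_that("events outside the genome are refused", {
  kar <- toy_karyotype(with_nm = FALSE)
  f <- withr::local_tempfile(fileext = ".sam")
  expect_error(simulate_pairs(kar, list(planted_event(
    "foreign_insertion", chr = "ec", pos = 999999999, n_pairs = 5)), f),
    "outside the genome")
  expect_error(simulate_pairs(kar, list(planted_event(
    "translocation", chr = "nope", pos = 10, chr2 = "ec", pos2 = 10,
    n_pairs = 5)), f), "outside the genome")
})

test_that("fixture writers and adapters are exact inverses", {
  kar <- toy_karyotype(with_nm = FALSE)
  set.seed(87)
  links <- random_links(25, kar)
  f <- withr::local_tempfile()
  make_svdetect_file(links, f)
  expect_same_records(svd_links_adapt(f), links)
  cnv <- random_segments(25, kar, "value", seed = 88)
  cnv$color <- NA_character_
  make_freec_file(cnv, f)
  expect_same_records(freec_cnv_adapt(f), cnv)
  ann <- random_segments(25, kar, "annot", seed = 89)
  ann$color <- NA_character_
  make_annot_file(ann, f)
  expect_same_records(tab_annot_adapt(f, column_map(1, 4, 5, 7, 3)), ann)
  # by-construction type counts
  ty <- link_records(rep("ec", 5), 1:5, 2:6, rep("ec", 5), 11:15, 12:16,
                     c(rep("TRANSLOC", 3), rep("INV_TRANSLOC", 2)), 1:5)
  make_svdetect_file(ty, f)
  expect_identical(as.integer(table(svd_links_adapt(f)$type)[
    c("TRANSLOC", "INV_TRANSLOC")]), c(3L, 2L))
})

test_that("planted insertions recover as NM links exactly at the threshold", {
  kar <- toy_karyotype()
  f <- withr::local_tempfile(fileext = ".sam")
  events <- list(
    planted_event("foreign_insertion", chr = "ec", pos = 20000,
                  n_pairs = 52),
    planted_event("foreign_insertion", chr = "ec", pos = 100000,
                  n_pairs = 50),
    planted_event("foreign_insertion", chr = "p1", pos = 40000,
                  n_pairs = 49))
  simulate_pairs(kar, events, f, n_background = 500, seed = 90)
  nml <- nm_paint(nm_adapt(f), kar, frag_size = 330, threshold = 50)
  expect_identical(nrow(nml), 2L)
  expect_setequal(nml$support, c(52, 50))
  expect_false("p1" %in% nml$chrA)
})

test_that("planted translocations survive view filtering iff loci overlap views", {
  kar <- toy_karyotype(with_nm = FALSE)
  truth <- link_records(
    chrA = c("ec", "ec", "p1"), startA = c(10000, 120000, 30000),
    endA = c(10330, 120330, 30330),
    chrB = c("ec", "p1", "p1"), startB = c(80000, 50000, 70000),
    endB = c(80330, 50330, 70330),
    type = "TRANSLOC", support = 20)
  f <- withr::local_tempfile()
  make_svdetect_file(truth, f)
  links <- svd_links_adapt(f)
  v <- view_spec("ec", 5000, 15000)
  kept <- filter_links_by_views(links, v)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$startA, 10000)
})
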