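# The composer: Circos file-set emission, view restriction, logging,
# cross-reference validation, determinism.

compose_fixture <- function(out_dir, seed = 71, ...) {
  fx <- simulate_fixture_set(withr::local_tempdir(), seed = seed)
  kar <- append_nm(fx$karyotype)
  cov <- coverage_adapt(fx$paths$sam, win = 10000, karyotype = kar)
  nml <- nm_paint(nm_adapt(fx$paths$sam), kar)
  links <- links_paint(svd_links_adapt(fx$paths$svdetect),
                       type_conv(c("TRANSLOC", "INV_TRANSLOC"), c(2, 4)))
  cnv <- cnv_paint(freec_cnv_adapt(fx$paths$freec))
  ann <- annot_paint(tab_annot_adapt(fx$paths$annot,
                                     column_map(1, 4, 5, 7, 3)))
  cfg <- plot_config("ec", out_dir = out_dir, ...)
  chromosome_image(cfg, kar, links = links, nm = nml, coverage = cov,
                   cnv = cnv, annot = ann)
  list(kar = kar, cfg = cfg, links = links, nm = nml, cov = cov,
       cnv = cnv, ann = ann)
}

test_that("a full composition emits all tracks, links and includes", {
  d <- withr::local_tempdir()
  compose_fixture(file.path(d, "img"), ext_fraction = 5)
  out <- file.path(d, "img")
  for (f in c("circos.conf", "ideogram.conf", "ticks.conf", "karyotype.txt",
              "links.txt", "nm_links.txt", "coverage.txt", "cnv.txt",
              "annot.txt", "run.log")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  conf <- readLines(file.path(out, "circos.conf"))
  # three ring tracks at their fixed radial bands, links in the center
  expect_identical(sum(conf == "type = highlight"), 1L)
  expect_identical(sum(conf == "type = histogram"), 1L)
  expect_identical(sum(conf == "type = heatmap"), 1L)
  expect_identical(sum(conf == "<link>"), 2L)
  expect_true("r0 = 0.9r" %in% conf)    # annotations outermost
  expect_true("r0 = 0.8r" %in% conf)    # coverage middle
  expect_true("r0 = 0.7r" %in% conf)    # CNV innermost
  expect_true("scale = 5" %in% conf)
  expect_true("file = circos_image.png" %in% conf)
})

test_that("an open view end covers the whole chromosome of interest", {
  d <- withr::local_tempdir()
  compose_fixture(file.path(d, "img"), view1 = c(1, NA))
  conf <- readLines(file.path(d, "img", "circos.conf"))
  expect_true("start = 1u" %in% conf)
  expect_true("end = 200000u" %in% conf)   # the fixture ec length
})

test_that("a karyotype-only composition is valid and minimal", {
  d <- withr::local_tempdir()
  kar <- toy_karyotype(with_nm = FALSE)
  cfg <- plot_config("ec", out_dir = file.path(d, "min"))
  chromosome_image(cfg, kar)
  files <- list.files(file.path(d, "min"))
  expect_setequal(files, c("circos.conf", "ideogram.conf", "ticks.conf",
                           "karyotype.txt", "run.log"))
  conf <- readLines(file.path(d, "min", "circos.conf"))
  expect_false(any(grepl("<plots>", conf)))
  expect_false(any(grepl("<links>", conf)))
})

test_that("out-of-range views and unknown track chromosomes are refused", {
  kar <- toy_karyotype(with_nm = FALSE)
  d <- withr::local_tempdir()
  cfg <- plot_config("ec", view1 = c(1, 999999999),
                     out_dir = file.path(d, "x"))
  expect_error(chromosome_image(cfg, kar), "beyond")
  cfg <- plot_config("ec", out_dir = file.path(d, "y"))
  bad_cov <- segment_records("chrZ", 1, 10, value = 1)
  expect_error(chromosome_image(cfg, kar, coverage = bad_cov), "chrZ")
  nm_links <- link_records("ec", 1, 10, "NM", 1, 5, "NM", 60)
  expect_error(chromosome_image(cfg, kar, nm = nm_links),
               "pseudo-chromosome")
})

test_that("flag_view_outer FALSE restricts the annotation ring to the views", {
  kar <- toy_karyotype(with_nm = FALSE)
  set.seed(72)
  ann <- annot_paint(random_segments(80, kar, "annot"))
  views <- list(view_spec("ec", 50000, 90000),
                view_spec("ec", 150000, 160000))
  got <- flag_view_outer_apply(ann, views, flag_view_outer = FALSE)
  # oracle: clip each record to each view it overlaps
  want <- list()
  for (v in views) {
    for (i in seq_len(nrow(ann))) {
      if (ann$chr[i] == v$chr && ann$start[i] <= v$end &&
          ann$end[i] >= v$start) {
        r <- ann[i, ]
        r$start <- max(r$start, v$start)
        r$end <- min(r$end, v$end)
        want[[length(want) + 1L]] <- r
      }
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want$chr, want$start, want$end), ]
  expect_same_records(got, want)
  expect_true(all(got$start >= 50000 & got$end <= 160000))
  # TRUE (default) and no-annotation cases pass through untouched
  expect_same_records(flag_view_outer_apply(ann, views, TRUE), ann)
  expect_null(flag_view_outer_apply(NULL, views, FALSE))
})

test_that("the run log lists every argument once and each input once", {
  d <- withr::local_tempdir()
  compose_fixture(file.path(d, "img"))
  log <- readLines(file.path(d, "img", "run.log"))
  for (arg in c("chr:", "view1:", "view2:", "ext_fraction:",
                "flag_view_outer:", "image_format:", "image_name:",
                "out_dir:")) {
    expect_identical(sum(grepl(paste0("^  ", arg), log)), 1L, label = arg)
  }
  for (tr in c("links", "nm", "coverage", "cnv", "annot")) {
    expect_identical(sum(grepl(paste0("^  ", tr, " \\("), log)), 1L,
                     label = tr)
  }
  expect_error(run_log("x", arguments = list(a = 1, a = 2)), "duplicate")
})

test_that("two identical compositions are byte-identical apart from the log timestamp", {
  d <- withr::local_tempdir()
  compose_fixture(file.path(d, "img1"), seed = 73)
  compose_fixture(file.path(d, "img2"), seed = 73)
  files <- list.files(file.path(d, "img1"))
  expect_setequal(files, list.files(file.path(d, "img2")))
  for (f in setdiff(files, "run.log")) {
    a <- file.path(d, "img1", f)
    b <- file.path(d, "img2", f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)), label = f)
  }
  # the two runs differ only in timestamp and target directory
  strip_ts <- function(p) grep("^timestamp:|^  out_dir:", readLines(p),
                               invert = TRUE, value = TRUE)
  expect_identical(strip_ts(file.path(d, "img1", "run.log")),
                   strip_ts(file.path(d, "img2", "run.log")))
})

test_that("the cross-reference validator passes emitted sets and catches corruption", {
  d <- withr::local_tempdir()
  compose_fixture(file.path(d, "img"))
  out <- file.path(d, "img")
  expect_identical(nrow(check_output(out)), 0L)
  cov <- readLines(file.path(out, "coverage.txt"))
  cov[1] <- "ghost 1 10 5"
  cov[2] <- "ec 10 999999999 5"
  writeLines(cov, file.path(out, "coverage.txt"))
  bad <- check_output(out)
  expect_identical(nrow(bad), 2L)
  expect_true(any(grepl("unknown chromosome", bad$problem)))
  expect_true(any(grepl("invalid", bad$problem)))
})
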