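# Color assignment: hue families, support gradients, NM clustering.

shade_of <- function(color, ramp) match(color, ramp)

test_that("links_paint assigns the converted hue family per type", {
  pal <- palette_spec()
  links <- link_records(rep("ec", 4), c(1, 10, 20, 30), c(5, 15, 25, 35),
                        rep("ec", 4), 100 + 1:4, 200 + 1:4,
                        c("TRANSLOC", "TRANSLOC", "INV_TRANSLOC",
                          "INV_TRANSLOC"),
                        c(5, 50, 7, 7))
  got <- links_paint(links, type_conv(c("TRANSLOC", "INV_TRANSLOC"),
                                      c(2, 4)), pal)
  expect_true(all(got$color[got$type == "TRANSLOC"] %in% pal$hues$green))
  expect_true(all(got$color[got$type == "INV_TRANSLOC"] %in% pal$hues$pink))
})

test_that("shade darkness is non-decreasing in support within each type", {
  pal <- palette_spec()
  set.seed(51)
  for (trial in 1:20) {
    n <- sample(2:40, 1)
    supports <- sample.int(1000, n, replace = TRUE)
    links <- link_records(rep("ec", n), seq_len(n), seq_len(n) + 1,
                          rep("ec", n), 1000 + seq_len(n),
                          1001 + seq_len(n), "TRANSLOC", supports)
    got <- links_paint(links, type_conv("TRANSLOC", 2), pal)
    sh <- shade_of(got$color, pal$hues$green)
    expect_false(anyNA(sh))
    ord <- order(got$support)
    expect_true(all(diff(sh[ord]) >= 0))
  }
})

test_that("a degenerate support range paints the darkest shade", {
  pal <- palette_spec()
  one <- links_paint(link_records("ec", 1, 2, "ec", 5, 6, "TRANSLOC", 123),
                     type_conv("TRANSLOC", 2), pal)
  expect_identical(one$color, pal$hues$green[pal$shades_per_hue])
})

test_that("unknown types are dropped with a warning; empty conv errors", {
  links <- link_records(c("ec", "ec"), c(1, 5), c(2, 6), c("ec", "ec"),
                        c(10, 20), c(11, 21), c("TRANSLOC", "MYSTERY"),
                        c(1, 2))
  expect_warning(got <- links_paint(links, type_conv("TRANSLOC", 2)),
                 "1 link")
  expect_identical(nrow(got), 1L)
  expect_error(links_paint(links, list()), "type_conv")
})

test_that("painting alters only the color column", {
  kar <- toy_karyotype(with_nm = FALSE)
  links <- random_links(30, kar, seed = 52)
  conv <- type_conv(unique(links$type), seq_along(unique(links$type)) + 1)
  got <- links_paint(links, conv)
  expect_same_records(got[names(got) != "color"],
                      links[names(links) != "color"])
})

test_that("nm_paint matches the brute-force single-linkage oracle", {
  kar <- toy_karyotype()
  set.seed(53)
  for (trial in 1:10) {
    n <- sample.int(500, 1)
    anchors <- data.frame(
      chr = sample(c("ec", "p1"), n, replace = TRUE),
      pos = sample.int(200000, n, replace = TRUE),
      strand = "+", stringsAsFactors = FALSE)
    frag <- sample(c(50, 330, 2000), 1)
    thr <- sample(c(1, 3, 10), 1)
    got <- nm_paint(anchors, kar, frag_size = frag, threshold = thr)
    want <- oracle_cluster_anchors(anchors, frag)
    want <- want[want$size >= thr, , drop = FALSE]
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$chrA, want$chr)
    expect_identical(got$startA, as.numeric(want$start))
    expect_identical(got$endA, as.numeric(want$end))
    expect_identical(got$support, as.numeric(want$size))
  }
})

test_that("nm_paint thresholds clusters and separates distant sites", {
  kar <- toy_karyotype()
  # 60 anchors within a 300 bp window -> one link of support 60
  a1 <- data.frame(chr = "ec", pos = seq(5000, 5300, length.out = 60),
                   strand = "+", stringsAsFactors = FALSE)
  a1$pos <- round(a1$pos)
  got <- nm_paint(a1, kar, frag_size = 330, threshold = 50)
  expect_identical(nrow(got), 1L)
  expect_identical(got$support, 60)
  expect_identical(got$type, "NM")
  expect_identical(got$chrB, "NM")
  # 10 anchors below the threshold -> nothing
  got <- nm_paint(a1[1:10, ], kar, frag_size = 330, threshold = 50)
  expect_identical(nrow(got), 0L)
  # two 60-anchor clusters separated by 5 kb -> two links
  a2 <- a1
  a2$pos <- a2$pos + 5000 + 330
  got <- nm_paint(rbind(a1, a2), kar, frag_size = 330, threshold = 50)
  expect_identical(nrow(got), 2L)
  expect_identical(got$support, c(60, 60))
})

test_that("nm links sit left-to-right on NM in the reserved red family", {
  kar <- toy_karyotype()
  pal <- palette_spec()
  anchors <- data.frame(
    chr = "ec",
    pos = c(seq(1000, 1290, 5), seq(50000, 50440, 4)),
    strand = "+", stringsAsFactors = FALSE)
  got <- nm_paint(anchors, kar, frag_size = 330, threshold = 50)
  expect_identical(nrow(got), 2L)
  # NM feet: non-overlapping, ordered, inside the pseudo-chromosome
  expect_true(got$startB[2] > got$endB[1])
  expect_true(all(got$endB <= kar$length[kar$id == "NM"]))
  expect_true(all(got$color %in% pal$hues$red))
  # darker red for the larger cluster
  expect_true(shade_of(got$color[2], pal$hues$red) >=
                shade_of(got$color[1], pal$hues$red))
  expect_error(nm_paint(anchors, toy_karyotype(with_nm = FALSE)), "NM")
})

test_that("cnv_paint maps copy-number statuses to the fixed colors", {
  segs <- segment_records(rep("ec", 5), c(1, 11, 21, 31, 41),
                          c(10, 20, 30, 40, 50), value = c(0, 1, 2, 3, 7))
  got <- cnv_paint(segs)
  expect_identical(got$color,
                   c("173,216,230",   # 0 -> light blue
                     "255,255,224",   # 1 -> background light yellow
                     "255,165,0",     # 2 -> orange
                     "255,0,0",       # 3 -> red
                     "255,0,0"))      # >= 4 saturates at red
  expect_identical(nrow(got), 5L)    # baseline segments still emitted
  expect_error(cnv_paint(segment_records("ec", 1, 2, value = -1)),
               "negative")
})

test_that("annot_paint colors Watson grey and Crick dark green", {
  feats <- segment_records(rep("ec", 3), c(1, 11, 21), c(10, 20, 30),
                           strand = c("+", "-", "."),
                           label = c("a", "b", "c"))
  got <- annot_paint(feats)
  expect_identical(got$color, c("128,128,128", "0,100,0", "128,128,128"))
})
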