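# Shared fixture builders and independent brute-force oracles used across
# the suite. Oracles are deliberately naive (per-record loops) so they
# stay independent of the vectorized implementation paths they check.

toy_karyotype <- function(with_nm = TRUE) {
  kar <- karyotype(id = c("ec", "p1"), length = c(200000, 80000))
  if (with_nm) kar <- append_nm(kar, 5600) else kar
}

random_links <- function(n, kar, seed = NULL, with_color = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(kar), n, replace = TRUE)
  idx2 <- sample.int(nrow(kar), n, replace = TRUE)
  foot <- function(i) {
    len <- kar$length[i]
    s <- 1 + floor(runif(length(i)) * (len - 500))
    list(s = s, e = s + floor(runif(length(i)) * 400))
  }
  a <- foot(idx)
  b <- foot(idx2)
  link_records(kar$id[idx], a$s, a$e, kar$id[idx2], b$s, b$e,
               type = sample(c("TRANSLOC", "INV_TRANSLOC", "INS_FRAGMT",
                               "INV_INS_FRAGMT"), n, replace = TRUE),
               support = sample.int(500, n, replace = TRUE),
               color = if (with_color) {
                 ifelse(runif(n) < 0.5, "10,20,30", NA_character_)
               } else NA_character_)
}

random_segments <- function(n, kar, kind = c("value", "annot"),
                            seed = NULL, with_color = FALSE) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(kar), n, replace = TRUE)
  len <- kar$length[idx]
  s <- 1 + floor(runif(n) * (len - 500))
  e <- s + floor(runif(n) * 400)
  col <- if (with_color) {
    ifelse(runif(n) < 0.5, "99,98,97", NA_character_)
  } else NA_character_
  if (kind == "value") {
    segment_records(kar$id[idx], s, e, value = sample(0:7, n, replace = TRUE),
                    color = col)
  } else {
    segment_records(kar$id[idx], s, e,
                    strand = sample(c("+", "-", "."), n, replace = TRUE),
                    label = sprintf("g%03d", seq_len(n)), color = col)
  }
}

# naive per-link interval-overlap scan (the filtering oracle)
oracle_filter_links <- function(links, views) {
  keep <- logical(nrow(links))
  for (i in seq_len(nrow(links))) {
    for (v in views) {
      hitA <- links$chrA[i] != "NM" && links$chrA[i] == v$chr &&
        links$startA[i] <= v$end && links$endA[i] >= v$start
      hitB <- links$chrB[i] != "NM" && links$chrB[i] == v$chr &&
        links$startB[i] <= v$end && links$endB[i] >= v$start
      if (hitA || hitB) keep[i] <- TRUE
    }
  }
  links[keep, , drop = FALSE]
}

# quadratic brute-force single-linkage clustering of anchors
oracle_cluster_anchors <- function(anchors, frag_size) {
  if (!nrow(anchors)) {
    return(data.frame(chr = character(0), start = numeric(0),
                      end = numeric(0), size = integer(0)))
  }
  anchors <- anchors[order(anchors$chr, anchors$pos), , drop = FALSE]
  grp <- integer(nrow(anchors))
  grp[1L] <- 1L
  for (i in seq_len(nrow(anchors))[-1L]) {
    same <- anchors$chr[i] == anchors$chr[i - 1L] &&
      anchors$pos[i] - anchors$pos[i - 1L] <= frag_size
    grp[i] <- if (same) grp[i - 1L] else grp[i - 1L] + 1L
  }
  out <- lapply(unique(grp), function(g) {
    p <- anchors$pos[grp == g]
    data.frame(chr = anchors$chr[grp == g][1L], start = min(p),
               end = max(p), size = length(p))
  })
  do.call(rbind, out)
}

# minimal hand-rolled SAM writer for targeted flag/position cases
write_sam <- function(path, sq, records) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(sq), "\tLN:", sq))
  body <- vapply(records, function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, 60,
          if (bitwAnd(r$flag, 4L)) "*" else "10M",
          "=", r$pos, 0, "AAAAAAAAAA", "IIIIIIIIII", sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

sam_rec <- function(qname, flag, rname, pos) {
  list(qname = qname, flag = flag, rname = rname, pos = pos)
}

# independent count of primary mapped alignments straight off the SAM text
oracle_counted_alignments <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  n <- 0L
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) == 0L && bitwAnd(flag, 256L) == 0L &&
        bitwAnd(flag, 2048L) == 0L && f[3L] != "*") {
      n <- n + 1L
    }
  }
  n
}

expect_same_records <- function(got, want) {
  got <- as.data.frame(got)
  want <- as.data.frame(want)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
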