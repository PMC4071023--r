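# Deterministic synthetic-data generation: random genomes, paired-end
# alignments with planted structural variants and half-mapped pairs, and
# the third-party caller dialects the adapters consume. Every function
# draws from one explicit seed through a scoped RNG so repeated calls are
# byte-identical and nothing leaks into the caller's random state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random reference genome
#'
#' Writes uniform-random A/C/G/T FASTA records of the requested lengths.
#' Identical arguments always produce byte-identical files.
#'
#' @param lengths Positive integer vector of chromosome lengths.
#' @param path Output FASTA path.
#' @param seed Integer seed driving all randomness.
#' @param ids Chromosome identifiers; default `chr1`, `chr2`, ...
#' @return `path`, invisibly.
#' @export
make_genome <- function(lengths, path, seed = 1,
                        ids = paste0("chr", seq_along(lengths))) {
  stopifnot(length(lengths) >= 1, all(lengths >= 1),
            length(ids) == length(lengths))
  seqs <- with_seed(seed, lapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }))
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Describe a planted structural event
#'
#' Truth records consumed by [simulate_pairs()]. Kinds:
#' `"translocation"` and `"inversion_translocation"` join `(chr, pos)` to
#' `(chr2, pos2)` with `n_pairs` discordant read pairs;
#' `"foreign_insertion"` plants `n_pairs` half-mapped pairs anchored
#' within one fragment length upstream of `pos`; `"cnv"` adds `n_pairs`
#' extra concordant pairs inside `[start, end]`, emulating a gain.
#'
#' @param kind Event kind (see above).
#' @param chr,pos First locus (all kinds; for `"cnv"` use `start`/`end`).
#' @param chr2,pos2 Second locus (translocation kinds).
#' @param start,end Affected interval (`"cnv"`).
#' @param n_pairs Number of supporting read pairs (>= 1).
#' @return A list of class `planted_event`.
#' @export
planted_event <- function(kind = c("translocation",
                                   "inversion_translocation",
                                   "foreign_insertion", "cnv"),
                          chr, pos = NULL, chr2 = NULL, pos2 = NULL,
                          start = NULL, end = NULL, n_pairs = 1) {
  kind <- match.arg(kind)
  stopifnot(n_pairs >= 1)
  if (kind %in% c("translocation", "inversion_translocation")) {
    stopifnot(!is.null(pos), !is.null(chr2), !is.null(pos2))
  } else if (kind == "foreign_insertion") {
    stopifnot(!is.null(pos))
  } else {
    stopifnot(!is.null(start), !is.null(end), start <= end)
  }
  out <- list(kind = kind, chr = chr, pos = pos, chr2 = chr2, pos2 = pos2,
              start = start, end = end, n_pairs = as.integer(n_pairs))
  class(out) <- "planted_event"
  out
}

sam_line <- function(qname, flag, rname, pos, mapq, cigar, rnext, pnext,
                     tlen, seq, qual) {
  paste(qname, flag, rname, fmt_bp(pos), mapq, cigar, rnext, fmt_bp(pnext),
        fmt_bp(tlen), seq, qual, sep = "\t")
}

#' Simulate paired-end alignments with planted events
#'
#' Emits a SAM file (with `@SQ` header) containing uniform background
#' concordant pairs over the genome plus, per planted event, the evidence
#' a caller would see: discordant pairs joining the two loci of a
#' translocation, half-mapped pairs (mapped mate carries the
#' mate-unmapped flag; the unmapped mate record is emitted too) anchored
#' within one fragment length of a foreign insertion site, and extra
#' concordant pairs inside a CNV gain.
#'
#' @param karyotype A `circus_karyotype` (NM entry, if present, is
#'   ignored), or a FASTA path.
#' @param events List of [planted_event()]s; coordinates must lie inside
#'   the genome.
#' @param path Output SAM path.
#' @param n_background Number of background concordant pairs.
#' @param frag_size Fragment length in bp (default 330).
#' @param read_len Read length in bp (default 100).
#' @param seed Integer seed driving all randomness.
#' @return `path`, invisibly.
#' @export
simulate_pairs <- function(karyotype, events = list(), path,
                           n_background = 1000, frag_size = 330,
                           read_len = 100, seed = 1) {
  if (is.character(karyotype)) karyotype <- create_karyotype(karyotype)
  stopifnot(inherits(karyotype, "circus_karyotype"),
            frag_size > read_len)
  gen <- karyotype[karyotype$id != "NM", , drop = FALSE]
  if (any(gen$length < frag_size)) {
    stop("every chromosome must be at least one fragment length long")
  }
  len <- stats::setNames(gen$length, gen$id)
  in_genome <- function(chr, pos) {
    !is.null(chr) && chr %in% names(len) && all(pos >= 1) &&
      all(pos <= len[[chr]])
  }
  for (ev in events) {
    stopifnot(inherits(ev, "planted_event"))
    ok <- switch(ev$kind,
      translocation = ,
      inversion_translocation =
        in_genome(ev$chr, ev$pos) && in_genome(ev$chr2, ev$pos2),
      foreign_insertion = in_genome(ev$chr, ev$pos),
      cnv = in_genome(ev$chr, c(ev$start, ev$end)) &&
        ev$start <= len[[ev$chr]] - frag_size + 1)
    if (!ok) stop("planted ", ev$kind, " event lies outside the genome")
  }
  seq <- strrep("A", read_len)
  qual <- strrep("I", read_len)
  lines <- with_seed(seed, {
    out <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", gen$id, "\tLN:", fmt_bp(gen$length)))
    conc_pair <- function(qname, chr, p1) {
      p2 <- p1 + frag_size - read_len
      c(sam_line(qname, 99L, chr, p1, 60, paste0(read_len, "M"), "=",
                 p2, frag_size, seq, qual),
        sam_line(qname, 147L, chr, p2, 60, paste0(read_len, "M"), "=",
                 p1, -frag_size, seq, qual))
    }
    draw_conc <- function(qname_prefix, n, chrs, los, his) {
      if (n == 0L) return(character(0))
      pick <- sample.int(length(chrs), n, replace = TRUE,
                         prob = his - los + 1)
      p1 <- los[pick] + floor(stats::runif(n) * (his[pick] - los[pick] + 1))
      unlist(lapply(seq_len(n), function(i) {
        conc_pair(sprintf("%s%06d", qname_prefix, i), chrs[pick[i]], p1[i])
      }))
    }
    his <- pmax(1, unname(len) - frag_size + 1)
    out <- c(out, draw_conc("bg", n_background, gen$id,
                            rep(1, nrow(gen)), his))
    for (k in seq_along(events)) {
      ev <- events[[k]]
      tag <- sprintf("ev%02d", k)
      if (ev$kind %in% c("translocation", "inversion_translocation")) {
        inv <- ev$kind == "inversion_translocation"
        f1 <- if (inv) 97L else 65L     # paired, first; mate reverse if inv
        f2 <- if (inv) 145L else 129L   # paired, second
        for (i in seq_len(ev$n_pairs)) {
          j1 <- floor(stats::runif(1) * (frag_size - read_len + 1))
          j2 <- floor(stats::runif(1) * (frag_size - read_len + 1))
          p1 <- max(1, min(len[[ev$chr]] - read_len + 1, ev$pos + j1))
          p2 <- max(1, min(len[[ev$chr2]] - read_len + 1, ev$pos2 + j2))
          q <- sprintf("%s_%04d", tag, i)
          out <- c(out,
                   sam_line(q, f1, ev$chr, p1, 60, paste0(read_len, "M"),
                            ev$chr2, p2, 0, seq, qual),
                   sam_line(q, f2, ev$chr2, p2, 60, paste0(read_len, "M"),
                            ev$chr, p1, 0, seq, qual))
        }
      } else if (ev$kind == "foreign_insertion") {
        lo <- max(1, ev$pos - frag_size + read_len)
        for (i in seq_len(ev$n_pairs)) {
          p <- lo + floor(stats::runif(1) * (ev$pos - lo + 1))
          q <- sprintf("%s_%04d", tag, i)
          out <- c(out,
                   # mapped mate: paired + mate-unmapped + first in pair
                   sam_line(q, 73L, ev$chr, p, 60, paste0(read_len, "M"),
                            "=", p, 0, seq, qual),
                   # unmapped mate placed at the mapped mate per convention
                   sam_line(q, 133L, ev$chr, p, 0, "*", "=", p, 0,
                            seq, qual))
        }
      } else {                          # cnv gain: extra concordant pairs
        hi <- max(ev$start, min(ev$end, len[[ev$chr]]) - frag_size + 1)
        out <- c(out, draw_conc(paste0(tag, "_"), ev$n_pairs, ev$chr,
                                ev$start, hi))
      }
    }
    out
  })
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write truth records in third-party caller dialects
#'
#' Emit exactly the file dialects the adapters consume, from the given
#' truth records, for round-trip testing: `make_svdetect_file()` writes
#' the tab-delimited links layout read by [svd_links_adapt()],
#' `make_freec_file()` the `_CNVs` layout read by [freec_cnv_adapt()],
#' `make_annot_file()` a GTF-like table read by [tab_annot_adapt()] with
#' `column_map(1, 4, 5, 7, 3)`, and `make_pindel_file()` record headers
#' read by [pindel_adapt()].
#'
#' @param links A `circus_links` data frame of truth links (for the
#'   Pindel writer, intra-chromosomal with types DEL/DUP/INV and
#'   two-base feet).
#' @param segments A `circus_segments` data frame of value records.
#' @param features A `circus_segments` data frame of annotation records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name fixture_writers
NULL

#' @rdname fixture_writers
#' @export
make_svdetect_file <- function(links, path) {
  links <- as_links(links)
  lines <- character(0)
  if (nrow(links)) {
    lines <- paste(links$chrA, fmt_bp(links$startA), fmt_bp(links$endA),
                   links$chrB, fmt_bp(links$startB), fmt_bp(links$endB),
                   links$type, fmt_bp(links$support), sep = "\t")
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname fixture_writers
#' @export
make_freec_file <- function(segments, path) {
  segments <- as_segments(segments)
  lines <- character(0)
  if (nrow(segments)) {
    status <- ifelse(segments$value < 1, "loss",
                     ifelse(segments$value > 1, "gain", "normal"))
    lines <- paste(segments$chr, fmt_bp(segments$start),
                   fmt_bp(segments$end), fmt_bp(segments$value),
                   status, sep = "\t")
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname fixture_writers
#' @export
make_annot_file <- function(features, path) {
  features <- as_segments(features)
  lines <- character(0)
  if (nrow(features)) {
    lines <- paste(features$chr, "circosviz", features$label,
                   fmt_bp(features$start), fmt_bp(features$end), ".",
                   features$strand, ".",
                   paste0("gene_id \"", features$label, "\""),
                   sep = "\t")
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname fixture_writers
#' @export
make_pindel_file <- function(links, path) {
  links <- as_links(links)
  cls <- c(DEL = "D", DUP = "TD", INV = "INV")[links$type]
  if (nrow(links) && any(is.na(cls))) {
    stop("Pindel writer supports types DEL, DUP, INV only")
  }
  lines <- character(0)
  if (nrow(links)) {
    size <- links$startB - links$startA
    lines <- as.vector(rbind(
      strrep("#", 40),
      paste0(seq_len(nrow(links)) - 1L, "\t", cls, " ", fmt_bp(size),
             "\tNT 0 \"\"\tChrID ", links$chrA,
             "\tBP ", fmt_bp(links$startA), "\t", fmt_bp(links$startB),
             "\tBP_range ", fmt_bp(links$startA), "\t",
             fmt_bp(links$startB + 1),
             "\tSupports ", fmt_bp(links$support), " ",
             fmt_bp(links$support))))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}
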