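# Native extraction of evidence from SAM/BAM alignments: binned read
# coverage and the anchors of half-mapped ("No Match") read pairs. SAM
# text is parsed directly; BAM goes through Rsamtools under the same
# reader contract.

FLAG_PAIRED <- 1L
FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L
FLAG_REVERSE <- 16L
FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

# Unified alignment reader: data.frame(qname, flag, rname, pos) plus the
# @SQ header lengths (named numeric, possibly empty for headerless SAM).
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::scanBam(
      path, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos")))[[1L]]
    hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
    aln <- data.frame(qname = bam$qname, flag = as.integer(bam$flag),
                      rname = as.character(bam$rname),
                      pos = as.numeric(bam$pos), stringsAsFactors = FALSE)
    aln$rname[is.na(aln$rname)] <- "*"
    return(list(aln = aln, sq = hdr))
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- numeric(0)
  sq_lines <- lines[is_hdr & startsWith(lines, "@SQ")]
  if (length(sq_lines)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq_lines)
    ln <- as.numeric(sub(".*\tLN:([0-9]+).*", "\\1", sq_lines))
    sq <- stats::setNames(ln, sn)
  }
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(list(aln = data.frame(qname = character(0), flag = integer(0),
                                 rname = character(0), pos = numeric(0),
                                 stringsAsFactors = FALSE),
                sq = sq))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short)) {
    stop("line ", which(!is_hdr)[short[1L]], " of '", path,
         "': fewer than 11 SAM fields")
  }
  flag_chr <- vapply(fields, `[`, character(1), 2L)
  flag <- suppressWarnings(as.integer(flag_chr))
  bad <- which(is.na(flag))
  if (length(bad)) {
    stop("line ", which(!is_hdr)[bad[1L]], of_path(path),
         ": unparseable FLAG field '", flag_chr[bad[1L]], "'")
  }
  list(aln = data.frame(
         qname = vapply(fields, `[`, character(1), 1L),
         flag = flag,
         rname = vapply(fields, `[`, character(1), 3L),
         pos = as.numeric(vapply(fields, `[`, character(1), 4L)),
         stringsAsFactors = FALSE),
       sq = sq)
}

of_path <- function(path) paste0(" of '", path, "'")

flag_set <- function(flag, bit) bitwAnd(flag, bit) != 0L

# mapped, primary, non-supplementary
is_counted <- function(flag) {
  !flag_set(flag, FLAG_UNMAPPED) & !flag_set(flag, FLAG_SECONDARY) &
    !flag_set(flag, FLAG_SUPPLEMENTARY)
}

#' Bin read coverage from a SAM/BAM file
#'
#' Tiles every chromosome with contiguous windows `[1, win]`,
#' `[win + 1, 2 win]`, ... (the last window truncated at the chromosome
#' end) and counts, per window, the alignments whose leftmost mapped
#' position falls inside it. Counted alignments are mapped, primary and
#' non-supplementary, with mapping quality at or above `min_mapq`.
#' Zero-valued windows are emitted, so the windows tile each chromosome
#' exactly once and the values sum to the number of counted alignments.
#'
#' @param sam_path Path to a SAM or BAM file.
#' @param win Window width in base pairs (default 10000).
#' @param karyotype A `circus_karyotype` giving chromosome lengths; when
#'   omitted the `@SQ` header of the file is used. The NM pseudo-chromosome
#'   is never binned.
#' @param min_mapq Minimum mapping quality; default 0 (no filter). Only
#'   applied to SAM/BAM inputs carrying a MAPQ column.
#' @return A `circus_segments` data frame of coverage windows
#'   (one value record per window).
#' @export
coverage_adapt <- function(sam_path, win = 10000, karyotype = NULL,
                           min_mapq = 0) {
  stopifnot(is.finite(win), win >= 1)
  rd <- read_alignments(sam_path)
  if (is.null(karyotype)) {
    if (!length(rd$sq)) {
      stop("no @SQ header in '", sam_path, "' and no karyotype supplied")
    }
    karyotype <- karyotype(id = names(rd$sq), length = unname(rd$sq))
  }
  genomic <- karyotype[karyotype$id != "NM", , drop = FALSE]
  aln <- rd$aln[is_counted(rd$aln$flag) & rd$aln$rname != "*", , drop = FALSE]
  unknown <- setdiff(unique(aln$rname), genomic$id)
  if (length(unknown)) {
    stop("alignment references chromosome absent from the karyotype: ",
         unknown[1L])
  }
  out <- lapply(seq_len(nrow(genomic)), function(i) {
    id <- genomic$id[i]
    len <- genomic$length[i]
    n_bins <- ceiling(len / win)
    starts <- (seq_len(n_bins) - 1) * win + 1
    ends <- pmin(starts + win - 1, len)
    pos <- aln$pos[aln$rname == id]
    counts <- if (length(pos)) {
      tabulate((pos - 1) %/% win + 1, nbins = n_bins)
    } else {
      integer(n_bins)
    }
    data.frame(chr = id, start = starts, end = ends, value = counts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  segment_records(out$chr, out$start, out$end, value = out$value)
}

#' Extract half-mapped pair anchors from a SAM/BAM file
#'
#' A half-mapped (or "No Match") pair is a read pair in which exactly one
#' mate aligns to the reference — the classic signature of a foreign-DNA
#' insertion at the mapped mate's locus. One anchor is produced per such
#' pair, at the leftmost mapped position and strand of the mapped mate:
#' the record must be paired, itself mapped, primary, non-supplementary,
#' and carry the mate-unmapped flag. Each pair contributes at most one
#' anchor.
#'
#' @param sam_path Path to a SAM or BAM file with paired records.
#' @return A data frame of class `nm_anchors` with columns `chr`, `pos`,
#'   `strand`, sorted by `(chr, pos)`.
#' @seealso [nm_paint()] which clusters anchors into NM links.
#' @export
nm_adapt <- function(sam_path) {
  rd <- read_alignments(sam_path)
  aln <- rd$aln
  keep <- flag_set(aln$flag, FLAG_PAIRED) &
    !flag_set(aln$flag, FLAG_UNMAPPED) &
    flag_set(aln$flag, FLAG_MATE_UNMAPPED) &
    !flag_set(aln$flag, FLAG_SECONDARY) &
    !flag_set(aln$flag, FLAG_SUPPLEMENTARY) &
    aln$rname != "*"
  hit <- aln[keep, , drop = FALSE]
  # one anchor per pair even if a malformed file repeats the mapped mate
  hit <- hit[!duplicated(hit$qname), , drop = FALSE]
  out <- data.frame(chr = hit$rname, pos = hit$pos,
                    strand = ifelse(flag_set(hit$flag, FLAG_REVERSE),
                                    "-", "+"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nm_anchors", "data.frame")
  out
}

#' Write / read NM anchors as a tab-delimited file
#'
#' Three tab-separated columns, no header: `chr pos strand`.
#'
#' @param anchors An `nm_anchors` data frame.
#' @param path File path.
#' @return `path` (write) or an `nm_anchors` data frame (read).
#' @export
write_nm_anchors <- function(anchors, path) {
  lines <- character(0)
  if (nrow(anchors)) {
    lines <- paste(anchors$chr, fmt_bp(anchors$pos), anchors$strand,
                   sep = "\t")
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_nm_anchors
#' @export
read_nm_anchors <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    out <- data.frame(chr = character(0), pos = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
    class(out) <- c("nm_anchors", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("line ", bad[1L], of_path(path), ": expected 3 columns")
  }
  out <- data.frame(chr = vapply(fields, `[`, character(1), 1L),
                    pos = as.numeric(vapply(fields, `[`, character(1), 2L)),
                    strand = vapply(fields, `[`, character(1), 3L),
                    stringsAsFactors = FALSE)
  class(out) <- c("nm_anchors", "data.frame")
  out
}
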