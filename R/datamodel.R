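# Shared domain types: karyotypes, link records, segment records, and the
# tab-delimited ".circus" intermediate format that ties the pipeline stages
# together. All coordinates are 1-based inclusive base pairs; the only
# coordinate conversion in the whole package is the 0 start written into the
# Circos karyotype file (see write_karyotype()).

#' Construct a karyotype
#'
#' A karyotype is the ordered chromosome catalogue that anchors every
#' coordinate check in the package: each entry has a short identifier,
#' a display label, a length in base pairs and a Circos color token.
#'
#' @param id Character vector of chromosome identifiers. Must be unique and
#'   contain no whitespace. The identifier `"NM"` is reserved for the
#'   "No Match" pseudo-chromosome appended with [append_nm()].
#' @param length Integer vector of chromosome lengths in base pairs
#'   (all >= 1).
#' @param label Display labels; defaults to the identifiers.
#' @param color Circos color tokens (`"r,g,b"`); defaults cycle a fixed
#'   palette.
#' @return A data frame of class `circus_karyotype` with columns
#'   `id`, `label`, `length`, `color`.
#' @seealso [create_karyotype()] to build one from a FASTA file,
#'   [append_nm()] to add the pseudo-chromosome.
#' @export
#' @examples
#' kar <- karyotype(id = "ec", length = 4641652)
karyotype <- function(id, length, label = id, color = NULL) {
  id <- as.character(id)
  if (length(id) < 1L) stop("a karyotype needs at least one chromosome")
  if (anyDuplicated(id)) {
    stop("duplicate chromosome id: ", id[duplicated(id)][1L])
  }
  if (any(grepl("[ \t]", id))) {
    stop("chromosome ids must not contain whitespace")
  }
  length <- as.numeric(length)
  if (length(length) != length(id)) stop("id and length differ in length")
  if (any(!is.finite(length) | length < 1)) {
    stop("chromosome lengths must be positive integers")
  }
  nm_at <- which(id == "NM")
  if (length(nm_at) > 1L || (length(nm_at) == 1L && nm_at != length(id))) {
    stop("the NM pseudo-chromosome must be the single last entry")
  }
  if (is.null(color)) {
    color <- rep_len(ideogram_palette(), length(id))
    if (length(nm_at) == 1L) color[nm_at] <- "150,150,150"
  }
  out <- data.frame(id = id, label = as.character(label),
                    length = length, color = as.character(color),
                    stringsAsFactors = FALSE)
  class(out) <- c("circus_karyotype", "data.frame")
  out
}

# fixed ideogram color cycle (Circos r,g,b tokens)
ideogram_palette <- function() {
  c("102,102,102", "204,102,102", "102,153,102", "102,102,204",
    "204,153,102", "153,102,153", "102,153,153", "153,153,102")
}

#' @export
print.circus_karyotype <- function(x, ...) {
  cat("karyotype:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Test whether a karyotype carries the NM pseudo-chromosome
#'
#' @param karyotype A `circus_karyotype`.
#' @return `TRUE` if the last entry is the reserved `"NM"` pseudo-chromosome.
#' @export
has_nm <- function(karyotype) {
  stopifnot(inherits(karyotype, "circus_karyotype"))
  "NM" %in% karyotype$id
}

#' Construct link records
#'
#' A link is a two-footed genomic connection: either a structural-variant
#' call joining two loci, or a cluster of half-mapped read pairs joining a
#' genomic locus to the NM pseudo-chromosome. Coordinates are 1-based
#' inclusive.
#'
#' @param chrA,chrB Chromosome identifiers of the two feet.
#' @param startA,endA,startB,endB Foot intervals in base pairs
#'   (`startA <= endA`, `startB <= endB`).
#' @param type Type label, e.g. `"TRANSLOC"`, `"INV_TRANSLOC"`,
#'   `"INS_FRAGMT"`, `"INV_INS_FRAGMT"`, `"NM"`.
#' @param support Number of supporting read pairs (>= 0).
#' @param color Optional Circos color token per record (`NA` = unpainted).
#' @return A data frame of class `circus_links`.
#' @export
link_records <- function(chrA, startA, endA, chrB, startB, endB,
                         type, support, color = NA_character_) {
  color <- rep_len(as.character(color), length(chrA))
  out <- data.frame(chrA = as.character(chrA),
                    startA = as.numeric(startA), endA = as.numeric(endA),
                    chrB = as.character(chrB),
                    startB = as.numeric(startB), endB = as.numeric(endB),
                    type = as.character(type), support = as.numeric(support),
                    color = as.character(color),
                    stringsAsFactors = FALSE)
  check_link_invariants(out)
  class(out) <- c("circus_links", "data.frame")
  out
}

check_link_invariants <- function(x) {
  bad <- which(!is.finite(x$startA) | !is.finite(x$endA) |
               !is.finite(x$startB) | !is.finite(x$endB) |
               x$startA < 1 | x$startB < 1 |
               x$startA > x$endA | x$startB > x$endB)
  if (length(bad)) {
    stop("invalid link coordinates at record ", bad[1L],
         " (need 1 <= start <= end on both feet)")
  }
  bad <- which(!is.finite(x$support) | x$support < 0)
  if (length(bad)) stop("negative or missing support at record ", bad[1L])
  invisible(x)
}

#' Construct segment records
#'
#' A segment is a single-footed interval carrying either a numeric value
#' (coverage bin count, copy number) or a strand plus label (gene
#' annotation). Exactly one of `value`/`strand` must be set per record.
#'
#' @param chr Chromosome identifiers.
#' @param start,end 1-based inclusive interval (`start <= end`).
#' @param value Numeric value (`NA` for annotation records).
#' @param strand One of `"+"`, `"-"`, `"."` (`NA` for value records).
#' @param label Annotation label; required when `strand` is set.
#' @param color Optional Circos color token.
#' @return A data frame of class `circus_segments`.
#' @export
segment_records <- function(chr, start, end, value = NA_real_,
                            strand = NA_character_, label = NA_character_,
                            color = NA_character_) {
  n <- length(chr)
  value <- rep_len(as.numeric(value), n)
  strand <- rep_len(as.character(strand), n)
  label <- rep_len(as.character(label), n)
  color <- rep_len(as.character(color), n)
  out <- data.frame(chr = as.character(chr),
                    start = as.numeric(start), end = as.numeric(end),
                    value = as.numeric(value), strand = as.character(strand),
                    label = as.character(label), color = as.character(color),
                    stringsAsFactors = FALSE)
  check_segment_invariants(out)
  class(out) <- c("circus_segments", "data.frame")
  out
}

check_segment_invariants <- function(x) {
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
               x$start < 1 | x$start > x$end)
  if (length(bad)) {
    stop("invalid segment coordinates at record ", bad[1L],
         " (need 1 <= start <= end)")
  }
  has_val <- !is.na(x$value)
  has_str <- !is.na(x$strand)
  bad <- which(has_val == has_str)
  if (length(bad)) {
    stop("record ", bad[1L], " must carry exactly one of value or strand")
  }
  bad <- which(has_str & !(x$strand %in% c("+", "-", ".")))
  if (length(bad)) {
    stop("record ", bad[1L], " has strand outside {+,-,.}")
  }
  bad <- which(has_str & is.na(x$label))
  if (length(bad)) {
    stop("annotation record ", bad[1L], " lacks a label")
  }
  invisible(x)
}

empty_links <- function() {
  link_records(character(), numeric(), numeric(), character(),
               numeric(), numeric(), character(), numeric(), character())
}

empty_segments <- function() {
  segment_records(character(), numeric(), numeric(), numeric(),
                  character(), character(), character())
}

fmt_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write link records in the ".circus" intermediate format
#'
#' The links dialect is tab-delimited, headerless, UTF-8 with LF line
#' endings: columns `chrA startA endA chrB startB endB type support`
#' plus an optional trailing `color` token per line. Serialization is
#' deterministic: the same record list always yields a byte-identical file.
#'
#' @param records A `circus_links` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circus_links <- function(records, path) {
  records <- as_links(records)
  check_link_invariants(records)
  lines <- character(0)
  if (nrow(records)) {
    base <- paste(records$chrA, fmt_bp(records$startA), fmt_bp(records$endA),
                  records$chrB, fmt_bp(records$startB), fmt_bp(records$endB),
                  records$type, fmt_bp(records$support), sep = "\t")
    has_col <- !is.na(records$color)
    base[has_col] <- paste(base[has_col], records$color[has_col], sep = "\t")
    lines <- base
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read link records from a ".circus" file
#'
#' @param path Path to a file written by [write_circus_links()].
#' @return A `circus_links` data frame, records in file order.
#' @export
read_circus_links <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(empty_links())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 8L | nf > 9L)
  if (length(bad)) {
    stop("line ", bad[1L], " of '", path, "': expected 8 or 9 columns, got ",
         nf[bad[1L]])
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  color <- vapply(fields, function(f) {
    if (length(f) >= 9L) f[9L] else NA_character_
  }, character(1))
  num <- function(x, what, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) {
      stop("line ", bad[1L], " of '", path, "': non-numeric ", what,
           " in column ", col)
    }
    v
  }
  link_records(get(1), num(get(2), "startA", 2), num(get(3), "endA", 3),
               get(4), num(get(5), "startB", 5), num(get(6), "endB", 6),
               get(7), num(get(8), "support", 8), color)
}

#' Write segment records in the ".circus" intermediate format
#'
#' The segments dialect is tab-delimited and headerless. Value records
#' (coverage, CNV) are `chr start end value [color]`; annotation records
#' are `chr start end strand label [color]`. The fourth column
#' disambiguates the two on read: a token in `{+,-,.}` marks an
#' annotation record.
#'
#' @inheritParams write_circus_links
#' @param records A `circus_segments` data frame.
#' @return `path`, invisibly.
#' @export
write_circus_segments <- function(records, path) {
  records <- as_segments(records)
  check_segment_invariants(records)
  lines <- character(0)
  if (nrow(records)) {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      f <- c(r$chr, fmt_bp(r$start), fmt_bp(r$end))
      if (!is.na(r$value)) {
        f <- c(f, fmt_bp(r$value))
      } else {
        f <- c(f, r$strand, r$label)
      }
      if (!is.na(r$color)) f <- c(f, r$color)
      paste(f, collapse = "\t")
    }, character(1))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read segment records from a ".circus" file
#'
#' @param path Path to a file written by [write_circus_segments()].
#' @return A `circus_segments` data frame, records in file order.
#' @export
read_circus_segments <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(empty_segments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  one <- function(i, f) {
    n <- length(f)
    if (n < 4L) stop("line ", i, " of '", path, "': expected >= 4 columns")
    is_annot <- f[4L] %in% c("+", "-", ".")
    if (is_annot) {
      if (n < 5L || n > 6L) {
        stop("line ", i, " of '", path,
             "': annotation record needs 5 or 6 columns, got ", n)
      }
      list(value = NA_real_, strand = f[4L], label = f[5L],
           color = if (n == 6L) f[6L] else NA_character_)
    } else {
      if (n > 5L) {
        stop("line ", i, " of '", path,
             "': value record needs 4 or 5 columns, got ", n)
      }
      v <- suppressWarnings(as.numeric(f[4L]))
      if (is.na(v)) {
        stop("line ", i, " of '", path, "': non-numeric value '", f[4L], "'")
      }
      list(value = v, strand = NA_character_, label = NA_character_,
           color = if (n == 5L) f[5L] else NA_character_)
    }
  }
  parts <- Map(one, seq_along(fields), fields)
  num <- function(x, what, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("line ", bad[1L], " of '", path, "': non-numeric ", what)
    }
    v
  }
  segment_records(
    chr = vapply(fields, `[`, character(1), 1L),
    start = num(vapply(fields, `[`, character(1), 2L), "start", 2),
    end = num(vapply(fields, `[`, character(1), 3L), "end", 3),
    value = vapply(parts, function(p) p$value, numeric(1)),
    strand = vapply(parts, function(p) p$strand, character(1)),
    label = vapply(parts, function(p) p$label, character(1)),
    color = vapply(parts, function(p) p$color, character(1)))
}

as_links <- function(x) {
  if (inherits(x, "circus_links")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_circus_links(x))
  need <- c("chrA", "startA", "endA", "chrB", "startB", "endB",
            "type", "support")
  if (is.data.frame(x) && all(need %in% names(x))) {
    if (is.null(x$color)) x$color <- NA_character_
    return(link_records(x$chrA, x$startA, x$endA, x$chrB, x$startB, x$endB,
                        x$type, x$support, x$color))
  }
  stop("cannot interpret input as link records")
}

as_segments <- function(x) {
  if (inherits(x, "circus_segments")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_circus_segments(x))
  if (is.data.frame(x) && all(c("chr", "start", "end") %in% names(x))) {
    return(segment_records(
      x$chr, x$start, x$end,
      value = if (is.null(x$value)) NA_real_ else x$value,
      strand = if (is.null(x$strand)) NA_character_ else x$strand,
      label = if (is.null(x$label)) NA_character_ else x$label,
      color = if (is.null(x$color)) NA_character_ else x$color))
  }
  stop("cannot interpret input as segment records")
}

#' Validate records against a karyotype
#'
#' Checks every record's chromosome identifiers against the karyotype and
#' every coordinate against the chromosome length (1-based inclusive, so a
#' segment ending exactly at the chromosome length is valid). The check is
#' report-based: it never throws on invalid records.
#'
#' @param records A `circus_links` or `circus_segments` data frame.
#' @param karyotype A `circus_karyotype`.
#' @return A data frame with one row per violation (columns `record`,
#'   `chr`, `problem`); zero rows means every record is valid.
#' @export
validate_records <- function(records, karyotype) {
  stopifnot(inherits(karyotype, "circus_karyotype"))
  len <- stats::setNames(karyotype$length, karyotype$id)
  out <- list()
  add <- function(record, chr, problem) {
    out[[length(out) + 1L]] <<- data.frame(
      record = record, chr = chr, problem = problem,
      stringsAsFactors = FALSE)
  }
  check_foot <- function(i, chr, start, end) {
    if (!(chr %in% names(len))) {
      add(i, chr, "unknown chromosome")
    } else if (end > len[[chr]]) {
      add(i, chr, sprintf("end %s exceeds chromosome length %s",
                          fmt_bp(end), fmt_bp(len[[chr]])))
    }
  }
  if (all(c("chrA", "chrB") %in% names(records))) {
    for (i in seq_len(nrow(records))) {
      check_foot(i, records$chrA[i], records$startA[i], records$endA[i])
      check_foot(i, records$chrB[i], records$startB[i], records$endB[i])
    }
  } else {
    for (i in seq_len(nrow(records))) {
      check_foot(i, records$chr[i], records$start[i], records$end[i])
    }
  }
  if (!length(out)) {
    return(data.frame(record = integer(0), chr = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
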