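# Adapters for third-party caller output dialects. Every adapter is
# line-local: one output record per data line, lines starting with "#"
# skipped, coordinates copied verbatim (adapters never invent positions).

data_lines <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(lines = lines[keep], lineno = which(keep))
}

parse_num <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop("line ", lineno[bad[1L]], of_path(path), ": non-numeric ", what,
         " '", x[bad[1L]], "'")
  }
  v
}

#' Column map for tabular adapters
#'
#' Selects the 1-based column positions holding, in order: chromosome,
#' start, end, strand and label.
#'
#' @param chr,start,end,strand,label 1-based column indices, pairwise
#'   distinct.
#' @return An integer vector of class `column_map`.
#' @export
column_map <- function(chr, start, end, strand, label) {
  idx <- as.integer(c(chr = chr, start = start, end = end,
                      strand = strand, label = label))
  if (any(is.na(idx) | idx < 1L)) stop("column indices must be >= 1")
  if (anyDuplicated(idx)) stop("column indices must be pairwise distinct")
  names(idx) <- c("chr", "start", "end", "strand", "label")
  class(idx) <- "column_map"
  idx
}

#' Adapt SVDetect filtered links
#'
#' Reads the tab-delimited `.links.filtered` dialect into link records.
#' The default column layout is
#' `chrA startA endA chrB startB endB sv_type nb_pairs`; because field
#' order differs across SVDetect versions, `columns` can remap it. Type
#' labels (e.g. `INS_FRAGMT`, `INV_INS_FRAGMT`, `TRANSLOC`,
#' `INV_TRANSLOC`) pass through verbatim for later palette mapping.
#'
#' @param path Path to the links file.
#' @param columns Optional integer vector of eight 1-based column indices
#'   in the order chrA, startA, endA, chrB, startB, endB, type, support.
#' @return A `circus_links` data frame, one record per data line.
#' @export
svd_links_adapt <- function(path, columns = 1:8) {
  stopifnot(length(columns) == 8L, !anyDuplicated(columns))
  dl <- data_lines(path)
  if (!length(dl$lines)) return(empty_links())
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < max(columns))
  if (length(short)) {
    stop("line ", dl$lineno[short[1L]], of_path(path),
         ": fewer columns than the layout requires")
  }
  get <- function(i) vapply(fields, `[`, character(1), columns[i])
  link_records(get(1),
               parse_num(get(2), dl$lineno, path, "startA"),
               parse_num(get(3), dl$lineno, path, "endA"),
               get(4),
               parse_num(get(5), dl$lineno, path, "startB"),
               parse_num(get(6), dl$lineno, path, "endB"),
               get(7),
               parse_num(get(8), dl$lineno, path, "support"))
}

#' Adapt Pindel text output
#'
#' Parses Pindel record header lines (index, SV class, `ChrID`, the two
#' breakpoint positions after `BP`, and the supporting-read count after
#' `Supports`) into intra-chromosomal link records joining the two
#' breakpoints; each foot is the two-base interval starting at its
#' breakpoint. SV classes map to type labels D -> DEL, TD -> DUP,
#' INV -> INV; separator and per-read evidence lines are ignored.
#'
#' @param path Path to a Pindel text-output file.
#' @return A `circus_links` data frame.
#' @export
pindel_adapt <- function(path) {
  lines <- readLines(path)
  is_rec <- grepl("^[0-9]+\t(D|TD|INV)[ \t]", lines)
  if (!any(is_rec)) return(empty_links())
  recs <- lines[is_rec]
  lineno <- which(is_rec)
  grab <- function(pattern, what) {
    hit <- regmatches(recs, regexec(pattern, recs))
    bad <- which(lengths(hit) < 2L)
    if (length(bad)) {
      stop("line ", lineno[bad[1L]], of_path(path),
           ": malformed Pindel record header (missing ", what, ")")
    }
    vapply(hit, `[`, character(1), 2L)
  }
  class_raw <- sub("^[0-9]+\t(D|TD|INV)[ \t].*", "\\1", recs)
  chr <- grab("ChrID[ \t]+([^ \t]+)", "ChrID")
  bp1 <- parse_num(grab("\tBP[ \t]+([0-9]+)", "BP"), lineno, path, "BP start")
  bp2 <- parse_num(grab("\tBP[ \t]+[0-9]+[ \t]+([0-9]+)", "BP"),
                   lineno, path, "BP end")
  supp <- parse_num(grab("Supports[ \t]+([0-9]+)", "Supports"),
                    lineno, path, "Supports")
  type <- c(D = "DEL", TD = "DUP", INV = "INV")[class_raw]
  link_records(chr, bp1, bp1 + 1, chr, bp2, bp2 + 1, unname(type), supp)
}

#' Adapt Control-FREEC CNV segments
#'
#' Reads the tab-delimited `_CNVs` dialect (chromosome, start, end,
#' predicted copy number, optional status) into value segment records,
#' value = copy number.
#'
#' @param path Path to a `_CNVs` file.
#' @return A `circus_segments` data frame.
#' @export
freec_cnv_adapt <- function(path) {
  dl <- data_lines(path)
  if (!length(dl$lines)) return(empty_segments())
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 4L)
  if (length(short)) {
    stop("line ", dl$lineno[short[1L]], of_path(path),
         ": expected at least 4 columns")
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  segment_records(get(1),
                  parse_num(get(2), dl$lineno, path, "start"),
                  parse_num(get(3), dl$lineno, path, "end"),
                  value = parse_num(get(4), dl$lineno, path, "copy number"))
}

#' Adapt a tab-delimited annotation file
#'
#' Converts a GTF-like tab-delimited annotation table into strand-labelled
#' segment records using a user-supplied [column_map()]. Strand tokens
#' other than `"+"` or `"-"` are normalized to `"."`.
#'
#' @param path Path to the annotation file.
#' @param columns A [column_map()] naming the chromosome, start, end,
#'   strand and label columns.
#' @return A `circus_segments` data frame of annotation records.
#' @export
tab_annot_adapt <- function(path, columns) {
  stopifnot(inherits(columns, "column_map"))
  dl <- data_lines(path)
  if (!length(dl$lines)) return(empty_segments())
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < max(columns))
  if (length(short)) {
    stop("line ", dl$lineno[short[1L]], of_path(path),
         ": column index ", max(columns), " beyond the ",
         lengths(fields)[short[1L]], " columns present")
  }
  get <- function(nm) vapply(fields, `[`, character(1), columns[[nm]])
  strand <- get("strand")
  strand[!(strand %in% c("+", "-"))] <- "."
  segment_records(get("chr"),
                  parse_num(get("start"), dl$lineno, path, "start"),
                  parse_num(get("end"), dl$lineno, path, "end"),
                  strand = strand, label = get("label"))
}
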