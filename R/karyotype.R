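# Karyotype construction from a reference FASTA and emission in Circos
# karyotype syntax. Internal coordinates are 1-based; the Circos file
# writes start 0 per Circos convention — the single coordinate conversion
# in the package.

#' Build a karyotype from a reference FASTA
#'
#' Creates one chromosome entry per FASTA record, in file order. The
#' identifier is the first whitespace-delimited token of the header, the
#' label defaults to the identifier, and the length is the number of
#' sequence characters (lowercase and ambiguity codes included: length is
#' physical). When `out_path` is given, the karyotype is also written in
#' Circos syntax via [write_karyotype()].
#'
#' @param fasta_path Path to a readable FASTA file with at least one record.
#' @param out_path Optional path for the Circos karyotype file.
#' @param labels Optional named character vector mapping chromosome ids to
#'   display labels.
#' @return A `circus_karyotype`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">ec test genome", "ACGTACGT"), fa)
#' create_karyotype(fa)
create_karyotype <- function(fasta_path, out_path = NULL, labels = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome id in FASTA: ", ids[duplicated(ids)][1L])
  }
  lens <- Biostrings::width(seqs)
  if (any(lens == 0L)) {
    stop("zero-length FASTA record: ", ids[which(lens == 0L)[1L]])
  }
  lab <- ids
  if (!is.null(labels)) {
    hit <- ids %in% names(labels)
    lab[hit] <- unname(labels[ids[hit]])
  }
  kar <- karyotype(id = ids, length = lens, label = lab)
  if (!is.null(out_path)) write_karyotype(kar, out_path)
  kar
}

#' Append the NM pseudo-chromosome
#'
#' The "No Match" pseudo-chromosome is an artificial arc that anchors the
#' second foot of links whose unmapped mate maps nowhere on the reference —
#' the signature of a foreign-sequence insertion. It is always the last
#' karyotype entry and its id is `"NM"`. Its length only needs to provide
#' enough arc for link feet; the default is 2 percent of the genome.
#'
#' @param karyotype A `circus_karyotype` without an NM entry.
#' @param nm_length Pseudo-chromosome length in pseudo-coordinate units;
#'   defaults to 2 percent of the total genome length (at least 1000).
#' @return The karyotype with the NM entry appended.
#' @export
append_nm <- function(karyotype,
                      nm_length = max(1000, round(0.02 * sum(karyotype$length)))) {
  stopifnot(inherits(karyotype, "circus_karyotype"))
  if (has_nm(karyotype)) stop("karyotype already has an NM pseudo-chromosome")
  if (!is.finite(nm_length) || nm_length < 1) {
    stop("nm_length must be a positive integer")
  }
  karyotype(id = c(karyotype$id, "NM"),
            length = c(karyotype$length, nm_length),
            label = c(karyotype$label, "NM"),
            color = c(karyotype$color, "150,150,150"))
}

#' Write a karyotype in Circos syntax
#'
#' Emits one line per chromosome:
#' `chr - <id> <label> 0 <length> <color>`. The 0 start is the Circos
#' convention; everywhere else in the package coordinates stay 1-based.
#'
#' @param karyotype A `circus_karyotype`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(karyotype, path) {
  stopifnot(inherits(karyotype, "circus_karyotype"))
  lines <- paste("chr", "-", karyotype$id, karyotype$label, "0",
                 fmt_bp(karyotype$length), karyotype$color)
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a karyotype file in Circos syntax
#'
#' @param path Path to a file written by [write_karyotype()].
#' @return A `circus_karyotype`.
#' @export
read_karyotype <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 7L |
               vapply(fields, `[`, character(1), 1L) != "chr")
  if (length(bad)) {
    stop("line ", bad[1L], " of '", path,
         "' is not a 7-field Circos karyotype line")
  }
  karyotype(id = vapply(fields, `[`, character(1), 3L),
            label = vapply(fields, `[`, character(1), 4L),
            length = as.numeric(vapply(fields, `[`, character(1), 6L)),
            color = vapply(fields, `[`, character(1), 7L))
}
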