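# The core composer: filters links by views, allocates the circular
# layout, and emits the complete, self-consistent Circos file set (main
# configuration, ideogram and ticks includes, karyotype, data files, run
# log). The three rings sit at fixed radial bands — annotations outermost
# (0.90-0.98r), coverage histogram in the middle (0.80-0.88r), CNV heatmap
# innermost (0.70-0.78r) — with links filling the center below 0.70r.

RADIAL_BANDS <- list(annot = c(0.90, 0.98), coverage = c(0.80, 0.88),
                     cnv = c(0.70, 0.78), links = 0.70)

#' Build a plot configuration
#'
#' Collects everything the composer needs besides the data: the
#' chromosome of interest, one or two views on it, the view magnification,
#' whether the outer annotation ring spans the whole circle or only the
#' views, and the image request passed through to Circos.
#'
#' @param chr Identifier of the chromosome of interest.
#' @param view1 A [view_spec()], or a numeric `c(start, end)` on `chr`
#'   (`NA` end = chromosome end). Default: the whole chromosome.
#' @param view2 Optional second view, same forms; must be on the same
#'   chromosome as `view1` and not overlap it.
#' @param ext_fraction Linear magnification applied to views when
#'   apportioning circumference (default 10).
#' @param flag_view_outer When `TRUE` (default) the outer annotation ring
#'   is drawn over the whole circle; when `FALSE` only over the view
#'   segments.
#' @param image_format `"png"` or `"svg"`.
#' @param image_name Basename of the image Circos will render.
#' @param out_dir Output directory for the emitted file set.
#' @return A list of class `plot_config`.
#' @export
plot_config <- function(chr, view1 = c(1, NA), view2 = NULL,
                        ext_fraction = 10, flag_view_outer = TRUE,
                        image_format = c("png", "svg"),
                        image_name = "circos_image", out_dir = "circos_out") {
  image_format <- match.arg(image_format)
  as_view <- function(v) {
    if (is.null(v)) return(NULL)
    if (inherits(v, "view_spec")) {
      if (v$chr != chr) stop("views must lie on the chromosome of interest")
      return(v)
    }
    stopifnot(is.numeric(v), length(v) == 2L)
    view_spec(chr, v[1L], v[2L])
  }
  stopifnot(is.finite(ext_fraction), ext_fraction > 0)
  out <- list(chr = as.character(chr), view1 = as_view(view1),
              view2 = as_view(view2), ext_fraction = ext_fraction,
              flag_view_outer = isTRUE(flag_view_outer),
              image_format = image_format,
              image_name = as.character(image_name),
              out_dir = as.character(out_dir))
  class(out) <- "plot_config"
  out
}

#' Restrict the outer annotation ring to the views
#'
#' Implements the `flag_view_outer` switch: when `FALSE`, annotation
#' records are clipped to the view intervals (records outside every view
#' are dropped, overlapping records are trimmed to the view bounds) so the
#' outermost ring is only drawn over the magnified part of the circle.
#' When `TRUE`, or when there is no annotation track, the records pass
#' through unchanged.
#'
#' @param annot A `circus_segments` data frame of annotation records, or
#'   `NULL`.
#' @param views List of resolved [view_spec()]s.
#' @param flag_view_outer Logical switch (default `TRUE`).
#' @return The (possibly restricted) annotation records.
#' @export
flag_view_outer_apply <- function(annot, views, flag_view_outer = TRUE) {
  if (is.null(annot) || isTRUE(flag_view_outer) || !length(views)) {
    return(annot)
  }
  annot <- as_segments(annot)
  pieces <- lapply(views, function(v) {
    keep <- overlaps(annot$chr, annot$start, annot$end, v)
    p <- annot[keep, , drop = FALSE]
    p$start <- pmax(p$start, v$start)
    p$end <- pmin(p$end, v$end)
    p
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chr, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("circus_segments", "data.frame")
  out
}

token_opt <- function(color, fallback) {
  ifelse(is.na(color), fallback, color)
}

write_circos_link_data <- function(links, path) {
  lines <- character(0)
  if (nrow(links)) {
    lines <- paste(links$chrA, fmt_bp(links$startA), fmt_bp(links$endA),
                   links$chrB, fmt_bp(links$startB), fmt_bp(links$endB),
                   paste0("color=", token_opt(links$color, "0,0,0")))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_circos_value_data <- function(segments, path, with_color = FALSE) {
  lines <- character(0)
  if (nrow(segments)) {
    lines <- paste(segments$chr, fmt_bp(segments$start),
                   fmt_bp(segments$end), fmt_bp(segments$value))
    if (with_color) {
      lines <- paste(lines,
                     paste0("fill_color=",
                            token_opt(segments$color, "0,0,0")))
    }
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_circos_highlight_data <- function(segments, path) {
  lines <- character(0)
  if (nrow(segments)) {
    lines <- paste(segments$chr, fmt_bp(segments$start),
                   fmt_bp(segments$end),
                   paste0("fill_color=",
                          token_opt(segments$color,
                                    CIRCUS_COLORS[["grey"]])))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

ideogram_conf_lines <- function() {
  c("<ideogram>",
    "<spacing>",
    "default = 0.002r",
    "</spacing>",
    "radius = 0.90r",
    "thickness = 40p",
    "fill = yes",
    "stroke_color = dgrey",
    "stroke_thickness = 2p",
    "show_label = yes",
    "label_font = default",
    "label_radius = 1r + 75p",
    "label_size = 40",
    "label_parallel = yes",
    "</ideogram>")
}

ticks_conf_lines <- function() {
  c("show_ticks = yes",
    "show_tick_labels = yes",
    "<ticks>",
    "radius = 1r",
    "color = black",
    "thickness = 2p",
    "multiplier = 1e-6",
    "format = %.2f",
    "<tick>",
    "spacing = 100000u",
    "size = 10p",
    "</tick>",
    "<tick>",
    "spacing = 500000u",
    "size = 15p",
    "show_label = yes",
    "label_size = 20p",
    "label_offset = 10p",
    "</tick>",
    "</ticks>")
}

#' Compose the full Circos file set
#'
#' The package core. Validates every supplied track against the
#' karyotype, filters the link tracks down to links with at least one
#' foot in the view(s), applies the `flag_view_outer` restriction to the
#' annotation ring, allocates the circular layout, and writes a
#' self-consistent Circos file set into `config$out_dir`: `circos.conf`
#' (with image, zoom, plot and link blocks), `ideogram.conf`,
#' `ticks.conf`, `karyotype.txt`, one data file per enabled track, and —
#' last, after the internal cross-reference check has passed — the run
#' log. Emission is deterministic: identical inputs give a byte-identical
#' file set apart from the log timestamp.
#'
#' @param config A [plot_config()].
#' @param karyotype A `circus_karyotype` (must carry NM when `nm` links
#'   are supplied).
#' @param links Painted intra-genomic `circus_links` (data frame or
#'   ".circus" path), or `NULL`.
#' @param nm Painted NM `circus_links` (from [nm_paint()]), or `NULL`.
#' @param coverage Coverage `circus_segments` (from [coverage_adapt()]),
#'   or `NULL`.
#' @param cnv Painted CNV `circus_segments` (from [cnv_paint()]), or
#'   `NULL`.
#' @param annot Painted annotation `circus_segments` (from
#'   [annot_paint()]), or `NULL`.
#' @return The output directory path, invisibly.
#' @export
chromosome_image <- function(config, karyotype, links = NULL, nm = NULL,
                             coverage = NULL, cnv = NULL, annot = NULL) {
  stopifnot(inherits(config, "plot_config"),
            inherits(karyotype, "circus_karyotype"))
  if (!(config$chr %in% karyotype$id)) {
    stop("chromosome of interest not in karyotype: ", config$chr)
  }
  view1 <- resolve_view(config$view1, karyotype)
  view2 <- if (is.null(config$view2)) NULL else {
    resolve_view(config$view2, karyotype)
  }
  views <- c(list(view1), if (is.null(view2)) NULL else list(view2))

  tracks <- list(links = if (is.null(links)) NULL else as_links(links),
                 nm = if (is.null(nm)) NULL else as_links(nm),
                 coverage = if (is.null(coverage)) NULL else
                   as_segments(coverage),
                 cnv = if (is.null(cnv)) NULL else as_segments(cnv),
                 annot = if (is.null(annot)) NULL else as_segments(annot))
  if (!is.null(tracks$nm) && !has_nm(karyotype)) {
    stop("NM links supplied but karyotype lacks the NM pseudo-chromosome")
  }
  for (nmn in names(tracks)) {
    tr <- tracks[[nmn]]
    if (is.null(tr)) next
    bad <- validate_records(tr, karyotype)
    if (nrow(bad)) {
      stop(nmn, " track record ", bad$record[1L], ": ", bad$problem[1L],
           " (", bad$chr[1L], ")")
    }
  }

  in_counts <- vapply(tracks[!vapply(tracks, is.null, logical(1))],
                      nrow, integer(1))

  # only links with at least one foot in the view(s) are displayed
  if (!is.null(tracks$links)) {
    tracks$links <- filter_links_by_views(tracks$links, view1, view2)
  }
  if (!is.null(tracks$nm)) {
    tracks$nm <- filter_links_by_views(tracks$nm, view1, view2)
  }
  tracks$annot <- flag_view_outer_apply(tracks$annot, views,
                                        config$flag_view_outer)

  layout <- allocate_layout(karyotype, views,
                            ext_fraction = config$ext_fraction)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_karyotype(karyotype, p("karyotype.txt"))
  writeLines(ideogram_conf_lines(), p("ideogram.conf"), useBytes = TRUE)
  writeLines(ticks_conf_lines(), p("ticks.conf"), useBytes = TRUE)

  data_files <- character(0)
  if (!is.null(tracks$links)) {
    write_circos_link_data(tracks$links, p("links.txt"))
    data_files["links"] <- "links.txt"
  }
  if (!is.null(tracks$nm)) {
    write_circos_link_data(tracks$nm, p("nm_links.txt"))
    data_files["nm"] <- "nm_links.txt"
  }
  if (!is.null(tracks$coverage)) {
    write_circos_value_data(tracks$coverage, p("coverage.txt"))
    data_files["coverage"] <- "coverage.txt"
  }
  if (!is.null(tracks$cnv)) {
    write_circos_value_data(tracks$cnv, p("cnv.txt"), with_color = TRUE)
    data_files["cnv"] <- "cnv.txt"
  }
  if (!is.null(tracks$annot)) {
    write_circos_highlight_data(tracks$annot, p("annot.txt"))
    data_files["annot"] <- "annot.txt"
  }

  writeLines(main_conf_lines(config, karyotype, views, data_files),
             p("circos.conf"), useBytes = TRUE)

  # internal cross-reference check is the last emission step before the log
  bad <- check_output(config$out_dir)
  if (nrow(bad)) {
    stop("emitted file set fails cross-reference validation: ",
         bad$problem[1L], " in ", bad$file[1L])
  }

  log <- run_log("chromosome_image",
                 arguments = list(chr = config$chr,
                                  view1 = view_label(view1),
                                  view2 = if (is.null(view2)) "none" else
                                    view_label(view2),
                                  ext_fraction = config$ext_fraction,
                                  flag_view_outer = config$flag_view_outer,
                                  image_format = config$image_format,
                                  image_name = config$image_name,
                                  out_dir = config$out_dir),
                 input_files = as.list(in_counts))
  write_log(log, p("run.log"))
  invisible(config$out_dir)
}

view_label <- function(v) {
  paste0(v$chr, ":", fmt_bp(v$start), "-", fmt_bp(v$end),
         if (v$reversed) " (reversed)" else "")
}

main_conf_lines <- function(config, karyotype, views, data_files) {
  lines <- c("# circos.conf generated by circosviz",
             "karyotype = karyotype.txt",
             "chromosomes_units = 1000",
             "chromosomes_display_default = yes",
             "")
  if (length(views)) {
    lines <- c(lines, "<zooms>")
    for (v in views) {
      lines <- c(lines, "<zoom>",
                 paste0("chr = ", v$chr),
                 paste0("start = ", fmt_bp(v$start), "u"),
                 paste0("end = ", fmt_bp(v$end), "u"),
                 paste0("scale = ", fmt_bp(config$ext_fraction)),
                 "</zoom>")
    }
    lines <- c(lines, "</zooms>", "")
  }
  link_files <- data_files[names(data_files) %in% c("links", "nm")]
  if (length(link_files)) {
    lines <- c(lines, "<links>")
    for (f in link_files) {
      lines <- c(lines, "<link>",
                 paste0("file = ", f),
                 paste0("radius = ", fmt_bp(RADIAL_BANDS$links), "r"),
                 "bezier_radius = 0r",
                 "thickness = 2",
                 "</link>")
    }
    lines <- c(lines, "</links>", "")
  }
  plot_files <- data_files[names(data_files) %in%
                             c("annot", "coverage", "cnv")]
  if (length(plot_files)) {
    lines <- c(lines, "<plots>")
    if ("annot" %in% names(plot_files)) {
      b <- RADIAL_BANDS$annot
      lines <- c(lines, "<plot>",
                 "type = highlight",
                 paste0("file = ", plot_files[["annot"]]),
                 paste0("r0 = ", b[1L], "r"),
                 paste0("r1 = ", b[2L], "r"),
                 "</plot>")
    }
    if ("coverage" %in% names(plot_files)) {
      b <- RADIAL_BANDS$coverage
      lines <- c(lines, "<plot>",
                 "type = histogram",
                 paste0("file = ", plot_files[["coverage"]]),
                 paste0("r0 = ", b[1L], "r"),
                 paste0("r1 = ", b[2L], "r"),
                 "fill_color = dgrey",
                 "color = dgrey",
                 "extend_bin = no",
                 "</plot>")
    }
    if ("cnv" %in% names(plot_files)) {
      b <- RADIAL_BANDS$cnv
      lines <- c(lines, "<plot>",
                 "type = heatmap",
                 paste0("file = ", plot_files[["cnv"]]),
                 paste0("r0 = ", b[1L], "r"),
                 paste0("r1 = ", b[2L], "r"),
                 "</plot>")
    }
    lines <- c(lines, "</plots>", "")
  }
  c(lines,
    "<image>",
    "dir = .",
    paste0("file = ", config$image_name, ".", config$image_format),
    if (config$image_format == "svg") "svg = yes" else "png = yes",
    "radius = 1500p",
    "angle_offset = -90",
    "background = white",
    "</image>",
    "",
    "<<include ideogram.conf>>",
    "<<include ticks.conf>>")
}

#' Cross-reference validator for an emitted file set
#'
#' Reads the emitted karyotype and every data file back from `dir` and
#' checks that each referenced chromosome exists in the karyotype and
#' each coordinate lies within the chromosome length. Run automatically
#' as the last emission step of [chromosome_image()].
#'
#' @param dir Directory written by [chromosome_image()].
#' @return A data frame with one row per violation (columns `file`,
#'   `line`, `problem`); zero rows means the file set is self-consistent.
#' @export
check_output <- function(dir) {
  kar_path <- file.path(dir, "karyotype.txt")
  if (!file.exists(kar_path)) stop("no karyotype.txt in ", dir)
  kar <- read_karyotype(kar_path)
  len <- stats::setNames(kar$length, kar$id)
  out <- list()
  add <- function(file, line, problem) {
    out[[length(out) + 1L]] <<- data.frame(
      file = file, line = line, problem = problem, stringsAsFactors = FALSE)
  }
  check_interval <- function(file, line, chr, start, end) {
    if (!(chr %in% names(len))) {
      add(file, line, paste0("unknown chromosome '", chr, "'"))
    } else if (is.na(start) || is.na(end) || start < 1 || end < start ||
               end > len[[chr]]) {
      add(file, line, paste0("coordinates ", start, "-", end,
                             " invalid on '", chr, "'"))
    }
  }
  scan_file <- function(file, feet) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(invisible())
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "[ \t]+")[[1L]]
      if (feet == 2L) {
        check_interval(file, i, f[1L], as.numeric(f[2L]), as.numeric(f[3L]))
        check_interval(file, i, f[4L], as.numeric(f[5L]), as.numeric(f[6L]))
      } else {
        check_interval(file, i, f[1L], as.numeric(f[2L]), as.numeric(f[3L]))
      }
    }
  }
  scan_file("links.txt", 2L)
  scan_file("nm_links.txt", 2L)
  scan_file("coverage.txt", 1L)
  scan_file("cnv.txt", 1L)
  scan_file("annot.txt", 1L)
  if (!length(out)) {
    return(data.frame(file = character(0), line = integer(0),
                      problem = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
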