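# Views and circular layout. The circle splits into two parts: one or two
# magnified views of the chromosome of interest, then the whole-genome
# part (every chromosome full length, NM last). Sweeps are apportioned by
# displayed length — physical length times ext_fraction for views — over
# the gap-reduced 360 degrees.

#' Specify a zoomed view
#'
#' A view is a sub-region of the chromosome of interest that occupies its
#' own, magnified arc of the circle. An `NA` end means "to the chromosome
#' end" and is resolved against the karyotype at layout time.
#'
#' @param chr Chromosome identifier.
#' @param start 1-based start position (>= 1).
#' @param end End position, or `NA` for the chromosome end.
#' @param reversed Draw the view in reversed orientation?
#' @return A list of class `view_spec`.
#' @export
#' @examples
#' view_spec("ec", 930000, 1002000)
#' view_spec("ec", 1, NA)  # the whole chromosome
view_spec <- function(chr, start, end = NA, reversed = FALSE) {
  stopifnot(is.finite(start), start >= 1)
  if (!is.na(end) && end < start) stop("view end precedes start")
  out <- list(chr = as.character(chr), start = as.numeric(start),
              end = as.numeric(end), reversed = isTRUE(reversed))
  class(out) <- "view_spec"
  out
}

resolve_view <- function(view, karyotype) {
  stopifnot(inherits(view, "view_spec"))
  hit <- match(view$chr, karyotype$id)
  if (is.na(hit)) stop("view chromosome not in karyotype: ", view$chr)
  len <- karyotype$length[hit]
  if (is.na(view$end)) view$end <- len
  if (view$end > len) {
    stop("view end ", fmt_bp(view$end), " beyond chromosome ", view$chr,
         " length ", fmt_bp(len))
  }
  view
}

overlaps <- function(chr, start, end, view) {
  chr == view$chr & start <= view$end & end >= view$start
}

#' Filter links by views
#'
#' A link is retained if and only if at least one foot overlaps (1-based
#' inclusive interval intersection) one of the views; only retained links
#' are displayed. A link overlapping through both feet or both views is
#' kept once. Feet on the NM pseudo-chromosome never match a genomic
#' view, but NM links are retained through their genomic foot.
#'
#' @param links A `circus_links` data frame.
#' @param view1 A [view_spec()] (must be resolved, or supply `karyotype`).
#' @param view2 Optional second [view_spec()].
#' @param karyotype Optional `circus_karyotype` used to resolve open view
#'   ends.
#' @return The retained links, in input order.
#' @export
filter_links_by_views <- function(links, view1, view2 = NULL,
                                  karyotype = NULL) {
  links <- as_links(links)
  if (!is.null(karyotype)) {
    view1 <- resolve_view(view1, karyotype)
    if (!is.null(view2)) view2 <- resolve_view(view2, karyotype)
  }
  if (is.na(view1$end)) stop("view1 has an unresolved end; pass a karyotype")
  views <- list(view1)
  if (!is.null(view2)) {
    if (is.na(view2$end)) stop("view2 has an unresolved end")
    views <- c(views, list(view2))
  }
  keep <- rep(FALSE, nrow(links))
  for (v in views) {
    keep <- keep |
      (links$chrA != "NM" &
         overlaps(links$chrA, links$startA, links$endA, v)) |
      (links$chrB != "NM" &
         overlaps(links$chrB, links$startB, links$endB, v))
  }
  out <- links[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allocate the circular layout
#'
#' Splits the circle into ordered segments: the view(s) first, then every
#' chromosome of the karyotype full length (NM last, when present). Each
#' segment's displayed length is its physical length multiplied by
#' `ext_fraction` for views and by 1 otherwise; angular sweeps are
#' proportional to displayed length over the circle minus one
#' `gap_degrees` gap at every segment boundary. Sweeps plus gaps always
#' sum to exactly 360 degrees.
#'
#' @param karyotype A `circus_karyotype`.
#' @param views List of resolved or resolvable [view_spec()]s (0, 1 or 2),
#'   all on one chromosome and non-overlapping.
#' @param ext_fraction Linear magnification applied to views (default 10).
#' @param gap_degrees Gap at each segment boundary in degrees (default 1).
#' @return A data frame of class `circus_layout` with one row per segment:
#'   `source`, `start`, `end`, `displayed_length`, `sweep`, `role`
#'   (`view`, `whole` or `nm`), `reversed`, and the cumulative
#'   `angle_start`/`angle_end` in degrees.
#' @export
allocate_layout <- function(karyotype, views = list(), ext_fraction = 10,
                            gap_degrees = 1) {
  stopifnot(inherits(karyotype, "circus_karyotype"),
            is.finite(ext_fraction), ext_fraction > 0, gap_degrees >= 0)
  if (inherits(views, "view_spec")) views <- list(views)
  if (length(views) > 2L) stop("at most two views are supported")
  views <- lapply(views, resolve_view, karyotype = karyotype)
  if (length(views) == 2L) {
    if (views[[1L]]$chr != views[[2L]]$chr) {
      stop("both views must lie on the same chromosome")
    }
    if (views[[1L]]$start <= views[[2L]]$end &&
        views[[2L]]$start <= views[[1L]]$end) {
      stop("views overlap each other")
    }
  }
  seg <- data.frame(
    source = c(vapply(views, function(v) v$chr, character(1)),
               karyotype$id),
    start = c(vapply(views, function(v) v$start, numeric(1)),
              rep(1, nrow(karyotype))),
    end = c(vapply(views, function(v) v$end, numeric(1)),
            karyotype$length),
    role = c(rep("view", length(views)),
             ifelse(karyotype$id == "NM", "nm", "whole")),
    reversed = c(vapply(views, function(v) v$reversed, logical(1)),
                 rep(FALSE, nrow(karyotype))),
    stringsAsFactors = FALSE)
  seg$displayed_length <- (seg$end - seg$start + 1) *
    ifelse(seg$role == "view", ext_fraction, 1)
  n <- nrow(seg)
  total_gap <- n * gap_degrees   # one gap per boundary around the circle
  avail <- 360 - total_gap
  if (avail <= 0) stop("gaps consume the whole circle")
  seg$sweep <- seg$displayed_length / sum(seg$displayed_length) * avail
  bound <- cumsum(c(0, (seg$sweep + gap_degrees)[-n]))
  seg$angle_start <- bound
  seg$angle_end <- bound + seg$sweep
  class(seg) <- c("circus_layout", "data.frame")
  seg
}

#' Map a genomic position to its display angle
#'
#' Linear interpolation within the sweep of the first layout segment that
#' displays the position (views take precedence over the whole-genome
#' copy of the same chromosome). Reversed segments interpolate from their
#' far end.
#'
#' @param layout A `circus_layout` from [allocate_layout()].
#' @param chr Chromosome identifier.
#' @param pos 1-based position.
#' @return The angle in degrees (0 at the first segment's start, growing
#'   clockwise).
#' @export
pos_to_angle <- function(layout, chr, pos) {
  stopifnot(inherits(layout, "circus_layout"), length(chr) == 1L,
            length(pos) == 1L)
  hit <- which(layout$source == chr & layout$start <= pos &
                 layout$end >= pos)
  if (!length(hit)) {
    stop("position ", chr, ":", fmt_bp(pos),
         " is displayed in no layout segment")
  }
  s <- layout[hit[1L], ]
  span <- s$end - s$start
  frac <- if (span == 0) 0 else (pos - s$start) / span
  if (s$reversed) frac <- 1 - frac
  s$angle_start + frac * s$sweep
}
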