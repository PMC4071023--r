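# Color assignment. Links get a hue family per SV type with darkness
# increasing in supporting read count ("darker = more significant"); CNV
# segments get fixed status colors; annotations get strand colors; NM
# anchors are clustered, thresholded, and painted in the reserved red
# family. All colors are emitted as Circos "r,g,b" tokens from the single
# palette table below.

# named colors used verbatim in emitted files
CIRCUS_COLORS <- c(
  light_blue   = "173,216,230",
  orange       = "255,165,0",
  red          = "255,0,0",
  light_yellow = "255,255,224",
  grey         = "128,128,128",
  dark_green   = "0,100,0"
)

# light -> dark ramp endpoints per hue; index 1 (red) is reserved for NM
HUE_ENDPOINTS <- list(
  red    = c("#FFC4C4", "#8B0000"),
  green  = c("#C8EBC8", "#0B5A0B"),
  blue   = c("#C6D8FF", "#00008B"),
  pink   = c("#FFD6EB", "#C71585"),
  orange = c("#FFE0B8", "#B35900"),
  purple = c("#E0CCF5", "#4B0082"),
  brown  = c("#E8D2BE", "#5C3317"),
  teal   = c("#C4ECEC", "#005F5F")
)

hex_to_token <- function(hex) {
  m <- grDevices::col2rgb(hex)
  paste(m[1, ], m[2, ], m[3, ], sep = ",")
}

#' Color palette for link painting
#'
#' The palette maps palette indices to hue families (1 red, 2 green,
#' 3 blue, 4 pink, then a fixed cycle of orange, purple, brown, teal),
#' each family holding `shades_per_hue` shades ordered light to dark.
#' Index 1 (red) is reserved for NM links.
#'
#' @param shades_per_hue Number of discrete shades per hue (>= 2,
#'   default 5).
#' @return A list of class `palette_spec` with elements `hues` (list of
#'   character vectors of `"r,g,b"` tokens, light to dark) and
#'   `shades_per_hue`.
#' @export
palette_spec <- function(shades_per_hue = 5) {
  stopifnot(shades_per_hue >= 2)
  hues <- lapply(HUE_ENDPOINTS, function(ep) {
    hex_to_token(grDevices::colorRampPalette(ep)(shades_per_hue))
  })
  out <- list(hues = hues, shades_per_hue = as.integer(shades_per_hue))
  class(out) <- "palette_spec"
  out
}

palette_hue <- function(palette, index) {
  hues <- palette$hues
  # indices beyond the table wrap around the fixed cycle (index 1 excluded)
  if (index > length(hues)) {
    index <- 2L + (index - 2L) %% (length(hues) - 1L)
  }
  hues[[index]]
}

#' Map SV type labels to palette indices
#'
#' @param types Character vector of SV type labels (unique).
#' @param indices Palette indices (>= 2; index 1 is reserved for NM links).
#' @return A data frame of class `type_conv` with columns `type`, `index`.
#' @export
#' @examples
#' type_conv(c("INS_FRAGMT", "INV_INS_FRAGMT"), c(2, 3))
type_conv <- function(types, indices) {
  types <- as.character(types)
  indices <- as.integer(indices)
  if (!length(types)) stop("type_conv needs at least one type")
  if (length(types) != length(indices)) stop("types and indices differ")
  if (anyDuplicated(types)) stop("duplicate type label in conversion table")
  if (any(indices < 2L)) {
    stop("palette index 1 (red) is reserved for NM links")
  }
  out <- data.frame(type = types, index = indices, stringsAsFactors = FALSE)
  class(out) <- c("type_conv", "data.frame")
  out
}

# discrete shade: linear binning over the observed support range;
# a degenerate range maps everything to the darkest shade
shade_index <- function(support, shades) {
  lo <- min(support)
  hi <- max(support)
  if (hi == lo) return(rep(shades, length(support)))
  pmin(shades, 1 + floor((support - lo) / (hi - lo + 1) * shades))
}

#' Paint links with per-type gradients
#'
#' Each SV type is assigned a hue family through `conv`; within a type,
#' darkness increases with the number of supporting read pairs, so darker
#' links are more significant. Shades are binned linearly over the
#' observed support range of that type; if all supports are equal the
#' darkest shade is used. Links whose type is absent from `conv` are
#' dropped with a warning stating how many.
#'
#' @param links A `circus_links` data frame (or path to a ".circus" file).
#' @param conv A [type_conv()] mapping type labels to palette indices.
#' @param palette A [palette_spec()].
#' @return The retained links with the `color` column filled.
#' @export
links_paint <- function(links, conv, palette = palette_spec()) {
  links <- as_links(links)
  if (!inherits(conv, "type_conv") || !nrow(conv)) {
    stop("conv must be a non-empty type_conv")
  }
  known <- links$type %in% conv$type
  if (any(!known)) {
    warning(sum(!known), " link(s) dropped: type not in conversion table")
  }
  links <- links[known, , drop = FALSE]
  if (!nrow(links)) {
    out <- empty_links()
    return(out)
  }
  for (ty in unique(links$type)) {
    sel <- links$type == ty
    idx <- conv$index[conv$type == ty]
    ramp <- palette_hue(palette, idx)
    sh <- shade_index(links$support[sel], palette$shades_per_hue)
    links$color[sel] <- ramp[sh]
  }
  rownames(links) <- NULL
  links
}

# greedy single-linkage clustering of sorted positions: consecutive
# anchors join while the gap is <= frag_size
cluster_anchors <- function(anchors, frag_size) {
  if (!nrow(anchors)) {
    return(data.frame(chr = character(0), start = numeric(0),
                      end = numeric(0), size = integer(0),
                      stringsAsFactors = FALSE))
  }
  anchors <- anchors[order(anchors$chr, anchors$pos), , drop = FALSE]
  new_cluster <- c(TRUE, anchors$chr[-1L] != anchors$chr[-nrow(anchors)] |
                     diff(anchors$pos) > frag_size)
  grp <- cumsum(new_cluster)
  data.frame(
    chr = as.vector(tapply(anchors$chr, grp, `[`, 1L)),
    start = as.vector(tapply(anchors$pos, grp, min)),
    end = as.vector(tapply(anchors$pos, grp, max)),
    size = as.vector(tapply(anchors$pos, grp, length)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster and paint NM anchors into pseudo-chromosome links
#'
#' Anchors (from [nm_adapt()]) are sorted by chromosome and position and
#' clustered by greedy single linkage: consecutive anchors on one
#' chromosome join a cluster while the gap between them is at most
#' `frag_size` (the sequencing fragment length, so mates of one insertion
#' site fall in one cluster). Every cluster of at least `threshold`
#' anchors becomes one NM link: foot A spans the cluster on its
#' chromosome, foot B is an interval allocated on the NM pseudo-chromosome
#' (clusters placed left to right in discovery order, equal widths), and
#' support is the cluster size. Links are painted in the reserved red hue
#' family with darkness increasing in support, as in [links_paint()].
#'
#' @param anchors An `nm_anchors` data frame (or path to an anchors file).
#' @param karyotype A `circus_karyotype` carrying the NM pseudo-chromosome.
#' @param frag_size Maximum gap in bp joining consecutive anchors
#'   (default 330).
#' @param threshold Minimum cluster size for a link to be reported
#'   (default 50).
#' @param palette A [palette_spec()].
#' @return A `circus_links` data frame of painted `"NM"`-type links.
#' @export
nm_paint <- function(anchors, karyotype, frag_size = 330, threshold = 50,
                     palette = palette_spec()) {
  if (is.character(anchors) && length(anchors) == 1L) {
    anchors <- read_nm_anchors(anchors)
  }
  stopifnot(inherits(karyotype, "circus_karyotype"))
  if (!has_nm(karyotype)) {
    stop("karyotype lacks the NM pseudo-chromosome; see append_nm()")
  }
  cl <- cluster_anchors(anchors, frag_size)
  cl <- cl[cl$size >= threshold, , drop = FALSE]
  if (!nrow(cl)) return(empty_links())
  nm_len <- karyotype$length[karyotype$id == "NM"]
  n <- nrow(cl)
  w <- nm_len / n
  nm_start <- floor((seq_len(n) - 1) * w) + 1
  nm_end <- pmax(nm_start, floor(seq_len(n) * w))
  ramp <- palette_hue(palette, 1L)
  col <- ramp[shade_index(cl$size, palette$shades_per_hue)]
  link_records(cl$chr, cl$start, cl$end, "NM", nm_start, nm_end,
               "NM", cl$size, col)
}

#' Paint CNV segments by copy-number status
#'
#' Fixed status colors: copy number 0 (full loss) light blue, 2 orange,
#' 3 or more red; the diploid-equivalent baseline value 1 gets the
#' track's light-yellow background color but the segment is still
#' emitted. Values are rounded to the nearest integer before mapping.
#'
#' @param segments A `circus_segments` data frame of value records (or a
#'   path to a ".circus" file); values must be non-negative.
#' @return The segments with the `color` column filled.
#' @export
cnv_paint <- function(segments) {
  segments <- as_segments(segments)
  if (any(is.na(segments$value))) {
    stop("cnv_paint expects value records (copy numbers)")
  }
  if (any(segments$value < 0)) stop("negative copy number")
  v <- round(segments$value)
  segments$color <- ifelse(
    v == 0, CIRCUS_COLORS[["light_blue"]],
    ifelse(v == 1, CIRCUS_COLORS[["light_yellow"]],
           ifelse(v == 2, CIRCUS_COLORS[["orange"]],
                  CIRCUS_COLORS[["red"]])))
  segments
}

#' Paint annotation segments by strand
#'
#' Watson (`+`) features are grey, Crick (`-`) features dark green;
#' strandless features (`.`) fall back to grey.
#'
#' @param features A `circus_segments` data frame of annotation records
#'   (or a path to a ".circus" file).
#' @return The features with the `color` column filled.
#' @export
annot_paint <- function(features) {
  features <- as_segments(features)
  if (any(is.na(features$strand))) {
    stop("annot_paint expects annotation records (with strand)")
  }
  features$color <- ifelse(features$strand == "-",
                           CIRCUS_COLORS[["dark_green"]],
                           CIRCUS_COLORS[["grey"]])
  features
}
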