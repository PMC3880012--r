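#' Layout configuration for the circular view
#'
#' Geometry and styling knobs for the circle. Angles are in degrees; the
#' first chromosome starts at `start_angle_deg` (default 90, i.e. 12
#' o'clock) and chromosomes run clockwise. Radii are unitless canvas units
#' on a `canvas x canvas` viewport centred at `canvas/2`; the radius order
#' must be glyphs > reference ring > annotation rings > edge chord region.
#'
#' @param gap_deg Gap between consecutive chromosome arcs (degrees). A fixed
#'   per-chromosome gap (rather than a proportional one) keeps small
#'   chromosomes visible.
#' @param start_angle_deg Angle of the first chromosome's start.
#' @param canvas Canvas side length.
#' @param radius_outer Outer radius of the reference (cytoband) ring.
#' @param ring_thickness,ring_spacing Radial thickness of and spacing
#'   between annotation rings.
#' @param edge_radius Radius at which edge curves attach; annotation rings
#'   must stay outside it.
#' @param glyph_radius Radius of phenotype glyph ticks (outside the
#'   reference ring).
#' @param glyph_length Radial length of a glyph tick.
#' @param weight_colors Diverging colormap endpoints
#'   `c(negative, zero, positive)`; defaults to pink-grey-green so positive
#'   correlations read green and negative pink.
#' @param type_palette Named colors for node source types GENO, GEXP, PROT,
#'   PHENO and untyped nodes.
#' @param default_edge_color Edge color when neither an explicit color nor a
#'   weight is present.
#' @return A list of class `layout_config`.
#' @export
layout_config <- function(gap_deg = 1, start_angle_deg = 90, canvas = 1000,
                          radius_outer = 400, ring_thickness = 16, ring_spacing = 6,
                          edge_radius = 250, glyph_radius = 412, glyph_length = 14,
                          weight_colors = c("#ff69b4", "#bbbbbb", "#2ca02c"),
                          type_palette = c(GENO = "#1f77b4", GEXP = "#d62728",
                                           PROT = "#9467bd", PHENO = "#ff7f0e",
                                           none = "#555555"),
                          default_edge_color = "#888888") {
  if (gap_deg < 0) abort("gap_deg must be >= 0")
  if (!(glyph_radius > radius_outer && radius_outer > edge_radius && edge_radius > 0)) {
    abort("radii must satisfy glyph_radius > radius_outer > edge_radius > 0")
  }
  structure(
    list(gap_deg = gap_deg, start_angle_deg = start_angle_deg, canvas = canvas,
         radius_outer = radius_outer, ring_thickness = ring_thickness,
         ring_spacing = ring_spacing, edge_radius = edge_radius,
         glyph_radius = glyph_radius, glyph_length = glyph_length,
         weight_colors = weight_colors, type_palette = type_palette,
         default_edge_color = default_edge_color),
    class = "layout_config"
  )
}

#' Read a `key = value` layout configuration file
#'
#' Numeric fields of [layout_config()] can be overridden from a plain text
#' file with one `key = value` assignment per line; `#` comments and blank
#' lines are skipped.
#' @param path File path.
#' @param base Config to override; default [layout_config()] defaults.
#' @return A `layout_config`.
#' @export
read_layout_config <- function(path, base = layout_config()) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines)) & !startsWith(stringr::str_trim(lines), "#")]
  for (ln in lines) {
    m <- stringr::str_match(ln, "^\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$")
    if (is.na(m[1, 1])) abort(paste0("malformed config line: '", ln, "'"))
    key <- m[1, 2]; val <- m[1, 3]
    if (!key %in% names(base)) abort(paste0("unknown config key '", key, "'"))
    num <- suppressWarnings(as.numeric(val))
    base[[key]] <- if (!is.na(num)) num else val
  }
  do.call(layout_config, base[names(base) %in% names(formals(layout_config))])
}

#' Assign chromosomes to circle arcs
#'
#' Chromosomes are laid out in reference order starting at
#' `start_angle_deg`, running clockwise, separated by fixed gaps. Each arc
#' span is proportional to the chromosome's base length: span_i =
#' usable_deg * length_i / genome_length with usable_deg = 360 - n_chrom *
#' gap_deg. Angles decrease clockwise, so `theta_end < theta_start` for
#' every chromosome.
#'
#' @param reference A `genome_ref`.
#' @param config A [layout_config()].
#' @return An `arcmap`: tibble `chrom, length_bp, span, theta_start,
#'   theta_end` with attributes `genome_length`, `usable_deg`, `config`.
#' @export
#' @examples
#' ref <- define_custom_reference("toy",
#'   data.frame(chrom = c("a", "b"), length_bp = c(100, 300)))
#' build_arcmap(ref, layout_config(gap_deg = 0))
build_arcmap <- function(reference, config = layout_config()) {
  chroms <- reference$chromosomes
  n <- nrow(chroms)
  usable <- 360 - n * config$gap_deg
  if (usable <= 0) {
    abort(paste0("gap_deg too large: ", n, " chromosomes x ", config$gap_deg,
                 " degrees leaves no usable circumference"))
  }
  total <- sum(chroms$length_bp)
  span <- usable * chroms$length_bp / total
  theta_start <- config$start_angle_deg - (cumsum(span) - span) -
    (seq_len(n) - 1) * config$gap_deg
  arc <- tibble::tibble(chrom = chroms$chrom, length_bp = chroms$length_bp,
                        span = span, theta_start = theta_start,
                        theta_end = theta_start - span)
  attr(arc, "genome_length") <- total
  attr(arc, "usable_deg") <- usable
  attr(arc, "config") <- config
  class(arc) <- c("arcmap", class(arc))
  arc
}

#' Map genomic positions to circle angles
#'
#' Linear interpolation of a base position within its chromosome's arc:
#' position p (1-based) sits at fraction (p - 0.5) / length of the arc, so
#' base 1 maps to the arc start within half a base and base `length` to the
#' arc end likewise. Angles never fall inside inter-chromosome gaps.
#'
#' @param chrom Chromosome names (vectorized).
#' @param pos Base positions (1-based).
#' @param arcmap An [build_arcmap()] result.
#' @return Angles in degrees (decreasing clockwise from the arc start).
#' @export
locus_to_angle <- function(chrom, pos, arcmap) {
  idx <- match(chrom, arcmap$chrom)
  if (anyNA(idx)) {
    abort(paste0("unknown chromosome in angle lookup: ",
                 paste(unique(chrom[is.na(idx)]), collapse = ", ")))
  }
  frac <- (pos - 0.5) / arcmap$length_bp[idx]
  arcmap$theta_start[idx] - frac * arcmap$span[idx]
}

#' Radial bands for the reference and uploaded annotation rings
#'
#' The reference ring is outermost; uploaded rings stack inward in upload
#' order, each `ring_thickness` thick and `ring_spacing` apart. Edge curves
#' occupy the disc inside the innermost ring.
#'
#' @param n_rings Number of uploaded annotation rings (>= 0).
#' @param config A [layout_config()].
#' @return Tibble `ring, r_inner, r_outer`; ring 0 is the reference ring.
#' @export
ring_radii <- function(n_rings, config = layout_config()) {
  if (n_rings < 0) abort("n_rings must be >= 0")
  r_outer <- config$radius_outer - (0:n_rings) * (config$ring_thickness + config$ring_spacing)
  bands <- tibble::tibble(ring = 0:n_rings, r_outer = r_outer,
                          r_inner = r_outer - config$ring_thickness)
  if (any(bands$r_inner <= config$edge_radius)) {
    abort(paste0("rings would cross the edge chord region (edge_radius = ",
                 config$edge_radius, "); use thinner rings or fewer of them"))
  }
  bands
}

#' Place phenotype glyph ticks
#'
#' Edges with exactly one mapped endpoint (the other a `^PHENO` phenotype
#' node) are drawn as radial ticks outside the reference ring at the mapped
#' endpoint's angle. Edges with no mapped endpoint cannot be placed and are
#' reported back.
#'
#' @param set An `assoc_set`.
#' @param arcmap An `arcmap` built on the same reference.
#' @param config A [layout_config()].
#' @return List with `glyphs` (tibble `angle, radius, label, pheno_label`)
#'   and `skipped` (edge tibble with no mappable endpoint).
#' @export
place_glyphs <- function(set, arcmap, config = layout_config()) {
  e <- set$edges
  pheno_a <- !is.na(e$type_a) & e$type_a == "PHENO"
  pheno_b <- !is.na(e$type_b) & e$type_b == "PHENO"
  single_a <- pheno_a & e$mapped_b  # pheno on a, anchored at b
  single_b <- pheno_b & e$mapped_a
  skipped <- e[(pheno_a | pheno_b) & !e$mapped_a & !e$mapped_b, , drop = FALSE]
  glyphs <- dplyr::bind_rows(
    tibble::tibble(chrom = e$chrom_b[single_a], mid = e$mid_b[single_a],
                   label = e$label_b[single_a], pheno_label = e$label_a[single_a]),
    tibble::tibble(chrom = e$chrom_a[single_b], mid = e$mid_a[single_b],
                   label = e$label_a[single_b], pheno_label = e$label_b[single_b])
  )
  if (nrow(glyphs)) {
    glyphs$angle <- locus_to_angle(glyphs$chrom, glyphs$mid, arcmap)
  } else {
    glyphs$angle <- numeric()
  }
  glyphs$radius <- rep(config$glyph_radius, nrow(glyphs))
  list(glyphs = glyphs, skipped = skipped)
}

#' Plot an arc map (or an association set on one) with ggplot2
#'
#' A quick-look companion to the SVG renderer: chromosome arcs on the
#' circumference and, when an `assoc_set` is supplied, straight chords
#' between mapped endpoints.
#'
#' @param object An `arcmap`.
#' @param set Optional `assoc_set` resolved on the same reference.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot arcmap
#' @export
autoplot.arcmap <- function(object, set = NULL, ...) {
  cfg <- attr(object, "config")
  arc_pts <- purrr::pmap_dfr(
    list(object$chrom, object$theta_start, object$theta_end),
    function(chrom, t0, t1) {
      th <- seq(t0, t1, length.out = 40) * pi / 180
      tibble::tibble(chrom = chrom, x = cos(th), y = sin(th))
    })
  p <- ggplot2::ggplot(arc_pts, ggplot2::aes(x = .data$x, y = .data$y, group = .data$chrom)) +
    ggplot2::geom_path(linewidth = 2, ggplot2::aes(color = .data$chrom),
                       show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(set)) {
    e <- set$edges[set$edges$mapped_a & set$edges$mapped_b, , drop = FALSE]
    if (nrow(e)) {
      th_a <- locus_to_angle(e$chrom_a, e$mid_a, object) * pi / 180
      th_b <- locus_to_angle(e$chrom_b, e$mid_b, object) * pi / 180
      chords <- tibble::tibble(x = cos(th_a) * 0.97, y = sin(th_a) * 0.97,
                               xend = cos(th_b) * 0.97, yend = sin(th_b) * 0.97)
      p <- p + ggplot2::geom_segment(
        data = chords,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
        inherit.aes = FALSE, alpha = 0.4, linewidth = 0.3)
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
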