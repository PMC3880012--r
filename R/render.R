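STAIN_PALETTE <- c(gneg = "#f7f7f7", gpos25 = "#c8c8c8", gpos50 = "#969696",
                   gpos75 = "#646464", gpos100 = "#323232", acen = "#d92f27",
                   gvar = "#dcdcdc", stalk = "#7f7f7f")

fmt_coord <- function(x) sprintf("%.4f", x)

polar_xy <- function(angle_deg, r, config) {
  th <- angle_deg * pi / 180
  c(x = config$canvas / 2 + r * cos(th),
    y = config$canvas / 2 - r * sin(th))
}

# annular sector between two angles (theta decreasing clockwise on screen)
sector_path <- function(theta_start, theta_end, r_inner, r_outer, config) {
  span <- theta_start - theta_end
  large <- if (span > 180) 1 else 0
  p1 <- polar_xy(theta_start, r_outer, config)
  p2 <- polar_xy(theta_end, r_outer, config)
  p3 <- polar_xy(theta_end, r_inner, config)
  p4 <- polar_xy(theta_start, r_inner, config)
  sprintf("M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
          fmt_coord(p1["x"]), fmt_coord(p1["y"]),
          fmt_coord(r_outer), fmt_coord(r_outer), large,
          fmt_coord(p2["x"]), fmt_coord(p2["y"]),
          fmt_coord(p3["x"]), fmt_coord(p3["y"]),
          fmt_coord(r_inner), fmt_coord(r_inner), large,
          fmt_coord(p4["x"]), fmt_coord(p4["y"]))
}

# quadratic chord: control point sits at 0.2 * edge_radius from the centre,
# along the bisecting direction of the two anchors (the centre itself for
# diametrically opposed anchors), pulling long chords through the middle
edge_curve_path <- function(angle_a, angle_b, config) {
  r <- config$edge_radius
  pa <- polar_xy(angle_a, r, config)
  pb <- polar_xy(angle_b, r, config)
  va <- c(cos(angle_a * pi / 180), sin(angle_a * pi / 180))
  vb <- c(cos(angle_b * pi / 180), sin(angle_b * pi / 180))
  vm <- va + vb
  nrm <- sqrt(sum(vm^2))
  ctrl <- if (nrm < 1e-9) {
    c(config$canvas / 2, config$canvas / 2)
  } else {
    c(config$canvas / 2 + 0.2 * r * vm[1] / nrm,
      config$canvas / 2 - 0.2 * r * vm[2] / nrm)
  }
  sprintf("M %s %s Q %s %s %s %s",
          fmt_coord(pa["x"]), fmt_coord(pa["y"]),
          fmt_coord(ctrl[1]), fmt_coord(ctrl[2]),
          fmt_coord(pb["x"]), fmt_coord(pb["y"]))
}

weight_color_fn <- function(weights, config) {
  ramp <- grDevices::colorRamp(config$weight_colors)
  finite <- weights[!is.na(weights)]
  m <- if (length(finite)) max(abs(finite)) else 0
  function(w) {
    if (is.na(w)) return(config$default_edge_color)
    frac <- if (m == 0) 0.5 else (w + m) / (2 * m)
    rgb <- ramp(max(0, min(1, frac)))
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the circular genome view as SVG
#'
#' Draws, from the outside in: phenotype glyph ticks, chromosome arc bands
#' (Giemsa stain colors where the reference carries cytobands, member
#' perimeter colors for composites), uploaded annotation rings in upload
#' order, and edge curves as quadratic chords through the disc. Edge stroke
#' color precedence: explicit record color, then the diverging weight
#' colormap (positive green, negative pink, symmetric about zero over the
#' rendered set), then the default grey. At most `limit` curves are drawn
#' (the render limit truncates the drawable mapped-mapped curve list by
#' input order; filters always act on the full set beforehand). When
#' `bundles` is supplied the bundled curves are drawn instead of individual
#' member edges, with stroke width growing as log2(count + 1). The output
#' embeds no timestamps or random ids, so identical inputs give
#' byte-identical files.
#'
#' @param set An `assoc_set`.
#' @param reference The `genome_ref` the set was resolved on.
#' @param rings List of `annotation_ring` objects, in upload order.
#' @param config A [layout_config()].
#' @param limit Render limit (default 2000 curves).
#' @param bundles Optional `edge_bundles` from [bundle_edges()].
#' @return An `svg_document` (character vector of lines).
#' @export
render_circular <- function(set, reference, rings = list(), config = layout_config(),
                            limit = 2000, bundles = NULL) {
  arcmap <- build_arcmap(reference, config)
  bands <- ring_radii(length(rings), config)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
                   "height=\"%d\" viewBox=\"0 0 %d %d\">"),
            config$canvas, config$canvas, config$canvas, config$canvas),
    sprintf("<metadata>arcomics %s; reference=%s; filters=%s; limit=%d</metadata>",
            as.character(utils::packageVersion("arcomics")),
            xml_escape(set$ref_id),
            xml_escape(if (length(set$provenance)) paste(set$provenance, collapse = "; ")
                       else "none"),
            as.integer(limit))
  )

  out <- c(out, render_chrom_bands(reference, arcmap, bands[1, ], config))

  ring_band_i <- 2
  for (ring in rings) {
    rr <- render_annotation_ring(ring, bands[ring_band_i, ], arcmap, reference, config)
    if (length(rr$elements)) {
      out <- c(out, sprintf("<g class=\"annotation-ring\" data-style=\"%s\">", ring$style),
               rr$elements, "</g>")
      ring_band_i <- ring_band_i + 1
    }
  }

  wcol <- weight_color_fn(set$edges$weight, config)
  edge_color <- function(color, weight) {
    if (!is.na(color)) color else wcol(weight)
  }

  if (is.null(bundles)) {
    mm <- set$edges[set$edges$mapped_a & set$edges$mapped_b, , drop = FALSE]
    mm <- utils::head(mm, limit)
    if (nrow(mm)) {
      ang_a <- locus_to_angle(mm$chrom_a, mm$mid_a, arcmap)
      ang_b <- locus_to_angle(mm$chrom_b, mm$mid_b, arcmap)
      curves <- vapply(seq_len(nrow(mm)), function(i) {
        sprintf("<path class=\"edge\" d=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"1\"/>",
                edge_curve_path(ang_a[i], ang_b[i], config),
                edge_color(mm$color[i], mm$weight[i]))
      }, character(1))
      out <- c(out, "<g class=\"edges\">", curves, "</g>")
    }
  } else {
    out <- c(out, render_bundles(bundles, arcmap, config, limit, edge_color))
  }

  gl <- place_glyphs(set, arcmap, config)
  if (nrow(gl$glyphs)) {
    g <- gl$glyphs
    ticks <- vapply(seq_len(nrow(g)), function(i) {
      p1 <- polar_xy(g$angle[i], config$glyph_radius, config)
      p2 <- polar_xy(g$angle[i], config$glyph_radius + config$glyph_length, config)
      sprintf(paste0("<line class=\"glyph\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                     "stroke=\"%s\" stroke-width=\"2\"/>"),
              fmt_coord(p1["x"]), fmt_coord(p1["y"]),
              fmt_coord(p2["x"]), fmt_coord(p2["y"]),
              config$type_palette[["PHENO"]])
    }, character(1))
    out <- c(out, "<g class=\"glyphs\">", ticks, "</g>")
  }

  out <- c(out, "</svg>")
  structure(out, class = "svg_document")
}

render_chrom_bands <- function(reference, arcmap, band, config) {
  r_in <- band$r_inner; r_out <- band$r_outer
  member_color <- NULL
  if (inherits(reference, "composite_ref")) {
    member_color <- stats::setNames(reference$members$color, reference$members$prefix)
  }
  out <- character()
  for (i in seq_len(nrow(arcmap))) {
    ch <- arcmap$chrom[i]
    fill <- "#d9d9d9"
    if (!is.null(member_color)) {
      pfx <- sub("\\..*$", "", ch)
      if (pfx %in% names(member_color)) fill <- member_color[[pfx]]
    }
    inner <- character()
    cyto <- reference$cytobands
    if (is.null(member_color) && !is.null(cyto) && ch %in% cyto$chrom) {
      cb <- cyto[cyto$chrom == ch, , drop = FALSE]
      inner <- vapply(seq_len(nrow(cb)), function(j) {
        t0 <- locus_to_angle(ch, cb$start[j], arcmap)
        t1 <- locus_to_angle(ch, cb$end[j], arcmap)
        stain <- if (cb$stain[j] %in% names(STAIN_PALETTE)) {
          STAIN_PALETTE[[cb$stain[j]]]
        } else "#e0e0e0"
        sprintf("<path class=\"cytoband\" d=\"%s\" fill=\"%s\" stroke=\"none\"/>",
                sector_path(t0, t1, r_in, r_out, config), stain)
      }, character(1))
    }
    lbl_p <- polar_xy(arcmap$theta_start[i] - arcmap$span[i] / 2,
                      config$glyph_radius + config$glyph_length + 8, config)
    out <- c(out,
             sprintf("<g class=\"chrom-band\" data-chrom=\"%s\">", xml_escape(ch)),
             sprintf("<path d=\"%s\" fill=\"%s\" stroke=\"#333333\" stroke-width=\"0.5\"/>",
                     sector_path(arcmap$theta_start[i], arcmap$theta_end[i],
                                 r_in, r_out, config), fill),
             inner,
             sprintf(paste0("<text class=\"chrom-label\" x=\"%s\" y=\"%s\" ",
                            "font-size=\"11\" text-anchor=\"middle\">%s</text>"),
                     fmt_coord(lbl_p["x"]), fmt_coord(lbl_p["y"]), xml_escape(ch)),
             "</g>")
  }
  out
}

render_bundles <- function(bundles, arcmap, config, limit, edge_color) {
  w <- bundles$window_bp
  cell_angle <- function(chrom, win) {
    len <- arcmap$length_bp[match(chrom, arcmap$chrom)]
    mid <- pmin((win - 0.5) * w, len)
    locus_to_angle(chrom, pmax(mid, 1), arcmap)
  }
  b <- bundles$bundles
  pieces <- list()
  if (nrow(b)) {
    pieces$bundle <- tibble::tibble(
      path = purrr::pmap_chr(list(b$chrom_1, b$win_1, b$chrom_2, b$win_2),
                             function(c1, w1, c2, w2) {
                               edge_curve_path(cell_angle(c1, w1), cell_angle(c2, w2), config)
                             }),
      stroke = config$default_edge_color,
      width = log2(b$count + 1),
      class = "bundle",
      count = b$count)
  }
  p <- bundles$passthrough
  if (nrow(p)) {
    pieces$pass <- tibble::tibble(
      path = purrr::pmap_chr(list(p$chrom_a, p$mid_a, p$chrom_b, p$mid_b),
                             function(ca, ma, cb, mb) {
                               edge_curve_path(locus_to_angle(ca, ma, arcmap),
                                               locus_to_angle(cb, mb, arcmap), config)
                             }),
      stroke = purrr::map2_chr(p$color, p$weight, edge_color),
      width = 1,
      class = "edge",
      count = NA_integer_)
  }
  all <- dplyr::bind_rows(pieces)
  all <- utils::head(all, limit)
  if (!nrow(all)) return(character())
  c("<g class=\"edges\">",
    purrr::pmap_chr(all, function(path, stroke, width, class, count) {
      extra <- if (!is.na(count)) sprintf(" data-count=\"%d\"", count) else ""
      sprintf("<path class=\"%s\" d=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"%s\"%s/>",
              class, path, stroke, fmt_coord(width), extra)
    }),
    "</g>")
}

#' Render one annotation ring's drawing elements
#'
#' Targets (gene labels or positional segments) are resolved against the
#' reference; unresolvable targets are skipped and reported. Styles: `bar`
#' draws a radial bar per entry with height proportional to
#' value / max|value| within the band; `histogram` sets a baseline at the
#' band middle, positive values growing outward and negative inward;
#' `heatmap` fills an arc cell per entry, colored by the diverging value
#' colormap (or by the entry's own color for color-typed rings).
#'
#' @param ring An `annotation_ring`.
#' @param band One row of [ring_radii()] (`r_inner`, `r_outer`).
#' @param arcmap The active `arcmap`.
#' @param reference The active reference.
#' @param config A [layout_config()].
#' @return List with `elements` (SVG strings) and `skipped` (unresolved
#'   target labels).
#' @export
render_annotation_ring <- function(ring, band, arcmap, reference, config = layout_config()) {
  entries <- ring$entries
  loci <- translate_labels(entries$target, reference)
  ok <- loci$mapped
  skipped <- entries$target[!ok]
  if (!any(ok)) {
    warn(paste0("annotation ring skipped: no resolvable targets (e.g. ",
                paste(utils::head(skipped, 3), collapse = ", "), ")"))
    return(list(elements = character(), skipped = skipped))
  }
  entries <- entries[ok, , drop = FALSE]
  loci <- loci[ok, , drop = FALSE]
  colored <- any(!is.na(entries$color))
  vmax <- if (colored) 1 else max(abs(entries$value))
  if (vmax == 0) vmax <- 1
  ramp <- grDevices::colorRamp(config$weight_colors)
  val_color <- function(v) {
    rgb <- ramp(max(0, min(1, (v + vmax) / (2 * vmax))))
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }
  thick <- band$r_outer - band$r_inner
  mid_r <- (band$r_outer + band$r_inner) / 2
  elements <- vapply(seq_len(nrow(entries)), function(i) {
    t0 <- locus_to_angle(loci$chrom[i], loci$start[i], arcmap)
    t1 <- locus_to_angle(loci$chrom[i], loci$end[i], arcmap)
    tm <- (t0 + t1) / 2
    fill <- if (colored) entries$color[i] else val_color(entries$value[i])
    if (ring$style == "heatmap") {
      sprintf("<path class=\"ring-cell\" d=\"%s\" fill=\"%s\" stroke=\"none\"/>",
              sector_path(t0, t1, band$r_inner, band$r_outer, config), fill)
    } else if (ring$style == "bar") {
      h <- if (colored) thick else abs(entries$value[i]) / vmax * thick
      p1 <- polar_xy(tm, band$r_inner, config)
      p2 <- polar_xy(tm, band$r_inner + h, config)
      sprintf(paste0("<line class=\"ring-bar\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                     "stroke=\"%s\" stroke-width=\"2\"/>"),
              fmt_coord(p1["x"]), fmt_coord(p1["y"]),
              fmt_coord(p2["x"]), fmt_coord(p2["y"]), fill)
    } else {  # histogram
      v <- if (colored) 1 else entries$value[i]
      h <- abs(v) / vmax * thick / 2
      r2 <- if (v >= 0) mid_r + h else mid_r - h
      p1 <- polar_xy(tm, mid_r, config)
      p2 <- polar_xy(tm, r2, config)
      sprintf(paste0("<line class=\"ring-hist\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                     "stroke=\"%s\" stroke-width=\"2\"/>"),
              fmt_coord(p1["x"]), fmt_coord(p1["y"]),
              fmt_coord(p2["x"]), fmt_coord(p2["y"]), fill)
    }
  }, character(1))
  list(elements = elements, skipped = skipped)
}

locus_string <- function(chrom, start, end, mapped) {
  ifelse(mapped, sprintf("%s:%s:%s", chrom,
                         format(start, scientific = FALSE, trim = TRUE),
                         format(end, scientific = FALSE, trim = TRUE)),
         "unmapped")
}

#' Tabular (grid) view of an association set
#'
#' One row per edge in set order: both labels, source types, resolved loci
#' (`chrom:start:end`, or `"unmapped"`), weight and color. The label and
#' weight columns re-parse to the same edges, so the grid TSV doubles as an
#' exchange format.
#'
#' @param set An `assoc_set`.
#' @return A tibble.
#' @export
render_grid <- function(set) {
  e <- set$edges
  tibble::tibble(
    labelA = e$label_a, typeA = e$type_a,
    locusA = locus_string(e$chrom_a, e$start_a, e$end_a, e$mapped_a),
    labelB = e$label_b, typeB = e$type_b,
    locusB = locus_string(e$chrom_b, e$start_b, e$end_b, e$mapped_b),
    weight = e$weight, color = e$color
  )
}

#' Write the grid view as TSV or a standalone HTML table
#' @param set An `assoc_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_grid_tsv <- function(set, path) {
  g <- render_grid(set)
  g$weight <- fmt_num(g$weight)
  lines <- c(paste(names(g), collapse = "\t"),
             apply(as.matrix(g), 1, function(r) paste(ifelse(is.na(r), "", r), collapse = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
write_grid_html <- function(set, path) {
  g <- render_grid(set)
  cells <- function(tag, vals) {
    paste0("<", tag, ">", xml_escape(ifelse(is.na(vals), "", as.character(vals))),
           "</", tag, ">", collapse = "")
  }
  rows <- vapply(seq_len(nrow(g)), function(i) {
    paste0("<tr>", cells("td", unlist(g[i, ], use.names = FALSE)), "</tr>")
  }, character(1))
  lines <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
             "<title>association grid</title></head><body>",
             "<table border=\"1\">",
             paste0("<tr>", cells("th", names(g)), "</tr>"),
             rows, "</table></body></html>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write an SVG document to disk
#'
#' Re-rendering identical inputs writes byte-identical files (no timestamps
#' or random ids are embedded).
#' @param doc An `svg_document` from [render_circular()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_svg <- function(doc, path) {
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    abort(paste0("cannot write SVG to '", path, "': ", conditionMessage(e))))
  on.exit(close(con))
  writeLines(as.character(doc), con, useBytes = TRUE)
  invisible(path)
}

#' @export
print.svg_document <- function(x, ...) {
  cat(sprintf("<svg_document> %d lines, %d bytes\n", length(x),
              sum(nchar(x, type = "bytes")) + length(x)))
  invisible(x)
}
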