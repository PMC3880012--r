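svg_xml <- function(doc) xml2::read_xml(paste(as.character(doc), collapse = "\n"))

count_class <- function(x, class) {
  length(xml2::xml_find_all(x, sprintf("//*[@class='%s']", class)))
}

test_that("the circular view draws one band per chromosome and obeys the limit", {
  ref <- toy_ref()
  set <- resolve_set(parse_associations(sprintf("G7 Wnt1 0.%d", 1:3), "space"), ref)

  x <- svg_xml(render_circular(set, ref, limit = 2))
  expect_equal(count_class(x, "chrom-band"), 2)
  expect_equal(count_class(x, "edge"), 2)

  # a set filtered down to nothing still renders the reference ring
  none <- filter_weight(set, ">", 99)
  x0 <- svg_xml(render_circular(none, ref))
  expect_equal(count_class(x0, "chrom-band"), 2)
  expect_equal(count_class(x0, "edge"), 0)

  # partially unmapped edges draw no curve; single-pheno edges draw glyphs
  mix <- resolve_set(parse_associations(
    c("G7 Wnt1 0.5", "G7 NOGENE", "G7 tired^PHENO", "Wnt1 sad^PHENO"), "space"), ref)
  xm <- svg_xml(render_circular(mix, ref))
  expect_equal(count_class(xm, "edge"), 1)
  expect_equal(count_class(xm, "glyph"), 2)
})

test_that("edge colors follow explicit color, then weight colormap, then grey", {
  ref <- toy_ref()
  set <- resolve_set(parse_associations(
    c("G7 Wnt1 #112233", "G7 Wnt1 0.9", "G7 Wnt1 -0.9", "G7 Wnt1"), "space"), ref)
  x <- svg_xml(render_circular(set, ref, config = layout_config()))
  strokes <- xml2::xml_attr(xml2::xml_find_all(x, "//*[@class='edge']"), "stroke")
  expect_identical(strokes[[1]], "#112233")
  chan <- function(s) as.integer(grDevices::col2rgb(s))
  # positive weights stroke from the green side, negative from the pink side
  expect_gt(chan(strokes[[2]])[2], chan(strokes[[2]])[1])
  expect_gt(chan(strokes[[3]])[1], chan(strokes[[3]])[2])
  expect_identical(strokes[[4]], layout_config()$default_edge_color)
})

test_that("annotation rings render per style with value-proportional geometry", {
  ref <- toy_ref()
  cfg <- layout_config()
  am <- build_arcmap(ref, cfg)
  band <- ring_radii(1, cfg)[2, ]
  center <- cfg$canvas / 2
  radial <- function(node, a1 = "x1", a2 = "y1") {
    sqrt((as.numeric(xml2::xml_attr(node, a1)) - center)^2 +
           (as.numeric(xml2::xml_attr(node, a2)) - center)^2)
  }

  # heatmap: one arc cell spanning the whole chromosome
  heat <- parse_annotation_ring(c("#ring heatmap", "chr1:1:1000\t0.8"))
  rh <- render_annotation_ring(heat, band, am, ref, cfg)
  expect_length(rh$elements, 1)
  expect_match(rh$elements, "ring-cell")

  # histogram: +1 and -1 reach equally far on opposite sides of the baseline
  hist <- parse_annotation_ring(c("#ring histogram", "G7\t1", "Wnt1\t-1"))
  xh <- svg_xml(render_circular(
    resolve_set(parse_associations("G7 Wnt1 0.5", "space"), ref), ref,
    rings = list(hist), config = cfg))
  segs <- xml2::xml_find_all(xh, "//*[@class='ring-hist']")
  expect_length(segs, 2)
  r_from <- vapply(segs, radial, numeric(1))
  r_to <- vapply(segs, function(n) radial(n, "x2", "y2"), numeric(1))
  mid_r <- (band$r_inner + band$r_outer) / 2
  expect_equal(r_from, rep(mid_r, 2), tolerance = 1e-3)
  expect_equal(abs(r_to - mid_r), rep(cfg$ring_thickness / 2, 2), tolerance = 1e-3)
  expect_gt(r_to[[1]], mid_r); expect_lt(r_to[[2]], mid_r)

  # bar: 10 random entries draw 10 bars and the max bar touches the band edge
  vals <- withr::with_seed(8, round(stats::runif(10, -1, 1), 3))
  bar <- parse_annotation_ring(c("#ring bar",
                                 sprintf("chr1:%d:%d\t%s", 1:10 * 50, 1:10 * 50 + 9, vals)))
  rb <- render_annotation_ring(bar, band, am, ref, cfg)
  expect_length(rb$elements, 10)
  doc <- xml2::read_xml(paste0("<g>", paste(rb$elements, collapse = ""), "</g>"))
  bars <- xml2::xml_find_all(doc, "//*[@class='ring-bar']")
  heights <- vapply(bars, function(n) radial(n, "x2", "y2") - radial(n), numeric(1))
  expect_equal(max(heights), cfg$ring_thickness, tolerance = 1e-3)
  expect_equal(heights, abs(vals) / max(abs(vals)) * cfg$ring_thickness,
               tolerance = 1e-3)

  # unresolvable targets are skipped; a fully unresolvable ring is dropped
  part <- parse_annotation_ring(c("#ring bar", "G7\t1", "GHOST\t2"))
  rp <- render_annotation_ring(part, band, am, ref, cfg)
  expect_length(rp$elements, 1)
  expect_identical(rp$skipped, "GHOST")
  allbad <- parse_annotation_ring(c("#ring bar", "GHOST\t2"))
  expect_warning(rab <- render_annotation_ring(allbad, band, am, ref, cfg), "skipped")
  expect_length(rab$elements, 0)
})

test_that("the correlation-study scenario renders with rings in upload order", {
  sc <- fixture_scenario_fig2like(31, n_edges = 400)
  set <- resolve_set(sc$records, sc$reference)
  filtered <- filter_labels(filter_weight(set, "abs>=", 0.5), sc$gene_set)
  doc <- render_circular(filtered, sc$reference, rings = sc$rings)
  x <- svg_xml(doc)
  expect_equal(count_class(x, "chrom-band"), nrow(sc$reference$chromosomes))
  styles <- xml2::xml_attr(xml2::xml_find_all(x, "//*[@class='annotation-ring']"),
                           "data-style")
  expect_identical(styles, c("heatmap", "heatmap", "bar", "bar"))
  mm <- filtered$edges[filtered$edges$mapped_a & filtered$edges$mapped_b, ]
  expect_equal(count_class(x, "edge"), min(nrow(mm), 2000))
})

test_that("rendering is deterministic and embeds filter provenance", {
  ref <- toy_ref()
  set <- filter_weight(resolve_set(
    parse_associations(sprintf("G7 Wnt1 0.%d", 1:5), "space"), ref), "abs>=", 0.2)
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  export_svg(render_circular(set, ref), p1)
  export_svg(render_circular(set, ref), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  x <- xml2::read_xml(p1)
  meta <- xml2::xml_text(xml2::xml_find_first(x, "//*[local-name()='metadata']"))
  expect_match(meta, "weight abs>= 0.2", fixed = TRUE)
  expect_identical(xml2::xml_name(xml2::xml_root(x)), "svg")
  expect_false(is.na(xml2::xml_attr(xml2::xml_root(x), "width")))
})

test_that("bundled rendering draws one curve per bundle with log-scaled width", {
  rref <- fixture_reference(17, n_chrom = 2, n_genes = 30)
  set <- resolve_set(fixture_associations(17, rref, n_edges = 100,
                                          positional_fraction = 0), rref)
  b <- bundle_edges(set, 5e5, exclude_abs_weight_ge = 0.9)
  x <- svg_xml(render_circular(set, rref, bundles = b))
  drawn <- xml2::xml_find_all(x, "//*[@class='bundle']")
  expect_length(drawn, nrow(b$bundles))
  expect_equal(count_class(x, "edge"), nrow(b$passthrough))
  widths <- as.numeric(xml2::xml_attr(drawn, "stroke-width"))
  counts <- as.integer(xml2::xml_attr(drawn, "data-count"))
  expect_equal(widths, as.numeric(sprintf("%.4f", log2(counts + 1))))
})

test_that("the grid view lists every edge and round-trips labels and weights", {
  ref <- toy_ref()
  set <- resolve_set(parse_associations(
    c("G7 Wnt1 0.5", "G7 NOGENE 0.25"), "space"), ref)
  g <- render_grid(set)
  expect_equal(nrow(g), 2)
  expect_identical(g$locusA, c("chr1:500:900", "chr1:500:900"))
  expect_identical(g$locusB[[2]], "unmapped")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(set, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 2)
  back <- resolve_set(parse_associations(
    sprintf("%s %s %s", tab$labelA, tab$labelB, tab$weight), "space"), ref)
  expect_equal(back$edges$weight, set$edges$weight)
  expect_identical(back$edges$label_a, set$edges$label_a)

  html <- withr::local_tempfile(fileext = ".html")
  write_grid_html(set, html)
  expect_length(xml2::xml_find_all(xml2::read_html(html), "//tr"), 3)
})

test_that("composite rendering colors member perimeters", {
  hs <- define_custom_reference("hs", data.frame(chrom = "chr1", length_bp = 1000))
  mm <- define_custom_reference("mm", data.frame(chrom = "chr1", length_bp = 2000))
  cmp <- combine_references(list(hsa = hs, mmu = mm), colors = c("#800080", "#0000ff"))
  set <- resolve_set(parse_associations("hsa|chr1:1:10 mmu|chr1:5:15 0.5", "space"), cmp)
  x <- svg_xml(render_circular(set, cmp))
  fills <- xml2::xml_attr(
    xml2::xml_find_all(x, "//*[@class='chrom-band']/*[1]"), "fill")
  expect_identical(fills, c("#800080", "#0000ff"))
})
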