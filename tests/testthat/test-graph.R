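test_that("resolution reports mapped, unmapped and phenotype labels", {
  ref <- toy_ref()
  recs <- parse_associations(c("G7 Wnt1 0.5", "G7 chr2:10:20", "Wnt1 G7"), "space")
  set <- resolve_set(recs, ref)
  cts <- set$report$counts
  expect_equal(cts[["total"]], 3)
  expect_equal(cts[["mapped"]], 3)
  expect_equal(cts[["unmapped"]], 0)
  expect_equal(nrow(set$edges), 3)
  # edge order is input order
  expect_identical(set$edges$label_a, recs$label_a)

  pheno <- resolve_set(parse_associations("G7 obesity^PHENO", "space"), ref)
  expect_equal(pheno$report$counts[["pheno"]], 1)
  expect_equal(nrow(pheno$edges), 1)
  expect_false(pheno$edges$mapped_b)

  # partially unmapped edges are retained but flagged
  part <- resolve_set(parse_associations(c("G7 NOGENE", "G7 Wnt1"), "space"), ref)
  expect_equal(nrow(part$edges), 2)
  expect_equal(part$report$counts[["unmapped"]], 1)
  expect_identical(part$report$unmapped_labels$label, "NOGENE")

  expect_error(resolve_set(parse_associations("BOGUS1 BOGUS2", "space"), ref),
               "nothing to plot.*BOGUS")
})

test_that("weight filtering matches its predicate on known and random sets", {
  ref <- toy_ref()
  recs <- parse_associations(c("G7 Wnt1 0.5", "G7 Wnt1 -0.95", "G7 Wnt1 0.93"), "space")
  set <- resolve_set(recs, ref)
  expect_equal(nrow(filter_weight(set, "abs>=", 0.92)$edges), 2)
  expect_equal(nrow(filter_weight(set, ">=", -1e9)$edges), 3)

  # weight-less edges are dropped by any weight filter
  mixed <- resolve_set(parse_associations(c("G7 Wnt1 0.5", "G7 Wnt1"), "space"), ref)
  expect_equal(nrow(filter_weight(mixed, ">=", -1e9)$edges), 1)

  big <- resolve_set(fixture_associations(5, fixture_reference(5, n_genes = 40),
                                          n_edges = 200, positional_fraction = 0),
                     fixture_reference(5, n_genes = 40))
  ops <- c("<", "<=", ">", ">=", "==", "abs>=", "abs<=")
  for (op in ops) {
    for (t in c(-0.5, 0, 0.42)) {
      got <- filter_weight(big, op, t)$edges$weight
      oracle <- Filter(function(w) switch(op, "<" = w < t, "<=" = w <= t,
                                          ">" = w > t, ">=" = w >= t, "==" = w == t,
                                          "abs>=" = abs(w) >= t, "abs<=" = abs(w) <= t),
                       big$edges$weight[!is.na(big$edges$weight)])
      expect_equal(got, as.numeric(oracle))
    }
  }
  expect_error(filter_weight(set, "~=", 0.5), "unknown weight operator")
})

test_that("label filtering honors any/both endpoint modes", {
  ref <- attach_gene_index(
    define_custom_reference("r", data.frame(chrom = "chr1", length_bp = 1e4)),
    data.frame(label = c("A", "B", "C", "D"), chrom = "chr1",
               start = c(1, 11, 21, 31), end = c(10, 20, 30, 40)))
  set <- resolve_set(parse_associations(c("A B", "B C", "C D"), "space"), ref)
  expect_identical(filter_labels(set, "A", "any")$edges$label_a, "A")
  both <- filter_labels(set, c("B", "C"), "both")
  expect_equal(nrow(both$edges), 1)
  expect_identical(both$edges$label_a, "B")
  # membership is normalized like translation: symbols case-insensitively
  expect_equal(nrow(filter_labels(set, "a", "any")$edges), 1)
  expect_error(filter_labels(set, character(0)), "non-empty")

  rref <- fixture_reference(6, n_genes = 30)
  rnd <- resolve_set(fixture_associations(6, rref, n_edges = 200,
                                          positional_fraction = 0), rref)
  wanted <- rref$gene_index$label[seq(1, 60, by = 7)]
  for (mode in c("any", "both")) {
    got <- filter_labels(rnd, wanted, mode)$edges
    ina <- rnd$edges$label_a %in% wanted
    inb <- rnd$edges$label_b %in% wanted
    keep <- if (mode == "any") ina | inb else ina & inb
    expect_equal(got, rnd$edges[keep, ], ignore_attr = TRUE)
  }
})

test_that("filters commute and are idempotent", {
  rref <- fixture_reference(9, n_genes = 30)
  set <- resolve_set(fixture_associations(9, rref, n_edges = 300), rref)
  labels <- rref$gene_index$label[1:20]
  wl <- filter_labels(filter_weight(set, "abs>=", 0.3), labels)
  lw <- filter_weight(filter_labels(set, labels), "abs>=", 0.3)
  expect_equal(wl$edges, lw$edges)
  expect_equal(filter_weight(wl, "abs>=", 0.3)$edges, wl$edges)
  expect_equal(filter_labels(wl, labels)$edges, wl$edges)
})

test_that("the render limit truncates by input order, after filtering", {
  ref <- toy_ref()
  set <- resolve_set(parse_associations(sprintf("G7 Wnt1 0.%d", 1:5), "space"), ref)
  lim <- apply_render_limit(set, 2)
  expect_equal(lim$edges$weight, c(0.1, 0.2))
  expect_equal(apply_render_limit(set, 99)$edges, set$edges)
  expect_error(apply_render_limit(set, 0), "positive")

  # crafted case where filter-then-limit and limit-then-filter disagree:
  # weights 0.1..0.9 interleaved so the first 3 edges are all weak
  w <- c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.95)
  set10 <- resolve_set(parse_associations(sprintf("G7 Wnt1 %.2f", w), "space"), ref)
  filter_then_limit <- apply_render_limit(filter_weight(set10, ">=", 0.5), 3)
  limit_then_filter <- filter_weight(apply_render_limit(set10, 3), ">=", 0.5)
  expect_equal(filter_then_limit$edges$weight, c(0.9, 0.8, 0.7))
  expect_false(isTRUE(all.equal(filter_then_limit$edges$weight,
                                limit_then_filter$edges$weight)))
})

test_that("bundling partitions edges by window pairs and conserves counts", {
  ref <- define_custom_reference("r", data.frame(chrom = c("c1", "c2"),
                                                 length_bp = c(1e6, 1e6)))
  recs <- parse_associations(
    c("c1:100:200 c2:500:600 0.1", "c1:300:400 c2:700:800 0.2",
      "c2:550:650 c1:50:150 0.99"), "space")
  set <- resolve_set(recs, ref)
  b <- bundle_edges(set, 1000)
  # all three edges share (c1, win 1) x (c2, win 1); A-B merges with B-A
  expect_equal(nrow(b$bundles), 1)
  expect_equal(b$bundles$count, 3)

  excl <- bundle_edges(set, 1000, exclude_abs_weight_ge = 0.9)
  expect_equal(nrow(excl$passthrough), 1)
  expect_equal(sum(excl$bundles$count) + nrow(excl$passthrough), 3)

  # window 1: bundles merge only on identical midpoints
  one <- bundle_edges(set, 1)
  expect_equal(nrow(one$bundles), 3)
  expect_true(all(one$bundles$count == 1))
})

test_that("bundling matches brute-force key grouping on random sets", {
  rref <- fixture_reference(13, n_chrom = 3, n_genes = 60)
  set <- resolve_set(fixture_associations(13, rref, n_edges = 500), rref)
  window <- 250000
  b <- bundle_edges(set, window, exclude_abs_weight_ge = 0.95)

  e <- set$edges[set$edges$mapped_a & set$edges$mapped_b, ]
  expect_equal(sum(b$bundles$count) + nrow(b$passthrough), nrow(e))

  excl <- !is.na(e$weight) & abs(e$weight) >= 0.95
  keyfun <- function(ch, mid) paste0(ch, "#", ((mid - 1) %/% window) + 1)
  ka <- keyfun(e$chrom_a, e$mid_a); kb <- keyfun(e$chrom_b, e$mid_b)
  key <- paste(pmin(ka, kb), pmax(ka, kb), sep = "||")
  oracle <- sort(table(key[!excl]))
  got <- sort(stats::setNames(b$bundles$count, b$bundles$key))
  expect_equal(as.vector(got[order(names(got))]),
               as.vector(oracle[order(names(oracle))]))
  expect_identical(sort(names(got)), sort(names(oracle)))
  expect_equal(nrow(b$passthrough), sum(excl))
})

test_that("exported filtered sets re-import to the identical edge multiset", {
  rref <- fixture_reference(21, n_genes = 40)
  set <- resolve_set(fixture_associations(21, rref, n_edges = 300,
                                          positional_fraction = 0.2), rref)
  filtered <- filter_weight(set, "abs>=", 0.4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations_tsv(filtered$edges, path)
  back <- resolve_set(read_associations(path), rref)
  expect_equal(edge_multiset(back$edges), edge_multiset(filtered$edges),
               ignore_attr = TRUE)
  expect_equal(back$report$counts, filtered$report$counts)
})

test_that("tidy and glance expose the edges and the report", {
  ref <- toy_ref()
  set <- resolve_set(parse_associations("G7 Wnt1 0.5", "space"), ref)
  expect_identical(tidy(set), set$edges)
  g <- glance(set)
  expect_equal(g$edges, 1)
  expect_equal(g$mapped, 2)
})
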