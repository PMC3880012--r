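#' Generate a synthetic organism reference
#'
#' Builds a seeded random genome (chromosome count and length range of a
#' small model organism by default) plus a gene index in which every locus
#' carries three aliases - a symbol (`G0001`-style), an ENSEMBL-like
#' accession and a numeric ENTREZ-like id - so label resolution can be
#' exercised on all three branches. Identical seeds give identical
#' references.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes.
#' @param length_range Chromosome length range in bp.
#' @param n_genes Number of indexed loci (0 for an empty index).
#' @param gene_span_range Gene length range in bp.
#' @return A `genome_ref` with the gene index attached.
#' @export
fixture_reference <- function(seed, n_chrom = 3, length_range = c(1e6, 5e6),
                              n_genes = 50, gene_span_range = c(1e3, 1e4)) {
  withr::with_seed(seed, {
    lengths <- sample(seq(length_range[1], length_range[2]), n_chrom, replace = TRUE)
    chroms <- tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)), length_bp = lengths)
    if (n_genes > sum(lengths)) {
      abort("infeasible fixture: more genes requested than bases in the genome")
    }
    gi <- NULL
    if (n_genes > 0) {
      gchrom <- sample(chroms$chrom, n_genes, replace = TRUE, prob = lengths)
      glen <- pmin(sample(seq(gene_span_range[1], gene_span_range[2]), n_genes,
                          replace = TRUE),
                   chroms$length_bp[match(gchrom, chroms$chrom)])
      gstart <- floor(stats::runif(n_genes, 1,
                                   chroms$length_bp[match(gchrom, chroms$chrom)] - glen + 1))
      loci <- tibble::tibble(chrom = gchrom, start = gstart, end = gstart + glen - 1)
      gi <- dplyr::bind_rows(
        dplyr::mutate(loci, label = sprintf("G%04d", seq_len(n_genes))),
        dplyr::mutate(loci, label = sprintf("ENSTST%011d", seq_len(n_genes))),
        dplyr::mutate(loci, label = as.character(100000 + seq_len(n_genes)))
      )
    }
    ref <- define_custom_reference(paste0("fixture", seed), chroms)
    if (!is.null(gi)) ref <- attach_gene_index(ref, gi)
    ref
  })
}

#' Write a fixture reference's tables in the package file formats
#' @param ref A `genome_ref`.
#' @param dir Output directory (created if needed).
#' @return Paths of the chromosome table and gene index, invisibly.
#' @export
fixture_reference_files <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chrom_path <- file.path(dir, "chromosomes.tsv")
  writeLines(c("chrom\tlength_bp",
               sprintf("%s\t%s", ref$chromosomes$chrom,
                       format(ref$chromosomes$length_bp, scientific = FALSE, trim = TRUE))),
             chrom_path)
  index_path <- file.path(dir, "gene_index.tsv")
  gi <- ref$gene_index
  writeLines(c("label\tchrom\tstart\tend",
               sprintf("%s\t%s\t%s\t%s", gi$label, gi$chrom,
                       format(gi$start, scientific = FALSE, trim = TRUE),
                       format(gi$end, scientific = FALSE, trim = TRUE))),
             index_path)
  invisible(c(chromosomes = chrom_path, gene_index = index_path))
}

#' Generate a synthetic association set
#'
#' Samples edge endpoints from the reference's gene index (mixing symbol,
#' ENSEMBL-like and ENTREZ-like aliases, plus a configurable share of
#' positional `chr:start:end` labels) and attaches weights drawn
#' uniform(-1, 1) - emulating correlation edges - or explicit colors, or
#' phenotype (`^PHENO`) endpoints, at the requested fractions. Identical
#' seeds give identical records.
#'
#' @param seed Integer seed.
#' @param reference A `genome_ref` with a non-empty gene index (or
#'   `positional_fraction = 1`).
#' @param n_edges Number of edges.
#' @param weight_fraction Fraction of edges carrying a numeric weight.
#' @param color_fraction Fraction carrying an explicit color instead
#'   (weight and color are mutually exclusive per edge).
#' @param pheno_fraction Per-endpoint probability of being a phenotype node.
#' @param positional_fraction Per-endpoint probability of a positional label.
#' @param path Optional output file; the dialect follows its extension.
#' @return Edge record tibble (also written to `path` when given).
#' @export
fixture_associations <- function(seed, reference, n_edges = 100,
                                 weight_fraction = 1, color_fraction = 0,
                                 pheno_fraction = 0, positional_fraction = 0.1,
                                 path = NULL) {
  if (weight_fraction + color_fraction > 1) {
    abort("weight_fraction + color_fraction must be <= 1")
  }
  records <- withr::with_seed(seed, {
    gi <- reference$gene_index
    if (!nrow(gi) && positional_fraction < 1) {
      abort("reference has an empty gene index; use positional_fraction = 1")
    }
    draw_label <- function() {
      u <- stats::runif(1)
      if (u < pheno_fraction) {
        sprintf("PHENOTYPE_%03d^PHENO", sample.int(50, 1))
      } else if (u < pheno_fraction + positional_fraction * (1 - pheno_fraction)) {
        ch <- sample.int(nrow(reference$chromosomes), 1)
        len <- reference$chromosomes$length_bp[ch]
        s <- sample.int(max(len - 1000, 1), 1)
        sprintf("%s:%d:%d", reference$chromosomes$chrom[ch], s,
                min(s + sample.int(1000, 1), len))
      } else {
        gi$label[sample.int(nrow(gi), 1)]
      }
    }
    la <- replicate(n_edges, draw_label())
    lb <- replicate(n_edges, draw_label())
    u <- stats::runif(n_edges)
    weight <- ifelse(u < weight_fraction, stats::runif(n_edges, -1, 1), NA_real_)
    palette <- c("#e41a1c", "#377eb8", "#4daf4a", "#ff7f00", "#984ea3")
    color <- ifelse(is.na(weight) & u < weight_fraction + color_fraction,
                    sample(palette, n_edges, replace = TRUE), NA_character_)
    edge_tibble(la, lb, weight = weight, color = color, line = seq_len(n_edges))
  })
  if (!is.null(path)) write_associations(records, path)
  records
}

#' Generate a synthetic annotation ring
#'
#' Pairs values (or colors) with gene labels drawn from the reference's
#' index, in the annotation-ring text format.
#'
#' @param seed Integer seed.
#' @param reference A `genome_ref` with a gene index.
#' @param style `"bar"`, `"histogram"` or `"heatmap"`.
#' @param n_entries Number of entries.
#' @param colored Emit colors instead of numeric values.
#' @param path Optional output file.
#' @return An `annotation_ring`.
#' @export
fixture_ring <- function(seed, reference, style = "heatmap", n_entries = 20,
                         colored = FALSE, path = NULL) {
  lines <- withr::with_seed(seed, {
    gi <- reference$gene_index
    symbols <- unique(gi$label[grepl("^G[0-9]+$", gi$label)])
    targets <- sample(symbols, min(n_entries, length(symbols)))
    second <- if (colored) {
      sample(c("#d73027", "#fc8d59", "#91bfdb", "#4575b4"), length(targets), replace = TRUE)
    } else {
      fmt_num(round(stats::runif(length(targets), -1, 1), 3))
    }
    c(paste0("#ring ", style), paste0(targets, "\t", second))
  })
  if (!is.null(path)) writeLines(lines, path)
  parse_annotation_ring(lines)
}

#' Generate a complete correlation-study-like scenario
#'
#' An end-to-end input bundle shaped like a stem-cell copy-number /
#' expression correlation study: a multi-chromosome reference with an
#' aliased gene index, a dense set of correlation-weighted edges, four
#' annotation rings (two heatmap, two bar - emulating per-sample-group copy
#' number and expression tracks), and a pathway-like gene subset list for
#' label filtering. All pieces are deterministic in the seed and written in
#' the package's text formats when `dir` is given.
#'
#' @param seed Integer seed.
#' @param n_edges Number of edges (default 5000).
#' @param n_chrom,n_genes Genome shape.
#' @param dir Optional directory to write the scenario files into.
#' @return List: `reference`, `records`, `rings` (list of 4),
#'   `gene_set` (character), and `paths` when `dir` was given.
#' @export
fixture_scenario_fig2like <- function(seed, n_edges = 5000, n_chrom = 8,
                                      n_genes = 300, dir = NULL) {
  reference <- fixture_reference(seed, n_chrom = n_chrom,
                                 length_range = c(5e6, 2e7), n_genes = n_genes)
  records <- fixture_associations(seed + 1, reference, n_edges = n_edges,
                                  weight_fraction = 1, positional_fraction = 0.05)
  rings <- list(
    fixture_ring(seed + 2, reference, style = "heatmap", n_entries = 40),
    fixture_ring(seed + 3, reference, style = "heatmap", n_entries = 40),
    fixture_ring(seed + 4, reference, style = "bar", n_entries = 30),
    fixture_ring(seed + 5, reference, style = "bar", n_entries = 30)
  )
  gene_set <- withr::with_seed(seed + 6, {
    sort(sample(sprintf("G%04d", seq_len(n_genes)), min(40, n_genes)))
  })
  out <- list(reference = reference, records = records, rings = rings,
              gene_set = gene_set)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- fixture_reference_files(reference, dir)
    assoc_path <- file.path(dir, "associations.tsv")
    write_associations(records, assoc_path)
    ring_paths <- vapply(seq_along(rings), function(i) {
      p <- file.path(dir, sprintf("ring%d.txt", i))
      writeLines(c(paste0("#ring ", rings[[i]]$style),
                   paste0(rings[[i]]$entries$target, "\t",
                          ifelse(is.na(rings[[i]]$entries$value),
                                 rings[[i]]$entries$color,
                                 fmt_num(rings[[i]]$entries$value)))), p)
      p
    }, character(1))
    set_path <- file.path(dir, "gene_set.txt")
    writeLines(gene_set, set_path)
    out$paths <- c(paths, associations = assoc_path,
                   stats::setNames(ring_paths, paste0("ring", seq_along(ring_paths))),
                   gene_set = set_path)
  }
  out
}
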