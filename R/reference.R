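#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr %>%
NULL

ref_data_path <- function(...) {
  system.file("extdata", "references", ..., package = "arcomics", mustWork = FALSE)
}

#' Construct a genome reference object
#'
#' A genome reference holds an ordered chromosome table, an optional cytoband
#' track, and a (possibly empty) gene index mapping labels - gene symbols,
#' ENSEMBL or ENTREZ identifiers - to loci. All coordinates are 1-based and
#' inclusive: `start = end` denotes a single base.
#'
#' @param id Short identifier (e.g. `"human"`).
#' @param chromosomes Data frame with columns `chrom` (unique, non-empty) and
#'   `length_bp` (positive integers), in display order.
#' @param display_name Human-readable organism name.
#' @param species Species string.
#' @param build Genome build string.
#' @param cytobands Optional data frame `chrom, start, end, band, stain` with
#'   non-overlapping, ordered bands per chromosome.
#' @param gene_index Optional data frame `label, chrom, start, end`; multiple
#'   alias rows may point at one locus.
#' @return An object of class `genome_ref`.
#' @export
new_reference <- function(id, chromosomes, display_name = id, species = NA_character_,
                          build = NA_character_, cytobands = NULL, gene_index = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  if (!all(c("chrom", "length_bp") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns `chrom` and `length_bp`")
  }
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length_bp <- as.numeric(chromosomes$length_bp)
  bad <- which(is.na(chromosomes$length_bp) | chromosomes$length_bp < 1 |
                 chromosomes$length_bp != floor(chromosomes$length_bp) |
                 is.na(chromosomes$chrom) | !nzchar(chromosomes$chrom))
  if (length(bad)) {
    abort(paste0("invalid chromosome rows (need non-empty name, positive integer length): ",
                 paste(bad, collapse = ", ")))
  }
  dup <- chromosomes$chrom[duplicated(chromosomes$chrom)]
  if (length(dup)) {
    abort(paste0("duplicate chromosome names: ", paste(unique(dup), collapse = ", ")))
  }
  if (nrow(chromosomes) < 1) abort("a reference needs at least one chromosome")

  gene_index <- normalize_gene_index(gene_index, chromosomes)
  if (!is.null(cytobands)) {
    cytobands <- tibble::as_tibble(cytobands)
    cytobands$start <- as.numeric(cytobands$start)
    cytobands$end <- as.numeric(cytobands$end)
    check_loci(cytobands, chromosomes, what = "cytoband")
  }
  structure(
    list(id = id, display_name = display_name, species = species, build = build,
         chromosomes = chromosomes, cytobands = cytobands, gene_index = gene_index),
    class = "genome_ref"
  )
}

normalize_gene_index <- function(gene_index, chromosomes) {
  if (is.null(gene_index)) {
    return(tibble::tibble(label = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  gene_index <- tibble::as_tibble(gene_index)
  if (!all(c("label", "chrom", "start", "end") %in% names(gene_index))) {
    abort("gene index needs columns `label`, `chrom`, `start`, `end`")
  }
  gene_index$label <- stringr::str_trim(as.character(gene_index$label))
  gene_index$start <- as.numeric(gene_index$start)
  gene_index$end <- as.numeric(gene_index$end)
  check_loci(gene_index, chromosomes, what = "gene index")
  gene_index
}

check_loci <- function(df, chromosomes, what) {
  len <- stats::setNames(chromosomes$length_bp, chromosomes$chrom)
  unknown <- setdiff(unique(df$chrom), names(len))
  if (length(unknown)) {
    abort(paste0(what, " references unknown chromosomes: ", paste(unknown, collapse = ", ")))
  }
  bad <- which(df$start < 1 | df$end < df$start | df$end > len[df$chrom])
  if (length(bad)) {
    abort(paste0(what, " rows violate 1 <= start <= end <= chromosome length: row ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(df)
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %s (%s, build %s)\n", x$display_name, x$species, x$build))
  cat(sprintf("  %d chromosomes, %s bp, %d gene index entries\n",
              nrow(x$chromosomes), format(genome_length(x), big.mark = ","),
              nrow(x$gene_index)))
  invisible(x)
}

#' Total genome length of a reference, in base pairs
#' @param ref A `genome_ref`.
#' @return A number (bp).
#' @export
genome_length <- function(ref) sum(ref$chromosomes$length_bp)

#' Load the built-in organism reference catalog
#'
#' The catalog bundles chromosome length tables for ten organisms (human,
#' fly, mouse, worm, yeast, zebrafish, Arabidopsis, rice, tomato and
#' E. coli) at fixed genome builds, plus a coarse arm-level cytoband track
#' for human. Built-in references ship without genome-scale gene indexes;
#' attach one with [attach_gene_index()] or [read_gene_index()].
#'
#' @return A named list of [new_reference()] objects, in catalog order.
#' @export
#' @examples
#' refs <- load_catalog()
#' names(refs)
#' refs$yeast$build
load_catalog <- function() {
  path <- ref_data_path("catalog.tsv")
  if (!file.exists(path)) abort("bundled reference catalog not found: catalog.tsv")
  cat_tbl <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  refs <- purrr::pmap(cat_tbl, function(id, display_name, species, build, file, cytoband_file) {
    chrom_path <- ref_data_path(file)
    chroms <- tryCatch(
      utils::read.delim(chrom_path, stringsAsFactors = FALSE),
      error = function(e) abort(paste0("corrupted bundled reference table: ", file))
    )
    if (!all(c("chrom", "length_bp") %in% names(chroms))) {
      abort(paste0("corrupted bundled reference table: ", file))
    }
    cyto <- NULL
    if (nzchar(cytoband_file)) {
      cyto <- utils::read.delim(ref_data_path(cytoband_file), stringsAsFactors = FALSE)
    }
    new_reference(id, chroms, display_name = display_name, species = species,
                  build = build, cytobands = cyto)
  })
  stats::setNames(refs, cat_tbl$id)
}

#' Fetch one built-in reference by id
#' @param id Catalog id, e.g. `"human"` or `"yeast"`.
#' @return A `genome_ref`.
#' @export
get_reference <- function(id) {
  refs <- load_catalog()
  if (!id %in% names(refs)) {
    abort(paste0("unknown organism id '", id, "'; available: ",
                 paste(names(refs), collapse = ", ")))
  }
  refs[[id]]
}

#' Define a custom organism reference from a chromosome table
#'
#' Lets unsupported organisms, single contigs (e.g. an organelle genome) or
#' subsets of an existing genome be plotted: only chromosome names and base
#' lengths are required.
#'
#' @param name Reference name (used as id and display name).
#' @param chrom_table Data frame with columns `chrom` and `length_bp`, or a
#'   two-column data frame coerced positionally.
#' @return A `genome_ref` with an empty gene index and no cytobands.
#' @export
#' @examples
#' define_custom_reference("plasmid", data.frame(chrom = "p1", length_bp = 5000))
define_custom_reference <- function(name, chrom_table) {
  chrom_table <- tibble::as_tibble(chrom_table)
  if (!all(c("chrom", "length_bp") %in% names(chrom_table)) && ncol(chrom_table) >= 2) {
    names(chrom_table)[1:2] <- c("chrom", "length_bp")
  }
  new_reference(name, chrom_table, display_name = name, build = "custom")
}

#' Read a custom organism definition file
#'
#' Expects tab-delimited `chrom<TAB>length_bp` rows; a header line is
#' optional and `#` comments are skipped.
#' @param path File path.
#' @param name Reference name; defaults to the file stem.
#' @return A `genome_ref`.
#' @export
read_custom_reference <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines)) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^chrom\\b", lines[[1]])) lines <- lines[-1]
  parts <- stringr::str_split(lines, "\t")
  bad <- which(lengths(parts) < 2)
  if (length(bad)) abort(paste0("malformed organism file line ", bad[[1]], " in ", path))
  tbl <- tibble::tibble(chrom = purrr::map_chr(parts, 1),
                        length_bp = suppressWarnings(as.numeric(purrr::map_chr(parts, 2))))
  define_custom_reference(name, tbl)
}

#' Read a gene index table
#'
#' Format: tab-delimited `label<TAB>chrom<TAB>start<TAB>end`, one row per
#' alias (so a locus may carry a symbol, an ENSEMBL id and an ENTREZ id on
#' three rows). Coordinates are 1-based inclusive.
#' @param path File path.
#' @return A tibble suitable for [attach_gene_index()].
#' @export
read_gene_index <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(stringr::str_trim(lines)) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^label\\b", lines[[1]])) lines <- lines[-1]
  parts <- stringr::str_split(lines, "\t")
  bad <- which(lengths(parts) < 4)
  if (length(bad)) abort(paste0("malformed gene index line ", bad[[1]], " in ", path))
  tibble::tibble(
    label = purrr::map_chr(parts, 1),
    chrom = purrr::map_chr(parts, 2),
    start = as.numeric(purrr::map_chr(parts, 3)),
    end = as.numeric(purrr::map_chr(parts, 4))
  )
}

#' Attach a gene index to a reference
#' @param ref A `genome_ref`.
#' @param gene_index Data frame `label, chrom, start, end` (validated against
#'   the reference's chromosomes).
#' @return The reference with the index attached.
#' @export
attach_gene_index <- function(ref, gene_index) {
  ref$gene_index <- normalize_gene_index(gene_index, ref$chromosomes)
  ref
}

#' Join references into a composite multi-organism reference
#'
#' Places two or more genomes on one circle for between-organism association
#' plots (orthologs, phenologs, strain comparisons). Member chromosomes are
#' renamed `<prefix>.<chrom>`; node labels may use `<prefix>|<label>` to
#' restrict resolution to one member, and un-prefixed labels resolve against
#' members in order (first hit wins).
#'
#' @param members Named list of `genome_ref` objects; names become prefixes.
#' @param colors Perimeter color per member (recycled if length 1); used for
#'   the chromosome bands in the circular view.
#' @return An object of class `composite_ref` (also a `genome_ref`).
#' @export
#' @examples
#' hs <- define_custom_reference("hs", data.frame(chrom = "chr1", length_bp = 1e6))
#' mm <- define_custom_reference("mm", data.frame(chrom = "chr1", length_bp = 2e6))
#' cmp <- combine_references(list(hsa = hs, mmu = mm), colors = c("purple", "blue"))
#' cmp$chromosomes$chrom
combine_references <- function(members, colors = grDevices::palette()[seq_along(members)]) {
  if (length(members) < 2) abort("a composite reference needs at least two members")
  prefixes <- names(members)
  if (is.null(prefixes) || any(!nzchar(prefixes))) {
    abort("`members` must be a named list; names are the member prefixes")
  }
  if (anyDuplicated(prefixes)) {
    abort(paste0("duplicate member prefixes: ",
                 paste(unique(prefixes[duplicated(prefixes)]), collapse = ", ")))
  }
  colors <- rep_len(colors, length(members))
  chroms <- purrr::map2_dfr(members, prefixes, function(ref, pfx) {
    dplyr::mutate(ref$chromosomes, chrom = paste0(pfx, ".", .data$chrom))
  })
  gi <- purrr::map2_dfr(members, prefixes, function(ref, pfx) {
    if (!nrow(ref$gene_index)) return(NULL)
    dplyr::mutate(ref$gene_index, chrom = paste0(pfx, ".", .data$chrom), member = pfx)
  })
  ref <- new_reference(
    id = paste(prefixes, collapse = "+"),
    chromosomes = chroms,
    display_name = paste(purrr::map_chr(members, "display_name"), collapse = " + "),
    build = "composite"
  )
  if (!is.null(gi) && nrow(gi)) ref$gene_index <- gi
  ref$members <- tibble::tibble(prefix = prefixes, color = colors,
                                id = purrr::map_chr(members, "id"))
  ref$member_refs <- stats::setNames(members, prefixes)
  class(ref) <- c("composite_ref", class(ref))
  ref
}

#' Parse a positional node label of the form `chr:start:end`
#'
#' @param label The label string. Coordinates are 1-based inclusive;
#'   `start = end` denotes a single base.
#' @return A one-row tibble `chrom, start, end`.
#' @export
#' @examples
#' parse_position_label("chr12:100:200")
parse_position_label <- function(label) {
  label <- stringr::str_trim(label)
  m <- stringr::str_match(label, "^(.+):([0-9]+):([0-9]+)$")
  if (is.na(m[1, 1])) {
    abort(paste0("malformed positional label (want chr:start:end): '", label, "'"))
  }
  start <- as.numeric(m[1, 3]); end <- as.numeric(m[1, 4])
  if (start < 1) abort(paste0("positional label start must be >= 1 (1-based): '", label, "'"))
  if (start > end) abort(paste0("positional label has start > end: '", label, "'"))
  tibble::tibble(chrom = m[1, 2], start = start, end = end)
}

is_position_label <- function(label) {
  stringr::str_detect(label, "^.+:[0-9]+:[0-9]+$")
}

# Identifier-style labels (ENSEMBL accessions, numeric ENTREZ ids) are matched
# verbatim; everything else is treated as a gene symbol and matched
# case-insensitively.
is_idlike <- function(label) {
  stringr::str_detect(label, "^ENS[A-Z0-9]+$") | stringr::str_detect(label, "^[0-9]+$")
}

unmapped_row <- function(reason) {
  tibble::tibble(chrom = NA_character_, start = NA_real_, end = NA_real_,
                 mapped = FALSE, reason = reason, n_hits = 0L)
}

mapped_row <- function(chrom, start, end, n_hits = 1L) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 mapped = TRUE, reason = NA_character_, n_hits = n_hits)
}

lookup_gene <- function(label, gene_index) {
  hit <- which(gene_index$label == label)
  if (!length(hit) && !is_idlike(label)) {
    # symbols fold case; accession/numeric ids only ever match verbatim
    hit <- which(tolower(gene_index$label) == tolower(label) &
                   !is_idlike(gene_index$label))
  }
  hit
}

#' Translate a node label to a genomic locus
#'
#' Resolution order: positional `chr:start:end` syntax first, then exact gene
#' index lookup, then case-insensitive symbol lookup. On a composite
#' reference a `<prefix>|<label>` form restricts lookup to that member;
#' un-prefixed labels try members in order and the first hit wins. The
#' function never raises for an unresolvable label - it reports it as
#' unmapped with a reason.
#'
#' @param label A single label.
#' @param ref A `genome_ref` or `composite_ref`.
#' @return A one-row tibble `chrom, start, end, mapped, reason, n_hits`;
#'   `n_hits > 1` flags a label found in several composite members.
#' @export
translate_label <- function(label, ref) {
  label <- stringr::str_trim(label)
  if (!nzchar(label)) return(unmapped_row("empty label"))

  member_pfx <- NULL
  if (inherits(ref, "composite_ref") && stringr::str_detect(label, stringr::fixed("|"))) {
    parts <- stringr::str_split_fixed(label, stringr::fixed("|"), 2)
    member_pfx <- parts[1, 1]
    label <- stringr::str_trim(parts[1, 2])
    if (!member_pfx %in% ref$members$prefix) {
      return(unmapped_row(paste0("unknown member prefix '", member_pfx, "'")))
    }
  }

  if (is_position_label(label)) {
    loc <- tryCatch(parse_position_label(label), error = function(e) NULL)
    if (is.null(loc)) return(unmapped_row("malformed positional label"))
    chrom <- loc$chrom
    if (!is.null(member_pfx)) chrom <- paste0(member_pfx, ".", chrom)
    if (!chrom %in% ref$chromosomes$chrom && inherits(ref, "composite_ref") &&
        is.null(member_pfx)) {
      # un-prefixed position on a composite: first member whose chromosome fits it
      fallback <- NULL
      for (pfx in ref$members$prefix) {
        cand <- paste0(pfx, ".", loc$chrom)
        at <- match(cand, ref$chromosomes$chrom)
        if (!is.na(at)) {
          fallback <- fallback %||% cand
          if (loc$end <= ref$chromosomes$length_bp[at]) { chrom <- cand; break }
        }
      }
      if (!chrom %in% ref$chromosomes$chrom && !is.null(fallback)) chrom <- fallback
    }
    if (!chrom %in% ref$chromosomes$chrom) return(unmapped_row("unknown chromosome"))
    len <- ref$chromosomes$length_bp[match(chrom, ref$chromosomes$chrom)]
    if (loc$end > len) return(unmapped_row("position beyond chromosome end"))
    return(mapped_row(chrom, loc$start, loc$end))
  }

  gi <- ref$gene_index
  if (!is.null(member_pfx)) gi <- gi[gi$member == member_pfx, , drop = FALSE]
  if (!nrow(gi)) return(unmapped_row("label not in gene index"))
  hit <- lookup_gene(label, gi)
  if (!length(hit)) return(unmapped_row("label not in gene index"))
  n_hits <- if ("member" %in% names(gi)) length(unique(gi$member[hit])) else 1L
  mapped_row(gi$chrom[hit[[1]]], gi$start[hit[[1]]], gi$end[hit[[1]]], n_hits = n_hits)
}

#' Translate many labels at once
#' @param labels Character vector of labels.
#' @param ref A `genome_ref`.
#' @return A tibble with one row per label (column `label` first), in input
#'   order.
#' @export
translate_labels <- function(labels, ref) {
  res <- purrr::map_dfr(labels, translate_label, ref = ref)
  dplyr::bind_cols(tibble::tibble(label = as.character(labels)), res)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # accepts both \n and \r\n endings
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}
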