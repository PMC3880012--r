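SOURCE_TYPES <- c("GENO", "GEXP", "PROT", "PHENO")

#' Map a file name to its edge-list dialect
#'
#' Extensions map to delimiters: `.txt` space, `.tsv` tab, `.csv` comma, and
#' `.sif` the Simple Interaction Format (extended with an optional trailing
#' weight-or-color column).
#'
#' @param filename File name or path.
#' @return A list with `name`, `delimiter` (regex) and `supports_multi_target`.
#' @export
#' @examples
#' detect_dialect("net.tsv")$name
detect_dialect <- function(filename) {
  ext <- tolower(sub("^.*\\.", "", basename(filename)))
  dialects <- list(
    txt = list(name = "space", delimiter = "[ ]+", supports_multi_target = FALSE),
    tsv = list(name = "tab", delimiter = "\t", supports_multi_target = FALSE),
    csv = list(name = "comma", delimiter = ",", supports_multi_target = FALSE),
    sif = list(name = "sif", delimiter = "[ \t]+", supports_multi_target = TRUE)
  )
  if (!ext %in% names(dialects)) {
    abort(paste0("unsupported extension '.", ext,
                 "'; supported: .txt (space), .tsv (tab), .csv (comma), .sif"))
  }
  dialects[[ext]]
}

#' Is a string an HTML-style color?
#'
#' Accepts `#rgb` / `#rrggbb` hex forms and named colors
#' (`grDevices::colors()`).
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_color_string <- function(x) {
  hex <- stringr::str_detect(x, "^#([0-9a-fA-F]{3}|[0-9a-fA-F]{6})$")
  named <- tolower(x) %in% grDevices::colors()
  hex | named
}

# strips an optional ^TYPE source-type suffix off a node label
split_type <- function(labels) {
  m <- stringr::str_match(labels, "^(.*)\\^([A-Za-z]+)$")
  type <- toupper(m[, 3])
  ok <- !is.na(type) & type %in% SOURCE_TYPES
  tibble::tibble(label = ifelse(ok, m[, 2], labels),
                 type = ifelse(ok, type, NA_character_))
}

edge_tibble <- function(label_a, label_b, relation = NA_character_,
                        weight = NA_real_, color = NA_character_, line = NA_integer_) {
  a <- split_type(label_a); b <- split_type(label_b)
  tibble::tibble(
    label_a = a$label, type_a = a$type,
    label_b = b$label, type_b = b$type,
    relation = relation, weight = weight, color = color, line = line
  )
}

empty_edges <- function() edge_tibble(character(), character())[0, ]

strip_skipped <- function(lines) {
  keep <- nzchar(stringr::str_trim(lines)) & !startsWith(stringr::str_trim(lines), "#")
  tibble::tibble(line = seq_along(lines), text = lines)[keep, ]
}

#' Parse delimited association records
#'
#' Each data line carries `labelA<delim>labelB[<delim>weight-or-color]`. The
#' optional third field is taken as a numeric weight when it parses as a real
#' number and as a color string otherwise. Blank lines and `#` comments are
#' skipped. Node labels may carry a `^TYPE` source-type suffix with TYPE in
#' GENO, GEXP, PROT, PHENO.
#'
#' @param lines Character vector of file lines.
#' @param dialect A dialect from [detect_dialect()] (or one of `"space"`,
#'   `"tab"`, `"comma"`).
#' @return A tibble of edge records (`label_a, type_a, label_b, type_b,
#'   relation, weight, color, line`).
#' @export
parse_associations <- function(lines, dialect) {
  if (is.character(dialect)) {
    dialect <- detect_dialect(paste0("x.", c(space = "txt", tab = "tsv", comma = "csv",
                                             sif = "sif")[[dialect]]))
  }
  if (isTRUE(dialect$supports_multi_target)) return(parse_sif(lines))
  kept <- strip_skipped(lines)
  if (!nrow(kept)) return(empty_edges())
  recs <- purrr::map2_dfr(kept$text, kept$line, function(text, lineno) {
    fields <- stringr::str_trim(stringr::str_split_1(stringr::str_trim(text),
                                                     dialect$delimiter))
    if (length(fields) < 2 || length(fields) > 3) {
      abort(paste0("line ", lineno, ": expected 2 or 3 fields, got ", length(fields)))
    }
    w <- NA_real_; col <- NA_character_
    if (length(fields) == 3) {
      num <- suppressWarnings(as.numeric(fields[[3]]))
      if (!is.na(num)) w <- num else col <- fields[[3]]
    }
    edge_tibble(fields[[1]], fields[[2]], weight = w, color = col, line = lineno)
  })
  recs
}

#' Parse (extended) Simple Interaction Format
#'
#' Plain SIF lines `A rel B [C D ...]` expand to one record per target, all
#' sharing the relation. The extended dialect allows a fourth field on
#' three-node lines: a real number is read as an edge weight, a recognized
#' HTML color (hex or named) as an edge color, and anything else as a second
#' target. Multi-target lines cannot carry weights or colors.
#'
#' @param lines Character vector of file lines.
#' @return A tibble of edge records.
#' @export
parse_sif <- function(lines) {
  kept <- strip_skipped(lines)
  if (!nrow(kept)) return(empty_edges())
  purrr::map2_dfr(kept$text, kept$line, function(text, lineno) {
    fields <- stringr::str_split_1(stringr::str_trim(text), "[ \t]+")
    if (length(fields) < 3) {
      abort(paste0("line ", lineno, ": SIF needs at least `source relation target`"))
    }
    src <- fields[[1]]; rel <- fields[[2]]; rest <- fields[-(1:2)]
    if (length(rest) == 2) {
      num <- suppressWarnings(as.numeric(rest[[2]]))
      if (!is.na(num)) {
        return(edge_tibble(src, rest[[1]], relation = rel, weight = num, line = lineno))
      }
      if (is_color_string(rest[[2]])) {
        return(edge_tibble(src, rest[[1]], relation = rel, color = rest[[2]], line = lineno))
      }
    }
    purrr::map_dfr(rest, function(tgt) edge_tibble(src, tgt, relation = rel, line = lineno))
  })
}

#' Parse an inline edge declaration string
#'
#' A compact form for small networks: semicolon-separated items
#' `A,B[,weight-or-color]`, e.g. `"TP53,MDM2,0.9;TP53,EGFR"`.
#'
#' @param decl Declaration string; empty yields zero records.
#' @return A tibble of edge records.
#' @export
parse_inline_edges <- function(decl) {
  decl <- stringr::str_trim(decl)
  if (!nzchar(decl)) return(empty_edges())
  items <- stringr::str_split_1(decl, ";")
  items <- items[nzchar(stringr::str_trim(items))]
  purrr::imap_dfr(items, function(item, i) {
    fields <- stringr::str_trim(stringr::str_split_1(item, ","))
    if (length(fields) < 2 || length(fields) > 3) {
      abort(paste0("inline edge item ", i, " ('", item, "'): expected 2 or 3 fields"))
    }
    w <- NA_real_; col <- NA_character_
    if (length(fields) == 3) {
      num <- suppressWarnings(as.numeric(fields[[3]]))
      if (!is.na(num)) w <- num else col <- fields[[3]]
    }
    edge_tibble(fields[[1]], fields[[2]], weight = w, color = col, line = i)
  })
}

#' Read an association file, detecting the dialect from its extension
#' @param path Path to a `.txt`, `.tsv`, `.csv` or `.sif` file.
#' @return A tibble of edge records.
#' @export
read_associations <- function(path) {
  dialect <- detect_dialect(path)
  parse_associations(read_text_lines(path), dialect)
}

#' Parse an annotation ring file
#'
#' Format: a header line `#ring <style>` with style one of `bar`,
#' `histogram`, `heatmap`, followed by tab-delimited `target<TAB>value` or
#' `target<TAB>color` lines. Targets are gene labels or positional
#' `chr:start:end` segments; they are resolved against the active reference
#' at render time. A ring is either value-typed or color-typed - mixing the
#' two is an error.
#'
#' @param lines Character vector of file lines.
#' @return An `annotation_ring` object: list with `style` and an `entries`
#'   tibble (`target, value, color`).
#' @export
parse_annotation_ring <- function(lines) {
  trimmed <- stringr::str_trim(lines)
  nonblank <- which(nzchar(trimmed))
  if (!length(nonblank)) abort("annotation ring file is empty")
  header <- trimmed[nonblank[[1]]]
  m <- stringr::str_match(header, "^#ring[ \t]+([A-Za-z]+)$")
  if (is.na(m[1, 1])) abort("annotation ring must start with a '#ring <style>' header")
  style <- tolower(m[1, 2])
  if (!style %in% c("bar", "histogram", "heatmap")) {
    abort(paste0("unknown ring style '", style, "'; supported: bar, histogram, heatmap"))
  }
  body <- lines[-seq_len(nonblank[[1]])]
  kept <- strip_skipped(body)
  if (!nrow(kept)) abort("annotation ring has no entries")
  entries <- purrr::map2_dfr(kept$text, kept$line, function(text, lineno) {
    fields <- stringr::str_trim(stringr::str_split_1(text, "\t"))
    if (length(fields) != 2) {
      abort(paste0("ring entry line ", lineno, ": expected `target<TAB>value-or-color`"))
    }
    if (is_position_label(fields[[1]])) parse_position_label(fields[[1]])  # validates coords
    num <- suppressWarnings(as.numeric(fields[[2]]))
    tibble::tibble(target = fields[[1]],
                   value = num,
                   color = ifelse(is.na(num), fields[[2]], NA_character_))
  })
  has_val <- !is.na(entries$value); has_col <- !is.na(entries$color)
  if (any(has_val) && any(has_col)) {
    abort("annotation ring mixes numeric values and colors; use one kind per ring")
  }
  structure(list(style = style, entries = entries), class = "annotation_ring")
}

#' @rdname parse_annotation_ring
#' @param path Path to a ring file.
#' @export
read_annotation_ring <- function(path) parse_annotation_ring(read_text_lines(path))

# decimal rendering that survives a parse round trip exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- format(v, digits = 15, scientific = FALSE)
    if (as.numeric(s) != v) s <- format(v, digits = 17, scientific = FALSE)
    s
  }, character(1))
}

label_with_type <- function(label, type) {
  ifelse(is.na(type), label, paste0(label, "^", type))
}

#' Write edge records as tab-separated text
#'
#' The output (`labelA<TAB>labelB[<TAB>weight-or-color]`) is itself a valid
#' `.tsv` association input, so exported filtered sets can be re-imported
#' directly; `parse(write(x))` preserves the edge multiset.
#'
#' @param records Edge record tibble (from the parsers or [tidy()] on an
#'   association set).
#' @param path Output path; omit to return the lines invisibly.
#' @return The written lines, invisibly.
#' @export
write_associations_tsv <- function(records, path = NULL) {
  third <- ifelse(!is.na(records$weight), fmt_num(records$weight),
                  ifelse(!is.na(records$color), records$color, ""))
  lines <- c("# labelA\tlabelB\tweight_or_color",
             sprintf("%s\t%s%s",
                     label_with_type(records$label_a, records$type_a),
                     label_with_type(records$label_b, records$type_b),
                     ifelse(nzchar(third), paste0("\t", third), "")))
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Write edge records choosing the dialect from the file extension
#'
#' `.txt`/`.tsv`/`.csv` emit delimited `labelA labelB [weight-or-color]`
#' lines; `.sif` delegates to [write_network_sif()].
#' @inheritParams write_associations_tsv
#' @param path Output path with a supported extension.
#' @return The written lines, invisibly.
#' @export
write_associations <- function(records, path) {
  dialect <- detect_dialect(path)
  if (dialect$name == "sif") return(write_network_sif(records, path))
  delim <- c(space = " ", tab = "\t", comma = ",")[[dialect$name]]
  third <- ifelse(!is.na(records$weight), fmt_num(records$weight),
                  ifelse(!is.na(records$color), records$color, ""))
  lines <- sprintf("%s%s%s%s",
                   label_with_type(records$label_a, records$type_a), delim,
                   label_with_type(records$label_b, records$type_b),
                   ifelse(nzchar(third), paste0(delim, third), ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Write edge records as (extended) SIF
#'
#' One `source relation target [weight-or-color]` line per record; records
#' without a relation get the default relation `assoc`. Output re-parses to
#' the same edge multiset.
#'
#' @inheritParams write_associations_tsv
#' @return The written lines, invisibly.
#' @export
write_network_sif <- function(records, path = NULL) {
  rel <- ifelse(is.na(records$relation), "assoc", records$relation)
  fourth <- ifelse(!is.na(records$weight), fmt_num(records$weight),
                   ifelse(!is.na(records$color), records$color, ""))
  lines <- sprintf("%s\t%s\t%s%s",
                   label_with_type(records$label_a, records$type_a), rel,
                   label_with_type(records$label_b, records$type_b),
                   ifelse(nzchar(fourth), paste0("\t", fourth), ""))
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}
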