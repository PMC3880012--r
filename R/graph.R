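WEIGHT_OPS <- c("<", "<=", ">", ">=", "==", "abs>=", "abs<=")

node_cols <- function(side) paste0(c("chrom_", "start_", "end_", "mid_", "mapped_", "reason_"), side)

#' Resolve parsed edge records against a reference
#'
#' Translates every distinct node label once (positional syntax, then gene
#' index), attaches loci and locus midpoints to both endpoints of each edge,
#' and compiles a mapping report. Edges with an unresolvable non-phenotype
#' endpoint are retained in the set - they still appear in grid/text exports
#' - but are excluded from circular geometry. Endpoints tagged `^PHENO` are
#' phenotype nodes: they carry no genomic position by design and are drawn
#' as outer glyph ticks at their mapped partner's angle.
#'
#' @param records Edge record tibble from the `assoc_io` parsers.
#' @param reference A `genome_ref` or `composite_ref`.
#' @return An `assoc_set`: list with `edges` (input order preserved),
#'   `report` (label counts and unmapped listing), `ref_id`, `provenance`.
#' @export
#' @examples
#' ref <- define_custom_reference("toy", data.frame(chrom = "chr1", length_bp = 1000))
#' recs <- parse_inline_edges("chr1:10:20,chr1:500:600,0.8")
#' resolve_set(recs, ref)$report$counts
resolve_set <- function(records, reference) {
  records <- tibble::as_tibble(records)
  if (!nrow(records)) abort("nothing to plot: the association set is empty")
  labels <- unique(c(records$label_a, records$label_b))
  loci <- translate_labels(labels, reference)

  attach_side <- function(df, side) {
    idx <- match(df[[paste0("label_", side)]], loci$label)
    pheno <- !is.na(df[[paste0("type_", side)]]) & df[[paste0("type_", side)]] == "PHENO"
    out <- df
    out[[paste0("chrom_", side)]] <- ifelse(pheno, NA_character_, loci$chrom[idx])
    out[[paste0("start_", side)]] <- ifelse(pheno, NA_real_, loci$start[idx])
    out[[paste0("end_", side)]] <- ifelse(pheno, NA_real_, loci$end[idx])
    out[[paste0("mapped_", side)]] <- !pheno & loci$mapped[idx]
    out[[paste0("reason_", side)]] <- dplyr::case_when(
      pheno ~ "phenotype node (unmapped by design)",
      loci$mapped[idx] ~ NA_character_,
      TRUE ~ loci$reason[idx]
    )
    out[[paste0("mid_", side)]] <- floor((out[[paste0("start_", side)]] +
                                            out[[paste0("end_", side)]]) / 2)
    out
  }
  edges <- attach_side(attach_side(records, "a"), "b")

  set <- structure(
    list(edges = edges, report = NULL, ref_id = reference$id, provenance = character()),
    class = "assoc_set"
  )
  set$report <- build_report(set)
  ambiguous <- loci$label[loci$n_hits > 1]
  if (length(ambiguous)) {
    set$report$ambiguous_labels <- ambiguous
    warn(paste0("labels found in more than one composite member (first hit used): ",
                paste(utils::head(ambiguous, 5), collapse = ", ")))
  }
  if (set$report$counts[["drawable_edges"]] == 0) {
    top <- utils::head(set$report$unmapped_labels$label, 5)
    abort(paste0("nothing to plot: no edge has two resolvable endpoints; top unmapped labels: ",
                 paste(top, collapse = ", ")))
  }
  set
}

build_report <- function(set) {
  e <- set$edges
  nodes <- tibble::tibble(
    label = c(e$label_a, e$label_b),
    type = c(e$type_a, e$type_b),
    mapped = c(e$mapped_a, e$mapped_b),
    reason = c(e$reason_a, e$reason_b)
  )
  per_label <- nodes %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(mapped = any(.data$mapped),
                     pheno = any(!is.na(.data$type) & .data$type == "PHENO"),
                     reason = .data$reason[!is.na(.data$reason)][1],
                     .groups = "drop")
  drawable <- sum((e$mapped_a & e$mapped_b) |
                    (e$mapped_a & !is.na(e$type_b) & e$type_b == "PHENO") |
                    (e$mapped_b & !is.na(e$type_a) & e$type_a == "PHENO"))
  counts <- c(
    total = nrow(per_label),
    mapped = sum(per_label$mapped),
    unmapped = sum(!per_label$mapped),
    pheno = sum(per_label$pheno),
    edges = nrow(e),
    drawable_edges = drawable,
    self_edges = sum(e$label_a == e$label_b),
    duplicate_edges = sum(duplicated(cbind(pmin(e$label_a, e$label_b),
                                           pmax(e$label_a, e$label_b))))
  )
  list(counts = counts,
       unmapped_labels = per_label[!per_label$mapped, c("label", "reason")])
}

refresh <- function(set, edges, note) {
  amb <- set$report$ambiguous_labels
  set$edges <- edges
  set$provenance <- c(set$provenance, note)
  set$report <- build_report(set)
  if (!is.null(amb)) set$report$ambiguous_labels <- amb
  set
}

weight_predicate <- function(op) {
  if (!op %in% WEIGHT_OPS) {
    abort(paste0("unknown weight operator '", op, "'; supported: ",
                 paste(WEIGHT_OPS, collapse = ", ")))
  }
  switch(op,
         "<" = function(w, t) w < t,
         "<=" = function(w, t) w <= t,
         ">" = function(w, t) w > t,
         ">=" = function(w, t) w >= t,
         "==" = function(w, t) w == t,
         "abs>=" = function(w, t) abs(w) >= t,
         "abs<=" = function(w, t) abs(w) <= t)
}

#' Filter edges by association weight
#'
#' Keeps edges whose weight satisfies `op threshold`. Operators: `<`, `<=`,
#' `>`, `>=`, `==`, `abs>=`, `abs<=` (the absolute-value forms suit signed
#' correlations). Edges without a numeric weight are dropped by weight
#' filters. Edge order is preserved and the mapping report is recomputed.
#' Filters always act on the full association set, never on a
#' render-truncated view.
#'
#' @param set An `assoc_set`.
#' @param op Operator string.
#' @param threshold Numeric threshold.
#' @return The filtered `assoc_set`.
#' @export
filter_weight <- function(set, op, threshold) {
  pred <- weight_predicate(op)
  keep <- !is.na(set$edges$weight) & pred(set$edges$weight, threshold)
  refresh(set, set$edges[keep, , drop = FALSE],
          paste0("weight ", op, " ", format(threshold)))
}

norm_label <- function(x) {
  x <- stringr::str_trim(x)
  ifelse(is_idlike(x), x, tolower(x))
}

#' Filter edges by a gene label set
#'
#' Keeps edges touching a supplied label list (e.g. a pathway's members).
#' Labels are normalized as in [translate_label()] (symbols
#' case-insensitive, identifiers verbatim). Mode `"any"` keeps edges with at
#' least one endpoint in the set; `"both"` requires both endpoints.
#'
#' @param set An `assoc_set`.
#' @param labels Character vector of labels; must be non-empty (an empty
#'   vector is an error, to distinguish it from "no filter").
#' @param mode `"any"` (default) or `"both"`.
#' @return The filtered `assoc_set`.
#' @export
filter_labels <- function(set, labels, mode = c("any", "both")) {
  mode <- match.arg(mode)
  labels <- labels[nzchar(stringr::str_trim(labels))]
  if (!length(labels)) abort("label filter needs a non-empty label set")
  wanted <- unique(norm_label(labels))
  in_a <- norm_label(set$edges$label_a) %in% wanted
  in_b <- norm_label(set$edges$label_b) %in% wanted
  keep <- if (mode == "any") in_a | in_b else in_a & in_b
  refresh(set, set$edges[keep, , drop = FALSE],
          paste0("labels[", mode, "] n=", length(wanted)))
}

#' Truncate a set to its first n edges (render limit)
#'
#' Dense genome-wide sets overwhelm a circular plot, so rendering caps the
#' number of drawn curves (default 2000). The cap is a pure view-layer
#' truncation applied after all filters - filters themselves always see the
#' full set - and keeps the first `n` edges in input order.
#'
#' @param set An `assoc_set`.
#' @param n Positive integer limit.
#' @return An `assoc_set` holding the first `n` edges.
#' @export
apply_render_limit <- function(set, n = 2000) {
  if (!is.numeric(n) || n < 1) abort("render limit must be a positive integer")
  if (nrow(set$edges) <= n) return(set)
  refresh(set, utils::head(set$edges, n), paste0("render-limit ", n))
}

window_index <- function(mid, window_bp) ((mid - 1) %/% window_bp) + 1

#' Bundle edges into fixed genomic windows
#'
#' De-clutters dense plots by merging edges whose endpoint midpoints fall in
#' the same pair of genomic windows. Each chromosome is partitioned into
#' consecutive windows of `window_bp` starting at base 1; an edge's bundle
#' key is the unordered pair of its endpoint (chromosome, window index)
#' cells, so A-B and B-A edges merge. Only edges with both endpoints mapped
#' participate. With `exclude_abs_weight_ge`, strongly weighted edges
#' (|weight| at or above the threshold) skip bundling and are returned
#' individually as passthrough.
#'
#' @param set An `assoc_set`.
#' @param window_bp Window width in base pairs (>= 1).
#' @param exclude_abs_weight_ge Optional |weight| threshold exempting edges
#'   from bundling.
#' @return A list of class `edge_bundles`: `bundles` (one row per bundle
#'   with endpoint cells, `count`, and member rows as a list column),
#'   `passthrough` (edge tibble), `window_bp`.
#' @export
bundle_edges <- function(set, window_bp, exclude_abs_weight_ge = NULL) {
  if (!is.numeric(window_bp) || window_bp < 1) abort("window_bp must be >= 1")
  e <- set$edges[set$edges$mapped_a & set$edges$mapped_b, , drop = FALSE]
  excl <- if (is.null(exclude_abs_weight_ge)) rep(FALSE, nrow(e)) else
    !is.na(e$weight) & abs(e$weight) >= exclude_abs_weight_ge
  pass <- e[excl, , drop = FALSE]
  el <- e[!excl, , drop = FALSE]
  if (nrow(el)) {
    cell_a <- paste0(el$chrom_a, "#", window_index(el$mid_a, window_bp))
    cell_b <- paste0(el$chrom_b, "#", window_index(el$mid_b, window_bp))
    key <- paste(pmin(cell_a, cell_b), pmax(cell_a, cell_b), sep = "||")
    bundles <- tibble::tibble(key = key, cell_1 = pmin(cell_a, cell_b),
                              cell_2 = pmax(cell_a, cell_b),
                              row = seq_len(nrow(el))) %>%
      dplyr::group_by(.data$key, .data$cell_1, .data$cell_2) %>%
      dplyr::summarise(count = dplyr::n(), rows = list(.data$row), .groups = "drop") %>%
      dplyr::arrange(.data$key)
    bundles$members <- purrr::map(bundles$rows, ~ el[.x, , drop = FALSE])
    bundles$rows <- NULL
    split_cell <- function(cell) {
      m <- stringr::str_match(cell, "^(.*)#([0-9]+)$")
      list(chrom = m[, 2], win = as.numeric(m[, 3]))
    }
    c1 <- split_cell(bundles$cell_1); c2 <- split_cell(bundles$cell_2)
    bundles$chrom_1 <- c1$chrom; bundles$win_1 <- c1$win
    bundles$chrom_2 <- c2$chrom; bundles$win_2 <- c2$win
  } else {
    bundles <- tibble::tibble(key = character(), cell_1 = character(),
                              cell_2 = character(), count = integer(),
                              members = list(), chrom_1 = character(),
                              win_1 = numeric(), chrom_2 = character(),
                              win_2 = numeric())
  }
  structure(list(bundles = bundles, passthrough = pass, window_bp = window_bp),
            class = "edge_bundles")
}

#' @export
print.assoc_set <- function(x, ...) {
  cts <- x$report$counts
  cat(sprintf("<assoc_set> %d edges on reference '%s'\n", cts[["edges"]], x$ref_id))
  cat(sprintf("  labels: %d total, %d mapped, %d unmapped (%d phenotype)\n",
              cts[["total"]], cts[["mapped"]], cts[["unmapped"]], cts[["pheno"]]))
  if (length(x$provenance)) cat("  filters:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Tidy an association set into its edge tibble
#' @param x An `assoc_set`.
#' @param ... Unused.
#' @return The edge tibble (one row per association, input order).
#' @method tidy assoc_set
#' @export
tidy.assoc_set <- function(x, ...) x$edges

#' One-row summary of an association set
#' @param x An `assoc_set`.
#' @param ... Unused.
#' @return A one-row tibble of the mapping-report counts.
#' @method glance assoc_set
#' @export
glance.assoc_set <- function(x, ...) {
  tibble::as_tibble(as.list(x$report$counts))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
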