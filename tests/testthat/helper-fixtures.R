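# shared tiny fixtures; everything is built in code, nothing is read from disk

toy_ref <- function() {
  ref <- define_custom_reference(
    "toy", data.frame(chrom = c("chr1", "chr2"), length_bp = c(1000, 2000)))
  attach_gene_index(ref, data.frame(
    label = c("G7", "Wnt1", "ENSTST00000000007", "100007"),
    chrom = c("chr1", "chr2", "chr1", "chr1"),
    start = c(500, 100, 500, 500),
    end = c(900, 300, 900, 900)))
}

# independent random edge-record generator used by round-trip property tests;
# weights/colors are drawn so that every field survives every dialect
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    lab <- function() paste0(sample(c(LETTERS, letters, 0:9), 6, replace = TRUE),
                             collapse = "")
    labs_a <- replicate(n, lab())
    labs_b <- replicate(n, lab())
    types <- sample(c(NA, "GENO", "GEXP", "PROT", "PHENO"), n, replace = TRUE,
                    prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
    kind <- sample(c("weight", "color", "none"), n, replace = TRUE)
    weight <- ifelse(kind == "weight", round(stats::runif(n, -1, 1), 6), NA_real_)
    color <- ifelse(kind == "color",
                    sample(c("#ff0000", "#00ff00", "#0f0", "red", "steelblue"),
                           n, replace = TRUE),
                    NA_character_)
    tibble::tibble(
      label_a = ifelse(is.na(types), labs_a, paste0(labs_a, "^", types)),
      label_b = labs_b, weight = weight, color = color)
  })
}

# canonical multiset view of edge records for order-free comparison
edge_multiset <- function(records) {
  df <- data.frame(a = records$label_a, ta = records$type_a,
                   b = records$label_b, tb = records$type_b,
                   w = records$weight, col = records$color)
  df[do.call(order, df), ]
}
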