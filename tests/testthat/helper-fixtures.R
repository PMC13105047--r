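# Shared fixtures, built once per test run and cached by (n_genes, seed).

.fixture_cache <- new.env(parent = emptyenv())

get_bundle <- function(n_genes, seed, ...) {
  key <- paste0("bundle_", n_genes, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_rs_bundle(
      synthetic_config(n_genes = as.integer(n_genes), seed = as.integer(seed), ...))
  }
  .fixture_cache[[key]]
}

get_classified <- function(n_genes, seed, ...) {
  key <- paste0("classified_", n_genes, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    b <- get_bundle(n_genes, seed, ...)
    introns <- extract_constitutive_introns(b$annotation)
    .fixture_cache[[key]] <- classify_junctions(introns, b$nascent, b$mature)
  }
  .fixture_cache[[key]]
}

get_first_features <- function(n_genes, seed) {
  key <- paste0("features_", n_genes, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    b <- get_bundle(n_genes, seed)
    cls <- get_classified(n_genes, seed)
    .fixture_cache[[key]] <- suppressWarnings(
      build_features(cls, b$annotation, b$genome, b$tpm, b$methylation,
                     scope = "first", seed = as.integer(seed)))
  }
  .fixture_cache[[key]]
}

# a tiny two-gene annotation used by several io / classification tests
toy_annotation <- function() {
  genome_annotation(data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB"),
    transcript_id = c("tA", "tA", "tA", "tB", "tB", "tB"),
    chrom = "chr1",
    start = c(100L, 301L, 1001L, 5000L, 6001L, 7001L),
    end = c(200L, 400L, 1100L, 5100L, 6100L, 7100L),
    strand = c("+", "+", "+", "-", "-", "-"),
    stringsAsFactors = FALSE))
}

# minimal intron table in the layout classify_junctions() expects
make_introns <- function(chrom, start, end, strand,
                         gene_id = paste0("g", seq_along(start)),
                         position_class = "first") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, gene_id = gene_id,
             transcript_id = paste0(gene_id, ".t1"), intron_rank = 1L,
             position_class = position_class,
             length = as.integer(end - start + 1L), stringsAsFactors = FALSE)
}

make_junctions <- function(chrom, start, end, strand, unique_reads = 5L,
                           phase = "nascent", sample_id = "s1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, unique_reads = as.integer(unique_reads),
             multimap_reads = 0L, annotated = FALSE, phase = phase,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}
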