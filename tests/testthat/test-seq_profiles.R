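# GC profiles, enrichment volcano statistics, information content

test_that("metagene bins report GC fractions with known composition", {
  gseq <- paste(c(rep("G", 200), rep("C", 100),            # exon1 + intron start
                  rep(c("A", "T", "G", "C"), 100),         # rest of intron
                  rep("A", 200)), collapse = "")           # exon2
  g <- Biostrings::DNAStringSet(c(chrM = gseq))
  ann <- genome_annotation(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "chrM",
    start = c(1L, 701L), end = c(200L, 900L), strand = "+",
    stringsAsFactors = FALSE))
  ci <- make_introns("chrM", 201L, 700L, "+")
  ci$rs_class <- "basic"
  mg <- metagene_gc(ci, ann, g, bins = 5L)
  up <- mg[mg$segment == "upstream_exon", ]
  dn <- mg[mg$segment == "downstream_exon", ]
  expect_true(all(up$mean_gc == 1))
  expect_true(all(dn$mean_gc == 0))
  mid <- mg[mg$segment == "intron", ]
  expect_equal(mid$mean_gc[1], 1)              # first 100 intron bases all C
  expect_equal(mid$mean_gc[2:5], rep(0.5, 4))  # ATGC repeats, period-aligned bins
  # a segment shorter than the bin count is interpolated, staying in [0,1]
  ci2 <- make_introns("chrM", 201L, 206L, "+")
  ci2$rs_class <- "basic"
  ann2 <- genome_annotation(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "chrM",
    start = c(195L, 207L), end = c(200L, 215L), strand = "+",
    stringsAsFactors = FALSE))
  mg2 <- metagene_gc(ci2, ann2, g, bins = 10L)   # 6-nt intron, interpolated
  expect_true(all(mg2$mean_gc >= 0 & mg2$mean_gc <= 1))
})

test_that("RS first introns show the planted GC excess at the intron start", {
  b <- get_bundle(200, 7)
  cls <- get_classified(200, 7)
  ci <- cls$introns[cls$introns$position_class == "first", ]
  mg <- metagene_gc(ci, b$annotation, b$genome, bins = 50L)
  intron_start <- mg[mg$segment == "intron" & mg$bin <= 3, ]
  rs <- mean(intron_start$mean_gc[intron_start$rs_class != "basic"])
  basic <- mean(intron_start$mean_gc[intron_start$rs_class == "basic"])
  expect_gt(rs, basic)
})

test_that("window GC separates planted RS from basic first introns", {
  ss <- data.frame(site_type = "canonical5", rs_class = c("RS5", "basic"),
                   intron_position = "first",
                   sequence = c("GGCCGGCC", "AATTAATT"), stringsAsFactors = FALSE)
  wg <- window_gc(ss)
  expect_equal(wg$gc, c(1, 0))
  b <- get_bundle(200, 7)
  cls <- get_classified(200, 7)
  wide <- extract_site_sequences(cls, b$genome, "canonical5", window = c(-50L, 100L))
  wide <- wide[wide$intron_position == "first", , drop = FALSE]
  wg2 <- window_gc(wide)
  rs <- wg2$gc[wg2$rs_class != "basic"]; ba <- wg2$gc[wg2$rs_class == "basic"]
  expect_lt(stats::wilcox.test(rs, ba, alternative = "greater")$p.value, 0.01)
})

test_that("tetramer enrichment is null on identical groups and antisymmetric", {
  set.seed(4)
  a <- random_dna(30, 60)
  te0 <- tetramer_enrichment(a, a)
  expect_true(all(te0$log2fc == 0))
  expect_true(all(te0$q_value >= 0.999))
  b <- random_dna(30, 60)
  ab <- tetramer_enrichment(a, b)
  ba <- tetramer_enrichment(b, a)
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_true(all(ab$q_value >= ab$p_value - 1e-12))
  # monotone BH: q ordering follows p ordering
  expect_true(all(diff(ab$q_value[order(ab$p_value)]) >= -1e-12))
  # extreme composition
  te <- tetramer_enrichment(rep(paste(rep("CG", 30), collapse = ""), 20),
                            rep(paste(rep("AT", 30), collapse = ""), 20))
  row <- te[te$kmer == "CGCG", ]
  expect_gt(row$log2fc, 0)
  expect_lt(row$q_value, 1e-10)
  expect_error(tetramer_enrichment(character(0), a), "non-empty")
})

test_that("information content matches closed-form entropies", {
  ic <- pwm_information(c("GAAC", "GCAC", "GAAC", "GCAC"))
  expect_equal(ic$ic[1], 2, tolerance = 1e-4)       # invariant G
  expect_equal(ic$ic[2], 1, tolerance = 1e-4)       # 0.5/0.5 split
  expect_equal(ic$ic[3], 2, tolerance = 1e-4)
  uni <- pwm_information(c("ACGT", "CGTA", "GTAC", "TACG"))
  expect_true(all(abs(uni$ic) < 1e-4))
  expect_true(all(ic$ic >= 0 & ic$ic <= 2))
  expect_error(pwm_information(c("AAA", "AAAA")), "equal length")
})
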