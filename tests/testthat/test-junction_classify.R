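# constitutive-intron rules and boundary classification

test_that("alternative-isoform rule discards isoform-specific introns", {
  # two isoforms share intron 201-300; intron 500-700 exists in one isoform
  # while the other isoform's exon spans it
  ann <- genome_annotation(data.frame(
    gene_id = "g1",
    transcript_id = c("t1", "t1", "t1", "t2", "t2"),
    chrom = "chr1",
    start = c(100L, 301L, 701L, 100L, 301L),
    end = c(200L, 499L, 900L, 200L, 900L),
    strand = "+", stringsAsFactors = FALSE))
  ci <- extract_constitutive_introns(ann)
  expect_equal(nrow(ci), 1L)
  expect_equal(c(ci$start, ci$end), c(201L, 300L))
})

test_that("overlapping introns of different genes are both discarded", {
  ann <- genome_annotation(data.frame(
    gene_id = c("g1", "g1", "g2", "g2"),
    transcript_id = c("t1", "t1", "t2", "t2"),
    chrom = "chr1",
    start = c(50L, 201L, 120L, 251L),
    end = c(99L, 260L, 149L, 320L),
    strand = "+", stringsAsFactors = FALSE))
  # introns: 100-200 (g1) and 150-250 (g2) overlap
  expect_equal(nrow(extract_constitutive_introns(ann)), 0L)
  # with same-strand-only overlap checking and opposite strands, both survive
  ann2 <- genome_annotation(data.frame(
    gene_id = c("g1", "g1", "g2", "g2"),
    transcript_id = c("t1", "t1", "t2", "t2"),
    chrom = "chr1",
    start = c(50L, 201L, 120L, 251L),
    end = c(99L, 260L, 149L, 320L),
    strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE))
  expect_equal(nrow(extract_constitutive_introns(ann2)), 0L)
  expect_equal(nrow(extract_constitutive_introns(ann2, ignore_strand_overlap = FALSE)), 2L)
})

test_that("a single-isoform gene keeps disjoint introns with first/last classes", {
  ci <- extract_constitutive_introns(toy_annotation())
  gA <- ci[ci$gene_id == "gA", ]
  expect_equal(nrow(gA), 2L)
  expect_setequal(gA$position_class, c("first", "last"))
})

test_that("boundary classification follows the distance rules on both strands", {
  introns <- make_introns("chr1", c(1001L, 1001L), c(5000L, 5000L), c("+", "-"),
                          gene_id = c("gp", "gm"))
  introns$chrom <- c("chr1", "chr2")   # keep strands on separate contigs
  nas <- rbind(
    make_junctions("chr1", 1101L, 5000L, "+"),   # RS5, distance 100
    make_junctions("chr1", 1001L, 5000L, "+"),   # exact -> basic
    make_junctions("chr1", 1041L, 5000L, "+"),   # distance 40 -> discarded
    make_junctions("chr2", 1001L, 4900L, "-"))   # minus-strand RS5 at 4900
  cls <- classify_junctions(introns, nas, recsplice:::empty_junctions())
  plus <- cls$introns[cls$introns$chrom == "chr1", ]
  expect_equal(plus$rs_class, "RS5")
  expect_equal(plus$recursive_5ss, 1101)
  minus <- cls$introns[cls$introns$chrom == "chr2", ]
  expect_equal(minus$rs_class, "RS5")
  expect_equal(minus$recursive_5ss, 4900)
  expect_true("recursive_site_too_close" %in% cls$discarded$reason)
  # the exact junction is basic evidence, superseded by the RS5 row
  expect_false("basic" %in% plus$rs_class)
})

test_that("nascent-unique filtering and read thresholds apply", {
  introns <- make_introns("chr1", 1001L, 5000L, "+")
  nas <- rbind(make_junctions("chr1", 1101L, 5000L, "+", unique_reads = 2L,
                              sample_id = "n1"),
               make_junctions("chr1", 1101L, 5000L, "+", unique_reads = 2L,
                              sample_id = "n2"),
               make_junctions("chr1", 1201L, 5000L, "+", unique_reads = 9L))
  mat <- make_junctions("chr1", 1201L, 5000L, "+", unique_reads = 1L,
                        phase = "mature")
  cls <- classify_junctions(introns, nas, mat)
  # reads summed across nascent samples: 2+2 = 4 >= 3 passes
  expect_equal(cls$introns$rs_class, "RS5")
  expect_equal(cls$introns$recursive_5ss, 1101)
  # the 1201 junction is present in mature at any depth -> not nascent-unique
  expect_true("present_in_mature" %in% cls$discarded$reason)
  # strand-unknown and orphan junctions land in the discard log
  nas2 <- rbind(make_junctions("chr1", 1101L, 5000L, "*"),
                make_junctions("chr1", 9001L, 9200L, "+"))
  cls2 <- classify_junctions(introns, nas2, recsplice:::empty_junctions())
  expect_setequal(cls2$discarded$reason, c("strand_unknown", "no_constitutive_intron"))
})

test_that("classification matches a brute-force boundary oracle on random pairs", {
  # independent re-statement of the rules, one pair at a time
  oracle <- function(js, je, is, ie, strand, min_d = 75L, min_len = 150L,
                     min_basic = 75L) {
    if (js < is || je > ie) return("outside")
    if (js == is && je == ie) {
      return(if (ie - is + 1L >= min_basic) "basic" else "none")
    }
    if (strand == "+") { r5 <- js > is; r3 <- je < ie; a5 <- js; a3 <- je }
    else { r5 <- je < ie; r3 <- js > is; a5 <- je; a3 <- js }
    if (ie - is + 1L < min_len) return("none")
    if (r5 && min(abs(a5 - is), abs(a5 - ie)) < min_d) return("none")
    if (r3 && min(abs(a3 - is), abs(a3 - ie)) < min_d) return("none")
    if (r5 && r3) "nested" else if (r5) "RS5" else "RS3"
  }
  set.seed(101)
  n <- 1200L
  is <- cumsum(sample(3000:5000, n))        # disjoint introns along one contig
  len <- sample(c(60:400, 1000:2000), n, replace = TRUE)
  ie <- is + len - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  off5 <- sample(c(0L, 0L, 10L, 40L, 75L, 80L, 120L), n, replace = TRUE)
  off3 <- sample(c(0L, 0L, 10L, 40L, 75L, 80L, 120L), n, replace = TRUE)
  js <- pmin(is + off5, ie); je <- pmax(ie - off3, js)
  introns <- make_introns("chr1", is, ie, strand, gene_id = sprintf("g%d", seq_len(n)))
  nas <- make_junctions("chr1", js, je, strand)
  cls <- classify_junctions(introns, nas, recsplice:::empty_junctions())
  got <- rep("none", n)
  ck <- paste(cls$introns$start, cls$introns$end, cls$introns$strand)
  ik <- paste(is, ie, strand)
  got[match(ck, ik)] <- cls$introns$rs_class
  want <- vapply(seq_len(n), function(i) {
    oracle(js[i], je[i], is[i], ie[i], strand[i])
  }, "")
  want[want == "outside"] <- "none"
  expect_identical(got, want)
  # no output row ever violates the 75/150 invariants
  rs <- cls$introns[cls$introns$rs_class != "basic", ]
  expect_true(all(rs$length >= 150L))
})

test_that("length and position summaries report per class", {
  introns <- make_introns("chr1", c(1001L, 10001L, 20001L), c(1300L, 10300L, 21000L),
                          "+", gene_id = c("g1", "g2", "g3"),
                          position_class = c("first", "first", "middle"))
  nas <- rbind(make_junctions("chr1", 1001L, 1300L, "+"),
               make_junctions("chr1", 10001L, 10300L, "+"),
               make_junctions("chr1", 20101L, 21000L, "+"))
  cls <- classify_junctions(introns, nas, recsplice:::empty_junctions())
  sm <- junction_length_summary(cls)
  basic <- sm$lengths[sm$lengths$rs_class == "basic", ]
  expect_equal(basic$n, 2L)
  expect_equal(basic$mean_length, 300)
  expect_equal(basic$median_length, 300)
  pos <- sm$positions
  expect_equal(pos$first_fraction[pos$rs_class == "basic"], 1)
  expect_equal(pos$middle_fraction[pos$rs_class == "RS5"], 1)
})

test_that("RS classes are first-intron enriched relative to basic on synthetic data", {
  cls <- get_classified(200, 7)
  sm <- junction_length_summary(cls)
  pos <- sm$positions
  rs_first <- with(pos, weighted.mean(first_fraction[rs_class != "basic"],
                                      n[rs_class != "basic"]))
  expect_gt(rs_first, pos$first_fraction[pos$rs_class == "basic"])
})

test_that("AGGU motif fractions match the planted intact fraction", {
  b <- get_bundle(2000, 11)
  cls <- get_classified(2000, 11)
  mo <- motif_at_recursive_sites(cls, b$genome)
  rs5 <- mo[mo$rs_class == "RS5" & mo$site_type == "recursive5", ]
  expect_gte(rs5$n_sites, 500L)
  expect_lt(abs(rs5$aggu_fraction - 0.6), 0.05)
  # an empty class reports NA
  small <- get_classified(200, 7)
  sub <- small
  sub$junctions <- sub$junctions[sub$junctions$rs_class != "nested", , drop = FALSE]
  mo2 <- motif_at_recursive_sites(sub, get_bundle(200, 7)$genome)
  expect_true(is.na(mo2$aggu_fraction[mo2$rs_class == "nested" &
                                      mo2$site_type == "recursive5"]))
})
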