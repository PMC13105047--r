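# synthetic-bundle generator: planted structure, coupling, determinism

test_that("plant_motif changes only the window and calibrates the CG excess", {
  s <- random_dna(1, 200, seed = 1)
  expect_identical(plant_motif(s, c(50, 129), 0, seed = 1), s)
  expect_identical(plant_motif(s, c(10, 9), 0.3, seed = 1), s)  # length-0 window
  expect_error(plant_motif(s, c(150, 250), 0.3), "out of range")
  out <- plant_motif(s, c(50, 129), 0.3, seed = 1)
  expect_identical(substr(out, 1, 49), substr(s, 1, 49))
  expect_identical(substr(out, 130, 200), substr(s, 130, 200))

  # Monte-Carlo calibration against the generator's own background sampler
  cg_density <- function(x) {
    h <- gregexpr("CG", x, fixed = TRUE)[[1L]]
    (if (h[1L] == -1L) 0 else length(h)) / (nchar(x) - 1L)
  }
  set.seed(42)
  base <- random_dna(1000, 80)
  planted <- vapply(base, plant_motif, "", window = c(1, 80), composition_shift = 0.3)
  excess <- mean(vapply(planted, cg_density, 0)) - mean(vapply(base, cg_density, 0))
  expect_lt(abs(excess - 0.3), 0.03)
})

test_that("conditional downstream probabilities reproduce the target odds ratio", {
  for (or in c(1, 2.2, 5)) {
    q <- recsplice:::solve_coupling(0.4, 0.4, or)
    odds <- function(p) p / (1 - p)
    expect_equal(odds(q["q1"]) / odds(q["q0"]), or, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(0.4 * q["q1"] + 0.6 * q["q0"], 0.4, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("rs_gene_fraction 0 yields an all-basic truth table and no nascent-only junctions", {
  b <- generate_rs_bundle(synthetic_config(n_genes = 40L, rs_gene_fraction = 0,
                                           noise_junction_fraction = 0, seed = 3L))
  expect_true(all(b$truth$introns$rs_class == "basic"))
  expect_equal(nrow(b$truth$sites), 0L)
  nk <- unique(unlist(lapply(b$nascent, recsplice:::junction_key)))
  mk <- recsplice:::junction_key(b$mature)
  expect_true(all(nk %in% mk))
})

test_that("planted recursive sites respect the 75/150-nt geometry and AGGU planting", {
  b <- get_bundle(200, 7)
  sites <- b$truth$sites
  intr <- b$truth$introns
  key <- paste(sites$gene_id, sites$intron_rank)
  ikey <- paste(intr$gene_id, intr$intron_rank)
  host <- intr[match(key, ikey), ]
  expect_true(all(host$end - host$start + 1L >= 150L))
  for (col in c("rec5", "rec3")) {
    p <- sites[[col]]
    ok <- !is.na(p)
    expect_true(all(pmin(abs(p[ok] - host$start[ok]), abs(p[ok] - host$end[ok])) >= 75L))
  }
  # intact recursive 5'SS carry the literal AGGT ratchet on the sense strand
  s5 <- sites[sites$has5 & sites$intact5, ]
  seqs <- extract_window(b$genome, s5$chrom, s5$rec5, s5$strand, c(-2L, 1L))
  expect_true(all(seqs == "AGGT"))
  # canonical boundaries are GT..AG in >= 99% of introns
  gt <- extract_window(b$genome, intr$chrom,
                       ifelse(intr$strand == "+", intr$start, intr$end),
                       intr$strand, c(0L, 1L))
  expect_gte(mean(gt == "GT"), 0.99)
})

test_that("the same seed reproduces a byte-identical bundle", {
  cfg <- synthetic_config(n_genes = 30L, seed = 11L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_rs_bundle(cfg, dir = d1)$paths
  p2 <- generate_rs_bundle(cfg, dir = d2)$paths
  f1 <- unlist(p1); f2 <- unlist(p2)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("truth-table odds ratio is recovered at coupling 1.0", {
  b <- generate_rs_bundle(synthetic_config(n_genes = 5000L, coupling_odds_ratio = 1.0,
                                           seed = 19L))
  tt <- b$truth$transcripts
  ft <- stats::fisher.test(table(tt$first_rs, tt$downstream_rs))
  expect_true(ft$conf.int[1] <= 1 && ft$conf.int[2] >= 1)
})

test_that("classification recovers the planted truth labels exactly", {
  b <- get_bundle(200, 7)
  cls <- get_classified(200, 7)
  truth <- b$truth$introns
  tkey <- paste(truth$chrom, truth$start, truth$end, truth$strand, sep = ":")
  ckey <- paste(cls$introns$chrom, cls$introns$start, cls$introns$end,
                cls$introns$strand, sep = ":")
  rs_truth <- sort(tkey[truth$is_rs])
  rs_found <- sort(unique(ckey[cls$introns$rs_class != "basic"]))
  expect_identical(rs_found, rs_truth)
  # and per-class agreement
  found <- unique(data.frame(key = ckey, cls = cls$introns$rs_class,
                             stringsAsFactors = FALSE))
  found <- found[found$cls != "basic", ]
  expect_identical(found$cls, truth$rs_class[match(found$key, tkey)])
})

test_that("config text serialization round-trips", {
  cfg <- synthetic_config(n_genes = 77L, coupling_odds_ratio = 3.1, seed = 5L)
  f <- withr::local_tempfile()
  write_synthetic_config(cfg, f)
  back <- read_synthetic_config(f)
  expect_equal(back$n_genes, 77L)
  expect_equal(back$coupling_odds_ratio, 3.1)
  expect_equal(back$rs_class_probs, cfg$rs_class_probs)
  expect_equal(back$seed, 5L)
})
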