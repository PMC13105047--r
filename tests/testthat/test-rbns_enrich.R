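# RBNS matrix assembly and positional enrichment mapping

toy_rbns <- function(k = 2L) {
  km <- all_kmers(k)
  rbind(data.frame(protein = "P1", concentration = 5, kmer = km,
                   R = seq(1, 2, length.out = length(km))),
        data.frame(protein = "P1", concentration = 20, kmer = km,
                   R = seq(1, 3.1, length.out = length(km))),
        data.frame(protein = "P2", concentration = 80, kmer = km, R = 1))
}

test_that("the max-enrichment concentration is selected per protein", {
  rm <- load_rbns(toy_rbns())
  expect_equal(unname(rm$concentrations["P1"]), 20)
  expect_equal(unname(rm$concentrations["P2"]), 80)   # single concentration
  expect_equal(max(rm$R["P1", ]), 3.1)
  expect_equal(rm$k, 2L)
  # defects are rejected with informative errors: a k-mer absent from the
  # selected concentration of P2 (its only one) names the protein
  bad <- toy_rbns()
  drop <- which(bad$protein == "P2")[1]
  expect_error(load_rbns(bad[-drop, ]), "missing for protein P2")
  mixed <- rbind(bad, data.frame(protein = "P1", concentration = 5,
                                 kmer = "AAA", R = 1))
  expect_error(load_rbns(mixed), "mixed k-mer lengths")
})

test_that("position enrichment equals a double-loop dot-product oracle", {
  set.seed(12)
  k <- 3L
  rb <- do.call(rbind, lapply(c("A1", "B2"), function(p) {
    data.frame(protein = p, concentration = 20, kmer = all_kmers(k),
               R = exp(rnorm(4^k, 0, 0.4)))
  }))
  rm <- load_rbns(rb)
  seqs <- random_dna(25, 160)
  ss <- data.frame(site_type = "canonical5", rs_class = "RS5",
                   intron_position = "first", sequence = seqs,
                   stringsAsFactors = FALSE)
  attr(ss, "window") <- c(-80L, 79L)
  pe <- position_enrichment(ss, rm, bin = 15L, span = 75L)
  # oracle: loop over sequences, k-mer starts and proteins
  vocab <- all_kmers(k)
  n_bins <- 10L
  counts <- matrix(0, n_bins, length(vocab), dimnames = list(NULL, vocab))
  for (s in seqs) {
    for (st in 1:(nchar(s) - k + 1)) {
      off <- -80L + st - 1L
      if (off < -75 || off > 74) next
      b <- (off + 75) %/% 15 + 1
      km <- substr(s, st, st + k - 1)
      counts[b, km] <- counts[b, km] + 1
    }
  }
  E_oracle <- matrix(0, n_bins, 2, dimnames = list(NULL, rownames(rm$R)))
  for (b in 1:n_bins) {
    f <- counts[b, ] / sum(counts[b, ])
    for (p in rownames(rm$R)) {
      E_oracle[b, p] <- sum(f * rm$R[p, ])
    }
  }
  got <- pe$E[pe$E$site_type == "canonical5", ]
  for (p in rownames(rm$R)) {
    expect_lt(max(abs(got$E[got$protein == p] - E_oracle[, p])), 1e-10)
  }
  # fraction vectors are row-stochastic
  expect_true(all(abs(rowSums(pe$f[["canonical5|RS"]]) - 1) < 1e-8))
})

test_that("uniform R gives E = 1 everywhere and group swap flips log2fc", {
  k <- 2L
  rb <- data.frame(protein = "U", concentration = 1, kmer = all_kmers(k), R = 1)
  rm <- load_rbns(rb)
  mk <- function(cls) {
    ss <- data.frame(site_type = "canonical5", rs_class = cls,
                     intron_position = "first",
                     sequence = random_dna(10, 160), stringsAsFactors = FALSE)
    attr(ss, "window") <- c(-80L, 79L)
    ss
  }
  set.seed(3)
  both <- rbind(mk("RS5"), mk("basic"))
  attr(both, "window") <- c(-80L, 79L)
  pe <- position_enrichment(both, rm)
  expect_true(all(abs(pe$E$E - 1) < 1e-12))
  expect_true(all(abs(pe$log2fc$log2fc) < 1e-12))
  # swapping the group labels negates every log2fc
  swapped <- both
  swapped$rs_class <- ifelse(swapped$rs_class == "basic", "RS5", "basic")
  rb2 <- data.frame(protein = "V", concentration = 1, kmer = all_kmers(k),
                    R = exp(seq(-0.5, 0.5, length.out = 4^k)))
  rm2 <- load_rbns(rb2)
  f1 <- position_enrichment(both, rm2)$log2fc
  f2 <- position_enrichment(swapped, rm2)$log2fc
  expect_equal(f1$log2fc, -f2$log2fc)
})

test_that("protein ranking takes the max |log2fc| with stable ties", {
  fc <- data.frame(comparison = "canonical5:RS_vs_noRS",
                   bin = rep(1:3, 3), bin_start = rep(c(-75, -60, -45), 3),
                   protein = rep(c("B", "A", "C"), each = 3),
                   log2fc = c(0, 0, 0, 0.5, -2, 0.3, 0, 0, 0))
  pe <- structure(list(log2fc = fc), class = "rbns_position_enrichment")
  rk <- rank_proteins(pe)
  expect_equal(rk$protein[1], "A")
  expect_equal(rk$max_abs_log2fc[1], 2)
  expect_equal(rk$protein[2:3], c("B", "C"))    # all-zero tie broken by name
  # ranking is invariant to bin order permutation
  pe2 <- structure(list(log2fc = fc[sample(nrow(fc)), ]), class = "rbns_position_enrichment")
  expect_equal(rank_proteins(pe2)$protein, rk$protein)
})

test_that("the planted CG binder is enriched where the motif was planted", {
  b <- get_bundle(800, 5)
  cls <- get_classified(800, 5)
  rm <- load_rbns(b$rbns)
  win <- c(-75L, 75L + rm$k)
  ss <- do.call(rbind, lapply(c("canonical5", "canonical3"), function(st) {
    s <- extract_site_sequences(cls, b$genome, st, window = win)
    s[s$intron_position == "first", , drop = FALSE]
  }))
  attr(ss, "window") <- win
  pe <- position_enrichment(ss, rm)
  fc <- pe$log2fc
  cg <- fc[fc$comparison == "canonical5:RS_vs_noRS" & fc$protein == "CGBP1", ]
  # positive enrichment in the bins overlapping the planted -30..+50 window
  expect_true(all(cg$log2fc[cg$bin_start %in% c(-30, -15, 0, 15, 30)] > 0))
  rk <- rank_proteins(pe)
  expect_equal(rk$protein[1], "CGBP1")
  expect_gt(rk$max_abs_log2fc[rk$protein == "CGBP1"],
            rk$max_abs_log2fc[rk$protein == "NEUT1"] + 0.05)
})
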