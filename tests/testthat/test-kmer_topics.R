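# positional/grouped k-mer matrices, LDA fits, expectations, driving k-mers

toy_sites <- function(seqs, site_type = "canonical5", rs_class = "basic",
                      window = NULL) {
  out <- data.frame(site_id = paste0("s", seq_along(seqs)), site_type = site_type,
                    rs_class = rs_class, intron_position = "first",
                    sequence = seqs, stringsAsFactors = FALSE)
  attr(out, "window") <- if (is.null(window)) c(0L, unique(nchar(seqs)) - 1L) else window
  out
}

test_that("site sequences anchor position 0 on the splice site, strand-aware", {
  b <- get_bundle(60, 2)
  cls <- get_classified(60, 2)
  ss <- extract_site_sequences(cls, b$genome, "canonical5", window = c(-2L, 2L))
  # positions 0..1 are the canonical GU in essentially all planted introns
  expect_gte(mean(substr(ss$sequence, 3, 4) == "GT"), 0.99)
  s3 <- extract_site_sequences(cls, b$genome, "canonical3", window = c(-2L, 2L))
  expect_gte(mean(substr(s3$sequence, 2, 3) == "AG"), 0.99)
  # explicit coordinate check on a plus-strand intron
  g <- Biostrings::DNAStringSet(c(chr9 = paste(rep("ACGT", 300), collapse = "")))
  intr <- make_introns("chr9", 1001L, 1100L, "+")
  intr$rs_class <- "basic"
  w <- extract_site_sequences(intr, g, "canonical5", window = c(-2L, 2L))
  expect_equal(w$sequence, as.character(Biostrings::subseq(g[[1]], 999, 1003)))
  # minus strand: reverse complement of end-anchored window
  intr_m <- make_introns("chr9", 1001L, 1100L, "-")
  intr_m$rs_class <- "basic"
  wm <- extract_site_sequences(intr_m, g, "canonical5", window = c(-2L, 2L))
  expect_equal(wm$sequence, as.character(Biostrings::reverseComplement(
    Biostrings::subseq(g[[1]], 1098, 1102))))
})

test_that("positional counts follow the hand-enumerated smoothing convention", {
  m <- positional_kmer_matrix(toy_sites("AAGGTAAGGT"), k = 4L, window_smooth = 6L)
  d0 <- m$counts[m$docs$position == 0, ]
  expect_equal(unname(d0["AAGG"]), 2)
  expect_equal(unname(d0[c("AGGT", "GGTA", "GTAA", "TAAG")]), rep(1, 4))
  expect_equal(sum(d0), 6)
  # smooth = 1: document p holds exactly the tetramer starting at p
  m1 <- positional_kmer_matrix(toy_sites("AAGGTAAGGT"), k = 4L, window_smooth = 1L)
  expect_equal(unname(m1$counts[m1$docs$position == 1, "AGGT"]), 1)
  expect_equal(unname(rowSums(m1$counts)), rep(1, 7))
})

test_that("a planted AGGU at offset -2 marks documents -7..-2 at smooth 6", {
  seqs <- random_dna(40, 81, seed = 5)
  # window -30..+50; offset -2 is character position 29
  substr(seqs, 29, 32) <- "AGGT"
  # avoid chance AGGT elsewhere for a clean read-out
  seqs <- vapply(seqs, function(s) {
    pre <- gsub("AGGT", "AGCT", substr(s, 1, 28), fixed = TRUE)
    post <- gsub("AGGT", "AGCT", substr(s, 33, 81), fixed = TRUE)
    paste0(substr(paste0(pre, "AGGT", post), 1, 81))
  }, "")
  m <- positional_kmer_matrix(toy_sites(seqs, window = c(-30L, 50L)),
                              k = 4L, window_smooth = 6L)
  pos_with_aggt <- m$docs$position[m$counts[, "AGGT"] > 0]
  expect_true(all(pos_with_aggt %in% (-7):(-2)))
  expect_setequal(pos_with_aggt, (-7):(-2))
})

test_that("count conservation holds between positional and grouped matrices", {
  seqs <- random_dna(30, 40, seed = 6)
  st <- toy_sites(seqs)
  pm <- positional_kmer_matrix(st, k = 4L, window_smooth = 1L)
  gm1 <- grouped_kmer_matrix(st, group_size = 1L, seed = 1)
  total <- length(seqs) * (40 - 4 + 1)
  expect_equal(sum(pm$counts), total)
  expect_equal(sum(gm1$counts), total)
  expect_equal(colSums(pm$counts), colSums(gm1$counts))
})

test_that("grouping partitions sequences and drops remainders", {
  expect_equal(nrow(grouped_kmer_matrix(toy_sites(random_dna(30, 20, seed = 1)),
                                        group_size = 15L, seed = 1)$counts), 2L)
  expect_equal(nrow(grouped_kmer_matrix(toy_sites(random_dna(31, 20, seed = 2)),
                                        group_size = 15L, seed = 1)$counts), 2L)
  # a subtype below group_size is skipped with a warning, others proceed
  mixed <- rbind(toy_sites(random_dna(30, 20, seed = 3)),
                 toy_sites(random_dna(10, 20, seed = 4), rs_class = "RS5"))
  attr(mixed, "window") <- c(0L, 19L)
  expect_warning(gm <- grouped_kmer_matrix(mixed, group_size = 15L, seed = 1),
                 "fewer than")
  expect_equal(nrow(gm$counts), 2L)
  expect_true(all(gm$docs$rs_class == "basic"))
})

test_that("pseudo-AGGU sampling is uniform over eligible internal sites", {
  g <- Biostrings::DNAStringSet(c(chrP = paste(c(rep("A", 50),
    rep(c("AGGT", paste(rep("C", 21), collapse = "")), 40), rep("A", 50)),
    collapse = "")))
  L <- Biostrings::width(g)[1]
  intr <- make_introns("chrP", 11L, L - 10L, "+")
  ps <- sample_pseudo_aggu(intr, g, n = 1e6, min_distance = 75L, seed = 1)
  # enumeration oracle: eligible AGGT site offsets inside the intron
  iseq <- as.character(Biostrings::subseq(g[[1]], 11, L - 10))
  occ <- as.integer(gregexpr("AGGT", iseq, fixed = TRUE)[[1]]) + 1L
  Li <- nchar(iseq)
  elig <- occ[occ >= 75 & (Li - 1 - occ) >= 75]
  expect_equal(nrow(ps), length(elig))
  # repeated single draws are uniform over the eligible sites
  draws <- vapply(1:800, function(s) {
    sample_pseudo_aggu(intr, g, n = 1, seed = s)$site_id
  }, "")
  elig_ids <- paste("chrP", 11L + elig, "+", sep = ":")
  tab <- table(factor(draws, levels = elig_ids))
  expect_gt(stats::chisq.test(as.vector(tab),
                              p = rep(1 / length(elig), length(elig)))$p.value, 0.01)
  # degenerate inputs
  gpoly <- Biostrings::DNAStringSet(c(chrA = paste(rep("A", 400), collapse = "")))
  expect_warning(out <- sample_pseudo_aggu(make_introns("chrA", 11L, 390L, "+"),
                                           gpoly, n = 10, seed = 1),
                 "no eligible")
  expect_equal(nrow(out), 0L)
})

test_that("LDA recovers degenerate and separable corpora deterministically", {
  vocab <- all_kmers(4)
  X <- matrix(0, 12, 256, dimnames = list(NULL, vocab))
  X[, "CGCG"] <- 50
  m <- fit_mixture(X, n_topics = 3, seed = 1)
  dom <- apply(m$memberships, 1, which.max)
  expect_true(all(m$topics[dom, "CGCG"] > 0.99))
  # two-block corpus separates perfectly with 2 topics
  X2 <- matrix(0, 20, 256, dimnames = list(NULL, vocab))
  X2[1:10, "AAAA"] <- 30; X2[11:20, "TTTT"] <- 30
  m2 <- fit_mixture(X2, n_topics = 2, seed = 1)
  dom2 <- apply(m2$memberships, 1, which.max)
  expect_equal(length(unique(dom2[1:10])), 1L)
  expect_equal(length(unique(dom2[11:20])), 1L)
  expect_false(dom2[1] == dom2[11])
  # row-stochastic within 1e-8 and seed-deterministic
  expect_lt(max(abs(rowSums(m2$topics) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(m2$memberships) - 1)), 1e-8)
  m2b <- fit_mixture(X2, n_topics = 2, seed = 1)
  expect_identical(m2$topics, m2b$topics)
  expect_identical(m2$memberships, m2b$memberships)
  # degenerate inputs are rejected
  X3 <- X2; X3[1, ] <- 0
  expect_error(fit_mixture(X3, n_topics = 2, seed = 1), "all-zero")
  expect_error(fit_mixture(X2, n_topics = 1, seed = 1), "n_topics")
})

test_that("held-out expectations are consistent with training memberships", {
  set.seed(3)
  X <- matrix(rpois(40 * 256, 2), 40, 256, dimnames = list(NULL, all_kmers(4)))
  X[1:20, "CGCG"] <- 120
  m <- fit_mixture(X, n_topics = 3, seed = 2)
  te <- topic_expectations(m, X)
  expect_lt(max(rowSums(abs(te - m$memberships))), 0.05)
  expect_lt(max(abs(rowSums(te) - 1)), 1e-8)
  # pure CGCG vector loads on the CGCG topic
  v <- matrix(0, 1, 256, dimnames = list(NULL, all_kmers(4)))
  v[, "CGCG"] <- 60
  cg_topic <- which.max(m$topics[, "CGCG"])
  expect_gt(topic_expectations(m, v)[1, cg_topic], 0.9)
  expect_error(topic_expectations(m, v * 0), "all-zero")
  expect_error(topic_expectations(m, v[, 1:100, drop = FALSE]), "vocabulary")
})

test_that("driving k-mer scores follow the Poisson-KL closed form", {
  topics <- matrix(1 / 256, 3, 256, dimnames = list(paste0("topic", 1:3), all_kmers(4)))
  m <- structure(list(topics = topics, n_topics = 3L), class = "rs_topic_model")
  dk <- driving_kmers(m)
  expect_true(all(abs(dk$kl_score) < 1e-12))
  expect_true(all(tapply(dk$rank, dk$topic, function(r) identical(sort(r), 1:256))))
  # p = 0.5 vs q = 0.1 -> 0.5 ln 5 + 0.1 - 0.5
  p <- 0.5; q <- 0.1
  expect_equal(p * log(p / q) + q - p, 0.4047, tolerance = 1e-4)
  t2 <- topics
  t2[1, ] <- c(0.5, rep(0.5 / 255, 255))
  t2[2, ] <- c(0.1, rep(0.9 / 255, 255))
  t2[3, ] <- c(0.1, rep(0.9 / 255, 255))
  m2 <- structure(list(topics = t2, n_topics = 3L), class = "rs_topic_model")
  dk2 <- driving_kmers(m2)
  expect_equal(dk2$kl_score[dk2$topic == "topic1" & dk2$kmer == "AAAA"],
               0.5 * log(5) + 0.1 - 0.5, tolerance = 1e-10)
})
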