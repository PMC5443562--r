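make_proteome <- function(n, len = 90, seed = 1, prefix = "pA") {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  setNames(
    vapply(seq_len(n), function(i)
      paste0("M", paste(sample(aa, len - 1, replace = TRUE), collapse = "")),
      character(1)),
    sprintf("%s%03d", prefix, seq_len(n))
  )
}

test_that("alignment scoring reports identity, coverage, and E-value sanely", {
  p <- make_proteome(1, len = 100)[[1]]
  self <- align_and_score(p, p)
  expect_equal(self$identity, 100)
  expect_equal(self$coverage, 100)
  expect_lt(self$evalue, 1e-20)

  # unrelated random sequences fail the E-value threshold
  others <- make_proteome(8, len = 100, seed = 99)
  es <- vapply(others, function(q) align_and_score(q, p)$evalue, numeric(1))
  expect_true(all(es > 1e-5))

  expect_error(align_and_score("MKTAYIAK1X", p), "amino acids")
  expect_error(align_and_score("MKT", p), "at least 10")
})

test_that("reciprocal best hits recover identity and planted ortholog maps", {
  a <- make_proteome(12, len = 80, seed = 7, prefix = "a")
  rbh_self <- reciprocal_best_hits(a, setNames(a, sub("^a", "b", names(a))))
  expect_equal(nrow(rbh_self), 12)
  expect_equal(sub("^a", "b", rbh_self$locus_a), rbh_self$locus_b)
  expect_true(all(rbh_self$identity == 100))

  # mutated copies at ~88% identity are still each other's best hits
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  b <- vapply(a, function(p) {
    ch <- strsplit(p, "")[[1]]
    mut <- runif(length(ch)) > 0.88
    ch[mut] <- sample(aa, sum(mut), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  names(b) <- sub("^a", "b", names(a))
  rbh <- reciprocal_best_hits(a, b)
  expect_equal(nrow(rbh), 12)
  expect_equal(sub("^a", "b", rbh$locus_a), rbh$locus_b)
  expect_true(all(rbh$identity >= 50 & rbh$coverage >= 80 & rbh$evalue <= 1e-5))
})

test_that("RBH is symmetric in its arguments", {
  a <- make_proteome(6, len = 80, seed = 17, prefix = "a")
  b <- make_proteome(6, len = 80, seed = 18, prefix = "b")
  b[1] <- a[1]  # one conserved pair
  ab <- reciprocal_best_hits(a, b)
  ba <- reciprocal_best_hits(b, a)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$locus_a, ab$locus_b),
                  paste(ba$locus_b, ba$locus_a))
})

test_that("source-organism choice maximizes bit score among eligible candidates", {
  cand <- tibble::tibble(
    organism = c("orgA", "orgB", "orgC"),
    bit_score = c(310, 290, 350),
    has_orthologous_pair = c(TRUE, TRUE, FALSE)
  )
  expect_equal(choose_source(cand), "orgA")   # orgC ineligible despite top score
  expect_equal(choose_source(cand[1, ]), "orgA")
  cand2 <- cand; cand2$has_orthologous_pair <- FALSE
  expect_warning(got <- choose_source(cand2), "No candidate")
  expect_true(is.na(got))
  # deterministic tie-break by organism id
  cand3 <- tibble::tibble(organism = c("z", "a"), bit_score = 300,
                          has_orthologous_pair = TRUE)
  expect_equal(choose_source(cand3), "a")
})

test_that("upstream windows are strand-aware, enumerated per sub-operon, and clamped", {
  # singleton + gene at 1000 -> [750, 999]
  a1 <- annotation_from(1000, 1900, "+")
  r1 <- maximal_runs(a1)
  w1 <- upstream_windows("g01", a1, r1)
  expect_equal(c(w1$start, w1$end), c(750L, 999L))

  # third gene of a 4-gene run -> 3 windows (upstream of genes 1..3)
  a2 <- annotation_from(c(1000, 2000, 3000, 4000), c(1900, 2900, 3900, 4900),
                        rep("+", 4))
  w2 <- upstream_windows("g03", a2, maximal_runs(a2))
  expect_equal(nrow(w2), 3)
  expect_equal(w2$upstream_locus, c("g01", "g02", "g03"))

  # gene starting at 40 -> truncated window [1, 39]
  a3 <- annotation_from(40, 900, "+")
  w3 <- upstream_windows("g01", a3, maximal_runs(a3))
  expect_equal(c(w3$start, w3$end), c(1L, 39L))

  # minus strand: window sits 3' in genome coordinates, clamped by scaffold
  a4 <- annotation_from(1000, 1900, "-")
  w4 <- upstream_windows("g01", a4, maximal_runs(a4),
                         scaffold_lengths = c(sc1 = 2000))
  expect_equal(c(w4$start, w4$end), c(1901L, 2000L))
})

test_that("PWM scanning finds planted sites and is strand-symmetric", {
  p <- test_pwm(10, seed = 41)
  cons <- cofitval:::pwm_consensus(p)
  set.seed(42)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  seq1 <- bg
  substr(seq1, 101, 110) <- cons
  a <- annotation_from(351, 1200, "+")   # window [101, 350] holds the site
  runs <- maximal_runs(a)
  hit <- pwm_best_hit(upstream_windows("g01", a, runs), p, list(sc1 = seq1))
  expect_equal(hit$position, 1L)     # site at the window's first offset
  expect_equal(hit$strand, "+")
  lodds <- log2(p$probs / 0.25)
  expect_equal(hit$score, sum(apply(lodds, 1, max)), tolerance = 1e-9)

  # planting the reverse complement scores identically on the minus strand
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]), collapse = ""))
  seq2 <- bg
  substr(seq2, 101, 110) <- rc
  hit2 <- pwm_best_hit(upstream_windows("g01", a, runs), p, list(sc1 = seq2))
  expect_equal(hit2$score, hit$score)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$position, 1L)

  # a window shorter than the motif yields no hit
  short <- annotation_from(5, 900, "+")
  expect_null(pwm_best_hit(upstream_windows("g01", short, maximal_runs(short)),
                           p, list(sc1 = seq1)))
})

test_that("a uniform PWM scores zero everywhere and gives p = 1", {
  uni <- pwm(matrix(0.25, 6, 4), motif_id = "u", pseudocount = 0)
  cfg <- sim_config(n_genes = 30, mean_run_length = 1, seed = 43)
  genome <- simulate_genome(cfg)
  runs <- maximal_runs(genome$annotation)
  g <- genome$annotation$locus_id[5]
  hit <- pwm_best_hit(upstream_windows(g, genome$annotation, runs), uni,
                      genome$sequences)
  expect_equal(hit$score, 0)
  pv <- motif_empirical_pvalue(g, hit$score, genome$annotation, runs, uni,
                               genome$sequences)
  expect_equal(pv, 1)
})

test_that("the empirical motif p-value hits its floor for a unique best site", {
  p <- test_pwm(12, seed = 47)
  cfg <- sim_config(n_genes = 40, mean_run_length = 1, seed = 49)
  genome <- simulate_genome(cfg)
  target <- genome$annotation$locus_id[10]
  genome <- plant_motif_sites(genome, p, target)
  runs <- maximal_runs(genome$annotation)
  hit <- pwm_best_hit(upstream_windows(target, genome$annotation, runs), p,
                      genome$sequences)
  bs <- cofitval:::genome_best_scores(genome$annotation, runs, p, genome$sequences)
  pv <- motif_empirical_pvalue(target, hit$score, genome$annotation, runs, p,
                               genome$sequences, best_scores = bs)
  G <- sum(!is.na(bs[setdiff(names(bs), target)])) + 1
  expect_equal(pv, 1 / G)
  # p can never undercut the 1/G floor for any score
  pv_low <- motif_empirical_pvalue(target, -100, genome$annotation, runs, p,
                                   genome$sequences, best_scores = bs)
  expect_equal(pv_low, 1)
})

test_that("propagation keeps motif-supported orthologous pairs", {
  p <- test_pwm(12, seed = 53)
  cfg <- sim_config(n_genes = 25, mean_run_length = 1, protein_length = 80,
                    seed = 55)
  src <- simulate_genome(cfg, genome_id = "src")
  dst <- simulate_ortholog_genome(src, identity = 0.9, genome_id = "dst", seed = 56)
  ids <- src$annotation$locus_id
  preds <- dplyr::tibble(tf_locus = ids[1], group_id = "gr1", sign = "activator",
                         motif_id = "M1", targets = list(ids[2:4]))
  # plant sites upstream of two of the three mapped targets
  planted <- unname(dst$ortholog_map[ids[2:3]])
  dst <- plant_motif_sites(dst, p, planted)
  out <- propagate(preds, src$proteins, dst$proteins, dst$annotation,
                   as.list(dst$sequences), list(M1 = p))
  expect_equal(nrow(out$rbh), 25)   # all orthologs recovered
  expect_equal(nrow(out$pairs), 3)
  kept <- out$pairs$target_target[out$pairs$kept]
  # with only 25 genes the empirical p cannot resolve 0.01, so nothing can
  # pass at the default threshold; the planted sites dominate the ranking
  expect_true(all(out$pairs$motif_p[out$pairs$target_target %in% planted] <=
                    3 / 25))
  out2 <- propagate(preds, src$proteins, dst$proteins, dst$annotation,
                    as.list(dst$sequences), list(M1 = p), motif_alpha = 0.2)
  kept2 <- out2$pairs$target_target[out2$pairs$kept]
  expect_setequal(kept2, planted)
  expect_equal(out2$predictions$tf_locus, unname(dst$ortholog_map[ids[1]]))
  expect_setequal(out2$predictions$targets[[1]], planted)
})
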