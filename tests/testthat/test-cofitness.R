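test_that("pearson cofitness matches hand computation and is symmetric", {
  expect_equal(pearson_cofitness(1:10, 1:10, min_shared = 5)$cofitness, 1)
  expect_equal(pearson_cofitness(1:10, -(1:10), min_shared = 5)$cofitness, -1)
  got <- pearson_cofitness(c(1, 2, 3, 4), c(2, 1, 4, 3), min_shared = 2)
  expect_equal(got$cofitness, 0.6)
  expect_equal(got$m_shared, 4)

  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    x[sample(30, 5)] <- NA; y[sample(30, 5)] <- NA
    a <- pearson_cofitness(x, y, min_shared = 5)
    b <- pearson_cofitness(y, x, min_shared = 5)
    expect_identical(a$cofitness, b$cofitness)
    expect_equal(a$cofitness, suppressWarnings(cor(x, y, use = "pairwise.complete.obs")))
  }
})

test_that("cofitness is undefined under thin overlap or zero variance", {
  x <- c(1, 2, NA, NA, NA); y <- c(2, 1, 3, 4, 5)
  expect_true(is.na(pearson_cofitness(x, y, min_shared = 3)$cofitness))
  expect_true(is.na(pearson_cofitness(rep(1, 20), rnorm(20), min_shared = 5)$cofitness))
})

test_that("profile correlations agree with the per-pair oracle under missingness", {
  tab <- tiny_table(15, 40, seed = 9, genome_id = "g")
  tab$fitness[sample(length(tab$fitness), 60)] <- NA
  pc <- cofitval:::profile_correlations(tab$fitness, 1, min_shared = 10)
  for (j in 2:15) {
    oracle <- pearson_cofitness(tab$fitness[1, ], tab$fitness[j, ], min_shared = 10)
    expect_equal(pc$r[j], oracle$cofitness, tolerance = 1e-12)
    expect_equal(pc$m_shared[j], oracle$m_shared)
  }
})

test_that("gene distance is the midpoint distance, infinite across scaffolds", {
  a <- list(scaffold = "s1", begin = 500, end = 1500)    # midpoint 1000
  b <- list(scaffold = "s1", begin = 14500, end = 15500) # midpoint 15000
  expect_equal(gene_distance(a, a), 0)
  expect_equal(gene_distance(a, b), 14000)
  expect_equal(gene_distance(a, list(scaffold = "s2", begin = 500, end = 1500)), Inf)
})

test_that("bias subtraction touches only positive nearby pairs and reranks", {
  # profile against a table built so raw cofitness is controlled
  set.seed(1)
  z1 <- rnorm(100); z2 <- rnorm(100)
  mix <- function(rho, z, noise) rho * z + sqrt(1 - rho^2) * noise
  rows <- list(
    tf = z1,
    near_pos = mix(0.5, z1, rnorm(100)),
    near_neg = mix(-0.5, z1, rnorm(100)),
    far_pos = mix(0.5, z1, rnorm(100)),
    filler1 = rnorm(100), filler2 = rnorm(100)
  )
  tab <- table_from_rows(rows)
  # tf at 1kb; near genes ~6kb away; far gene 100kb away
  ann <- annotation_from(
    begin = c(1000, 6500, 7600, 101000, 52000, 64000),
    end = c(1900, 7400, 8500, 101900, 52900, 64900),
    strand = rep("+", 6),
    ids = names(rows)
  )
  b <- structure(list(genome_id = "built", bias = 0.02, median_close = NA,
                      median_far = NA, n_close = 0L, n_far = 0L, seed = 1L),
                 class = "bias_estimate")
  prof <- corrected_cofitness_profile("tf", tab, ann, bias = b, min_shared = 10)
  near_pos <- prof[prof$partner == "near_pos", ]
  near_neg <- prof[prof$partner == "near_neg", ]
  far_pos <- prof[prof$partner == "far_pos", ]
  expect_equal(near_pos$corrected, near_pos$raw - 0.02)
  expect_equal(near_neg$corrected, near_neg$raw)   # negative pairs untouched
  expect_equal(far_pos$corrected, far_pos$raw)     # distant pairs untouched

  prof0 <- corrected_cofitness_profile("tf", tab, ann, bias = zero_bias(), min_shared = 10)
  expect_equal(prof0$corrected, prof0$raw)
  expect_equal(prof0$rank, rank(-prof0$raw, ties.method = "min"))
})

test_that("profile ranks satisfy the competition-rank contract", {
  tab <- tiny_table(60, 50, seed = 21, genome_id = "g")
  prof <- corrected_cofitness_profile("g01", tab, min_shared = 10)
  def <- !is.na(prof$corrected)
  expect_equal(prof$partner[which(prof$rank == 1)],
               prof$partner[def][which.max(prof$corrected[def])])
  expect_equal(prof$partner[which(prof$anti_rank == 1)],
               prof$partner[def][which.min(prof$corrected[def])])
  for (i in sample(which(def), 10)) {
    expect_equal(sum(prof$corrected[def] > prof$corrected[i]), prof$rank[i] - 1)
  }
  # ranks are permutations-with-ties of 1..n_defined
  expect_true(all(prof$rank[def] >= 1 & prof$rank[def] <= sum(def)))
  expect_equal(min(prof$rank[def]), 1L)
  expect_equal(min(prof$anti_rank[def]), 1L)
})

test_that("planted proximity bias is recovered and never negative", {
  cfg <- sim_config(n_genes = 250, n_experiments = 150, mean_run_length = 1,
                    inter_gap_range = c(2200, 3000), bias_amplitude = 0.3,
                    bias_tau = 40000, seed = 31)
  genome <- simulate_genome(cfg)
  tab <- simulate_fitness(genome, NULL, seed = 32)
  est <- estimate_position_bias(tab, genome$annotation, n_pairs = 400, seed = 33)
  expect_gte(est$bias, 0)
  expect_equal(est$bias, 0.3, tolerance = 0.35)  # right order, small genome
  expect_equal(est$bias, max(0, est$median_close - est$median_far))
})

test_that("the bias estimator is deterministic under a fixed seed", {
  tab <- tiny_table(80, 60, seed = 5, genome_id = "g")
  ann <- linear_annotation(80, gene_len = 900, gap = 2100)
  e1 <- estimate_position_bias(tab, ann, n_pairs = 200, seed = 7)
  e2 <- estimate_position_bias(tab, ann, n_pairs = 200, seed = 7)
  expect_identical(glance(e1), glance(e2))
})
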