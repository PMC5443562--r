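test_that("the significant-phenotype gate uses strict thresholds on both values", {
  expect_true(significant_phenotype(c(-0.6, 0.1), c(-5, 1)))
  expect_false(significant_phenotype(c(-0.6, 0.9), c(-3.9, 3.9)))
  expect_false(significant_phenotype(c(0.5, 0.2), c(10, 1)))   # |fit| not > 0.5
  expect_false(significant_phenotype(c(NA, 0.9), c(10, NA)))   # both must be present
})

test_that("the rank-based p-value matches the extreme-value formula", {
  expect_equal(rank_pvalue(1, 19, 3789), 2 * (1 - (1 - 1 / 3788)^19))
  expect_gt(rank_pvalue(1, 19, 3789), 0.01)
  expect_lte(rank_pvalue(1, 18, 3789), 0.01)
  expect_equal(rank_pvalue(3788, 5, 3789), 1)   # R = N-1 caps at 1
  expect_error(rank_pvalue(1, 0, 3789), "T = 0")
  expect_error(rank_pvalue(0, 3, 3789), "1..N-1")
})

test_that("rank p is monotone in rank and in target count", {
  for (T_ in c(1, 3, 10)) {
    p <- rank_pvalue(1:50, T_, 1000)
    expect_true(all(diff(p) >= 0))
  }
  for (R_ in c(1, 5, 25)) {
    p <- vapply(1:30, function(T_) rank_pvalue(R_, T_, 1000), numeric(1))
    expect_true(all(diff(p) >= 0))
  }
})

test_that("the rank p-value matches a with-replacement Monte-Carlo draw", {
  # small-n version of the sampling model: top rank of T uniform draws
  set.seed(101)
  N <- 200; T_ <- 4; reps <- 20000
  top <- matrix(sample.int(N - 1, T_ * reps, replace = TRUE), ncol = T_) |>
    apply(1, min)
  for (R_ in c(1, 5, 15)) {
    p_model <- 1 - (1 - R_ / (N - 1))^T_
    p_hat <- mean(top <= R_)
    se <- sqrt(p_model * (1 - p_model) / reps)
    expect_lt(abs(p_hat - p_model), 3.5 * se)
  }
})

test_that("the Fisher-transform p-value matches the closed form", {
  expect_equal(fisher_pvalue(0, 50, 1, "positive"), 1)
  got <- fisher_pvalue(0.5, 103, 1, "positive")
  expect_equal(got, 2 * pnorm(sqrt(100) * atanh(0.5), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(got, 3.95e-8, tolerance = 0.01)
  expect_equal(fisher_pvalue(-0.5, 103, 1, "negative"),
               fisher_pvalue(0.5, 103, 1, "positive"))
  expect_gt(fisher_pvalue(1, 50, 1, "positive"), 0)   # underflow, not error
  expect_error(fisher_pvalue(0.5, 3, 1, "positive"), "M >= 4")
  # monotone in |r| and M
  expect_true(all(diff(fisher_pvalue(seq(0.1, 0.9, 0.1), 50, 2, "positive")) <= 0))
  expect_true(all(diff(vapply(c(10, 40, 160), function(M)
    fisher_pvalue(0.5, M, 2, "positive"), numeric(1))) <= 0))
})

test_that("plug-in FDR arithmetic matches its definition", {
  expect_equal(estimate_fdr(0.01, 100, 100), 0.01)
  expect_equal(estimate_fdr(0.05, 40, 10), 0.2)
  expect_warning(got <- estimate_fdr(0.01, 50, 0), "undefined")
  expect_true(is.na(got))
})

test_that("planted activators and repressors validate with the correct sign", {
  cfg <- sim_config(n_genes = 2000, n_experiments = 100, mean_run_length = 1,
                    seed = 51,
                    tf_specs = tibble::tibble(sign = c("activator", "repressor"),
                                              n_targets = c(2, 2),
                                              coupling = c(0.9, 0.9),
                                              polar = c(FALSE, FALSE)))
  st <- simulate_regulon_study(cfg)
  res <- validate_predictions(st$predictions, st$table, st$genome$annotation,
                              correct_bias = FALSE)
  expect_true(all(res$tested))
  expect_true(all(res$validated))
  expect_equal(res$sign, st$truth$sign)
  expect_equal(res$top_target_act[res$sign == "activator"],
               st$truth$primary_target[st$truth$sign == "activator"])
  g <- glance(res)
  expect_equal(g$n_validated, 2L)
  expect_equal(g$fdr, 0.01 * 2 / 2)
})

test_that("two anti-correlated targets yield an ambiguous sign call", {
  set.seed(61)
  z <- rnorm(120)
  rows <- c(
    list(tf = z,
         t_plus = 0.95 * z + sqrt(1 - 0.95^2) * rnorm(120),
         t_minus = -0.95 * z + sqrt(1 - 0.95^2) * rnorm(120)),
    setNames(lapply(1:600, function(i) rnorm(120)), sprintf("f%03d", 1:600))
  )
  tab <- table_from_rows(rows)
  prof <- corrected_cofitness_profile("tf", tab)
  res <- validate_tf("tf", c("t_plus", "t_minus"), prof, tab)
  expect_true(res$validated)
  expect_equal(res$sign, "ambiguous")
  expect_lte(res$p_activator, 0.01)
  expect_lte(res$p_repressor, 0.01)
  expect_equal(res$R, 1L)
  expect_equal(res$R_prime, 1L)
})

test_that("combined p-values obey the max rule and untestable TFs are recorded", {
  tab <- tiny_table(50, 40, seed = 71, genome_id = "g")
  prof <- corrected_cofitness_profile("g01", tab, min_shared = 10)
  res <- validate_tf("g01", c("g10", "g20", "g30"), prof, tab)
  expect_equal(res$p_activator, max(res$p_fisher_act, res$p_rank_act))
  expect_equal(res$p_repressor, max(res$p_fisher_rep, res$p_rank_rep))
  expect_equal(res$T, 3L)
  expect_equal(res$N, 50L)

  # all targets unknown -> untestable, not an error
  expect_warning(res2 <- validate_tf("g01", c("zz1", "zz2"), prof, tab),
                 "without fitness data")
  expect_false(res2$tested)
  expect_equal(res2$note, "no usable targets")

  # the TF itself is excluded from its own target list
  res3 <- validate_tf("g01", c("g01", "g10"), prof, tab)
  expect_equal(res3$T, 1L)
})

test_that("TFs without a significant phenotype are gated out, not validated", {
  set.seed(81)
  z <- rnorm(80)
  rows <- c(list(tf = z * 0.1, target = z * 0.1),
            setNames(lapply(1:300, function(i) rnorm(80)), sprintf("f%03d", 1:300)))
  tab <- table_from_rows(rows)   # t = 4*fit stays below the gate for tf
  prof <- corrected_cofitness_profile("tf", tab)
  res <- validate_tf("tf", "target", prof, tab)
  expect_false(res$has_phenotype)
  expect_false(res$tested)
  expect_false(res$validated)
  # gate off: same inputs now validate on the perfect correlation
  res2 <- validate_tf("tf", "target", prof, tab, gate_phenotype = FALSE)
  expect_true(res2$validated)
})

test_that("association-matrix mode reproduces the cofitness test without the gate", {
  tab <- tiny_table(120, 60, seed = 91, genome_id = "g")
  prof <- corrected_cofitness_profile("g01", tab, min_shared = 10)
  # build the association matrix whose row for g01 equals the profile
  ids <- c("g01", prof$partner)
  m <- diag(1, length(ids)); dimnames(m) <- list(ids, ids)
  m["g01", prof$partner] <- prof$corrected
  m[prof$partner, "g01"] <- prof$corrected
  targets <- c("g10", "g50", "g99")
  M <- prof$m_shared[match("g10", prof$partner)]
  a <- validate_from_association("g01", targets, m, M = M)
  b <- validate_tf("g01", targets, prof, tab, gate_phenotype = FALSE)
  expect_equal(a$p_activator, b$p_activator, tolerance = 1e-12)
  expect_equal(a$p_repressor, b$p_repressor, tolerance = 1e-12)
  expect_equal(a$R, b$R)

  # a planted coexpressed target validates once the genome is large enough
  # for a rank of 1 to clear the threshold (2/(N-1) <= 0.01 needs N > 200)
  set.seed(97)
  ids3 <- sprintf("x%03d", 1:300)
  m2 <- diag(1, 300); dimnames(m2) <- list(ids3, ids3)
  off <- row(m2) != col(m2)
  noise <- matrix(0, 300, 300); noise[off] <- runif(sum(off), -0.2, 0.2)
  noise <- (noise + t(noise)) / 2
  m2 <- pmax(pmin(m2 + noise, 1), -1); diag(m2) <- 1
  m2["x001", "x010"] <- m2["x010", "x001"] <- 0.8
  got <- validate_from_association("x001", "x010", m2, M = 200)
  expect_true(got$validated)
  expect_equal(got$sign, "activator")
  none <- validate_from_association("x001", c("x002", "x003"), m2, M = 200)
  expect_false(none$validated)
  expect_error(validate_from_association("nope", "x002", m2, M = 100), "absent")
})
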