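# Cofitness: Pearson correlation of fitness profiles, estimation and
# subtraction of the chromosomal-proximity bias, and (anti-)cofitness ranks.

#' Pearson cofitness of two fitness vectors
#'
#' Cofitness is the Pearson correlation of two genes' fitness patterns over
#' the experiments where both are measured. The correlation is undefined
#' (`NA`) when fewer than `min_shared` experiments are shared or when either
#' restricted vector has zero variance — undefined is a value, not an error.
#'
#' @param x,y Numeric fitness vectors indexed by the same experiments.
#' @param min_shared Minimum number of shared experiments for a defined
#'   correlation (default 10; guards against spurious ±1 from tiny overlap).
#' @return A list with `cofitness` (possibly `NA`) and `m_shared`, the count
#'   of shared experiments.
#' @export
pearson_cofitness <- function(x, y, min_shared = 10) {
  if (length(x) != length(y)) abort("`x` and `y` must be indexed by the same experiments.")
  ok <- !is.na(x) & !is.na(y)
  m <- sum(ok)
  r <- NA_real_
  if (m >= max(min_shared, 2)) {
    xs <- x[ok]; ys <- y[ok]
    if (stats::sd(xs) > 0 && stats::sd(ys) > 0) r <- cor(xs, ys)
  }
  list(cofitness = r, m_shared = m)
}

# Correlations of one focal row against every row of a matrix, pairwise
# complete, in one set of matrix products. Returns cofitness + shared counts.
profile_correlations <- function(fit, focal_row, min_shared = 10) {
  f <- fit[focal_row, ]
  fm <- !is.na(f)
  f0 <- ifelse(fm, f, 0)
  M <- !is.na(fit)
  X0 <- ifelse(M, fit, 0)
  fmn <- as.numeric(fm)
  n <- as.vector(M %*% fmn)
  Sx <- as.vector(X0 %*% fmn)
  Sxx <- as.vector((X0^2) %*% fmn)
  Sy <- as.vector(M %*% f0)
  Syy <- as.vector(M %*% (f0^2))
  Sxy <- as.vector(X0 %*% f0)
  num <- n * Sxy - Sx * Sy
  den2 <- (n * Sxx - Sx^2) * (n * Syy - Sy^2)
  r <- ifelse(n >= max(min_shared, 2) & den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  # clamp numerical overshoot
  r <- pmin(1, pmax(-1, r))
  list(r = r, m_shared = n)
}

#' Distance between two genes
#'
#' The absolute difference of gene midpoints `(begin + end) / 2`, or `Inf`
#' when the genes lie on different scaffolds (the far class of the bias
#' estimation includes cross-scaffold pairs).
#'
#' @param a,b One-row data frames (or lists) with `scaffold`, `begin`, `end`.
#' @return Distance in bp, possibly `Inf`.
#' @export
gene_distance <- function(a, b) {
  if (!identical(as.character(a$scaffold), as.character(b$scaffold))) return(Inf)
  abs((a$begin + a$end) / 2 - (b$begin + b$end) / 2)
}

# midpoints aligned to the fitness table's gene order; NA for genes without
# annotation
gene_midpoints <- function(ann, gene_ids) {
  i <- match(gene_ids, ann$locus_id)
  list(
    mid = (ann$begin[i] + ann$end[i]) / 2,
    scaffold = ann$scaffold[i]
  )
}

#' Estimate the chromosomal-proximity cofitness bias
#'
#' Closely located gene pairs tend to have slightly higher cofitness than
#' distant pairs (a residue of chromosomal-position effects on DNA copy
#' number). The bias for a genome is estimated by sampling `n_pairs` gene
#' pairs at most `close_max` bp apart and `n_pairs` pairs at least `far_min`
#' bp apart or on different scaffolds, taking the median cofitness of each
#' sample, and setting `bias = max(0, median_close - median_far)`.
#'
#' Pairs are sampled uniformly with replacement from the eligible pairs of
#' each distance class using a seeded generator; pairs with undefined
#' cofitness are skipped. If a class has no eligible pair the bias is 0 with
#' a warning.
#'
#' @param table A [fitness_table()].
#' @param ann A `genome_annotation`.
#' @param n_pairs Pairs to sample per distance class (default 1000).
#' @param close_max Maximum midpoint distance of the close class (bp).
#' @param far_min Minimum midpoint distance of the far class (bp).
#' @param min_shared Passed to the correlation (see [pearson_cofitness()]).
#' @param seed Integer seed for the pair sampling.
#' @return An object of class `bias_estimate` with fields `genome_id`,
#'   `bias`, `median_close`, `median_far`, `n_close`, `n_far`, `seed`.
#' @export
estimate_position_bias <- function(table, ann, n_pairs = 1000, close_max = 20000,
                                   far_min = 50000, min_shared = 10, seed = 1) {
  ids <- intersect(table$gene_ids, ann$locus_id)
  if (length(ids) < 4) abort("Too few annotated genes with fitness data.")
  fit <- table$fitness[ids, , drop = FALSE]
  pos <- gene_midpoints(ann, ids)
  ord <- order(pos$scaffold, pos$mid)
  G <- length(ids)

  pair_cor <- function(i, j) {
    ok <- !is.na(fit[i, ]) & !is.na(fit[j, ])
    if (sum(ok) < max(min_shared, 2)) return(NA_real_)
    xi <- fit[i, ok]; xj <- fit[j, ok]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) return(NA_real_)
    cor(xi, xj)
  }

  # enumerate close pairs by sliding over midpoint-sorted genes per scaffold
  close_i <- integer(0); close_j <- integer(0)
  for (sc in unique(pos$scaffold)) {
    idx <- ord[pos$scaffold[ord] == sc]
    mids <- pos$mid[idx]
    lo <- 1
    for (k in seq_along(idx)) {
      while (mids[k] - mids[lo] > close_max) lo <- lo + 1
      if (lo < k) {
        close_i <- c(close_i, idx[lo:(k - 1)])
        close_j <- c(close_j, rep(idx[k], k - lo))
      }
    }
  }

  rng <- local_rng(seed)
  sample_class <- function(kind) {
    vals <- numeric(0)
    attempts <- 0
    max_attempts <- 200 * n_pairs
    if (kind == "close" && length(close_i) == 0) return(vals)
    while (length(vals) < n_pairs && attempts < max_attempts) {
      need <- n_pairs - length(vals)
      draw <- max(need * 2, 32)
      attempts <- attempts + draw
      if (kind == "close") {
        k <- rng$sample_int(length(close_i), draw, replace = TRUE)
        ii <- close_i[k]; jj <- close_j[k]
        keepf <- rep(TRUE, draw)
      } else {
        ii <- rng$sample_int(G, draw, replace = TRUE)
        jj <- rng$sample_int(G, draw, replace = TRUE)
        d <- ifelse(pos$scaffold[ii] == pos$scaffold[jj],
                    abs(pos$mid[ii] - pos$mid[jj]), Inf)
        keepf <- ii != jj & (d >= far_min)
      }
      for (t in which(keepf)) {
        if (length(vals) >= n_pairs) break
        r <- pair_cor(ii[t], jj[t])
        if (!is.na(r)) vals <- c(vals, r)
      }
    }
    vals
  }

  close_vals <- sample_class("close")
  far_vals <- sample_class("far")
  if (length(close_vals) == 0 || length(far_vals) == 0) {
    warn("A distance class has no eligible pairs; proximity bias set to 0.")
    est <- list(bias = 0, median_close = NA_real_, median_far = NA_real_)
  } else {
    mc <- median(close_vals); mf <- median(far_vals)
    est <- list(bias = max(0, mc - mf), median_close = mc, median_far = mf)
  }
  structure(
    list(genome_id = table$genome_id, bias = est$bias,
         median_close = est$median_close, median_far = est$median_far,
         n_close = length(close_vals), n_far = length(far_vals), seed = seed),
    class = "bias_estimate"
  )
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("<bias_estimate> %s: bias %.4f (median close %.4f, far %.4f; n = %d/%d, seed %d)\n",
              x$genome_id, x$bias,
              x$median_close %||% NA, x$median_far %||% NA,
              x$n_close, x$n_far, x$seed))
  invisible(x)
}

#' @rdname estimate_position_bias
#' @param x A `bias_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.bias_estimate <- function(x, ...) {
  tibble(genome_id = x$genome_id, bias = x$bias, median_close = x$median_close,
         median_far = x$median_far, n_close = x$n_close, n_far = x$n_far,
         seed = x$seed)
}

#' Zero bias estimate
#'
#' Convenience constructor for running the pipeline without bias correction.
#'
#' @param genome_id Genome identifier.
#' @return A `bias_estimate` with bias 0.
#' @export
zero_bias <- function(genome_id = "genome") {
  structure(list(genome_id = genome_id, bias = 0, median_close = NA_real_,
                 median_far = NA_real_, n_close = 0L, n_far = 0L, seed = NA_integer_),
            class = "bias_estimate")
}

#' Bias-corrected cofitness profile of a focal gene
#'
#' Computes the focal gene's cofitness with every other gene that has
#' fitness data, subtracts the proximity bias from positively cofit pairs at
#' most `close_max` bp apart (negative pairs and distant pairs are left
#' untouched), and ranks the corrected values. The cofitness rank is a
#' competition ("min") rank by descending corrected cofitness (rank 1 = most
#' positive); the anti-cofitness rank is by ascending value (rank 1 = most
#' negative). Partners with undefined cofitness are excluded from ranking.
#'
#' @param focal Locus id of the focal gene (typically a TF).
#' @param table A [fitness_table()].
#' @param ann A `genome_annotation` (may omit genes; unannotated partners get
#'   infinite distance and hence no correction).
#' @param bias A `bias_estimate` (see [estimate_position_bias()]), or `NULL`
#'   for no correction.
#' @param min_shared Minimum shared experiments for a defined correlation.
#' @param close_max Maximum midpoint distance for the correction (bp).
#' @return A tibble of class `cofitness_profile` with columns `partner`,
#'   `raw`, `corrected`, `m_shared`, `rank`, `anti_rank` and attributes
#'   `focal`, `bias`, `n_defined`.
#' @export
corrected_cofitness_profile <- function(focal, table, ann = NULL, bias = NULL,
                                        min_shared = 10, close_max = 20000) {
  if (!focal %in% table$gene_ids) {
    abort(sprintf("Focal gene '%s' has no fitness data.", focal))
  }
  i <- match(focal, table$gene_ids)
  pc <- profile_correlations(table$fitness, i, min_shared = min_shared)
  partners <- setdiff(seq_along(table$gene_ids), i)
  raw <- pc$r[partners]
  m_shared <- pc$m_shared[partners]
  ids <- table$gene_ids[partners]

  b <- if (is.null(bias)) 0 else bias$bias
  corrected <- raw
  if (b > 0 && !is.null(ann)) {
    pos <- gene_midpoints(ann, c(focal, ids))
    fmid <- pos$mid[1]; fsc <- pos$scaffold[1]
    d <- ifelse(!is.na(pos$scaffold[-1]) & !is.na(fsc) & pos$scaffold[-1] == fsc,
                abs(pos$mid[-1] - fmid), Inf)
    near_pos <- !is.na(raw) & raw > 0 & d <= close_max
    corrected[near_pos] <- raw[near_pos] - b
  }

  rk <- rep(NA_integer_, length(corrected))
  ark <- rk
  def <- !is.na(corrected)
  if (any(def)) {
    rk[def] <- as.integer(rank(-corrected[def], ties.method = "min"))
    ark[def] <- as.integer(rank(corrected[def], ties.method = "min"))
  }
  out <- tibble(partner = ids, raw = raw, corrected = corrected,
                m_shared = as.integer(m_shared), rank = rk, anti_rank = ark)
  class(out) <- c("cofitness_profile", class(out))
  attr(out, "focal") <- focal
  attr(out, "bias") <- b
  attr(out, "n_defined") <- sum(def)
  out
}

#' @export
print.cofitness_profile <- function(x, ...) {
  cat(sprintf("<cofitness_profile> focal %s: %d partners (%d defined), bias %.4f\n",
              attr(x, "focal"), nrow(x), attr(x, "n_defined"), attr(x, "bias")))
  NextMethod()
}
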