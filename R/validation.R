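# The core hypothesis test. A TF-motif prediction is statistically
# validated when (i) the TF has a significant phenotype, and (ii) both the
# rank-based test on the top target's (anti-)cofitness rank and the
# Fisher-transform test on the top target's cofitness give p <= alpha. The
# sign of the regulation follows from which side passes.

#' Significant-phenotype gate
#'
#' A gene has a significant phenotype if in at least one experiment both
#' `|fitness| > fit_thresh` and `|t| > t_thresh` (strict inequalities, both
#' values present). Only TFs passing this gate are tested.
#'
#' @param fit_row,t_row Fitness and t-statistic vectors aligned by experiment.
#' @param fit_thresh Fitness threshold (default 0.5).
#' @param t_thresh t threshold (default 4).
#' @return Logical scalar.
#' @export
significant_phenotype <- function(fit_row, t_row, fit_thresh = 0.5, t_thresh = 4) {
  ok <- !is.na(fit_row) & !is.na(t_row)
  any(abs(fit_row[ok]) > fit_thresh & abs(t_row[ok]) > t_thresh)
}

#' Rank-based extreme-value p-value
#'
#' Under the null, a TF's predicted targets behave like a random sample of
#' `T` genes, so their top (anti-)cofitness rank `R` among the `N - 1` other
#' genes follows the minimum of `T` uniform draws (with replacement). The
#' p-value is `2 * [1 - (1 - R/(N-1))^T]`, capped at 1; the factor 2 is the
#' Bonferroni correction for testing both regulatory signs. The same formula
#' serves activators (cofitness rank) and repressors (anti-cofitness rank).
#'
#' @param R_obs Observed top rank among the targets (1 = most extreme).
#' @param T_targets Number of predicted targets with data, excluding the TF.
#' @param N Number of genes with fitness data in the genome.
#' @return p-value in (0, 1].
#' @export
rank_pvalue <- function(R_obs, T_targets, N) {
  if (any(T_targets < 1)) abort("TF has no targets with data (T = 0 is untestable).")
  if (any(N < 3)) abort("Need N >= 3 genes with fitness data.")
  if (any(R_obs < 1 | R_obs > N - 1)) abort("Rank must lie in 1..N-1.")
  pmin(1, 2 * (1 - (1 - R_obs / (N - 1))^T_targets))
}

#' Fisher-transform p-value for a top cofitness value
#'
#' Transforms the top target's correlation `r`, computed from `M` shared
#' fitness values, to `z = sqrt(M - 3) * atanh(r)`; the one-sided standard
#' normal tail is then Bonferroni-corrected for testing both signs and `T`
#' targets: `p = min(1, 2 * T * p1)`.
#'
#' @param r Correlation of the top pair, `|r| < 1` (at `|r| = 1` the p-value
#'   underflows to the smallest positive double rather than erroring).
#' @param M Number of shared fitness values behind `r` (must be >= 4).
#' @param T_targets Number of targets tested (Bonferroni multiplier).
#' @param side `"positive"` tests for cofitness (activators), `"negative"`
#'   for anti-cofitness (repressors).
#' @return p-value in (0, 1].
#' @export
fisher_pvalue <- function(r, M, T_targets, side = c("positive", "negative")) {
  side <- match.arg(side)
  if (any(M < 4)) abort("Fisher test needs M >= 4 fitness values.")
  if (any(T_targets < 1)) abort("T must be >= 1.")
  z <- sqrt(M - 3) * atanh(pmin(1 - 1e-16, pmax(-1 + 1e-16, r)))
  p1 <- if (side == "positive") pnorm(z, lower.tail = FALSE) else pnorm(z)
  pmax(.Machine$double.xmin, pmin(1, 2 * T_targets * p1))
}

#' Plug-in false discovery rate
#'
#' The FDR of the validated set is estimated as the expected false positives
#' over the observed positives: `alpha * n_tested / n_validated`, treating
#' the combined procedure as a single test at level `alpha`.
#'
#' @param alpha Significance threshold used for validation (default 0.01).
#' @param n_tested Number of TFs tested.
#' @param n_validated Number of TFs validated.
#' @return FDR estimate (may exceed 1 for tiny validated sets).
#' @export
estimate_fdr <- function(alpha, n_tested, n_validated) {
  if (n_validated < 1) {
    warn("No validated TFs; FDR is undefined.")
    return(NA_real_)
  }
  alpha * n_tested / n_validated
}

empty_result <- function(tf, reason, N = NA_integer_, has_phenotype = NA) {
  tibble(
    tf_locus = tf, N = N, T = NA_integer_, M_top = NA_integer_,
    R = NA_integer_, R_prime = NA_integer_, r_max = NA_real_, r_min = NA_real_,
    top_target_act = NA_character_, top_target_rep = NA_character_,
    p_rank_act = NA_real_, p_rank_rep = NA_real_,
    p_fisher_act = NA_real_, p_fisher_rep = NA_real_,
    p_activator = NA_real_, p_repressor = NA_real_,
    has_phenotype = has_phenotype, tested = FALSE, validated = FALSE,
    sign = "none", note = reason
  )
}

#' Test one TF against its predicted targets
#'
#' Given the TF's bias-corrected cofitness profile, takes the most favorable
#' target on each side (top cofitness rank `R`, top anti-cofitness rank
#' `R'`), computes the rank-based and Fisher p-values for each side,
#' combines them as `p_side = max(p_fisher_side, p_rank_side)`, and applies
#' the significant-phenotype gate. The TF is validated when it has a
#' phenotype and `min(p_activator, p_repressor) <= alpha`; the sign call is
#' `activator` if only the activator side passes, `repressor` if only the
#' repressor side, `ambiguous` if both (two targets with anti-correlated
#' phenotypes), `none` otherwise.
#'
#' `M` for the Fisher test is the shared-experiment count of the specific
#' top pair on that side. Targets equal to the TF, absent from the table, or
#' with undefined cofitness are dropped (with a warning for absent ones);
#' `T` counts the remaining targets.
#'
#' @param tf Locus id of the TF.
#' @param targets Character vector of predicted target locus ids.
#' @param profile The TF's [corrected_cofitness_profile()].
#' @param table The [fitness_table()] (used for the phenotype gate).
#' @param alpha Significance threshold (default 0.01).
#' @param gate_phenotype Apply the significant-phenotype gate (default TRUE;
#'   the coexpression mode turns it off).
#' @param fit_thresh,t_thresh Phenotype gate thresholds.
#' @return A one-row tibble (fields of the TF test result; see README).
#' @export
validate_tf <- function(tf, targets, profile, table = NULL, alpha = 0.01,
                        gate_phenotype = TRUE, fit_thresh = 0.5, t_thresh = 4) {
  stopifnot(inherits(profile, "cofitness_profile"))
  if (!identical(attr(profile, "focal"), tf)) {
    abort("`profile` was computed for a different focal gene.")
  }
  targets <- setdiff(unique(targets), tf)

  has_phen <- NA
  if (gate_phenotype) {
    if (is.null(table)) abort("`table` is required when the phenotype gate is on.")
    i <- match(tf, table$gene_ids)
    if (is.na(i)) abort(sprintf("TF '%s' has no fitness data.", tf))
    has_phen <- significant_phenotype(table$fitness[i, ], table$t_stats[i, ],
                                      fit_thresh, t_thresh)
  }

  known <- targets %in% profile$partner
  if (any(!known) && length(targets) > 0) {
    warn(sprintf("Dropping %d target(s) of %s without fitness data: %s",
                 sum(!known), tf, paste(targets[!known], collapse = ", ")))
  }
  idx <- match(targets[known], profile$partner)
  idx <- idx[!is.na(profile$corrected[idx])]
  N <- attr(profile, "n_defined") + 1L

  if (length(idx) == 0) {
    return(empty_result(tf, "no usable targets", N = N, has_phenotype = has_phen))
  }
  if (isFALSE(has_phen)) {
    res <- empty_result(tf, "no significant phenotype", N = N, has_phenotype = FALSE)
    res$T <- length(idx)
    return(res)
  }

  T_targets <- length(idx)
  i_act <- idx[which.max(profile$corrected[idx])]
  i_rep <- idx[which.min(profile$corrected[idx])]
  R <- min(profile$rank[idx])
  R_prime <- min(profile$anti_rank[idx])
  r_max <- profile$corrected[i_act]
  r_min <- profile$corrected[i_rep]
  M_act <- profile$m_shared[i_act]
  M_rep <- profile$m_shared[i_rep]

  p_rank_act <- rank_pvalue(R, T_targets, N)
  p_rank_rep <- rank_pvalue(R_prime, T_targets, N)
  p_fisher_act <- fisher_pvalue(r_max, M_act, T_targets, side = "positive")
  p_fisher_rep <- fisher_pvalue(r_min, M_rep, T_targets, side = "negative")
  p_activator <- max(p_fisher_act, p_rank_act)
  p_repressor <- max(p_fisher_rep, p_rank_rep)

  act <- p_activator <= alpha
  rep_ <- p_repressor <= alpha
  gate_ok <- !isFALSE(has_phen)
  validated <- gate_ok && (act || rep_)
  sign <- if (!validated) "none"
          else if (act && rep_) "ambiguous"
          else if (act) "activator" else "repressor"

  tibble(
    tf_locus = tf, N = N, T = T_targets, M_top = as.integer(M_act),
    R = as.integer(R), R_prime = as.integer(R_prime),
    r_max = r_max, r_min = r_min,
    top_target_act = profile$partner[i_act], top_target_rep = profile$partner[i_rep],
    p_rank_act = p_rank_act, p_rank_rep = p_rank_rep,
    p_fisher_act = p_fisher_act, p_fisher_rep = p_fisher_rep,
    p_activator = p_activator, p_repressor = p_repressor,
    has_phenotype = has_phen, tested = TRUE, validated = validated,
    sign = sign, note = NA_character_
  )
}

#' Validate a whole prediction set
#'
#' Runs the complete procedure over a predictions tibble: estimates the
#' proximity bias once for the genome (unless one is supplied or correction
#' is off), computes each TF's corrected cofitness profile, tests each TF,
#' and flags predictions vulnerable to polar effects (TF co-transcribed with
#' a predicted target). The returned tibble has one row per prediction and
#' carries `alpha`, the bias estimate, and the tested/validated tallies as
#' attributes; [glance()] summarizes them and [estimate_fdr()] arithmetic is
#' included.
#'
#' @param predictions Tibble with `tf_locus`, list-column `targets`, and
#'   optionally `group_id`, `sign` (annotated), `motif_id` (see
#'   [read_predictions()]).
#' @param table A [fitness_table()].
#' @param ann A `genome_annotation`, or `NULL` (no bias correction, no polar
#'   flags).
#' @param alpha Significance threshold (default 0.01).
#' @param bias A precomputed `bias_estimate`, or `NULL` to estimate it here.
#' @param correct_bias Apply proximity-bias correction (default TRUE).
#' @param seed Seed for the bias-estimation sampling.
#' @param min_shared Minimum shared experiments for defined cofitness.
#' @param fit_thresh,t_thresh Phenotype gate thresholds.
#' @param operon_max_gap Intergenic gap (bp) below which adjacent same-strand
#'   genes are treated as one potential operon, for the polar flag.
#' @return A tibble of class `tf_validation`.
#' @export
validate_predictions <- function(predictions, table, ann = NULL, alpha = 0.01,
                                 bias = NULL, correct_bias = TRUE, seed = 1,
                                 min_shared = 10, fit_thresh = 0.5, t_thresh = 4,
                                 operon_max_gap = 250) {
  stopifnot(is.data.frame(predictions), inherits(table, "fitness_table"))
  if (is.null(bias)) {
    bias <- if (correct_bias && !is.null(ann)) {
      estimate_position_bias(table, ann, min_shared = min_shared, seed = seed)
    } else {
      zero_bias(table$genome_id)
    }
  }
  runs <- if (!is.null(ann)) maximal_runs(ann, max_gap = operon_max_gap) else NULL

  rows <- vector("list", nrow(predictions))
  for (k in seq_len(nrow(predictions))) {
    tf <- predictions$tf_locus[k]
    tg <- predictions$targets[[k]]
    if (!tf %in% table$gene_ids) {
      r <- empty_result(tf, "TF has no fitness data")
    } else {
      prof <- corrected_cofitness_profile(tf, table, ann = ann, bias = bias,
                                          min_shared = min_shared)
      r <- validate_tf(tf, tg, prof, table, alpha = alpha,
                       fit_thresh = fit_thresh, t_thresh = t_thresh)
    }
    r$group_id <- (predictions$group_id %||% rep(NA_character_, nrow(predictions)))[k]
    r$annotated_sign <- (predictions$sign %||% rep(NA_character_, nrow(predictions)))[k]
    r$motif_id <- (predictions$motif_id %||% rep(NA_character_, nrow(predictions)))[k]
    r$polar <- if (is.null(runs)) NA else flag_polar(list(tf_locus = tf, targets = tg), runs)
    rows[[k]] <- r
  }
  out <- bind_rows(rows)
  class(out) <- c("tf_validation", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "bias") <- bias
  attr(out, "seed") <- seed
  out
}

#' Summarize a validation run
#'
#' @param x A `tf_validation` tibble.
#' @param ... Unused.
#' @return A one-row tibble: TFs tested, validated, plug-in FDR, and sign
#'   tallies.
#' @exportS3Method generics::glance
glance.tf_validation <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.01
  n_tested <- sum(x$tested)
  n_validated <- sum(x$validated)
  tibble(
    alpha = alpha,
    n_predictions = nrow(x),
    n_tested = n_tested,
    n_validated = n_validated,
    fdr = if (n_validated > 0) estimate_fdr(alpha, n_tested, n_validated) else NA_real_,
    n_activator = sum(x$sign == "activator"),
    n_repressor = sum(x$sign == "repressor"),
    n_ambiguous = sum(x$sign == "ambiguous"),
    bias = (attr(x, "bias") %||% list(bias = NA_real_))$bias
  )
}

#' @exportS3Method generics::tidy
tidy.tf_validation <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tf_validation")
  out
}

#' @export
print.tf_validation <- function(x, ...) {
  if (!all(c("tested", "validated", "sign") %in% names(x))) return(NextMethod())
  g <- glance(x)
  cat(sprintf("<tf_validation> %d predictions; %d tested, %d validated (alpha %.3g, FDR %.3f)\n",
              g$n_predictions, g$n_tested, g$n_validated, g$alpha, g$fdr))
  cat(sprintf("  signs: %d activator, %d repressor, %d ambiguous\n",
              g$n_activator, g$n_repressor, g$n_ambiguous))
  NextMethod()
}

#' Validate TFs against a generic association matrix (coexpression mode)
#'
#' Identical logic to [validate_tf()], but ranks and values come from a
#' supplied symmetric association matrix (e.g. microarray coexpression); no
#' proximity-bias correction and no phenotype gate are applied, and `M` (the
#' number of arrays behind the correlations) is supplied by the caller. An
#' optional exclusion list (e.g. targets co-transcribed with the TF) is
#' honored.
#'
#' @param tf Locus id of the TF (must be a row of `assoc`).
#' @param targets Predicted target locus ids.
#' @param assoc Symmetric correlation matrix (see [read_association_matrix()]).
#' @param M Number of arrays underlying the correlations.
#' @param alpha Significance threshold.
#' @param exclude Locus ids to drop from the targets (default none).
#' @return A one-row tibble as from [validate_tf()].
#' @export
validate_from_association <- function(tf, targets, assoc, M, alpha = 0.01,
                                      exclude = character(0)) {
  if (!tf %in% rownames(assoc)) abort(sprintf("TF '%s' absent from association matrix.", tf))
  vals <- assoc[tf, ]
  partners <- setdiff(names(vals), tf)
  v <- vals[partners]
  def <- !is.na(v)
  rk <- rep(NA_integer_, length(v)); ark <- rk
  rk[def] <- as.integer(rank(-v[def], ties.method = "min"))
  ark[def] <- as.integer(rank(v[def], ties.method = "min"))
  prof <- tibble(partner = partners, raw = unname(v), corrected = unname(v),
                 m_shared = as.integer(M), rank = rk, anti_rank = ark)
  class(prof) <- c("cofitness_profile", class(prof))
  attr(prof, "focal") <- tf
  attr(prof, "bias") <- 0
  attr(prof, "n_defined") <- sum(def)
  validate_tf(tf, setdiff(targets, exclude), prof, table = NULL, alpha = alpha,
              gate_phenotype = FALSE)
}
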