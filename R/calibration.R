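# Null calibration of the hypothesis test: rerun the validation with
# randomly drawn "targets" (the same number per TF) and count how often the
# smaller of the two combined p-values falls below 0.01 or 0.05.

#' Resample targets for a TF
#'
#' Draws `T` distinct loci uniformly without replacement from the pool of
#' genes with fitness data, excluding the TF itself. (The analytic rank
#' p-value assumes sampling with replacement; for `T << N` the two are
#' nearly identical.)
#'
#' @param tf Locus id of the TF (excluded from the pool).
#' @param T_targets Number of targets to draw.
#' @param gene_pool Character vector of genes with fitness data.
#' @param rng A seeded stream from the calling function.
#' @return Character vector of `T` loci, or `NULL` when the pool is smaller
#'   than `T` (the TF is skipped).
#' @keywords internal
resample_targets_impl <- function(tf, T_targets, gene_pool, rng) {
  pool <- setdiff(gene_pool, tf)
  if (length(pool) < T_targets) return(NULL)
  pool[rng$sample_int(length(pool), T_targets, replace = FALSE)]
}

#' @rdname calibrate
#' @param tf Locus id of the TF (excluded from the pool).
#' @param T_targets Number of targets to draw.
#' @param gene_pool Character vector of candidate target loci.
#' @export
resample_targets <- function(tf, T_targets, gene_pool, seed = 1) {
  rng <- local_rng(seed)
  out <- resample_targets_impl(tf, T_targets, gene_pool, rng)
  if (is.null(out)) warn(sprintf("Pool smaller than T = %d for TF %s; skipped.", T_targets, tf))
  out
}

new_calibration_report <- function(n_tfs, reps, n_p01, n_p05, seed) {
  n_cases <- n_tfs * reps
  structure(
    list(n_tfs = n_tfs, reps = reps, n_cases = n_cases,
         n_p01 = n_p01, n_p05 = n_p05,
         frac_p01 = if (n_cases > 0) n_p01 / n_cases else NA_real_,
         frac_p05 = if (n_cases > 0) n_p05 / n_cases else NA_real_,
         seed = seed),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %d TFs x %d reps = %d cases (seed %d)\n",
              x$n_tfs, x$reps, x$n_cases, x$seed))
  if (x$n_cases > 0) {
    cat(sprintf("  min(p) <= 0.01: %d (%s);  <= 0.05: %d (%s)\n",
                x$n_p01, format_fraction(x$frac_p01),
                x$n_p05, format_fraction(x$frac_p05)))
  }
  invisible(x)
}

#' Format a calibration fraction as a percentage
#'
#' One decimal place, e.g. 9/2280 prints as `"0.4%"`.
#'
#' @param frac Proportion in \[0, 1\].
#' @return Character scalar.
#' @export
format_fraction <- function(frac) sprintf("%.1f%%", 100 * frac)

#' @rdname calibrate
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.calibration_report <- function(x, ...) {
  tibble(n_tfs = x$n_tfs, reps = x$reps, n_cases = x$n_cases,
         n_p01 = x$n_p01, n_p05 = x$n_p05,
         frac_p01 = x$frac_p01, frac_p05 = x$frac_p05, seed = x$seed)
}

#' Calibrate the test with randomized targets
#'
#' For each testable TF in the prediction set and each repetition, replaces
#' the predicted targets with a random draw of the same size (targets with
#' fitness data only) and reruns the test, then counts how often
#' `min(p_activator, p_repressor)` falls at or below 0.01 and 0.05. On a
#' well-calibrated test these fractions sit at or below the nominal levels;
#' correlated gene blocks in real compendia can push the 5% count slightly
#' above nominal.
#'
#' The TF's bias-corrected profile is computed once and reused across
#' repetitions (only the target identities change). Counts are bit-exact
#' reproducible under a fixed seed.
#'
#' @param predictions Predictions tibble (see [read_predictions()]).
#' @param table A [fitness_table()].
#' @param ann A `genome_annotation` or `NULL`.
#' @param reps Repetitions per TF (default 10).
#' @param seed Integer seed.
#' @param gate_phenotype Apply the significant-phenotype gate (default TRUE).
#' @param bias Optional precomputed `bias_estimate`.
#' @param min_shared Minimum shared experiments for defined cofitness.
#' @return A `calibration_report`.
#' @export
calibrate <- function(predictions, table, ann = NULL, reps = 10, seed = 1,
                      gate_phenotype = TRUE, bias = NULL, min_shared = 10) {
  stopifnot(reps >= 0)
  rng <- local_rng(seed)
  if (is.null(bias)) bias <- zero_bias(table$genome_id)

  n_p01 <- 0L; n_p05 <- 0L; n_tfs <- 0L
  if (reps > 0) {
    for (k in seq_len(nrow(predictions))) {
      tf <- predictions$tf_locus[k]
      if (!tf %in% table$gene_ids) next
      i <- match(tf, table$gene_ids)
      if (gate_phenotype &&
          !significant_phenotype(table$fitness[i, ], table$t_stats[i, ])) next
      prof <- corrected_cofitness_profile(tf, table, ann = ann, bias = bias,
                                          min_shared = min_shared)
      usable <- prof$partner[!is.na(prof$corrected)]
      tg <- setdiff(unique(predictions$targets[[k]]), tf)
      T_targets <- sum(tg %in% usable)
      if (T_targets < 1 || length(usable) < T_targets) next
      n_tfs <- n_tfs + 1L
      for (rep_i in seq_len(reps)) {
        draw <- resample_targets_impl(tf, T_targets, usable, rng)
        res <- validate_tf(tf, draw, prof, table,
                           gate_phenotype = gate_phenotype)
        pmin_ <- min(res$p_activator, res$p_repressor)
        if (!is.na(pmin_)) {
          if (pmin_ <= 0.01) n_p01 <- n_p01 + 1L
          if (pmin_ <= 0.05) n_p05 <- n_p05 + 1L
        }
      }
    }
  }
  new_calibration_report(n_tfs, reps, n_p01, n_p05, seed)
}
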