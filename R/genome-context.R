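# Potential operons (maximal same-strand runs with short intergenic gaps),
# polar-effect flagging of predictions, and the validation-rate comparison
# between polar-flagged and other predictions.

#' Infer potential operons (maximal same-strand runs)
#'
#' A potential operon is any maximal series of adjacent genes on the same
#' scaffold and strand where every adjacent intergenic gap
#' (`next begin - previous end - 1`, clamped at 0 for overlapping genes) is
#' strictly less than `max_gap`. Singleton genes form singleton runs, so the
#' runs partition the gene set.
#'
#' @param ann A `genome_annotation`.
#' @param max_gap Gap threshold in bp (default 250; a gap of exactly 250
#'   splits the run).
#' @return A tibble of class `operon_runs` with columns `operon_id`,
#'   `scaffold`, `strand`, `members` (list, ordered 5'→3' in transcription
#'   direction), `n_members`, `upstream_end` (coordinate of the
#'   transcriptional 5' boundary).
#' @export
maximal_runs <- function(ann, max_gap = 250) {
  df <- as_tibble(as.data.frame(ann)) |> arrange(.data$scaffold, .data$begin, .data$end)
  n <- nrow(df)
  run_id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    new_run <- i == 1 ||
      df$scaffold[i] != df$scaffold[i - 1] ||
      df$strand[i] != df$strand[i - 1] ||
      max(0, df$begin[i] - df$end[i - 1] - 1) >= max_gap
    if (new_run) cur <- cur + 1L
    run_id[i] <- cur
  }
  out <- df |>
    mutate(.run = run_id) |>
    group_by(.data$.run) |>
    summarise(
      scaffold = .data$scaffold[1],
      strand = .data$strand[1],
      members = list(if (.data$strand[1] == "+") .data$locus_id else rev(.data$locus_id)),
      n_members = dplyr::n(),
      upstream_end = if (.data$strand[1] == "+") min(.data$begin) else max(.data$end),
      .groups = "drop"
    ) |>
    mutate(operon_id = sprintf("run%04d", .data$.run)) |>
    select("operon_id", "scaffold", "strand", "members", "n_members", "upstream_end")
  class(out) <- c("operon_runs", class(out))
  out
}

run_lookup <- function(runs) {
  members <- runs$members
  setNames(rep(seq_along(members), lengths(members)), unlist(members))
}

#' Are two genes in the same potential operon?
#'
#' @param a,b Locus ids.
#' @param runs Output of [maximal_runs()].
#' @return Logical; a gene is trivially in the same run as itself.
#' @export
same_operon <- function(a, b, runs) {
  lk <- run_lookup(runs)
  if (!a %in% names(lk)) abort(sprintf("Unknown locus '%s'.", a))
  if (!b %in% names(lk)) abort(sprintf("Unknown locus '%s'.", b))
  unname(lk[a] == lk[b])
}

#' Flag a prediction as vulnerable to polar effects
#'
#' A prediction is potentially affected by polar effects when its TF is
#' co-transcribed with any predicted target (transposon insertions in the TF
#' then silence the target too, creating artifactual positive cofitness).
#'
#' @param prediction A list or one-row tibble with `tf_locus` and `targets`.
#' @param runs Output of [maximal_runs()].
#' @return Logical.
#' @export
flag_polar <- function(prediction, runs) {
  tf <- prediction$tf_locus
  targets <- unique(unlist(prediction$targets))
  targets <- setdiff(targets, tf)
  if (length(targets) == 0) return(FALSE)
  lk <- run_lookup(runs)
  if (!tf %in% names(lk)) abort(sprintf("TF '%s' is not annotated.", tf))
  tr <- lk[targets]
  any(!is.na(tr) & tr == lk[tf])
}

#' Two-proportion difference with unpooled Wald confidence interval
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param level Confidence level (default 0.95).
#' @return A list with `diff` (`k1/n1 - k2/n2`) and `half_width`
#'   (`z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`).
#' @export
two_proportion_diff_ci <- function(k1, n1, k2, n2, level = 0.95) {
  if (n1 < 1 || n2 < 1) abort("Both groups need at least one observation.")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(diff = p1 - p2, half_width = z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2))
}

#' Compare validation rates between polar-flagged and other predictions
#'
#' Partitions the tested predictions (TF with a significant phenotype and at
#' least one usable target) by the polar flag and compares validation rates
#' in each direction separately: validation by positive cofitness
#' (`p_activator <= alpha`) and by anti-cofitness (`p_repressor <= alpha`),
#' each with an unpooled two-proportion Wald CI. Polar effects predict an
#' excess only in the positive direction; the anti-cofitness comparison is
#' the negative control.
#'
#' @param results A `tf_validation` tibble with a `polar` column (from
#'   [validate_predictions()] run with an annotation).
#' @param alpha Threshold defining per-direction validation (default: the
#'   run's alpha).
#' @param level Confidence level.
#' @return A tibble of class `polar_comparison`, one row per direction, with
#'   counts, rates, `diff`, and `ci95` half-width.
#' @export
polar_validation_comparison <- function(results, alpha = NULL, level = 0.95) {
  alpha <- alpha %||% attr(results, "alpha") %||% 0.01
  elig <- results |> filter(.data$tested, !is.na(.data$polar))
  if (nrow(elig) == 0) {
    warn("No eligible predictions; empty polar comparison.")
    out <- tibble(direction = character(0), n_polar = integer(0), k_polar = integer(0),
                  n_other = integer(0), k_other = integer(0), rate_polar = numeric(0),
                  rate_other = numeric(0), diff = numeric(0), ci95 = numeric(0))
    class(out) <- c("polar_comparison", class(out))
    return(out)
  }
  one <- function(direction, hit) {
    np <- sum(elig$polar); no <- sum(!elig$polar)
    kp <- sum(hit & elig$polar); ko <- sum(hit & !elig$polar)
    ci <- two_proportion_diff_ci(kp, max(np, 1), ko, max(no, 1), level = level)
    tibble(direction = direction, n_polar = np, k_polar = kp, n_other = no,
           k_other = ko, rate_polar = kp / max(np, 1), rate_other = ko / max(no, 1),
           diff = ci$diff, ci95 = ci$half_width)
  }
  out <- bind_rows(
    one("cofitness", !is.na(elig$p_activator) & elig$p_activator <= alpha),
    one("anti-cofitness", !is.na(elig$p_repressor) & elig$p_repressor <= alpha)
  )
  class(out) <- c("polar_comparison", class(out))
  out
}
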