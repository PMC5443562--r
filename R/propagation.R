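# Propagating regulatory predictions to a related genome: reciprocal-best-hit
# orthologs from Smith-Waterman protein alignment, choice of source organism
# by TF bit score, and PWM scanning of 250-bp upstream windows with an
# empirical genome-wide motif p-value.

# Karlin-Altschul constants for gapped BLOSUM62 (gap open 11, extend 1), the
# standard protein-BLAST parameterization.
KA_LAMBDA <- 0.267
KA_K <- 0.041

as_aa_set <- function(x) {
  if (inherits(x, "AAStringSet")) return(x)
  Biostrings::AAStringSet(unlist(x))
}

#' Locally align two proteins and score the hit
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (open 11,
#' extend 1). The raw score is converted to a bit score with the standard
#' gapped Karlin-Altschul scaling, and the E-value is computed against a
#' database of `db_residues` total residues. Identity is measured over
#' aligned columns; coverage is the aligned query span over the query
#' length.
#'
#' @param query,subject Amino-acid sequences (character or `AAString`).
#' @param db_residues Total residues of the search database (defaults to the
#'   subject length, i.e. a single-sequence database).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A list: `score` (raw), `bit_score`, `identity` (percent),
#'   `coverage` (percent of query), `evalue`.
#' @export
align_and_score <- function(query, subject, db_residues = NULL,
                            gap_open = 11, gap_extend = 1) {
  qc <- toupper(as.character(query))
  sc <- toupper(as.character(subject))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", qc) || grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", sc)) {
    abort("Sequences must be amino acids (ACDEFGHIKLMNPQRSTVWYX).")
  }
  if (nchar(qc) < 10 || nchar(sc) < 10) abort("Sequences must be at least 10 aa.")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qc), Biostrings::AAString(sc), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- Biostrings::score(al)
  bit <- (KA_LAMBDA * s - log(KA_K)) / log(2)
  n <- db_residues %||% nchar(sc)
  e <- nchar(qc) * n * 2^(-bit)
  span <- Biostrings::end(Biostrings::pattern(al)) - Biostrings::start(Biostrings::pattern(al)) + 1
  list(
    score = s,
    bit_score = bit,
    identity = 100 * Biostrings::nmatch(al) / Biostrings::nchar(al),
    coverage = 100 * span / nchar(qc),
    evalue = e
  )
}

# all-vs-one alignment of a proteome against one subject; returns a tibble
align_set <- function(patterns, subject_seq, db_residues, gap_open, gap_extend) {
  al <- Biostrings::pairwiseAlignment(
    patterns, subject_seq, type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- Biostrings::score(al)
  bit <- (KA_LAMBDA * s - log(KA_K)) / log(2)
  qlen <- Biostrings::width(patterns)
  span <- Biostrings::end(Biostrings::pattern(al)) - Biostrings::start(Biostrings::pattern(al)) + 1
  tibble(
    query = names(patterns),
    score = s,
    bit_score = bit,
    identity = 100 * Biostrings::nmatch(al) / Biostrings::nchar(al),
    coverage = 100 * span / qlen,
    evalue = qlen * db_residues * 2^(-bit)
  )
}

#' Reciprocal-best-hit orthologs between two proteomes
#'
#' All-vs-all local alignment in both directions with the printed ublast
#' thresholds: a hit counts only when E <= `max_evalue`, identity >=
#' `min_identity` %, and query coverage >= `min_coverage` % (coverage is
#' checked on the query of each direction). Two genes are potential
#' orthologs when each is the other's best-scoring surviving hit. Score ties
#' are broken by lexicographic locus id, with a warning.
#'
#' @param proteome_a,proteome_b Named `AAStringSet`s (or named character
#'   vectors) of protein sequences.
#' @param max_evalue,min_identity,min_coverage Hit thresholds.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A tibble with `locus_a`, `locus_b`, `bit_score`, `identity`,
#'   `coverage` (the smaller of the two directions), `evalue` (the larger).
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, max_evalue = 1e-5,
                                 min_identity = 50, min_coverage = 80,
                                 gap_open = 11, gap_extend = 1) {
  a <- as_aa_set(proteome_a)
  b <- as_aa_set(proteome_b)
  if (length(a) == 0 || length(b) == 0) abort("Both proteomes must be non-empty.")
  db_a <- sum(Biostrings::width(a))
  db_b <- sum(Biostrings::width(b))

  # one alignment per (a, b) pair; direction-specific E and coverage derive
  # from the same alignment since SW scores are symmetric
  hits <- vector("list", length(b))
  for (j in seq_along(b)) {
    h <- align_set(a, b[[j]], db_residues = db_b, gap_open = gap_open,
                   gap_extend = gap_extend)
    h$subject <- names(b)[j]
    h$subject_len <- Biostrings::width(b)[j]
    hits[[j]] <- h
  }
  hits <- bind_rows(hits)
  qlen <- setNames(Biostrings::width(a), names(a))
  span_q <- hits$coverage * qlen[hits$query] / 100
  hits$coverage_b <- 100 * pmin(span_q, hits$subject_len) / hits$subject_len
  # span on the subject is not directly available from the pooled run; the
  # subject-side span equals the alignment span minus subject gaps, which is
  # bounded by the query span -- recompute exactly for candidate pairs below.
  hits$evalue_b <- hits$subject_len * db_a * 2^(-hits$bit_score)

  passes <- function(h, direction) {
    if (direction == "ab") {
      h$evalue <= max_evalue & h$identity >= min_identity & h$coverage >= min_coverage
    } else {
      h$evalue_b <= max_evalue & h$identity >= min_identity & h$cov_subject >= min_coverage
    }
  }

  # exact subject-side coverage for pairs that pass the a->b filter
  cand <- hits |> filter(.data$evalue <= max_evalue, .data$identity >= min_identity)
  cov_sub <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    al <- Biostrings::pairwiseAlignment(
      b[[cand$subject[k]]], a[[cand$query[k]]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = gap_open, gapExtension = gap_extend
    )
    sp <- Biostrings::end(Biostrings::pattern(al)) - Biostrings::start(Biostrings::pattern(al)) + 1
    cov_sub[k] <- 100 * sp / cand$subject_len[k]
  }
  cand$cov_subject <- cov_sub

  ok <- cand |>
    filter(passes(cand, "ab"), passes(cand, "ba"))
  if (nrow(ok) == 0) return(tibble(locus_a = character(0), locus_b = character(0),
                                   bit_score = numeric(0), identity = numeric(0),
                                   coverage = numeric(0), evalue = numeric(0)))

  best_of <- function(df, key) {
    df |>
      group_by(.data[[key]]) |>
      group_modify(function(g, ...) {
        top <- g[g$bit_score == max(g$bit_score), , drop = FALSE]
        if (nrow(top) > 1) {
          other <- setdiff(c("query", "subject"), key)
          warn(sprintf("Best-hit tie broken lexicographically for %s.", g[[1]][1] %||% key))
          top <- top[order(top[[other]]), , drop = FALSE]
        }
        top[1, , drop = FALSE]
      }) |>
      ungroup()
  }
  best_ab <- best_of(ok, "query")      # best subject for each query a
  best_ba <- best_of(ok, "subject")    # best query for each subject b
  rbh <- inner_join(
    best_ab |> select("query", "subject", "bit_score", "identity", "coverage",
                      "cov_subject", "evalue", "evalue_b"),
    best_ba |> select("query", "subject"),
    by = c("query", "subject")
  )
  rbh |>
    transmute(
      locus_a = .data$query, locus_b = .data$subject,
      bit_score = .data$bit_score, identity = .data$identity,
      coverage = pmin(.data$coverage, .data$cov_subject),
      evalue = pmax(.data$evalue, .data$evalue_b)
    )
}

#' Choose the source organism for propagation
#'
#' Among candidate source organisms that have at least one orthologous
#' TF-target pair, picks the one whose TF ortholog is most similar to the TF
#' of interest (highest alignment bit score); ties break deterministically
#' by organism id.
#'
#' @param candidates Tibble with columns `organism`, `bit_score`,
#'   `has_orthologous_pair`.
#' @return The chosen organism id, or `NA_character_` when no candidate is
#'   eligible (no propagation).
#' @export
choose_source <- function(candidates) {
  elig <- candidates |> filter(.data$has_orthologous_pair)
  if (nrow(elig) == 0) {
    warn("No candidate source with an orthologous TF-target pair; no propagation.")
    return(NA_character_)
  }
  elig <- elig |> arrange(desc(.data$bit_score), .data$organism)
  elig$organism[1]
}

#' Upstream scanning windows for a target gene
#'
#' For the maximal same-strand run containing the target, returns one
#' `window`-bp region immediately 5' of the transcriptional start of the
#' target itself and of each run member 5' of the target — i.e. one window
#' per potential (sub-)operon the target belongs to. Windows are strand
#' aware and truncated at scaffold edges; zero-length windows are dropped.
#'
#' @param target Locus id.
#' @param ann A `genome_annotation`.
#' @param runs Output of [maximal_runs()].
#' @param window Window size in bp (default 250).
#' @param scaffold_lengths Optional named vector of scaffold lengths for
#'   right-edge truncation on the minus strand.
#' @return A tibble with `upstream_locus`, `scaffold`, `start`, `end`,
#'   `strand` (1-based inclusive genomic coordinates).
#' @export
upstream_windows <- function(target, ann, runs, window = 250,
                             scaffold_lengths = NULL) {
  lk <- run_lookup(runs)
  if (!target %in% names(lk)) abort(sprintf("Unknown locus '%s'.", target))
  run <- runs[lk[target], ]
  members <- run$members[[1]]            # 5' -> 3' in transcription direction
  upto <- seq_len(match(target, members))
  out <- list()
  for (m in members[upto]) {
    g <- ann[ann$locus_id == m, ]
    if (g$strand == "+") {
      s <- max(1L, g$begin - window)
      e <- g$begin - 1L
    } else {
      s <- g$end + 1L
      e <- g$end + window
      if (!is.null(scaffold_lengths) && g$scaffold %in% names(scaffold_lengths)) {
        e <- min(e, as.integer(scaffold_lengths[[g$scaffold]]))
      }
    }
    if (e >= s) {
      out[[length(out) + 1]] <- tibble(upstream_locus = m, scaffold = g$scaffold,
                                       start = as.integer(s), end = as.integer(e),
                                       strand = g$strand)
    }
  }
  bind_rows(out)
}

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_seq <- function(s) {
  v <- BASE_CODE[strsplit(toupper(s), "")[[1]]]
  v[is.na(v)] <- NA_integer_   # ambiguous bases never match
  v
}

revcomp_code <- function(code) rev(5L - code)

# log2-odds scores of a pwm at every offset of an encoded sequence (forward
# reading); NA bases score -Inf
scan_scores <- function(code, lodds) {
  w <- nrow(lodds)
  L <- length(code)
  if (L < w) return(numeric(0))
  K <- L - w + 1
  sc <- numeric(K)
  for (j in seq_len(w)) {
    b <- code[j:(j + K - 1)]
    contrib <- ifelse(is.na(b), -Inf, lodds[j, ifelse(is.na(b), 1L, b)])
    sc <- sc + contrib
  }
  unname(sc)
}

pwm_log_odds <- function(pwm) {
  if (any(pwm$probs <= 0)) abort(sprintf("Motif %s has zero probabilities; use a positive pseudocount.", pwm$motif_id))
  log2(sweep(pwm$probs, 2, pwm$background, "/"))
}

extract_window_seq <- function(seqs, scaffold, start, end) {
  s <- seqs[[scaffold]]
  if (is.null(s)) return(NULL)
  sc <- as.character(s)
  end <- min(end, nchar(sc))
  if (start > end) return(NULL)
  substr(sc, start, end)
}

#' Best PWM hit across a set of upstream windows
#'
#' Scores every offset of both strands of every window with the motif's
#' log2(probability / background) and returns the maximum-scoring hit. Ties
#' break deterministically: leftmost window/offset first, then the + strand.
#' Windows shorter than the motif are skipped.
#'
#' @param windows Tibble from [upstream_windows()].
#' @param pwm A [pwm()].
#' @param seqs Named list / `DNAStringSet` of scaffold sequences.
#' @return A one-row tibble (`upstream_locus`, `position` offset within the
#'   window, `strand`, `score`) or `NULL` when no window can be scored.
#' @export
pwm_best_hit <- function(windows, pwm, seqs) {
  if (is.null(windows) || nrow(windows) == 0) return(NULL)
  lodds <- pwm_log_odds(pwm)
  best <- NULL
  for (k in seq_len(nrow(windows))) {
    sq <- extract_window_seq(seqs, windows$scaffold[k], windows$start[k], windows$end[k])
    if (is.null(sq) || nchar(sq) < pwm$width) next
    code <- encode_seq(sq)
    fw <- scan_scores(code, lodds)
    rv <- scan_scores(revcomp_code(code), lodds)
    # map reverse-scan offsets back to forward coordinates (leftmost base)
    L <- length(code)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") fw else rv
      if (length(sc) == 0) next
      i <- which.max(sc)
      pos <- if (strand == "+") i else L - pwm$width - i + 2L
      cand <- tibble(upstream_locus = windows$upstream_locus[k],
                     window = k, position = as.integer(pos),
                     strand = strand, score = sc[i])
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score &&
           (cand$window < best$window ||
            (cand$window == best$window &&
             (cand$position < best$position ||
              (cand$position == best$position && cand$strand == "+")))))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best |> select(-"window")
}

# best upstream motif score for every gene in the genome (named vector; NA
# where no scorable window exists). The expensive part of the empirical p.
genome_best_scores <- function(ann, runs, pwm, seqs, window = 250) {
  lens <- vapply(seqs, function(s) nchar(as.character(s)), numeric(1))
  out <- setNames(rep(NA_real_, nrow(ann)), ann$locus_id)
  for (g in ann$locus_id) {
    w <- upstream_windows(g, ann, runs, window = window, scaffold_lengths = lens)
    hit <- pwm_best_hit(w, pwm, seqs)
    if (!is.null(hit)) out[g] <- hit$score
  }
  out
}

#' Empirical genome-wide p-value of a target's motif hit
#'
#' The best motif hit is computed for every gene in the genome with the same
#' upstream-window procedure; the p-value is the fraction of scored genes
#' whose best hit scores at least as well as the target's. Genes in the same
#' potential operon as the target are excluded from both numerator and
#' denominator; genes with no scorable window count as scoring below. The
#' target scores at least as well as itself, so the minimum attainable p is
#' 1 over the number of genes scored. The p-value is invariant to monotone
#' rescaling of the PWM scores.
#'
#' @param target Locus id whose hit is being tested.
#' @param target_score Best upstream score of the target (from
#'   [pwm_best_hit()]).
#' @param ann,runs,pwm,seqs As in [pwm_best_hit()].
#' @param window Window size in bp.
#' @param best_scores Optional precomputed result of the genome-wide scan
#'   (named score vector), reused across targets of the same motif.
#' @return Empirical p in (0, 1].
#' @export
motif_empirical_pvalue <- function(target, target_score, ann, runs, pwm, seqs,
                                   window = 250, best_scores = NULL) {
  if (is.null(best_scores)) {
    best_scores <- genome_best_scores(ann, runs, pwm, seqs, window = window)
  }
  lk <- run_lookup(runs)
  run_members <- runs$members[[lk[target]]]
  pool <- setdiff(names(best_scores), run_members)
  scored <- best_scores[pool]
  scored <- scored[!is.na(scored)]   # genes with no scorable window drop out
  if (length(scored) == 0) return(1)
  # the target's own run is excluded, so count it once as its own tie
  (sum(scored >= target_score) + 1) / (length(scored) + 1)
}

#' Propagate predictions to a related genome
#'
#' Maps each source prediction into the target organism through
#' reciprocal-best-hit orthologs of the TF and of each target gene, scans
#' the 250-bp upstream windows of each mapped target's potential operons for
#' the prediction's motif, and keeps the orthologous pair when the empirical
#' genome-wide motif p-value is at or below `motif_alpha`. The output is a
#' prediction set in the target organism carrying the source group id and
#' annotated sign.
#'
#' @param source_predictions Predictions tibble in the source organism.
#' @param source_proteome,target_proteome Named protein sets.
#' @param target_ann Target `genome_annotation`.
#' @param target_seqs Named scaffold sequences of the target genome.
#' @param pwms Named list of [pwm()]s (by `motif_id`).
#' @param motif_alpha Motif significance threshold (default 0.01).
#' @param window Upstream window size (bp).
#' @param operon_max_gap Operon gap threshold (bp).
#' @param rbh Optional precomputed [reciprocal_best_hits()] table.
#' @param genome_background Compute the PWM background from the target
#'   genome sequence (default TRUE).
#' @param ... Passed to [reciprocal_best_hits()].
#' @return A list with `predictions` (propagated prediction tibble),
#'   `pairs` (per orthologous TF-target pair: mapped loci, motif score and
#'   empirical p, kept flag), and `rbh`.
#' @export
propagate <- function(source_predictions, source_proteome, target_proteome,
                      target_ann, target_seqs, pwms, motif_alpha = 0.01,
                      window = 250, operon_max_gap = 250, rbh = NULL,
                      genome_background = TRUE, ...) {
  if (is.null(rbh)) {
    rbh <- reciprocal_best_hits(source_proteome, target_proteome, ...)
  }
  omap <- setNames(rbh$locus_b, rbh$locus_a)
  runs <- maximal_runs(target_ann, max_gap = operon_max_gap)

  bg <- NULL
  if (genome_background) {
    all_seq <- paste(vapply(target_seqs, function(s) as.character(s), character(1)),
                     collapse = "")
    counts <- vapply(c("A", "C", "G", "T"),
                     function(b) stringr::str_count(toupper(all_seq), stringr::fixed(b)),
                     numeric(1))
    bg <- counts / sum(counts)
  }

  score_cache <- list()
  pair_rows <- list()
  for (k in seq_len(nrow(source_predictions))) {
    tf <- source_predictions$tf_locus[k]
    motif_id <- source_predictions$motif_id[k]
    tf_t <- omap[tf]
    if (is.na(tf_t)) next
    p <- pwms[[motif_id]]
    if (is.null(p)) {
      warn(sprintf("No PWM for motif '%s'; prediction skipped.", motif_id))
      next
    }
    if (!is.null(bg)) p <- pwm(p$probs, motif_id = p$motif_id, background = bg,
                               pseudocount = 0)
    if (is.null(score_cache[[motif_id]])) {
      score_cache[[motif_id]] <- genome_best_scores(target_ann, runs, p, target_seqs,
                                                    window = window)
    }
    bs <- score_cache[[motif_id]]
    lens <- vapply(target_seqs, function(s) nchar(as.character(s)), numeric(1))
    for (tg in setdiff(unique(source_predictions$targets[[k]]), tf)) {
      tg_t <- omap[tg]
      if (is.na(tg_t) || !tg_t %in% target_ann$locus_id) next
      w <- upstream_windows(tg_t, target_ann, runs, window = window,
                            scaffold_lengths = lens)
      hit <- pwm_best_hit(w, p, target_seqs)
      if (is.null(hit)) {
        pair_rows[[length(pair_rows) + 1]] <- tibble(
          tf_source = tf, target_source = tg, tf_target = unname(tf_t),
          target_target = unname(tg_t), score = NA_real_, motif_p = NA_real_,
          kept = FALSE, group_id = source_predictions$group_id[k],
          sign = source_predictions$sign[k], motif_id = motif_id
        )
        next
      }
      pv <- motif_empirical_pvalue(tg_t, hit$score, target_ann, runs, p,
                                   target_seqs, window = window, best_scores = bs)
      pair_rows[[length(pair_rows) + 1]] <- tibble(
        tf_source = tf, target_source = tg, tf_target = unname(tf_t),
        target_target = unname(tg_t), score = hit$score, motif_p = pv,
        kept = pv <= motif_alpha, group_id = source_predictions$group_id[k],
        sign = source_predictions$sign[k], motif_id = motif_id
      )
    }
  }
  pairs <- bind_rows(pair_rows)
  if (nrow(pairs) == 0) {
    preds <- tibble(tf_locus = character(0), group_id = character(0),
                    sign = character(0), motif_id = character(0), targets = list())
  } else {
    preds <- pairs |>
      filter(.data$kept) |>
      group_by(.data$tf_target, .data$group_id, .data$sign, .data$motif_id) |>
      summarise(targets = list(unique(.data$target_target)), .groups = "drop") |>
      rename(tf_locus = "tf_target")
  }
  list(predictions = preds, pairs = pairs, rbh = rbh)
}
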