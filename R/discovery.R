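# Candidate-target nomination for putative TFs that lack predictions: the
# conserved-cofitness rule. A strong functional association is either
# cofitness > 0.8 in the focal organism alone, or cofitness > 0.6 that is
# conserved (an orthologous gene pair also has cofitness > 0.6) with a
# conserved-cofitness rank of at most 10.

#' Cofitness of the orthologous pair in a second organism
#'
#' Maps both genes of a pair through an ortholog map and returns the
#' orthologous pair's cofitness in the second organism, or `NA` when either
#' ortholog is missing or lacks fitness data.
#'
#' @param tf,gene Locus ids in the focal organism.
#' @param ortholog_map Named character vector: focal locus -> ortholog locus.
#' @param other_table The second organism's [fitness_table()].
#' @param min_shared Minimum shared experiments for a defined correlation.
#' @return Cofitness value or `NA`.
#' @export
conserved_cofitness <- function(tf, gene, ortholog_map, other_table, min_shared = 10) {
  o_tf <- unname(ortholog_map[tf])
  o_g <- unname(ortholog_map[gene])
  if (is.na(o_tf) || is.na(o_g)) return(NA_real_)
  if (!o_tf %in% other_table$gene_ids || !o_g %in% other_table$gene_ids) return(NA_real_)
  i <- match(o_tf, other_table$gene_ids)
  j <- match(o_g, other_table$gene_ids)
  pearson_cofitness(other_table$fitness[i, ], other_table$fitness[j, ],
                    min_shared = min_shared)$cofitness
}

#' Nominate a candidate target for a putative TF
#'
#' Among genes not already predicted as targets (the exclusion list), a gene
#' qualifies when either (a) its cofitness with the TF exceeds 0.6, the
#' orthologous pair in a second organism also has cofitness above 0.6, and
#' its cofitness rank in the TF's profile is at most 10 (criterion
#' `"conserved"`), or (b) its cofitness exceeds 0.8 outright (criterion
#' `"strong"`). The candidate is the qualifying gene with the highest
#' corrected cofitness; `NULL` when none qualifies. The result does not
#' depend on gene order.
#'
#' @param tf Locus id of the putative TF.
#' @param profile The TF's [corrected_cofitness_profile()].
#' @param ortholog_map Named vector mapping focal loci to the second
#'   organism (may be empty; then only the strong criterion can fire).
#' @param other_table The second organism's [fitness_table()] (or `NULL`).
#' @param exclusions Locus ids already predicted for this TF (from original
#'   or propagated predictions).
#' @param conserved_min Cofitness floor of the conserved criterion (0.6).
#' @param conserved_max_rank Rank ceiling of the conserved criterion (10),
#'   evaluated in the focal organism's profile.
#' @param strong_min Cofitness floor of the strong criterion (0.8).
#' @return A one-row tibble (`tf_locus`, `target_locus`, `cofitness`,
#'   `conserved_cofitness`, `conserved_rank`, `criterion`) or `NULL`.
#' @export
find_candidate_target <- function(tf, profile, ortholog_map = NULL,
                                  other_table = NULL, exclusions = character(0),
                                  conserved_min = 0.6, conserved_max_rank = 10,
                                  strong_min = 0.8) {
  stopifnot(inherits(profile, "cofitness_profile"))
  cand <- profile |>
    filter(!is.na(.data$corrected), !.data$partner %in% exclusions)
  if (nrow(cand) == 0) return(NULL)

  strong <- cand$corrected > strong_min
  conserved_val <- rep(NA_real_, nrow(cand))
  if (!is.null(ortholog_map) && !is.null(other_table)) {
    maybe <- which(cand$corrected > conserved_min & cand$rank <= conserved_max_rank)
    for (i in maybe) {
      conserved_val[i] <- conserved_cofitness(tf, cand$partner[i], ortholog_map,
                                              other_table)
    }
  }
  conserved <- !is.na(conserved_val) & conserved_val > conserved_min &
    cand$corrected > conserved_min & cand$rank <= conserved_max_rank
  qual <- strong | conserved
  if (!any(qual)) return(NULL)
  i <- which(qual)[which.max(cand$corrected[qual])]
  tibble(
    tf_locus = tf,
    target_locus = cand$partner[i],
    cofitness = cand$corrected[i],
    conserved_cofitness = conserved_val[i],
    conserved_rank = if (conserved[i]) as.integer(cand$rank[i]) else NA_integer_,
    criterion = if (conserved[i]) "conserved" else "strong"
  )
}
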