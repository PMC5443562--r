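# Synthetic-data generator: genomes with operon structure, proteomes (with
# mutated ortholog copies), nucleotide sequences with planted motif sites,
# and fitness compendia realizing configured TF-target couplings, polar
# leakage, and a chromosomal-proximity correlation bias — with full ground
# truth, in the formats the rest of the package reads.

#' Simulation configuration
#'
#' Bundles the knobs of the generator. Defaults describe a small bacterial
#' genome sampled across a generic fitness compendium: ~2-gene mean operons
#' with sub-250-bp intra-operon gaps, 100 experiments, per-gene fitness
#' s.d. 1.2 (so most genes show at least one strong phenotype), and t
#' statistics from 4 pseudo-replicates with measurement s.d. 0.3.
#'
#' @param n_genes,n_scaffolds,n_experiments Genome and compendium size.
#' @param mean_run_length Mean potential-operon length (geometric); 1 means
#'   all singletons.
#' @param intra_gap_range,inter_gap_range Intergenic gap ranges (bp) within
#'   and between runs; the intra range must stay below the 250-bp operon
#'   threshold and the inter range above it.
#' @param gene_length Gene length in bp.
#' @param protein_length Protein length in residues.
#' @param tf_specs Tibble with columns `sign` ("activator"/"repressor"),
#'   `n_targets`, `coupling` (target correlation, in (-1,1) magnitude),
#'   `polar` (logical: TF co-transcribed with a leaking operon mate).
#' @param polar_leak Correlation leaked from the downstream operon member
#'   into a polar TF's fitness row.
#' @param bias_amplitude Proximity-correlation bias planted for nearby gene
#'   pairs (correlation units; 0 disables the positional field).
#' @param bias_tau Length scale (bp) of the positional field's Gaussian
#'   correlation kernel.
#' @param sd_fit Per-gene fitness standard deviation (log2 units).
#' @param noise_sd Measurement s.d. entering the t statistics.
#' @param pseudo_replicates Pseudo-replicate count behind the t statistics.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, n_scaffolds = 1, n_experiments = 100,
                       mean_run_length = 2, intra_gap_range = c(20, 150),
                       inter_gap_range = c(300, 800), gene_length = 900,
                       protein_length = 100, tf_specs = NULL, polar_leak = 0.6,
                       bias_amplitude = 0, bias_tau = 30000, sd_fit = 1.2,
                       noise_sd = 0.3, pseudo_replicates = 4, seed = 1) {
  stopifnot(mean_run_length >= 1, intra_gap_range[2] < 250, inter_gap_range[1] >= 250,
            bias_amplitude >= 0, bias_amplitude < 1)
  if (!is.null(tf_specs)) {
    stopifnot(all(abs(tf_specs$coupling) < 1))
  }
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n, rng) {
  paste(c("A", "C", "G", "T")[rng$sample_int(4, n, replace = TRUE)], collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, rng) {
  paste0("M", paste(AA20[rng$sample_int(20, len - 1, replace = TRUE)], collapse = ""))
}

#' Simulate a genome: annotation, sequences, proteins
#'
#' Lays genes along scaffolds with the configured operon geometry (run
#' lengths geometric with the given mean, same-strand genes within runs,
#' intra-run gaps below and inter-run gaps above the 250-bp operon
#' threshold), draws random nucleotide scaffolds and random proteins.
#'
#' @param config A [sim_config()].
#' @param genome_id Genome identifier (also prefixes locus ids).
#' @return A list of class `sim_genome`: `annotation`
#'   (`genome_annotation`), `sequences` (named character, one per
#'   scaffold), `proteins` (named character), `runs` (planted run id per
#'   gene), `config`.
#' @export
simulate_genome <- function(config, genome_id = "synth") {
  rng <- local_rng(config$seed)
  per_scaffold <- rep(config$n_genes %/% config$n_scaffolds, config$n_scaffolds)
  if (sum(per_scaffold) < config$n_genes) {
    per_scaffold[1] <- per_scaffold[1] + config$n_genes - sum(per_scaffold)
  }
  rows <- list()
  run_ids <- integer(0)
  gi <- 0L; run_i <- 0L
  for (sc in seq_len(config$n_scaffolds)) {
    pos <- 1000L
    remaining <- per_scaffold[sc]
    while (remaining > 0) {
      run_i <- run_i + 1L
      len <- if (config$mean_run_length <= 1) 1L else
        min(remaining, 1L + rng$rgeom(1, 1 / config$mean_run_length))
      strand <- c("+", "-")[rng$sample_int(2, 1)]
      for (j in seq_len(len)) {
        gi <- gi + 1L
        begin <- pos
        end <- pos + config$gene_length - 1L
        rows[[gi]] <- list(locus_id = sprintf("%s_%05d", genome_id, gi),
                           scaffold = sprintf("%s_sc%d", genome_id, sc),
                           begin = begin, end = end, strand = strand)
        run_ids[gi] <- run_i
        gap <- if (j < len) {
          round(rng$runif(1, config$intra_gap_range[1], config$intra_gap_range[2]))
        } else {
          round(rng$runif(1, config$inter_gap_range[1], config$inter_gap_range[2]))
        }
        pos <- end + 1L + as.integer(gap)
      }
      remaining <- remaining - len
    }
  }
  df <- bind_rows(lapply(rows, as_tibble))
  df$description <- NA_character_
  ann <- new_genome_annotation(df, genome_id = genome_id)

  seq_len_by_sc <- df |> group_by(.data$scaffold) |> summarise(L = max(.data$end) + 1000L)
  sequences <- setNames(
    vapply(seq_len_by_sc$L, function(L) random_dna(L, rng), character(1)),
    seq_len_by_sc$scaffold
  )
  proteins <- setNames(
    vapply(seq_len(nrow(df)), function(i) random_protein(config$protein_length, rng),
           character(1)),
    df$locus_id
  )
  structure(list(annotation = ann, sequences = sequences, proteins = proteins,
                 run_ids = setNames(run_ids, df$locus_id), config = config,
                 genome_id = genome_id),
            class = "sim_genome")
}

#' Derive an ortholog copy of a simulated genome
#'
#' Copies the genome layout and mutates each protein at `1 - identity` of
#' its residues, producing a second organism whose reciprocal-best-hit
#' orthologs are known ground truth. Nucleotide scaffolds are redrawn (the
#' ortholog map, not sequence conservation, links the organisms).
#'
#' @param genome A `sim_genome`.
#' @param identity Expected residue identity of ortholog pairs (0..1).
#' @param genome_id Identifier of the derived organism.
#' @param seed Seed for the mutations.
#' @return A `sim_genome` with an extra field `ortholog_map` (named vector,
#'   source locus -> derived locus).
#' @export
simulate_ortholog_genome <- function(genome, identity = 0.9, genome_id = "synthB",
                                     seed = 1) {
  rng <- local_rng(seed)
  src <- genome$annotation
  new_ids <- sub(genome$genome_id, genome_id, src$locus_id, fixed = TRUE)
  df <- as_tibble(as.data.frame(src))
  df$locus_id <- new_ids
  df$scaffold <- sub(genome$genome_id, genome_id, df$scaffold, fixed = TRUE)
  ann <- new_genome_annotation(df, genome_id = genome_id)
  sequences <- setNames(
    vapply(genome$sequences, function(s) random_dna(nchar(s), rng), character(1)),
    sub(genome$genome_id, genome_id, names(genome$sequences), fixed = TRUE)
  )
  proteins <- vapply(genome$proteins, function(p) {
    chars <- strsplit(p, "")[[1]]
    mut <- rng$runif(length(chars)) > identity
    mut[1] <- FALSE  # keep the initial M
    chars[mut] <- AA20[rng$sample_int(20, sum(mut), replace = TRUE)]
    paste(chars, collapse = "")
  }, character(1))
  names(proteins) <- new_ids
  structure(list(annotation = ann, sequences = sequences, proteins = proteins,
                 run_ids = setNames(unname(genome$run_ids), new_ids),
                 config = genome$config, genome_id = genome_id,
                 ortholog_map = setNames(new_ids, names(genome$proteins))),
            class = "sim_genome")
}

pwm_consensus <- function(pwm) {
  paste(colnames(pwm$probs)[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Plant motif consensus sites upstream of chosen genes
#'
#' Writes the motif's consensus sequence into the upstream window of each
#' listed gene (strand-aware, at a fixed offset inside the 250-bp window)
#' and records the planted coordinates.
#'
#' @param genome A `sim_genome`.
#' @param pwm A [pwm()].
#' @param loci Genes whose own upstream windows receive a site.
#' @param offset Offset of the site inside the window (bp from the window's
#'   5' edge).
#' @param window Window size in bp.
#' @return The genome with mutated `sequences` and a `planted_sites` tibble
#'   field.
#' @export
plant_motif_sites <- function(genome, pwm, loci, offset = 100, window = 250) {
  ann <- genome$annotation
  runs <- maximal_runs(ann)
  cons <- pwm_consensus(pwm)
  w <- nchar(cons)
  lens <- vapply(genome$sequences, nchar, numeric(1))
  planted <- list()
  for (g in loci) {
    wins <- upstream_windows(g, ann, runs, window = window, scaffold_lengths = lens)
    wins <- wins[wins$upstream_locus == g, ]
    if (nrow(wins) == 0) next
    sta <- wins$start[1]; en <- wins$end[1]
    site_start <- min(sta + offset, en - w + 1)
    if (site_start < sta) next
    sc <- wins$scaffold[1]
    s <- genome$sequences[[sc]]
    substr(s, site_start, site_start + w - 1) <- cons
    genome$sequences[[sc]] <- s
    planted[[length(planted) + 1]] <- tibble(locus_id = g, scaffold = sc,
                                             start = site_start,
                                             end = site_start + w - 1L)
  }
  genome$planted_sites <- bind_rows(planted)
  genome
}

#' Assign TF/target roles for the configured couplings
#'
#' Realizes `config$tf_specs` on a simulated genome: each spec row gets a TF
#' locus, a primary coupled target, and filler targets, all disjoint across
#' specs. Polar TFs are placed at the 5' head of a multi-gene run with the
#' co-transcribed second member among their predicted targets; other TFs
#' and all targets come from distinct runs.
#'
#' @param genome A `sim_genome`.
#' @param seed Seed for the role assignment.
#' @return A list with `predictions` (tibble ready for
#'   [validate_predictions()]) and `truth` (per-TF tibble: locus, sign,
#'   coupling, primary target, polar partner).
#' @export
assign_regulators <- function(genome, seed = 1) {
  config <- genome$config
  specs <- config$tf_specs
  if (is.null(specs) || nrow(specs) == 0) {
    return(list(predictions = tibble(tf_locus = character(0), group_id = character(0),
                                     sign = character(0), motif_id = character(0),
                                     targets = list()),
                truth = tibble()))
  }
  rng <- local_rng(seed)
  runs <- maximal_runs(genome$annotation)
  lk <- run_lookup(runs)
  used_runs <- integer(0)
  multi <- which(runs$n_members >= 2)
  preds <- list(); truth <- list()
  take_run <- function(pool) {
    avail <- setdiff(pool, used_runs)
    if (length(avail) == 0) abort("Simulated genome too small for the requested tf_specs.")
    avail[rng$sample_int(length(avail), 1)]
  }
  for (k in seq_len(nrow(specs))) {
    polar <- isTRUE(specs$polar[k])
    if (polar) {
      ri <- take_run(multi)
      used_runs <- c(used_runs, ri)
      members <- runs$members[[ri]]
      tf <- members[1]
      partner <- members[2]
    } else {
      ri <- take_run(seq_len(nrow(runs)))
      used_runs <- c(used_runs, ri)
      tf <- runs$members[[ri]][1]
      partner <- NA_character_
    }
    n_t <- specs$n_targets[k]
    targets <- character(0)
    if (!is.na(partner)) targets <- partner
    while (length(targets) < n_t) {
      ri2 <- take_run(seq_len(nrow(runs)))
      used_runs <- c(used_runs, ri2)
      targets <- c(targets, runs$members[[ri2]][1])
    }
    primary <- if (specs$coupling[k] != 0) targets[if (!is.na(partner)) min(2, length(targets)) else 1] else NA_character_
    preds[[k]] <- tibble(tf_locus = tf, group_id = sprintf("grp%03d", k),
                         sign = specs$sign[k], motif_id = NA_character_,
                         targets = list(targets))
    truth[[k]] <- tibble(tf_locus = tf, sign = specs$sign[k],
                         coupling = specs$coupling[k], primary_target = primary,
                         polar = polar, polar_partner = partner)
  }
  list(predictions = bind_rows(preds), truth = bind_rows(truth))
}

# positional latent field with Gaussian correlation kernel, per scaffold
bias_field <- function(ann, n_experiments, tau, rng) {
  G <- nrow(ann)
  out <- matrix(0, G, n_experiments)
  mid <- (ann$begin + ann$end) / 2
  for (sc in unique(ann$scaffold)) {
    i <- which(ann$scaffold == sc)
    d <- abs(outer(mid[i], mid[i], "-"))
    S <- exp(-d^2 / (2 * tau^2)) + diag(1e-6, length(i))
    L <- chol(S)
    Z <- matrix(rng$rnorm(length(i) * n_experiments), length(i), n_experiments)
    out[i, ] <- t(L) %*% Z
  }
  out
}

#' Simulate a fitness compendium over a genome
#'
#' Per-gene fitness profiles are unit-variance latent Gaussian draws scaled
#' to `sd_fit`. Configured couplings are realized by mixing the primary
#' target's latent into the TF's row
#' (`tf = sign * rho * target + sqrt(1 - rho^2) * noise`), so the realized
#' TF-target correlation approximates the configured strength. Polar TFs
#' additionally receive a `polar_leak` share of their downstream operon
#' mate's latent (always positive — a transposon in the TF also silences
#' the mate). When `bias_amplitude > 0`, every gene receives a
#' `sqrt(bias_amplitude)` share of a positional random field whose
#' correlation decays with a Gaussian kernel of scale `bias_tau`, so nearby
#' pairs (well within `bias_tau`) correlate at about `bias_amplitude`.
#' t statistics are `fitness / (noise_sd / sqrt(pseudo_replicates))`.
#'
#' @param genome A `sim_genome`.
#' @param truth Truth tibble from [assign_regulators()] (or `NULL` for a
#'   coupling-free compendium).
#' @param seed Seed for the fitness draws.
#' @return A [fitness_table()].
#' @export
simulate_fitness <- function(genome, truth = NULL, seed = 1) {
  config <- genome$config
  rng <- local_rng(seed)
  ann <- genome$annotation
  G <- nrow(ann); E <- config$n_experiments
  Z <- matrix(rng$rnorm(G * E), G, E, dimnames = list(ann$locus_id, NULL))

  S <- Z
  if (!is.null(truth) && nrow(truth) > 0) {
    for (k in seq_len(nrow(truth))) {
      tf <- truth$tf_locus[k]
      rho <- truth$coupling[k]
      sgn <- if (truth$sign[k] == "repressor") -1 else 1
      row <- Z[tf, ]
      if (!is.na(truth$primary_target[k]) && rho != 0) {
        row <- sgn * rho * Z[truth$primary_target[k], ] + sqrt(1 - rho^2) * row
      }
      if (isTRUE(truth$polar[k]) && !is.na(truth$polar_partner[k])) {
        lam <- config$polar_leak
        row <- lam * Z[truth$polar_partner[k], ] + sqrt(1 - lam^2) * row
      }
      S[tf, ] <- row
    }
  }
  b <- config$bias_amplitude
  if (b > 0) {
    F_ <- bias_field(ann, E, config$bias_tau, rng)
    S <- sqrt(1 - b) * S + sqrt(b) * F_
  }
  fit <- config$sd_fit * S
  colnames(fit) <- sprintf("exp%03d", seq_len(E))
  tst <- fit / (config$noise_sd / sqrt(config$pseudo_replicates))
  fitness_table(fit, tst, genome_id = genome$genome_id)
}

#' Simulate a complete regulon-validation study
#'
#' Convenience wrapper: genome, TF/target role assignment, and fitness
#' compendium in one call, with derived seeds for each stage.
#'
#' @param config A [sim_config()].
#' @param genome_id Genome identifier.
#' @return A list: `genome`, `predictions`, `truth`, `table`.
#' @export
simulate_regulon_study <- function(config, genome_id = "synth") {
  rng <- local_rng(config$seed)
  genome <- simulate_genome(config, genome_id = genome_id)
  roles <- assign_regulators(genome, seed = rng$spawn_seed())
  table <- simulate_fitness(genome, roles$truth, seed = rng$spawn_seed())
  list(genome = genome, predictions = roles$predictions, truth = roles$truth,
       table = table)
}

#' Null fitness compendium
#'
#' Independent Gaussian fitness values (no couplings, no positional
#' structure) with consistent t statistics — the substrate of type-I-error
#' and calibration checks.
#'
#' @param n_genes,n_experiments Compendium size.
#' @param seed Integer seed.
#' @param sd_fit Per-gene fitness s.d.
#' @param noise_sd,pseudo_replicates t-statistic scaling.
#' @return A [fitness_table()].
#' @export
make_null_compendium <- function(n_genes, n_experiments, seed = 1, sd_fit = 1.2,
                                 noise_sd = 0.3, pseudo_replicates = 4) {
  rng <- local_rng(seed)
  fit <- matrix(rng$rnorm(n_genes * n_experiments, sd = sd_fit), n_genes, n_experiments,
                dimnames = list(sprintf("null_%05d", seq_len(n_genes)),
                                sprintf("exp%03d", seq_len(n_experiments))))
  tst <- fit / (noise_sd / sqrt(pseudo_replicates))
  fitness_table(fit, tst, genome_id = "null")
}
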