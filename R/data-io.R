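# Readers and writers for the external formats: fitness + t-statistic TSVs
# (Fitness-Browser-style), genome annotation (tab or GFF3), regulatory
# predictions (TSV or JSON), MEME minimal motifs, association matrices, and
# the per-TF results table.

#' Construct a fitness table
#'
#' A fitness table holds a genes-by-experiments matrix of gene fitness values
#' (log2 ratios describing the change in abundance of a gene's pooled
#' transposon mutants over a growth experiment) and a parallel matrix of
#' t-like test statistics. Missing entries are allowed in either matrix and
#' are carried as `NA`, never imputed; all correlation work downstream is
#' pairwise-complete.
#'
#' @param fitness Numeric matrix, genes in rows, experiments in columns, with
#'   rownames (locus ids) and colnames (experiment ids).
#' @param t_stats Numeric matrix of identical shape and dimnames.
#' @param genome_id Identifier for the genome the genes belong to.
#' @return An object of class `fitness_table` with fields `genome_id`,
#'   `gene_ids`, `experiment_ids`, `fitness`, `t_stats`.
#' @export
fitness_table <- function(fitness, t_stats, genome_id = "genome") {
  if (!is.matrix(fitness) || !is.matrix(t_stats)) {
    abort("`fitness` and `t_stats` must be matrices.")
  }
  if (!identical(dim(fitness), dim(t_stats))) {
    abort("`fitness` and `t_stats` must have identical shape.")
  }
  if (is.null(rownames(fitness)) || is.null(colnames(fitness))) {
    abort("`fitness` must carry gene ids as rownames and experiment ids as colnames.")
  }
  if (!identical(dimnames(fitness), dimnames(t_stats))) {
    abort("`fitness` and `t_stats` must index the same genes and experiments.")
  }
  bad <- is.infinite(fitness) | is.infinite(t_stats)
  if (any(bad, na.rm = TRUE)) abort("All present fitness/t values must be finite.")
  structure(
    list(
      genome_id = genome_id,
      gene_ids = rownames(fitness),
      experiment_ids = colnames(fitness),
      fitness = fitness,
      t_stats = t_stats
    ),
    class = "fitness_table"
  )
}

#' @export
print.fitness_table <- function(x, ...) {
  cat(sprintf(
    "<fitness_table> %s: %d genes x %d experiments (%.1f%% missing)\n",
    x$genome_id, length(x$gene_ids), length(x$experiment_ids),
    100 * mean(is.na(x$fitness))
  ))
  invisible(x)
}

#' @export
dim.fitness_table <- function(x) dim(x$fitness)

#' Turn a fitness table into a long tibble
#'
#' @param x A [fitness_table()].
#' @param ... Unused.
#' @return A tibble with columns `locus_id`, `experiment`, `fitness`, `t`.
#' @exportS3Method generics::tidy
tidy.fitness_table <- function(x, ...) {
  tibble(
    locus_id = rep(x$gene_ids, times = length(x$experiment_ids)),
    experiment = rep(x$experiment_ids, each = length(x$gene_ids)),
    fitness = as.vector(x$fitness),
    t = as.vector(x$t_stats)
  )
}

read_value_tsv <- function(path, what) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE)
  id_col <- intersect(c("locusId", "locus_id", "locus"), names(df))[1]
  if (is.na(id_col)) {
    abort(sprintf("%s file %s lacks a locusId column.", what, path))
  }
  meta <- intersect(c("sysName", "desc", "description"), names(df))
  exps <- setdiff(names(df), c(id_col, meta))
  if (length(exps) == 0) abort(sprintf("%s file %s has no experiment columns.", what, path))
  vals <- suppressWarnings(
    vapply(df[exps], function(col) as.numeric(col), numeric(nrow(df)))
  )
  # locate non-numeric cells precisely for the error message
  for (j in seq_along(exps)) {
    raw <- df[[exps[j]]]
    bad <- which(!is.na(raw) & is.na(suppressWarnings(as.numeric(raw))))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s file %s: non-numeric cell '%s' at row %d, column '%s'.",
        what, path, raw[bad[1]], bad[1], exps[j]
      ))
    }
  }
  m <- matrix(vals, nrow = nrow(df), dimnames = list(df[[id_col]], exps))
  m
}

#' Read a fitness compendium (fitness + t-statistics TSV pair)
#'
#' Both files are tab-separated with a `locusId` column (optionally `sysName`
#' and `desc`) followed by one column per experiment. Empty cells and `"NA"`
#' become missing values.
#'
#' @param fitness_path Path to the gene-fitness TSV.
#' @param t_path Path to the matching t-statistic TSV.
#' @param genome_id Genome identifier stored on the table.
#' @return A [fitness_table()].
#' @export
read_fitness_table <- function(fitness_path, t_path, genome_id = "genome") {
  fit <- read_value_tsv(fitness_path, "fitness")
  tst <- read_value_tsv(t_path, "t-statistic")
  if (!identical(rownames(fit), rownames(tst))) {
    d <- union(setdiff(rownames(fit), rownames(tst)), setdiff(rownames(tst), rownames(fit)))
    if (length(d) == 0) d <- rownames(fit)[rownames(fit) != rownames(tst)]
    abort(sprintf("Gene sets differ between fitness and t files (first discrepancy: '%s').", d[1]))
  }
  if (!identical(colnames(fit), colnames(tst))) {
    d <- union(setdiff(colnames(fit), colnames(tst)), setdiff(colnames(tst), colnames(fit)))
    if (length(d) == 0) d <- colnames(fit)[colnames(fit) != colnames(tst)]
    abort(sprintf("Experiment sets differ between fitness and t files (first discrepancy: '%s').", d[1]))
  }
  fitness_table(fit, tst, genome_id = genome_id)
}

#' Write a fitness table as a TSV pair
#'
#' @param table A [fitness_table()].
#' @param fitness_path,t_path Output paths.
#' @export
write_fitness_table <- function(table, fitness_path, t_path) {
  wr <- function(m, path) {
    df <- as_tibble(m, rownames = "locusId")
    readr::write_tsv(df, path, progress = FALSE)
  }
  wr(table$fitness, fitness_path)
  wr(table$t_stats, t_path)
  invisible(table)
}

new_genome_annotation <- function(df, genome_id = "genome") {
  req <- c("locus_id", "scaffold", "begin", "end", "strand")
  if (!all(req %in% names(df))) {
    abort(sprintf("Annotation lacks column(s): %s.",
                  paste(setdiff(req, names(df)), collapse = ", ")))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort(sprintf("Unknown strand symbol '%s' (must be + or -).",
                  setdiff(df$strand, c("+", "-"))[1]))
  }
  bad <- which(df$begin > df$end)
  if (length(bad) > 0) {
    abort(sprintf("Gene '%s' has begin > end (%d > %d).",
                  df$locus_id[bad[1]], df$begin[bad[1]], df$end[bad[1]]))
  }
  if (anyDuplicated(df$locus_id)) {
    abort(sprintf("Duplicated locus id '%s'.", df$locus_id[duplicated(df$locus_id)][1]))
  }
  if (!"description" %in% names(df)) df$description <- NA_character_
  df$description <- as.character(df$description)
  out <- df |>
    select(all_of(c(req, "description"))) |>
    mutate(begin = as.integer(.data$begin), end = as.integer(.data$end)) |>
    arrange(.data$scaffold, .data$begin, .data$end)
  out <- as_tibble(out)
  class(out) <- c("genome_annotation", class(out))
  attr(out, "genome_id") <- genome_id
  out
}

#' Read a genome annotation
#'
#' Coordinates are 1-based inclusive throughout the package (the GFF3
#' convention); no silent 0-based conversion happens anywhere. Genes are
#' grouped by scaffold and sorted by begin coordinate.
#'
#' @param path Path to the annotation file.
#' @param format `"tab"` for a TSV with columns
#'   locus_id/scaffold/begin/end/strand (optional description), `"gff3"` for
#'   GFF3 (gene or CDS features; locus id from `ID` or `locus_tag`).
#' @param genome_id Genome identifier.
#' @return A `genome_annotation`: a tibble of gene records.
#' @export
read_genome_annotation <- function(path, format = c("tab", "gff3"), genome_id = "genome") {
  format <- match.arg(format)
  if (format == "tab") {
    df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    names(df) <- sub("^locus$", "locus_id", names(df))
  } else {
    g <- rtracklayer::readGFF(path)
    g <- as.data.frame(g)
    keep_types <- intersect(c("gene", "CDS"), unique(as.character(g$type)))
    if (length(keep_types) > 0) g <- g[as.character(g$type) %in% keep_types[1], ]
    id <- if (!is.null(g$locus_tag) && !all(is.na(g$locus_tag))) g$locus_tag else g$ID
    df <- tibble(
      locus_id = as.character(id),
      scaffold = as.character(g$seqid),
      begin = as.integer(g$start),
      end = as.integer(g$end),
      strand = as.character(g$strand),
      description = if (is.null(g$product)) NA_character_ else as.character(g$product)
    )
  }
  new_genome_annotation(df, genome_id = genome_id)
}

#' Write a genome annotation as a tab file
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @export
write_genome_annotation <- function(ann, path) {
  readr::write_tsv(as_tibble(as.data.frame(ann)), path, progress = FALSE)
  invisible(ann)
}

#' Construct a position weight matrix
#'
#' @param probs Width x 4 matrix of letter probabilities, columns A,C,G,T.
#' @param motif_id Motif identifier.
#' @param background Genome nucleotide frequencies (A,C,G,T), summing to 1.
#' @param pseudocount Nonnegative pseudocount mixed into each row before
#'   re-normalization (per letter, as a fraction of one observation).
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, motif_id = "motif", background = rep(0.25, 4), pseudocount = 0.5) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) abort("`probs` must have 4 columns (A,C,G,T).")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("Each PWM row must sum to 1.")
  }
  if (abs(sum(background) - 1) > 1e-9) abort("`background` must sum to 1.")
  if (pseudocount < 0) abort("`pseudocount` must be nonnegative.")
  if (pseudocount > 0) {
    probs <- probs + pseudocount / 4
    probs <- probs / rowSums(probs)
  } else if (any(probs == 0)) {
    warn(sprintf("Motif %s contains zero probabilities with pseudocount 0; log-odds scoring will fail there.", motif_id))
  }
  colnames(probs) <- c("A", "C", "G", "T")
  structure(
    list(motif_id = motif_id, width = nrow(probs), probs = probs,
         background = setNames(background, c("A", "C", "G", "T")),
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d\n", x$motif_id, x$width))
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses the `MEME version` / `ALPHABET= ACGT` / `letter-probability matrix`
#' minimal dialect. Probabilities are pseudocount-mixed and re-normalized.
#'
#' @param path Path to the MEME minimal file.
#' @param background Background nucleotide frequencies (A,C,G,T); overrides
#'   any background line in the file.
#' @param pseudocount Pseudocount passed to [pwm()].
#' @return A named list of [pwm()] objects.
#' @export
read_pwm_meme <- function(path, background = rep(0.25, 4), pseudocount = 0.5) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) abort("Not a MEME minimal file (no 'MEME version' line).")
  alpha <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alpha) > 0) {
    a <- gsub("\\s", "", sub("^ALPHABET=", "", alpha[1]))
    if (toupper(a) != "ACGT") abort(sprintf("Unsupported alphabet '%s' (only ACGT).", a))
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) abort("No MOTIF blocks found.")
  out <- list()
  for (s in starts) {
    motif_id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + which(grepl("letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    if (is.na(hdr)) abort(sprintf("Motif %s lacks a letter-probability matrix.", motif_id))
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- list()
    i <- hdr + 1
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(MOTIF|URL|letter)", ln)) break
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) break
      rows[[length(rows) + 1]] <- v
      i <- i + 1
    }
    m <- do.call(rbind, rows)
    if (!is.na(w) && nrow(m) != w) {
      abort(sprintf("Motif %s: matrix has %d rows but header says w=%d.", motif_id, nrow(m), w))
    }
    if (any(abs(rowSums(m) - 1) > 1e-3)) {
      abort(sprintf("Motif %s: a probability row does not sum to ~1.", motif_id))
    }
    m <- m / rowSums(m)
    out[[motif_id]] <- pwm(m, motif_id = motif_id, background = background,
                           pseudocount = pseudocount)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms A list of [pwm()] objects.
#' @param path Output path.
#' @export
write_pwm_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", p$width), con)
    apply(p$probs, 1, function(r) writeLines(paste(sprintf("%.6f", r), collapse = " "), con))
    writeLines("", con)
  }
  invisible(pwms)
}

#' Read regulatory predictions
#'
#' A prediction record couples a TF locus with its predicted targets, the
#' ortholog-group (regulog) id the prediction came from, the annotated
#' regulatory sign, and optionally a motif id. TSV columns:
#' `tf_locus`, `group_id`, `sign`, `motif_id`, `targets` (comma-separated).
#' A JSON file holding an array of objects with the same fields is also
#' accepted.
#'
#' @param path Path to the predictions TSV or JSON.
#' @return A tibble with columns `tf_locus`, `group_id`, `sign`, `motif_id`
#'   and list-column `targets`.
#' @export
read_predictions <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- tibble(
      tf_locus = map_chr(js, "tf_locus"),
      group_id = map_chr(js, ~ .x$group_id %||% NA_character_),
      sign = map_chr(js, ~ .x$sign %||% "unknown"),
      motif_id = map_chr(js, ~ .x$motif_id %||% NA_character_),
      targets = map(js, ~ as.character(unlist(.x$targets)))
    )
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    df <- tibble(
      tf_locus = raw$tf_locus,
      group_id = raw$group_id %||% NA_character_,
      sign = raw$sign %||% "unknown",
      motif_id = raw$motif_id %||% NA_character_,
      targets = map(raw$targets, ~ strsplit(.x, ",")[[1]] |> trimws())
    )
  }
  df$sign[is.na(df$sign)] <- "unknown"
  bad <- setdiff(unique(df$sign), c("activator", "repressor", "dual", "unknown"))
  if (length(bad) > 0) abort(sprintf("Unknown annotated sign '%s'.", bad[1]))
  df
}

#' Write regulatory predictions as TSV
#'
#' @param predictions Tibble as returned by [read_predictions()].
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions |>
    mutate(targets = map_chr(.data$targets, ~ paste(.x, collapse = ","))) |>
    select(any_of(c("tf_locus", "group_id", "sign", "motif_id", "targets")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(predictions)
}

#' Read a symmetric gene association (e.g. coexpression) matrix
#'
#' The TSV has a `locus_id` first column and one column per gene. Values must
#' lie in \[-1, 1\], the matrix must be symmetric (to 1e-9 beyond missing
#' entries), and defined diagonal entries must be 1.
#'
#' @param path Path to the matrix TSV.
#' @return A numeric matrix with identical row and column locus ids.
#' @export
read_association_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), na = c("", "NA"), progress = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1])
  rownames(m) <- ids
  if (!identical(rownames(m), colnames(m))) abort("Association matrix rows and columns must match.")
  if (any(abs(m) > 1 + 1e-9, na.rm = TRUE)) abort("Association values must lie in [-1, 1].")
  ok <- !is.na(m) & !is.na(t(m))
  if (any(abs(m[ok] - t(m)[ok]) > 1e-9)) abort("Association matrix must be symmetric.")
  d <- diag(m)
  if (any(!is.na(d) & abs(d - 1) > 1e-9)) abort("Association diagonal must equal 1 where defined.")
  m
}

result_columns <- c(
  "tf_locus", "group_id", "annotated_sign", "motif_id", "N", "T", "M_top",
  "R", "R_prime", "r_max", "r_min", "top_target_act", "top_target_rep",
  "p_rank_act", "p_rank_rep", "p_fisher_act", "p_fisher_rep",
  "p_activator", "p_repressor", "has_phenotype", "tested", "validated",
  "sign", "polar"
)

#' Write per-TF validation results as TSV
#'
#' One row per TF with a deterministic column order; numeric columns are
#' written at 6 significant digits. An empty result set yields a header-only
#' file.
#'
#' @param results A tibble of TF test results (see [validate_predictions()]).
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  res <- as_tibble(results)
  for (col in result_columns) {
    if (!col %in% names(res)) res[[col]] <- NA
  }
  res <- res[, result_columns]
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(x) signif(x, 6))
  readr::write_tsv(res, path, progress = FALSE)
  invisible(results)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path Path to the results TSV.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), na = c("", "NA"), progress = FALSE)
}
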