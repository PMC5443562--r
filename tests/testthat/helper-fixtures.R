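# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# small fitness table with optional missing cells
tiny_table <- function(genes = 3, exps = 4, seed = 1, na_cells = NULL,
                       genome_id = "tiny") {
  set.seed(seed)
  m <- matrix(round(rnorm(genes * exps), 3), genes, exps,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("e%02d", seq_len(exps))))
  t <- round(m * 4, 3)
  if (!is.null(na_cells)) m[na_cells] <- NA
  fitness_table(m, t, genome_id = genome_id)
}

# linear annotation: n genes on one scaffold, fixed length/gap
linear_annotation <- function(n, gene_len = 900, gap = 100, strand = "+",
                              scaffold = "sc1", prefix = "g") {
  begin <- 1000 + (seq_len(n) - 1) * (gene_len + gap)
  cofitval:::new_genome_annotation(tibble::tibble(
    locus_id = sprintf("%s%02d", prefix, seq_len(n)),
    scaffold = scaffold, begin = as.integer(begin),
    end = as.integer(begin + gene_len - 1),
    strand = if (length(strand) == 1) rep(strand, n) else strand
  ))
}

# annotation directly from begin/end/strand vectors
annotation_from <- function(begin, end, strand, scaffold = "sc1",
                            ids = sprintf("g%02d", seq_along(begin))) {
  cofitval:::new_genome_annotation(tibble::tibble(
    locus_id = ids, scaffold = scaffold,
    begin = as.integer(begin), end = as.integer(end), strand = strand
  ))
}

# fitness table with exact planted structure: a named list of rows
table_from_rows <- function(rows, genome_id = "built") {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("e%03d", seq_len(ncol(m)))
  fitness_table(m, m * 4, genome_id = genome_id)
}

# a cofitness_profile built directly from corrected values (for tests of
# consumers that only need the profile contract)
profile_from_values <- function(focal, partners, corrected, m_shared = 100) {
  def <- !is.na(corrected)
  rk <- rep(NA_integer_, length(corrected)); ark <- rk
  rk[def] <- as.integer(rank(-corrected[def], ties.method = "min"))
  ark[def] <- as.integer(rank(corrected[def], ties.method = "min"))
  out <- tibble::tibble(partner = partners, raw = corrected,
                        corrected = corrected,
                        m_shared = as.integer(rep_len(m_shared, length(partners))),
                        rank = rk, anti_rank = ark)
  class(out) <- c("cofitness_profile", class(out))
  attr(out, "focal") <- focal
  attr(out, "bias") <- 0
  attr(out, "n_defined") <- sum(def)
  out
}

# an informative test motif: near-consensus PWM of the given width
test_pwm <- function(width = 12, motif_id = "M1", seed = 5, pseudocount = 0.5) {
  set.seed(seed)
  cons <- sample(4, width, replace = TRUE)
  probs <- matrix(0.01, width, 4)
  probs[cbind(seq_len(width), cons)] <- 0.97
  pwm(probs, motif_id = motif_id, pseudocount = pseudocount)
}
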