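# Small in-code fixtures shared across test files.

toy_db <- function() {
  tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    sequence = c("AAAAAAAK",                          # 1 tryptic peptide
                 "AAAAAAAKCCCCCCCKDDDDDDDKEEEEEEEK",  # 4 tryptic peptides
                 "HPHPHPHPHP"),
    is_decoy = FALSE,
    is_contaminant = FALSE
  )
}

# one observation row with defaults filled in
obs_row <- function(peptide, group, intensity, sample = "V", rep = "R1",
                    method = "tryptic", score = 100) {
  tibble::tibble(peptide_sequence = peptide, group_id = group,
                 sample_id = sample, replicate_id = rep, method = method,
                 intensity = intensity, psm_score = score)
}

# a quant tibble set up by hand (already normalized weights)
toy_quant <- function(ids, il_rel, sample = "V", rep = "R1",
                      method = "tryptic", intensity = NULL, ribaq = NULL) {
  tibble::tibble(
    group_id = ids, sample_id = sample, replicate_id = rep, method = method,
    summed_intensity = intensity %||% (il_rel * 1000),
    il_rel = il_rel, ribaq = ribaq %||% il_rel
  )
}

`%||%` <- rlang::`%||%`
`%+%` <- function(a, b) paste0(a, b)

random_protein <- function(len) {
  paste(sample(phycoprot::aa_alphabet(), len, replace = TRUE),
        collapse = "")
}

# A synthetic beta-emulsifier score table whose top 85 records form exactly
# four overlap chains (each chain's members share a common residue) and
# whose 86th-ranked record lies in untouched territory: the structure where
# greedy top-5 selection must reach down to rank 86 for its fifth pick.
build_four_chain_table <- function() {
  rows <- purrr::map_dfr(1:85, function(rank) {
    chain <- (rank - 1) %% 4 + 1
    center <- 300 * chain
    half <- 3 + (rank - 1) %/% 4   # widening intervals around the center
    tibble::tibble(
      peptide_sequence = strrep("A", 2 * half + 1),
      protein_id = "parent", start = center - half, end = center + half,
      class = "beta", score = 100 - rank, rank = rank)
  })
  dplyr::bind_rows(rows, tibble::tibble(
    peptide_sequence = strrep("A", 7), protein_id = "parent",
    start = 2000, end = 2006, class = "beta", score = 100 - 86, rank = 86))
}
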