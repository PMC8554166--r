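# Seeded synthetic-data generator: a toy proteome with known molar
# abundances and compartments, realized in-silico digestion under three
# specificity modes, MS1 intensities with residue-dependent detectability
# bias, duplicate technical replicates with multiplicative noise, dropout,
# contaminants, reversed decoys and spurious single-peptide groups.

#' Synthetic-data generator configuration
#'
#' Defaults emulate the structure of the enzymatic-extract study design:
#' three extracts (`V`, `A`, `SC`) in technical duplicate, three digestion
#' specificity modes, log-normal protein lengths (median 200 residues) and
#' molar abundances (sigma 1.5), a multiplicative detectability penalty of
#' 0.7 per Met/His/Trp/Cys residue, 20% CV replicate noise and 10% peptide
#' dropout. The generated MS1 intensity of a peptide is proportional to
#' molar abundance x peptide length (the convention under which riBAQ-style
#' and length-normalized estimators are exact in the noise-free limit);
#' `length_independent_intensity = TRUE` switches this off to study
#' short-peptide bias.
#'
#' @param n_proteins Number of target proteins.
#' @param length_meanlog,length_sdlog Log-normal protein length parameters.
#' @param aa_freq Background residue frequencies (named over the alphabet).
#' @param compartment_probs Prior over the ten-compartment vocabulary.
#' @param abundance_sdlog Log-normal sigma of molar abundances.
#' @param extract_intracellular_multiplier Named per-extract multiplier
#'   applied to the abundance of non-extracellular proteins, emulating
#'   extraction chemistry (an Alcalase-like profile suppresses intracellular
#'   protein).
#' @param methods Digestion modes to simulate.
#' @param n_replicates Technical replicates per extract.
#' @param missed_cleavage_prob Probability that a tryptic site is skipped in
#'   the realized digest (the realized digest stays a complete,
#'   non-overlapping partition of the sequence).
#' @param detect_penalty Multiplicative intensity penalty per Met/His/Trp/
#'   Cys residue of a peptide (1 = no bias).
#' @param cv Coefficient of variation of multiplicative replicate noise.
#' @param dropout Probability a peptide is missed in a replicate.
#' @param length_independent_intensity Draw intensity independent of peptide
#'   length.
#' @param contaminant_fraction Contaminant proteins as a fraction of
#'   `n_proteins`; their total signal share matches this fraction.
#' @param decoys Append reversed-sequence decoy records to the database.
#' @param n_spurious Spurious single-peptide, single-method groups injected
#'   with low scores (exercises outlier flagging).
#' @param score_meanlog,score_sdlog Log-normal protein-score parameters for
#'   genuine groups; spurious groups draw scores uniformly on (2, 20).
#' @return A named list of class `sim_config`.
#' @export
simulation_config <- function(n_proteins = 50,
                              length_meanlog = log(200),
                              length_sdlog = 0.35,
                              aa_freq = NULL,
                              compartment_probs = NULL,
                              abundance_sdlog = 1.5,
                              extract_intracellular_multiplier =
                                c(V = 1, A = 0.25, SC = 1.5),
                              methods = c("tryptic", "semi", "unspecific"),
                              n_replicates = 2,
                              missed_cleavage_prob = 0.2,
                              detect_penalty = 0.7,
                              cv = 0.2,
                              dropout = 0.1,
                              length_independent_intensity = FALSE,
                              contaminant_fraction = 0.05,
                              decoys = TRUE,
                              n_spurious = 2,
                              score_meanlog = log(150),
                              score_sdlog = 0.8) {
  if (is.null(aa_freq)) {
    # typical proteome-average residue frequencies
    aa_freq <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
                 G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
                 M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
                 S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92)
  }
  aa_freq <- aa_freq[aa_alphabet()]
  aa_freq <- aa_freq / sum(aa_freq)
  if (is.null(compartment_probs)) {
    compartment_probs <- c(
      "Cytoplasm" = 0.28, "Nucleus" = 0.18, "Extracellular" = 0.14,
      "Mitochondrion" = 0.08, "Plastid" = 0.10,
      "Endoplasmic reticulum" = 0.06, "Golgi apparatus" = 0.04,
      "Lysosome/Vacuole" = 0.04, "Cell membrane" = 0.05,
      "Peroxisome" = 0.03)
  }
  stopifnot(setequal(names(compartment_probs), deeploc_compartments()),
            all(compartment_probs >= 0),
            detect_penalty > 0, detect_penalty <= 1,
            dropout >= 0, dropout <= 1,
            missed_cleavage_prob >= 0, missed_cleavage_prob <= 1)
  compartment_probs <- compartment_probs / sum(compartment_probs)
  cfg <- list(
    n_proteins = n_proteins, length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, aa_freq = aa_freq,
    compartment_probs = compartment_probs,
    abundance_sdlog = abundance_sdlog,
    extract_intracellular_multiplier = extract_intracellular_multiplier,
    methods = methods, n_replicates = n_replicates,
    missed_cleavage_prob = missed_cleavage_prob,
    detect_penalty = detect_penalty, cv = cv, dropout = dropout,
    length_independent_intensity = length_independent_intensity,
    contaminant_fraction = contaminant_fraction, decoys = decoys,
    n_spurious = n_spurious, score_meanlog = score_meanlog,
    score_sdlog = score_sdlog)
  class(cfg) <- c("sim_config", "list")
  cfg
}

random_sequence <- function(len, aa_freq) {
  paste(sample(names(aa_freq), len, replace = TRUE, prob = aa_freq),
        collapse = "")
}

#' Generate a synthetic proteome with ground truth
#'
#' Draws protein sequences, compartments, molar abundances and group scores
#' from the configured distributions; appends contaminant records
#' (`CON_` prefix), reversed decoys (`REV_` prefix) and spurious
#' low-score proteins. Per-extract molar fractions are obtained by
#' reweighting non-extracellular abundances with the extract's multiplier
#' and renormalizing.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; fixes all randomness of the proteome.
#' @return A list of class `sim_proteome`: `proteins` (with `is_decoy`,
#'   `is_contaminant`, `is_spurious`, `score`, `compartment`), `truth`
#'   (long tibble `protein_id`, `sample_id`, `molar_fraction` over target
#'   proteins), `localization`, `config`.
#' @export
simulate_proteome <- function(config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_proteins
  n_cont <- round(config$contaminant_fraction * n)
  n_spur <- config$n_spurious

  lens <- pmax(30L, round(stats::rlnorm(n + n_cont + n_spur,
                                        config$length_meanlog,
                                        config$length_sdlog)))
  seqs <- vapply(lens, random_sequence, character(1),
                 aa_freq = config$aa_freq)
  ids <- c(sprintf("P%04d", seq_len(n)),
           if (n_cont > 0) sprintf("CON_%04d", seq_len(n_cont)),
           if (n_spur > 0) sprintf("SPUR%02d", seq_len(n_spur)))
  kind <- rep(c("target", "contaminant", "spurious"),
              times = c(n, n_cont, n_spur))
  comp <- sample(names(config$compartment_probs), length(ids),
                 replace = TRUE, prob = config$compartment_probs)
  score <- stats::rlnorm(length(ids), config$score_meanlog,
                         config$score_sdlog)
  score[kind == "spurious"] <- stats::runif(sum(kind == "spurious"), 2, 20)

  proteins <- tibble::tibble(
    protein_id = ids, sequence = seqs,
    is_contaminant = kind == "contaminant",
    is_decoy = FALSE,
    is_spurious = kind == "spurious",
    compartment = comp, score = score)

  if (config$decoys) {
    rev_seqs <- vapply(strsplit(proteins$sequence, ""),
                       function(x) paste(rev(x), collapse = ""),
                       character(1))
    decoys <- tibble::tibble(
      protein_id = paste0("REV_", proteins$protein_id),
      sequence = rev_seqs, is_contaminant = FALSE, is_decoy = TRUE,
      is_spurious = FALSE, compartment = "unknown",
      score = stats::runif(nrow(proteins), 0, 10))
    proteins <- dplyr::bind_rows(proteins, decoys)
  }

  base_ab <- stats::rlnorm(n, 0, config$abundance_sdlog)
  target <- ids[kind == "target"]
  target_comp <- comp[kind == "target"]
  truth <- purrr::imap_dfr(
    as.list(config$extract_intracellular_multiplier),
    function(mult, extract) {
      w <- base_ab * ifelse(target_comp == "Extracellular", 1, mult)
      tibble::tibble(protein_id = target, sample_id = extract,
                     compartment = target_comp,
                     molar_fraction = w / sum(w))
    })

  out <- list(
    proteins = proteins, truth = truth,
    localization = tibble::tibble(protein_id = proteins$protein_id,
                                  compartment = proteins$compartment),
    config = config)
  class(out) <- c("sim_proteome", "list")
  out
}

# A realized digest: a complete, non-overlapping partition of the sequence,
# drawn once per protein x method.
realized_partition <- function(sequence, method, config) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (method %in% c("tryptic", "semi")) {
    sites <- which(chars %in% c("K", "R"))
    sites <- sites[sites < n & chars[sites + 1L] != "P"]
    kept <- sites[stats::runif(length(sites)) >= config$missed_cleavage_prob]
    bounds <- c(0L, kept, n)
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1]
    if (method == "semi") {
      # split some fragments at a random internal point: ragged termini with
      # coverage preserved
      s2 <- integer(0); e2 <- integer(0)
      for (i in seq_along(starts)) {
        L <- ends[i] - starts[i] + 1L
        if (L >= 4 && stats::runif(1) < 0.5) {
          cut <- starts[i] + sample.int(L - 1L, 1) - 1L
          s2 <- c(s2, starts[i], cut + 1L); e2 <- c(e2, cut, ends[i])
        } else {
          s2 <- c(s2, starts[i]); e2 <- c(e2, ends[i])
        }
      }
      starts <- s2; ends <- e2
    }
  } else {
    # unspecific: consecutive random fragments within the 5-65 bound
    starts <- integer(0); ends <- integer(0)
    pos <- 1L
    while (pos <= n) {
      L <- sample(5:30, 1)
      e <- min(n, pos + L - 1L)
      if (n - e < 5 && n - e > 0) e <- n  # absorb a too-short tail
      starts <- c(starts, pos); ends <- c(ends, e)
      pos <- e + 1L
    }
  }
  tibble::tibble(peptide = substring(sequence, starts, ends),
                 start = starts, end = ends)
}

#' Simulate peptide observation tables
#'
#' Realizes a digestion partition per protein and method, then draws MS1
#' intensities per extract and replicate: base intensity = molar abundance
#' x peptide length x detectability penalty per Met/His/Trp/Cys residue,
#' multiplied by log-normal replicate noise of the configured CV, with
#' peptides dropped out independently per replicate. Contaminant proteins
#' contribute their configured signal share; spurious proteins appear as a
#' single peptide in a single method.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param seed Integer seed for the observation-level randomness.
#' @return A list of class `sim_observations`: `observations` (peptide
#'   table), `groups` (`group_id`, `score`, flags), `promiscuity`
#'   (`peptide_sequence`, `n_matches` with large counts for the spurious
#'   peptides).
#' @export
simulate_observations <- function(proteome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- proteome$config
  prot <- dplyr::filter(proteome$proteins, !.data$is_decoy)
  sigma <- sqrt(log(1 + config$cv^2))
  penalty_count <- function(pep) {
    vapply(strsplit(pep, "", fixed = TRUE),
           function(x) sum(x %in% c("M", "H", "W", "C")), numeric(1))
  }

  # molar abundance per protein x extract on a common scale: targets carry
  # the truth fractions; contaminants are scaled to their signal share
  extracts <- names(config$extract_intracellular_multiplier)
  target_ab <- proteome$truth[, c("protein_id", "sample_id",
                                  "molar_fraction")]
  names(target_ab)[3] <- "abundance"
  cont <- dplyr::filter(prot, .data$is_contaminant)
  cont_ab <- tibble::tibble()
  if (nrow(cont) > 0 && config$contaminant_fraction > 0) {
    raw <- stats::rlnorm(nrow(cont), 0, config$abundance_sdlog)
    cont_ab <- purrr::map_dfr(extracts, function(e) {
      tgt <- dplyr::filter(target_ab, .data$sample_id == e)
      tgt_len <- nchar(prot$sequence[match(tgt$protein_id,
                                           prot$protein_id)])
      signal_target <- sum(tgt$abundance * tgt_len)
      cont_len <- nchar(cont$sequence)
      share <- config$contaminant_fraction
      scale <- share / (1 - share) * signal_target / sum(raw * cont_len)
      tibble::tibble(protein_id = cont$protein_id, sample_id = e,
                     abundance = raw * scale)
    })
  }
  abundance <- dplyr::bind_rows(target_ab, cont_ab)

  quantified <- dplyr::filter(prot, !.data$is_spurious)
  obs <- purrr::map_dfr(config$methods, function(m) {
    parts <- purrr::map2_dfr(quantified$protein_id, quantified$sequence,
                             function(id, s) {
      p <- realized_partition(s, m, config)
      p$protein_id <- id
      p
    })
    if (m == "unspecific") {
      parts <- dplyr::filter(parts, nchar(.data$peptide) >= 5,
                             nchar(.data$peptide) <= 65)
    }
    parts$penalty <- config$detect_penalty^penalty_count(parts$peptide)
    parts$method <- m
    parts
  })

  rows <- purrr::map_dfr(extracts, function(e) {
    ab <- dplyr::filter(abundance, .data$sample_id == e)
    o <- dplyr::inner_join(obs, ab[, c("protein_id", "abundance")],
                           by = "protein_id")
    base <- if (config$length_independent_intensity) {
      o$abundance * o$penalty
    } else {
      o$abundance * nchar(o$peptide) * o$penalty
    }
    purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      keep <- stats::runif(nrow(o)) >= config$dropout
      noise <- if (config$cv > 0) {
        stats::rlnorm(nrow(o), -sigma^2 / 2, sigma)
      } else {
        rep(1, nrow(o))
      }
      tibble::tibble(
        peptide_sequence = o$peptide[keep], group_id = o$protein_id[keep],
        sample_id = e, replicate_id = paste0("R", r), method = o$method[keep],
        intensity = (base * noise)[keep],
        psm_score = stats::rlnorm(sum(keep), log(60), 0.6))
    })
  })

  # spurious single-peptide, single-method observations in every extract
  spur <- dplyr::filter(prot, .data$is_spurious)
  promiscuity <- tibble::tibble(peptide_sequence = character(),
                                n_matches = numeric())
  if (nrow(spur) > 0) {
    spur_rows <- purrr::map_dfr(seq_len(nrow(spur)), function(i) {
      part <- realized_partition(spur$sequence[i], "tryptic", config)
      part <- dplyr::filter(part, nchar(.data$peptide) >= 6)
      pep <- if (nrow(part) > 0) {
        part$peptide[sample.int(nrow(part), 1)]
      } else {
        substr(spur$sequence[i], 1, 10)
      }
      m <- sample(config$methods, 1)
      purrr::map_dfr(extracts, function(e) {
        tot <- sum(rows$intensity[rows$sample_id == e])
        purrr::map_dfr(paste0("R", seq_len(config$n_replicates)),
                       function(r) {
          tibble::tibble(peptide_sequence = pep,
                         group_id = spur$protein_id[i], sample_id = e,
                         replicate_id = r, method = m,
                         intensity = 0.002 * tot *
                           stats::rlnorm(1, 0, sigma),
                         psm_score = stats::runif(1, 5, 20))
        })
      })
    })
    rows <- dplyr::bind_rows(rows, spur_rows)
    promiscuity <- tibble::tibble(
      peptide_sequence = unique(spur_rows$peptide_sequence),
      n_matches = stats::runif(length(unique(spur_rows$peptide_sequence)),
                               3000, 8000))
  }

  groups <- prot[, c("protein_id", "score", "is_contaminant", "is_decoy",
                     "is_spurious")]
  names(groups)[1] <- "group_id"
  out <- list(observations = rows, groups = groups,
              promiscuity = promiscuity)
  class(out) <- c("sim_observations", "list")
  out
}

#' True abundance-weighted amino-acid composition of a simulated extract
#'
#' @param proteome A [simulate_proteome()] result.
#' @param sample_id Extract label.
#' @return An `aa_composition` tibble with `source = "reference"`.
#' @export
true_composition <- function(proteome, sample_id = "V") {
  tr <- dplyr::filter(proteome$truth, .data$sample_id == !!sample_id)
  if (nrow(tr) == 0) rlang::abort(sprintf("no extract '%s'", sample_id))
  seqs <- proteome$proteins$sequence[match(tr$protein_id,
                                           proteome$proteins$protein_id)]
  lens <- nchar(seqs)
  # residue fractions weighted by residue counts: molar_fraction x length
  w <- tr$molar_fraction * lens / sum(tr$molar_fraction * lens)
  fm <- frequency_matrix(seqs)
  freq <- colSums(fm * w)
  new_aa_composition(tibble::tibble(aa = names(freq),
                                    frequency = unname(freq)),
                     source = "reference")
}

#' Simulate a complete dataset
#'
#' Runs [simulate_proteome()] and [simulate_observations()] under one seed
#' and assembles every artifact the pipeline consumes, including a
#' synthetic AAA table per extract (true composition converted back to
#' mg/g with the free amino-acid molecular weights, Asx/Glx pooled) and a
#' synthetic prediction-score table.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_dataset` with elements `proteins`, `truth`,
#'   `localization`, `observations`, `groups`, `promiscuity`, `aaa`,
#'   `predictions`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  proteome <- simulate_proteome(config)
  simobs <- simulate_observations(proteome)

  extracts <- names(config$extract_intracellular_multiplier)
  aaa <- purrr::map_dfr(extracts, function(e) {
    comp <- pool_asx_glx(true_composition(proteome, e))
    mw <- aa_molecular_weights()
    wt <- comp$frequency * mw[comp$aa]
    tibble::tibble(sample_id = e, aa = comp$aa,
                   mg_per_g = unname(500 * wt / sum(wt)))
  })

  # synthetic prediction records: random windows with random class/score
  tgt <- dplyr::filter(proteome$proteins, !.data$is_decoy,
                       !.data$is_contaminant, !.data$is_spurious)
  n_pred <- min(60L, 4L * nrow(tgt))
  idx <- sample.int(nrow(tgt), n_pred, replace = TRUE)
  len <- sample(5:25, n_pred, replace = TRUE)
  maxstart <- pmax(1L, nchar(tgt$sequence[idx]) - len + 1L)
  start <- vapply(maxstart, function(m) sample.int(m, 1), integer(1))
  cls <- sample(c("alpha", "beta", "gamma", "SCA", "CHE"), n_pred,
                replace = TRUE)
  predictions <- tibble::tibble(
    peptide_sequence = substring(tgt$sequence[idx], start,
                                 pmin(nchar(tgt$sequence[idx]),
                                      start + len - 1L)),
    protein_id = tgt$protein_id[idx],
    start = start,
    end = pmin(nchar(tgt$sequence[idx]), start + len - 1L),
    class = cls,
    score = ifelse(cls %in% c("SCA", "CHE"), stats::runif(n_pred, 0, 1),
                   stats::rnorm(n_pred, 2, 1)))

  out <- c(proteome[c("proteins", "truth", "localization")],
           simobs[c("observations", "groups", "promiscuity")],
           list(aaa = aaa, predictions = predictions, config = config))
  class(out) <- c("sim_dataset", "list")
  out
}

#' Write a simulated dataset to disk
#'
#' Emits every artifact type as plain text: the protein FASTA, the peptide
#' observation TSV, the protein-group TSV, the localization TSV, the
#' synthetic AAA TSV, the synthetic prediction TSV and the ground truth as
#' JSON. Re-running with the same seed reproduces identical files.
#'
#' @param sim A [simulate_dataset()] result.
#' @param out_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_fasta(sim$proteins, file.path(out_dir, "proteins.fasta"))
  write_peptide_table(sim$observations, file.path(out_dir, "peptides.tsv"))
  readr::write_tsv(sim$groups, file.path(out_dir, "groups.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$localization, file.path(out_dir, "localization.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$aaa, file.path(out_dir, "aaa.tsv"), progress = FALSE)
  readr::write_tsv(sim$predictions, file.path(out_dir, "predictions.tsv"),
                   progress = FALSE)
  jsonlite::write_json(sim$truth, file.path(out_dir, "ground_truth.json"),
                       digits = NA)
  invisible(out_dir)
}
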