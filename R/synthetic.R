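#' Configuration for the synthetic-data generator
#'
#' Describes a two-class study with the structure the pipeline assumes: a
#' layered signed PKN (stimuli -> inhibitors -> readouts), one planted
#' ground-truth Boolean network per response class differing in a controlled
#' number of clauses, and a continuous patient x protein table obtained by
#' mapping Boolean signals onto an RPPA-like positive scale with Gaussian
#' noise.
#'
#' @param n_stimuli,n_inhibitors,n_readouts layer sizes of the generated PKN.
#' @param n_patients_per_class patients per class; a length-2 vector gives
#'   (CR, PR) counts separately.
#' @param clause_density probability of adding extra OR clauses beyond the
#'   one clause each regulated node always carries.
#' @param divergence exact number of clauses by which the PR truth network
#'   differs from the CR one (symmetric difference); changes are applied to
#'   readout-target clauses so the two classes differ in observable behavior.
#' @param noise_sd standard deviation of the Gaussian measurement noise, on
#'   the Boolean \[0,1\] signal scale before rescaling.
#' @param input_bit_prob Bernoulli probability of a 1 input bit per patient
#'   and input protein (ignored when `complete_inputs` is set).
#' @param complete_inputs if `TRUE`, patients enumerate all `2^n` input-bit
#'   patterns (cycled to the requested patient count) instead of sampling,
#'   so the experiments cover the full input space.
#' @param seed integer seed making the whole generation deterministic.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_stimuli = 3, n_inhibitors = 3, n_readouts = 2,
                         n_patients_per_class = 8, clause_density = 0.15,
                         divergence = 2, noise_sd = 0.1,
                         input_bit_prob = 0.5, complete_inputs = FALSE,
                         seed = 1) {
  stopifnot(n_stimuli >= 1, n_inhibitors >= 1, n_readouts >= 1,
            all(n_patients_per_class >= 1),
            clause_density >= 0, clause_density <= 1,
            divergence >= 0, noise_sd >= 0,
            input_bit_prob > 0, input_bit_prob < 1)
  n_pat <- if (length(n_patients_per_class) == 1L) {
    rep(n_patients_per_class, 2L)
  } else n_patients_per_class[1:2]
  structure(list(n_stimuli = n_stimuli, n_inhibitors = n_inhibitors,
                 n_readouts = n_readouts, n_patients_per_class = n_pat,
                 clause_density = clause_density, divergence = divergence,
                 noise_sd = noise_sd, input_bit_prob = input_bit_prob,
                 complete_inputs = complete_inputs, seed = as.integer(seed)),
            class = "synth_config")
}

# layered acyclic signed PKN honoring the intended role partition
synth_pkn <- function(cfg) {
  sti <- sprintf("S%02d", seq_len(cfg$n_stimuli))
  inh <- sprintf("I%02d", seq_len(cfg$n_inhibitors))
  rdo <- sprintf("R%02d", seq_len(cfg$n_readouts))
  edge <- function(src, tgt) {
    tibble::tibble(source = src, sign = sample(c(1L, -1L), length(src),
                                               replace = TRUE),
                   target = tgt)
  }
  # each inhibitor: 1-2 stimulus parents; each readout: 1-2 inhibitor
  # parents, the first carrying both an activating and an inhibiting edge
  # (context-dependent dual regulation), which keeps class divergence by
  # sign flips expressible within the PKN
  e1 <- dplyr::bind_rows(lapply(inh, function(i) {
    edge(sample(sti, min(sample(1:2, 1), length(sti))), i)
  }))
  e2 <- dplyr::bind_rows(lapply(rdo, function(r) {
    parents <- sample(inh, min(sample(1:2, 1), length(inh)))
    dplyr::bind_rows(
      tibble::tibble(source = parents[1], sign = c(1L, -1L), target = r),
      if (length(parents) > 1L) edge(parents[-1], r)
    )
  }))
  ed <- dplyr::bind_rows(e1, e2)
  # patch dangling layers so roles come out as intended
  no_out_sti <- setdiff(sti, ed$source)
  if (length(no_out_sti) > 0L) {
    ed <- dplyr::bind_rows(ed, edge(no_out_sti,
                                    sample(inh, length(no_out_sti),
                                           replace = TRUE)))
  }
  no_out_inh <- setdiff(inh, ed$source)
  if (length(no_out_inh) > 0L) {
    ed <- dplyr::bind_rows(ed, edge(no_out_inh,
                                    sample(rdo, length(no_out_inh),
                                           replace = TRUE)))
  }
  ed <- ed[!duplicated(paste(ed$source, ed$sign, ed$target)), ]
  # a node regulated both positively and negatively by one parent is fine in
  # the PKN; keep it, the hypergraph treats the two signs as distinct clauses
  pkn(ed)
}

# one planted network: per regulated node one single-literal clause, plus
# extra clauses (with probability clause_density) on inhibitor targets only,
# so each readout's logic stays a single signed literal whose sign flip is
# observable on every input pattern
synth_truth <- function(hg, cfg) {
  cl <- hg$clauses
  rdo <- pkn_nodes(hg$pkn, "readout")
  pick1 <- function(ids) if (length(ids) == 1L) ids else sample(ids, 1L)
  singles <- cl[is.na(cl$source2), ]
  base <- vapply(split(seq_len(nrow(singles)), singles$target), function(i) {
    rows <- singles[i, ]
    if (rows$target[1] %in% rdo) {
      # prefer a clause whose complement is also in the catalogue
      has_comp <- vapply(seq_len(nrow(rows)), function(j) {
        any(rows$source1 == rows$source1[j] & rows$sign1 == -rows$sign1[j])
      }, logical(1))
      if (any(has_comp)) return(pick1(rows$id[has_comp]))
    }
    pick1(rows$id)
  }, integer(1))
  extra <- setdiff(cl$id[!(cl$target %in% rdo)], base)
  extra <- extra[stats::runif(length(extra)) < cfg$clause_density]
  boolean_network(hg, c(base, extra))
}

# apply `divergence` clause changes to readout-target clauses: sign flips of
# single-literal clauses (2 changes each) and, for an odd remainder, one
# clause addition (1 change)
diverge_truth <- function(truth, hg, cfg) {
  cl <- hg$clauses
  ids <- truth$clauses
  rdo <- pkn_nodes(hg$pkn, "readout")
  flippable <- ids[ids %in% cl$id[cl$target %in% rdo & is.na(cl$source2)]]
  # a sign flip needs the opposite-sign clause in the catalogue
  partner <- vapply(flippable, function(i) {
    row <- cl[cl$id == i, ]
    hit <- cl$id[cl$target == row$target & cl$source1 == row$source1 &
                   cl$sign1 == -row$sign1 & is.na(cl$source2)]
    if (length(hit) == 1L && !(hit %in% ids)) hit else NA_integer_
  }, integer(1))
  flippable <- flippable[!is.na(partner)]
  partner <- partner[!is.na(partner)]
  n_flip <- cfg$divergence %/% 2L
  odd <- cfg$divergence %% 2L
  addable <- setdiff(cl$id[cl$target %in% rdo], ids)
  if (length(flippable) < n_flip || (odd == 1L && length(addable) == 0L)) {
    stop("impossible divergence: the generated network supports at most ",
         2L * length(flippable) + sign(length(addable)),
         " clause changes on readout targets", call. = FALSE)
  }
  new_ids <- ids
  if (n_flip > 0L) {
    pick <- seq_len(n_flip)
    new_ids <- c(setdiff(new_ids, flippable[pick]), partner[pick])
  }
  if (odd == 1L) {
    add <- setdiff(addable, new_ids)
    new_ids <- c(new_ids, add[sample.int(length(add), 1L)])
  }
  boolean_network(hg, new_ids)
}

#' Generate a synthetic two-class study
#'
#' Builds a layered acyclic PKN whose edges superset both planted truth
#' networks, derives the CR truth network and a PR truth network differing
#' from it in exactly `divergence` clauses (changes target the readout layer,
#' so the class difference is observable), draws per-patient input bits,
#' propagates each class's truth network to its logical steady state, and
#' maps bits and readout signals onto a continuous positive measurement scale
#' with Gaussian noise. Deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `pkn`, `hypergraph`, `truth_cr`, `truth_pr`
#'   ([boolean_network()] objects), `data` (patient tibble: `patient`,
#'   `class`, proteins), `bits` (the true input-bit matrix) and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  net <- synth_pkn(config)
  hg <- expand_hypergraph(net)
  truth_cr <- synth_truth(hg, config)
  truth_pr <- diverge_truth(truth_cr, hg, config)

  inputs <- c(pkn_nodes(net, "stimulus"), pkn_nodes(net, "inhibitor"))
  rdo <- pkn_nodes(net, "readout")
  n_in <- length(inputs)
  draw_bits <- function(n) {
    if (config$complete_inputs) {
      pat <- all_clampings(inputs)
      pat[rep_len(seq_len(nrow(pat)), n), , drop = FALSE]
    } else {
      matrix(stats::rbinom(n * n_in, 1L, config$input_bit_prob),
             nrow = n, dimnames = list(NULL, inputs))
    }
  }
  class_table <- function(truth, n, cl, offset) {
    bits <- draw_bits(n)
    cand <- hg$clauses[match(truth$clauses, hg$clauses$id), , drop = FALSE]
    res <- bn_engine(net$nodes, cand,
                     submask = matrix(TRUE, 1L, nrow(cand)), clamp = bits)
    signal <- res$state[, match(rdo, net$nodes), drop = FALSE] * 1
    noisy_in <- bits + stats::rnorm(length(bits), sd = config$noise_sd)
    noisy_out <- pmin(pmax(signal +
                             stats::rnorm(length(signal),
                                          sd = config$noise_sd), 0), 1)
    raw_in <- 2 + 4 * noisy_in          # RPPA-like positive scale
    raw_out <- 1 + 3 * noisy_out
    colnames(raw_in) <- inputs
    colnames(raw_out) <- rdo
    list(tab = dplyr::bind_cols(
      tibble::tibble(patient = sprintf("%s%03d", cl, offset + seq_len(n)),
                     class = cl),
      tibble::as_tibble(raw_in), tibble::as_tibble(raw_out)),
      bits = bits)
  }
  cr <- class_table(truth_cr, config$n_patients_per_class[1], "CR", 0L)
  pr <- class_table(truth_pr, config$n_patients_per_class[2], "PR", 0L)
  bits <- rbind(cr$bits, pr$bits)
  data <- dplyr::bind_rows(cr$tab, pr$tab)
  rownames(bits) <- data$patient
  list(pkn = net, hypergraph = hg, truth_cr = truth_cr, truth_pr = truth_pr,
       data = data, bits = bits, config = config)
}

#' Draw additional patients from an existing synthetic study
#'
#' Samples new patient tables from the same PKN and planted truth networks
#' as `study`, e.g. as a held-out set for classification. Input bits are
#' always sampled (never the complete enumeration), so held-out patients are
#' exchangeable draws from the study population.
#'
#' @param study a list from [synth_generate()].
#' @param n_per_class patients per class (length 1 or 2).
#' @param noise_sd measurement noise (default: the study's).
#' @param seed seed for the new draw.
#' @return list with `data` (patient tibble) and `bits`.
#' @export
synth_patients <- function(study, n_per_class,
                           noise_sd = study$config$noise_sd, seed = 1) {
  cfg <- study$config
  cfg$noise_sd <- noise_sd
  cfg$complete_inputs <- FALSE
  set.seed(seed)
  net <- study$pkn
  hg <- study$hypergraph
  inputs <- c(pkn_nodes(net, "stimulus"), pkn_nodes(net, "inhibitor"))
  rdo <- pkn_nodes(net, "readout")
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  one <- function(truth, n, cl) {
    bits <- matrix(stats::rbinom(n * length(inputs), 1L, cfg$input_bit_prob),
                   nrow = n, dimnames = list(NULL, inputs))
    cand <- hg$clauses[match(truth$clauses, hg$clauses$id), , drop = FALSE]
    res <- bn_engine(net$nodes, cand,
                     submask = matrix(TRUE, 1L, nrow(cand)), clamp = bits)
    signal <- res$state[, match(rdo, net$nodes), drop = FALSE] * 1
    noisy_in <- bits + stats::rnorm(length(bits), sd = cfg$noise_sd)
    noisy_out <- pmin(pmax(signal + stats::rnorm(length(signal),
                                                 sd = cfg$noise_sd), 0), 1)
    raw_in <- 2 + 4 * noisy_in
    raw_out <- 1 + 3 * noisy_out
    colnames(raw_in) <- inputs
    colnames(raw_out) <- rdo
    list(tab = dplyr::bind_cols(
      tibble::tibble(patient = sprintf("H%s%03d", cl, seq_len(n)),
                     class = cl),
      tibble::as_tibble(raw_in), tibble::as_tibble(raw_out)),
      bits = bits)
  }
  cr <- one(study$truth_cr, n_per_class[1], "CR")
  pr <- one(study$truth_pr, n_per_class[2], "PR")
  data <- dplyr::bind_rows(cr$tab, pr$tab)
  bits <- rbind(cr$bits, pr$bits)
  rownames(bits) <- data$patient
  list(data = data, bits = bits)
}

#' Write a named synthetic fixture bundle to disk
#'
#' Presets: `"tiny"` (3 stimuli / 3 inhibitors / 2 readouts, 8+8 patients),
#' `"small"` (5/8/4, 30+30) and `"cohort"` (17/62/23, 96+95 — the
#' dimensionality of a realistic RPPA study). Writes `pkn.sif`, a
#' `patients.csv` table and the two truth networks as JSON under
#' `<dir>/<name>/`.
#'
#' @param name preset name.
#' @param dir parent directory.
#' @param seed generator seed.
#' @param noise_sd measurement noise (default 0.1).
#' @return the bundle directory path, invisibly; the generated study as
#'   attribute `"study"`.
#' @export
make_fixture <- function(name = c("tiny", "small", "cohort"),
                         dir = ".", seed = 1, noise_sd = 0.1) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = synth_config(3, 3, 2, n_patients_per_class = 8, seed = seed,
                        noise_sd = noise_sd),
    small = synth_config(5, 8, 4, n_patients_per_class = 30, seed = seed,
                         noise_sd = noise_sd),
    `cohort` = synth_config(17, 62, 23,
                                  n_patients_per_class = c(96, 95),
                                  seed = seed, noise_sd = noise_sd)
  )
  study <- synth_generate(cfg)
  path <- file.path(dir, name)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_sif(study$pkn, file.path(path, "pkn.sif"))
  utils::write.csv(study$data, file.path(path, "patients.csv"),
                   row.names = FALSE, quote = FALSE)
  write_network_json(study$truth_cr, file.path(path, "truth_cr.json"))
  write_network_json(study$truth_pr, file.path(path, "truth_pr.json"))
  invisible(structure(path, study = study))
}
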