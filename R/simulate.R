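#' Describe a planted protein complex for the simulator
#'
#' A complex is a named set of prey proteins recovered by one or more baits.
#' Complexes flagged `coupled_to_hub` model stoichiometric partners of the
#' modulated hub bait: their abundance scales with hub expression, so their
#' intensities are multiplied by the up/down modulation multipliers in the
#' modulated conditions.
#'
#' @param complex_id Label, unique within a simulation.
#' @param members Character vector of protein IDs (non-empty, disjoint from
#'   other complexes in the same configuration).
#' @param baits_detecting Character vector of bait labels whose pull-downs
#'   recover this complex (non-empty; must not include the mock label).
#' @param coupled_to_hub Logical; does member abundance follow the modulated
#'   hub bait?
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(complex_id, members, baits_detecting,
                          coupled_to_hub = FALSE) {
  if (!is.character(complex_id) || length(complex_id) != 1L || !nzchar(complex_id))
    stop_config("complex_id", "must be a single non-empty label")
  if (!is.character(members) || length(members) == 0L)
    stop_config("members", "must be a non-empty character vector")
  if (anyDuplicated(members))
    stop_config("members", "contains duplicated protein IDs")
  if (!is.character(baits_detecting) || length(baits_detecting) == 0L)
    stop_config("baits_detecting", "must be a non-empty character vector")
  structure(list(complex_id = complex_id,
                 members = members,
                 baits_detecting = baits_detecting,
                 coupled_to_hub = isTRUE(coupled_to_hub)),
            class = "complex_model")
}

#' Configure a synthetic bait-prey pull-down experiment
#'
#' Defines the factorial design (cell lines x genotype conditions x baits
#' incl. a mock x independent cultures x technical replicates), the planted
#' complexes, contaminant behaviour and noise model from which
#' [simulate_interactome()] draws an experiment.
#'
#' Intensities are log-normal: each protein gets a baseline log2 intensity
#' drawn around `baseline_log_intensity_mean`, and each measurement adds
#' N(0, `log_noise_sd`) log2 noise. Values below `dropout_threshold` are
#' recorded as not detected (`NA`). Hub-coupled complex members are
#' multiplied by `modulation_multiplier_up` in the modulated condition of
#' `line_up` (the overexpression line) and by `modulation_multiplier_down`
#' in the modulated condition of `line_down` (the knockdown line).
#' Contaminants appear in every run - mocks included - with probability
#' `contaminant_detection_prob`; unaffiliated background proteins appear
#' sporadically in non-mock runs with probability `background_detection_prob`.
#'
#' @param n_proteins Total number of simulated proteins (complex members +
#'   contaminants + unaffiliated background).
#' @param complexes List of [complex_model()] objects with disjoint members.
#' @param n_contaminants Number of contaminant proteins.
#' @param contaminant_detection_prob Per-run detection probability of each
#'   contaminant, in (0, 1].
#' @param baseline_log_intensity_mean Mean per-protein baseline, log2
#'   intensity units.
#' @param protein_baseline_sd Between-protein sd of the baseline, log2 units.
#' @param log_noise_sd Per-measurement log2 noise sd.
#' @param dropout_threshold Intensity below which a measurement is recorded
#'   as not detected; >= 0.
#' @param modulation_multiplier_up Fold change applied to coupled members in
#'   the modulated overexpression line; > 1.
#' @param modulation_multiplier_down Fold change applied to coupled members
#'   in the modulated knockdown line; in (0, 1).
#' @param cell_lines Character vector of cell-line labels (>= 1).
#' @param line_up,line_down Which cell line carries the up- / down-modulation
#'   of the hub; must be members of `cell_lines`.
#' @param baits Character vector of bait labels, including `mock_bait`.
#' @param mock_bait Label of the no-antibody mock pull-down.
#' @param n_cultures Independent cultures per condition; >= 1.
#' @param n_tech_reps Technical replicates per culture; >= 1.
#' @param background_detection_prob Per-run sporadic detection probability of
#'   unaffiliated proteins in non-mock runs, in [0, 1).
#' @param background_log_intensity_offset Log2 offset of contaminant /
#'   background baselines below `baseline_log_intensity_mean` (they are
#'   low-abundance relative to specific preys).
#' @param mock_carryover_prob Probability that a true complex member appears
#'   in a mock run (bead carry-over); default 0.
#' @param seed Integer seed driving all randomness of the simulation.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_proteins,
                              complexes,
                              n_contaminants = 0L,
                              contaminant_detection_prob = 0.5,
                              baseline_log_intensity_mean = 20,
                              protein_baseline_sd = 1,
                              log_noise_sd = 0.5,
                              dropout_threshold = 1000,
                              modulation_multiplier_up = 4,
                              modulation_multiplier_down = 0.25,
                              cell_lines = c("U87MG", "LN428"),
                              line_up = cell_lines[[1L]],
                              line_down = cell_lines[[length(cell_lines)]],
                              baits = c("BMI1", "RYBP", "H2AK119ub", "mock"),
                              mock_bait = "mock",
                              n_cultures = 2L,
                              n_tech_reps = 2L,
                              background_detection_prob = 0.05,
                              background_log_intensity_offset = 5,
                              mock_carryover_prob = 0,
                              seed = 1L) {
  if (!is.numeric(n_proteins) || n_proteins < 1)
    stop_config("n_proteins", "must be >= 1")
  if (!is.list(complexes) || !all(vapply(complexes, inherits, TRUE, "complex_model")))
    stop_config("complexes", "must be a list of complex_model objects")
  ids <- vapply(complexes, `[[`, "", "complex_id")
  if (anyDuplicated(ids))
    stop_config("complexes", "complex_ids must be unique")
  members <- unlist(lapply(complexes, `[[`, "members"))
  if (anyDuplicated(members))
    stop_config("complexes", "complex members must be disjoint")
  if (!is.numeric(n_contaminants) || n_contaminants < 0)
    stop_config("n_contaminants", "must be >= 0")
  if (length(members) + n_contaminants > n_proteins)
    stop_config("n_proteins",
                "smaller than complex members + contaminants")
  if (contaminant_detection_prob <= 0 || contaminant_detection_prob > 1)
    stop_config("contaminant_detection_prob", "must be in (0, 1]")
  if (background_detection_prob < 0 || background_detection_prob >= 1)
    stop_config("background_detection_prob", "must be in [0, 1)")
  if (mock_carryover_prob < 0 || mock_carryover_prob > 1)
    stop_config("mock_carryover_prob", "must be in [0, 1]")
  if (log_noise_sd < 0) stop_config("log_noise_sd", "must be >= 0")
  if (protein_baseline_sd < 0) stop_config("protein_baseline_sd", "must be >= 0")
  if (dropout_threshold < 0) stop_config("dropout_threshold", "must be >= 0")
  if (!(modulation_multiplier_up > 1))
    stop_config("modulation_multiplier_up", "must be > 1")
  if (!(modulation_multiplier_down > 0 && modulation_multiplier_down < 1))
    stop_config("modulation_multiplier_down", "must be in (0, 1)")
  if (length(cell_lines) < 1 || anyDuplicated(cell_lines))
    stop_config("cell_lines", "must be unique labels")
  if (!line_up %in% cell_lines) stop_config("line_up", "not a listed cell line")
  if (!line_down %in% cell_lines) stop_config("line_down", "not a listed cell line")
  if (!mock_bait %in% baits)
    stop_config("baits", sprintf("must include the mock label '%s'", mock_bait))
  bad_baits <- setdiff(unlist(lapply(complexes, `[[`, "baits_detecting")),
                       setdiff(baits, mock_bait))
  if (length(bad_baits))
    stop_config("complexes", sprintf("baits_detecting references unknown bait(s): %s",
                                     paste(unique(bad_baits), collapse = ", ")))
  if (!is.numeric(n_cultures) || n_cultures < 1)
    stop_config("n_cultures", "must be >= 1")
  if (!is.numeric(n_tech_reps) || n_tech_reps < 1)
    stop_config("n_tech_reps", "must be >= 1")
  if (!is.numeric(seed) || is.na(seed))
    stop_config("seed", "must be an integer")
  structure(list(n_proteins = as.integer(n_proteins),
                 complexes = complexes,
                 n_contaminants = as.integer(n_contaminants),
                 contaminant_detection_prob = contaminant_detection_prob,
                 baseline_log_intensity_mean = baseline_log_intensity_mean,
                 protein_baseline_sd = protein_baseline_sd,
                 log_noise_sd = log_noise_sd,
                 dropout_threshold = dropout_threshold,
                 modulation_multiplier_up = modulation_multiplier_up,
                 modulation_multiplier_down = modulation_multiplier_down,
                 cell_lines = cell_lines,
                 line_up = line_up,
                 line_down = line_down,
                 baits = baits,
                 mock_bait = mock_bait,
                 n_cultures = as.integer(n_cultures),
                 n_tech_reps = as.integer(n_tech_reps),
                 background_detection_prob = background_detection_prob,
                 background_log_intensity_offset = background_log_intensity_offset,
                 mock_carryover_prob = mock_carryover_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default synthetic experiment: a PRC1-like three-complex interactome
#'
#' The default study conditions of the package: 500 proteins comprising a
#' canonical-complex module of 105 hub-coupled members recovered by the hub
#' bait only, a shared core of 30 hub-coupled members recovered by both
#' proteome baits and the catalytic-mark pull-down, a non-canonical module of
#' 80 uncoupled members recovered by the second bait only, 50 bead
#' contaminants, and 285 unaffiliated background proteins. The design is
#' 2 cell lines x {control, modulated} x 4 pull-downs (two protein baits, one
#' histone-mark ChIP, one mock) x 2 cultures x 2 technical replicates.
#'
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
default_simulation_config <- function(seed = 1L) {
  canonical <- complex_model(
    "canonical_module",
    sprintf("CAN_%03d", seq_len(105L)),
    baits_detecting = "BMI1",
    coupled_to_hub = TRUE)
  core <- complex_model(
    "shared_core",
    sprintf("CORE_%03d", seq_len(30L)),
    baits_detecting = c("BMI1", "RYBP", "H2AK119ub"),
    coupled_to_hub = TRUE)
  noncanonical <- complex_model(
    "noncanonical_module",
    sprintf("NCAN_%03d", seq_len(80L)),
    baits_detecting = "RYBP",
    coupled_to_hub = FALSE)
  simulation_config(
    n_proteins = 500L,
    complexes = list(canonical, core, noncanonical),
    n_contaminants = 50L,
    seed = seed)
}

#' Simulate a bait-prey pull-down experiment with known ground truth
#'
#' Draws one complete MS experiment under `config`: one sample column per
#' (cell line x condition x bait x culture x technical replicate), mock
#' pull-downs included. Complex members receive high log-normal intensities
#' in the runs of their detecting baits; contaminants appear in all runs
#' (mocks included) with the configured probability; hub-coupled members are
#' scaled by the modulation multipliers in modulated conditions; values below
#' the dropout threshold are recorded as not detected. The same seed always
#' reproduces the same experiment.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `matrix` (an [intensity_matrix()]) and
#'   `truth` (data frame: `protein_id`, `true_complex` (`NA` = none),
#'   `is_contaminant`, `is_modulation_coupled`).
#' @export
simulate_interactome <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must be a simulation_config", call. = FALSE)

  samples <- expand.grid(tech_rep = seq_len(config$n_tech_reps),
                         culture = seq_len(config$n_cultures),
                         bait = config$baits,
                         condition = c("control", "modulated"),
                         cell_line = config$cell_lines,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("cell_line", "condition", "bait", "culture", "tech_rep")]
  samples$is_mock <- as.integer(samples$bait == config$mock_bait)
  samples$sample_id <- sprintf("%s.%s.%s.c%d.r%d", samples$cell_line,
                               samples$condition, samples$bait,
                               samples$culture, samples$tech_rep)
  samples <- samples[, c("sample_id", "cell_line", "bait", "condition",
                         "culture", "tech_rep", "is_mock")]

  members <- unlist(lapply(config$complexes, `[[`, "members"))
  complex_of <- rep(vapply(config$complexes, `[[`, "", "complex_id"),
                    vapply(config$complexes, function(cc) length(cc$members), 0L))
  coupled_of <- rep(vapply(config$complexes, `[[`, TRUE, "coupled_to_hub"),
                    vapply(config$complexes, function(cc) length(cc$members), 0L))
  n_bg <- config$n_proteins - length(members) - config$n_contaminants
  contaminant_ids <- if (config$n_contaminants > 0)
    sprintf("CONT_%03d", seq_len(config$n_contaminants)) else character(0)
  background_ids <- if (n_bg > 0) sprintf("BG_%03d", seq_len(n_bg)) else character(0)
  protein_ids <- c(members, contaminant_ids, background_ids)

  truth <- data.frame(
    protein_id = protein_ids,
    true_complex = c(complex_of, rep(NA_character_, config$n_contaminants + n_bg)),
    is_contaminant = c(rep(FALSE, length(members)),
                       rep(TRUE, config$n_contaminants),
                       rep(FALSE, n_bg)),
    is_modulation_coupled = c(coupled_of,
                              rep(FALSE, config$n_contaminants + n_bg)),
    stringsAsFactors = FALSE)

  n <- length(protein_ids)
  m <- nrow(samples)
  kind <- c(rep("member", length(members)),
            rep("contaminant", config$n_contaminants),
            rep("background", n_bg))

  # design: which (protein, sample) pairs carry true signal
  bait_by_protein <- c(lapply(config$complexes,
                              function(cc) rep(list(cc$baits_detecting),
                                               length(cc$members))),
                       recursive = FALSE)
  bait_by_protein <- unlist(bait_by_protein, recursive = FALSE)
  signal <- matrix(FALSE, n, m)
  if (length(members)) {
    for (i in seq_along(members)) {
      signal[i, ] <- samples$bait %in% bait_by_protein[[i]] & samples$is_mock == 0L
    }
  }

  vals <- local_seed(config$seed, {
    baseline <- stats::rnorm(
      n,
      mean = ifelse(kind == "member", config$baseline_log_intensity_mean,
                    config$baseline_log_intensity_mean -
                      config$background_log_intensity_offset),
      sd = config$protein_baseline_sd)
    noise <- matrix(stats::rnorm(n * m, 0, config$log_noise_sd), n, m)
    u <- matrix(stats::runif(n * m), n, m)

    detected <- signal
    detected[kind == "contaminant", ] <-
      u[kind == "contaminant", , drop = FALSE] < config$contaminant_detection_prob
    is_mock_col <- samples$is_mock == 1L
    bg_rows <- kind == "background"
    detected[bg_rows, ] <- u[bg_rows, , drop = FALSE] < config$background_detection_prob
    detected[bg_rows, is_mock_col] <- FALSE
    if (config$mock_carryover_prob > 0 && length(members)) {
      carry <- u[kind == "member", is_mock_col, drop = FALSE] <
        config$mock_carryover_prob
      detected[kind == "member", is_mock_col] <- carry
    }

    # modulation of hub-coupled members in modulated conditions, per line
    shift <- matrix(0, n, m)
    coupled_rows <- truth$is_modulation_coupled
    mod_up <- samples$condition == "modulated" & samples$cell_line == config$line_up
    mod_down <- samples$condition == "modulated" & samples$cell_line == config$line_down
    shift[coupled_rows, mod_up] <- log2(config$modulation_multiplier_up)
    shift[coupled_rows, mod_down] <- log2(config$modulation_multiplier_down)

    out <- 2^(baseline + shift + noise)
    out[!detected] <- NA_real_
    out[!is.na(out) & out < config$dropout_threshold] <- NA_real_
    out
  })

  rownames(vals) <- protein_ids
  colnames(vals) <- samples$sample_id
  list(matrix = intensity_matrix(vals, samples), truth = truth)
}

#' Build an idealized contaminant-repository table from simulation truth
#'
#' Converts the ground-truth contaminant flags of a simulated experiment into
#' a contaminant-repository frequency table (the frequency with which each
#' protein appears across negative-control AP-MS runs), for use with
#' [filter_contaminants()]. Synthetic stand-in for a community contaminant
#' repository export.
#'
#' @param truth Ground-truth data frame from [simulate_interactome()].
#' @param frequency Control-run detection frequency recorded for true
#'   contaminants.
#' @param n_control_runs Nominal number of control runs behind the table.
#' @return A [contaminant_repository()].
#' @export
repository_from_truth <- function(truth, frequency = 0.6, n_control_runs = 411L) {
  ids <- truth$protein_id[truth$is_contaminant]
  contaminant_repository(data.frame(protein_id = ids,
                                    frequency = rep(frequency, length(ids)),
                                    n_runs = rep(as.integer(n_control_runs),
                                                 length(ids)),
                                    stringsAsFactors = FALSE))
}
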