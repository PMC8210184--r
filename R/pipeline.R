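#' Assemble and validate a pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis (simulate or
#' load -> filter -> quantify -> deconvolve -> enrich) in one auditable
#' object. All parameters are echoed into the run log so every analytical
#' choice is explicit.
#'
#' @param simulation A [simulation_config()] to generate the experiment, or
#'   `NULL` to read it from `intensity_path` / `meta_path`.
#' @param intensity_path,meta_path,truth_path Input TSV paths when not
#'   simulating (`truth_path` optional).
#' @param repository A [contaminant_repository()], a path to one, or `NULL`
#'   to derive an idealized one from simulated truth
#'   ([repository_from_truth()]).
#' @param hub_bait Bait whose interactome is deconvolved and quantified
#'   (default `"BMI1"`).
#' @param partner_bait Discriminating second bait (default `"RYBP"`).
#' @param mark_bait Optional histone-mark pull-down for the chromatome
#'   partition (`NULL` to skip).
#' @param min_runs Detection rule: minimum replicate runs with signal.
#' @param max_freq Contaminant-repository frequency cutoff.
#' @param normalize,pseudo,fc_min,alpha Modulation-stage parameters, see
#'   [quantify_modulation()].
#' @param collections Optional [gene_set_collection()] for enrichment of the
#'   concordant set.
#' @param truth_map Named character `complex_id -> category` used to score
#'   recovery when ground truth is available.
#' @param seed Integer seed (overrides the simulation config's seed so one
#'   value drives the whole run).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = default_simulation_config(),
                            intensity_path = NULL, meta_path = NULL,
                            truth_path = NULL, repository = NULL,
                            hub_bait = "BMI1", partner_bait = "RYBP",
                            mark_bait = "H2AK119ub",
                            min_runs = 2L, max_freq = 0.10,
                            normalize = "none", pseudo = 1,
                            fc_min = 0, alpha = NULL,
                            collections = NULL,
                            truth_map = c(canonical_module = "canonical_only",
                                          shared_core = "shared_core",
                                          noncanonical_module = "noncanonical_only"),
                            seed = NULL) {
  if (is.null(simulation) &&
      (is.null(intensity_path) || is.null(meta_path)))
    stop_config("intensity_path",
                "required (with meta_path) when no simulation is configured")
  if (!is.null(simulation) && !inherits(simulation, "simulation_config"))
    stop_config("simulation", "must be a simulation_config or NULL")
  if (!is.null(seed) && !is.null(simulation)) {
    simulation$seed <- as.integer(seed)
  }
  if (is.character(repository))
    repository <- read_contaminant_repository(repository)
  structure(list(simulation = simulation,
                 intensity_path = intensity_path, meta_path = meta_path,
                 truth_path = truth_path, repository = repository,
                 hub_bait = hub_bait, partner_bait = partner_bait,
                 mark_bait = mark_bait,
                 min_runs = as.integer(min_runs), max_freq = max_freq,
                 normalize = normalize, pseudo = pseudo,
                 fc_min = fc_min, alpha = alpha,
                 collections = collections, truth_map = truth_map,
                 seed = if (is.null(seed)) simulation$seed else as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads scalar stage parameters (`hub_bait`, `partner_bait`, `mark_bait`,
#' `min_runs`, `max_freq`, `normalize`, `pseudo`, `fc_min`, `alpha`, `seed`,
#' input paths, `repository` path) from YAML and builds a
#' [pipeline_config()]. A `simulate: true` entry uses the default synthetic
#' experiment.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (isTRUE(y$simulate) || is.null(y$intensity_path))
    default_simulation_config(seed = y$seed %||% 1L) else NULL
  pipeline_config(
    simulation = sim,
    intensity_path = y$intensity_path, meta_path = y$meta_path,
    truth_path = y$truth_path, repository = y$repository,
    hub_bait = y$hub_bait %||% "BMI1",
    partner_bait = y$partner_bait %||% "RYBP",
    mark_bait = y$mark_bait %||% "H2AK119ub",
    min_runs = y$min_runs %||% 2L, max_freq = y$max_freq %||% 0.10,
    normalize = y$normalize %||% "none", pseudo = y$pseudo %||% 1,
    fc_min = y$fc_min %||% 0, alpha = y$alpha,
    seed = y$seed)
}

#' Run the full interactome-deconvolution pipeline
#'
#' Executes simulate (or load) -> per-(bait, line) filtering (detection
#' rule, mock subtraction, contaminant-frequency filter) -> cross-line
#' intersection per bait -> two-bait membership deconvolution -> modulation
#' quantification and concordance classification of the hub interactome ->
#' optional chromatome partition and enrichment -> recovery scoring against
#' ground truth when available. Every intermediate table is written to
#' `out_dir` along with a JSON summary and a parameter log; the same config
#' and seed always reproduce the same bundle.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for the report bundle (`NULL` = don't
#'   write, return results only).
#' @return Invisibly, a list with elements `matrix`, `truth`, `sets`
#'   (per-bait, per-line [interactor_set()]s), `line_venns`, `shared`,
#'   `baits_venn`, `membership`, `modulation`, `chromatome`, `recovery`,
#'   `enrichment` and `summary` (the JSON-ready summary list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("apmsdecon pipeline"),
                 sprintf("parameters: hub_bait=%s partner_bait=%s mark_bait=%s",
                         config$hub_bait, config$partner_bait,
                         config$mark_bait %||% "<none>"),
                 sprintf("parameters: min_runs=%d max_freq=%g normalize=%s pseudo=%g fc_min=%g alpha=%s seed=%s",
                         config$min_runs, config$max_freq, config$normalize,
                         config$pseudo, config$fc_min,
                         if (is.null(config$alpha)) "off" else config$alpha,
                         config$seed %||% "NA"))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }

  # --- input stage -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_interactome(config$simulation))
    mat <- sim$matrix
    truth <- sim$truth
  } else {
    mat <- stage("read", read_intensity_table(config$intensity_path,
                                              config$meta_path))
    if (!is.null(config$truth_path))
      truth <- stage("read", read_ground_truth(config$truth_path))
  }
  repo <- config$repository
  if (is.null(repo) && !is.null(truth)) repo <- repository_from_truth(truth)
  log_lines <- c(log_lines,
                 sprintf("input: %d proteins x %d samples", nrow(mat$values),
                         ncol(mat$values)))

  lines <- unique(mat$samples$cell_line)
  mock_bait <- unique(mat$samples$bait[mat$samples$is_mock == 1L])
  if (length(mock_bait) != 1L)
    stop("pipeline stage 'filter' failed: expected exactly one mock bait",
         call. = FALSE)
  baits <- c(config$hub_bait, config$partner_bait, config$mark_bait)
  baits <- baits[!vapply(baits, is.null, TRUE)]
  baits <- unlist(baits)

  # --- filter stage ----------------------------------------------------
  sets <- list()
  for (b in baits) for (ln in lines) {
    s <- stage("filter",
               filtered_interactors(mat, b, ln, condition = "control",
                                    min_runs = config$min_runs, repo = repo,
                                    mock_bait = mock_bait,
                                    max_freq = config$max_freq))
    sets[[paste(b, ln, sep = ".")]] <- s
    log_lines <- c(log_lines,
                   sprintf("filter: %s / %s -> %d proteins (%s)", b, ln,
                           length(s$proteins),
                           paste(sprintf("%s removed %d", s$provenance$filter,
                                         s$provenance$removed),
                                 collapse = "; ")))
  }

  # --- deconvolution stage --------------------------------------------
  line_venns <- list()
  shared <- list()
  for (b in baits) {
    per_line <- sets[paste(b, lines, sep = ".")]
    v <- stage("deconvolve", intersect_lines(per_line[[1L]], per_line[[2L]]))
    line_venns[[b]] <- v
    shared[[b]] <- region_members(v, lines)
    log_lines <- c(log_lines,
                   sprintf("deconvolve: %s shared across lines = %d", b,
                           length(shared[[b]])))
  }
  baits_venn <- stage("deconvolve",
                      compare_baits(shared[[config$hub_bait]],
                                    shared[[config$partner_bait]],
                                    labels = c(config$hub_bait,
                                               config$partner_bait)))
  universe <- unique(unlist(lapply(sets, `[[`, "proteins"), use.names = FALSE))
  membership <- assign_membership(baits_venn, universe = universe)

  chromatome <- NULL
  if (!is.null(config$mark_bait) && config$mark_bait %in% names(shared)) {
    chromatome <- stage("deconvolve",
                        chromatome_partition(shared[[config$hub_bait]],
                                             shared[[config$partner_bait]],
                                             shared[[config$mark_bait]],
                                             labels = c(config$hub_bait,
                                                        config$partner_bait,
                                                        config$mark_bait)))
  }

  # --- modulation stage ------------------------------------------------
  hub_interactome <- shared[[config$hub_bait]]
  sim_cfg <- config$simulation
  line_up <- if (!is.null(sim_cfg)) sim_cfg$line_up else lines[[1L]]
  line_down <- if (!is.null(sim_cfg)) sim_cfg$line_down else lines[[length(lines)]]
  modulation <- stage("quantify",
                      quantify_modulation(mat, config$hub_bait,
                                          proteins = hub_interactome,
                                          line_up = line_up,
                                          line_down = line_down,
                                          normalize = config$normalize,
                                          pseudo = config$pseudo,
                                          fc_min = config$fc_min,
                                          alpha = config$alpha))
  n_concordant <- sum(modulation$concordance == "concordant")
  log_lines <- c(log_lines,
                 sprintf("quantify: %d of %d hub interactors concordant",
                         n_concordant, nrow(modulation)))

  # --- scoring / enrichment -------------------------------------------
  recovery <- NULL
  if (!is.null(truth))
    recovery <- stage("score",
                      recovery_metrics(membership, truth, config$truth_map))
  enrichment <- NULL
  if (!is.null(config$collections))
    enrichment <- stage("enrich",
                        ora_collections(
                          modulation$protein_id[modulation$concordance ==
                                                  "concordant"],
                          config$collections, universe))

  summary <- list(
    parameters = list(hub_bait = config$hub_bait,
                      partner_bait = config$partner_bait,
                      mark_bait = config$mark_bait,
                      min_runs = config$min_runs, max_freq = config$max_freq,
                      normalize = config$normalize, pseudo = config$pseudo,
                      fc_min = config$fc_min,
                      alpha = config$alpha %||% "off",
                      seed = config$seed),
    n_proteins = nrow(mat$values),
    n_samples = ncol(mat$values),
    interactor_set_sizes = lapply(sets, function(s) length(s$proteins)),
    line_venn_counts = lapply(line_venns, function(v) as.list(v$counts)),
    bait_venn_counts = as.list(baits_venn$counts),
    chromatome_venn_counts = if (!is.null(chromatome))
      as.list(chromatome$venn$counts) else NULL,
    membership_counts = as.list(table(membership$category)),
    n_hub_interactome = length(hub_interactome),
    n_concordant = n_concordant,
    n_not_concordant = nrow(modulation) - n_concordant,
    enrichment_p = if (!is.null(enrichment))
      stats::setNames(as.list(enrichment$p_value), enrichment$set) else NULL)

  res <- list(matrix = mat, truth = truth, sets = sets,
              line_venns = line_venns, shared = shared,
              baits_venn = baits_venn, membership = membership,
              modulation = modulation, chromatome = chromatome,
              recovery = recovery, enrichment = enrichment,
              summary = summary)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_fixture(mat, out_dir, truth = truth)
    if (!is.null(repo))
      write_contaminant_repository(repo, file.path(out_dir, "contaminant_repository.tsv"))
    set_dir <- file.path(out_dir, "interactor_sets")
    if (!dir.exists(set_dir)) dir.create(set_dir)
    for (nm in names(sets))
      write_interactor_set(sets[[nm]], file.path(set_dir, paste0(nm, ".tsv")))
    for (b in names(shared))
      write_tsv_strict(data.frame(protein_id = shared[[b]],
                                  stringsAsFactors = FALSE),
                       file.path(out_dir, paste0("shared_", b, ".tsv")))
    write_venn_report(baits_venn, file.path(out_dir, "bait_venn.json"))
    if (!is.null(chromatome))
      write_venn_report(chromatome$venn, file.path(out_dir, "chromatome_venn.json"))
    write_tsv_strict(membership, file.path(out_dir, "membership.tsv"))
    write_tsv_strict(modulation, file.path(out_dir, "modulation.tsv"))
    if (!is.null(recovery))
      write_tsv_strict(recovery, file.path(out_dir, "recovery.tsv"))
    if (!is.null(enrichment))
      write_tsv_strict(enrichment, file.path(out_dir, "enrichment.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  invisible(res)
}
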