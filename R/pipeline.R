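# End-to-end orchestration: simulate (or load) genotype libraries, run
# align -> dedup -> extract -> validate -> normalize -> differential
# methylation, and write TSV artifacts plus a JSON run manifest.

#' Pipeline configuration
#'
#' Assembles and validates the parameters of a full run. All randomness
#' derives from the single `seed` through fixed per-stage substreams, so the
#' same configuration reproduces every artifact byte for byte.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer master seed.
#' @param genome_fasta Optional path to a single-record FASTA; when `NULL` a
#'   synthetic reference (see [synthetic_reference_genome()]) is generated.
#' @param genome_length,n_cpg Size of the synthetic reference.
#' @param groups Named integer vector: group label -> number of replicate
#'   samples.
#' @param group_effects Passed to [methylome_spec()].
#' @param contrasts List of `c(A, B)` group pairs to test.
#' @param read_sim A [read_sim_config()].
#' @param controls A [control_spec()].
#' @param methylome A [methylome_spec()] (its `group_effects` are overridden
#'   by `group_effects` when given).
#' @param min_reads Minimum coverage for site validation.
#' @param min_potential Minimum full potential (percentage points).
#' @param alpha Significance level for contrasts.
#' @param min_difference Joint-rule difference threshold (points).
#' @param difference_rule Apply the difference rule to the contrasts.
#' @param normalization_mode `"subtract"` or `"ratio"`.
#' @param max_mismatches Aligner mismatch cap per mate.
#' @param annotation Optional annotation tibble (see [annotate_sites()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, genome_fasta = NULL,
                            genome_length = 16569L, n_cpg = 435L,
                            groups = c(A = 3L, B = 3L),
                            group_effects = list(),
                            contrasts = list(names(groups)[1:2]),
                            read_sim = read_sim_config(),
                            controls = control_spec(),
                            methylome = methylome_spec(),
                            min_reads = 10L, min_potential = 10,
                            alpha = 0.05, min_difference = 5,
                            difference_rule = TRUE,
                            normalization_mode = "subtract",
                            max_mismatches = 10L, annotation = NULL) {
  stopifnot(length(groups) >= 1L, all(groups >= 1L),
            !is.null(names(groups)),
            alpha > 0, alpha < 1, min_reads >= 1L,
            normalization_mode %in% c("subtract", "ratio"))
  if (!is.null(genome_fasta) && !file.exists(genome_fasta)) {
    rlang::abort(sprintf("genome FASTA not found: %s", genome_fasta))
  }
  methylome$group_effects <- utils::modifyList(methylome$group_effects,
                                               group_effects)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         genome_fasta = genome_fasta, genome_length = genome_length,
         n_cpg = n_cpg, groups = groups, contrasts = contrasts,
         read_sim = read_sim, controls = controls, methylome = methylome,
         min_reads = min_reads, min_potential = min_potential,
         alpha = alpha, min_difference = min_difference,
         difference_rule = difference_rule,
         normalization_mode = normalization_mode,
         max_mismatches = max_mismatches, annotation = annotation),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys map directly onto [pipeline_config()] arguments; nested
#' `read_sim`, `controls` and `methylome` maps are passed to the respective
#' constructors.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$read_sim)) y$read_sim <- do.call(read_sim_config, y$read_sim)
  if (!is.null(y$controls)) {
    if (!is.null(y$controls$amplicons)) {
      y$controls$amplicons <- lapply(y$controls$amplicons, as.integer)
    }
    y$controls <- do.call(control_spec, y$controls)
  }
  if (!is.null(y$methylome)) y$methylome <- do.call(methylome_spec, y$methylome)
  if (!is.null(y$groups)) y$groups <- unlist(y$groups)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

# deterministic per-stage substream seeds derived from the master seed
stage_seed <- function(seed, stage) {
  (seed * 1000L + stage) %% .Machine$integer.max
}

# sample -> cytosine call table through align/dedup/extract
calls_from_sim <- function(sim, genome, max_mismatches) {
  aln <- align_bisulfite(sim$reads, genome, max_mismatches = max_mismatches)
  extract_methylation(deduplicate(aln), sim$reads, genome)
}

#' Run the full pipeline
#'
#' Simulates (or loads) the genotype genome, generates the long-PCR control
#' libraries and one bisulfite library per replicate sample, runs
#' align/dedup/extract per library, validates sites against the controls,
#' computes the full-potential table, normalises every sample, and tests the
#' configured contrasts. Artifacts (`cpg_sites.tsv`, `full_potential.tsv`,
#' `profiles.tsv`, `differential.tsv`) and a JSON run manifest land in
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the genome, call tables,
#'   potentials, profiles, differential results and the manifest, invisibly
#'   returned components all re-readable from the TSVs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- if (!is.null(config$genome_fasta)) {
    read_genome_fasta(config$genome_fasta)
  } else {
    synthetic_reference_genome(length = config$genome_length,
                               n_cpg = config$n_cpg,
                               seed = stage_seed(config$seed, 1L))
  }
  sites <- cpg_sites(genome)
  write_cpg_sites(sites, file.path(config$out_dir, "cpg_sites.tsv"),
                  genome_name = genome$name)

  ctrl <- simulate_controls(genome, config$controls, config$read_sim,
                            seed = stage_seed(config$seed, 2L))
  neg_calls <- calls_from_sim(ctrl$negative, genome, config$max_mismatches)
  pos_calls <- calls_from_sim(ctrl$positive, genome, config$max_mismatches)
  valid <- validate_sites(list(neg_calls, pos_calls),
                          min_reads = config$min_reads)
  potentials <- compute_full_potential(neg_calls, pos_calls, valid,
                                       min_potential = config$min_potential)
  write_site_table(potentials, file.path(config$out_dir, "full_potential.tsv"))

  profiles <- list()
  stage <- 10L
  for (grp in names(config$groups)) {
    # one methylome per group: replicates share it and differ only through
    # library sampling, mirroring biological replicates of the same tumor type
    meth <- draw_methylome(genome, config$methylome,
                           seed = stage_seed(config$seed, 3L), group = grp)
    for (rep_i in seq_len(config$groups[[grp]])) {
      stage <- stage + 1L
      sim <- simulate_bisulfite_reads(genome, meth, config$read_sim,
                                      seed = stage_seed(config$seed,
                                                        stage + 500L))
      calls <- calls_from_sim(sim, genome, config$max_mismatches)
      calls <- coverage_filter(calls, config$min_reads)
      sample_id <- sprintf("%s_%d", grp, rep_i)
      profiles[[sample_id]] <- normalize_profile(
        calls, potentials, sample_id = sample_id,
        mode = config$normalization_mode
      )
    }
  }
  long <- bind_profiles(profiles)
  write_site_table(long, file.path(config$out_dir, "profiles.tsv"))

  design <- tibble::tibble(
    sample = unlist(lapply(names(config$groups), function(g) {
      sprintf("%s_%d", g, seq_len(config$groups[[g]]))
    })),
    group = rep(names(config$groups), unlist(config$groups))
  )
  differential <- pairwise_contrasts(
    long, design, config$contrasts,
    alpha = config$alpha, min_difference = config$min_difference,
    difference_rule = config$difference_rule,
    annotation = config$annotation
  )
  write_site_table(differential,
                   file.path(config$out_dir, "differential.tsv"))

  manifest <- list(
    package = "mitomethr",
    version = as.character(utils::packageVersion("mitomethr")),
    seed = config$seed,
    genome = list(name = genome$name, length = length(genome),
                  source = if (is.null(config$genome_fasta)) "synthetic"
                           else config$genome_fasta),
    parameters = list(
      min_reads = config$min_reads, min_potential = config$min_potential,
      alpha = config$alpha, min_difference = config$min_difference,
      normalization_mode = config$normalization_mode,
      max_mismatches = config$max_mismatches,
      mean_coverage = config$read_sim$mean_coverage,
      read_length = config$read_sim$read_length
    ),
    groups = as.list(config$groups),
    rows = list(
      cpg_sites = nrow(sites),
      validated_sites = nrow(valid),
      full_potential = nrow(potentials),
      profiles = nrow(long),
      differential = nrow(differential)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(structure(
    list(genome = genome, cpg_sites = sites, potentials = potentials,
         profiles = long, design = design, differential = differential,
         manifest = manifest),
    class = "pipeline_result"
  ))
}
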