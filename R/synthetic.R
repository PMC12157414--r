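# Synthetic ASE cohorts with the BLN generative structure and
# genotype-mismatch contamination, mixed at the allelic-count level.

#' Simulation configuration
#'
#' Generative settings for synthetic allele-specific expression cohorts.
#' Per gene, a total count is drawn from the depth law, the latent reference
#' ratio from `plogis(Normal(mu, sigma))`, and reads are binomial. With
#' contamination fraction `c > 0`, a fraction `c` of each gene's reads comes
#' from a second individual whose genotype at the host's heterozygous site is
#' hom-ref, het, or hom-alt with the given probabilities (default
#' Hardy-Weinberg at allele frequency 0.5), contributing expected reference
#' ratio 1, a fresh logit-normal draw, or 0 respectively.
#'
#' @param n_genes Genes per sample.
#' @param mu Mean logit reference ratio; the default 0.1 mimics mild
#'   reference bias.
#' @param sigma Logit-scale SD of the latent ratio (the quantity the fit
#'   recovers).
#' @param depth_law Either `list("uniform", lo, hi)` (integer depths uniform
#'   on `{lo, ..., hi}`) or `list("lognormal", meanlog, sdlog)` (rounded and
#'   clipped to `[5, 5000]`).
#' @param contamination Contamination fraction `c` in `[0, 1]`.
#' @param genotype_probs Length-3 probabilities for the contaminator genotype
#'   `(hom-ref, het, hom-alt)` at the host's het sites; must sum to 1.
#' @param n_samples Samples per cohort for [simulate_ase_cohort()].
#' @param seed Master seed. Per-sample streams are derived from it with a
#'   stable counter, so adding samples never perturbs existing ones.
#' @return A list of class `aseqc_sim_config`.
#' @export
sim_config <- function(n_genes = 5000L,
                       mu = 0.1,
                       sigma = 0.3,
                       depth_law = list("uniform", 20L, 200L),
                       contamination = 0,
                       genotype_probs = c(hom_ref = 0.25, het = 0.5,
                                          hom_alt = 0.25),
                       n_samples = 1L,
                       seed = 1L) {
  check_count_scalar(n_genes, "n_genes", min = 1L)
  check_count_scalar(n_samples, "n_samples", min = 1L)
  check_count_scalar(seed, "seed")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.",
          class = "aseqc_config_error")
  }
  if (!is.numeric(contamination) || length(contamination) != 1 ||
      contamination < 0 || contamination > 1) {
    abort("`contamination` must be in [0, 1].", class = "aseqc_config_error")
  }
  if (!is.numeric(genotype_probs) || length(genotype_probs) != 3 ||
      any(genotype_probs < 0) || abs(sum(genotype_probs) - 1) > 1e-8) {
    abort("`genotype_probs` must be 3 non-negative numbers summing to 1.",
          class = "aseqc_config_error")
  }
  law <- as.character(depth_law[[1]])
  if (!law %in% c("uniform", "lognormal") || length(depth_law) != 3) {
    abort("`depth_law` must be list(\"uniform\", lo, hi) or list(\"lognormal\", meanlog, sdlog).",
          class = "aseqc_config_error")
  }
  if (law == "uniform" &&
      (depth_law[[2]] < 1 || depth_law[[2]] > depth_law[[3]])) {
    abort("uniform depth law needs 1 <= lo <= hi.",
          class = "aseqc_config_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      mu = as.numeric(mu),
      sigma = as.numeric(sigma),
      depth_law = list(law, as.numeric(depth_law[[2]]),
                       as.numeric(depth_law[[3]])),
      contamination = as.numeric(contamination),
      genotype_probs = setNames(as.numeric(genotype_probs),
                                c("hom_ref", "het", "hom_alt")),
      n_samples = as.integer(n_samples),
      seed = as.integer(seed)
    ),
    class = "aseqc_sim_config"
  )
}

draw_depths <- function(config) {
  law <- config$depth_law
  if (law[[1]] == "uniform") {
    sample(seq.int(law[[2]], law[[3]]), config$n_genes, replace = TRUE)
  } else {
    pmin(pmax(round(stats::rlnorm(config$n_genes, law[[2]], law[[3]])), 5),
         5000)
  }
}

# seed stream: stable counter so sample i always gets the same sub-seed
sample_stream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
}

#' Simulate one sample of gene-level allelic counts
#'
#' Draws `n_genes` records from the contaminated BLN generative model (see
#' [sim_config()]): `t ~ depth_law`, `logit(lambda) ~ N(mu, sigma)`,
#' effective ratio `p = (1 - c) * lambda + c * lambda_cont`, and
#' `r ~ Binomial(t, p)`. Deterministic given the seed; the caller's RNG
#' state is untouched.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample identifier for the emitted records.
#' @param seed Seed for this sample; defaults to the config's master seed.
#' @return A tibble of gene-level records (`sample_id, gene_id, ref_count,
#'   alt_count, total_count`) plus the latent `lambda_true` column.
#' @export
simulate_ase_sample <- function(config = sim_config(), sample_id = "S1",
                                seed = config$seed) {
  stopifnot(inherits(config, "aseqc_sim_config"))
  with_local_seed(seed, {
    n <- config$n_genes
    t <- draw_depths(config)
    lam <- plogis(rnorm(n, config$mu, config$sigma))
    # The contaminator's variables and the binomial inversion uniforms are
    # drawn unconditionally, so two runs from the same seed that differ only
    # in the contamination fraction share every latent draw: the counts of a
    # replicate vary smoothly and monotonically in c, exactly as when one
    # source sample is re-mixed at graded fractions.
    geno <- sample(c("hom_ref", "het", "hom_alt"), n, replace = TRUE,
                   prob = config$genotype_probs)
    lam_het <- plogis(rnorm(n, config$mu, config$sigma))
    u <- runif(n)
    lam_cont <- ifelse(geno == "hom_ref", 1,
                       ifelse(geno == "hom_alt", 0, lam_het))
    c_frac <- config$contamination
    p <- (1 - c_frac) * lam + c_frac * lam_cont
    r <- stats::qbinom(u, t, p)
    tibble::tibble(
      sample_id = sample_id,
      gene_id = sprintf("G%05d", seq_len(n)),
      ref_count = as.integer(r),
      alt_count = as.integer(t - r),
      total_count = as.integer(t),
      lambda_true = lam
    )
  })
}

#' Simulate a cohort of samples
#'
#' `n_samples` independent samples from one configuration; sample `i` uses
#' the derived seed stream `i`, so regenerating with a larger `n_samples`
#' reproduces the earlier samples byte for byte.
#'
#' @param config A [sim_config()].
#' @param sample_ids Optional character vector of ids (default
#'   `S001, S002, ...`).
#' @return A tibble of gene-level records for all samples.
#' @export
simulate_ase_cohort <- function(config = sim_config(), sample_ids = NULL) {
  stopifnot(inherits(config, "aseqc_sim_config"))
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  }
  purrr::imap(sample_ids, function(id, i) {
    simulate_ase_sample(config, sample_id = id,
                        seed = sample_stream_seed(config$seed, i))
  }) |>
    dplyr::bind_rows()
}

#' The 21 predefined contamination levels
#'
#' Quadratically spaced fractions `(k/20)^2` for `k = 0..20`: 0, 0.0025,
#' 0.01, 0.0225, ..., 1. Percentages 0%, 0.25%, 1%, 2.25%, ..., 100%.
#'
#' @return A strictly increasing numeric vector of length 21.
#' @examples
#' contamination_levels()[1:4]  # 0.0000 0.0025 0.0100 0.0225
#' @export
contamination_levels <- function() {
  (0:20 / 20)^2
}

#' Simulate a contamination benchmark cohort
#'
#' Emits `n_per_level` samples at each contamination level, with a truth
#' table recording each sample's level — the count-level analogue of
#' spiking a cohort with reads from a second individual at graded fractions.
#' The design is paired: replicate `i` uses the same derived seed stream at
#' every level, so across levels the replicate represents one source sample
#' re-mixed at increasing fractions (as when one library is resampled at
#' graded contamination), and level effects are not confounded with
#' between-sample noise. Sample ids encode the level index and replicate
#' (`L<index>_R<replicate>`). Deterministic given the master seed.
#'
#' @param config A [sim_config()]; its `contamination` field is overridden
#'   per level.
#' @param levels Contamination fractions (default the full 21-level series).
#' @param n_per_level Replicate samples per level.
#' @return A list with elements `counts` (gene-level records for all
#'   samples) and `truth` (tibble `sample_id, level`).
#' @examples
#' bench <- simulate_benchmark_cohort(
#'   sim_config(n_genes = 200, seed = 3),
#'   levels = c(0, 0.25), n_per_level = 2
#' )
#' bench$truth
#' @export
simulate_benchmark_cohort <- function(config = sim_config(),
                                      levels = contamination_levels(),
                                      n_per_level = 1L) {
  stopifnot(inherits(config, "aseqc_sim_config"))
  check_count_scalar(n_per_level, "n_per_level", min = 1L)
  if (any(levels < 0 | levels > 1)) {
    abort("Contamination levels must lie in [0, 1].",
          class = "aseqc_config_error")
  }
  grid <- tidyr::expand_grid(level_index = seq_along(levels),
                             replicate = seq_len(n_per_level))
  counts <- purrr::pmap(grid, function(level_index, replicate) {
    cfg <- config
    cfg$contamination <- levels[level_index]
    simulate_ase_sample(
      cfg,
      sample_id = sprintf("L%02d_R%02d", level_index, replicate),
      seed = sample_stream_seed(config$seed, replicate)
    )
  }) |>
    dplyr::bind_rows()
  truth <- tibble::tibble(
    sample_id = sprintf("L%02d_R%02d", grid$level_index, grid$replicate),
    level = levels[grid$level_index]
  )
  list(counts = counts, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the long-dialect count TSV, the truth table, and the exact
#' simulation configuration as YAML for provenance.
#'
#' @param bench A list as returned by [simulate_benchmark_cohort()], or a
#'   plain counts tibble (then no truth table is written).
#' @param config The [sim_config()] used.
#' @param out_prefix Path prefix; writes `<prefix>_counts.tsv`,
#'   `<prefix>_truth.tsv` and `<prefix>_config.yaml`.
#' @return Character vector of paths written, invisibly.
#' @export
write_simulation <- function(bench, config, out_prefix) {
  counts <- if (is.data.frame(bench)) bench else bench$counts
  paths <- character()
  p <- paste0(out_prefix, "_counts.tsv")
  write_ase_counts(counts, p)
  paths <- c(paths, p)
  if (!is.data.frame(bench) && !is.null(bench$truth)) {
    p <- paste0(out_prefix, "_truth.tsv")
    readr::write_tsv(bench$truth, p, progress = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(out_prefix, "_config.yaml")
  cfg <- unclass(config)
  yaml::write_yaml(cfg, p)
  paths <- c(paths, p)
  invisible(paths)
}
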