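# End-to-end orchestration on synthetic data: simulate every input, write
# the standard file formats, read them back (exercising the I/O layer),
# and run each analysis stage. The exported functions are the interface;
# run_all() is the one-shot demo driver.

pkg_version <- function() {
  as.character(utils::packageVersion("bisreact"))
}

config_fingerprint <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

provenance <- function(config) {
  c(paste("bisreact", pkg_version()),
    paste("seed", config$seed),
    paste("config", config_fingerprint(config)))
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a genome, pileups, dyads, mutations and a cyclizability table
#' under \code{config}; writes every artifact to \code{outdir}; reads the
#' files back; and runs conversion scoring, gradient, flanking, A-tract
#' GLM, nucleosome, cyclizability and mutation-rate analyses. Output TSVs
#' carry '#' provenance headers (package version, seed, config
#' fingerprint). Stage progress is logged to stderr.
#'
#' @param config A \code{sim_config}.
#' @param outdir Output directory (created if needed).
#' @param roll Optional \code{roll_profile} (a synthetic profile is used
#'   when omitted).
#' @param quiet Suppress stage logging.
#' @return Invisible list with every stage result plus \code{files}, the
#'   manifest of written artifacts.
#' @export
run_all <- function(config, outdir, roll = NULL, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message("[bisreact] ", ...)
  prov <- provenance(config)
  files <- list()
  w <- function(name) {
    files[[name]] <<- file.path(outdir, name)
    files[[name]]
  }

  log_stage("simulate: genome")
  gen <- generate_genome(config)
  write_fasta(gen$genome, w("genome.fa"))
  if (is.null(roll)) roll <- synthetic_roll_profile()
  write_roll_tsv(roll, w("roll.tsv"))

  log_stage("simulate: pileups")
  sim <- simulate_pileups(gen$genome, config)
  write_pileup_tsv(sim$pileup, w("pileup.tsv"), prov)
  write_tsv_commented(sim$truth, w("truth_sites.tsv"), prov)

  log_stage("simulate: dyads, mutations, cyclizability")
  dyads <- simulate_dyads(gen$genome, gen$manifest, roll, config)
  write_dyads_bed(dyads, w("dyads.bed"))
  muts <- simulate_mutations(gen$genome, config)
  write_mutations_tsv(muts, w("mutations.tsv"), prov)
  cyc <- simulate_cyclizability(gen$genome, config)
  write_cyclizability_tsv(cyc, w("cyclizability.tsv"))

  log_stage("count: reading back and folding")
  genome <- read_fasta(files[["genome.fa"]])
  pileup <- read_pileup_tsv(files[["pileup.tsv"]], genome)
  sites <- fold_pileup(pileup, genome)
  filt <- apply_site_filters(sites)
  write_tsv_commented(filt$kept, w("sites.tsv"), prov)
  err <- summarize_error(filt$kept)

  log_stage("contexts: runs and gradient")
  runs <- find_polyc_runs(genome)
  runs_r <- attach_run_reactivities(runs, filt$kept)
  grad <- gradient_profile(runs_r)
  write_tsv_commented(grad$profile, w("gradient_profile.tsv"), prov)
  prev <- gradient_prevalence(runs_r)
  write_tsv_commented(prev, w("gradient_prevalence.tsv"), prov)
  flank <- flanking_effects(filt$kept)
  write_tsv_commented(flank, w("flanking_effects.tsv"), prov)
  motifs <- motif_reactivity_table(filt$kept, k = 7L)
  write_tsv_commented(utils::head(motifs, 50), w("top_motifs.tsv"), prov)

  log_stage("glm: A-tract model")
  glm_fit <- atract_glm(filt$kept, genome, runs = runs)
  write_tsv_commented(glm_fit$coefficients, w("atract_glm.tsv"), prov)

  log_stage("nucleosome: end enrichment")
  dyads_in <- read_dyads_bed(files[["dyads.bed"]], genome)
  roll_in <- read_roll_tsv(files[["roll.tsv"]])
  enr <- end_enrichment(runs[runs$n >= 2L, , drop = FALSE], dyads_in,
                        roll_in)
  write_tsv_commented(enr$table, w("end_positions.tsv"), prov)
  write_tsv_commented(enr$stats, w("end_enrichment.tsv"), prov)

  log_stage("cyclize: regressions")
  cyc_in <- read_cyclizability_tsv(files[["cyclizability.tsv"]])
  model <- fit_reactivity_model(filt$kept, k = 4L)
  cyc_reg <- cyclizability_regressions(cyc_in, model)
  write_tsv_commented(cyc_reg, w("cyclizability_regressions.tsv"), prov)
  cyc_enr <- polyc_enrichment_by_score(cyc_in)
  noise <- replicate_noise_report(cyc_in)

  log_stage("mutrates: poly-C end rates")
  muts_in <- read_mutations_tsv(files[["mutations.tsv"]], genome)
  mrates <- polyc_end_rates(muts_in, genome)
  write_tsv_commented(mrates$rates, w("mutation_rates.tsv"), prov)
  roll_strat <- stratify_by_roll(muts_in, genome, dyads_in, roll_in)
  if (nrow(roll_strat$rates) > 0L)
    write_tsv_commented(roll_strat$rates, w("mutation_rates_by_roll.tsv"),
                        prov)

  log_stage("done")
  invisible(list(
    config = config, manifest = gen$manifest, truth = sim$truth,
    sites = filt$kept, excluded = filt$excluded, error_summary = err,
    runs = runs_r, gradient = grad, prevalence = prev, flanking = flank,
    motifs = motifs, atract_glm = glm_fit, dyads = dyads_in,
    end_enrichment = enr, cyclizability = cyc_in,
    cyclizability_regressions = cyc_reg, polyc_enrichment = cyc_enr,
    replicate_noise = noise, mutation_rates = mrates,
    roll_stratified = roll_strat, files = files))
}
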