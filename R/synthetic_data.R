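# Seeded generators for every input the pipeline consumes, with planted
# ground truth. One root seed is split into fixed per-component substreams
# (documented offsets) so adding a generator never shifts existing streams.

.substream <- function(seed, offset) {
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
}

#' Default simulation configuration
#'
#' Emulates the RIP-seq study design: two exposure conditions x two
#' fractions (input, rip) x `n_replicates` biological replicates,
#' NB-distributed counts with library-size variation, a planted set of
#' transcripts 8-oxoG-enriched only under exposure, a set enriched under
#' both conditions (with an exposure/control effect ratio), and planted
#' up/down differential expression.
#'
#' Defaults: 2000 transcripts; baseline log2 mean ~ Normal(5, 2);
#' dispersion log-uniform on [0.01, 0.3]; library factors log-uniform on
#' [0.5, 2]; 100 exposed-only enriched transcripts with log2 enrichment
#' ~ Uniform(3, 8); 50 both-condition enriched with control log2
#' enrichment ~ Uniform(3, 8) and exposed/control linear ratio
#' ~ Uniform(1, 3); 50 up- and 50 down-regulated with |log2 effect|
#' ~ Uniform(1, 3). Three replicates per cell by default (a deeper design
#' than the two-replicate bench study, for stable dispersion estimation);
#' set `n_replicates = 2` for the bench-design preset.
#'
#' @param n_transcripts total transcripts.
#' @param n_replicates biological replicates per (condition, fraction).
#' @param baseline_log2_mean,baseline_log2_sd baseline expression scale.
#' @param dispersion_range log-uniform support for NB alpha.
#' @param lib_factor_range log-uniform support for library-size factors.
#' @param n_enriched_exposed_only,n_enriched_both,n_de_up,n_de_down planted
#'   set sizes (pairwise disjoint).
#' @param enrich_effect_range log2 enrichment support, Uniform.
#' @param both_ratio_range linear exposed/control enrichment-ratio support.
#' @param de_effect_range |log2| DE effect support.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 2000, n_replicates = 3,
                       baseline_log2_mean = 5, baseline_log2_sd = 2,
                       dispersion_range = c(0.01, 0.3),
                       lib_factor_range = c(0.5, 2),
                       n_enriched_exposed_only = 100,
                       n_enriched_both = 50,
                       n_de_up = 50, n_de_down = 50,
                       enrich_effect_range = c(3, 8),
                       both_ratio_range = c(1, 3),
                       de_effect_range = c(1, 3)) {
  cfg <- list(n_transcripts = n_transcripts, n_replicates = n_replicates,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              dispersion_range = dispersion_range,
              lib_factor_range = lib_factor_range,
              n_enriched_exposed_only = n_enriched_exposed_only,
              n_enriched_both = n_enriched_both,
              n_de_up = n_de_up, n_de_down = n_de_down,
              enrich_effect_range = enrich_effect_range,
              both_ratio_range = both_ratio_range,
              de_effect_range = de_effect_range)
  n_planted <- n_enriched_exposed_only + n_enriched_both + n_de_up + n_de_down
  if (n_planted > n_transcripts) {
    stop("planted sets (", n_planted, ") exceed n_transcripts (",
         n_transcripts, ")")
  }
  stopifnot(n_replicates >= 2, all(dispersion_range > 0),
            all(lib_factor_range > 0))
  class(cfg) <- "sim_config"
  cfg
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Simulate a RIP-seq experiment with planted ground truth
#'
#' Counts for transcript i in library j are drawn from
#' `NB(mean = s_j * mu_i * 2^(e_i(cond_j) * [frac_j == rip])
#'  * 2^(d_i * [cond_j == exposed]), dispersion = alpha_i)`
#' where `e_i(cond)` is the planted per-condition log2 enrichment effect
#' (acting only on rip libraries) and `d_i` the planted log2 expression
#' effect (acting on exposed libraries of both fractions). Deterministic
#' given `(config, seed)`.
#'
#' @param config a [sim_config()] list.
#' @param seed integer root seed.
#' @return list with `counts` (`ox_counts`), `truth` (data.frame
#'   `transcript_id`, `class`, `baseline_mean`, `dispersion`,
#'   `enrich_exposed`, `enrich_control`, `de_log2fc`), `lib_factors`,
#'   `config`, `seed`.
#' @export
simulate_ripseq <- function(config = sim_config(), seed = 1) {
  cfg <- config
  n <- cfg$n_transcripts
  .substream(seed, 0L)

  ids <- sprintf("TX%05d", seq_len(n))
  mu <- 2^stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  alpha <- .runif_log(n, cfg$dispersion_range)

  planted <- sample.int(n, cfg$n_enriched_exposed_only + cfg$n_enriched_both +
                          cfg$n_de_up + cfg$n_de_down)
  idx_only <- planted[seq_len(cfg$n_enriched_exposed_only)]
  idx_both <- planted[cfg$n_enriched_exposed_only + seq_len(cfg$n_enriched_both)]
  idx_up <- planted[cfg$n_enriched_exposed_only + cfg$n_enriched_both +
                      seq_len(cfg$n_de_up)]
  idx_down <- planted[cfg$n_enriched_exposed_only + cfg$n_enriched_both +
                        cfg$n_de_up + seq_len(cfg$n_de_down)]

  e_exp <- e_ctl <- d <- numeric(n)
  e_exp[idx_only] <- stats::runif(cfg$n_enriched_exposed_only,
                                  cfg$enrich_effect_range[1],
                                  cfg$enrich_effect_range[2])
  e_ctl[idx_both] <- stats::runif(cfg$n_enriched_both,
                                  cfg$enrich_effect_range[1],
                                  cfg$enrich_effect_range[2])
  ratio_both <- stats::runif(cfg$n_enriched_both, cfg$both_ratio_range[1],
                             cfg$both_ratio_range[2])
  e_exp[idx_both] <- e_ctl[idx_both] + log2(ratio_both)
  d[idx_up] <- stats::runif(cfg$n_de_up, cfg$de_effect_range[1],
                            cfg$de_effect_range[2])
  d[idx_down] <- -stats::runif(cfg$n_de_down, cfg$de_effect_range[1],
                               cfg$de_effect_range[2])

  cls <- rep("null", n)
  cls[idx_only] <- "enriched_exposed_only"
  cls[idx_both] <- "enriched_both"
  cls[idx_up] <- "de_up"
  cls[idx_down] <- "de_down"

  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        fraction = c("input", "rip"),
                        condition = c("control", "exposed"),
                        stringsAsFactors = FALSE)
  design$sample_id <- with(design, paste(condition, fraction, replicate,
                                         sep = "_"))
  samples <- sample_sheet(design$sample_id, design$condition, design$fraction,
                          design$replicate)
  m <- nrow(samples)
  s_j <- .runif_log(m, cfg$lib_factor_range)
  names(s_j) <- samples$sample_id

  e_mat <- cbind(exposed = e_exp, control = e_ctl)
  counts <- matrix(0L, n, m, dimnames = list(ids, samples$sample_id))
  for (j in seq_len(m)) {
    is_rip <- samples$fraction[j] == "rip"
    is_exp <- samples$condition[j] == "exposed"
    mean_j <- s_j[j] * mu *
      2^(e_mat[, samples$condition[j]] * is_rip) *
      2^(d * is_exp)
    counts[, j] <- stats::rnbinom(n, mu = mean_j, size = 1 / alpha)
  }

  truth <- data.frame(transcript_id = ids, class = cls, baseline_mean = mu,
                      dispersion = alpha, enrich_exposed = e_exp,
                      enrich_control = e_ctl, de_log2fc = d,
                      stringsAsFactors = FALSE)
  list(counts = rip_counts(counts, samples), truth = truth,
       lib_factors = s_j, config = cfg, seed = seed)
}

#' Simulate a gene-set collection with one spiked positive set
#'
#' Random sets drawn from the transcript universe, plus one spiked set
#' drawn mostly (`purity`) from the planted exposure-only enriched
#' transcripts, giving over-representation analysis a known positive.
#' Uses the root seed with substream offset 1000.
#'
#' @param truth the `truth` data.frame from [simulate_ripseq()].
#' @param n_sets number of random background sets (default 20).
#' @param set_size_range integer range of random set sizes.
#' @param spike_size size of the spiked set (default 30).
#' @param purity fraction of the spiked set drawn from planted enriched
#'   transcripts (default 0.9).
#' @param seed root seed.
#' @return an `ox_genesets` collection; the spiked set is named
#'   `"spiked_oxidized"`.
#' @export
simulate_gmt <- function(truth, n_sets = 20, set_size_range = c(10, 50),
                         spike_size = 30, purity = 0.9, seed = 1) {
  .substream(seed, 1000L)
  ids <- truth$transcript_id
  enriched <- truth$transcript_id[truth$class == "enriched_exposed_only"]
  sets <- list()
  for (i in seq_len(n_sets)) {
    sz <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
    sets[[sprintf("random_set_%02d", i)]] <-
      list(description = "background", members = sample(ids, sz))
  }
  n_spike <- min(round(purity * spike_size), length(enriched))
  n_fill <- spike_size - round(purity * spike_size)
  spike <- c(sample(enriched, n_spike),
             sample(setdiff(ids, enriched), n_fill))
  sets[["spiked_oxidized"]] <- list(description = "planted positive",
                                    members = spike)
  structure(sets, class = "ox_genesets")
}

#' Simulate competitive-ELISA readings
#'
#' Triplicate standards on a known logit-log curve with Gaussian noise on
#' the logit scale, plus sample readings at two dilutions of a known true
#' concentration. Uses the root seed with substream offset 2000. Default
#' curve (a = 3.885, b = -0.9) has its midpoint near 75 pg/ml, inside the
#' assay's linear range.
#'
#' @param a,b true curve intercept/slope (`b < 0`).
#' @param noise_sd Gaussian noise sd on the logit scale (0 = noiseless).
#' @param true_conc true sample concentration, pg/ml.
#' @param dilutions dilution factors for the sample readings.
#' @param standard_concs standard concentrations, pg/ml.
#' @param n_reps technical replicates per standard.
#' @param seed root seed.
#' @return list with `standards` (data.frame `conc`, `b_over_b0`),
#'   `samples` (data.frame `b_over_b0`, `dilution`) and `truth`
#'   (list `a`, `b`, `conc`).
#' @export
simulate_elisa <- function(a = 3.885, b = -0.9, noise_sd = 0.05,
                           true_conc = 500, dilutions = c(1, 2),
                           standard_concs = 3000 / 2^(0:7),
                           n_reps = 3, seed = 1) {
  if (b >= 0) stop("true slope b must be negative (competitive curve)")
  .substream(seed, 2000L)
  conc <- rep(standard_concs, each = n_reps)
  logit_true <- a + b * log(conc)
  standards <- data.frame(
    conc = conc,
    b_over_b0 = stats::plogis(logit_true + stats::rnorm(length(conc), 0,
                                                        noise_sd)))
  assay_conc <- true_conc / dilutions
  samples <- data.frame(
    b_over_b0 = stats::plogis(a + b * log(assay_conc) +
                                stats::rnorm(length(dilutions), 0, noise_sd)),
    dilution = dilutions)
  list(standards = standards, samples = samples,
       truth = list(a = a, b = b, conc = true_conc))
}
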