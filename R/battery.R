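#' Simulation designs of the standard evaluation battery
#'
#' Twenty desk-scale samples spanning one-, two- and three-strain mixtures
#' at unequal frequencies (e.g. 80/20, 70/20/10), references of 50 genes
#' of 900 bp, per-strain identities of 98-99% to the reference, and total
#' coverages chosen so that every strain is covered at >= 20x (so that
#' every strain's alleles clear the 20-read support filter). Frequency
#' vectors are identifiable: configurations in which one strain's
#' frequency equals the sum of the other two collapse two hexamodal peaks
#' onto the same value and are ambiguous by construction. These are the
#' package's standard conditions for measuring strain-count recovery,
#' frequency accuracy, genotype accuracy and the uncalled fraction.
#'
#' @return List of `sim_design` objects.
#' @export
battery_designs <- function() {
  d <- function(freqs, coverage, identity) {
    sim_design(n_strains = length(freqs), frequencies = freqs,
               coverage = coverage, identity = identity)
  }
  list(
    d(1, 30, 0.99), d(1, 60, 0.985), d(1, 100, 0.99), d(1, 50, 0.98),
    d(c(0.8, 0.2), 150, 0.99), d(c(0.7, 0.3), 120, 0.985),
    d(c(0.6, 0.4), 100, 0.99), d(c(0.9, 0.1), 250, 0.985),
    d(c(0.8, 0.2), 120, 0.985), d(c(0.75, 0.25), 120, 0.99),
    d(c(0.65, 0.35), 100, 0.985), d(c(0.85, 0.15), 170, 0.99),
    d(c(0.7, 0.2, 0.1), 250, 0.99), d(c(0.6, 0.3, 0.1), 250, 0.985),
    d(c(0.45, 0.35, 0.2), 125, 0.99), d(c(0.55, 0.3, 0.15), 170, 0.985),
    d(c(0.7, 0.2, 0.1), 250, 0.985), d(c(0.6, 0.25, 0.15), 170, 0.99),
    d(c(0.65, 0.25, 0.1), 250, 0.99), d(c(0.75, 0.15, 0.1), 250, 0.985)
  )
}

#' Equal-frequency stress designs (three strains at 1/3 each)
#'
#' The hardest regime for frequency-based deconvolution: all hexamodal
#' peaks coincide at 1/3 and 2/3.
#'
#' @return List of five `sim_design` objects.
#' @export
equal_freq_designs <- function() {
  f <- rep(1 / 3, 3)
  list(sim_design(n_strains = 3L, frequencies = f, coverage = 90,
                  identity = 0.99),
       sim_design(n_strains = 3L, frequencies = f, coverage = 120,
                  identity = 0.985),
       sim_design(n_strains = 3L, frequencies = f, coverage = 90,
                  identity = 0.985),
       sim_design(n_strains = 3L, frequencies = f, coverage = 120,
                  identity = 0.99),
       sim_design(n_strains = 3L, frequencies = f, coverage = 100,
                  identity = 0.99))
}

#' Four-strain stress designs (beyond the model's three-strain capacity)
#'
#' @return List of five `sim_design` objects.
#' @export
four_strain_designs <- function() {
  f <- c(0.4, 0.3, 0.2, 0.1)
  list(sim_design(n_strains = 4L, frequencies = f, coverage = 200,
                  identity = 0.99),
       sim_design(n_strains = 4L, frequencies = f, coverage = 220,
                  identity = 0.985),
       sim_design(n_strains = 4L, frequencies = c(0.35, 0.3, 0.2, 0.15),
                  coverage = 200, identity = 0.99),
       sim_design(n_strains = 4L, frequencies = f, coverage = 220,
                  identity = 0.99),
       sim_design(n_strains = 4L, frequencies = c(0.45, 0.25, 0.2, 0.1),
                  coverage = 200, identity = 0.985))
}

#' Simulate, run and evaluate a battery of designs
#'
#' For each design: simulate a sample (GenBank reference, paired reads,
#' perfect SAM), run the full pipeline with default parameters from the
#' written files, and score the result against the truth. Per-sample
#' seeds are derived deterministically from `seed`.
#'
#' @param designs List of `sim_design` objects.
#' @param seed Master integer seed.
#' @param injective Passed to [evaluate_sample()]; set `FALSE` for
#'   designs that exceed the three-strain model capacity.
#' @param verbose Print per-sample progress.
#' @return `data.table` with one row per sample: `sample`, `n_true`,
#'   `n_inferred`, `count_correct`, `genotype_acc`, `freq_acc`,
#'   `uncalled_frac`, `dominant_acc`.
#' @export
run_battery <- function(designs, seed = 1L, injective = TRUE,
                        verbose = FALSE) {
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, length(designs))
  rows <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    dir <- tempfile(sprintf("battery_%02d_", i))
    sim <- simulate_sample(designs[[i]], seed = sample_seeds[i], dir = dir)
    res <- suppressMessages(suppressWarnings(run_pipeline(
      sim$files$genbank, sam = sim$files$sam,
      config = run_config(seed = sample_seeds[i]))))
    ev <- evaluate_sample(res, sim, injective = injective)
    rows[[i]] <- data.table::data.table(
      sample = i, n_true = ev$n_true, n_inferred = ev$n_inferred,
      count_correct = ev$n_true == ev$n_inferred,
      genotype_acc = ev$genotype_acc, freq_acc = ev$freq_acc,
      uncalled_frac = ev$uncalled_frac, dominant_acc = ev$dominant_acc)
    if (verbose) {
      message(sprintf(
        "sample %02d: true %d inferred %d, genotype %.3f, freq %.4f, N %.4f",
        i, ev$n_true, ev$n_inferred, ev$genotype_acc, ev$freq_acc,
        ev$uncalled_frac))
    }
    unlink(dir, recursive = TRUE)
  }
  data.table::rbindlist(rows)
}
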