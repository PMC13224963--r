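#' Hexamodal peak frequencies of a strain distribution
#'
#' Three strains at frequencies `(f1, f2, f3)` produce six expected
#' allele-frequency modes: the three strain-private frequencies and the
#' three pairwise sums (alleles shared by two strains).
#'
#' @param dist Numeric vector `(f1, f2, f3)` on the simplex.
#' @return Named numeric vector of the six peak frequencies, in the order
#'   `1, 2, 3, 1+2, 1+3, 2+3`.
#' @export
#' @examples
#' peaks_from(c(0.7, 0.2, 0.1))
peaks_from <- function(dist) {
  stopifnot(length(dist) == 3L, all(dist >= -1e-9),
            abs(sum(dist) - 1) < 1e-6)
  setNames(c(dist[1], dist[2], dist[3], dist[1] + dist[2],
             dist[1] + dist[3], dist[2] + dist[3]), SUBSET_LABELS)
}

#' Assign frequencies to their nearest hexamodal peak
#'
#' Returns, for each input frequency, the peak minimizing the absolute
#' distance. Ties are broken deterministically in favour of the smaller
#' subset, then lexicographically (i.e. the lowest canonical peak index).
#'
#' @param freq Numeric vector of frequencies in `[0, 1]`.
#' @param dist Strain distribution `(f1, f2, f3)`.
#' @return `list(subset=, distance=)`: integer peak indices (1..6, see
#'   [peaks_from()] for the order) and the absolute distances.
#' @export
assign_peak <- function(freq, dist) {
  p <- peaks_from(dist)
  d <- abs(outer(freq, unname(p), "-"))
  idx <- max.col(-d, ties.method = "first")
  list(subset = idx, distance = d[cbind(seq_along(freq), idx)])
}

#' Score a strain distribution against observed allele-pair frequencies
#'
#' Each allele pair contributes the distance of its frequency to the
#' nearest peak plus the distance of its complement frequency (1 - f) to
#' the nearest peak, provided the two land on complementary strain
#' subsets; when the complement is assigned an incompatible peak (e.g.
#' peak 1 and peak 1+3) the pair's contribution is set to 1. The overall
#' score S is the (weight-)summed contribution over pairs; the search
#' minimizes S.
#'
#' @param freq Pair frequencies, or a pair table from [extract_pairs()]
#'   (its `pair_freq` column is used).
#' @param dist Strain distribution `(f1, f2, f3)`.
#' @param weights Optional per-pair weights (default 1).
#' @return The score S (non-negative scalar).
#' @export
pair_score <- function(freq, dist, weights = NULL) {
  if (is.data.frame(freq)) freq <- freq$pair_freq
  if (!length(freq)) stop("empty allele-pair list")
  if (is.null(weights)) weights <- rep(1, length(freq))
  p <- unname(peaks_from(dist))
  d1m <- abs(outer(freq, p, "-"))        # pairs x 6
  d2m <- abs(outer(1 - freq, p, "-"))
  d1 <- do.call(pmin, as.data.frame(d1m))
  d2 <- do.call(pmin, as.data.frame(d2m))
  # ties between coinciding peaks are resolved in favour of compatibility
  eps <- 1e-9
  compat <- rep(FALSE, length(freq))
  for (k in 1:6) {
    compat <- compat | (d1m[, k] <= d1 + eps &
                        d2m[, COMPLEMENT[k]] <= d2 + eps)
  }
  sum(weights * ifelse(compat, d1 + d2, 1))
}

#' Fit strain frequencies by stochastic search over the simplex
#'
#' Runs the greedy stochastic search that minimizes the hexamodal score S.
#' Walkers start from Gaussian perturbations of the equal-frequency
#' distribution (1/3, 1/3, 1/3) — the first walker starts exactly there —
#' and iterate accept-if-better proposals in which two randomly chosen
#' strain frequencies are shifted by signed draws from Normal(0.002,
#' 0.002) and the third is set to the complement. Every `jump_every`
#' iterations, and whenever `stall_jump` consecutive iterations fail to
#' improve, a big jump is attempted instead: with equal probability the
#' proposal scale is inflated 5-fold, 10-fold or 100-fold, or a fresh
#' distribution is drawn uniformly from the simplex. A walker stops after
#' `converge` consecutive non-improving iterations.
#'
#' @param pairs Pair table from [extract_pairs()] or a numeric vector of
#'   pair frequencies.
#' @param weights Optional per-pair weights when `pairs` is numeric.
#' @param spans Optional per-pair spanning-fragment counts (taken from
#'   the pair table when available); used to compute the binomial noise
#'   floor that calibrates degenerate-solution selection. Without spans
#'   the floor is zero, i.e. only exactly score-equivalent simpler
#'   configurations are preferred.
#' @param n_walkers Number of walkers (default 500).
#' @param converge Consecutive non-improving iterations that define
#'   convergence (default 100).
#' @param stall_jump Non-improving iterations before big jumps engage
#'   (default 20).
#' @param jump_every Period of scheduled big jumps (default 10).
#' @param init_sd SD of the Gaussian walker initialization around
#'   (1/3, 1/3, 1/3) (default 0.1).
#' @param seed Optional integer seed (sets R's RNG).
#' @param agg_bin When more than 2000 distinct pair frequencies are
#'   present they are aggregated into bins of this width for scoring
#'   speed (default 0.001); smaller instances are scored exactly.
#' @param simplify Report the simplest configuration (single strain,
#'   equal frequencies, or a refitted two-strain fit) that explains the
#'   pair spectrum to within its binomial sampling noise (default
#'   TRUE); guards against phantom strains from degenerate split-peak
#'   optima.
#' @return `list(freqs=, score=, trace=)` of class `strain_fit`: the
#'   best-scoring distribution found (sorted decreasing), its exact score
#'   S, and a per-walker trace (`walker`, `iterations`, `score`,
#'   `f1..f3`).
#' @export
run_search <- function(pairs, weights = NULL, spans = NULL,
                       n_walkers = 500L,
                       converge = 100L, stall_jump = 20L, jump_every = 10L,
                       init_sd = 0.1, seed = NULL, agg_bin = 0.001,
                       simplify = TRUE) {
  if (is.data.frame(pairs) && is.null(spans)) spans <- pairs$span_count
  freq <- if (is.data.frame(pairs)) pairs$pair_freq else pairs
  if (!length(freq)) stop("empty allele-pair list")
  if (is.null(weights)) weights <- rep(1, length(freq))
  stopifnot(length(weights) == length(freq))
  if (!is.null(seed)) set.seed(seed)

  agg <- data.table::data.table(freq = freq, w = weights)
  if (data.table::uniqueN(agg$freq) > 2000L) {
    agg[, freq := round(freq / agg_bin) * agg_bin]
  }
  agg <- agg[, .(w = sum(w)), by = freq]

  fit <- cpp_run_search(agg$freq, agg$w, as.integer(n_walkers),
                        as.integer(converge), as.integer(stall_jump),
                        as.integer(jump_every), init_sd, 200000L)
  best <- fit$freqs
  best_s <- fit$score
  if (simplify) {
    # Degenerate-solution selection. The distance score weakly prefers
    # "split" optima that straddle one empirical frequency cluster with
    # two nearby peaks, which manifests as a phantom low-frequency
    # strain. Simpler configurations are therefore tested against a
    # model-independent noise floor: under a correct model each pair's
    # expected contribution is 2*sqrt(2/pi) times its binomial sampling
    # deviation sqrt(p(1-p)/span). A configuration scoring within 1.5x
    # this floor explains the spectrum to within sampling noise; the
    # simplest such configuration is reported (single strain, then the
    # equal-frequency starting assumption when it matches the best
    # two-strain fit to within the proposal resolution of 0.002 per
    # pair, then the best two-strain fit).
    W <- sum(weights)
    floor_s <- if (is.null(spans)) 0 else {
      sum(weights * 2 * sqrt(2 / pi) * sqrt(freq * (1 - freq) / spans))
    }
    adequate <- function(s) s <= 1.5 * floor_s + 1e-9
    s1 <- cpp_pair_score(agg$freq, agg$w, c(1, 0, 0))
    r2 <- cpp_refit2(agg$freq, agg$w)
    s_eq <- cpp_pair_score(agg$freq, agg$w, rep(1 / 3, 3))
    if (adequate(s1)) {
      best <- c(1, 0, 0)
      best_s <- s1
    } else if (adequate(s_eq) && s_eq <= r2$score + 0.002 * W) {
      best <- rep(1 / 3, 3)
      best_s <- s_eq
    } else if (adequate(r2$score)) {
      best <- c(r2$a, 1 - r2$a, 0)
      best_s <- r2$score
    }
  }
  best <- sort(best, decreasing = TRUE)
  trace <- data.table::as.data.table(fit$trace)
  data.table::setnames(trace, c("walker", "iterations", "score",
                                "f1", "f2", "f3"))
  structure(list(freqs = best,
                 score = pair_score(freq, best, weights),
                 trace = trace),
            class = "strain_fit")
}

#' @export
print.strain_fit <- function(x, ...) {
  cat("Strain-frequency fit (hexamodal peak model)\n")
  cat(sprintf("  frequencies: %s\n",
              paste(sprintf("%.4f", x$freqs), collapse = " / ")))
  cat(sprintf("  score S: %.6f over %d walkers\n", x$score, nrow(x$trace)))
  invisible(x)
}

# Single proposal / big-jump steps, exposed for testing the search's
# transition kernel in isolation.
propose_step <- function(dist, scale = 1) cpp_propose(dist, scale)
big_jump_step <- function(dist) cpp_big_jump(dist)
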