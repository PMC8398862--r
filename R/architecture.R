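#' Define the genetic architecture of an additive trait
#'
#' An architecture holds the per-locus effect sizes of `n` unlinked diallelic
#' loci and the symmetric per-locus mutation rate. The "+" allele at locus
#' `i` contributes `+effects[i]/2` to the phenotype, the "-" allele
#' `-effects[i]/2`, so the population trait mean can range over
#' `[-sum(effects), +sum(effects)]`.
#'
#' @param effects numeric vector of positive per-locus effect sizes
#'   (trait units).
#' @param mutation_rate symmetric per-locus mutation rate between the two
#'   alleles, per generation (>= 0).
#' @param mean_effect mean of the effect-size distribution the effects are
#'   regarded as drawn from (trait units); defaults to `mean(effects)`.
#' @return An object of class `trait_architecture` with fields `n_loci`,
#'   `effects`, `mean_effect` and `mutation_rate`.
#' @seealso [sample_architecture()] for drawing exponential effect sizes.
#' @export
trait_architecture <- function(effects, mutation_rate, mean_effect = mean(effects)) {
  effects <- as.numeric(effects)
  if (length(effects) < 1L || any(!is.finite(effects)) || any(effects <= 0))
    stop("all effect sizes must be finite and > 0")
  if (!is.finite(mutation_rate) || mutation_rate < 0)
    stop("mutation_rate must be >= 0")
  if (!is.finite(mean_effect) || mean_effect <= 0)
    stop("mean_effect must be > 0")
  structure(
    list(n_loci = length(effects), effects = effects,
         mean_effect = mean_effect, mutation_rate = mutation_rate),
    class = "trait_architecture")
}

#' Sample an exponential-effects architecture
#'
#' Effect sizes are drawn i.i.d. from an exponential distribution with mean
#' `mean_effect`, the standard assumption for the distribution of allelic
#' effects on a polygenic trait in this model family.
#'
#' @param n number of loci (>= 1).
#' @param mean_effect mean effect size (trait units, > 0).
#' @param mutation_rate symmetric per-locus mutation rate (>= 0).
#' @param seed integer seed; the same seed always yields the same
#'   architecture.
#' @param minor_only if `TRUE`, effects at or above the minor/major threshold
#'   `effect_threshold(mutation_rate, s)` are redrawn so the architecture
#'   contains only minor loci; requires `s`.
#' @param s selection strength, only used when `minor_only = TRUE`.
#' @return A [trait_architecture()].
#' @export
sample_architecture <- function(n, mean_effect, mutation_rate, seed,
                                minor_only = FALSE, s = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (mean_effect <= 0) stop("mean_effect must be > 0")
  eff <- withr_seed(seed, {
    e <- rexp(n, rate = 1 / mean_effect)
    if (minor_only) {
      if (is.null(s)) stop("minor_only = TRUE requires s")
      gh <- effect_threshold(mutation_rate, s)
      while (any(bad <- e >= gh)) e[bad] <- rexp(sum(bad), rate = 1 / mean_effect)
    }
    e
  })
  arch <- trait_architecture(eff, mutation_rate, mean_effect = mean_effect)
  arch$seed <- as.integer(seed)
  arch
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("Trait architecture:", x$n_loci, "unlinked diallelic loci\n")
  cat("  effect sizes: mean", signif(mean(x$effects), 4),
      " range [", signif(min(x$effects), 3), ",", signif(max(x$effects), 3), "]\n")
  cat("  mutation rate:", x$mutation_rate, "per locus per generation\n")
  invisible(x)
}

#' Define a selection regime (Gaussian fitness with an optimum shift)
#'
#' Fitness of phenotype `z` is `exp(-(s/2) * (z - z_opt)^2)`; the optimum is
#' `optimum_before` up to (excluding) generation `shift_time` and
#' `optimum_after` from then on.
#'
#' For an optimum-shift experiment the model requires
#' `0 < optimum_before < optimum_after < n * mean_effect`, which guarantees
#' the trait mean can settle close to the new optimum. Violations of the
#' upper bound produce a warning only, since exploratory runs may use
#' unreachable optima on purpose.
#'
#' @param s selection strength (1 / trait-units^2, > 0); `1/s` should be
#'   large relative to the phenotypic variance.
#' @param optimum_before equilibrium optimum `z0` (trait units).
#' @param optimum_after post-shift optimum `zf`; defaults to no shift.
#' @param shift_time generation at which the optimum jumps.
#' @param arch optional [trait_architecture()] used to validate the
#'   reachability bounds above.
#' @return An object of class `selection_regime`.
#' @export
selection_regime <- function(s, optimum_before, optimum_after = optimum_before,
                             shift_time = 0, arch = NULL) {
  if (!is.finite(s) || s <= 0) stop("s must be > 0")
  if (optimum_before <= 0)
    warning("optimum_before <= 0: equilibrium analyses assume z0 > 0")
  if (!is.null(arch)) {
    zmax <- arch$n_loci * arch$mean_effect
    if (optimum_before >= zmax || optimum_after >= zmax)
      warning("optimum at or beyond n * mean_effect: the trait mean cannot ",
              "settle near the optimum")
    if (optimum_after < optimum_before)
      warning("optimum_after < optimum_before: shift analyses assume zf > z0")
  }
  structure(list(s = s, optimum_before = optimum_before,
                 optimum_after = optimum_after, shift_time = shift_time),
            class = "selection_regime")
}

#' Optimum trait value at a given generation
#'
#' @param regime a [selection_regime()].
#' @param t generation (vectorized).
#' @return Optimum phenotype at each `t`.
#' @export
optimum_at <- function(regime, t) {
  ifelse(t < regime$shift_time, regime$optimum_before, regime$optimum_after)
}

#' Gaussian stabilizing fitness
#'
#' `w(z) = exp(-(s/2) * (z - z_opt(t))^2)`, equal to 1 at the optimum.
#'
#' @param z phenotype (vectorized, trait units).
#' @param regime a [selection_regime()].
#' @param t generation used to resolve the current optimum.
#' @return Fitness in (0, 1].
#' @export
fitness <- function(z, regime, t = 0) {
  zopt <- optimum_at(regime, t)
  exp(-(regime$s / 2) * (z - zopt)^2)
}

#' Trait cumulants from allele frequencies
#'
#' For "+"-allele frequencies `p` (with `q = 1 - p`), the cumulants of the
#' trait distribution are
#' `c1 = sum(gamma * (2p - 1))`, `c2 = 2 * sum(gamma^2 * p * q)` and
#' `c3 = 2 * sum(gamma^3 * p * q * (q - p))`; `delta_c1 = c1 - optimum` is
#' the deviation of the trait mean from the current fitness optimum, the
#' quantity that drives directional selection.
#'
#' @param arch a [trait_architecture()].
#' @param freqs numeric vector of "+"-allele frequencies in \[0, 1\], one
#'   per locus.
#' @param optimum current optimum (trait units).
#' @return A list of class `cumulant_set` with `c1`, `c2`, `c3`, `delta_c1`.
#' @export
compute_cumulants <- function(arch, freqs, optimum = 0) {
  if (length(freqs) != arch$n_loci)
    stop("freqs must have one entry per locus (", arch$n_loci, ")")
  if (any(!is.finite(freqs)) || any(freqs < 0 | freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  g <- arch$effects
  q <- 1 - freqs
  pq <- freqs * q
  structure(list(c1 = sum(g * (2 * freqs - 1)),
                 c2 = 2 * sum(g^2 * pq),
                 c3 = 2 * sum(g^3 * pq * (q - freqs)),
                 delta_c1 = sum(g * (2 * freqs - 1)) - optimum),
            class = "cumulant_set")
}

#' Minor/major effect-size threshold
#'
#' The stability threshold separating minor from major loci,
#' `gamma_hat = 2 * sqrt(2 * mu / s)`. Loci with smaller effects equilibrate
#' at intermediate frequency (near 1/2); loci with larger effects sit in
#' mutation-selection balance near the frequency boundaries. With `mu = 0`
#' the threshold is 0 and every locus is major.
#'
#' @param mu per-locus mutation rate (>= 0).
#' @param s selection strength (> 0).
#' @return The threshold effect size (trait units).
#' @export
effect_threshold <- function(mu, s) {
  if (!is.finite(s) || s <= 0) stop("s must be > 0")
  if (mu < 0) stop("mu must be >= 0")
  2 * sqrt(2 * mu / s)
}

#' Classify loci as minor or major
#'
#' @param arch a [trait_architecture()].
#' @param s selection strength.
#' @return Character vector, `"minor"` for effects below
#'   [effect_threshold()], `"major"` otherwise.
#' @export
classify_loci <- function(arch, s) {
  gh <- effect_threshold(arch$mutation_rate, s)
  ifelse(arch$effects < gh, "minor", "major")
}

#' Write / read an architecture as TSV
#'
#' The file is a two-column TSV (`locus_id`, `effect_size`) preceded by
#' `#`-prefixed header lines carrying a JSON record of `n`, `mean_effect`,
#' `mutation_rate` and (if present) the sampling seed, so a run can be
#' reproduced bit-for-bit from its serialized architecture.
#'
#' @param arch a [trait_architecture()].
#' @param path file path.
#' @return `write_architecture()` returns `path` invisibly;
#'   `read_architecture()` returns a [trait_architecture()].
#' @export
write_architecture <- function(arch, path) {
  hdr <- list(n = arch$n_loci, mean_effect = arch$mean_effect,
              mutation_rate = arch$mutation_rate)
  if (!is.null(arch$seed)) hdr$seed <- arch$seed
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)), con)
  writeLines("locus_id\teffect_size", con)
  writeLines(sprintf("%d\t%.17g", seq_len(arch$n_loci), arch$effects), con)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- jsonlite::fromJSON(sub("^#\\s*", "", hdr_lines[1]))
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  arch <- trait_architecture(tab$effect_size, hdr$mutation_rate,
                             mean_effect = hdr$mean_effect)
  if (!is.null(hdr$seed)) arch$seed <- as.integer(hdr$seed)
  arch
}
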