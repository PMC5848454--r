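## Seeded generators for synthetic co-evolved protein/motif families and
## PWM-driven probe sets. These emulate the statistical structure of an
## in vitro motif compendium — a homologous family whose motif divergence
## tracks sequence divergence, and probe sets whose intensities are noisy
## functions of a ground-truth PWM's scan score — so every estimator in the
## package can be exercised end to end without external data.

#' Configuration for the synthetic generators
#'
#' @param n_proteins family size.
#' @param protein_length amino-acid sequence length (default 100, the size
#'   of a small RNA-binding domain construct).
#' @param pwm_width motif width (default 7).
#' @param coevo_strength in [0, 1]: 1 means motif divergence is fully
#'   proportional to sequence divergence, 0 means independent of it.
#' @param mutation_rate in [0, 1]: upper bound of each descendant's per-site
#'   substitution probability (drawn uniformly per descendant, so the family
#'   spans a range of evolutionary distances).
#' @param probe_count number of probes (default 2000).
#' @param probe_length probe length in nt (default 35, within the 30-41 nt
#'   range typical of designed probe libraries).
#' @param noise_sd standard deviation of the Gaussian noise added to probe
#'   intensities (default 0.1).
#' @param seed RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 20, protein_length = 100,
                         pwm_width = 7, coevo_strength = 0.8,
                         mutation_rate = 0.3, probe_count = 2000,
                         probe_length = 35, noise_sd = 0.1, seed = 1) {
  n_proteins <- .check_count(n_proteins, "n_proteins")
  protein_length <- .check_count(protein_length, "protein_length")
  pwm_width <- .check_count(pwm_width, "pwm_width")
  probe_count <- .check_count(probe_count, "probe_count")
  probe_length <- .check_count(probe_length, "probe_length")
  for (nm in c("coevo_strength", "mutation_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_input(sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop_input("'noise_sd' must be a nonnegative number")
  structure(list(n_proteins = n_proteins, protein_length = protein_length,
                 pwm_width = pwm_width, coevo_strength = coevo_strength,
                 mutation_rate = mutation_rate, probe_count = probe_count,
                 probe_length = probe_length, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

## One Dirichlet draw of length 4; floor keeps PWM entries strictly positive.
.rdirichlet4 <- function(alpha, floor = 0.01) {
  g <- rgamma(4, shape = alpha) + floor
  g / sum(g)
}

## One ancestral motif column: a consensus base carrying most of the mass
## (strongly informative, like experimentally derived RBP motifs), the
## remainder split at random with a small floor keeping entries positive.
.ancestral_column <- function() {
  cons <- sample.int(4, 1)
  p <- numeric(4)
  p[cons] <- runif(1, 0.75, 0.95)
  rest <- rgamma(3, shape = 1) + 0.02
  p[-cons] <- (1 - p[cons]) * rest / sum(rest)
  p
}

#' Generate a synthetic co-evolved RBP family
#'
#' Starts from one ancestral protein and one ancestral PWM whose columns
#' each concentrate 0.75-0.95 of their mass on a consensus base (strongly
#' informative, as experimentally derived RBP motifs are). Each of the
#' `n_proteins` descendants receives point substitutions at a per-descendant
#' rate drawn uniformly from `[0, mutation_rate]`, and its PWM columns are
#' mixed with Dirichlet noise whose magnitude is
#' `coevo_strength * (realized sequence divergence) +
#' (1 - coevo_strength) * (independent uniform draw on the same range)`.
#' With `coevo_strength = 1` and `mutation_rate = 0` all records and PWMs
#' are identical; with `coevo_strength = 0` motif divergence carries no
#' information about sequence divergence. The Dirichlet concentration (4
#' per base) makes a full-strength perturbation near-uniform.
#'
#' @param config a [synth_config()].
#' @return list of [rbp_record()]s with attached probability-scale PWMs.
#'   Attributes: `ancestral_pwm` (the ground-truth ancestor) and
#'   `divergence` (realized per-descendant substitution fractions).
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    L <- config$protein_length
    n <- config$n_proteins
    k <- config$pwm_width
    anc_seq <- sample(AA20, L, replace = TRUE)
    anc_pwm <- vapply(seq_len(k), function(j) .ancestral_column(),
                      numeric(4))
    records <- vector("list", n)
    divergence <- numeric(n)
    for (i in seq_len(n)) {
      rate <- runif(1, 0, config$mutation_rate)
      hit <- which(runif(L) < rate)
      s <- anc_seq
      for (pos in hit) s[pos] <- sample(setdiff(AA20, s[pos]), 1)
      divergence[i] <- length(hit) / L
      m <- config$coevo_strength * divergence[i] +
        (1 - config$coevo_strength) * runif(1, 0, config$mutation_rate)
      m <- min(max(m, 0), 1)
      w <- vapply(seq_len(k), function(j)
        (1 - m) * anc_pwm[, j] + m * .rdirichlet4(4), numeric(4))
      records[[i]] <- rbp_record(
        rbp_id = sprintf("RBP%03d", i),
        aa_sequence = paste(s, collapse = ""),
        family = "RRM", construct = "RBR",
        species = sprintf("species_%03d", i),
        pwm = pwm(w, scale = "probability",
                  motif_id = sprintf("RBP%03d", i)))
    }
    structure(records,
              ancestral_pwm = pwm(anc_pwm, scale = "probability",
                                  motif_id = "ancestor"),
              divergence = divergence)
  })
}

#' Generate a probe set driven by a ground-truth PWM
#'
#' Uniform-random RNA sequences; the first half of the probes has a motif
#' instance (sampled position-wise from the PWM's probabilities) planted at
#' a random offset and is labeled bound (1), the second half is unplanted
#' and labeled unbound (0). Intensities are the PWM's arcsinh-gated scan
#' score of each probe plus Gaussian noise of sd `noise_sd`.
#'
#' @param x the ground-truth [pwm()] (either scale).
#' @param config a [synth_config()] (`probe_count`, `probe_length`,
#'   `noise_sd` are used).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a [probe_set()] with both intensities and labels.
#' @export
generate_probes <- function(x, config, seed = config$seed) {
  stopifnot(inherits(x, "pwm"), inherits(config, "synth_config"))
  k <- pwm_width(x)
  len <- config$probe_length
  if (len < k) stop_input("'probe_length' must be >= the PWM width")
  n <- config$probe_count
  prob <- unclass(pwm_convert_scale(x, "probability"))
  with_seed(seed, {
    mat <- matrix(sample.int(4, n * len, replace = TRUE), n, len)
    n_planted <- n %/% 2
    if (n_planted > 0) {
      starts <- sample.int(len - k + 1, n_planted, replace = TRUE)
      for (l in seq_len(k)) {
        bases <- sample.int(4, n_planted, replace = TRUE, prob = prob[, l])
        mat[cbind(seq_len(n_planted), starts + l - 1)] <- bases
      }
    }
    seqs <- apply(mat, 1, function(r) paste(RNA_BASES[r], collapse = ""))
    y <- score_probeset(x, seqs, convert = TRUE)
    intensities <- y + rnorm(n, 0, config$noise_sd)
    labels <- c(rep(1L, n_planted), rep(0L, n - n_planted))
    probe_set(seqs, intensities = intensities, labels = labels)
  })
}
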