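#' Synthetic-data generators with planted ground truth
#'
#' Every generator here is seeded and deterministic: identical configuration
#' plus seed yields bit-identical output. Each records the parameters it drew
#' from (`truth` attribute or column), so recovery tests close the loop
#' between generator and fitter without any laboratory data.
#'
#' Defaults encode the reference assay design: 8 equilibration steps per
#' saturation curve (protocols use 5-8), triplicate replicates, saturation
#' noise sd 0.01, 90-hour autoxidation series sampled hourly.
#'
#' @name simulate
NULL

#' Generate Hill-shaped O2 saturation curves
#'
#' PO2 steps are log-spaced over `[p50/8, 8 * p50]` (the measurable sweep
#' around the midpoint); Gaussian noise on saturation is clipped to `[0, 1]`
#' and clipping events are counted in the `clipped` attribute.
#'
#' @param p50,n50 vectors of true parameters, recycled to equal length; one
#'   genotype/curve family per entry.
#' @param genotypes labels per family; defaults to `g1, g2, ...`.
#' @param steps equilibration steps per curve (5-8 in the reference design).
#' @param noise_sd Gaussian saturation noise sd.
#' @param replicates replicate curves per family.
#' @param seed integer seed (mandatory; determinism is a contract).
#' @return list of [saturation_curve()] objects with a `truth` data.frame
#'   attribute (`genotype`, `p50`, `n50`) and a `clipped` count.
#' @export
gen_saturation_curves <- function(p50, n50, genotypes = NULL, steps = 8L,
                                  noise_sd = 0.01, replicates = 3L, seed) {
  if (missing(seed)) stop_hb("config", "seed is mandatory")
  if (steps < 5L || steps > 8L)
    stop_hb("config", "steps must be in 5..8 (assay design)")
  if (noise_sd < 0) stop_hb("config", "noise_sd must be >= 0")
  k <- max(length(p50), length(n50))
  p50 <- rep_len(p50, k)
  n50 <- rep_len(n50, k)
  if (is.null(genotypes)) genotypes <- paste0("g", seq_len(k))
  set.seed(seed)
  curves <- list()
  clipped <- 0L
  for (i in seq_len(k)) {
    po2 <- exp(seq(log(p50[i] / 8), log(8 * p50[i]), length.out = steps))
    for (r in seq_len(replicates)) {
      y <- hill_saturation(po2, p50[i], n50[i]) +
        stats::rnorm(steps, 0, noise_sd)
      clipped <- clipped + sum(y < 0 | y > 1)
      y <- pmin(pmax(y, 0), 1)
      curves[[length(curves) + 1L]] <-
        saturation_curve(po2, y, genotype = genotypes[i],
                         treatment = "stripped", replicate_id = r)
    }
  }
  structure(curves,
            truth = data.frame(genotype = genotypes, p50 = p50, n50 = n50,
                               stringsAsFactors = FALSE),
            clipped = clipped)
}

gen_exponential_traces <- function(rate, kind, genotypes, times, offset,
                                   amplitude, noise_sd, replicates, seed) {
  set.seed(seed)
  k <- length(rate)
  traces <- list()
  for (i in seq_len(k)) for (r in seq_len(replicates)) {
    y <- offset + amplitude * exp(-rate[i] * times) +
      stats::rnorm(length(times), 0, noise_sd)
    traces[[length(traces) + 1L]] <-
      kinetic_trace(times, y, kind = kind, genotype = genotypes[i],
                    replicate_id = r)
  }
  structure(traces,
            truth = data.frame(genotype = genotypes, rate = rate,
                               offset = offset, amplitude = amplitude,
                               stringsAsFactors = FALSE))
}

#' Generate stopped-flow dissociation traces
#'
#' Monoexponential decays `offset + amplitude * exp(-rate * t)` with Gaussian
#' noise; times in seconds.
#'
#' @param rate true rates, `s^-1`.
#' @param genotypes labels per rate.
#' @param duration_s,points time grid: `points` samples over `[0, duration_s]`.
#' @param offset,amplitude signal parameters.
#' @param noise_sd Gaussian noise sd on the signal.
#' @param replicates traces per genotype.
#' @param seed integer seed.
#' @return list of [kinetic_trace()] with `truth` attribute.
#' @export
gen_kinetic_traces <- function(rate, genotypes = paste0("g", seq_along(rate)),
                               duration_s = 3, points = 50L, offset = 0.1,
                               amplitude = 0.5, noise_sd = 0.005,
                               replicates = 3L, seed) {
  if (missing(seed)) stop_hb("config", "seed is mandatory")
  gen_exponential_traces(rate, "dissociation", genotypes,
                         seq(0, duration_s, length.out = points),
                         offset, amplitude, noise_sd, replicates, seed)
}

#' Generate autoxidation A541/A630 ratio series
#'
#' Decaying ratio series per genotype over a 90-hour window at 1-hour
#' sampling, the reference assay design; rates in `h^-1`. Defaults for the
#' planted rates are the shipped 11-genotype autoxidation fixture, so the
#' default call emulates the full recombinant-Hb panel.
#'
#' @param rate true rates, `h^-1`; default the shipped fixture's 11 rates.
#' @param genotypes labels per rate.
#' @param duration_h,interval_h sampling window and spacing, hours.
#' @param offset,amplitude ratio-signal parameters.
#' @param noise_sd Gaussian noise sd on the ratio.
#' @param replicates series per genotype.
#' @param seed integer seed.
#' @return list of [kinetic_trace()] with `truth` attribute.
#' @export
gen_autoxidation_series <- function(rate = NULL, genotypes = NULL,
                                    duration_h = 90, interval_h = 1,
                                    offset = 0.6, amplitude = 2.4,
                                    noise_sd = 0.01, replicates = 3L, seed) {
  if (missing(seed)) stop_hb("config", "seed is mandatory")
  if (is.null(rate)) {
    fx <- goose_kauto_fixture()
    rate <- fx$mean
    genotypes <- fx$genotype
  }
  if (is.null(genotypes)) genotypes <- paste0("g", seq_along(rate))
  gen_exponential_traces(rate, "autoxidation", genotypes,
                         seq(0, duration_h, by = interval_h),
                         offset, amplitude, noise_sd, replicates, seed)
}

#' Generate a genotype-phenotype landscape with planted epistasis
#'
#' Per replicate, the log10 trait value of genotype `g` is
#' `baseline + sum(site effects over derived states) +
#' sum(pairwise epistasis over derived pairs) + Gaussian(0, noise_sd_log10)`;
#' the table stores per-genotype mean, SEM and n of the raw-scale trait.
#'
#' @param sites an [hb_sites()] set (2-4 sites typical).
#' @param effects named numeric: additive log10 effect of each site's derived
#'   state; names must be the site labels.
#' @param epistasis named numeric of log10 interaction terms, names like
#'   `"siteA:siteB"` (pairwise; higher orders like `"a:b:c"` are accepted
#'   too); a term applies when all named sites carry the derived state.
#'   Default none.
#' @param baseline_log10 log10 trait value of the all-ancestral genotype.
#' @param noise_sd_log10 replicate noise sd on the log10 scale (0.02 default,
#'   the scale of replicate SEs in the reference panel).
#' @param replicates replicates per genotype.
#' @param trait trait name for the table.
#' @param seed integer seed.
#' @return a [gp_table()] with a `truth` attribute holding the generating
#'   parameters.
#' @export
gen_landscape <- function(sites, effects, epistasis = numeric(0),
                          baseline_log10 = log10(4.3), noise_sd_log10 = 0.02,
                          replicates = 3L, trait = "trait", seed) {
  if (missing(seed)) stop_hb("config", "seed is mandatory")
  stopifnot(inherits(sites, "hb_sites"))
  if (!setequal(names(effects), sites$label))
    stop_hb("config", "effects must be named by the site labels")
  if (length(epistasis)) {
    pairs <- strsplit(names(epistasis), ":", fixed = TRUE)
    ok <- vapply(pairs, function(p) length(p) >= 2L &&
                   !anyDuplicated(p) && all(p %in% sites$label), logical(1))
    if (!all(ok))
      stop_hb("config", "epistasis names must be ':'-joined distinct known sites")
  }
  set.seed(seed)
  gts <- enumerate_genotypes(sites)
  rows <- lapply(gts$code, function(code) {
    bits <- code_to_bits(code, sites)
    mu <- baseline_log10 + sum(effects[sites$label][bits == 1L])
    if (length(epistasis)) for (p in seq_along(epistasis)) {
      pr <- strsplit(names(epistasis)[p], ":", fixed = TRUE)[[1]]
      if (all(bits[match(pr, sites$label)] == 1L))
        mu <- mu + epistasis[[p]]
    }
    reps <- 10^(mu + stats::rnorm(replicates, 0, noise_sd_log10))
    data.frame(genotype = code, trait = trait, mean = mean(reps),
               sem = if (replicates > 1L)
                 stats::sd(reps) / sqrt(replicates) else NA_real_,
               n = replicates, stringsAsFactors = FALSE)
  })
  tab <- gp_table(do.call(rbind, rows), sites)
  attr(tab, "truth") <- list(baseline_log10 = baseline_log10,
                             effects = effects, epistasis = epistasis,
                             noise_sd_log10 = noise_sd_log10,
                             replicates = replicates)
  tab
}

#' Generate a rooted tree and site-state matrix with a planted history
#'
#' Draws a random rooted binary tree and, per site, plants at most one
#' ancestral-to-derived substitution on a randomly chosen branch (tips below
#' that branch carry the derived state). The planted branch per site is the
#' recorded ground truth against which parsimony recovery is tested.
#'
#' @param n_tips number of tips (>= 4).
#' @param sites an [hb_sites()] set; one matrix column per site.
#' @param n_substitutions substitutions to plant per site: 0 (invariant) or 1.
#' @param seed integer seed.
#' @return list: `tree` (ape phylo), `matrix` ([site_state_matrix()]),
#'   `truth` (data.frame site / branch child node id / clade tips).
#' @export
gen_site_state_matrix <- function(n_tips, sites, n_substitutions = 1L, seed) {
  if (missing(seed)) stop_hb("config", "seed is mandatory")
  if (n_tips < 4L) stop_hb("config", "need >= 4 tips")
  set.seed(seed)
  tree <- ape::rtree(n_tips, rooted = TRUE,
                     tip.label = paste0("t", seq_len(n_tips)))
  ntip <- length(tree$tip.label)
  m <- matrix(rep(sites$ancestral, each = ntip), nrow = ntip,
              dimnames = list(tree$tip.label, sites$label))
  truth <- list()
  if (n_substitutions > 0L) {
    for (s in seq_len(nrow(sites))) {
      ## candidate branches whose clade is a strict, non-empty tip subset
      clade_tips <- lapply(seq_len(nrow(tree$edge)), function(e) {
        ch <- tree$edge[e, 2L]
        if (ch <= ntip) tree$tip.label[ch]
        else ape::extract.clade(tree, ch)$tip.label
      })
      ## exclude branches hanging off the root: without ancestral-state
      ## context above, parsimony cannot polarize the planted change
      root <- ntip + 1L
      ok <- vapply(clade_tips, function(tp)
        length(tp) >= 1L && length(tp) < ntip, logical(1)) &
        tree$edge[, 1L] != root
      e <- sample(which(ok), 1L)
      m[clade_tips[[e]], sites$label[s]] <- sites$derived[s]
      truth[[length(truth) + 1L]] <- data.frame(
        site = sites$label[s], child = tree$edge[e, 2L],
        clade = paste(clade_tips[[e]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  list(tree = tree, matrix = site_state_matrix(m),
       truth = if (length(truth)) do.call(rbind, truth)
       else data.frame(site = character(0), child = integer(0),
                       clade = character(0)))
}
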