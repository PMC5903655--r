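#' Genotype-phenotype table
#'
#' The hypercube substrate: per-genotype trait summaries (mean, SEM, replicate
#' count) for one or more traits, keyed by genotype code over an [hb_sites()]
#' set. Ratio-scale traits (P50, rates) must have positive means because
#' effects are defined on the log10 scale.
#'
#' @param data a `data.frame` with columns `genotype`, `trait`, `mean`, `sem`,
#'   `n` (long form; one row per genotype x trait).
#' @param sites the [hb_sites()] set the genotype codes are written over.
#' @return `data` with class `"gp_table"` and the site set attached as
#'   attribute `"sites"`.
#' @export
gp_table <- function(data, sites) {
  stopifnot(inherits(sites, "hb_sites"))
  need <- c("genotype", "trait", "mean", "sem", "n")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_hb("invalid_parameter", "gp_table is missing columns: ",
            paste(miss, collapse = ", "))
  invisible(lapply(unique(data$genotype), code_to_bits, sites = sites))
  if (anyDuplicated(data[, c("genotype", "trait")]))
    stop_hb("invalid_parameter", "duplicate genotype x trait rows")
  structure(as.data.frame(data), sites = sites,
            class = c("gp_table", "data.frame"))
}

gp_sites <- function(table) attr(table, "sites")

## row lookup; loud, names the genotype code as the error message
gp_row <- function(table, code, trait) {
  i <- which(table$genotype == code & table$trait == trait)
  if (length(i) != 1L)
    stop_hb("missing_data", "no row for genotype '", code, "', trait '",
            trait, "'")
  as.list(table[i, c("mean", "sem", "n")])
}

gp_mean <- function(table, code, trait) {
  m <- gp_row(table, code, trait)$mean
  if (!is.finite(m) || m <= 0)
    stop_hb("invalid_parameter", "trait '", trait, "' mean for '", code,
            "' must be positive for log-scale effects")
  m
}

## Welch's two-sample t from summary stats; s_i^2/n_i enters as sem_i^2
welch_from_summary <- function(m1, se1, n1, m2, se2, n2) {
  v <- se1^2 + se2^2
  if (!is.finite(v) || v <= 0 || n1 < 2 || n2 < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  t <- (m2 - m1) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Effect of one mutation on one genetic background
#'
#' The background genotype must carry the ancestral state at `site`; the
#' effect compares it with its single-site derived neighbour. The primary
#' effect size is `delta_log10 = log10(mean_derived) - log10(mean_background)`
#' (log effects telescope along pathways); `percent_change` is the signed raw
#' percent companion, `100 * (10^delta_log10 - 1)` (an 18% reduction prints as
#' -17.9). Significance is a Welch two-sample t-test reconstructed from
#' (mean, SEM, n) with Welch-Satterthwaite degrees of freedom, two-tailed.
#'
#' @param table a [gp_table()] holding both genotypes.
#' @param site site label to mutate (ancestral -> derived).
#' @param background genotype code carrying the ancestral state at `site`.
#' @param trait trait name.
#' @param alpha significance level for the `significant` flag.
#' @return list of class `"mutation_effect"`: `site`, `from`, `to`,
#'   `delta_log10`, `percent_change`, `welch_t`, `welch_df`, `p_value`,
#'   `significant`.
#' @export
mutation_effect <- function(table, site, background, trait, alpha = 0.05) {
  sites <- gp_sites(table)
  i <- site_index(site, sites)
  bits <- code_to_bits(background, sites)
  if (bits[i] != 0L)
    stop_hb("invalid_site_state", "background '", background,
            "' already carries the derived state at ", site)
  to <- bits_to_code(replace(bits, i, 1L), sites)
  a <- gp_row(table, background, trait)
  d <- gp_row(table, to, trait)
  if (!is.finite(a$mean) || a$mean <= 0 || !is.finite(d$mean) || d$mean <= 0)
    stop_hb("invalid_parameter", "trait means must be positive (", background,
            " -> ", to, ", ", trait, ")")
  delta <- log10(d$mean) - log10(a$mean)
  w <- welch_from_summary(a$mean, a$sem, a$n, d$mean, d$sem, d$n)
  structure(list(site = site, from = background, to = to, trait = trait,
                 delta_log10 = delta,
                 percent_change = 100 * (10^delta - 1),
                 welch_t = w$t, welch_df = w$df, p_value = w$p,
                 significant = is.finite(w$p) && w$p < alpha),
            class = "mutation_effect")
}

#' Fill a pathway with per-step mutation effects
#'
#' Walks one site-acquisition order from the all-ancestral to the all-derived
#' genotype, computing a [mutation_effect()] at every step. Step
#' `delta_log10` values telescope: their sum equals
#' `log10(derived mean) - log10(ancestral mean)` exactly.
#'
#' @param table a [gp_table()] with the full hypercube for `trait`.
#' @param order character vector: a permutation of the site labels.
#' @param trait trait name.
#' @return list of class `"hb_pathway"` with `order`, `steps` (list of
#'   mutation effects), `genotypes` (the k+1 codes visited) and `means`
#'   (trait means along the walk).
#' @export
pathway_trajectory <- function(table, order, trait) {
  sites <- gp_sites(table)
  if (!setequal(order, sites$label) || length(order) != n_sites(sites))
    stop_hb("invalid_parameter", "order must be a permutation of the site labels")
  code <- ancestral_code(sites)
  codes <- code
  steps <- vector("list", length(order))
  for (s in seq_along(order)) {
    eff <- mutation_effect(table, order[s], code, trait)
    steps[[s]] <- eff
    code <- eff$to
    codes <- c(codes, code)
  }
  structure(list(order = order, steps = steps, genotypes = codes,
                 means = vapply(codes, gp_mean, numeric(1),
                                table = table, trait = trait),
                 trait = trait),
            class = "hb_pathway")
}

#' @export
print.hb_pathway <- function(x, ...) {
  cat("Pathway:", paste(x$order, collapse = " -> "), "\n")
  cat(" ", paste(sprintf("%s (%.3g)", x$genotypes, x$means), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Largest-effect step in every forward pathway
#'
#' For each of the `k!` forward pathways, identifies the step whose
#' `delta_log10` is largest in the declared direction (most negative for
#' `direction = "decrease"`, most positive for `"increase"`), and tallies
#' winners per site. Ties within `tie_tol` are reported explicitly - both
#' sites are listed and the pathway is marked tied - never silently broken.
#'
#' @param table a [gp_table()] with the full hypercube.
#' @param trait trait name.
#' @param direction `"decrease"` or `"increase"`: what counts as the effect
#'   of interest (affinity gains are P50 decreases).
#' @param tie_tol absolute `delta_log10` tolerance within which steps tie.
#' @return list of class `"largest_effect_summary"`: `per_pathway`
#'   (data.frame pathway / winner(s) / first_step / delta / tied) and
#'   `counts` (named winner tally per site; tied pathways counted under every
#'   tying site and flagged).
#' @export
rank_largest_effect <- function(table, trait, direction = c("decrease", "increase"),
                                tie_tol = 1e-12) {
  direction <- match.arg(direction)
  sites <- gp_sites(table)
  paths <- enumerate_pathways(sites)
  sgn <- if (direction == "decrease") -1 else 1
  rows <- lapply(seq_along(paths), function(i) {
    pw <- pathway_trajectory(table, paths[[i]], trait)
    deltas <- vapply(pw$steps, `[[`, numeric(1), "delta_log10")
    score <- sgn * deltas            # larger = stronger in declared direction
    best <- max(score)
    win <- which(score >= best - tie_tol)
    data.frame(pathway = paste(paths[[i]], collapse = ">"),
               winner = paste(paths[[i]][win], collapse = "|"),
               first_step = paths[[i]][1L],
               delta_log10 = deltas[win[1L]],
               tied = length(win) > 1L,
               stringsAsFactors = FALSE)
  })
  per_pathway <- do.call(rbind, rows)
  counts <- stats::setNames(integer(n_sites(sites)), sites$label)
  for (w in strsplit(per_pathway$winner, "|", fixed = TRUE))
    counts[w] <- counts[w] + 1L
  structure(list(per_pathway = per_pathway, counts = counts,
                 direction = direction, trait = trait,
                 any_ties = any(per_pathway$tied)),
            class = "largest_effect_summary")
}

#' @export
print.largest_effect_summary <- function(x, ...) {
  cat(sprintf("Largest-%s step per pathway (%s):\n", x$direction, x$trait))
  print(x$per_pathway, row.names = FALSE)
  cat("Winner counts:", paste(names(x$counts), x$counts, sep = "=",
                              collapse = ", "),
      if (x$any_ties) " (ties present)" else "", "\n")
  invisible(x)
}

#' Effect of one mutation on every genetic background
#'
#' One [mutation_effect()] per combination of states at the other `k - 1`
#' sites (`2^(k-1)` backgrounds), in hypercube enumeration order.
#'
#' @inheritParams mutation_effect
#' @return list of `"mutation_effect"` objects.
#' @export
effects_on_all_backgrounds <- function(table, site, trait, alpha = 0.05) {
  sites <- gp_sites(table)
  i <- site_index(site, sites)
  gts <- enumerate_genotypes(sites)
  backs <- gts$code[vapply(gts$code, function(g)
    code_to_bits(g, sites)[i] == 0L, logical(1))]
  lapply(backs, function(b) mutation_effect(table, site, b, trait, alpha))
}

#' Forward/reverse symmetry of a mutation's effect
#'
#' Pairs each background with its complement (states flipped at all other
#' sites) and contrasts the forward effect on one with the reversion on the
#' other. On an additive (log-scale) landscape forward and reverse effects
#' cancel; the `asymmetry` index, forward `delta_log10` plus the reverse
#' effect measured on the complementary background (equivalently
#' `forward(b) - forward(complement(b))`), is then 0 and its magnitude
#' measures how background-dependent the mutation is.
#'
#' @inheritParams mutation_effect
#' @return data.frame with one row per unordered background pair:
#'   `background`, `complement_background`, `forward_delta` (on `background`),
#'   `reverse_delta` (reverting on the derived neighbour of the complement),
#'   `asymmetry`.
#' @export
reversion_symmetry <- function(table, site, trait) {
  sites <- gp_sites(table)
  i <- site_index(site, sites)
  effs <- effects_on_all_backgrounds(table, site, trait)
  backs <- vapply(effs, `[[`, character(1), "from")
  deltas <- vapply(effs, `[[`, numeric(1), "delta_log10")
  comp <- vapply(backs, function(b) {
    bits <- code_to_bits(b, sites)
    bits[-i] <- 1L - bits[-i]
    bits_to_code(bits, sites)
  }, character(1))
  seen <- character(0)
  rows <- list()
  for (j in seq_along(backs)) {
    if (backs[j] %in% seen) next
    seen <- c(seen, backs[j], comp[j])
    jj <- match(comp[j], backs)
    rows[[length(rows) + 1L]] <- data.frame(
      background = backs[j], complement_background = comp[j],
      forward_delta = deltas[j], reverse_delta = -deltas[jj],
      asymmetry = deltas[j] - deltas[jj], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Double-mutant-cycle epistasis between two sites
#'
#' Builds the four-corner cycle (ab, Ab, aB, AB) at a fixed background for
#' the remaining sites and quantifies non-additivity on the log10 scale:
#' `epistasis_log10 = [log10(AB) - log10(aB)] - [log10(Ab) - log10(ab)]`,
#' i.e. how much the effect of mutation A changes when B is present. The
#' `compensation_ratio`, AB-corner mean over ab-corner mean, is ~1 when the
#' second mutation fully compensates the first.
#'
#' @param table a [gp_table()].
#' @param site_a,site_b the two interacting site labels.
#' @param fixed_background genotype code (any code with the required states at
#'   the remaining sites; its states at `site_a`/`site_b` are ignored).
#' @param trait trait name.
#' @return list of class `"dm_cycle"`: `corners` (named means for ab, Ab, aB,
#'   AB), `epistasis_log10`, `compensation_ratio`, plus labels.
#' @export
double_mutant_cycle <- function(table, site_a, site_b, fixed_background, trait) {
  sites <- gp_sites(table)
  ia <- site_index(site_a, sites)
  ib <- site_index(site_b, sites)
  if (ia == ib) stop_hb("invalid_parameter", "site_a and site_b must differ")
  base <- code_to_bits(fixed_background, sites)
  corner <- function(a, b) {
    bits <- base; bits[ia] <- a; bits[ib] <- b
    bits_to_code(bits, sites)
  }
  codes <- c(ab = corner(0L, 0L), Ab = corner(1L, 0L),
             aB = corner(0L, 1L), AB = corner(1L, 1L))
  means <- vapply(codes, gp_mean, numeric(1), table = table, trait = trait)
  structure(list(site_a = site_a, site_b = site_b,
                 fixed_background = bits_to_code(base, sites),
                 corners = means, corner_codes = codes, trait = trait,
                 epistasis_log10 = (log10(means[["AB"]]) - log10(means[["aB"]])) -
                   (log10(means[["Ab"]]) - log10(means[["ab"]])),
                 compensation_ratio = means[["AB"]] / means[["ab"]]),
            class = "dm_cycle")
}

#' @export
print.dm_cycle <- function(x, ...) {
  cat(sprintf("Double-mutant cycle %s x %s (%s), background %s:\n",
              x$site_a, x$site_b, x$trait, x$fixed_background))
  print(stats::setNames(x$corners, paste0(names(x$corner_codes), " (",
                                          x$corner_codes, ")")))
  cat(sprintf("epistasis (log10) = %.4g; AB/ab compensation ratio = %.3g\n",
              x$epistasis_log10, x$compensation_ratio))
  invisible(x)
}
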