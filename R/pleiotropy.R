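#' Paired trait changes for the pleiotropy screen
#'
#' Builds the (delta X, delta Y) pairs over which trait trade-offs are
#' screened. Three pairing conventions are implemented because published
#' correlation screens rarely state one, and the choice matters:
#'
#' * `"all-hypercube-edges"`: one pair per single-site edge of the hypercube
#'   (`k * 2^(k-1)` edges), deltas taken ancestral-to-derived along the edge;
#' * `"first-step-from-ancestor"`: only the `k` edges leaving the
#'   all-ancestral genotype;
#' * `"genotype-level"`: no differencing; one pair per genotype, pairing the
#'   two trait values directly.
#'
#' Ratio-scale traits enter on the log10 scale by default, matching how
#' effects are defined elsewhere in the package.
#'
#' @param table a [gp_table()] carrying both traits.
#' @param trait_x,trait_y trait names.
#' @param convention pairing rule; see above.
#' @param log10_scale take log10 of trait means (default `TRUE`).
#' @return data.frame of class `"edge_deltas"`: `from`, `to`, `site` (NA for
#'   genotype-level), `delta_x`, `delta_y`, with the convention attached as an
#'   attribute.
#' @export
edge_deltas <- function(table, trait_x, trait_y,
                        convention = c("all-hypercube-edges",
                                       "first-step-from-ancestor",
                                       "genotype-level"),
                        log10_scale = TRUE) {
  convention <- tryCatch(match.arg(convention), error = function(e)
    stop_hb("config", "unknown pairing convention: ",
            paste(convention, collapse = "/")))
  val <- function(code, trait) {
    m <- gp_mean(table, code, trait)
    if (log10_scale) log10(m) else m
  }
  if (convention == "genotype-level") {
    ## no hypercube needed: any long table with genotype/trait/mean works
    codes <- sort(unique(table$genotype))
    out <- data.frame(from = codes, to = codes, site = NA_character_,
                      delta_x = vapply(codes, val, numeric(1), trait = trait_x),
                      delta_y = vapply(codes, val, numeric(1), trait = trait_y),
                      stringsAsFactors = FALSE)
  } else {
    sites <- gp_sites(table)
    if (is.null(sites))
      stop_hb("config", "edge conventions need a gp_table with a site set")
    gts <- enumerate_genotypes(sites)$code
    rows <- list()
    for (s in sites$label) {
      i <- site_index(s, sites)
      backs <- gts[vapply(gts, function(g) code_to_bits(g, sites)[i] == 0L,
                          logical(1))]
      if (convention == "first-step-from-ancestor")
        backs <- ancestral_code(sites)
      for (b in backs) {
        to <- set_site_state(b, s, 1L, sites)
        rows[[length(rows) + 1L]] <- data.frame(
          from = b, to = to, site = s,
          delta_x = val(to, trait_x) - val(b, trait_x),
          delta_y = val(to, trait_y) - val(b, trait_y),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
  }
  structure(out, convention = convention,
            class = c("edge_deltas", "data.frame"))
}

#' Pearson correlation of paired trait changes
#'
#' Textbook Pearson r over the `(delta_x, delta_y)` pairs, with a two-tailed
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. The pairing convention travels with the result so no correlation
#' is ever reported without its provenance.
#'
#' @param deltas an [edge_deltas()] data.frame (or any data.frame with
#'   `delta_x`, `delta_y`).
#' @return list of class `"correlation_result"`: `r`, `n`, `p_value`,
#'   `convention`.
#' @export
pearson <- function(deltas) {
  x <- deltas$delta_x
  y <- deltas$delta_y
  if (length(x) < 3L)
    stop_hb("insufficient_data", "need >= 3 pairs for a correlation, got ",
            length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_hb("invalid_parameter", "non-finite values in correlation input")
  sx <- x - mean(x)
  sy <- y - mean(y)
  vx <- sum(sx^2)
  vy <- sum(sy^2)
  if (vx == 0 || vy == 0)
    stop_hb("undefined_correlation", "zero variance in one coordinate")
  r <- sum(sx * sy) / sqrt(vx * vy)
  n <- length(x)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, n = n,
                 p_value = 2 * stats::pt(-abs(tval), n - 2),
                 convention = attr(deltas, "convention")),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g%s)\n", x$r, x$n, x$p_value,
              if (is.null(x$convention)) ""
              else paste0(", convention = ", x$convention)))
  invisible(x)
}

#' Trade-off screen across traits and conventions
#'
#' Correlates changes in a focal trait against changes in every other trait,
#' under one or more pairing conventions, returning a tidy table with the
#' convention recorded per row.
#'
#' @param table a [gp_table()].
#' @param trait_x focal trait (typically intrinsic affinity, log P50).
#' @param traits_y other traits; default all remaining traits in the table.
#' @param conventions conventions to evaluate.
#' @return data.frame: `trait_x`, `trait_y`, `convention`, `r`, `n`, `p_value`.
#' @export
pleiotropy_screen <- function(table, trait_x,
                              traits_y = setdiff(unique(table$trait), trait_x),
                              conventions = c("all-hypercube-edges",
                                              "first-step-from-ancestor",
                                              "genotype-level")) {
  rows <- list()
  for (ty in traits_y) for (cv in conventions) {
    res <- tryCatch(pearson(edge_deltas(table, trait_x, ty, cv)),
                    hbcube_error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      trait_x = trait_x, trait_y = ty, convention = cv,
      r = res$r, n = res$n, p_value = res$p_value, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trait_x = character(0), trait_y = character(0),
                      convention = character(0), r = numeric(0),
                      n = integer(0), p_value = numeric(0)))
  do.call(rbind, rows)
}
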