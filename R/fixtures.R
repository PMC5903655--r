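#' Shipped goose hemoglobin fixtures
#'
#' The package ships a transcription of the published functional summary of
#' the goose recombinant-Hb panel: stripped P50 (torr, +/- SE) with anion
#' sensitivities (delta log P50 for KCl, IHP and KCl+IHP) and autoxidation
#' rates (h^-1, +/- SEM) for the wildtype bar-headed goose (`SVA`), wildtype
#' greylag goose (`SE`), their reconstructed ancestor AncAnser (`GAP` at the
#' three alpha sites, `TD` at the two beta sites) and every mutational
#' intermediate. The `alpha` system covers sites alpha18/alpha63/alpha119
#' (GAP -> SVA); the `beta` system covers beta4/beta125 (TD -> SE).
#'
#' The companion tree and state matrix (`anserinae_*_synthetic.*`) are a
#' *synthetic emulation* of the waterfowl comparison, not a transcription:
#' the published per-species matrix is not machine-readable, so the shipped
#' fixture is constructed to make the documented summary facts (ancestral
#' states and branch substitution counts) the unique parsimonious solution.
#'
#' @param system which hypercube: `"alpha"` (3 sites) or `"beta"` (2 sites).
#' @name fixtures
NULL

extdata <- function(file) {
  path <- system.file("extdata", file, package = "hbcube")
  if (!nzchar(path))
    stop_hb("missing_data", "fixture not found: ", file)
  path
}

#' @rdname fixtures
#' @return `goose_sites()`: the [hb_sites()] set for one system.
#' @export
goose_sites <- function(system = c("alpha", "beta")) {
  system <- match.arg(system)
  if (system == "alpha")
    hb_sites(c("alpha18", "alpha63", "alpha119"),
             ancestral = c("G", "A", "P"), derived = c("S", "V", "A"))
  else
    hb_sites(c("beta4", "beta125"), ancestral = c("T", "D"),
             derived = c("S", "E"))
}

read_fixture_csv <- function(file) {
  utils::read.csv(extdata(file), stringsAsFactors = FALSE,
                  comment.char = "#")
}

#' @rdname fixtures
#' @return `goose_p50_fixture()`: a [gp_table()] with traits `p50_stripped`,
#'   `dlog_kcl`, `dlog_ihp`, `dlog_kcl_ihp` over the requested hypercube.
#' @export
goose_p50_fixture <- function(system = c("alpha", "beta")) {
  system <- match.arg(system)
  wide <- read_fixture_csv("goose_p50_table.csv")
  wide <- wide[wide$system == system, ]
  long <- do.call(rbind, lapply(
    c("p50_stripped", "dlog_kcl", "dlog_ihp", "dlog_kcl_ihp"),
    function(tr) data.frame(genotype = wide$genotype, trait = tr,
                            mean = wide[[tr]],
                            sem = if (tr == "p50_stripped") wide$p50_se
                                  else NA_real_,
                            n = wide$n, stringsAsFactors = FALSE)))
  gp_table(long, goose_sites(system))
}

#' @rdname fixtures
#' @param include duplicate-protein handling for `goose_kauto_fixture`:
#'   `"panel"` returns the 11 distinct recombinant Hbs (AncAnser appears once,
#'   as `GAP`); `"alpha"`/`"beta"` return one complete hypercube.
#' @return `goose_kauto_fixture()`: data.frame `genotype`, `mean`, `sem`, `n`
#'   of autoxidation rates (h^-1), or a [gp_table()] for a single system.
#' @export
goose_kauto_fixture <- function(include = c("panel", "alpha", "beta")) {
  include <- match.arg(include)
  wide <- read_fixture_csv("goose_kauto_table.csv")
  if (include == "panel") {
    wide <- wide[wide$genotype != "TD", ]  # same protein as GAP
    return(data.frame(genotype = wide$genotype, mean = wide$k_auto,
                      sem = wide$sem, n = wide$n, stringsAsFactors = FALSE))
  }
  wide <- wide[wide$system == include, ]
  gp_table(data.frame(genotype = wide$genotype, trait = "k_auto",
                      mean = wide$k_auto, sem = wide$sem, n = wide$n,
                      stringsAsFactors = FALSE),
           goose_sites(include))
}

#' @rdname fixtures
#' @return `goose_gp_fixture()`: a [gp_table()] combining the P50 traits and
#'   `k_auto` for one hypercube system.
#' @export
goose_gp_fixture <- function(system = c("alpha", "beta")) {
  system <- match.arg(system)
  p <- goose_p50_fixture(system)
  k <- goose_kauto_fixture(system)
  gp_table(rbind(as.data.frame(p), as.data.frame(k)), goose_sites(system))
}

#' @rdname fixtures
#' @return `goose_panel_fixture()`: plain long data.frame over the 11
#'   distinct recombinant Hbs (both systems' codes) with traits
#'   `p50_stripped` and `k_auto`; the substrate for genotype-level
#'   pleiotropy pairing.
#' @export
goose_panel_fixture <- function() {
  p <- read_fixture_csv("goose_p50_table.csv")
  p <- p[p$genotype != "TD", ]
  k <- goose_kauto_fixture("panel")
  rbind(data.frame(genotype = p$genotype, trait = "p50_stripped",
                   mean = p$p50_stripped, sem = p$p50_se, n = p$n,
                   stringsAsFactors = FALSE),
        data.frame(genotype = k$genotype, trait = "k_auto", mean = k$mean,
                   sem = k$sem, n = k$n, stringsAsFactors = FALSE))
}

#' @rdname fixtures
#' @return `anserinae_fixture()`: list with the synthetic waterfowl `tree`
#'   (rooted, 14 tips) and `matrix` ([site_state_matrix()], 5 sites). The
#'   ancestral node of interest is `getMRCA(tree, c("Anser_indicus",
#'   "Anser_anser"))`.
#' @export
anserinae_fixture <- function() {
  tree <- ape::read.tree(extdata("anserinae_tree_synthetic.nwk"))
  df <- read_fixture_csv("anserinae_sites_synthetic.csv")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$taxon
  list(tree = tree, matrix = site_state_matrix(m))
}
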