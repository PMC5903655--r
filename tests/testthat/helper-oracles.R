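## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: parsimony by exhaustive enumeration, epistasis
## by an exhaustive linear solve, correlations via stats::cor.test.

## minimum change count by brute force over all internal-state assignments
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  states <- sort(unique(tip_states))
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  grid <- expand.grid(rep(list(states), length(internal)),
                      stringsAsFactors = FALSE)
  node_state <- function(v, assign) {
    if (v <= ntip) tip_states[[tree$tip.label[v]]]
    else assign[[match(v, internal)]]
  }
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- as.character(grid[r, ])
    ch <- sum(vapply(seq_len(nrow(tree$edge)), function(e)
      node_state(tree$edge[e, 1L], assign) !=
        node_state(tree$edge[e, 2L], assign), logical(1)))
    if (ch < best) best <- ch
  }
  best
}

## exhaustive fit of the full 2^k interaction model to log10 means;
## returns named coefficients (base, per-site, and ":"-joined interactions)
full_interaction_solve <- function(table, trait) {
  sites <- attr(table, "sites")
  codes <- hbcube::enumerate_genotypes(sites)$code
  m <- vapply(codes, function(g)
    log10(table$mean[table$genotype == g & table$trait == trait]), numeric(1))
  k <- nrow(sites)
  bits <- t(vapply(codes, function(g)
    as.integer(strsplit(g, "")[[1]] == sites$derived), integer(k)))
  subsets <- unlist(lapply(0:k, function(r)
    utils::combn(seq_len(k), r, simplify = FALSE)), recursive = FALSE)
  X <- vapply(subsets, function(ss)
    if (!length(ss)) rep(1, length(codes))
    else apply(bits[, ss, drop = FALSE], 1L, prod), numeric(length(codes)))
  beta <- solve(X, m)
  names(beta) <- vapply(subsets, function(ss)
    if (!length(ss)) "base" else paste(sites$label[ss], collapse = ":"),
    character(1))
  beta
}

## the exact log10 interaction decomposition of the shipped alpha-system
## stripped-P50 fixture (computed by full_interaction_solve; used to plant
## a synthetic landscape identical to the fixture)
fixture_decomposition <- function() {
  full_interaction_solve(hbcube::goose_p50_fixture("alpha"), "p50_stripped")
}

alpha_sites <- function() hbcube::goose_sites("alpha")

## small rooted trees for parsimony tests
balanced_tree4 <- function() ape::read.tree(text = "((a,b),(c,d));")

## deterministic RNG scoping so tests never leak seeds into each other
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

round_half_away <- function(x, digits = 0)
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
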