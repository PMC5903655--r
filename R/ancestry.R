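#' Taxon x site amino-acid state matrix
#'
#' @param states a matrix or data.frame of single amino-acid letters with
#'   taxa as rownames and site labels as colnames.
#' @return character matrix of class `"site_state_matrix"`.
#' @export
site_state_matrix <- function(states) {
  m <- as.matrix(states)
  mode(m) <- "character"
  m[] <- toupper(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_hb("invalid_parameter", "state matrix needs taxon rownames and site colnames")
  if (anyDuplicated(rownames(m)))
    stop_hb("invalid_parameter", "duplicate taxon names in state matrix")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(m %in% aa))
    stop_hb("invalid_parameter", "states must be single letters from the 20-letter amino-acid alphabet")
  class(m) <- c("site_state_matrix", class(m))
  m
}

## unit-cost parsimony DP over one site on a rooted ape::phylo tree.
## Returns the minimum change count and, per node, the set of states that
## occur in at least one maximally parsimonious reconstruction (MPR sets).
## Equivalent to Fitch on binary trees; exact on multifurcations too.
parsimony_dp <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  states <- sort(unique(tip_states))
  ns <- length(states)
  BIG <- 1e9

  up <- matrix(BIG, total, ns)
  for (i in seq_len(ntip))
    up[i, match(tip_states[tree$tip.label[i]], states)] <- 0

  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(edge[, 2L], edge[, 1L])

  ## up pass: visit each internal node at its *last* postorder edge, by which
  ## point every child subtree (including internal children) is complete
  parent_order <- po[!duplicated(po[, 1L], fromLast = TRUE), 1L]
  for (par in parent_order) {
    kids <- children[[as.character(par)]]
    cost <- numeric(ns)
    for (s in seq_len(ns)) {
      tot <- 0
      for (k in kids) tot <- tot + min(up[k, ] + (seq_len(ns) != s))
      cost[s] <- tot
    }
    up[par, ] <- cost
  }

  root <- ntip + 1L
  min_changes <- min(up[root, ])

  ## down pass: cost of the rest of the tree given each node's state
  down <- matrix(BIG, total, ns)
  down[root, ] <- 0
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]  # parent-before-child
  for (r in seq_len(nrow(pre))) {
    par <- pre[r, 1L]
    ch <- pre[r, 2L]
    sibs <- setdiff(children[[as.character(par)]], ch)
    sib_cost <- numeric(ns)   # indexed by parent state
    for (s in seq_len(ns)) {
      tot <- 0
      for (w in sibs) tot <- tot + min(up[w, ] + (seq_len(ns) != s))
      sib_cost[s] <- tot
    }
    for (s in seq_len(ns))
      down[ch, s] <- min(down[par, ] + sib_cost + (seq_len(ns) != s))
  }

  node_sets <- vector("list", total)
  for (v in seq_len(total)) {
    tot <- up[v, ] + down[v, ]
    node_sets[[v]] <- states[tot <= min(tot) + 1e-9]
  }
  list(states = states, min_changes = min_changes, node_sets = node_sets)
}

#' Parsimony ancestral-state reconstruction
#'
#' Minimum-change (unordered, equal-cost) reconstruction of amino-acid states
#' at internal nodes of a rooted tree, per site. Change counts and per-node
#' sets of equally parsimonious states are computed by unit-cost dynamic
#' programming, which coincides with the classic Fitch intersection/union
#' passes on binary trees and remains exact on polytomies. Ambiguous nodes
#' carry their full state set; no arbitrary resolution is ever picked.
#'
#' @param tree a rooted `ape::phylo` with unique tip labels (>= 3 tips).
#' @param matrix a [site_state_matrix()] covering every tip.
#' @param sites site label(s) to reconstruct; default all columns.
#' @return object of class `"ancestral_reconstruction"`: per site, the
#'   minimum change count and a list of per-node state sets (ape node
#'   numbering: tips `1..n`, root `n+1`); plus the tree.
#' @export
fitch_parsimony <- function(tree, matrix, sites = colnames(matrix)) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop_hb("invalid_parameter", "tree must be rooted")
  if (length(tree$tip.label) < 3L)
    stop_hb("invalid_parameter", "need >= 3 tips for meaningful polarization")
  if (anyDuplicated(tree$tip.label))
    stop_hb("invalid_parameter", "tip names must be unique")
  missing <- setdiff(tree$tip.label, rownames(matrix))
  if (length(missing))
    stop_hb("missing_taxon", "tips absent from the state matrix: ",
            paste(missing, collapse = ", "))
  bad <- setdiff(sites, colnames(matrix))
  if (length(bad))
    stop_hb("invalid_parameter", "unknown sites: ", paste(bad, collapse = ", "))

  per_site <- lapply(sites, function(s) {
    tip_states <- stats::setNames(matrix[tree$tip.label, s], tree$tip.label)
    parsimony_dp(tree, tip_states)
  })
  names(per_site) <- sites
  structure(list(tree = tree, sites = sites, per_site = per_site),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction on %d tips, %d site(s):\n",
              length(x$tree$tip.label), length(x$sites)))
  for (s in x$sites)
    cat(sprintf("  %s: %d change(s), root states {%s}\n", s,
                x$per_site[[s]]$min_changes,
                paste(x$per_site[[s]]$node_sets[[length(x$tree$tip.label) + 1L]],
                      collapse = ",")))
  invisible(x)
}

#' Assign substitutions to branches
#'
#' A substitution is asserted on a branch only where the parent's and child's
#' equally-parsimonious state sets are disjoint (every maximally parsimonious
#' reconstruction changes state there); it is reported as `from -> to` when
#' both sets are singletons and flagged ambiguous otherwise.
#'
#' @param reconstruction a [fitch_parsimony()] result.
#' @return data.frame with one row per branch x site where a change is
#'   required: `parent`, `child` (ape node ids), `child_label` (tip name or
#'   `node<N>`), `site`, `from`, `to` (NA when ambiguous), `ambiguous`.
#' @export
assign_branches <- function(reconstruction) {
  tree <- reconstruction$tree
  ntip <- length(tree$tip.label)
  rows <- list()
  for (s in reconstruction$sites) {
    sets <- reconstruction$per_site[[s]]$node_sets
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]
      ch <- tree$edge[e, 2L]
      ps <- sets[[par]]
      cs <- sets[[ch]]
      if (length(intersect(ps, cs)) > 0L) next   # some MPR has no change here
      amb <- length(ps) > 1L || length(cs) > 1L
      rows[[length(rows) + 1L]] <- data.frame(
        parent = par, child = ch,
        child_label = if (ch <= ntip) tree$tip.label[ch] else paste0("node", ch),
        site = s,
        from = if (amb) NA_character_ else ps,
        to = if (amb) NA_character_ else cs,
        ambiguous = amb, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(parent = integer(0), child = integer(0),
                      child_label = character(0), site = character(0),
                      from = character(0), to = character(0),
                      ambiguous = logical(0)))
  do.call(rbind, rows)
}

#' Extract an ancestral genotype from a reconstruction
#'
#' @param reconstruction a [fitch_parsimony()] result covering `sites`.
#' @param node internal node: an ape node id, or a character vector of tip
#'   names whose most recent common ancestor is taken.
#' @param sites site labels, in genotype-code order.
#' @return the ancestral genotype code (e.g. `"GAP"`); errors if any queried
#'   state set is not a resolved singleton.
#' @export
ancestral_genotype <- function(reconstruction, node, sites = reconstruction$sites) {
  tree <- reconstruction$tree
  if (is.character(node)) node <- ape::getMRCA(tree, node)
  states <- vapply(sites, function(s) {
    set <- reconstruction$per_site[[s]]$node_sets[[node]]
    if (length(set) != 1L)
      stop_hb("unresolved_state", "node ", node, " is ambiguous at site ", s,
              ": {", paste(set, collapse = ","), "}")
    set
  }, character(1))
  paste(states, collapse = "")
}

#' Annotate a tree with per-branch substitution counts
#'
#' @param reconstruction a [fitch_parsimony()] result.
#' @return the tree with `node.label`/`edge` untouched and an added
#'   `substitutions` data.frame attribute; also returns newick text with
#'   branch substitution counts as comments via [write_branch_table()].
#' @keywords internal
branch_substitution_counts <- function(reconstruction) {
  br <- assign_branches(reconstruction)
  if (!nrow(br)) return(br)
  stats::aggregate(site ~ parent + child + child_label, data = br, FUN = length)
}
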