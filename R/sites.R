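#' Define a set of biallelic amino-acid sites
#'
#' A site set declares, for each variable position, a label (e.g. `"alpha119"`),
#' the ancestral one-letter state and the derived one-letter state. Genotypes
#' over the set are coded as concatenated state letters in site order, so with
#' sites alpha18/alpha63/alpha119 the ancestral genotype is `"GAP"` and the
#' fully derived one `"SVA"`.
#'
#' @param label character vector of unique site labels, in the order used by
#'   genotype codes.
#' @param ancestral,derived one-letter amino-acid states per site; must differ
#'   within each site.
#' @return A `data.frame` of class `"hb_sites"` with columns `label`,
#'   `ancestral`, `derived`.
#' @examples
#' hb_sites(c("alpha18", "alpha63", "alpha119"),
#'          ancestral = c("G", "A", "P"), derived = c("S", "V", "A"))
#' @export
hb_sites <- function(label, ancestral, derived) {
  label <- as.character(label)
  ancestral <- toupper(as.character(ancestral))
  derived <- toupper(as.character(derived))
  if (length(label) < 1L)
    stop_hb("invalid_sites", "at least one site is required")
  if (anyDuplicated(label))
    stop_hb("invalid_sites", "duplicate site labels: ",
            paste(unique(label[duplicated(label)]), collapse = ", "))
  if (length(ancestral) != length(label) || length(derived) != length(label))
    stop_hb("invalid_sites", "ancestral/derived must match the number of labels")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(c(ancestral, derived) %in% aa))
    stop_hb("invalid_sites", "states must be single letters from the 20-letter amino-acid alphabet")
  if (any(ancestral == derived))
    stop_hb("invalid_sites", "ancestral and derived states must differ at every site")
  structure(data.frame(label = label, ancestral = ancestral, derived = derived,
                       stringsAsFactors = FALSE),
            class = c("hb_sites", "data.frame"))
}

#' @export
print.hb_sites <- function(x, ...) {
  cat(sprintf("Biallelic site set: %d site(s), %s -> %s\n", nrow(x),
              ancestral_code(x), derived_code(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

n_sites <- function(sites) nrow(sites)

#' @rdname hb_sites
#' @param sites an `hb_sites` object.
#' @export
ancestral_code <- function(sites) paste(sites$ancestral, collapse = "")

#' @rdname hb_sites
#' @export
derived_code <- function(sites) paste(sites$derived, collapse = "")

## 0/1 vector (derived = 1) for a genotype code, validating every state
code_to_bits <- function(code, sites) {
  st <- strsplit(toupper(code), "")[[1]]
  if (length(st) != n_sites(sites))
    stop_hb("invalid_genotype", "genotype code '", code, "' has length ",
            length(st), ", expected ", n_sites(sites))
  bits <- integer(length(st))
  for (i in seq_along(st)) {
    if (st[i] == sites$derived[i]) bits[i] <- 1L
    else if (st[i] != sites$ancestral[i])
      stop_hb("invalid_genotype", "state '", st[i], "' at site ",
              sites$label[i], " is neither ancestral ('", sites$ancestral[i],
              "') nor derived ('", sites$derived[i], "') in code '", code, "'")
  }
  bits
}

bits_to_code <- function(bits, sites) {
  paste(ifelse(bits == 1L, sites$derived, sites$ancestral), collapse = "")
}

site_index <- function(site, sites) {
  i <- match(site, sites$label)
  if (is.na(i))
    stop_hb("invalid_sites", "unknown site label: ", site)
  i
}

## single-site neighbour of `code` with `state` (0/1) forced at `site`
set_site_state <- function(code, site, bit, sites) {
  b <- code_to_bits(code, sites)
  b[site_index(site, sites)] <- bit
  bits_to_code(b, sites)
}

#' Enumerate the genotype hypercube
#'
#' Returns all `2^k` genotypes over a biallelic site set, in deterministic
#' binary/lexicographic order (ancestral state sorts first at every site, so
#' the ancestral genotype is first and the fully derived genotype last). The
#' `2^k - 2` genotypes that are neither endpoint are the mutational
#' intermediates connecting ancestor and descendant.
#'
#' @param sites an [hb_sites()] set with `1 <= k <= 16` sites.
#' @return A `data.frame` with columns `code` (genotype string) and
#'   `n_derived` (number of derived states carried).
#' @examples
#' s <- hb_sites(c("alpha18", "alpha63", "alpha119"),
#'               c("G", "A", "P"), c("S", "V", "A"))
#' enumerate_genotypes(s)  # 8 genotypes, 6 intermediates
#' @export
enumerate_genotypes <- function(sites) {
  k <- n_sites(sites)
  if (k > 16L)
    stop_hb("size_limit", "hypercube enumeration limited to 16 sites (2^k growth)")
  grid <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  ## expand.grid varies the first factor fastest; reversed columns give
  ## binary counting order with the first site most significant
  codes <- apply(grid, 1L, bits_to_code, sites = sites)
  data.frame(code = codes, n_derived = rowSums(grid), stringsAsFactors = FALSE)
}

#' Enumerate forward mutational pathways
#'
#' A forward pathway is an ordering in which the `k` derived states are
#' acquired, so there are `k!` pathways between the ancestral and fully
#' derived genotypes.
#'
#' @inheritParams enumerate_genotypes
#' @return A list of character vectors, each a permutation of the site labels,
#'   in deterministic lexicographic order of site indices.
#' @examples
#' s <- hb_sites(c("a", "b"), c("T", "D"), c("S", "E"))
#' enumerate_pathways(s)
#' @export
enumerate_pathways <- function(sites) {
  k <- n_sites(sites)
  if (k > 8L)
    stop_hb("size_limit", "pathway enumeration limited to 8 sites (k! growth)")
  perms <- permutations_lex(k)
  lapply(seq_len(nrow(perms)), function(i) sites$label[perms[i, ]])
}

## all permutations of 1..k in lexicographic order (k! rows)
permutations_lex <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_lex(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

## classed conditions so callers/tests can catch specific failure kinds
stop_hb <- function(class, ...) {
  stop(errorCondition(paste0(...),
                      class = c(paste0("hbcube_", class), "hbcube_error",
                                "error", "condition")))
}
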