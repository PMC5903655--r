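test_that("invariant sites reconstruct with zero changes", {
  tree <- balanced_tree4()
  m <- site_state_matrix(matrix("T", 4, 1, dimnames = list(letters[1:4], "s1")))
  rec <- fitch_parsimony(tree, m)
  expect_equal(rec$per_site$s1$min_changes, 0)
  expect_identical(rec$per_site$s1$node_sets[[5]], "T")  # root
  expect_equal(nrow(assign_branches(rec)), 0)
})

test_that("change counts equal brute-force enumeration on trees <= 8 tips", {
  set.seed(42)
  for (rep in 1:12) {
    ntip <- sample(4:8, 1)
    tree <- ape::rtree(ntip, tip.label = paste0("t", 1:ntip))
    nstates <- sample(2:3, 1)
    states <- sample(c("A", "G", "S", "V", "P", "T"), nstates)
    tip_states <- stats::setNames(sample(states, ntip, replace = TRUE),
                                  tree$tip.label)
    m <- site_state_matrix(matrix(tip_states, ncol = 1,
                                  dimnames = list(tree$tip.label, "s1")))
    rec <- fitch_parsimony(tree, m)
    expect_equal(rec$per_site$s1$min_changes,
                 brute_force_parsimony(tree, tip_states),
                 info = paste("case", rep))
  }
})

test_that("the waterfowl emulation polarizes all five substitutions", {
  fx <- anserinae_fixture()
  rec <- fitch_parsimony(fx$tree, fx$matrix)
  anc <- c("Anser_indicus", "Anser_anser")
  expect_identical(ancestral_genotype(rec, anc,
                                      c("alpha18", "alpha63", "alpha119")),
                   "GAP")
  expect_identical(ancestral_genotype(rec, anc, c("beta4", "beta125")), "TD")
  ## every site changes exactly once
  expect_true(all(vapply(rec$per_site, `[[`, numeric(1), "min_changes") == 1))
  br <- assign_branches(rec)
  expect_false(any(br$ambiguous))
  on_indicus <- br[br$child_label == "Anser_indicus", ]
  expect_setequal(on_indicus$site, c("alpha18", "alpha63", "alpha119"))
  ## the two beta substitutions sit on one internal branch: the stem of the
  ## Anser clade minus A. indicus
  stem <- br[br$site %in% c("beta4", "beta125"), ]
  expect_equal(length(unique(stem$child)), 1)
  stem_clade <- ape::extract.clade(fx$tree, unique(stem$child))$tip.label
  expect_setequal(stem_clade, c("Anser_anser", "Anser_cygnoides",
                                "Anser_fabalis", "Anser_albifrons",
                                "Anser_erythropus"))
  expect_identical(unique(paste(stem$from, stem$to)), c("T S", "D E"))
})

test_that("planted single-origin substitutions are recovered exactly", {
  s <- hb_sites(c("x", "y"), c("G", "T"), c("S", "E"))
  for (seed in c(7, 19, 33)) {
    sim <- gen_site_state_matrix(n_tips = 12, sites = s, seed = seed)
    rec <- fitch_parsimony(sim$tree, sim$matrix)
    br <- assign_branches(rec)
    for (i in seq_len(nrow(sim$truth))) {
      hit <- br[br$site == sim$truth$site[i], ]
      expect_equal(rec$per_site[[sim$truth$site[i]]]$min_changes, 1)
      expect_equal(hit$child, sim$truth$child[i])
      expect_false(hit$ambiguous)
    }
  }
  ## zero planted substitutions: invariant matrix, empty branch table
  inv <- gen_site_state_matrix(12, s, n_substitutions = 0, seed = 7)
  expect_equal(nrow(assign_branches(fitch_parsimony(inv$tree, inv$matrix))), 0)
})

test_that("duplicating a taxon never changes the change count", {
  fx <- anserinae_fixture()
  txt <- ape::write.tree(fx$tree)
  txt2 <- sub("Anser_fabalis", "(Anser_fabalis,Anser_fabalis_dup)", txt,
              fixed = TRUE)
  tree2 <- ape::read.tree(text = txt2)
  m2 <- rbind(fx$matrix, Anser_fabalis_dup = fx$matrix["Anser_fabalis", ])
  rec1 <- fitch_parsimony(fx$tree, fx$matrix)
  rec2 <- fitch_parsimony(tree2, site_state_matrix(m2))
  for (s in rec1$sites)
    expect_equal(rec2$per_site[[s]]$min_changes,
                 rec1$per_site[[s]]$min_changes)
})

test_that("ambiguous placements are flagged, not asserted", {
  ## polytomy whose parsimonious state set {A,G} excludes the deviant tip's
  ## T: the terminal-branch change is certain but its from-state is not
  tree <- ape::read.tree(text = "((a,b,c,d,e),(o1,o2));")
  m <- site_state_matrix(matrix(c("A", "A", "G", "G", "T", "A", "G"),
                                ncol = 1,
                                dimnames = list(c(letters[1:5], "o1", "o2"),
                                                "s1")))
  rec <- fitch_parsimony(tree, m)
  expect_equal(rec$per_site$s1$min_changes, 4)
  poly <- ape::getMRCA(tree, letters[1:5])
  expect_setequal(rec$per_site$s1$node_sets[[poly]], c("A", "G"))
  br <- assign_branches(rec)
  row_e <- br[br$child_label == "e", ]
  expect_true(row_e$ambiguous)
  expect_true(is.na(row_e$from))
  expect_error(ancestral_genotype(rec, poly, "s1"),
               class = "hbcube_unresolved_state")
})

test_that("input validation names the offending taxa", {
  fx <- anserinae_fixture()
  m <- fx$matrix[rownames(fx$matrix) != "Chen_rossii", ]
  err <- tryCatch(fitch_parsimony(fx$tree, site_state_matrix(m)),
                  hbcube_missing_taxon = function(e) conditionMessage(e))
  expect_match(err, "Chen_rossii")
  expect_error(fitch_parsimony(ape::unroot(fx$tree), fx$matrix),
               class = "hbcube_invalid_parameter")
})
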