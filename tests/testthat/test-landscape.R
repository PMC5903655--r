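test_that("hypercube and pathway enumeration counts", {
  s3 <- alpha_sites()
  g <- enumerate_genotypes(s3)
  expect_equal(nrow(g), 8)
  expect_equal(sum(g$n_derived %in% 1:2), 6)          # mutational intermediates
  expect_identical(g$code[1], "GAP")
  expect_identical(g$code[8], "SVA")
  s2 <- goose_sites("beta")
  expect_equal(sum(enumerate_genotypes(s2)$n_derived == 1), 2)
  s1 <- hb_sites("x", "A", "V")
  expect_equal(nrow(enumerate_genotypes(s1)) - 2, 0)
  expect_length(enumerate_pathways(s3), 6)
  expect_length(enumerate_pathways(s2), 2)
  expect_length(enumerate_pathways(hb_sites(letters[1:4], rep("A", 4),
                                            rep("V", 4))), 24)
  expect_error(hb_sites(c("a", "a"), c("G", "G"), c("S", "S")),
               class = "hbcube_invalid_sites")
  expect_error(enumerate_pathways(hb_sites(letters[1:9], rep("A", 9),
                                           rep("V", 9))),
               class = "hbcube_size_limit")
})

test_that("mutation_effect reproduces the published first-step effects", {
  tab <- goose_p50_fixture("alpha")
  e119 <- mutation_effect(tab, "alpha119", "GAP", "p50_stripped")
  e18 <- mutation_effect(tab, "alpha18", "GAP", "p50_stripped")
  e63 <- mutation_effect(tab, "alpha63", "GAP", "p50_stripped")
  ## percent reductions round (half away from zero) to 18 / 7 / 14
  expect_equal(round_half_away(-e119$percent_change), 18)
  expect_equal(round_half_away(-e18$percent_change), 7)
  expect_equal(round_half_away(-e63$percent_change), 14)
  expect_equal(e119$delta_log10, log10(3.53 / 4.30), tolerance = 1e-12)
  expect_true(all(c(e119$significant, e18$significant, e63$significant)))
  ## sign consistency between log and raw scales
  expect_equal(sign(e119$delta_log10), sign(e119$percent_change))
  expect_error(mutation_effect(tab, "alpha119", "GAA", "p50_stripped"),
               class = "hbcube_invalid_site_state")
  expect_error(mutation_effect(tab, "alpha119", "GAP", "nope"),
               class = "hbcube_missing_data")
  sub <- gp_table(as.data.frame(tab)[tab$genotype != "GAA", ],
                  alpha_sites())
  err <- tryCatch(mutation_effect(sub, "alpha119", "GAP", "p50_stripped"),
                  hbcube_missing_data = function(e) conditionMessage(e))
  expect_match(err, "GAA")   # error names the missing genotype
})

test_that("pathway trajectories telescope and match the fixture sequence", {
  tab <- goose_p50_fixture("alpha")
  pw <- pathway_trajectory(tab, c("alpha119", "alpha63", "alpha18"),
                           "p50_stripped")
  expect_equal(unname(pw$means), c(4.30, 3.53, 3.52, 3.42))
  endpoint <- log10(3.42 / 4.30)
  for (ord in enumerate_pathways(alpha_sites())) {
    p <- pathway_trajectory(tab, ord, "p50_stripped")
    expect_equal(sum(vapply(p$steps, `[[`, numeric(1), "delta_log10")),
                 endpoint, tolerance = 1e-12)
  }
})

test_that("additive landscapes have order-independent step effects", {
  s <- alpha_sites()
  tab <- gen_landscape(s, effects = c(alpha18 = -0.03, alpha63 = -0.07,
                                      alpha119 = -0.09),
                       noise_sd_log10 = 0, trait = "p50_stripped", seed = 2)
  ref <- NULL
  for (ord in enumerate_pathways(s)) {
    d <- sort(vapply(pathway_trajectory(tab, ord, "p50_stripped")$steps,
                     `[[`, numeric(1), "delta_log10"))
    if (is.null(ref)) ref <- d else expect_equal(d, ref, tolerance = 1e-9)
  }
  ## reversion symmetry: asymmetry 0 for every site on an additive landscape
  for (st in s$label)
    expect_equal(reversion_symmetry(tab, st, "p50_stripped")$asymmetry,
                 rep(0, 2), tolerance = 1e-9)
})

test_that("rank_largest_effect reproduces the 4/2 winner split", {
  tab <- goose_p50_fixture("alpha")
  rk <- rank_largest_effect(tab, "p50_stripped", "decrease")
  expect_equal(rk$counts[["alpha119"]], 4)
  expect_equal(rk$counts[["alpha63"]], 2)
  expect_equal(rk$counts[["alpha18"]], 0)
  expect_false(rk$any_ties)
  ## the alpha63 wins are exactly the pathways where it is the first step
  win63 <- rk$per_pathway$winner == "alpha63"
  expect_identical(win63, rk$per_pathway$first_step == "alpha63")
  ## framing invariance: winner by percent change matches winner by dlog10
  for (i in seq_len(nrow(rk$per_pathway))) {
    pw <- pathway_trajectory(tab, strsplit(rk$per_pathway$pathway[i], ">",
                                           fixed = TRUE)[[1]], "p50_stripped")
    pc <- vapply(pw$steps, `[[`, numeric(1), "percent_change")
    expect_identical(pw$order[which.min(pc)], rk$per_pathway$winner[i])
  }
})

test_that("flat landscapes report ties, never a silent winner", {
  s <- alpha_sites()
  flat <- gp_table(expand.grid(genotype = enumerate_genotypes(s)$code,
                               trait = "p50_stripped", mean = 4, sem = 0.05,
                               n = 3, stringsAsFactors = FALSE), s)
  rk <- rank_largest_effect(flat, "p50_stripped", "decrease")
  expect_true(all(rk$per_pathway$tied))
  expect_true(rk$any_ties)
})

test_that("per-background effects match the fixture corner-by-corner", {
  tab <- goose_p50_fixture("alpha")
  effs <- effects_on_all_backgrounds(tab, "alpha119", "p50_stripped")
  expect_length(effs, 4)
  expect_true(all(vapply(effs, `[[`, numeric(1), "delta_log10") < 0))
  trans <- vapply(effs, function(e) paste(e$from, e$to), character(1))
  expect_setequal(trans, c("GAP GAA", "GVP GVA", "SAP SAA", "SVP SVA"))
  expect_length(effects_on_all_backgrounds(
    gp_table(data.frame(genotype = c("A", "V"), trait = "t", mean = c(1, 2),
                        sem = 0.1, n = 3), hb_sites("x", "A", "V")), "x", "t"),
    1)
})

test_that("reversion symmetry pairs forward and reverted effects", {
  tab <- goose_p50_fixture("alpha")
  rs <- reversion_symmetry(tab, "alpha119", "p50_stripped")
  row <- rs[rs$background == "GAP", ]
  expect_identical(row$complement_background, "SVP")
  expect_equal(row$forward_delta, log10(3.53 / 4.30), tolerance = 1e-12)
  expect_equal(row$reverse_delta, log10(3.88 / 3.42), tolerance = 1e-12)
  expect_equal(row$asymmetry, row$forward_delta + row$reverse_delta)
  sub <- gp_table(as.data.frame(tab)[tab$genotype != "SVP", ], alpha_sites())
  expect_error(reversion_symmetry(sub, "alpha119", "p50_stripped"),
               class = "hbcube_missing_data")
})

test_that("double-mutant cycles quantify the autoxidation compensation", {
  tab <- goose_kauto_fixture("alpha")
  cyA <- double_mutant_cycle(tab, "alpha18", "alpha63", "GAP", "k_auto")
  expect_equal(unname(cyA$corners),
               c(0.170, 0.149, 0.399, 0.159))  # ab, Ab, aB, AB
  expect_equal(cyA$epistasis_log10,
               log10(0.159 / 0.149) - log10(0.399 / 0.170),
               tolerance = 1e-12)
  expect_equal(round(cyA$epistasis_log10, 3), -0.342)
  expect_equal(cyA$compensation_ratio, 0.159 / 0.170, tolerance = 1e-12)
  expect_equal(round(cyA$compensation_ratio, 2), 0.94)
  sub <- gp_table(as.data.frame(tab)[tab$genotype != "SVP", ], alpha_sites())
  expect_error(double_mutant_cycle(sub, "alpha18", "alpha63", "GAP", "k_auto"),
               class = "hbcube_missing_data")
  expect_error(double_mutant_cycle(tab, "alpha18", "alpha18", "GAP", "k_auto"),
               class = "hbcube_invalid_parameter")
})

test_that("cycle epistasis equals the exhaustive interaction solve", {
  ## zero-noise synthetic landscapes, k = 2..4, planted pairwise terms
  for (k in 2:4) {
    s <- hb_sites(paste0("s", seq_len(k)), rep("A", k), rep("V", k))
    effects <- stats::setNames(seq(-0.1, -0.02, length.out = k), s$label)
    epi <- stats::setNames(c(0.06, if (k >= 3) -0.34, if (k >= 4) 0.02),
                           c("s1:s2", if (k >= 3) "s2:s3",
                             if (k >= 4) "s3:s4")[1:(k - 1)])
    tab <- gen_landscape(s, effects, epi, noise_sd_log10 = 0, seed = 9)
    beta <- full_interaction_solve(tab, "trait")
    for (nm in names(epi)) {
      expect_equal(beta[[nm]], epi[[nm]], tolerance = 1e-9)
      pr <- strsplit(nm, ":")[[1]]
      cy <- double_mutant_cycle(tab, pr[1], pr[2], ancestral_code(s), "trait")
      expect_equal(cy$epistasis_log10, epi[[nm]], tolerance = 1e-9)
    }
    ## un-planted pairs come back (near) zero everywhere
    zero <- setdiff(grep(":", names(beta), value = TRUE),
                    c(names(epi), grep(":.*:", names(beta), value = TRUE)))
    for (nm in zero) expect_equal(beta[[nm]], 0, tolerance = 1e-9)
  }
})

test_that("planted epistasis is recovered under noise, zero when absent", {
  s <- goose_sites("beta")
  noisy <- gen_landscape(s, c(beta4 = -0.02, beta125 = -0.01),
                         c("beta4:beta125" = -0.34),
                         noise_sd_log10 = 0.005, replicates = 3, seed = 13)
  cy <- double_mutant_cycle(noisy, "beta4", "beta125", "TD", "trait")
  expect_lt(abs(cy$epistasis_log10 - (-0.34)), 0.05)  # ~4 sd of the estimate
  none <- gen_landscape(s, c(beta4 = -0.02, beta125 = -0.01),
                        noise_sd_log10 = 0.005, replicates = 3, seed = 14)
  cy0 <- double_mutant_cycle(none, "beta4", "beta125", "TD", "trait")
  expect_lt(abs(cy0$epistasis_log10), 0.05)
})

test_that("site relabeling permutes outputs consistently", {
  tab <- goose_p50_fixture("alpha")
  s <- alpha_sites()
  perm <- c(3, 1, 2)
  s2 <- hb_sites(s$label[perm], s$ancestral[perm], s$derived[perm])
  remap <- function(code) paste(strsplit(code, "")[[1]][perm], collapse = "")
  df <- as.data.frame(tab)
  df$genotype <- vapply(df$genotype, remap, character(1))
  tab2 <- gp_table(df, s2)
  e1 <- mutation_effect(tab, "alpha119", "GAP", "p50_stripped")
  e2 <- mutation_effect(tab2, "alpha119", remap("GAP"), "p50_stripped")
  expect_equal(e2$delta_log10, e1$delta_log10)
  rk1 <- rank_largest_effect(tab, "p50_stripped", "decrease")
  rk2 <- rank_largest_effect(tab2, "p50_stripped", "decrease")
  expect_equal(rk2$counts[names(rk1$counts)], rk1$counts)
})
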