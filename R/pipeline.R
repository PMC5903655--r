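## Pipeline configuration, orchestration, and the command-line entry point.

config_known <- list(
  top = c("seed", "out_dir", "sites", "inputs", "options", "simulate"),
  sites = c("label", "ancestral", "derived"),
  inputs = c("gp_csv", "saturation_csv", "trace_csv", "tree", "site_matrix",
             "panel_csv"),
  options = c("alpha", "direction", "convention", "affinity_trait",
              "rate_trait", "ancestor_tips", "rounding"),
  simulate = c("effects", "epistasis", "baseline_log10", "noise_sd_log10",
               "replicates", "trait"))

check_keys <- function(x, where) {
  unknown <- setdiff(names(x), config_known[[where]])
  if (length(unknown))
    stop_hb("config", "unknown ", where, " key(s): ",
            paste(unknown, collapse = ", "))
}

#' Build and validate a pipeline configuration
#'
#' Validated before any stage runs; unknown keys are rejected so typos fail
#' loudly. File paths are checked lazily by the stages that use them.
#'
#' @param seed integer seed used by every stochastic stage.
#' @param out_dir output directory (created if absent).
#' @param sites list with `label`, `ancestral`, `derived` vectors, passed to
#'   [hb_sites()].
#' @param inputs list of file paths: `gp_csv` (genotype-phenotype long CSV),
#'   optional `saturation_csv`, `trace_csv`, `tree` + `site_matrix`,
#'   `panel_csv` (mixed-system panel for genotype-level pairing).
#' @param options list: `alpha` (significance level, default 0.05),
#'   `direction` (`"decrease"`), `convention` (pleiotropy pairing rule),
#'   `affinity_trait` (`"p50_stripped"`), `rate_trait` (`"k_auto"`),
#'   `ancestor_tips` (two tip names whose MRCA is the ancestral node of
#'   interest).
#' @param simulate optional list forwarded to [gen_landscape()] when no
#'   `gp_csv` is supplied.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = ".", sites, inputs = list(),
                            options = list(), simulate = NULL) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, sites = sites,
              inputs = inputs, options = options, simulate = simulate)
  check_keys(cfg, "top")
  check_keys(sites, "sites")
  check_keys(inputs, "inputs")
  check_keys(options, "options")
  if (!is.null(simulate)) check_keys(simulate, "simulate")
  defaults <- list(alpha = 0.05, direction = "decrease",
                   convention = "all-hypercube-edges",
                   affinity_trait = "p50_stripped", rate_trait = "k_auto",
                   ancestor_tips = NULL, rounding = "half-away-from-zero")
  cfg$options <- utils::modifyList(defaults, options)
  cfg$sites_obj <- hb_sites(sites$label, sites$ancestral, sites$derived)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return a validated `"pipeline_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_hb("io", "config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(raw, "top")
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- cfg[c("seed", "sites", "inputs", "options", "simulate")]
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, null = "null",
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

## percent rounding rule used when comparing against published integer
## percentages: round half away from zero
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Run the full analysis pipeline
#'
#' Stages, in order: fit O2 equilibria (when raw curves are supplied), fit
#' kinetics (when raw traces are supplied), hypercube landscape analysis
#' (per-background effects, pathway trajectories, largest-effect ranking,
#' double-mutant cycles), parsimony ancestry (when a tree and matrix are
#' supplied), and the pleiotropy correlation screen. Each stage writes a
#' stamped CSV into `out_dir`; a plain-text `report.txt` restates the
#' headline statistics. Every output is deterministic given the config and
#' seed.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run; default all applicable.
#' @return (invisibly) list with the computed objects and the report text.
#' @export
run_pipeline <- function(config,
                         stages = c("equilibria", "kinetics", "landscape",
                                    "ancestry", "pleiotropy", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  hash <- config_hash(config)
  opt <- config$options
  sites <- config$sites_obj
  out <- function(f) file.path(config$out_dir, f)
  res <- list(config_hash = hash)
  report <- c(sprintf("hbcube pipeline report (seed %d, config %s)", seed, hash),
              strrep("=", 60))

  ## --- equilibrium fitting ------------------------------------------------
  gp_rows <- NULL
  if ("equilibria" %in% stages && !is.null(config$inputs$saturation_csv)) {
    curves <- read_saturation_csv(config$inputs$saturation_csv)
    fits <- lapply(curves, fit_hill)
    keys <- unique(data.frame(
      genotype = vapply(fits, `[[`, character(1), "genotype"),
      treatment = vapply(fits, `[[`, character(1), "treatment"),
      stringsAsFactors = FALSE))
    eq <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sel <- fits[vapply(fits, function(f)
        f$genotype == keys$genotype[i] && f$treatment == keys$treatment[i],
        logical(1))]
      sm <- summarize_replicates(sel)
      data.frame(genotype = keys$genotype[i], treatment = keys$treatment[i],
                 p50 = sm$mean, p50_sem = sm$sem, n = sm$n,
                 n50 = summarize_replicates(sel, "n50")$mean,
                 stringsAsFactors = FALSE)
    }))
    write_stamped_csv(eq, out("fitted_equilibria.csv"), seed, hash)
    res$equilibria <- eq
    strip <- eq[eq$treatment == "stripped", ]
    gp_rows <- data.frame(genotype = strip$genotype, trait = "p50_stripped",
                          mean = strip$p50, sem = strip$p50_sem, n = strip$n,
                          stringsAsFactors = FALSE)
    for (tr in setdiff(unique(eq$treatment), "stripped")) {
      sub <- eq[eq$treatment == tr, ]
      m <- match(sub$genotype, strip$genotype)
      gp_rows <- rbind(gp_rows, data.frame(
        genotype = sub$genotype, trait = paste0("dlog_", gsub("\\+", "_", tr)),
        mean = vapply(seq_len(nrow(sub)), function(j)
          anion_sensitivity(strip$p50[m[j]], sub$p50[j])$delta_log_p50,
          numeric(1)),
        sem = NA_real_, n = sub$n, stringsAsFactors = FALSE))
    }
  }

  ## --- kinetics -----------------------------------------------------------
  if ("kinetics" %in% stages && !is.null(config$inputs$trace_csv)) {
    traces <- read_trace_csv(config$inputs$trace_csv)
    kf <- lapply(traces, fit_monoexponential)
    kin <- data.frame(
      genotype = vapply(kf, `[[`, character(1), "genotype"),
      kind = vapply(kf, `[[`, character(1), "kind"),
      replicate = vapply(kf, function(f) as.integer(f$replicate_id),
                         integer(1)),
      rate = vapply(kf, `[[`, numeric(1), "rate"),
      rate_unit = vapply(kf, `[[`, character(1), "rate_unit"),
      r_squared = vapply(kf, `[[`, numeric(1), "r_squared"),
      low_quality = vapply(kf, `[[`, logical(1), "low_quality"),
      stringsAsFactors = FALSE)
    write_stamped_csv(kin, out("fitted_kinetics.csv"), seed, hash)
    res$kinetics <- kin
    auto <- kin[kin$kind == "autoxidation", ]
    if (nrow(auto)) {
      agg <- stats::aggregate(rate ~ genotype, auto, function(x)
        c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
          n = length(x)))
      gp_rows <- rbind(gp_rows, data.frame(
        genotype = agg$genotype, trait = "k_auto",
        mean = agg$rate[, "mean"], sem = agg$rate[, "sem"],
        n = as.integer(agg$rate[, "n"]), stringsAsFactors = FALSE))
    }
  }

  ## --- genotype-phenotype table -------------------------------------------
  tab <- NULL
  if (!is.null(config$inputs$gp_csv)) {
    tab <- read_gp_csv(config$inputs$gp_csv, sites)
  } else if (!is.null(gp_rows)) {
    tab <- gp_table(gp_rows, sites)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    tab <- gen_landscape(sites,
                         effects = unlist(sim$effects),
                         epistasis = if (is.null(sim$epistasis)) numeric(0)
                         else unlist(sim$epistasis),
                         baseline_log10 = sim$baseline_log10 %||% log10(4.3),
                         noise_sd_log10 = sim$noise_sd_log10 %||% 0.02,
                         replicates = sim$replicates %||% 3L,
                         trait = sim$trait %||% opt$affinity_trait,
                         seed = seed)
    write_gp_csv(tab, out("simulated_gp.csv"), seed, hash)
  }
  res$gp_table <- tab

  ## --- landscape ----------------------------------------------------------
  if ("landscape" %in% stages && !is.null(tab) &&
      opt$affinity_trait %in% tab$trait) {
    trait <- opt$affinity_trait
    paths <- enumerate_pathways(sites)
    prows <- do.call(rbind, lapply(seq_along(paths), function(i) {
      pw <- pathway_trajectory(tab, paths[[i]], trait)
      do.call(rbind, lapply(seq_along(pw$steps), function(s) {
        e <- pw$steps[[s]]
        data.frame(pathway = paste(paths[[i]], collapse = ">"), step = s,
                   from = e$from, to = e$to, site = e$site,
                   delta_log10 = e$delta_log10, percent = e$percent_change,
                   p_value = e$p_value, stringsAsFactors = FALSE)
      }))
    }))
    write_stamped_csv(prows, out("pathways.csv"), seed, hash)
    rank <- rank_largest_effect(tab, trait, opt$direction)
    res$pathways <- prows
    res$rank <- rank
    report <- c(report, "", sprintf("Pathways (%s, direction = %s):", trait,
                                    opt$direction),
                sprintf("  %d genotypes, %d forward pathways",
                        2^n_sites(sites), factorial(n_sites(sites))),
                sprintf("  largest-effect winner counts: %s%s",
                        paste(names(rank$counts), rank$counts, sep = "=",
                              collapse = ", "),
                        if (rank$any_ties) " (ties present)" else ""))
    effs <- list()
    for (s in sites$label) {
      es <- effects_on_all_backgrounds(tab, s, trait, opt$alpha)
      effs[[s]] <- es
      report <- c(report, sprintf("  %s effects per background:", s),
                  vapply(es, function(e)
                    sprintf("    %s -> %s: dlog10 = %.4f (%.1f%%), p = %.3g",
                            e$from, e$to, e$delta_log10, e$percent_change,
                            e$p_value), character(1)))
    }
    res$effects <- effs

    rate_trait <- opt$rate_trait
    if (rate_trait %in% tab$trait && n_sites(sites) >= 2L) {
      pairs <- utils::combn(sites$label, 2L, simplify = FALSE)
      crows <- list()
      gts <- enumerate_genotypes(sites)$code
      for (pr in pairs) {
        ia <- site_index(pr[1L], sites); ib <- site_index(pr[2L], sites)
        backs <- unique(vapply(gts, function(g) {
          b <- code_to_bits(g, sites); b[c(ia, ib)] <- 0L
          bits_to_code(b, sites)
        }, character(1)))
        for (bg in backs) {
          cy <- double_mutant_cycle(tab, pr[1L], pr[2L], bg, rate_trait)
          crows[[length(crows) + 1L]] <- data.frame(
            site_a = pr[1L], site_b = pr[2L], background = bg,
            ab = cy$corners[["ab"]], Ab = cy$corners[["Ab"]],
            aB = cy$corners[["aB"]], AB = cy$corners[["AB"]],
            epistasis_log10 = cy$epistasis_log10,
            compensation_ratio = cy$compensation_ratio,
            stringsAsFactors = FALSE)
        }
      }
      cyc <- do.call(rbind, crows)
      write_stamped_csv(cyc, out("cycles.csv"), seed, hash)
      res$cycles <- cyc
      report <- c(report, "", sprintf("Double-mutant cycles (%s):", rate_trait),
                  vapply(seq_len(nrow(cyc)), function(i)
                    sprintf("  %s x %s | background %s: epistasis = %.4f, AB/ab = %.3f",
                            cyc$site_a[i], cyc$site_b[i], cyc$background[i],
                            cyc$epistasis_log10[i], cyc$compensation_ratio[i]),
                    character(1)))
    }
  }

  ## --- ancestry -----------------------------------------------------------
  if ("ancestry" %in% stages && !is.null(config$inputs$tree)) {
    tm <- read_tree_and_matrix(config$inputs$tree, config$inputs$site_matrix)
    rec <- fitch_parsimony(tm$tree, tm$matrix)
    br <- assign_branches(rec)
    write_stamped_csv(br, out("branch_substitutions.csv"), seed, hash)
    write_annotated_newick(rec, out("annotated_tree.nwk"))
    res$reconstruction <- rec
    res$branches <- br
    report <- c(report, "", "Ancestry (parsimony):",
                vapply(rec$sites, function(s)
                  sprintf("  %s: %d change(s)", s,
                          rec$per_site[[s]]$min_changes), character(1)))
    if (nrow(br)) {
      tally <- stats::aggregate(site ~ child_label, br, length)
      report <- c(report, "  substitutions per branch:",
                  sprintf("    %s: %d", tally$child_label, tally$site))
    }
    if (!is.null(opt$ancestor_tips)) {
      anc <- ancestral_genotype(rec, opt$ancestor_tips, sites$label)
      res$ancestral_genotype <- anc
      report <- c(report, sprintf("  ancestral genotype at MRCA(%s): %s",
                                  paste(opt$ancestor_tips, collapse = ","),
                                  anc))
    }
  }

  ## --- pleiotropy ---------------------------------------------------------
  if ("pleiotropy" %in% stages && !is.null(tab) &&
      length(unique(tab$trait)) >= 2L) {
    scr <- pleiotropy_screen(tab, opt$affinity_trait)
    if (!is.null(config$inputs$panel_csv)) {
      panel <- read_gp_csv(config$inputs$panel_csv, sites = NULL)
      extra <- pleiotropy_screen(panel, opt$affinity_trait,
                                 conventions = "genotype-level")
      scr <- rbind(scr, extra)
    }
    write_stamped_csv(scr, out("correlations.csv"), seed, hash)
    res$correlations <- scr
    report <- c(report, "", "Pleiotropy screen:",
                vapply(seq_len(nrow(scr)), function(i)
                  sprintf("  %s vs %s [%s]: r = %.3f (n = %d, p = %.3g)",
                          scr$trait_x[i], scr$trait_y[i], scr$convention[i],
                          scr$r[i], scr$n[i], scr$p_value[i]), character(1)))
  }

  if ("report" %in% stages) {
    writeLines(report, out("report.txt"))
    res$report <- report
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' `Rscript -e 'hbcube::hbcube_cli()' <subcommand> --config cfg.json
#' [--seed N] [--out-dir DIR] [--alpha A] [--convention C]`. Subcommands:
#' `run-all` (default), `simulate`, `fit-equilibria`, `fit-kinetics`,
#' `landscape`, `pathways`, `cycles`, `ancestry`, `pleiotropy`, `report`.
#' Logs go to stderr; results only ever touch the output files. Any stage
#' error exits with a nonzero status carrying the stage's message.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @param exit terminate the R process with the status code on failure
#'   (default only outside interactive sessions *and* outside testing).
#' @return exit status, invisibly (0 on success); called for side effects.
#' @export
hbcube_cli <- function(args = commandArgs(trailingOnly = TRUE),
                       exit = !interactive()) {
  subcommands <- c("run-all", "simulate", "fit-equilibria", "fit-kinetics",
                   "landscape", "pathways", "cycles", "ancestry",
                   "pleiotropy", "report")
  sub <- if (length(args) && !startsWith(args[1L], "--")) args[1L] else "run-all"
  if (!sub %in% subcommands) {
    message("unknown subcommand: ", sub)
    return(invisible(2L))
  }
  opts <- list()
  flags <- args[startsWith(args, "--")]
  vals <- args[which(startsWith(args, "--")) + 1L]
  for (i in seq_along(flags)) opts[[sub("^--", "", flags[i])]] <- vals[i]
  status <- tryCatch({
    if (is.null(opts$config)) stop_hb("config", "--config is required")
    cfg <- read_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$`out-dir`)) cfg$out_dir <- opts$`out-dir`
    if (!is.null(opts$alpha)) cfg$options$alpha <- as.numeric(opts$alpha)
    if (!is.null(opts$convention)) cfg$options$convention <- opts$convention
    stage_map <- list(
      "run-all" = c("equilibria", "kinetics", "landscape", "ancestry",
                    "pleiotropy", "report"),
      "simulate" = c("landscape", "report"),
      "fit-equilibria" = "equilibria", "fit-kinetics" = "kinetics",
      "landscape" = c("landscape", "report"),
      "pathways" = c("landscape", "report"),
      "cycles" = c("landscape", "report"),
      "ancestry" = c("ancestry", "report"),
      "pleiotropy" = c("pleiotropy", "report"),
      "report" = c("landscape", "ancestry", "pleiotropy", "report"))
    message("hbcube: running '", sub, "' into ", cfg$out_dir)
    run_pipeline(cfg, stages = stage_map[[sub]])
    0L
  }, error = function(e) {
    message("hbcube error: ", conditionMessage(e))
    1L
  })
  if (exit && status != 0L) quit(status = status, save = "no")
  invisible(status)
}
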