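## CSV dialects and newick I/O for every pipeline stage. All writers stamp a
## comment header (version, seed, config hash); all readers skip '#' lines.

hb_header <- function(seed = NA, config_hash = NA) {
  c(sprintf("# hbcube_version: %s",
            as.character(utils::packageVersion("hbcube"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash))
}

write_stamped_csv <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hb_header(seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_hb_csv <- function(path, required, allow_extra = FALSE) {
  if (!file.exists(path))
    stop_hb("io", "file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 comment.char = "#"),
                 error = function(e)
                   stop_hb("parse", "cannot parse ", path, ": ",
                           conditionMessage(e)))
  if (nrow(df) == 0L)
    stop_hb("parse", path, ": no data rows")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_hb("parse", path, ": missing column(s) ",
            paste(miss, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra) && !allow_extra)
    warning(path, ": extra column(s) preserved: ",
            paste(extra, collapse = ", "), call. = FALSE)
  df
}

#' Read and write saturation-curve CSVs
#'
#' Long form, one measured point per row: columns `genotype`, `treatment`,
#' `replicate`, `po2_torr`, `saturation`. PO2 may instead be supplied in kPa
#' (`po2_unit = "kPa"`), in which case it is converted on read
#' (1 kPa = 7.50062 torr); torr is the unit everywhere downstream.
#'
#' @param path CSV file path.
#' @param po2_unit `"torr"` (default) or `"kPa"`.
#' @return `read_saturation_csv()`: list of [saturation_curve()], one per
#'   genotype x treatment x replicate.
#' @export
read_saturation_csv <- function(path, po2_unit = c("torr", "kPa")) {
  po2_unit <- match.arg(po2_unit)
  df <- read_hb_csv(path, c("genotype", "treatment", "replicate",
                            "po2_torr", "saturation"))
  if (po2_unit == "kPa") df$po2_torr <- df$po2_torr * 7.50062
  keys <- unique(df[, c("genotype", "treatment", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$genotype == keys$genotype[i] &
                df$treatment == keys$treatment[i] &
                df$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$po2_torr), ]
    saturation_curve(sub$po2_torr, sub$saturation,
                     genotype = keys$genotype[i],
                     treatment = keys$treatment[i],
                     replicate_id = keys$replicate[i])
  })
}

#' @rdname read_saturation_csv
#' @param curves list of [saturation_curve()] objects.
#' @param seed,config_hash provenance stamped into the header comment.
#' @export
write_saturation_csv <- function(curves, path, seed = NA, config_hash = NA) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(genotype = cv$genotype, treatment = cv$treatment$label,
               replicate = cv$replicate_id, po2_torr = cv$po2_torr,
               saturation = cv$saturation, stringsAsFactors = FALSE)))
  write_stamped_csv(df, path, seed, config_hash)
}

#' Read and write kinetic-trace CSVs
#'
#' Columns `genotype`, `kind` (`dissociation`/`autoxidation`), `replicate`,
#' `time`, `value`; time in seconds for dissociation and hours for
#' autoxidation.
#'
#' @param path CSV file path.
#' @return `read_trace_csv()`: list of [kinetic_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- read_hb_csv(path, c("genotype", "kind", "replicate", "time", "value"))
  keys <- unique(df[, c("genotype", "kind", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$genotype == keys$genotype[i] & df$kind == keys$kind[i] &
                df$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$time), ]
    kinetic_trace(sub$time, sub$value, kind = keys$kind[i],
                  genotype = keys$genotype[i],
                  replicate_id = keys$replicate[i])
  })
}

#' @rdname read_trace_csv
#' @param traces list of [kinetic_trace()] objects.
#' @param seed,config_hash provenance stamped into the header comment.
#' @export
write_trace_csv <- function(traces, path, seed = NA, config_hash = NA) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(genotype = tr$genotype, kind = tr$kind,
               replicate = tr$replicate_id, time = tr$times,
               value = tr$values, stringsAsFactors = FALSE)))
  write_stamped_csv(df, path, seed, config_hash)
}

#' Read and write genotype-phenotype CSVs
#'
#' Long form: `genotype`, `trait`, `mean`, `sem`, `n`.
#'
#' @param path CSV file path.
#' @param sites an [hb_sites()] set validating the genotype codes; `NULL`
#'   returns a plain data.frame (e.g. for mixed-system panels).
#' @return `read_gp_csv()`: a [gp_table()] (or data.frame when `sites` is
#'   `NULL`).
#' @export
read_gp_csv <- function(path, sites = NULL) {
  df <- read_hb_csv(path, c("genotype", "trait", "mean", "sem", "n"))
  if (is.null(sites)) df else gp_table(df, sites)
}

#' @rdname read_gp_csv
#' @param table a [gp_table()] or compatible data.frame.
#' @param seed,config_hash provenance stamped into the header comment.
#' @export
write_gp_csv <- function(table, path, seed = NA, config_hash = NA) {
  write_stamped_csv(as.data.frame(table)[, c("genotype", "trait", "mean",
                                             "sem", "n")],
                    path, seed, config_hash)
}

#' Read a rooted tree and a taxon x site state matrix
#'
#' @param tree_path newick file with named tips.
#' @param matrix_path CSV with a `taxon` column followed by one column per
#'   site.
#' @return list with `tree` (ape phylo) and `matrix`
#'   ([site_state_matrix()]).
#' @export
read_tree_and_matrix <- function(tree_path, matrix_path) {
  if (!file.exists(tree_path)) stop_hb("io", "file not found: ", tree_path)
  tree <- tryCatch(ape::read.tree(tree_path), error = function(e)
    stop_hb("parse", "cannot parse newick ", tree_path, ": ",
            conditionMessage(e)))
  if (is.null(tree)) stop_hb("parse", tree_path, ": no tree parsed")
  df <- read_hb_csv(matrix_path, "taxon", allow_extra = TRUE)
  m <- as.matrix(df[, setdiff(names(df), "taxon"), drop = FALSE])
  rownames(m) <- df$taxon
  list(tree = tree, matrix = site_state_matrix(m))
}

#' Write an annotated newick with per-branch substitution counts
#'
#' Internal-node labels carry the number of substitutions inferred on the
#' subtending branch (blank when none).
#'
#' @param reconstruction a [fitch_parsimony()] result.
#' @param path output newick path.
#' @return the path, invisibly; side effect is the written file.
#' @export
write_annotated_newick <- function(reconstruction, path) {
  tree <- reconstruction$tree
  counts <- branch_substitution_counts(reconstruction)
  ntip <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  if (nrow(counts)) {
    internal <- counts[counts$child > ntip, ]
    lab[internal$child - ntip] <- as.character(internal$site)
  }
  tree$node.label <- lab
  ape::write.tree(tree, file = path)
  invisible(path)
}
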