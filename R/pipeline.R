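#' Pipeline run configuration
#'
#' Collects every setting of the full analysis chain
#' (convert -> filter -> diversity -> compare -> tmrca -> continuity ->
#' structure) with defaults matching the standard diachronic study design:
#' at most 3 missing loci, IAM likelihood, 33-year generations, a 300-500
#' year window and a decisive 50\% credible interval.
#'
#' @param genotypes Path to the genotype table (CSV) or a
#'   \code{ystr_haplotypes} object.
#' @param panel_name Panel of the input table.
#' @param dys389b Whether the input already uses the DYS389b nomenclature;
#'   if \code{FALSE} the conversion stage applies it.
#' @param max_missing Missing-locus filter threshold (default 3).
#' @param rates A \code{mutation_rates} table or path to a rate table file.
#' @param model,lambda,ci_levels Walsh settings (see
#'   \code{\link{walsh_config}}).
#' @param generation_time Years per generation (default 33).
#' @param window Continuity window in years (default \code{c(300, 500)}).
#' @param decisive_ci Decisive CI level for continuity (default 0.5).
#' @param ancient_pop,modern_pop Population labels in the table.
#' @param haplogroups Optional path to a CSV (\code{sample_id},
#'   \code{haplogroup}) of externally predicted lineage labels for the
#'   frequency-based FST; when absent, haplotype-cluster identities are
#'   used as the categorical unit.
#' @param n_permutations AMOVA permutation count (default 10000).
#' @param out_dir Output directory.
#' @param seed Integer seed for all stochastic stages.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(genotypes, panel_name = "YFILERPLUS27",
                            dys389b = TRUE, max_missing = 3,
                            rates = NULL, model = "IAM", lambda = 1000,
                            ci_levels = c(0.5, 0.95), generation_time = 33,
                            window = c(300, 500), decisive_ci = 0.5,
                            ancient_pop = "RP_A", modern_pop = "RP_M",
                            haplogroups = NULL, n_permutations = 10000,
                            out_dir = tempfile("ylineage_run"), seed = 1L) {
  if (is.character(genotypes) && !file.exists(genotypes))
    stop("genotype table not found: ", genotypes)
  if (is.character(haplogroups) && !file.exists(haplogroups))
    stop("haplogroup table not found: ", haplogroups)
  structure(list(genotypes = genotypes, panel_name = panel_name,
                 dys389b = dys389b, max_missing = max_missing, rates = rates,
                 model = model, lambda = lambda, ci_levels = ci_levels,
                 generation_time = generation_time, window = window,
                 decisive_ci = decisive_ci, ancient_pop = ancient_pop,
                 modern_pop = modern_pop, haplogroups = haplogroups,
                 n_permutations = n_permutations, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#'
#' @details \code{read_pipeline_config} loads a flat YAML key-value file;
#'   unknown keys are hard errors (a typo in an analysis setting must not
#'   fall through to a default silently).
#'
#' @param path Path to a YAML config file.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), "")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$rates) && is.character(vals$rates))
    vals$rates <- vals$rates  # resolved at run time
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing each stage's output as CSV under
#' \code{config$out_dir} plus a JSON manifest recording the package
#' version, seed, config hash, per-stage row counts and output file
#' checksums.  Any stage error aborts with the stage name.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "ylineage",
                   version = as.character(utils::packageVersion("ylineage")),
                   seed = config$seed, stages = list())
  outfile <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }
  log_stage <- function(name, rows, file = NULL) {
    manifest$stages[[name]] <<- list(rows = rows, file = file)
    message(sprintf("[%s] %d rows", name, rows))
  }

  # config hash (over the canonical YAML serialisation)
  cfg_file <- outfile("config.yaml")
  cfg_serial <- config
  cfg_serial$genotypes <- if (is.character(config$genotypes))
    config$genotypes else "<in-memory>"
  cfg_serial$rates <- if (is.character(config$rates))
    config$rates else if (is.null(config$rates)) "default" else "<in-memory>"
  yaml::write_yaml(lapply(unclass(cfg_serial), function(x)
    if (is.null(x)) "" else x), cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))

  panel_raw <- ystr_panel(config$panel_name, dys389b = config$dys389b)

  # stage 1: convert (read + DYS389b nomenclature + multi-copy split)
  haps <- stage("convert", {
    h <- if (inherits(config$genotypes, "ystr_haplotypes")) config$genotypes
    else read_haplotype_table(config$genotypes, panel_raw)
    if (!active_panel(h)$dys389b) h <- apply_dys389b(h)
    h
  })
  write_haplotype_table(haps, outfile("01_converted.csv"))
  log_stage("convert", nrow(haps), "01_converted.csv")

  # stage 2: filter by missingness
  kept <- stage("filter", filter_by_missing(haps, config$max_missing))
  write_haplotype_table(kept, outfile("02_filtered.csv"))
  log_stage("filter", nrow(kept), "02_filtered.csv")
  message(sprintf("[filter] %d %s retained",
                  sum(kept$population == config$ancient_pop),
                  config$ancient_pop))

  # stage 3: diversity report (full panel vs core-17 projection)
  div <- stage("diversity", {
    comp <- panel_comparison(kept, active_panel(kept))
    per_pop <- lapply(split(seq_len(nrow(kept)), kept$population),
                      function(idx) {
                        sub <- ystr_haplotypes(as.data.frame(kept)[idx, ],
                                               active_panel(kept))
                        haplotype_diversity(cluster_haplotypes(sub))
                      })
    list(comparison = comp, per_pop = per_pop)
  })
  div_rows <- data.frame(
    dataset = c("Total_full", "Total_core17", names(div$per_pop)),
    hd = c(div$comparison$full$hd, div$comparison$subset$hd,
           vapply(div$per_pop, `[[`, numeric(1), "hd")),
    hmp = c(div$comparison$full$hmp, div$comparison$subset$hmp,
            vapply(div$per_pop, `[[`, numeric(1), "hmp")),
    dc = c(div$comparison$full$dc, div$comparison$subset$dc,
           vapply(div$per_pop, `[[`, numeric(1), "dc")))
  utils::write.csv(div_rows, outfile("03_diversity.csv"), row.names = FALSE)
  gd_rows <- data.frame(series = names(div$comparison$gd),
                        gd = unname(div$comparison$gd))
  utils::write.csv(gd_rows, outfile("03_gene_diversity.csv"),
                   row.names = FALSE)
  log_stage("diversity", nrow(div_rows), "03_diversity.csv")

  # stage 4: pairwise sharing report
  shares <- stage("compare", sharing_report(kept, max_mismatch = 2))
  utils::write.csv(shares, outfile("04_sharing.csv"), row.names = FALSE)
  log_stage("compare", nrow(shares), "04_sharing.csv")

  # stage 5: TMRCA for all ancient x modern pairs
  rates <- if (is.null(config$rates)) default_mutation_rates(active_panel(kept))
  else if (is.character(config$rates)) read_rate_table(config$rates)
  else config$rates
  wcfg <- walsh_config(model = config$model, lambda = config$lambda,
                       ci_levels = config$ci_levels)
  tm <- stage("tmrca", tmrca_pairs(kept, rates, wcfg,
                                   from_pop = config$ancient_pop,
                                   to_pop = config$modern_pop,
                                   generation_time = config$generation_time))
  utils::write.csv(tm$summary, outfile("05_tmrca.csv"), row.names = FALSE)
  log_stage("tmrca", if (is.null(tm$summary)) 0L else nrow(tm$summary),
            "05_tmrca.csv")

  # stage 6: continuity verdicts
  ccfg <- continuity_config(window = config$window,
                            ci_level = config$decisive_ci,
                            generation_time = config$generation_time)
  cont <- stage("continuity", continuity_matrix(tm, ccfg))
  utils::write.csv(cont$pairs, outfile("06_continuity_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(cont$per_ancient, outfile("06_continuity_ancients.csv"),
                   row.names = FALSE)
  grDevices::pdf(outfile("06_continuity.pdf"), width = 7, height = 8)
  plot(cont, main = "pair separation vs chronological window")
  grDevices::dev.off()
  log_stage("continuity", nrow(cont$pairs), "06_continuity_pairs.csv")

  # stage 7: two-population structure
  struct <- stage("structure", {
    anc <- ystr_haplotypes(
      as.data.frame(kept)[kept$population == config$ancient_pop, ],
      active_panel(kept))
    mod <- ystr_haplotypes(
      as.data.frame(kept)[kept$population == config$modern_pop, ],
      active_panel(kept))
    labels <- if (!is.null(config$haplogroups)) {
      hg <- utils::read.csv(config$haplogroups, stringsAsFactors = FALSE)
      stats::setNames(hg$haplogroup, hg$sample_id)[kept$sample_id]
    } else {
      # haplotype-cluster identity as the categorical unit
      cl <- cluster_haplotypes(kept)$clusters
      lab <- rep(NA_character_, nrow(kept))
      names(lab) <- kept$sample_id
      for (i in seq_along(cl)) lab[cl[[i]]] <- sprintf("H%02d", i)
      lab
    }
    fst <- amova_fst(labels[anc$sample_id], labels[mod$sample_id],
                     n_permutations = config$n_permutations,
                     seed = config$seed)
    rst <- amova_rst(anc, mod, n_permutations = config$n_permutations,
                     seed = config$seed)
    list(fst = fst, rst = rst)
  })
  st_rows <- data.frame(
    statistic = c("FST", "RST"),
    estimate = c(struct$fst$estimate, struct$rst$estimate),
    p_value = c(struct$fst$p_value, struct$rst$p_value),
    n_permutations = config$n_permutations, seed = config$seed)
  utils::write.csv(st_rows, outfile("07_structure.csv"), row.names = FALSE)
  log_stage("structure", 2L, "07_structure.csv")

  # manifest with output checksums
  outputs <- setdiff(list.files(config$out_dir), "manifest.json")
  csvs <- outputs[grepl("\\.csv$", outputs)]
  manifest$output_md5 <- as.list(tools::md5sum(file.path(config$out_dir,
                                                         csvs)))
  names(manifest$output_md5) <- csvs
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(haplotypes = kept, diversity = div, sharing = shares,
                 tmrca = tm, continuity = cont, structure = struct,
                 manifest = manifest, out_dir = config$out_dir))
}
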