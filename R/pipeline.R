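#' Validate a full-pipeline run configuration
#'
#' A run configuration either names the three input TSVs (`genotypes`,
#' `variants`, `phenotypes`) or carries a `simulate` block of [sim_config()]
#' arguments. Thresholds: `min_call_rate` (default 0.9), `alpha_hwe` (0.05),
#' `alpha_report` (0.01), `alpha_enrich` (0.05), `alpha_sexdiff` (0.05),
#' plus `x_mode`, `out_dir` and `seed`.
#'
#' @param config A named list, or a path to a YAML file holding one.
#' @return The validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(min_call_rate = 0.9, alpha_hwe = 0.05, alpha_report = 0.01,
                   alpha_enrich = 0.05, alpha_sexdiff = 0.05,
                   x_mode = "hemizygous", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (a in c("alpha_hwe", "alpha_report", "alpha_enrich", "alpha_sexdiff")) {
    if (config[[a]] <= 0 || config[[a]] >= 1) {
      stop(a, " must be strictly inside (0, 1)")
    }
  }
  if (config$min_call_rate < 0 || config$min_call_rate > 1) {
    stop("min_call_rate must be in [0, 1]")
  }
  has_files <- all(c("genotypes", "variants", "phenotypes") %in% names(config))
  if (!has_files && is.null(config$simulate)) {
    stop("config needs either input file paths or a 'simulate' block")
  }
  if (is.null(config$out_dir)) stop("config needs out_dir")
  config
}

#' Run the full sex-stratified association pipeline
#'
#' Composes every stage on one dataset: QC (call-rate filter, minor-allele
#' orientation, HWE screen, per-sex MAF summary), per-sex additive logistic
#' association scans for the six traits and melanoma, the sex-differentiated
#' test per outcome, the direction-of-effect enrichment comparison, and the
#' figures. Writes all tables under `config$out_dir` together with a manifest
#' recording input checksums, the echoed configuration, the seed and the
#' package version.
#'
#' @param config A [run_config()] list (or YAML path).
#' @param plots Render figures (default `TRUE`).
#' @return Invisibly, a list with the main in-memory results: `qc`, `maf`,
#'   `assoc` (named by `outcome_stratum`), `sexdiff` (named by outcome),
#'   `enrichment`, `manifest`.
#' @export
run_full_pipeline <- function(config, plots = TRUE) {
  config <- run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("snpsexdiff")),
                   seed = config$seed, stages = character())

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    study <- generate_study(sim)
    gm <- study$genotypes; samples <- study$samples
    write_results(study$truth, file.path(out, "truth.tsv"))
    manifest$inputs <- list(simulated = TRUE)
  } else {
    for (f in c("genotypes", "variants", "phenotypes")) {
      if (!file.exists(config[[f]])) stop("missing input file: ", config[[f]])
    }
    variants <- read_variants(config$variants)
    gm <- read_genotypes(config$genotypes, dialect = "tsv", variants = variants)
    samples <- read_phenotypes(config$phenotypes)
    manifest$inputs <- lapply(
      config[c("genotypes", "variants", "phenotypes")],
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))
    )
  }
  manifest$stages <- c(manifest$stages, "input")

  # --- qc -----------------------------------------------------------------
  cr <- call_rate_filter(gm, config$min_call_rate)
  gm <- orient_minor_allele(cr$genotypes, samples, x_mode = config$x_mode)
  hwe <- hwe_screen(gm, samples, alpha = config$alpha_hwe, x_mode = config$x_mode)
  maf <- maf_by_sex(gm, samples, x_mode = config$x_mode)
  write_results(hwe$results, file.path(out, "hwe.tsv"))
  write_results(maf$summary, file.path(out, "maf.tsv"))
  writeLines(c(
    sprintf("variants in: %d", cr$report$n_removed + cr$report$n_retained),
    sprintf("variants removed by call-rate filter (< %.2f): %d (%.1f%%)",
            config$min_call_rate, cr$report$n_removed,
            100 * cr$report$removal_fraction),
    sprintf("variants retained: %d", cr$report$n_retained),
    sprintf("HWE Bonferroni threshold (alpha %.3g / %d tests): %.6g",
            config$alpha_hwe, nrow(gm$variants), hwe$threshold),
    sprintf("variants out of HWE (pooled stratum): %d",
            sum(hwe$results$out_of_hwe[hwe$results$stratum == "all"], na.rm = TRUE)),
    sprintf("female vs male MAF R-squared: %.4f", maf$r_squared)
  ), file.path(out, "qc_report.txt"))
  manifest$qc <- list(n_removed = cr$report$n_removed,
                      n_retained = cr$report$n_retained,
                      hwe_threshold = hwe$threshold,
                      maf_r_squared = maf$r_squared)
  manifest$stages <- c(manifest$stages, "qc")

  # --- association --------------------------------------------------------
  assoc <- list()
  for (oc in OUTCOME_NAMES) {
    for (st in c("F", "M")) {
      res <- assoc_scan(gm, samples, outcome = oc, stratum = st,
                        alpha_report = config$alpha_report,
                        alpha_enrich = config$alpha_enrich)
      assoc[[paste(oc, st, sep = "_")]] <- res
      write_results(res, file.path(out, sprintf("assoc_%s_%s.tsv", oc, st)))
    }
  }
  manifest$stages <- c(manifest$stages, "assoc")

  # --- sex-differentiated tests -------------------------------------------
  sexdiff <- list()
  for (oc in OUTCOME_NAMES) {
    sd <- sexdiff_scan(assoc[[paste0(oc, "_F")]], assoc[[paste0(oc, "_M")]],
                       alpha_sex = config$alpha_enrich,
                       alpha_het = config$alpha_sexdiff)
    sexdiff[[oc]] <- sd
    write_results(sd, file.path(out, sprintf("sexdiff_%s.tsv", oc)))
  }
  manifest$stages <- c(manifest$stages, "sexdiff")

  # --- enrichment ---------------------------------------------------------
  trait_tables <- dplyr::bind_rows(lapply(TRAIT_NAMES, function(t) {
    build_trait_table(assoc[[paste0(t, "_F")]], assoc[[paste0(t, "_M")]],
                      trait = t, alpha = config$alpha_enrich)
  }))
  enrichment <- dplyr::bind_rows(trait_tables, pooled_enrichment(trait_tables))
  write_results(enrichment, file.path(out, "enrichment.tsv"))
  manifest$stages <- c(manifest$stages, "enrichment")

  # --- figures ------------------------------------------------------------
  if (plots) {
    volcano(assoc[["melanoma_F"]], threshold = config$alpha_report,
            path = file.path(out, "volcano_melanoma_F.png"))
    volcano(assoc[["melanoma_M"]], threshold = config$alpha_report,
            path = file.path(out, "volcano_melanoma_M.png"))
    manhattan_sexdiff(sexdiff[["melanoma"]], gm$variants,
                      threshold = config$alpha_report,
                      path = file.path(out, "manhattan_melanoma.png"))
    maf_scatter(maf, path = file.path(out, "maf_scatter.png"))
    enrichment_bars(trait_tables, path = file.path(out, "enrichment_bars.png"))
    manifest$stages <- c(manifest$stages, "plots")
  }

  manifest$config <- config[setdiff(names(config), "simulate")]
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(list(qc = list(call_rate = cr$report, hwe = hwe), maf = maf,
                 assoc = assoc, sexdiff = sexdiff, enrichment = enrichment,
                 manifest = manifest))
}
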