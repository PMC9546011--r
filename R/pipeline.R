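#' Validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration, checks every key against the
#' documented schema, fills defaults mirroring the standard analysis
#' (call rate 0.75, MAF 0.05, 10,000 bp thinning, demographic projection
#' (100, 10), psi projection (10, 10), 1000 permutations) and returns the
#' fully defaulted config. Unknown keys and range violations are reported
#' with their key path.
#'
#' @param path configuration file path, or a named list already in memory.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a mapping")
  defaults <- list(
    input = list(vcf = NULL, popmap = NULL, outgroup = NULL),
    simulate = list(enabled = FALSE, preset = "serial_founder",
                    n_demes = 3, founder_fraction = 0.02, interval = 0.1,
                    migration = 0.05, n_per_deme = 8, n_loci = 1000,
                    theta = 1, missing_rate = 0),
    filters = list(call_rate = 0.75, maf = 0.05, thin_bp = 10000),
    sfs = list(projection = c(100, 10), psi_projection = c(10, 10)),
    stats = list(enabled = TRUE, n_perm = 1000),
    ibd = list(enabled = TRUE, n_perm = 999, distance = "edwards"),
    fit = list(enabled = FALSE, models = "found_and_grow",
               sizes = c(20, 10), passes = 3, runs_per_pass = 10,
               n_reps = 5000, maxit = 60, timeout = 60),
    out_dir = "pacifex_out",
    seed = 1)
  known <- names(defaults)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- defaults
  for (k in names(cfg)) {
    if (is.list(defaults[[k]])) {
      bad <- setdiff(names(cfg[[k]]), names(defaults[[k]]))
      if (length(bad))
        stop("unknown config key(s): ", paste(paste0(k, ".", bad),
                                              collapse = ", "))
      merged[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else {
      merged[[k]] <- cfg[[k]]
    }
  }
  chk <- function(cond, msg) if (!cond) stop("config error: ", msg)
  f <- merged$filters
  chk(f$call_rate >= 0 && f$call_rate <= 1, "filters.call_rate not in [0, 1]")
  chk(f$maf >= 0 && f$maf <= 0.5, "filters.maf not in [0, 0.5]")
  chk(f$thin_bp > 0, "filters.thin_bp must be > 0")
  chk(merged$stats$n_perm >= 1, "stats.n_perm must be >= 1")
  chk(merged$ibd$n_perm >= 1, "ibd.n_perm must be >= 1")
  chk(merged$ibd$distance %in% c("edwards", "ibs"),
      "ibd.distance must be 'edwards' or 'ibs'")
  chk(all(merged$sfs$projection >= 2), "sfs.projection sizes must be >= 2")
  chk(all(merged$fit$models %in% c("found_and_grow", "three_epoch",
                                   "two_epoch_admixture", "zhan")),
      "fit.models contains an unknown model")
  if (!merged$simulate$enabled) {
    for (k in c("vcf", "popmap", "outgroup")) {
      chk(!is.null(merged$input[[k]]), paste0("input.", k, " is required"))
      chk(file.exists(merged$input[[k]]),
          paste0("input.", k, ": file not found"))
    }
  }
  structure(merged, class = "pipeline_config")
}

# per-stage seeds derived from the master seed by a stable string hash, so
# adding a stage never shifts another stage's stream
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Chains the stages simulate | filter | sfs | stats | ibd | fit from one
#' validated config, writing every stage's outputs plus a manifest (inputs,
#' thresholds, per-stage counts, seeds and output checksums) under the
#' output directory. Re-running an identical config reproduces every
#' numeric output.
#'
#' @param config a `pipeline_config` from [validate_config()], or a path.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- simulate or load -----------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    stage <- "simulate"
    tryCatch({
      s <- config$simulate
      sc <- serial_founder_preset(s$n_demes,
                                  founder_fraction = s$founder_fraction,
                                  interval = s$interval,
                                  migration = s$migration)
      ds <- simulate_dataset(sc, rep(s$n_per_deme, s$n_demes), s$n_loci,
                             theta = s$theta, missing_rate = s$missing_rate,
                             seed = stage_seed(config$seed, stage))
      write_dataset(ds, file.path(out, "simulated"))
      gm <- ds$gm
      popmap <- ds$popmap
      outgroup <- ds$outgroup
      manifest$stages$simulate <- list(
        n_snps = ncol(gm$calls), n_samples = nrow(gm$calls),
        seed = stage_seed(config$seed, stage))
      log_stage(stage, ncol(gm$calls), " SNPs simulated")
    }, error = function(e) fail(stage, e))
  } else {
    stage <- "load"
    tryCatch({
      gm <- read_vcf(config$input$vcf)
      popmap <- read_popmap(config$input$popmap)
      og <- utils::read.table(config$input$outgroup, sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
      outgroup <- as_tibble(og)
      manifest$stages$load <- list(n_snps = ncol(gm$calls),
                                   n_samples = nrow(gm$calls))
      log_stage(stage, ncol(gm$calls), " SNPs loaded")
    }, error = function(e) fail(stage, e))
  }

  # --- filter ----------------------------------------------------------
  stage <- "filter"
  tryCatch({
    f <- config$filters
    r1 <- filter_individuals_by_call_rate(gm, f$call_rate)
    r2 <- filter_loci_by_maf(r1$gm, f$maf)
    r3 <- thin_loci_by_distance(r2$gm, f$thin_bp,
                                seed = stage_seed(config$seed, stage))
    write_filter_report(r1$report, file.path(out, "filter_call_rate.tsv"))
    write_filter_report(r2$report, file.path(out, "filter_maf.tsv"))
    write_filter_report(r3$report, file.path(out, "filter_thin.tsv"))
    gm_stats <- r2$gm   # diversity / F_ST / IBD use the unthinned set
    gm_sfs <- r3$gm     # spectra use the thinned set
    manifest$stages$filter <- list(
      call_rate = f$call_rate, maf = f$maf, thin_bp = f$thin_bp,
      removed_samples = r1$report$n_removed,
      removed_maf = r2$report$n_removed, removed_thin = r3$report$n_removed,
      n_snps_stats = ncol(gm_stats$calls), n_snps_sfs = ncol(gm_sfs$calls))
    log_stage(stage, ncol(gm_sfs$calls), " SNPs after thinning")
  }, error = function(e) fail(stage, e))

  pops <- unique(popmap$pop[popmap$sample %in% gm_stats$sample_ids])

  # --- sfs -------------------------------------------------------------
  stage <- "sfs"
  tryCatch({
    if (length(pops) >= 2) {
      sfs2 <- build_joint_sfs(gm_sfs, popmap, pops[1:2], outgroup)
      proj <- pmin(config$sfs$projection, sfs2$sizes)
      proj <- pmax(proj, 2)
      write_dadi_sfs(project(sfs2, proj), file.path(out, "joint_sfs.fs"))
      manifest$stages$sfs <- list(pops = pops[1:2], sizes = sfs2$sizes,
                                  projection = proj,
                                  n_sites = sfs_total(sfs2))
      log_stage(stage, round(sfs_total(sfs2)), " sites in joint SFS")
    }
  }, error = function(e) fail(stage, e))

  # --- stats -----------------------------------------------------------
  if (isTRUE(config$stats$enabled)) {
    stage <- "stats"
    tryCatch({
      div <- diversity(gm_stats, popmap)
      taj <- dplyr::bind_rows(lapply(pops, function(p) {
        s1 <- build_joint_sfs(gm_sfs, popmap, p, outgroup)
        d <- tryCatch(tajimas_d(s1), error = function(e) NULL)
        tibble(pop = p, tajimas_d = if (is.null(d)) NA_real_ else d$D,
               S = if (is.null(d)) 0 else d$S)
      }))
      readr::write_tsv(dplyr::left_join(div, taj, by = "pop"),
                       file.path(out, "diversity.tsv"))
      pairs <- utils::combn(pops, 2, simplify = FALSE)
      seedv <- stage_seed(config$seed, stage)
      fst <- dplyr::bind_rows(lapply(pairs, function(pr) {
        res <- tryCatch(
          fst_permutation_test(gm_stats, popmap, pr[1], pr[2],
                               n_perm = config$stats$n_perm, seed = seedv),
          error = function(e) tibble(theta = NA_real_, p = NA_real_,
                                     n_perm = config$stats$n_perm,
                                     seed = seedv))
        dplyr::bind_cols(tibble(pop_a = pr[1], pop_b = pr[2]), res)
      }))
      readr::write_tsv(fst, file.path(out, "fst.tsv"))
      npsi <- config$sfs$psi_projection[1]
      psis <- dplyr::bind_rows(lapply(pairs, function(pr) {
        s2 <- build_joint_sfs(gm_sfs, popmap, pr, outgroup)
        tgt <- min(npsi, s2$sizes)
        out_psi <- tryCatch(psi(project(s2, c(tgt, tgt))),
                            error = function(e)
                              tibble(from = pr[1], to = pr[2],
                                     psi = NA_real_, n_sites = 0))
        out_psi
      }))
      readr::write_tsv(psis, file.path(out, "psi.tsv"))
      tr <- neighbor_joining(ibs_distance(gm_stats))
      write_newick(tr, file.path(out, "nj_ibs.nwk"))
      manifest$stages$stats <- list(n_pops = length(pops), seed = seedv,
                                    n_perm = config$stats$n_perm)
      log_stage(stage, "diversity/F_ST/psi/NJ written")
    }, error = function(e) fail(stage, e))
  }

  # --- ibd -------------------------------------------------------------
  if (isTRUE(config$ibd$enabled) && "lat" %in% names(popmap)) {
    stage <- "ibd"
    tryCatch({
      keep <- match(popmap$sample, gm_stats$sample_ids)
      pm <- popmap[!is.na(keep), ]
      gmk <- gm_subset(gm_stats, samples = keep[!is.na(keep)])
      gen <- if (config$ibd$distance == "edwards") edwards_distance(gmk)
             else ibs_distance(gmk)
      geo <- geographic_distance(pm)
      mt <- mantel_test(gen, geo, n_perm = config$ibd$n_perm,
                        seed = stage_seed(config$seed, stage))
      readr::write_tsv(mt, file.path(out, "ibd_mantel.tsv"))
      manifest$stages$ibd <- as.list(mt)
      log_stage(stage, "Mantel r = ", round(mt$r, 3), ", p = ", mt$p)
    }, error = function(e) fail(stage, e))
  }

  # --- fit -------------------------------------------------------------
  if (isTRUE(config$fit$enabled) && length(pops) >= 2) {
    stage <- "fit"
    tryCatch({
      fc <- config$fit
      sfs2 <- build_joint_sfs(gm_sfs, popmap, pops[1:2], outgroup)
      tgt <- pmin(fc$sizes, sfs2$sizes)
      obs <- project(sfs2, tgt)
      seedv <- stage_seed(config$seed, stage)
      fits <- lapply(fc$models, function(mn) {
        fit_model(obs, dem_model(mn),
                  optimizer = optimizer_config(
                    passes = fc$passes, runs_per_pass = fc$runs_per_pass,
                    maxit = fc$maxit, timeout = fc$timeout, seed = seedv),
                  engine = engine_config(fc$n_reps, seed = seedv))
      })
      for (i in seq_along(fits))
        write_fit(fits[[i]], file.path(out, paste0("fit_", fc$models[i],
                                                   ".tsv")))
      readr::write_tsv(dplyr::bind_rows(lapply(fits, glance)),
                       file.path(out, "fit_summary.tsv"))
      manifest$stages$fit <- list(models = fc$models, sizes = tgt,
                                  seed = seedv)
      log_stage(stage, length(fits), " model(s) fitted")
    }, error = function(e) fail(stage, e))
  }

  # --- manifest --------------------------------------------------------
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest$outputs <- lapply(
    setNames(as.list(file.path(out, files)), files),
    function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
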