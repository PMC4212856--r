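#' Assemble a full-analysis run configuration
#'
#' @param genotype,samples input TSV paths (see [read_dataset()]).
#' @param out_dir output directory (created if absent).
#' @param filter_lower,filter_upper locus retention band
#'   ([filter_loci()]).
#' @param maf_threshold PLP criterion ([diversity()]).
#' @param first_width_km,n_classes distance-class scheme
#'   ([build_distance_classes()]).
#' @param n_perm correlogram permutations.
#' @param mantel_perm Mantel permutations.
#' @param outlier_enabled run the neutrality scan and drop flagged loci
#'   before SGS and inbreeding.
#' @param outlier_iterations,outlier_upper,outlier_lower,outlier_k
#'   [scan_outliers()] settings.
#' @param mcmc_steps,mcmc_burn_in,mcmc_thin,mcmc_shapes inbreeding MCMC
#'   settings ([prior_sensitivity()]).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list of class `run_config`.
#' @export
run_config <- function(genotype, samples, out_dir = "aflpsgs_out",
                       filter_lower = 0.03, filter_upper = 0.97,
                       maf_threshold = 0.05,
                       first_width_km = 10, n_classes = 6,
                       n_perm = 9999, mantel_perm = 9999,
                       outlier_enabled = TRUE, outlier_iterations = 50000,
                       outlier_upper = 0.99, outlier_lower = 0.01,
                       outlier_k = 2000,
                       mcmc_steps = 100000, mcmc_burn_in = 10000,
                       mcmc_thin = 10,
                       mcmc_shapes = list(c(0.1, 0.1), c(1, 1), c(5, 5)),
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Any field of [run_config()] may appear in the file; missing fields take
#' the defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  if (!is.null(y$mcmc_shapes)) y$mcmc_shapes <- lapply(y$mcmc_shapes, as.numeric)
  do.call(run_config, y)
}

.stage_seed <- function(master, k) (as.integer(master) * 97L + k * 1009L) %% 2000000011L

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

#' Run the full dominant-marker analysis pipeline
#'
#' Stages, in order: read and validate; locus frequency filter; per-patch
#' allele frequencies and diversity; FST-outlier neutrality scan (flagged
#' loci are removed from all downstream stages); pairwise/global FST and
#' Mantel test of isolation by distance; pairwise kinship, distance-class
#' autocorrelogram, log-distance regression and Sp; inbreeding MCMC under
#' several priors.  Per-stage TSV/JSON reports, a correlogram table and
#' figure, and a run log are written to `config$out_dir`.  A stage failure
#' aborts with the failing stage named; reports of completed stages are
#' retained.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all stage results.
#' @export
run_full_analysis <- function(config) {
  .assert(inherits(config, "run_config"), "config must come from run_config()",
          "aflpsgs_format_error")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t_all <- Sys.time()
  logmsg <- function(...) {
    line <- sprintf(...)
    writeLines(line, log_con)
    message(line)
  }
  logmsg("aflpsgs %s | master seed %s",
         as.character(utils::packageVersion("aflpsgs")), config$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      logmsg("stage %s FAILED: %s", name, conditionMessage(e))
      .err(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           "aflpsgs_stage_error")
    })
    logmsg("stage %-12s ok (%.2f s)", name,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  out <- list()

  ds <- stage("read", read_dataset(config$genotype, config$samples))
  ds <- stage("filter", filter_loci(ds, config$filter_lower, config$filter_upper))
  logmsg("  %d individuals, %d loci after filter; dropped: %s",
         nrow(ds$phenotypes), ncol(ds$phenotypes),
         paste(attr(ds, "dropped_loci"), collapse = ",") )

  out$diversity <- stage("diversity", {
    div <- diversity(ds, maf_threshold = config$maf_threshold)
    .write_tsv(div, file.path(config$out_dir, "diversity.tsv"))
    div
  })

  if (isTRUE(config$outlier_enabled)) {
    out$outliers <- stage("outliers", {
      sc <- scan_outliers(ds, iterations = config$outlier_iterations,
                          upper = config$outlier_upper,
                          lower = config$outlier_lower,
                          k_neighbors = config$outlier_k,
                          seed = .stage_seed(config$seed, 1L))
      .write_tsv(as.data.frame(sc), file.path(config$out_dir, "outliers.tsv"))
      sc
    })
    removed <- attr(out$outliers, "removed_loci")
    if (length(removed)) {
      keep <- setdiff(colnames(ds$phenotypes), removed)
      ds <- aflp_dataset(
        dominant_matrix(unclass(ds$phenotypes)[, keep, drop = FALSE]),
        ds$samples)
      logmsg("  removed %d outlier locus/loci: %s -> %d neutral loci retained",
             length(removed), paste(removed, collapse = ","), ncol(ds$phenotypes))
    }
  }
  out$n_loci_analysis <- ncol(ds$phenotypes)

  out$fst <- stage("fst", {
    fr <- locus_freqs(ds, per_population = TRUE)
    fst <- pairwise_fst(fr)
    pops <- fst$populations
    up <- which(upper.tri(fst$fst), arr.ind = TRUE)
    .write_tsv(data.frame(pop_i = pops[up[, 1]], pop_j = pops[up[, 2]],
                          fst = fst$fst[up], linearized = fst$linearized[up]),
               file.path(config$out_dir, "fst.tsv"))
    fst
  })

  out$mantel <- stage("mantel", {
    sm <- ds$samples[!duplicated(ds$samples$patch_id), ]
    sm <- sm[match(out$fst$populations, sm$patch_id), ]
    Dpop <- geo_distance_matrix(sample_table(data.frame(
      individual_id = sm$patch_id, patch_id = sm$patch_id,
      lat = sm$lat, lon = sm$lon)))
    mt <- mantel_test(out$fst$linearized, Dpop, n_perm = config$mantel_perm,
                      seed = .stage_seed(config$seed, 2L), log_geo = TRUE)
    .write_json(list(r = mt$r, p = mt$p, n_permutations = mt$n_permutations,
                     alternative = mt$alternative),
                file.path(config$out_dir, "mantel.json"))
    mt
  })

  classes <- build_distance_classes(config$first_width_km, config$n_classes)
  K <- stage("kinship", {
    K <- kinship_matrix(ds)
    .write_tsv(as.data.frame(K), file.path(config$out_dir, "kinship_pairs.tsv"))
    K
  })
  out$kinship <- K
  D <- geo_distance_matrix(ds$samples)

  out$correlogram <- stage("correlogram", {
    ac <- autocorrelogram(K, D, classes, n_perm = config$n_perm,
                          seed = .stage_seed(config$seed, 3L))
    .write_tsv(as.data.frame(ac)[, c("lower_km", "upper_km", "n_pairs",
                                     "mean_kinship", "jackknife_se",
                                     "env_lo", "env_hi")],
               file.path(config$out_dir, "correlogram.tsv"))
    grDevices::pdf(file.path(config$out_dir, "correlogram.pdf"), 6, 4)
    plot(ac)
    grDevices::dev.off()
    ac
  })

  out$sp <- stage("sp", {
    sp <- regression_slope_sp(K, D, classes)
    .write_json(list(b1 = sp$b1, se_b1 = sp$se_b1, f1 = sp$f1,
                     se_f1 = sp$se_f1, sp = sp$sp, se_sp = sp$se_sp,
                     detected = sgs_detected(out$correlogram, sp)),
                file.path(config$out_dir, "sp.json"))
    sp
  })

  out$inbreeding <- stage("inbreeding", {
    ps <- prior_sensitivity(ds, shapes = config$mcmc_shapes,
                            n_steps = config$mcmc_steps,
                            burn_in = config$mcmc_burn_in,
                            thin = config$mcmc_thin,
                            seed = .stage_seed(config$seed, 4L))
    .write_json(lapply(seq_len(nrow(ps)), function(k) {
      list(alpha = ps$alpha[k], beta = ps$beta[k], F = ps$F[k],
           ci = c(ps$ci_lower[k], ps$ci_upper[k]),
           logL_mean = ps$logL_mean[k], logL_sd = ps$logL_sd[k])
    }), file.path(config$out_dir, "inbreeding.json"))
    ps
  })

  logmsg("pipeline done (%.1f s total)",
         as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  invisible(out)
}
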