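#' Pipeline run configuration
#'
#' A single validated configuration for the end-to-end pipeline. Stage
#' parameter defaults mirror the package-wide analysis conventions: 0.6 cM
#' IBD gap merging, 2 cM ancestry-masked IBD threshold, 1 Mb minimum ROH,
#' DAF 0.05 rare stratum, r2 0.1 / 50 kb LD pruning, the five polygenic
#' score thresholds, FDR 0.05. Unknown keys are rejected.
#'
#' @param sim A [sim_config()] describing the synthetic cohort.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "roh", "ibd", "ne", "burden", "traits")` (dependencies
#'   of requested stages are implied: everything consumes `simulate`).
#' @param params Named list overriding stage parameters; recognised keys:
#'   `min_roh_kb`, `min_roh_snps`, `max_gap_cm`, `max_discordant`,
#'   `min_ibd_cm`, `ne_G`, `ne_lambda`, `daf_tau`, `ld_r2`, `window_kb`,
#'   `fdr_q`, `pgs_thresholds`, `ibd_ancestry`, `max_ibd_pairs`.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "roh", "ibd", "ne", "burden",
                                  "traits"),
                       params = list()) {
  all_stages <- c("simulate", "roh", "ibd", "ne", "burden", "traits")
  if (!all(stages %in% all_stages)) {
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, all_stages), collapse = ", ")))
  }
  defaults <- list(min_roh_kb = 1000, min_roh_snps = 10, max_gap_cm = 0.6,
                   max_discordant = 1, min_ibd_cm = 2, ne_G = 40,
                   ne_lambda = 1, daf_tau = 0.05, ld_r2 = 0.1,
                   window_kb = 50, fdr_q = 0.05,
                   pgs_thresholds = c(0.1, 0.01, 0.001, 1e-5, 1e-8),
                   ibd_ancestry = sim$ancestries[1L], max_ibd_pairs = 200)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown parameter key(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(params)] <- params
  structure(list(sim = sim, stages = union("simulate", stages),
                 params = defaults),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may carry `seed`, `stages`, a `sim` block (scalar
#' [sim_config()] fields) and a `params` block; anything else is
#' rejected.
#'
#' @param path YAML path.
#' @param seed Optional seed overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), c("seed", "stages", "sim", "params"))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  sim_args <- y$sim
  if (!is.null(seed)) sim_args$seed <- seed
  else if (!is.null(y$seed)) sim_args$seed <- y$seed
  sim <- do.call(sim_config, sim_args)
  run_config(sim = sim,
             stages = if (is.null(y$stages)) c("simulate", "roh", "ibd",
                                               "ne", "burden", "traits")
                      else unlist(y$stages),
             params = if (is.null(y$params)) list() else y$params)
}

#' Run the pipeline end to end
#'
#' Executes simulate -> ROH -> IBD merging/masking -> Ne inference ->
#' burden -> trait models in dependency order, skipping disabled stages,
#' writing standard-format outputs under `out_dir` and returning a
#' manifest with the config hash, per-stage seeds, output checksums and
#' wall times. Deterministic stages reproduce identical checksums under
#' identical configs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  manifest <- list(config_hash = hash_object(config),
                   seed = config$sim$seed, stages = list())
  outputs <- character(0)
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, wall_s = round(proc.time()[["elapsed"]] - t0, 3))
  }

  st <- t_stage({
    bundle <- simulate_cohort(config$sim, ibd_ancestry = p$ibd_ancestry,
                              max_ibd_pairs = p$max_ibd_pairs)
    write_vcf(bundle$geno, file.path(out_dir, "genotypes.vcf"))
    write_tracts(bundle$tracts, file.path(out_dir, "tracts.tsv"))
    write_segments(bundle$ibd, file.path(out_dir, "ibd.tsv"))
    write_segments(bundle$roh_truth, file.path(out_dir, "roh_truth.tsv"))
    write_phenotypes(bundle$phenotypes, file.path(out_dir, "phenotypes.tsv"))
    write_genetic_map(config$sim$map, file.path(out_dir, "genetic_map.txt"))
    ann <- simulate_annotations(config$sim, bundle$geno)
    write_annotations(ann, file.path(out_dir, "annotations.tsv"))
    list(bundle = bundle, ann = ann)
  })
  bundle <- st$value$bundle
  ann <- st$value$ann
  outputs <- c(outputs, "genotypes.vcf", "tracts.tsv", "ibd.tsv",
               "roh_truth.tsv", "phenotypes.tsv", "genetic_map.txt",
               "annotations.tsv")
  manifest$stages$simulate <- list(wall_s = st$wall_s,
                                   seeds = bundle$manifest$stage_seeds)
  map <- config$sim$map

  if ("roh" %in% config$stages) {
    st <- t_stage({
      roh <- detect_roh(bundle$geno, min_length_kb = p$min_roh_kb,
                        min_snps = p$min_roh_snps)
      roh <- add_segment_lengths(roh, map)
      if (nrow(roh)) {
        roh$class <- as.character(classify_roh(roh))
        roh <- assign_roh_ancestry(roh, bundle$tracts)
      }
      write_segments(roh, file.path(out_dir, "roh.tsv"))
      roh
    })
    manifest$stages$roh <- list(wall_s = st$wall_s, n_roh = nrow(st$value),
                                n_assigned = sum(st$value$status == "assigned"))
    outputs <- c(outputs, "roh.tsv")
  }

  if ("ibd" %in% config$stages || "ne" %in% config$stages) {
    st <- t_stage({
      merged <- merge_ibd_gaps(bundle$ibd, bundle$geno, map,
                               max_gap_cm = p$max_gap_cm,
                               max_discordant = p$max_discordant)
      masked <- ancestry_specific_ibd(merged, bundle$tracts, map,
                                      ancestry = p$ibd_ancestry,
                                      min_cm = p$min_ibd_cm)
      write_segments(masked, file.path(out_dir, "ibd_masked.tsv"))
      masked
    })
    manifest$stages$ibd <- list(wall_s = st$wall_s, n_masked = nrow(st$value))
    outputs <- c(outputs, "ibd_masked.tsv")
    masked <- st$value
  }

  if ("ne" %in% config$stages) {
    st <- t_stage({
      L_tot <- sum(attr(bundle$ibd, "pair_L"))
      sp <- ibd_spectrum(masked$length_cm,
                         edges_cm = c(default_ibd_bins(p$min_ibd_cm), Inf),
                         L_total = L_tot)
      fit <- fit_ne(sp, G = p$ne_G, lambda = p$ne_lambda)
      utils::write.table(ne_fit_table(fit),
                         file.path(out_dir, "ne_trajectory.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fit
    })
    manifest$stages$ne <- list(wall_s = st$wall_s,
                               loglik = st$value$loglik,
                               converged = st$value$convergence == 0)
    outputs <- c(outputs, "ne_trajectory.tsv")
  }

  if ("burden" %in% config$stages) {
    st <- t_stage({
      pol <- polarize_and_daf(bundle$geno)
      classes <- classify_consequence(
        ann$consequence[match(pol$variants$id, ann$id)],
        ann$damaging[match(pol$variants$id, ann$id)])
      bt <- compute_burden(pol$derived, pol$daf, classes, tau = p$daf_tau)
      prop <- tract_ancestry_proportions(bundle$tracts, map)
      cors <- correlate_burden(bt, prop)
      utils::write.table(bt, file.path(out_dir, "burden.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cors, file.path(out_dir, "burden_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cors
    })
    manifest$stages$burden <- list(wall_s = st$wall_s)
    outputs <- c(outputs, "burden.tsv", "burden_correlations.tsv")
  }

  if ("traits" %in% config$stages) {
    st <- t_stage({
      phen <- bundle$phenotypes
      grm <- compute_grm(bundle$geno, ld_r2 = p$ld_r2,
                         window_kb = p$window_kb)
      y <- inverse_normal(phen$trait)
      covs <- cbind(age = phen$age, sex = phen$sex, grm$pcs[, 1:4])
      scan <- assoc_scan(bundle$geno, y, covs)
      scores <- clump_and_score(scan, bundle$geno,
                                pgs_config(clump_r2 = p$ld_r2,
                                           p_thresholds = p$pgs_thresholds))
      preds <- two_sd_standardize(
        cbind(pgs = scores[, 1L], ancestry = phen$ancestry_prop,
              roh = phen$sum_roh_bp, urban = phen$urban, edu = phen$edu,
              age = phen$age, sex = phen$sex),
        c("numeric", "numeric", "numeric", "binary", "numeric", "numeric",
          "binary"))
      lmm <- fit_lmm(y, preds, grm$K, locality = phen$locality,
                     fdr_q = p$fdr_q)
      utils::write.table(scan, file.path(out_dir, "assoc_scan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(individual = rownames(scores), scores),
                         file.path(out_dir, "pgs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(lmm$fixed, file.path(out_dir, "lmm_fixed.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lmm
    })
    manifest$stages$traits <- list(wall_s = st$wall_s,
                                   varcomp = as.list(st$value$varcomp))
    outputs <- c(outputs, "assoc_scan.tsv", "pgs.tsv", "lmm_fixed.tsv")
  }

  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(manifest$checksums) <- outputs
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
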