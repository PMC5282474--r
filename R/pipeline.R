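#' Default pipeline configuration
#'
#' A nested list describing one full phantom study: grid, cohort design,
#' pathology-parameter overrides, analysis settings and the master seed.
#' Serializable to YAML ([write_config()]) so a run can be reproduced from
#' its resolved configuration file alone.
#'
#' @param seed master seed.
#' @return a named list (class `dualpet_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    grid = list(shape = c(36L, 51L, 31L), voxel_size = c(0.4, 0.4, 0.4)),
    design = list(ages = c(5, 8, 13, 16), n_per_group = 8L,
                  genotypes = c("TG", "WT"),
                  tracers = c("tspo", "amyloid")),
    params = list(),  # overrides of pathology_params() defaults
    analysis = list(q = 0.05, fwhm_mm = 0, two_sided = FALSE,
                    target_voi = "target_forebrain",
                    pool_ages = list(total_Abeta = c(5, 8)))
  ), class = "dualpet_config")
}

#' Validate a pipeline configuration
#'
#' Explicit structural and range checks over every field used by
#' [run_pipeline()]; returns the config (with defaults filled in) or raises
#' an informative error.
#'
#' @param config a config list as from [default_config()] or
#'   [read_config()].
#' @return the validated, fully resolved config.
#' @export
validate_config <- function(config) {
  base <- default_config()
  assert_that(is.list(config), "config must be a list")
  bad <- setdiff(names(config), names(base))
  assert_that(length(bad) == 0, "unknown config section(s): %s",
              paste(bad, collapse = ", "))
  cfg <- modifyList(unclass(base), config)
  assert_that(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
                cfg$seed == round(cfg$seed), "seed must be a single integer")
  grid_spec(cfg$grid$shape, cfg$grid$voxel_size)           # validates
  do.call(cohort_design, c(cfg$design, list(seed = cfg$seed)))
  do.call(pathology_params, cfg$params)
  a <- cfg$analysis
  assert_that(a$q > 0 && a$q < 1, "analysis q must be in (0, 1)")
  assert_that(a$fwhm_mm >= 0, "analysis fwhm_mm must be >= 0")
  assert_that(is.logical(a$two_sided), "two_sided must be logical")
  structure(cfg, class = "dualpet_config")
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cfg_objects <- function(config) {
  list(grid = grid_spec(config$grid$shape, config$grid$voxel_size),
       design = do.call(cohort_design,
                        c(config$design, list(seed = config$seed))),
       params = do.call(pathology_params, config$params))
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its outputs to, a run
#' directory, so stages are individually re-runnable from persisted
#' intermediates. [run_pipeline()] chains them.
#'
#' @param config a validated config (see [validate_config()]).
#' @param dir run directory.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config, dir) {
  config <- validate_config(config)
  ob <- cfg_objects(config)
  atlas <- build_atlas(ob$grid)
  cohort <- simulate_cohort(ob$design, ob$params, atlas)
  write_cohort(cohort, dir)
  invisible(dir)
}

load_run <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.nii.gz"))
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  list(atlas = atlas, manifest = manifest)
}

#' @rdname pipeline_stages
#' @export
stage_quantify <- function(config, dir) {
  config <- validate_config(config)
  run <- load_run(dir)
  atlas <- run$atlas
  m <- run$manifest
  tgt <- voi_mask(atlas, config$analysis$target_voi)
  suvr <- vapply(seq_len(nrow(m)), function(i) {
    img <- read_image(file.path(dir, m$path[i]))
    compute_suvr(img, tgt, voi_mask(atlas, ref_voi_for_tracer(m$tracer[i])))
  }, numeric(1))
  st <- data.frame(subject_id = m$subject_id, genotype = m$genotype,
                   age_months = m$age_months, tracer = m$tracer,
                   target_voi = config$analysis$target_voi, suvr = suvr,
                   stringsAsFactors = FALSE)
  write.csv(st, file.path(dir, "suvr_table.csv"), row.names = FALSE)

  bm <- read.csv(file.path(dir, "biomarkers.csv"), stringsAsFactors = FALSE)
  long <- rbind(
    data.frame(genotype = st$genotype, age_months = st$age_months,
               measure = paste0(st$tracer, "_suvr"), value = st$suvr,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(setdiff(names(bm),
                                  c("subject_id", "genotype", "age_months")),
                          function(v)
      data.frame(genotype = bm$genotype, age_months = bm$age_months,
                 measure = v, value = bm[[v]], stringsAsFactors = FALSE)))
  )
  write.csv(summarize_groups(long), file.path(dir, "group_summaries.csv"),
            row.names = FALSE)
  invisible(dir)
}

map_tag <- function(tracer, age) sprintf("%s_%02.0fmo", tracer, age)

#' @rdname pipeline_stages
#' @export
stage_voxelwise <- function(config, dir) {
  config <- validate_config(config)
  run <- load_run(dir)
  if (!all(c("TG", "WT") %in% run$manifest$genotype)) {
    message("stage_voxelwise: need both genotypes; skipping")
    return(invisible(dir))
  }
  atlas <- run$atlas
  bm <- brain_mask(atlas)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  for (tr in unique(run$manifest$tracer)) {
    for (age in sort(unique(run$manifest$age_months))) {
      sel <- run$manifest$tracer == tr & run$manifest$age_months == age
      grp <- split(run$manifest$path[sel], run$manifest$genotype[sel])
      load_group <- function(paths) lapply(paths, function(p) {
        img <- read_image(file.path(dir, p))
        if (config$analysis$fwhm_mm > 0)
          img <- smooth_volume(img, config$analysis$fwhm_mm)
        img
      })
      tmap <- voxelwise_ttest(load_group(grp$TG), load_group(grp$WT), bm,
                              alternative = if (config$analysis$two_sided)
                                "two.sided" else "greater",
                              tracer = tr, age_months = age)
      bin <- fdr_binarize(tmap, config$analysis$q)
      tag <- map_tag(tr, age)
      write_image(image_volume(ifelse(bm, tmap$t, NaN), atlas$grid),
                  file.path(dir, "maps", paste0("tmap_", tag, ".nii.gz")))
      write_image(image_volume(array(as.numeric(bin$elevated),
                                     dim = dim(bm)), atlas$grid),
                  file.path(dir, "maps", paste0("binary_", tag, ".nii.gz")))
      jsonlite::write_json(
        list(tracer = tr, age_months = age, df = tmap$df,
             n_per_group = tmap$n_per_group, q = bin$q,
             t_threshold = bin$t_threshold,
             n_significant = bin$n_significant),
        file.path(dir, "maps", paste0("map_", tag, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

# rebuild t_score_map / binary_map objects from a run directory
read_maps <- function(dir, atlas, tracer, age) {
  bm <- brain_mask(atlas)
  tag <- map_tag(tracer, age)
  side <- jsonlite::read_json(file.path(dir, "maps",
                                        paste0("map_", tag, ".json")),
                              simplifyVector = TRUE)
  tdata <- read_image(file.path(dir, "maps",
                                paste0("tmap_", tag, ".nii.gz")))$data
  tarr <- array(NA_real_, dim = dim(bm)); tarr[bm] <- tdata[bm]
  tmap <- structure(list(t = tarr, p = NULL, df = side$df, mask = bm,
                         grid = atlas$grid, n_per_group = side$n_per_group,
                         tracer = tracer, age_months = age),
                    class = "t_score_map")
  ed <- read_image(file.path(dir, "maps",
                             paste0("binary_", tag, ".nii.gz")))$data
  bin <- structure(list(elevated = array(ed > 0.5, dim = dim(bm)) & bm,
                        t_threshold = side$t_threshold, q = side$q,
                        n_significant = side$n_significant, mask = bm,
                        grid = atlas$grid, df = side$df, tracer = tracer,
                        age_months = age),
                   class = "binary_map")
  list(tmap = tmap, bin = bin)
}

#' @rdname pipeline_stages
#' @export
stage_overlap <- function(config, dir) {
  config <- validate_config(config)
  run <- load_run(dir)
  atlas <- run$atlas
  bm <- brain_mask(atlas)
  ages <- sort(unique(run$manifest$age_months))
  if (!file.exists(file.path(dir, "maps",
                             paste0("map_", map_tag("tspo", ages[1]),
                                    ".json")))) {
    message("stage_overlap: no voxel-wise maps present; skipping")
    return(invisible(dir))
  }
  occ <- list(); dice <- list(); cats <- list()
  for (age in ages) {
    ts <- read_maps(dir, atlas, "tspo", age)
    am <- read_maps(dir, atlas, "amyloid", age)
    cat_map <- combine_categories(ts$bin, am$bin, bm, age_months = age)
    cats[[as.character(age)]] <- cat_map
    codes <- cat_map$codes; codes[!bm] <- NaN
    write_image(image_volume(array(as.numeric(codes), dim = dim(bm)),
                             atlas$grid),
                file.path(dir, "maps", sprintf("categories_%02.0fmo.nii.gz",
                                               age)))
    occ[[as.character(age)]] <- occupancy(cat_map, bm)
    dice[[as.character(age)]] <-
      data.frame(age_months = age,
                 dice_binary = dice_binary(ts$bin, am$bin),
                 dice_continuous = dice_continuous(ts$tmap, am$tmap, bm))
  }
  write.csv(do.call(rbind, occ), file.path(dir, "occupancy.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, dice), file.path(dir, "dice.csv"),
            row.names = FALSE)
  if (length(ages) >= 2) {
    tf <- do.call(rbind, lapply(seq_len(length(ages) - 1), function(i)
      transition_flows(cats[[as.character(ages[i])]],
                       cats[[as.character(ages[i + 1])]], bm)))
    write.csv(tf, file.path(dir, "transitions.csv"), row.names = FALSE)
  }
  invisible(dir)
}

# wide per-subject table joining SUVR endpoints and biomarkers
subject_table <- function(dir) {
  st <- read.csv(file.path(dir, "suvr_table.csv"), stringsAsFactors = FALSE)
  bm <- read.csv(file.path(dir, "biomarkers.csv"), stringsAsFactors = FALSE)
  wide <- bm
  for (tr in unique(st$tracer)) {
    sub <- st[st$tracer == tr, c("subject_id", "suvr")]
    names(sub)[2] <- paste0(tr, "_suvr")
    wide <- merge(wide, sub, by = "subject_id", all.x = TRUE)
  }
  wide
}

#' @rdname pipeline_stages
#' @export
stage_associate <- function(config, dir) {
  config <- validate_config(config)
  wide <- subject_table(dir)
  gs <- read.csv(file.path(dir, "group_summaries.csv"),
                 stringsAsFactors = FALSE)

  # Pearson correlations of sTREM2 with each imaging endpoint and total
  # amyloid, per genotype
  cors <- list()
  for (g in unique(wide$genotype)) {
    d <- wide[wide$genotype == g, ]
    for (v in intersect(c("tspo_suvr", "amyloid_suvr", "total_Abeta"),
                        names(d))) {
      if (sum(is.finite(d[[v]])) >= 3 && sd(d[[v]]) > 0) {
        ct <- pearson(d[[v]], d$sTREM2)
        cors[[length(cors) + 1L]] <-
          data.frame(genotype = g, x = v, y = "sTREM2", R = ct$R, p = ct$p,
                     n = ct$n, stringsAsFactors = FALSE)
      }
    }
  }
  cors <- do.call(rbind, cors)

  # age-adjusted standardized regressions, one imaging predictor per model
  tg <- wide[wide$genotype == "TG", ]
  regs <- list()
  for (v in intersect(c("tspo_suvr", "amyloid_suvr"), names(tg))) {
    if (nrow(tg) > 3 && sd(tg[[v]]) > 0) {
      fr <- fit_regression(tg, "sTREM2", c(v, "age_months"))
      regs[[length(regs) + 1L]] <-
        data.frame(outcome = "sTREM2", predictor = v,
                   beta = fr$beta[[v]], beta_p = fr$p[[v]],
                   beta_age = fr$beta[["age_months"]],
                   r_squared = fr$r_squared,
                   adj_r_squared = fr$adj_r_squared,
                   F = fr$F, df1 = fr$df1, df2 = fr$df2, n = fr$n,
                   stringsAsFactors = FALSE)
    }
  }
  regs <- if (length(regs)) do.call(rbind, regs) else NULL
  write.csv(cors, file.path(dir, "associations.csv"), row.names = FALSE)
  if (!is.null(regs)) {
    write.csv(regs, file.path(dir, "regressions.csv"), row.names = FALSE)
  }

  # ANOVA with Tukey across transgenic ages, per measure
  measures <- unique(gs$measure)
  if (length(unique(tg$age_months)) >= 2 && nrow(tg) > 0) {
    anova_rows <- list()
    for (msr in measures) {
      vals <- measure_values(tg, msr)
      if (is.null(vals)) next
      at <- anova_tukey(vals, tg$age_months)
      anova_rows[[msr]] <- data.frame(
        measure = msr, F = at$F, df1 = at$df1, df2 = at$df2, p = at$p,
        ks_p = if (length(vals) >= 5 && sd(vals) > 0)
          ks_normality(vals) else NA_real_,
        stringsAsFactors = FALSE)
    }
    write.csv(do.call(rbind, anova_rows), file.path(dir, "anova.csv"),
              row.names = FALSE)
  }

  # standardized-difference timeline against linearly aging wild-types
  if (all(c("TG", "WT") %in% wide$genotype)) {
    sds <- list()
    wt_ages <- range(gs$age_months[gs$genotype == "WT"])
    for (msr in measures) {
      tg_s <- gs[gs$genotype == "TG" & gs$measure == msr, ]
      wt_s <- gs[gs$genotype == "WT" & gs$measure == msr &
                   gs$age_months %in% wt_ages, c("age_months", "mean")]
      if (nrow(tg_s) == 0 || nrow(wt_s) != 2) next
      pool <- config$analysis$pool_ages[[msr]]
      if (!is.null(pool) && !all(pool %in% tg_s$age_months)) pool <- NULL
      sds[[msr]] <- standardized_difference_series(tg_s, wt_s,
                                                   pool_ages = pool,
                                                   measure = msr)
    }
    write.csv(do.call(rbind, sds), file.path(dir, "std_differences.csv"),
              row.names = FALSE)
  }

  # percent change of each transgenic measure versus the youngest age
  pc <- list()
  tg_gs <- gs[gs$genotype == "TG", ]
  for (msr in unique(tg_gs$measure)) {
    s <- tg_gs[tg_gs$measure == msr, ]
    s <- s[order(s$age_months), ]
    if (nrow(s) < 2 || s$mean[1] <= 0) next
    pc[[msr]] <- data.frame(
      measure = msr, age_baseline = s$age_months[1],
      age_months = s$age_months[-1],
      pct_change = percent_change(s$mean[-1], s$mean[1]),
      stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, pc), file.path(dir, "percent_changes.csv"),
            row.names = FALSE)
  invisible(dir)
}

measure_values <- function(wide, measure) {
  col <- if (measure %in% names(wide)) measure else {
    tr <- sub("_suvr$", "", measure)
    if (paste0(tr, "_suvr") %in% names(wide)) paste0(tr, "_suvr") else NULL
  }
  if (is.null(col)) return(NULL)
  v <- wide[[col]]
  if (all(is.finite(v))) v else NULL
}

read_csv_if <- function(path) {
  if (file.exists(path)) read.csv(path, stringsAsFactors = FALSE) else NULL
}

#' @rdname pipeline_stages
#' @export
stage_report <- function(config, dir) {
  config <- validate_config(config)
  report <- list(
    package_version = as.character(packageVersion("dualpet")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = fnv1a_hash(yaml::as.yaml(unclass(config))),
    occupancy = read_csv_if(file.path(dir, "occupancy.csv")),
    dice = read_csv_if(file.path(dir, "dice.csv")),
    transitions = read_csv_if(file.path(dir, "transitions.csv")),
    percent_changes = read_csv_if(file.path(dir, "percent_changes.csv")),
    std_differences = read_csv_if(file.path(dir, "std_differences.csv")),
    correlations = read_csv_if(file.path(dir, "associations.csv")),
    regressions = read_csv_if(file.path(dir, "regressions.csv")),
    anova = read_csv_if(file.path(dir, "anova.csv"))
  )
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file.path(dir, "report.json"))
}

#' Run the full phantom pipeline
#'
#' Chains simulate, quantify, voxelwise, overlap, associate and report into
#' one reproducible run: identical configs (including the master seed)
#' reproduce all numeric outputs bit-identically. The resolved configuration
#' is written beside the outputs as `resolved_config.yaml`.
#'
#' @param config a config list (see [default_config()]); validated first.
#' @param dir output run directory (created if needed).
#' @return path to `report.json`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), dir) {
  config <- validate_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(dir, "resolved_config.yaml"))
  stages <- list(simulate = stage_simulate, quantify = stage_quantify,
                 voxelwise = stage_voxelwise, overlap = stage_overlap,
                 associate = stage_associate, report = stage_report)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config, dir), error = function(e) {
      stop_dualpet("pipeline stage '%s' failed: %s", nm, conditionMessage(e))
    })
  }
  invisible(file.path(dir, "report.json"))
}
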