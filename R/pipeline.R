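#' Default pipeline configuration
#'
#' The bundled synthetic demo: a small cohort of synthetic "cases", each with
#' an icosphere sac carrying a planted pulsatile WSS field, a tetrahedral ball
#' carrying swirling vortex blobs, and a textured image volume with the two
#' wall ROIs; per-case summaries feed the correlation screen. Case geometry,
#' reversal fractions, blob sizes and image heterogeneity vary monotonically
#' with a latent per-case severity so the screen has structure to find.
#'
#' @param seed master RNG seed
#' @return named list accepted by [run_pipeline()]
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = c("simulate", "wss", "vortex", "morphology", "radiomics",
               "correlate"),
    n_cases = 8,
    n_saccular = 4,
    phases = 20,
    period = 1,
    wss = list(weighting = "area", rule = "rectangle"),
    vortex = list(criterion = "Q", threshold = 1, min_cells = 5,
                  cyclic = TRUE, mesh_edge_factor = 0.28),
    radiomics = list(policy = "fixed_bin_count", n_bins = 16, alpha = 0,
                     shift = 0, image_shape = c(12, 12, 8)),
    correlate = list(rho_threshold = 0.7, alpha = 0.05, mode = "abs")
  )
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the selected stages in dependency order into one run directory:
#' per-case stage outputs, a consolidated cohort CSV, the correlation-screen
#' CSV, and `manifest.json` with the config, per-stage seeds, package version
#' and md5 hashes of every output (the reproducibility contract: same config
#' implies same manifest hashes).
#'
#' @param config list as produced by [default_config()], or a path to a
#'   YAML/JSON config file
#' @param out_dir run directory (created; must be empty or absent)
#' @return (invisibly) the manifest list
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  base <- default_config(if (is.null(config$seed)) 1 else config$seed)
  config <- utils::modifyList(base, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  seeds <- derive_seeds(config$seed, config$n_cases * 4 + 1)
  n <- config$n_cases
  note("seed=%d n_cases=%d phases=%d", config$seed, n, config$phases)

  # latent per-case severity in (0, 1), shared across generators
  set.seed(seeds[length(seeds)])
  severity <- sort(stats::runif(n, 0.05, 0.95))
  subgroup <- rep(c("saccular", "fusiform"), length.out = n)
  radius <- 3 + 5 * severity                       # mm
  cohort <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                       subgroup = subgroup, severity = severity,
                       stringsAsFactors = FALSE)
  cases <- vector("list", n)

  if ("simulate" %in% stages) {
    for (i in seq_len(n)) {
      sac <- make_sphere_surface(radius[i], subdivisions = 2)
      wss <- make_pulsatile_wss_series(
        sac, magnitude = 1 + 3 * (1 - severity[i]),
        reversal_fraction = 0.45 * severity[i],
        phases = config$phases, period = config$period, seed = seeds[i])
      ball <- make_tet_ball(radius[i] * 0.8,
                            target_edge = radius[i] * 0.8 *
                              config$vortex$mesh_edge_factor)
      sigma <- radius[i] * (0.15 + 0.25 * severity[i])
      drift <- radius[i] * 0.3 * severity[i]
      vel <- make_vortex_velocity_series(
        ball,
        blobs = list(list(
          center = function(t) c(drift * cos(2 * pi * t / config$period),
                                 drift * sin(2 * pi * t / config$period), 0),
          sigma = sigma, omega = 10, axis = c(0, 0, 1))),
        phases = config$phases, period = config$period)
      shp <- config$radiomics$image_shape
      half <- array(FALSE, shp)
      half[, , seq_len(floor(shp[3] / 2))] <- TRUE
      img <- make_texture_image(
        shp, pattern = "gaussian_random_field",
        correlation_length = 0.5 + 2.5 * (1 - severity[i]),
        variance = 1 + 9 * severity[i], mean = 50 * severity[i] + 10,
        masks = list(wall_free_of_IST = half, wall_next_to_IST = !half),
        seed = seeds[n + i])
      cases[[i]] <- list(sac = sac, wss = wss$field, vel = vel$field,
                         img = img$image)
      cdir <- file.path(out_dir, "simulate", cohort$case_id[i])
      write_field_series(wss$field, file.path(cdir, "wss"))
      write_stl(sac, file.path(cdir, "sac.stl"))
      write_image_volume(img$image, file.path(cdir, "image"))
      jsonlite::write_json(
        list(truth_wss = wss$truth[c("f_actual", "osi", "tawss")],
             severity = severity[i]),
        file.path(cdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    note("simulate: wrote %d cases", n)
  } else {
    stop("the synthetic demo pipeline requires the simulate stage",
         call. = FALSE)
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE))
  }

  if ("wss" %in% stages) run_stage("wss", function() {
    for (i in seq_len(n)) {
      wm <- wall_metrics(cases[[i]]$wss, rule = config$wss$rule)
      s <- summarize_wall_metrics(wm, weighting = config$wss$weighting)
      cohort[i, c("avg_osi", "avg_ecap", "avg_rrt", "max_tawss")] <<-
        c(s$avg_osi, s$avg_ecap, s$avg_rrt, s$max_tawss)
    }
    note("wss: summarized %d cases (%s weighting)", n, config$wss$weighting)
  })

  if ("vortex" %in% stages) run_stage("vortex", function() {
    for (i in seq_len(n)) {
      vs <- vortex_summary(cases[[i]]$vel,
                           criterion = config$vortex$criterion,
                           threshold = config$vortex$threshold,
                           min_cells = config$vortex$min_cells,
                           cyclic = config$vortex$cyclic)
      cohort[i, c("vv", "noc", "noc_std", "mean_dvo")] <<-
        c(vs$mean_vv, mean(vs$noc), vs$noc_std, vs$mean_dvo)
    }
    note("vortex: criterion=%s threshold=%g min_cells=%d",
         config$vortex$criterion, config$vortex$threshold,
         config$vortex$min_cells)
  })

  if ("morphology" %in% stages) run_stage("morphology", function() {
    for (i in seq_len(n)) {
      sac <- cases[[i]]$sac
      mm <- morphology_metrics(sac, neck_point = c(0, 0, -radius[i] - 1e-9),
                               neck_normal = c(0, 0, 1),
                               parent_diameter = 3)
      cohort[i, c("volume", "surface_area", "height", "width",
                  "aspect_ratio", "size_ratio")] <<-
        as.numeric(mm[1, c("volume", "surface_area", "height", "width",
                           "aspect_ratio", "size_ratio")])
    }
    note("morphology: %d cases", n)
  })

  if ("radiomics" %in% stages) run_stage("radiomics", function() {
    for (i in seq_len(n)) {
      fv <- extract_feature_vector(
        cases[[i]]$img, policy = config$radiomics$policy,
        n_bins = config$radiomics$n_bins, alpha = config$radiomics$alpha,
        shift = config$radiomics$shift)
      for (roi in c("wall_free_of_IST", "wall_next_to_IST")) {
        v <- fv[[roi]]
        pref <- if (roi == "wall_free_of_IST") "free" else "next"
        names(v) <- paste0(pref, ".", gsub("[^A-Za-z0-9.]", "_", names(v)))
        cohort[i, names(v)] <<- v
      }
    }
    note("radiomics: Ng=%d policy=%s", config$radiomics$n_bins,
         config$radiomics$policy)
  })

  cohort_path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)

  screen_path <- NULL
  if ("correlate" %in% stages && "radiomics" %in% stages) {
    run_stage("correlate", function() {
      feats <- grep("^(free|next)\\.", names(cohort), value = TRUE)
      params <- list()
      if ("morphology" %in% stages)
        params$morphology <- c("volume", "surface_area", "aspect_ratio",
                               "size_ratio")
      if ("wss" %in% stages)
        params$wss <- c("avg_osi", "avg_ecap", "avg_rrt", "max_tawss")
      if ("vortex" %in% stages)
        params$vortex <- c("vv", "noc", "noc_std", "mean_dvo")
      res <- correlation_screen(cohort, feats, params,
                                rho_threshold = config$correlate$rho_threshold,
                                alpha = config$correlate$alpha,
                                mode = config$correlate$mode,
                                subgroup_col = "subgroup")
      screen_path <<- file.path(out_dir, "correlation_screen.csv")
      utils::write.csv(res, screen_path, row.names = FALSE)
      note("correlate: %d pairs, %d strong", nrow(res), sum(res$strong))
    })
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg_canon <- config
  cfg_canon$stages <- as.list(cfg_canon$stages)
  jsonlite::write_json(cfg_canon, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- list.files(out_dir, recursive = TRUE)
  outputs <- setdiff(outputs, "manifest.json")
  hashes <- as.character(tools::md5sum(file.path(out_dir, outputs)))
  manifest <- list(package_version = as.character(utils::packageVersion("aneuhemo")),
                   config_hash = as.character(tools::md5sum(cfg_path)),
                   seed = config$seed, stages = stages,
                   decisions = log,
                   outputs = stats::setNames(as.list(hashes), outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a YAML or JSON run configuration
#' @param path file ending in .yaml/.yml or .json
#' @return config list
#' @export
read_config <- function(path) {
  stop_if_not(file.exists(path), "config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
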