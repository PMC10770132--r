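#' Run the full cristae sorting analysis pipeline
#'
#' Orchestrates geometry construction, trajectory acquisition (the built-in
#' sorting generator or supplied coordinate files), curvature summaries,
#' compartmental partitioning with enrichment factors and spatial maps, and
#' the enrichment-curvature correlation, writing every stage product plus a
#' manifest to an output directory. Reruns with the same configuration and
#' seed reproduce stochastic stages bit-for-bit.
#'
#' The configuration (YAML file or equivalent list) has blocks:
#' \describe{
#'   \item{geometry}{arguments of [imm_geometry()].}
#'   \item{generator}{arguments of [sorting_model()]/[mc_sort()]: `species`
#'     (data frame columns as lists), `spacing`, `sweep_ns`, `n_sweeps`,
#'     `record_every`, `seed`; mutually exclusive with `input`.}
#'   \item{input}{`path` (+ optional `format`) of a trajectory readable by
#'     [read_frames()]; mutually exclusive with `generator`.}
#'   \item{analysis}{`t_a`, `t_b` (ns; default final half), `block` (ns,
#'     default 80), `running_window` (ns, default 40), `threshold`
#'     (percent, default 1.5), `binsize` (Angstrom, default 10).}
#'   \item{output}{`dir`.}
#' }
#'
#' @param config path to a YAML config file, or a list with the same
#'   structure.
#' @param output_dir overrides `config$output$dir`.
#' @return (invisibly) a list with the stage results: `geometry`,
#'   `curvature`, `compartments`, `enrichment`, `maps`, `correlation`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  out <- output_dir %||% cfg$output$dir %||% stop("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(obj, name, writer = data.table::fwrite) {
    path <- file.path(out, name)
    writer(obj, path)
    files <<- c(files, name)
    path
  }

  geom <- do.call(imm_geometry, cfg$geometry %||% list())

  seed <- cfg$generator$seed %||% NA
  if (!is.null(cfg$generator)) {
    gb <- cfg$generator
    sp <- if (!is.null(gb$species)) as.data.frame(gb$species)
          else default_sorting_species()
    model <- sorting_model(geom, species = sp,
                           spacing = gb$spacing %||% 8,
                           sweep_ns = gb$sweep_ns %||% 0.8,
                           kT = gb$kT %||% 1)
    run <- mc_sort(model, n_sweeps = gb$n_sweeps %||% 1500,
                   record_every = gb$record_every %||% 10,
                   seed = gb$seed %||% 1L)
    series <- count_by_compartment(run)
    map_input <- run
    curv <- region_curvature_summary(
      cbind(model$sites[, c("leaflet", "region")],
            H = model$sites$H, K = model$sites$K))
  } else {
    traj <- read_frames(cfg$input$path,
                        format = cfg$input$format %||% "auto")
    traj <- label_trajectory(traj, geom)
    series <- count_by_compartment(traj)
    map_input <- traj
    fr <- traj$frames[[length(traj$frames)]]
    mk <- marker_positions(traj$topology, fr$coords)
    lab <- fr$lipids
    flds <- lapply(c("inner", "outer"), function(lft) {
      sel <- !is.na(lab$leaflet) & lab$leaflet == lft
      if (sum(sel) < 20) return(NULL)
      estimate_curvature(mk$xyz[sel, , drop = FALSE], geom_hint = geom,
                         leaflet = lft)
    })
    curv <- region_curvature_summary(do.call(rbind, flds))
  }

  an <- cfg$analysis %||% list()
  lf <- lipid_fraction(series)
  t_a <- an$t_a %||% (lf$times[1] + diff(range(lf$times)) / 2)
  t_b <- an$t_b %||% max(lf$times)
  enr <- enrichment_factor(lf, t_a, t_b, block = an$block %||% 80)
  maps <- spatial_percent_change_map(map_input, geom,
                                     binsize = an$binsize %||% 10,
                                     t_a = t_a, t_b = t_b,
                                     threshold = an$threshold %||% 1.5,
                                     min_occupancy = an$min_occupancy %||% 0)
  corr <- enrichment_curvature_correlation(enr, curv)

  put(as.data.frame(enr), "enrichment.csv")
  put(curv, "curvature_summary.csv")
  put(as.data.frame(corr), "correlation.csv")
  cs_long <- compartment_series_table(series)
  put(cs_long, "compartment_counts.csv")
  for (sp in names(maps$maps)) {
    m <- maps$maps[[sp]]
    dimnames(m) <- list(rho = head(maps$rho_edges, -1),
                        z = head(maps$z_edges, -1))
    put(as.data.frame(as.table(m), responseName = "percent_change"),
        sprintf("map_%s.csv", sp))
  }

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  files <- c(files, "config.yaml")
  # content hash of the analysis configuration (output location excluded,
  # so reruns in different directories compare equal)
  cfg_core <- cfg
  cfg_core$output <- NULL
  hash_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_core, hash_path)
  cfg_md5 <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  manifest <- list(
    package = "immsort",
    version = as.character(utils::packageVersion("immsort")),
    config_md5 = cfg_md5,
    seed = seed,
    window = c(t_a, t_b),
    files = files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$files <- c(manifest$files, "manifest.json")

  invisible(list(geometry = geom, curvature = curv, compartments = series,
                 enrichment = enr, maps = maps, correlation = corr,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list or YAML file")
  if (!is.null(cfg$generator) && !is.null(cfg$input))
    stop("config error: supply exactly one of 'generator' or 'input'")
  if (is.null(cfg$generator) && is.null(cfg$input))
    stop("config error: supply one of 'generator' or 'input'")
  if (!is.null(cfg$input) && is.null(cfg$input$path))
    stop("config error: input block needs a 'path'")
  an <- cfg$analysis
  if (!is.null(an$t_a) && !is.null(an$t_b) && an$t_a >= an$t_b)
    stop("config error: t_a must be < t_b")
  invisible(TRUE)
}

# long-format view of a compartment_series for CSV export
compartment_series_table <- function(series) {
  d <- as.data.frame(as.table(series$counts), responseName = "n")
  names(d)[1] <- "frame"
  d$frame <- as.integer(d$frame)
  d$time <- series$times[d$frame]
  d[, c("time", "leaflet", "region", "species", "n")]
}
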