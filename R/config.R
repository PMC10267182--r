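config_schema <- function() {
  list(
    surface = list(kind = "model", params = "list"),
    cavity = list(omega_cm1 = "number", g_au = "number",
                  volume_nm3 = "number", polarization = "any",
                  n_modes = "number"),
    sampling = list(quanta = "any", rescale = "string", seed = "number"),
    integrator = list(dt_fs = "number", t_max_ps = "number",
                      output_stride = "number", r_crit_ang = "number"),
    analysis = list(delta = "number"),
    spectrum = list(n_modes = "number", orders = "any",
                    excitation_space = "any", nbasis = "number",
                    nquad = "any"),
    run = list(n_traj = "number", seed = "number", outdir = "string"))
}

#' Default run configuration
#'
#' Mirrors the study conditions: dt = 0.12 fs, t_max = 25 ps, R_crit =
#' 10 angstrom, ZPE in every mode plus one quantum in the H-bonded OH
#' stretch, one cavity mode polarized along the O-O axis, excitation space
#' (10, 9, 8, 7).
#'
#' @return nested configuration list of class `pq_config`
#' @export
default_config <- function() {
  structure(list(
    surface = list(kind = "model"),
    cavity = list(polarization = "oo-axis", n_modes = 1),
    sampling = list(quanta = "zpe+hb", rescale = "kinetic", seed = 1),
    integrator = list(dt_fs = 0.12, t_max_ps = 25, output_stride = 100,
                      r_crit_ang = 10),
    analysis = list(delta = 0.1),
    spectrum = list(n_modes = 6, orders = c(4, 3),
                    excitation_space = c(10, 9, 8, 7), nbasis = 14,
                    nquad = c(20, 16, 10, 8)),
    run = list(n_traj = 100, seed = 1, outdir = "polariqct-out")),
    class = "pq_config")
}

check_unknown_keys <- function(cfg, schema, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(schema))
      stop("unknown configuration key: ", path, nm)
    if (is.list(schema[[nm]]) && is.list(cfg[[nm]]) &&
        !is.null(names(cfg[[nm]])))
      check_unknown_keys(cfg[[nm]], schema[[nm]],
                         paste0(path, nm, "."))
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected with their full path; defaults are filled in;
#' inconsistent cavity couplings (both `g_au` and `volume_nm3` given but
#' disagreeing) are an error.
#'
#' @param path YAML file
#' @return resolved `pq_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  check_unknown_keys(user, config_schema())
  cfg <- default_config()
  for (sec in names(user)) {
    if (is.list(user[[sec]]))
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    else cfg[[sec]] <- user[[sec]]
  }
  cav <- cfg$cavity
  if (!is.null(cav$g_au) && !is.null(cav$volume_nm3)) {
    if (is.null(cav$omega_cm1))
      stop("cavity.omega_cm1 required with cavity coupling")
    v <- coupling_volume_convert(omega_cm1 = cav$omega_cm1,
                                 g = cav$g_au)$volume_nm3
    if (abs(v - cav$volume_nm3) > 1e-6 * max(v, cav$volume_nm3))
      stop("cavity.g_au and cavity.volume_nm3 are inconsistent: g = ",
           cav$g_au, " implies V = ", signif(v, 6), " nm^3, got ",
           cav$volume_nm3)
  }
  cfg
}

#' Write a resolved configuration as YAML
#'
#' @param cfg a `pq_config`
#' @param path output file
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

cavity_from_config <- function(cfg) {
  cav <- cfg$cavity
  if (is.null(cav$g_au) && is.null(cav$volume_nm3)) return(NULL)
  list(omega_cm1 = cav$omega_cm1, g = cav$g_au,
       volume_nm3 = if (is.null(cav$g_au)) cav$volume_nm3 else NULL,
       polarization = cav$polarization)
}

#' Run a trajectory-ensemble simulation from a configuration
#'
#' @param cfg a `pq_config`
#' @param model optional prebuilt `pq_model_surface`
#' @return list with `ensemble`, `model`, `config`
#' @export
run_simulation <- function(cfg, model = NULL) {
  if (!identical(cfg$surface$kind, "model"))
    stop("only surface.kind = 'model' is built in; supply external ",
         "surfaces through the package API")
  if (is.null(model)) model <- model_dimer_surface()
  sampling <- sampling_spec(quanta = cfg$sampling$quanta,
                            rescale = cfg$sampling$rescale)
  integ <- integrator_spec(dt_fs = cfg$integrator$dt_fs,
                           t_max_ps = cfg$integrator$t_max_ps,
                           output_stride = cfg$integrator$output_stride,
                           r_crit_ang = cfg$integrator$r_crit_ang)
  ens <- run_ensemble(cfg$run$n_traj, model, sampling, integ,
                      cavity = cavity_from_config(cfg),
                      seed = cfg$run$seed)
  list(ensemble = ens, model = model, config = cfg)
}

#' Write simulation outputs (JSON summary, TSV series, resolved config)
#'
#' @param sim result of [run_simulation()]
#' @param outdir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_outputs <- function(sim, outdir = sim$config$run$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ens <- sim$ensemble
  paths <- character(0)
  p <- file.path(outdir, "ensemble.json")
  jsonlite::write_json(list(
    n_traj = ens$n_traj, master_seed = ens$master_seed,
    tau_half_ps = ens$tau_half_ps,
    frac_dissociated = mean(!is.na(ens$t_diss_ps)),
    t_grid_ps = ens$t_grid_ps, P_t = ens$P_t,
    seeds = ens$seeds, cavity = ens$cavity), p,
    auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  p <- file.path(outdir, "dissociation.tsv")
  write.table(data.frame(t_ps = ens$t_grid_ps, P = ens$P_t), p,
              sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "config.yaml")
  write_config(sim$config, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write a channel-population table (and J distributions) as TSV
#'
#' @param channels a `pq_channels`
#' @param outdir output directory
#' @return invisibly, the paths written
#' @export
write_channels <- function(channels, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(outdir, "channels.tsv")
  write.table(channels$table, p, sep = "\t", row.names = FALSE,
              quote = FALSE)
  paths <- p
  for (ch in rownames(channels$jdist)) {
    fn <- gsub("[()+]", "", ch)
    p <- file.path(outdir, paste0("jdist_", fn, ".tsv"))
    write.table(data.frame(J = as.integer(colnames(channels$jdist)),
                           weight = channels$jdist[ch, ]), p,
                sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write an IR stick spectrum as TSV
#'
#' @param spectrum a `pq_spectrum`
#' @param path output file
#' @export
write_spectrum <- function(spectrum, path = "lines.tsv") {
  write.table(spectrum$lines[, c("freq_cm", "intensity_km_mol",
                                 "assignment")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
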