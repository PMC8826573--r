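## Pipeline orchestration: one YAML run configuration wiring the stages
## together. Each command writes its standard outputs plus a manifest
## recording every effective parameter. The package's functions are the
## primary interface; inst/scripts/abinterface provides a thin shell
## wrapper over runPipeline() for command-line use.

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("input", "domain_a", "domain_b")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config lacks fields: ", paste(miss, collapse = ", "))
  config
}

.config_selection <- function(spec, label) {
  ## accept "A:1-107", a single member list, or a list of either
  if (is.character(spec) ||
      all(c("chain", "from", "to") %in% names(spec))) {
    spec <- list(spec)
  }
  do.call(domainSelection, c(list(label = label), spec))
}

.config_elements <- function(config, which, structure, sel) {
  src <- config[[paste0("elements_", which)]]
  if (is.null(src)) src <- "detect"
  if (identical(src, "detect")) {
    assignStrands(structure, sel)
  } else {
    canonicalElements(src, structure, sel)
  }
}

.config_criteria <- function(config, is_traj) {
  ov <- config$contact_criteria
  if (is.null(ov)) ov <- list()
  defaults <- list(hbond_da_max = 3.5, hbond_angle_min = 110,
                   saltbridge_max = 4.0, hydrophobic_max = 4.5,
                   vdw_slack = 0.5,
                   heavy_atom_fallback = !is_traj)
  args <- utils::modifyList(defaults, ov)
  do.call(contactCriteria, args)
}

#' Run one analysis stage from a configuration
#'
#' Commands: "contacts" (time-resolved contact table, per-kind coarse
#' frequency tables, flareplot JSON), "orient" (orientation series and
#' torsion KDE), "energy" (electrostatic energy series), "openbook"
#' (per-residue salt-bridge scores plus a B-factor-colored PDB),
#' "diffmap" (difference maps between two classes of frequency tables),
#' "synth" (synthetic complex + trajectory emission). Every run writes
#' `manifest.yaml` with all effective parameters.
#'
#' @param config path to a YAML file or an equivalent named list. Common
#'   fields: input (PDB path), domain_a/domain_b (chain, from, to),
#'   elements_a/elements_b (domain kind, or "detect"), out_dir,
#'   contact_criteria overrides, energy (cutoff, dielectric, pqr), seed.
#' @param command one of contacts, orient, energy, diffmap, openbook,
#'   synth.
#' @return named list of output file paths, invisibly.
#' @export
runPipeline <- function(config,
                        command = c("contacts", "orient", "energy",
                                    "diffmap", "openbook", "synth")) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  emit <- function(name) file.path(out_dir, name)

  if (command == "synth") {
    sp <- cfg$synth
    if (is.null(sp)) sp <- list()
    seed <- if (is.null(cfg$seed)) 1 else cfg$seed
    dom_a <- buildToyDomain(chain = "A")
    dom_b <- buildToyDomain(chain = "B")
    cx <- assembleComplex(dom_a, dom_b,
                          torsion = if (is.null(sp$torsion)) 90
                                    else sp$torsion,
                          dC = if (is.null(sp$dC)) 30 else sp$dC)
    sim <- synthTrajectory(cx,
                           n_frames = if (is.null(sp$n_frames)) 100
                                      else sp$n_frames,
                           noise_sigma = if (is.null(sp$noise_sigma)) 0.1
                                         else sp$noise_sigma,
                           seed = seed)
    paths$trajectory <- writePDB(sim$traj, emit("synthetic.pdb"))
    yaml::write_yaml(list(torsion = sim$torsion), emit("truth.yaml"))
    paths$truth <- emit("truth.yaml")
    manifest <- list(command = command, config = cfg,
                     package_version = as.character(
                       utils::packageVersion("AbInterface")),
                     outputs = lapply(paths, as.character))
    yaml::write_yaml(manifest, emit("manifest.yaml"))
    paths$manifest <- emit("manifest.yaml")
    return(invisible(paths))
  }
  if (command == "diffmap") {
    stop("diffmap runs from frequency tables: use classAverage() and ",
         "differenceMap() on coarseGrain() outputs, or the ",
         "contacts command per system first")
  }

  cfg <- .load_config(cfg)
  is_traj <- isTRUE(cfg$trajectory)
  obj <- if (is_traj) readTrajectory(cfg$input) else readPDB(cfg$input)
  sel_a_spec <- .config_selection(cfg$domain_a, "a")
  sel_b_spec <- .config_selection(cfg$domain_b, "b")
  sel_a <- selectDomain(obj, sel_a_spec)
  sel_b <- selectDomain(obj, sel_b_spec)

  as_traj <- function(x) {
    if (methods::is(x, "Trajectory")) return(x)
    methods::new("Trajectory", topology = x,
                 frames = array(coords(x), c(nrow(atoms(x)), 3, 1)))
  }

  if (command == "contacts") {
    criteria <- .config_criteria(cfg, is_traj)
    tab <- trajectoryContacts(as_traj(obj), sel_a, sel_b, criteria)
    paths$contacts <- writeContactTable(tab, emit("contacts.tsv"))
    map_a <- .config_elements(cfg, "a", obj, sel_a_spec)
    map_b <- .config_elements(cfg, "b", obj, sel_b_spec)
    freq <- coarseGrain(tab, map_a, map_b,
                        system = if (is.null(cfg$system)) "run"
                                 else cfg$system)
    for (k in names(freq)) {
      paths[[paste0("freq_", k)]] <-
        writeCoarseTSV(freq[[k]], emit(sprintf("freq_%s.tsv", k)))
      paths[[paste0("flare_", k)]] <-
        exportFlareJSON(freq[[k]], emit(sprintf("flare_%s.json", k)))
    }
  } else if (command == "orient") {
    ref_st <- if (is.null(cfg$reference)) obj else readPDB(cfg$reference)
    ref <- buildReference(ref_st, sel_a, sel_b)
    series <- measureTrajectory(as_traj(obj), ref,
                                aliases = cfg$aliases)
    paths$orientation <- writeOrientationTSV(series,
                                             emit("orientation.tsv"))
    tor <- series[[2]]
    if (nrow(series) >= 2 && stats::sd(tor) > 0) {
      kde <- kdeDensity(tor)
      utils::write.table(
        data.frame(angle = kde$grid, density = kde$density),
        emit("torsion_kde.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      paths$kde <- emit("torsion_kde.tsv")
    }
  } else if (command == "energy") {
    en <- cfg$energy
    if (is.null(en)) en <- list()
    charges <- if (!is.null(en$pqr)) {
      atoms(readPQR(en$pqr, if (is_traj) obj@topology else obj))$charge
    } else {
      coarseCharges(obj)
    }
    cutoff <- if (is.null(en$cutoff)) 12 else en$cutoff
    dielectric <- if (is.null(en$dielectric)) 1 else en$dielectric
    es <- energySeries(as_traj(obj), sel_a, sel_b, charges,
                       cutoff = cutoff, dielectric = dielectric)
    paths$energy <- writeEnergyTSV(es, emit("energy.tsv"))
  } else if (command == "openbook") {
    criteria <- .config_criteria(cfg, is_traj)
    tab <- trajectoryContacts(as_traj(obj), sel_a, sel_b, criteria)
    kind <- if (is.null(cfg$kind)) "saltbridge" else cfg$kind
    scores <- openBookCounts(tab, kind = kind)
    utils::write.table(
      data.frame(residue = names(scores), score = as.vector(scores)),
      emit("openbook.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    paths$openbook <- emit("openbook.tsv")
    st <- if (is_traj) obj@topology else obj
    paths$pdb <- writeBfactorPDB(st, scores, emit("openbook.pdb"))
  }

  manifest <- list(command = command, config = cfg,
                   package_version = as.character(
                     utils::packageVersion("AbInterface")),
                   outputs = lapply(paths, as.character))
  yaml::write_yaml(manifest, emit("manifest.yaml"))
  paths$manifest <- emit("manifest.yaml")
  invisible(paths)
}
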