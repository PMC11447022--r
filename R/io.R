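#' Write / read the columnar trajectory format
#'
#' Self-describing text format: `# key: value` header lines (particle
#' count, frame period, units, seed, column schema) followed by one
#' tab-separated row per frame holding coordinates, energy terms and boost
#' records. Round-trips losslessly to the printed precision (`%.17g`).
#'
#' @param traj a `gamd_trajectory`.
#' @param path output file.
#' @return `write_trajectory`: the path, invisibly; `read_trajectory`: a
#'   `gamd_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gamd_trajectory"))
  np <- n_particles(traj); nf <- n_frames(traj)
  coord_cols <- as.vector(t(outer(seq_len(np), c("x", "y", "z"),
                                  function(p, a) sprintf("p%d_%s", p, a))))
  df <- data.frame(frame = seq_len(nf))
  for (p in seq_len(np)) {
    for (k in 1:3) {
      df[[sprintf("p%d_%s", p, c("x", "y", "z")[k])]] <- traj$coords[, p, k]
    }
  }
  df$V_total <- traj$energies$V_total
  df$V_dihedral <- traj$energies$V_dihedral
  df$dV_dihedral <- traj$boost$dV_dihedral
  df$dV_total <- traj$boost$dV_total
  df$dV_sum <- traj$boost$dV_sum
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gamdr_trajectory: v1",
               sprintf("# n_particles: %d", np),
               sprintf("# period_ps: %.17g", traj$period_ps),
               "# units: kcal/mol, Angstrom, ps",
               sprintf("# seed: %s",
                       if (is.null(traj$metadata$seed)) "NA"
                       else traj$metadata$seed),
               paste0("# columns: ", paste(names(df), collapse = "\t"))),
             con)
  fmt <- paste(c("%d", rep("%.17g", ncol(df) - 1)), collapse = "\t")
  writeLines(do.call(sprintf, c(list(fmt), df)), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- lapply(hdr, function(l) {
    m <- regmatches(l, regexec("^# ([^:]+): (.*)$", l))[[1]]
    if (length(m) == 3) m[2:3] else NULL
  })
  kv <- Filter(Negate(is.null), kv)
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  if (is.null(meta$gamdr_trajectory)) stop("not a gamdr trajectory file: ", path)
  cols <- strsplit(meta$columns, "\t")[[1]]
  df <- utils::read.table(path, comment.char = "#", sep = "\t",
                          col.names = cols, colClasses = "numeric")
  np <- as.integer(meta$n_particles)
  nf <- nrow(df)
  coords <- array(0, dim = c(nf, np, 3))
  for (p in seq_len(np)) {
    for (k in 1:3) {
      coords[, p, k] <- df[[sprintf("p%d_%s", p, c("x", "y", "z")[k])]]
    }
  }
  seed <- suppressWarnings(as.integer(meta$seed))
  new_trajectory(
    coords,
    tibble::tibble(frame = seq_len(nf), V_total = df$V_total,
                   V_dihedral = df$V_dihedral),
    tibble::tibble(frame = seq_len(nf), dV_dihedral = df$dV_dihedral,
                   dV_total = df$dV_total, dV_sum = df$dV_sum),
    period_ps = as.numeric(meta$period_ps),
    metadata = list(seed = seed, source = path))
}

config_schema <- list(
  system = c("kind", "barrier", "separation", "asymmetry", "mass",
             "k_spring", "extent", "n_beads", "torsion_barrier"),
  protocol = c("dt", "friction", "temperature", "minimize", "thermalize",
               "cmd_collect", "gamd_equilibrate", "gamd_produce",
               "stats_interval", "record_stride", "n_replicas"),
  boost = c("enabled", "dual", "sigma0_total", "sigma0_dihedral",
            "bound_mode"),
  analysis = NULL, # free-form, validated at analysis time
  seeds = NULL,
  output_dir = NULL)

#' Validate a run configuration
#'
#' Checks the block structure of a configuration list (or YAML file):
#' unknown keys are rejected with the offending name, the system block is
#' mandatory, and the system kind must be known.
#'
#' @param config a list or path to a YAML file.
#' @return the validated configuration list, invisibly on error-free input.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown)) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$system)) stop("config is missing the 'system' block")
  for (blk in c("system", "protocol", "boost")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), config_schema[[blk]])
      if (length(bad)) {
        stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
      }
    }
  }
  kinds <- c("double_well", "harmonic_well", "bead_chain")
  if (is.null(config$system$kind) || !config$system$kind %in% kinds) {
    stop("system.kind must be one of: ", paste(kinds, collapse = ", "))
  }
  invisible(config)
}

build_system <- function(sys) {
  args <- sys[setdiff(names(sys), "kind")]
  switch(sys$kind,
         double_well = do.call(make_double_well, args),
         harmonic_well = do.call(make_harmonic_well, args),
         bead_chain = do.call(make_bead_chain, args),
         stop("unknown system kind: ", sys$kind))
}

#' Run the simulate stage of the pipeline
#'
#' Builds the system, protocol and boost controller from a configuration,
#' runs one trajectory per seed, and (if an output directory is given)
#' writes one trajectory file per replica together with the resolved
#' configuration and a log sufficient to reproduce the run bit-for-bit.
#'
#' @param config configuration list or YAML path (see
#'   [validate_run_config()]).
#' @param output_dir overrides `config$output_dir`; `NULL` writes nothing.
#' @return named list: `trajectories`, `paths` (or NULL), `config`.
#' @export
gamd_simulate <- function(config, output_dir = NULL) {
  config_path <- if (is.character(config)) config else NULL
  config <- validate_run_config(config)
  if (is.null(output_dir)) output_dir <- config$output_dir
  system <- build_system(config$system)
  prot <- do.call(protocol, config$protocol %||% list())
  controller <- NULL
  if (isTRUE(config$boost$enabled)) {
    b <- config$boost
    controller <- gamd_controller(
      sigma0_total = b$sigma0_total %||% 6,
      sigma0_dihedral = b$sigma0_dihedral %||% 6,
      bound_mode = b$bound_mode %||% "lower",
      dual = isTRUE(b$dual))
  }
  seeds <- as.integer(config$seeds %||% seq_len(prot$n_replicas))
  trajs <- run_replicas(system, prot, controller, seeds = seeds)
  paths <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(seq_along(trajs), function(i) {
      p <- file.path(output_dir, sprintf("traj_rep%d.tsv", i))
      write_trajectory(trajs[[i]], p)
      p
    }, character(1))
    yaml::write_yaml(config, file.path(output_dir, "config_resolved.yaml"))
    log_lines <- c(
      sprintf("gamdr %s", as.character(utils::packageVersion("gamdr"))),
      sprintf("seeds: %s", paste(seeds, collapse = ", ")),
      if (!is.null(config_path)) {
        sprintf("config md5: %s", unname(tools::md5sum(config_path)))
      },
      vapply(seq_along(trajs), function(i) {
        md <- trajs[[i]]$metadata
        sprintf("replica %d: sigma_dV = %.4f kcal/mol%s", i,
                md$sigma_dV %||% 0,
                if (!is.null(md$boost_params$total)) {
                  sprintf(" (E = %.4g, k0 = %.4g)",
                          md$boost_params$total$E, md$boost_params$total$k0)
                } else " (unboosted)")
      }, character(1)),
      sprintf("trajectory md5: %s",
              paste(unname(tools::md5sum(paths)), collapse = ", ")))
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }
  list(trajectories = trajs, paths = paths, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate a collective-variable spec on one trajectory
cv_values <- function(traj, cv) {
  if (is.function(cv)) return(cv(traj))
  if (is.character(cv) && length(cv) == 1 && cv == "x") return(traj_x(traj))
  if (is.list(cv) && !is.null(cv$a) && !is.null(cv$b)) {
    return(distance_timecourse(traj, cv$a, cv$b)$distance)
  }
  stop("unsupported cv spec; use \"x\", a function(traj), or list(a=, b=)")
}

#' Reweight one or more trajectories into a free-energy profile
#'
#' Trajectories (objects or file paths) are concatenated frame-wise —
#' replicas are pooled before binning — and passed through [pmf()].
#'
#' @param trajs a `gamd_trajectory`, a list of them, or character paths.
#' @param cv collective variable: `"x"`, a `function(traj)`, a
#'   `list(a =, b =)` particle pair, or a list of two such specs for a 2D
#'   profile.
#' @param bins,temperature,min_samples passed to [pmf()].
#' @param output_dir if non-NULL, writes `pmf.csv` (bin centres, free
#'   energy, counts) and `reweight_report.json` there.
#' @return a [pmf_grid].
#' @export
gamd_reweight <- function(trajs, cv = "x", bins = 50, temperature = 300,
                          min_samples = 10, output_dir = NULL) {
  if (inherits(trajs, "gamd_trajectory")) trajs <- list(trajs)
  if (length(trajs) == 0) stop("need at least one trajectory")
  trajs <- lapply(trajs, function(t) {
    if (is.character(t)) read_trajectory(t) else t
  })
  schemas <- vapply(trajs, n_particles, integer(1))
  if (length(unique(schemas)) != 1) {
    stop("trajectories have mismatched particle counts")
  }
  is_2d <- is.list(cv) && is.null(cv$a) && length(cv) == 2
  vals <- lapply(trajs, function(t) {
    if (is_2d) cbind(cv_values(t, cv[[1]]), cv_values(t, cv[[2]]))
    else cv_values(t, cv)
  })
  cvm <- do.call(rbind, lapply(vals, function(v) {
    if (is.null(dim(v))) matrix(v, ncol = 1) else v
  }))
  if (ncol(cvm) == 1) cvm <- cvm[, 1]
  dV <- unlist(lapply(trajs, function(t) t$boost$dV_sum))
  grid <- pmf(cvm, dV, bins = bins, temperature = temperature,
              min_samples = min_samples)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tibble::as_tibble(grid),
                     file.path(output_dir, "pmf.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(as.list(reweight_report(grid, dV)),
        list(temperature = temperature, n_frames = length(dV))),
      file.path(output_dir, "reweight_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  grid
}

#' Run a batch of trajectory measurements
#'
#' Applies named measurements to (concatenated) trajectories. Available
#' types: `distance` (`a`, `b`), `com_distance` (`group_a`, `group_b`),
#' `rmsd` (`reference` frame index or matrix, `selection`, `superpose`),
#' `rmsf` (`selection`), `cluster` (`selection`, `cutoff`).
#'
#' @param trajs trajectory, list of trajectories, or file paths.
#' @param measurements named list of measurement specs (each a list with a
#'   `type` and its arguments).
#' @param output_dir if non-NULL, one CSV per measurement is written there.
#' @return named list of result tibbles / `cluster_set`s.
#' @export
gamd_analyze <- function(trajs, measurements, output_dir = NULL) {
  if (inherits(trajs, "gamd_trajectory")) trajs <- list(trajs)
  trajs <- lapply(trajs, function(t) {
    if (is.character(t)) read_trajectory(t) else t
  })
  traj <- if (length(trajs) == 1) trajs[[1]] else traj_bind(trajs)
  available <- c("distance", "com_distance", "rmsd", "rmsf", "cluster")
  out <- lapply(measurements, function(m) {
    type <- m$type %||% "?"
    if (!type %in% available) {
      stop("unknown measurement '", type, "'; available: ",
           paste(available, collapse = ", "))
    }
    switch(type,
      distance = distance_timecourse(traj, m$a, m$b),
      com_distance = com_distance_timecourse(traj, m$group_a, m$group_b),
      rmsd = {
        ref <- m$reference %||% 1
        if (length(ref) == 1 && is.numeric(ref)) {
          ref <- frame_coords(traj, ref)
        }
        rmsd_timecourse(traj, ref, m$selection, m$superpose %||% TRUE)
      },
      rmsf = rmsf(traj, selection = m$selection),
      cluster = cluster_frames(traj, m$selection, m$cutoff %||% 2.0))
  })
  names(out) <- names(measurements)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      r <- out[[nm]]
      df <- if (inherits(r, "cluster_set")) {
        tibble::tibble(frame = seq_along(r$labels), cluster = r$labels)
      } else tibble::as_tibble(r)
      utils::write.csv(df, file.path(output_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}
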