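# File formats and reproducibility plumbing. All tables are long (tidy)
# CSV; angle columns are degrees, lengths cm, times seconds, encoded in the
# column-name suffixes (_deg, _cm, _s).

#' Read a trajectory table from CSV
#'
#' Expects columns `time_s`, `animal_id` (or `fish_id` / `agent_id`),
#' `x_cm`, `y_cm`, `heading_deg`. Rows may be in any order; the table is
#' sorted, validated (uniform frame spacing per animal, finite positions)
#' and headings are wrapped to (-180, 180].
#'
#' @param path CSV path.
#' @param arena_diameter_cm if given, positions are checked against the
#'   arena disc.
#' @return a trajectory table (`time_s`, `agent_id`, `x_cm`, `y_cm`,
#'   `heading_deg`, plus any extra columns present).
#' @export
read_trajectories <- function(path, arena_diameter_cm = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  idcol <- intersect(c("animal_id", "fish_id", "agent_id"), names(df))
  if (length(idcol) == 0) {
    stop("missing animal id column (animal_id / fish_id / agent_id)")
  }
  names(df)[names(df) == idcol[1]] <- "agent_id"
  req <- c("time_s", "agent_id", "x_cm", "y_cm", "heading_deg")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$x_cm) | !is.finite(df$y_cm))
  if (length(bad) > 0) {
    stop("non-finite positions at rows: ",
         paste(head(bad, 5), collapse = ", "))
  }
  df <- df[order(df$agent_id, df$time_s), , drop = FALSE]
  for (a in split(df$time_s, df$agent_id)) {
    if (any(diff(a) <= 0)) {
      stop("non-monotone time for an animal (duplicate or reversed frames)")
    }
    check_uniform_spacing(a)
  }
  df$heading_deg <- wrap_angle(df$heading_deg)
  if (!is.null(arena_diameter_cm)) {
    r <- sqrt(df$x_cm^2 + df$y_cm^2)
    out <- which(r > arena_diameter_cm / 2 + 1e-6)
    if (length(out) > 0) {
      stop("positions outside the declared arena at rows: ",
           paste(head(out, 5), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a trajectory table to CSV
#'
#' @param traj trajectory table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  write.csv(format(traj, digits = 12, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A snapshot sufficient to reproduce a run bitwise: the configuration,
#' master seed, derived seeds, package version and timestamps. Written by
#' [write_run()] before any computation output.
#'
#' @param config a [simulation_config()].
#' @param seed master seed (auto-generated and recorded when `NULL`).
#' @param rep_seeds optional derived per-repetition seeds.
#' @param inputs named character vector of input files; their MD5 digests
#'   are recorded.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed = NULL, rep_seeds = NULL,
                         inputs = character()) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  digests <- if (length(inputs) > 0) {
    vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  } else {
    character(0)
  }
  structure(list(
    package = "loomschool",
    version = as.character(utils::packageVersion("loomschool")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, rep_seeds = rep_seeds,
    config = unclass(config), input_digests = as.list(digests)
  ), class = "run_manifest")
}

#' Write a simulation run to a directory
#'
#' Writes `manifest.json` first, then `trajectories.csv`, `states.csv`,
#' `bouts.csv` and `segments.csv`. Re-running [run_session()] with the
#' manifest's config and seed reproduces the tables bitwise.
#'
#' @param run a `sim_run`.
#' @param out_dir output directory (created if needed).
#' @param manifest optional [run_manifest()]; built from the run when
#'   `NULL`.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, manifest = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  if (is.null(manifest)) manifest <- run_manifest(run$config, run$seed)
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_trajectories(run$trajectories, file.path(out_dir, "trajectories.csv"))
  write.csv(format(run$states, digits = 12, scientific = FALSE, trim = TRUE),
            file.path(out_dir, "states.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(run$bouts) && nrow(run$bouts) > 0) {
    write.csv(format(run$bouts, digits = 12, scientific = FALSE,
                     trim = TRUE),
              file.path(out_dir, "bouts.csv"), row.names = FALSE,
              quote = FALSE)
  }
  write.csv(run$segments, file.path(out_dir, "segments.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Read a run manifest
#'
#' @param path path to a `manifest.json`.
#' @return list of class `run_manifest`, with the config restored as a
#'   [simulation_config()].
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$config <- do.call(simulation_config, m$config)
  structure(m, class = "run_manifest")
}
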