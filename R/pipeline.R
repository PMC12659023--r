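#' Default analysis configuration
#'
#' Mirrors the standard nanopore non-equilibrium protocol: current
#' window tau = 20 ps, block size 10 ns, initial 10 ns discarded.
#'
#' @param tau current window, ps.
#' @param block block size for error estimation, ps.
#' @param discard initial time excluded from analysis, ps.
#' @param traj_format trajectory dialect for manifest paths.
#' @param include_other include charged non-ion particles in the total
#'   current?
#' @return a named list.
#' @export
pipeline_config <- function(tau = 20, block = 10000, discard = 10000,
                            traj_format = "table", include_other = FALSE) {
  list(tau = tau, block = block, discard = discard,
       traj_format = traj_format, include_other = include_other)
}

#' Read a run manifest
#'
#' TSV with header columns `traj`, `particles`, `voltage`, `replica`,
#' `group` and optional `concentration`.  Each row is one replica run at
#' one voltage.
#'
#' @param path manifest TSV.
#' @return a `data.frame` of class `RunManifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("traj", "particles", "voltage", "replica", "group")
  if (!all(need %in% names(df)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (!"concentration" %in% names(df)) df$concentration <- NA_real_
  key <- paste(df$voltage, df$replica, df$group)
  if (anyDuplicated(key))
    stop("duplicate (voltage, replica, group) combination in manifest")
  structure(df, class = c("RunManifest", "data.frame"))
}

#' Run the full per-voltage, per-replica analysis of a manifest
#'
#' For every manifest row: read the trajectory and particle table,
#' discard the equilibration stretch, compute windowed total / cation /
#' anion currents and the water flux, and block-average them.  Then
#' aggregate replicas within each (group, voltage) cell.  A failing row
#' aborts only its cell: the report marks the cell missing and the
#' reason is collected in the `failures` attribute.  The `provenance`
#' attribute records, per manifest row, the input paths, their md5
#' digests and the analysis parameters used.
#'
#' @param manifest a `RunManifest` (or path to one).
#' @param config a [pipeline_config()].
#' @return a `ReportTable`: data.frame with one row per (group, voltage),
#'   columns `group`, `voltage`, `n_replicas`, `I_total`, `I_total_err`,
#'   `I_cation`, `I_cation_err`, `I_anion`, `I_anion_err`, `EOF`,
#'   `EOF_err`, `concentration`.
#' @export
run_manifest <- function(manifest, config = pipeline_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0L) {
    warning("empty manifest: empty report")
    return(empty_report())
  }
  per_row <- vector("list", nrow(manifest))
  failures <- character(0)
  digest <- function(p) if (file.exists(p))
    unname(tools::md5sum(p)) else NA_character_
  provenance <- data.frame(
    group = manifest$group, voltage = manifest$voltage,
    replica = manifest$replica, traj = manifest$traj,
    traj_md5 = vapply(manifest$traj, digest, ""),
    particles = manifest$particles,
    particles_md5 = vapply(manifest$particles, digest, ""),
    tau = config$tau, block = config$block, discard = config$discard,
    row.names = NULL)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    per_row[[i]] <- tryCatch({
      traj <- read_trajectory(row$traj, config$traj_format)
      pt <- read_particle_table(row$particles)
      analyze_run(traj, pt, config)
    }, error = function(e) {
      failures <<- c(failures, sprintf("group=%s voltage=%s replica=%s: %s",
                                       row$group, row$voltage, row$replica,
                                       conditionMessage(e)))
      NULL
    })
  }
  cells <- split(seq_len(nrow(manifest)),
                 paste(manifest$group, manifest$voltage, sep = "\r"))
  rows <- lapply(cells, function(ix) {
    ests <- per_row[ix]
    ok <- !vapply(ests, is.null, TRUE)
    g <- manifest$group[ix[1]]; v <- manifest$voltage[ix[1]]
    conc <- manifest$concentration[ix[1]]
    if (!any(ok))
      return(data.frame(group = g, voltage = v, n_replicas = 0L,
                        I_total = NA_real_, I_total_err = NA_real_,
                        I_cation = NA_real_, I_cation_err = NA_real_,
                        I_anion = NA_real_, I_anion_err = NA_real_,
                        EOF = NA_real_, EOF_err = NA_real_,
                        concentration = conc))
    ests <- ests[ok]
    agg <- function(field) {
      es <- lapply(ests, `[[`, field)
      es <- es[!vapply(es, is.null, TRUE)]
      if (!length(es)) return(c(NA_real_, NA_real_))
      a <- suppressWarnings(replica_aggregate(es))
      c(a$mean, a$error)
    }
    it <- agg("all"); ic <- agg("cation"); ia <- agg("anion")
    eo <- agg("water")
    data.frame(group = g, voltage = v, n_replicas = length(ests),
               I_total = it[1], I_total_err = it[2],
               I_cation = ic[1], I_cation_err = ic[2],
               I_anion = ia[1], I_anion_err = ia[2],
               EOF = eo[1], EOF_err = eo[2], concentration = conc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$voltage), ]
  rownames(out) <- NULL
  structure(out, failures = failures, provenance = provenance,
            class = c("ReportTable", "data.frame"))
}

## one replica: block-averaged estimates for all observables
analyze_run <- function(traj, particles, config) {
  sc <- species_currents(traj, particles, config$tau,
                         include_other = config$include_other)
  est <- lapply(sc, block_error, block = config$block,
                discard = config$discard)
  est$water <- if (any(particles$species == "water_oxygen"))
    block_error(water_flux(traj, particles, config$tau),
                block = config$block, discard = config$discard)
  else NULL
  est
}

empty_report <- function() {
  structure(
    data.frame(group = character(0), voltage = numeric(0),
               n_replicas = integer(0), I_total = numeric(0),
               I_total_err = numeric(0), I_cation = numeric(0),
               I_cation_err = numeric(0), I_anion = numeric(0),
               I_anion_err = numeric(0), EOF = numeric(0),
               EOF_err = numeric(0), concentration = numeric(0)),
    failures = character(0), class = c("ReportTable", "data.frame"))
}

#' Serialise / read back a report table
#'
#' TSV with commented header lines documenting the columns, units and
#' sign convention (positive current / flux = motion toward +z, i.e.
#' trans to cis).  Missing cells are written as explicit `NA` tokens.
#'
#' @param table a `ReportTable`.
#' @param path output file.
#' @return `path` invisibly (`emit_report`); a `ReportTable`
#'   (`read_report`).
#' @export
emit_report <- function(table, path) {
  stopifnot(inherits(table, "ReportTable"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# poreflux report",
    "# currents in nA, EOF in molecules/ns, voltage in mV, concentration in mol/L",
    "# sign convention: positive current/EOF = net motion toward +z (trans to cis)",
    "# errors are replica standard errors (sd of replica means / sqrt(n))"),
    con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname emit_report
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  num <- setdiff(names(df), c("group", "n_replicas"))
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  if ("n_replicas" %in% names(df))
    df$n_replicas <- as.integer(df$n_replicas)
  structure(df, failures = character(0),
            class = c("ReportTable", "data.frame"))
}
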