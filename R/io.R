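fmt_num <- function(x) {
  # 12 significant digits: enough for byte-identical reruns, short enough
  # for stable CSVs
  ifelse(is.na(x), "", formatC(x, digits = 12, format = "g"))
}

schema_stop <- function(...) {
  stop(errorCondition(paste0(...), class = c("teleaccess_schema_error",
                                             "error", "condition")))
}

#' Write an instance to disk
#'
#' Writes \code{divisions}, \code{sites} and the long-form cost table
#' (\code{site_id, division_id, cost}) either as CSV or as RFC 7946 GeoJSON
#' Point features (costs always as CSV). Numbers are serialized at 12
#' significant digits so reruns are byte-identical.
#'
#' @param instance A [th_instance()].
#' @param dir Output directory (created if absent).
#' @param format \code{"csv"} (default) or \code{"geojson"}.
#' @return Invisibly, the paths written.
#' @export
write_instance <- function(instance, dir, format = c("csv", "geojson")) {
  format <- match.arg(format)
  stopifnot(inherits(instance, "th_instance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  costs_long <- data.frame(
    site_id = rep(rownames(instance$costs), ncol(instance$costs)),
    division_id = rep(colnames(instance$costs),
                      each = nrow(instance$costs)),
    cost = fmt_num(as.vector(instance$costs)))
  paths <- file.path(dir, "costs.csv")
  utils::write.csv(costs_long, paths, row.names = FALSE, quote = FALSE)
  if (format == "csv") {
    for (nm in c("divisions", "sites")) {
      df <- instance[[nm]]
      for (col in names(df)) if (is.numeric(df[[col]])) {
        df[[col]] <- fmt_num(df[[col]])
      }
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  } else {
    for (nm in c("divisions", "sites")) {
      p <- file.path(dir, paste0(nm, ".geojson"))
      write_geojson(instance[[nm]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

write_geojson <- function(df, path) {
  if (!all(c("lon", "lat") %in% names(df))) {
    schema_stop("geojson export needs lon/lat coordinates")
  }
  props <- df[, setdiff(names(df), c("lon", "lat")), drop = FALSE]
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) {
    schema_stop(path, ": not a GeoJSON FeatureCollection")
  }
  rows <- lapply(g$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      schema_stop(path, ": only Point features are supported")
    }
    c(list(lon = f$geometry$coordinates[[1]],
           lat = f$geometry$coordinates[[2]]),
      f$properties)
  })
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  df[, c(setdiff(names(df), c("lon", "lat"))[1], "lon", "lat",
         setdiff(names(df), c("lon", "lat"))[-1]), drop = FALSE]
}

#' Read an instance from disk
#'
#' Reads \code{divisions} and \code{sites} tables (CSV or GeoJSON, detected
#' by file presence) and the optional long-form cost table; when no cost
#' table exists, travel costs are computed from coordinates. Any schema
#' violation raises an error of class \code{"teleaccess_schema_error"}
#' naming the offending record.
#'
#' @param dir Directory holding \code{divisions.csv}/\code{.geojson},
#'   \code{sites.csv}/\code{.geojson} and optionally \code{costs.csv}.
#' @param cost_unit Unit label when costs are read from file.
#' @return A [th_instance()].
#' @export
read_instance <- function(dir, cost_unit = "km") {
  read_layer <- function(nm) {
    p_csv <- file.path(dir, paste0(nm, ".csv"))
    p_geo <- file.path(dir, paste0(nm, ".geojson"))
    if (file.exists(p_csv)) {
      utils::read.csv(p_csv, stringsAsFactors = FALSE)
    } else if (file.exists(p_geo)) {
      read_geojson(p_geo)
    } else {
      schema_stop("read_instance: no ", nm, " table in ", dir)
    }
  }
  div <- read_layer("divisions")
  sit <- read_layer("sites")
  p_costs <- file.path(dir, "costs.csv")
  costs <- NULL
  if (file.exists(p_costs)) {
    long <- utils::read.csv(p_costs, stringsAsFactors = FALSE)
    need <- c("site_id", "division_id", "cost")
    if (!all(need %in% names(long))) {
      schema_stop("costs.csv: need columns ", paste(need, collapse = ", "))
    }
    costs <- matrix(NA_real_, nrow(sit), nrow(div),
                    dimnames = list(as.character(sit$id),
                                    as.character(div$id)))
    bad_site <- setdiff(unique(long$site_id), rownames(costs))
    if (length(bad_site)) {
      schema_stop("costs.csv: unknown site_id '", bad_site[1], "'")
    }
    bad_div <- setdiff(unique(long$division_id), colnames(costs))
    if (length(bad_div)) {
      schema_stop("costs.csv: unknown division_id '", bad_div[1], "'")
    }
    costs[cbind(as.character(long$site_id),
                as.character(long$division_id))] <- long$cost
    miss <- which(is.na(costs), arr.ind = TRUE)
    if (nrow(miss)) {
      schema_stop("costs.csv: missing cost for pair (",
                  rownames(costs)[miss[1, 1]], ", ",
                  colnames(costs)[miss[1, 2]], ")")
    }
  }
  tryCatch(th_instance(div, sit, costs = costs, cost_unit = cost_unit),
           error = function(e) schema_stop(conditionMessage(e)))
}

config_defaults <- function() {
  list(instance_dir = NULL, generate = NULL,
       beta = 2, d0 = NULL, d_floor = 0.1,
       referral_rate = 0.2, q_poor = 0.35, q_good = 0.1,
       demand_stratum = "chronic", online_mode = "as_printed",
       offline_mode = "resource_shift", unit = "km",
       optimize = TRUE, G = 0.7, rho = NULL,
       bounds_mode = "variable_extremes", fixed_bounds = NULL,
       integrality = "continuous", seed = 1L)
}

#' Read and validate a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension), fills defaults,
#' and rejects unknown keys and out-of-range parameters. Recognized keys:
#' \code{instance_dir} or \code{generate} (a [city_config()] field list),
#' the [decay_spec()] fields \code{beta}, \code{d0}, \code{d_floor}, the
#' [th_params()] fields, \code{unit}, and the allocation fields
#' \code{optimize}, \code{G}, \code{rho}, \code{bounds_mode},
#' \code{fixed_bounds}, \code{integrality}, \code{seed}.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file, or a
#'   named list already in memory.
#' @return A validated configuration list of class \code{"run_config"}.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    schema_stop("read_config: unsupported config format: ", path)
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    schema_stop("read_config: unknown key(s): ",
                paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  if (!is.null(out$instance_dir) && !dir.exists(out$instance_dir)) {
    schema_stop("read_config: instance_dir does not exist: ",
                out$instance_dir)
  }
  tryCatch({
    decay_spec(out$beta, out$d0, out$d_floor)
    th_params(out$referral_rate, out$q_poor, out$q_good, out$online_mode,
              out$offline_mode, out$demand_stratum)
  }, error = function(e) schema_stop(conditionMessage(e)))
  if (out$G <= 0 || out$G > 1) schema_stop("read_config: G must be in (0,1]")
  structure(out, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Chains the package stages: load (or generate) an instance, compute the
#' purely offline baseline profile, assign the two-tier online preference,
#' compute the tele-health profile, optionally optimize the online
#' allocation, and write all artifacts: per-division profile CSVs, equity
#' report JSONs, the allocation result JSON, and a run log with every
#' parameter. Outputs are byte-identical across reruns of the same
#' configuration and seed.
#'
#' @param config A configuration accepted by [read_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the baseline fit, tele-health fit, and (if
#'   requested) the allocation result.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  decay <- decay_spec(cfg$beta, cfg$d0, cfg$d_floor)
  params <- th_params(cfg$referral_rate, cfg$q_poor, cfg$q_good,
                      cfg$online_mode, cfg$offline_mode, cfg$demand_stratum)
  instance <- if (!is.null(cfg$instance_dir)) {
    read_instance(cfg$instance_dir, cost_unit = cfg$unit)
  } else {
    gen <- cfg$generate
    if (is.null(gen)) gen <- list()
    if (is.null(gen$seed)) gen$seed <- cfg$seed
    generate_city(do.call(city_config, gen))
  }

  zeroQ <- stats::setNames(rep(0, nrow(instance$divisions)),
                           instance$divisions$id)
  baseline <- i2sfca(instance, decay, params, Q = zeroQ)
  Q <- assign_online_preference(
    stats::setNames(baseline$profile$a_total, baseline$profile$division),
    cfg$q_poor, cfg$q_good)
  th_fit <- i2sfca(instance, decay, params, Q = Q)

  write_profile <- function(fit, stem) {
    df <- fit$profile
    for (col in names(df)) if (is.numeric(df[[col]])) {
      df[[col]] <- fmt_num(df[[col]])
    }
    utils::write.csv(df, file.path(out_dir, paste0(stem, ".csv")),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(fit$equity),
                         file.path(out_dir, paste0(stem, "_equity.json")),
                         auto_unbox = TRUE, digits = 12)
  }
  write_profile(baseline, "baseline_profile")
  write_profile(th_fit, "telehealth_profile")

  alloc <- NULL
  if (isTRUE(cfg$optimize)) {
    prob <- allocation_problem(instance, decay, params, G = cfg$G,
                               rho = cfg$rho, Q = Q,
                               bounds_mode = cfg$bounds_mode,
                               fixed_bounds = cfg$fixed_bounds,
                               integrality = cfg$integrality)
    alloc <- solve_allocation(prob)
    if (alloc$status != "optimal") {
      stop(errorCondition(
        paste0("optimize stage: solver status ", alloc$status,
               if (!is.null(alloc$diagnostic)) paste0(
                 "; minimal achievable equilibrium index ",
                 fmt_num(alloc$diagnostic$min_achievable_equilibrium_index))),
        class = c("teleaccess_infeasible", "error", "condition")))
    }
    write_profile(alloc$profile, "optimized_profile")
    jsonlite::write_json(
      list(status = alloc$status, objective = alloc$objective,
           achieved_equilibrium_index = alloc$achieved_equilibrium_index,
           G = alloc$G, solver_gap = alloc$solver_gap,
           V = as.list(alloc$V)),
      file.path(out_dir, "allocation.json"), auto_unbox = TRUE, digits = 12)
  }

  log_lines <- c(
    "teleaccess run log",
    paste0("package_version: ", as.character(utils::packageVersion("teleaccess"))),
    paste0("seed: ", cfg$seed),
    paste0("beta: ", fmt_num(cfg$beta)),
    paste0("d0: ", if (is.null(cfg$d0)) "none" else fmt_num(cfg$d0)),
    paste0("d_floor: ", fmt_num(cfg$d_floor)),
    paste0("referral_rate: ", fmt_num(cfg$referral_rate)),
    paste0("q_poor: ", fmt_num(cfg$q_poor)),
    paste0("q_good: ", fmt_num(cfg$q_good)),
    paste0("demand_stratum: ", cfg$demand_stratum),
    paste0("online_mode: ", cfg$online_mode),
    paste0("offline_mode: ", cfg$offline_mode),
    paste0("optimize: ", cfg$optimize),
    paste0("G: ", fmt_num(cfg$G)),
    paste0("bounds_mode: ", cfg$bounds_mode),
    paste0("integrality: ", cfg$integrality),
    paste0("solver: boot::simplex (feasibility tolerance 1e-6)"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(baseline = baseline, telehealth = th_fit,
                 allocation = alloc, instance = instance))
}
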