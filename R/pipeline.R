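#' Run the full analysis pipeline
#'
#' Chains the stages simulate (optional) -> acquisition classification
#' -> demand fitting -> strain comparison, writing `sessions.csv` (when
#' simulated), `acquisition.csv`, `parameters.csv`, `comparisons.csv`
#' and a flat key-value `manifest.txt` to `out_dir`.  Identical
#' configuration and seed give identical outputs.  Only subjects
#' classified as acquired (by the two-part criterion or the demand-phase
#' re-check) enter demand fitting; subjects with demand sessions but no
#' acquired status, and acquired subjects without demand sessions, are
#' reported in the manifest rather than silently dropped.
#'
#' @param input Path to a sessions CSV (mutually exclusive with
#'   `config`).
#' @param config A [simulation_config()] to generate the cohort
#'   (mutually exclusive with `input`).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding `config$seed`.
#' @param k Fixed range constant (default 2.218, the published global
#'   fit); ignored when `estimate_k = TRUE`.
#' @param estimate_k Estimate a shared `k` across subjects with
#'   [fit_shared_k()] instead of fixing it.
#' @param saline_scope `"strain"` or `"pooled"` saline reference.
#' @param verbose Print stage-scoped progress lines.
#' @return The manifest as a named list, invisibly.
#' @export
run_pipeline <- function(input = NULL, config = NULL, out_dir,
                         seed = NULL, k = 2.218, estimate_k = FALSE,
                         saline_scope = c("strain", "pooled"),
                         verbose = TRUE) {
  saline_scope <- match.arg(saline_scope)
  if (is.null(input) == is.null(config))
    stop("supply exactly one of 'input' or 'config'")
  if (!estimate_k && (!is.numeric(k) || k <= 0))
    stop("fixed 'k' must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (verbose) message("[", stage, "] ", ...)

  manifest <- list(package = "opdemand",
                   version = as.character(utils::packageVersion("opdemand")),
                   saline_scope = saline_scope)

  if (!is.null(config)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    manifest$seed <- config$seed
    manifest$config_hash <- .config_hash(config)
    say("simulate", "generating cohort (seed ", config$seed, ")")
    sessions <- tryCatch(simulate_cohort(config),
                         error = function(e) stop("stage simulate: ",
                                                  conditionMessage(e)))
    write_sessions(sessions, file.path(out_dir, "sessions.csv"))
  } else {
    say("load", "reading ", input)
    sessions <- tryCatch(load_sessions(input),
                         error = function(e) stop("stage load: ",
                                                  conditionMessage(e)))
    manifest$input <- input
    manifest$config_hash <- unname(tools::md5sum(input))
  }
  manifest$n_sessions <- nrow(sessions)
  manifest$n_subjects <- length(unique(sessions$subject_id))

  say("acquire", "classifying acquisition (", saline_scope,
      " saline reference)")
  acq <- tryCatch(classify_cohort(sessions, saline_scope = saline_scope),
                  error = function(e) stop("stage acquire: ",
                                           conditionMessage(e)))
  utils::write.csv(acq, file.path(out_dir, "acquisition.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$n_classified <- nrow(acq)
  manifest$n_acquired <- sum(acq$acquired)

  dem <- sessions[sessions$phase == "demand", , drop = FALSE]
  has_demand <- unique(dem$subject_id)
  acquired_ids <- acq$subject_id[acq$acquired]
  skipped <- setdiff(has_demand, acquired_ids)
  missing_demand <- setdiff(acquired_ids, has_demand)
  if (length(skipped) > 0)
    say("demand", "excluding non-acquired subjects with demand data: ",
        paste(skipped, collapse = ", "))
  manifest$n_demand_excluded_not_acquired <- length(skipped)
  manifest$n_acquired_missing_demand <- length(missing_demand)
  if (length(missing_demand) > 0)
    manifest$acquired_missing_demand <- paste(missing_demand,
                                              collapse = ";")

  fit_ids <- intersect(acquired_ids, has_demand)
  if (length(fit_ids) == 0) stop("stage demand: no acquired subjects ",
                                 "with demand-phase sessions")
  say("demand", "fitting ", length(fit_ids), " demand curves")
  series <- lapply(fit_ids, function(id) {
    rows <- dem[dem$subject_id == id, , drop = FALSE]
    tryCatch(prepare_demand_series(rows, rows$unit_dose_ug_kg[1] / 1000),
             error = function(e) stop("stage demand (subject ", id, "): ",
                                      conditionMessage(e)))
  })
  if (estimate_k) {
    shared <- fit_shared_k(series)
    k_used <- shared$k
    fits <- shared$fits
    manifest$k_mode <- "estimated"
  } else {
    k_used <- k
    fits <- lapply(series, fit_demand, k = k)
    manifest$k_mode <- "fixed"
  }
  manifest$k <- k_used

  meta <- unique(sessions[, c("subject_id", "strain", "sex",
                              "unit_dose_ug_kg")])
  params <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    id <- fit_ids[i]
    m <- meta[meta$subject_id == id, , drop = FALSE][1, ]
    data.frame(subject_id = id, strain = m$strain, sex = m$sex,
               alpha = f$coefficients[["alpha"]],
               q0 = f$coefficients[["q0"]], k = k_used,
               pmax_exact = f$derived[["pmax_exact"]],
               pmax_approx = f$derived[["pmax_approx"]],
               omax = f$derived[["omax"]], r2 = f$r2, n_points = f$n,
               stringsAsFactors = FALSE)
  }))
  write_parameter_table(params, file.path(out_dir, "parameters.csv"))
  manifest$n_parameters <- nrow(params)

  say("compare", "strain comparisons of demand indices")
  comparisons <- tryCatch({
    if (length(unique(params$strain)) == 2 &&
        all(table(params$strain) >= 2))
      compare_all_parameters(params, k = k_used)
    else {
      say("compare", "skipped: need 2 strains with >= 2 subjects each")
      NULL
    }
  }, error = function(e) stop("stage compare: ", conditionMessage(e)))
  if (!is.null(comparisons)) {
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest$n_comparisons <- nrow(comparisons)
  } else manifest$n_comparisons <- 0

  mf <- file.path(out_dir, "manifest.txt")
  writeLines(paste0(names(manifest), " = ",
                    vapply(manifest, function(v) paste(format(v),
                                                       collapse = ","),
                           character(1))), mf)
  say("done", "outputs in ", out_dir)
  invisible(manifest)
}

# stable hash of a configuration: md5 of its deparsed text
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a flat key-value pipeline configuration file
#'
#' Plain-text `key = value` lines ('#' comments allowed).  Scalar keys
#' mirror [simulation_config()] arguments; cohort groups are given as
#' repeated `group = strain,dose_ug_kg,n_male,n_female,acquisition_prob`
#' lines and demand groups as `demand_group = strain,q0,alpha` lines.
#'
#' @param path Config file path.
#' @return A [simulation_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)

  args <- list()
  if (any(keys == "group")) {
    g <- do.call(rbind, lapply(strsplit(vals[keys == "group"], ","), trimws))
    args$groups <- data.frame(strain = g[, 1],
                              unit_dose_ug_kg = as.numeric(g[, 2]),
                              n_male = as.integer(g[, 3]),
                              n_female = as.integer(g[, 4]),
                              acquisition_prob = as.numeric(g[, 5]),
                              stringsAsFactors = FALSE)
  }
  if (any(keys == "demand_group")) {
    g <- do.call(rbind,
                 lapply(strsplit(vals[keys == "demand_group"], ","), trimws))
    args$demand_groups <- data.frame(strain = g[, 1],
                                     q0 = as.numeric(g[, 2]),
                                     alpha = as.numeric(g[, 3]),
                                     stringsAsFactors = FALSE)
  }
  scalar <- setdiff(unique(keys), c("group", "demand_group"))
  for (key in scalar) {
    v <- vals[keys == key][1]
    num <- suppressWarnings(as.numeric(v))
    args[[key]] <- if (is.na(num)) v else num
  }
  if (!is.null(args$fr_ladder))
    args$fr_ladder <- as.numeric(strsplit(as.character(args$fr_ladder),
                                          ",")[[1]])
  do.call(simulation_config, args)
}
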