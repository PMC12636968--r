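#' Read an analysis configuration
#'
#' Configurations are YAML or JSON.  A configuration describes one or more
#' populations, each given either as a scenario preset (synthetic data) or as
#' file inputs (a survey CSV plus one life-table CSV per sex):
#'
#' ```yaml
#' definitions: [disability, chronic]
#' start_age: 60
#' n_steps: 20
#' populations:
#'   - name: nullland
#'     preset: "null"
#'     seed: 7
#'   - name: fileland
#'     survey: surv.csv
#'     lifetable_women: lt_w.csv
#'     lifetable_men: lt_m.csv
#' ```
#'
#' A single population may also be given at the top level (`preset:` or
#' `survey:`/`lifetable_women:`/`lifetable_men:` without a `populations`
#' list).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return The configuration as a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml, .yml or .json, got: ", ext))
  if (!is.list(cfg)) stop("malformed config: expected a mapping at top level")
  cfg
}

normalise_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$populations)) {
    pop <- config[intersect(names(config),
                            c("name", "preset", "survey", "lifetable_women",
                              "lifetable_men", "seed", "n_per_sex"))]
    if (is.null(pop$preset) && is.null(pop$survey))
      stop("config must name either a scenario 'preset' or a 'survey' CSV ",
           "(missing key: preset or survey)")
    config$populations <- list(pop)
  }
  config$definitions <- config$definitions %||% c("disability", "chronic")
  bad <- setdiff(config$definitions, c("disability", "chronic"))
  if (length(bad)) stop("unknown definitions in config: ", paste(bad, collapse = ", "))
  config$start_age <- config$start_age %||% 60
  config$n_steps <- config$n_steps %||% 20
  config
}

load_population <- function(pop, start_age) {
  if (!is.null(pop$preset)) {
    args <- list(pop$preset)
    if (!is.null(pop$seed)) args$seed <- pop$seed
    if (!is.null(pop$n_per_sex)) args$n_per_sex <- pop$n_per_sex
    scn <- do.call(scenario_preset, args)
    gen <- generate_survey(scn)
    list(name = pop$name %||% pop$preset, survey = gen$survey,
         lifetables = list(woman = gen$truth$woman$lifetable,
                           man = gen$truth$man$lifetable),
         groups = scn$groups,
         provenance = list(scenario = pop$preset, seed = scn$seed,
                           n_per_sex = scn$n_per_sex))
  } else {
    for (key in c("survey", "lifetable_women", "lifetable_men"))
      if (is.null(pop[[key]]))
        stop("population config is missing required key: ", key)
    lts <- list(woman = read_lifetable(pop$lifetable_women),
                man = read_lifetable(pop$lifetable_men))
    lt60 <- truncate_lifetable(lts$woman, start_age)
    list(name = pop$name %||% basename(pop$survey),
         survey = read_survey(pop$survey), lifetables = lts,
         groups = data.frame(x = lt60$x, n = lt60$n),
         provenance = list(survey = pop$survey,
                           lifetable_women = pop$lifetable_women,
                           lifetable_men = pop$lifetable_men))
  }
}

#' Run the full gap analysis
#'
#' For every configured population and health definition, estimates
#' sex-specific prevalence schedules from the survey, computes Sullivan
#' health expectancies and the women-minus-men gap, and decomposes the gap
#' into mortality and health components.  Deterministic given the
#' configuration (synthetic populations carry their own seeds).
#'
#' @param config a configuration list, or a path passed to [read_config()].
#' @param verbose emit progress lines on standard error.
#' @return An object of class `analysis_report`: per population x definition,
#'   the two `health_expectancy` fits, the `hle_gap` and the
#'   `hle_decomposition`, plus provenance (inputs or scenario, seed,
#'   `n_steps`, package version).
#' @examples
#' rep <- run_analysis(list(preset = "null", definitions = "disability"))
#' rep
#' @export
run_analysis <- function(config, verbose = FALSE) {
  config <- normalise_config(config)
  say <- function(...) if (verbose) message(...)
  results <- list()
  for (pop in config$populations) {
    loaded <- load_population(pop, config$start_age)
    say("population ", loaded$name)
    for (def in config$definitions) {
      say("  definition ", def)
      hx <- list()
      sched <- list()
      for (sx in c("woman", "man")) {
        sched[[sx]] <- prevalence_schedule(loaded$survey, def, sx,
                                           groups = loaded$groups)
        lt <- truncate_lifetable(loaded$lifetables[[sx]], config$start_age)
        hx[[sx]] <- sullivan(lt, sched[[sx]], start_age = config$start_age)
      }
      gap <- gender_gap(hx$woman, hx$man)
      dec <- decompose_gap(loaded$lifetables$woman, loaded$lifetables$man,
                           sched$woman, sched$man,
                           start_age = config$start_age,
                           n_steps = config$n_steps)
      results[[length(results) + 1L]] <-
        list(population = loaded$name, definition = def,
             women = hx$woman, men = hx$man, gap = gap, decomposition = dec)
    }
  }
  structure(list(results = results,
                 provenance = list(
                   populations = lapply(config$populations, function(pop)
                     load_provenance(pop)),
                   definitions = config$definitions,
                   start_age = config$start_age, n_steps = config$n_steps,
                   version = as.character(utils::packageVersion("hegap")))),
            class = "analysis_report")
}

load_provenance <- function(pop) {
  if (!is.null(pop$preset))
    list(scenario = pop$preset, seed = pop$seed %||% 4242)
  else
    list(survey = pop$survey, lifetable_women = pop$lifetable_women,
         lifetable_men = pop$lifetable_men)
}

#' @export
print.analysis_report <- function(x, digits = 3, ...) {
  cat("Health-expectancy gap analysis (start age ",
      x$provenance$start_age, ")\n", sep = "")
  for (r in x$results) {
    cat("\n== ", r$population, " / ", r$definition, " ==\n", sep = "")
    print(r$women, digits = digits)
    print(r$men, digits = digits)
    print(r$gap, digits = digits)
    print(r$decomposition, digits = digits)
  }
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Writes, per population: `<name>_hle.csv` (both sexes, both definitions),
#' `<name>_gaps.csv`, and `<name>_decomposition_<definition>.csv`, plus a
#' `report.json` with provenance.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  pops <- unique(vapply(report$results, `[[`, "", "population"))
  for (p in pops) {
    rs <- Filter(function(r) r$population == p, report$results)
    hx <- unlist(lapply(rs, function(r) list(r$women, r$men)), recursive = FALSE)
    write_hle_results(hx, file.path(dir, paste0(p, "_hle.csv")))
    write_gaps(lapply(rs, `[[`, "gap"), file.path(dir, paste0(p, "_gaps.csv")))
    for (r in rs)
      write_decomposition(r$decomposition,
                          file.path(dir, paste0(p, "_decomposition_",
                                                r$definition, ".csv")))
  }
  jsonlite::write_json(report$provenance, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
summary.analysis_report <- function(object, ...) {
  do.call(rbind, lapply(object$results, function(r)
    data.frame(population = r$population, definition = r$definition,
               hle_women = r$women$hle, hle_men = r$men$hle,
               gap = r$gap$delta, gap_se = r$gap$se,
               mortality_component = r$decomposition$mortality_component,
               health_component = r$decomposition$health_component,
               residual = r$decomposition$residual)))
}
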