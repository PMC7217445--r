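#' Run the full design-simulate-estimate-report pipeline
#'
#' Executes the complete workflow behind a trait-preference choice
#' experiment as a pure function of a declarative config: build the
#' blocked fractional-factorial design with opt-outs, simulate
#' respondents from a truth preset, validate and opt-out-filter the
#' data, fit the baseline conditional logit, run the Hausman-McFadden
#' IIA test, fit the G-MNL by maximum simulated likelihood, and write
#' the odds-ratio and rank-index reports. Every artifact is written
#' under `out_dir` and is byte-reproducible from the config and its
#' seeds; the returned manifest records the package version, a hash of
#' the config and the MD5 checksum of every file.
#'
#' @param config path to a YAML/JSON config file, or an equivalent
#'   named list. Required fields: `scenario` (a [preset_truth()]
#'   label), `design` (`runs`, `blocks`, `resolution`, `seed`),
#'   `simulate` (`n_respondents`, `seed`, optional `opt_out_rate`),
#'   `estimate` (`random`, `draws`, `scheme`, `gamma`, `seed`,
#'   optional `iia_drop`).
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @examples
#' \donttest{
#' cfg_file <- system.file("extdata", "ram_table6.yaml",
#'                         package = "flockchoice")
#' cfg <- yaml::read_yaml(cfg_file)
#' cfg$simulate$n_respondents <- 60
#' cfg$estimate$draws <- 50
#' run_pipeline(cfg, out_dir = tempfile("run"))
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    design = list(runs = 16L, blocks = 4L, resolution = 4L),
    estimate = list(draws = 500L, scheme = "halton", gamma = 0,
                    iia_drop = 2L)
  )
  config <- modifyList(defaults, config)
  validate_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "flockchoice",
    version = as.character(utils::packageVersion("flockchoice")),
    config_hash = config_hash(config),
    scenario = config$scenario,
    stages = list(),
    files = list()
  )
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- res$log
    for (f in res$files) {
      manifest$files[[basename(f)]] <<- unname(tools::md5sum(f))
    }
    res$value
  }

  truth <- preset_truth(config$scenario)
  sex <- if (grepl("^ram", config$scenario)) "ram" else "ewe"
  if (!is.null(config$simulate$opt_out_rate)) {
    truth$opt_out_rate <- config$simulate$opt_out_rate
  }

  plan <- stage("design", {
    p <- add_opt_out(assign_blocks(
      fractional_factorial(truth$attributes, config$design$runs,
                           config$design$resolution),
      config$design$blocks, seed = config$design$seed))
    write_design_csv(p, path("design.csv"))
    write_design_json(p, path("design.json"))
    list(value = p,
         log = list(profiles = nrow(p$profiles), blocks = p$n_blocks,
                    resolution = p$resolution),
         files = c(path("design.csv"), path("design.json")))
  })

  dat <- stage("simulate", {
    d <- simulate_choices(plan, truth, config$simulate$n_respondents,
                          seed = config$simulate$seed)
    write_choice_csv(d, path("choices.csv"))
    # echo the generating parameters so recovery can be checked later
    jsonlite::write_json(list(
      beta = as.list(truth$beta), eta_sd = as.list(truth$eta_sd),
      tau = truth$tau, asc = truth$asc, gamma = truth$gamma,
      opt_out_rate = truth$opt_out_rate
    ), path("truth.json"), auto_unbox = TRUE, digits = 10)
    list(value = d,
         log = list(respondents = config$simulate$n_respondents,
                    rows = nrow(d)),
         files = c(path("choices.csv"), path("truth.json")))
  })

  filtered <- stage("validate", {
    issues <- validate_choices(dat)
    if (nrow(issues)) {
      stop(nrow(issues), " validation issue(s), first: ",
           issues$issue[1])
    }
    f <- drop_opt_outs(dat)
    list(value = f,
         log = list(situations = n_situations(f),
                    optout_situations_removed =
                      attr(f, "removed_situations")),
         files = character(0))
  })

  mnl <- stage("fit_mnl", {
    fit <- fit_mnl(filtered)
    write_fit_json(fit, path("mnl_fit.json"))
    list(value = fit,
         log = list(loglik = fit$loglik, rho2 = fit$rho2),
         files = path("mnl_fit.json"))
  })

  stage("iia_test", {
    test <- hausman_mcfadden(filtered, config$estimate$iia_drop)
    jsonlite::write_json(list(
      statistic = unname(test$statistic), df = unname(test$parameter),
      p_value = test$p.value,
      dropped_alternative = test$dropped_alternative,
      non_psd = test$non_psd
    ), path("iia_test.json"), auto_unbox = TRUE, digits = 10)
    list(value = test,
         log = list(statistic = unname(test$statistic),
                    p_value = test$p.value),
         files = path("iia_test.json"))
  })

  gfit <- stage("fit_gmnl", {
    fit <- fit_gmnl(filtered, random = unlist(config$estimate$random),
                    D = config$estimate$draws,
                    scheme = config$estimate$scheme,
                    gamma = config$estimate$gamma,
                    seed = config$estimate$seed,
                    start = c(mnl$beta,
                              mnl$coefficients[-seq_along(mnl$beta)],
                              rep(0.1, length(config$estimate$random)),
                              0.1))
    write_fit_json(fit, path("gmnl_fit.json"))
    list(value = fit,
         log = list(loglik = fit$loglik, rho2 = fit$rho2, tau = fit$tau),
         files = path("gmnl_fit.json"))
  })

  stage("report", {
    ors <- odds_ratios(gfit)
    write.csv(ors, path("odds_ratios.csv"), row.names = FALSE)
    idx <- rbind(
      cbind(table = "production_objectives",
            rank_index(production_objective_ranks())),
      cbind(table = paste0("selection_criteria_", sex),
            rank_index(selection_criteria_ranks(sex)))
    )
    write.csv(idx, path("rank_index.csv"), row.names = FALSE)
    list(value = NULL,
         log = list(odds_ratios = nrow(ors), indices = nrow(idx)),
         files = c(path("odds_ratios.csv"), path("rank_index.csv")))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

validate_config <- function(config) {
  need <- c("scenario", "design", "simulate", "estimate")
  missing_top <- setdiff(need, names(config))
  if (length(missing_top)) {
    stop("config is missing: ", paste(missing_top, collapse = ", "),
         call. = FALSE)
  }
  for (blk in c("design", "simulate", "estimate")) {
    if (is.null(config[[blk]]$seed)) {
      stop("config is missing an explicit seed in '", blk, "'",
           call. = FALSE)
    }
  }
  if (is.null(config$simulate$n_respondents)) {
    stop("config is missing simulate$n_respondents", call. = FALSE)
  }
  invisible(TRUE)
}

config_hash <- function(config) {
  config$out_dir <- NULL  # the output location is not part of the run
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = 10)
  unname(tools::md5sum(tmp))
}

write_fit_json <- function(fit, path) {
  obj <- list(
    model = class(fit)[1],
    coefficients = as.list(fit$coefficients),
    se = as.list(fit$se),
    loglik = fit$loglik,
    loglik_null = fit$loglik_null,
    rho2 = fit$rho2,
    n_obs = fit$n_obs,
    n_respondents = fit$n_respondents
  )
  if (inherits(fit, "gmnl_fit")) {
    obj$tau <- fit$tau
    obj$eta_sd <- as.list(fit$eta_sd)
    obj$gamma <- fit$gamma
    obj$draws <- list(D = fit$D, scheme = fit$scheme, seed = fit$seed)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
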