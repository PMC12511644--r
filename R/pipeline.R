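# Workflow orchestration: simulate -> fit all specifications -> average ->
# report. Configs are plain lists (or YAML/JSON files); outputs are CSV and
# JSON files in the configured output directory, so every stage can be
# rerun or audited independently.

.DIST_TAGS <- c(S = "normal", U = "uniform", T = "triangular",
                LN = "lognormal", LU = "loguniform",
                AT = "asym_triangular", FM2 = "fm2", FM3 = "fm3",
                MNL = "fixed")

#' Apply one mixing-distribution tag to every coefficient
#'
#' Builds the specification variant in which all coefficients share the
#' same mixing family — the conventional way these model ladders are
#' compared. Per-coefficient overrides replace the family of selected
#' coefficients.
#'
#' @param spec a [model_spec()].
#' @param tag one of \code{S, U, T, LN, LU, AT, FM2, FM3, MNL}.
#' @param overrides optional named list coefficient -> family tag.
#' @return A \code{model_spec}.
#' @export
apply_distribution <- function(spec, tag, overrides = NULL) {
  if (!tag %in% names(.DIST_TAGS)) {
    stop("unknown distribution tag: ", tag, call. = FALSE)
  }
  coefs <- lapply(unname(spec$coefficients), function(cf) {
    fam <- .DIST_TAGS[[tag]]
    if (!is.null(overrides) && cf$name %in% names(overrides)) {
      ov <- overrides[[cf$name]]
      fam <- if (ov %in% names(.DIST_TAGS)) .DIST_TAGS[[ov]] else ov
    }
    coef_spec(cf$name, fam, attributes = cf$attributes, sign = cf$sign,
              fix_c = cf$fix_c)
  })
  model_spec(coefs, space = spec$space,
             price_coefficient = spec$price_coefficient)
}

#' Base specification for the simulated drug-choice data
#'
#' One coefficient per attribute column of [simulate_drug_dce()] output
#' (branded, the country and characteristic dummies, risk, price), all of
#' the family given by \code{tag}.
#'
#' @param tag distribution tag, see [apply_distribution()].
#' @return A \code{model_spec}.
#' @export
drug_model_spec <- function(tag = "S") {
  base <- model_spec(lapply(
    c("branded", "country_CH", "country_IND", "char_fast", "char_double",
      "risk", "price"),
    function(nm) coef_spec(nm, "normal", attributes = nm, sign = -1)))
  apply_distribution(base, tag)
}

#' Read a pipeline run configuration
#'
#' @param config a list, or a path to a YAML/JSON file with the fields
#'   \code{output_dir}, \code{simulate} (kind, n_persons, n_tasks, seed),
#'   \code{models} (distribution tags), \code{R}, \code{seed},
#'   \code{ma_groups}.
#' @return The configuration list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  defaults <- list(output_dir = "hetlogit_run", R = 100, seed = 1,
                   models = c("S", "U", "T", "LN", "LU", "AT", "FM2", "FM3"),
                   ma_groups = ma_groups())
  # top-level defaults only; a user-supplied ma_groups list replaces the
  # presets wholesale rather than being merged into them
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (anyDuplicated(config$models)) {
    stop("model tags must be unique", call. = FALSE)
  }
  config
}

#' Serialize / deserialize a fitted model
#'
#' The JSON record keeps everything model averaging and reporting need:
#' estimates, standard errors, per-coefficient mixing families and
#' natural parameters, LL/AIC/BIC, settings, enumerated shares and the
#' person likelihoods.
#'
#' @param fit a \code{mixl_fit}.
#' @param path output path.
#' @param shares optional named share vector to embed.
#' @export
write_fit_json <- function(fit, path, shares = NULL) {
  coefs <- lapply(names(fit$spec$coefficients), function(nm) {
    cf <- fit$spec$coefficients[[nm]]
    list(name = nm, dist = cf$dist, sign = cf$sign,
         params = fit$natural[[nm]])
  })
  rec <- list(status = "ok",
              estimates = as.list(fit$estimates),
              se = as.list(fit$se),
              coefficients = coefs,
              space = fit$spec$space,
              price_coefficient = fit$spec$price_coefficient,
              LL = fit$LL, n_params = fit$n_params,
              AIC = fit$AIC, BIC = fit$BIC,
              R = fit$R, seed = fit$seed,
              converged = fit$convergence$converged,
              boundary = fit$convergence$boundary,
              shares = if (!is.null(shares)) as.list(shares),
              Pn = unname(fit$Pn))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Pipeline stage: simulate a dataset
#'
#' Writes \code{dataset.csv} and \code{truth.json} (generating families,
#' parameters and seed) to the output directory. \code{simulate$kind} is
#' \code{"drug"} (default) or \code{"rp"}.
#'
#' @param config see [read_run_config()].
#' @return Paths of the written files, invisibly.
#' @export
cmd_simulate <- function(config) {
  config <- read_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  if (is.null(sim)) sim <- list()
  kind <- if (is.null(sim$kind)) "drug" else sim$kind
  seed <- if (is.null(sim$seed)) config$seed else sim$seed
  data_path <- file.path(config$output_dir, "dataset.csv")
  truth_path <- file.path(config$output_dir, "truth.json")
  if (kind == "drug") {
    n <- if (is.null(sim$n_persons)) 1000 else sim$n_persons
    TT <- if (is.null(sim$n_tasks)) 10 else sim$n_tasks
    out <- simulate_drug_dce(n, TT, seed = seed)
    write_choice_data(out$data, data_path)
    truth <- list(kind = "drug", n_persons = n, n_tasks = TT, seed = seed,
                  config = lapply(out$truth$config, function(e) {
                    list(family = e$family, params = e$params)
                  }))
  } else if (kind == "rp") {
    n <- if (is.null(sim$n_persons)) 2031 else sim$n_persons
    sigma_rho <- if (is.null(sim$sigma_rho)) 0.5 else sim$sigma_rho
    shares <- if (is.null(sim$shares)) c(cig = 0.82, ecig = 0.38) else
      unlist(sim$shares)
    ic <- c(cig = rp_intercept_for_share(shares[["cig"]], sigma_rho),
            ecig = rp_intercept_for_share(shares[["ecig"]], sigma_rho))
    dat <- simulate_rp_binary(n, intercepts = ic, sigma_rho = sigma_rho,
                              seed = seed)
    write_binary_panel(dat, data_path)
    truth <- list(kind = "rp", n_persons = n, sigma_rho = sigma_rho,
                  intercepts = as.list(ic), seed = seed)
  } else {
    stop("unknown simulate kind: ", kind, call. = FALSE)
  }
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, truth_path))
}

#' Pipeline stage: fit the requested specifications
#'
#' Fits one model per distribution tag in \code{config$models} and writes
#' \code{fit_<tag>.json} for each. A specification that fails to estimate
#' (as flexible families sometimes do) is recorded with its error message
#' rather than aborting the run.
#'
#' @param config see [read_run_config()].
#' @return Named list of fit objects (or \code{NULL} for failures),
#'   invisibly.
#' @export
cmd_fit <- function(config) {
  config <- read_run_config(config)
  data_path <- if (is.null(config$dataset)) {
    file.path(config$output_dir, "dataset.csv")
  } else {
    config$dataset
  }
  data <- read_choice_data(data_path)
  groups <- config$alt_groups
  if (is.null(groups) && all(c("B1", "G1") %in% data$alt_id)) {
    groups <- list(branded = c("B1", "B2"), unbranded = c("G1", "G2"))
  }
  attr(data, "alt_groups") <- groups
  base <- if (is.null(config$spec)) drug_model_spec("S") else
    read_model_spec(config$spec)
  fits <- list()
  for (tag in config$models) {
    spec <- apply_distribution(base, tag, overrides = config$overrides)
    path <- file.path(config$output_dir, paste0("fit_", tag, ".json"))
    fit <- tryCatch(
      fit_msl(spec, data, R = config$R, seed = config$seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      jsonlite::write_json(list(status = "error",
                                message = conditionMessage(fit)),
                           path, auto_unbox = TRUE)
      fits[tag] <- list(NULL)
    } else {
      write_fit_json(fit, path, shares = sample_enumeration(fit))
      fits[[tag]] <- fit
    }
  }
  invisible(fits)
}

#' Pipeline stage: model averaging over fitted constituents
#'
#' For each configured group, loads the constituent \code{fit_<tag>.json}
#' files (model averaging needs only their person likelihoods and
#' parameter counts), estimates the weights and writes
#' \code{ma_<group>.json} with theta, pi, LL and the conservative AIC.
#'
#' @param config see [read_run_config()].
#' @return Named list of \code{model_average} objects, invisibly.
#' @export
cmd_average <- function(config) {
  config <- read_run_config(config)
  out <- list()
  for (g in names(config$ma_groups)) {
    tags <- config$ma_groups[[g]]
    recs <- list()
    for (tag in tags) {
      path <- file.path(config$output_dir, paste0("fit_", tag, ".json"))
      if (!file.exists(path)) {
        stop("missing constituent fit for tag '", tag, "': ", path,
             call. = FALSE)
      }
      rec <- read_fit_json(path)
      if (identical(rec$status, "ok")) recs[[tag]] <- rec
    }
    if (length(recs) < 2) next
    P <- do.call(cbind, lapply(recs, function(r) unlist(r$Pn)))
    ma <- fit_model_average(P, n_params_constituents =
                              vapply(recs, function(r) r$n_params,
                                     numeric(1)))
    shares <- Reduce(`+`, Map(function(r, w) unlist(r$shares) * w,
                              recs, as.list(ma$pi)))
    jsonlite::write_json(
      list(status = "ok", group = g, constituents = names(recs),
           theta = as.list(ma$theta), pi = as.list(ma$pi),
           LL = ma$LL, n_params_conservative = ma$n_params_conservative,
           AIC = ma$AIC, shares = as.list(shares)),
      file.path(config$output_dir, paste0("ma_", g, ".json")),
      auto_unbox = TRUE, digits = NA)
    out[[g]] <- ma
  }
  invisible(out)
}

#' Pipeline stage: comparison and density reports
#'
#' Writes \code{comparison.csv} (model, LL, parameter count, AIC, BIC,
#' sorted by AIC; model averages included when present),
#' \code{shares.csv} (enumerated shares per model and group) and, for
#' each coefficient of the first fitted model, a density CSV of its
#' unconditional distribution with the generating density overlaid when a
#' truth file is present.
#'
#' @param config see [read_run_config()].
#' @return The comparison data.frame, invisibly.
#' @export
cmd_report <- function(config) {
  config <- read_run_config(config)
  od <- config$output_dir
  fit_files <- list.files(od, pattern = "^fit_.*\\.json$", full.names = TRUE)
  ma_files <- list.files(od, pattern = "^ma_.*\\.json$", full.names = TRUE)
  rows <- list()
  share_rows <- list()
  recs <- list()
  for (f in fit_files) {
    tag <- sub("^fit_(.*)\\.json$", "\\1", basename(f))
    rec <- read_fit_json(f)
    if (!identical(rec$status, "ok")) next
    recs[[tag]] <- rec
    rows[[tag]] <- data.frame(model = tag, LL = rec$LL, k = rec$n_params,
                              AIC = rec$AIC, BIC = rec$BIC)
    if (!is.null(rec$shares)) {
      share_rows[[tag]] <- data.frame(model = tag,
                                      t(unlist(rec$shares)))
    }
  }
  for (f in ma_files) {
    rec <- read_fit_json(f)
    if (!identical(rec$status, "ok")) next
    tag <- paste0("MA_", rec$group)
    rows[[tag]] <- data.frame(model = tag, LL = rec$LL,
                              k = rec$n_params_conservative,
                              AIC = rec$AIC, BIC = NA_real_)
    if (!is.null(rec$shares)) {
      share_rows[[tag]] <- data.frame(model = tag, t(unlist(rec$shares)))
    }
  }
  comparison <- do.call(rbind, rows)
  comparison <- comparison[order(comparison$AIC), , drop = FALSE]
  utils::write.csv(comparison, file.path(od, "comparison.csv"),
                   row.names = FALSE)
  if (length(share_rows)) {
    utils::write.csv(do.call(rbind, share_rows),
                     file.path(od, "shares.csv"), row.names = FALSE)
  }

  truth_path <- file.path(od, "truth.json")
  truth <- if (file.exists(truth_path)) read_fit_json(truth_path)
  if (length(recs)) {
    rec <- recs[[1]]
    set.seed(config$seed)
    for (i in seq_along(rec$coefficients)) {
      cf <- rec$coefficients[i, ]
      nm <- cf$name
      pars <- as.list(rec$coefficients$params[i, ])
      pars$sign <- cf$sign
      vals <- mixing_sample(cf$dist, pars, 10000)
      ds <- density_summary(vals)
      if (ds$type != "density") next
      out <- data.frame(grid = ds$grid, density = ds$density)
      if (!is.null(truth) && !is.null(truth$config[[nm]])) {
        tr <- truth$config[[nm]]
        td <- tryCatch(mixing_density(tr$family,
                                      lapply(tr$params, unlist), ds$grid),
                       error = function(e) NULL)
        if (!is.null(td)) out$truth <- td
      }
      utils::write.csv(out, file.path(od, paste0("density_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(comparison)
}
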