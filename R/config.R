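#' Read a sources table from CSV
#'
#' The CSV must have a header with columns `mean`, `variance`, `w`
#' (additional columns are rejected to catch schema drift).
#'
#' @param path path to a CSV file.
#' @return A [historical_summary()].
#' @export
read_sources_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  need <- c("mean", "variance", "w")
  if (!identical(sort(names(df)), sort(need)))
    stop("sources CSV must have exactly the columns mean, variance, w; got: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  historical_summary(df$mean, df$variance, df$w)
}

# Allowed keys per config block; anything else is rejected so typos fail
# loudly instead of silently falling back to a default.
.config_keys <- list(
  top = c("name", "sources", "mixture", "s0", "variance", "criterion",
          "strategy", "ratio", "seed"),
  mixture = c("a01", "b01", "a02", "b02"),
  variance = c("kind", "sigma02", "c", "S"),
  criterion = c("kind", "l0", "alpha", "l", "alpha0", "eps0")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

#' Parse and validate a run configuration
#'
#' Reads a YAML or JSON configuration (by extension: `.yaml`/`.yml` or
#' `.json`), validates it, and applies defaults: mixture
#' Gamma(2,2)/Gamma(18,3), `s0 = 0.05`, `ratio = 1`, `strategy = "robust"`.
#' `sources` may be inline (a list of `{mean, variance, w}` records) or a
#' path to a CSV table (resolved relative to the config file). Unknown keys
#' anywhere are rejected with a message naming the offending key.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return An object of class `"run_config"`: list with `name`, `scenario`,
#'   `variance` (spec list or `NULL`), `criterion` (a criterion or `NULL`),
#'   `strategy`, `ratio`, `seed`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys(raw, .config_keys$top, "config")
  if (is.null(raw$sources)) stop("config must provide `sources`", call. = FALSE)

  src <- raw$sources
  if (is.character(src) && length(src) == 1) {
    csv <- if (file.exists(src)) src else file.path(dirname(path), src)
    sources <- read_sources_csv(csv)
  } else {
    for (i in seq_along(src)) {
      check_keys(src[[i]], c("mean", "variance", "w"), sprintf("sources[%d]", i))
      if (is.null(src[[i]]$mean) || is.null(src[[i]]$variance))
        stop(sprintf("sources[%d] needs `mean` and `variance`", i), call. = FALSE)
    }
    get_num <- function(field, default = NA_real_)
      vapply(src, function(s) as.numeric(if (is.null(s[[field]])) default else s[[field]]), 0)
    w <- get_num("w")
    bad <- !is.na(w) & (w < 0 | w > 1)
    if (any(bad))
      stop("sources[", paste(which(bad), collapse = ", "),
           "]: `w` must lie in [0, 1]", call. = FALSE)
    sources <- historical_summary(get_num("mean"), get_num("variance"), w)
  }

  mix_spec <- raw$mixture
  if (!is.null(mix_spec)) check_keys(mix_spec, .config_keys$mixture, "mixture")
  mixture <- do.call(precision_mixture, as.list(mix_spec %||% list()))
  s0 <- raw$s0 %||% 0.05

  variance <- raw$variance
  if (!is.null(variance)) {
    check_keys(variance, .config_keys$variance, "variance")
    if (is.null(variance$kind) || !variance$kind %in% c("known", "invgamma"))
      stop("variance `kind` must be 'known' or 'invgamma'", call. = FALSE)
  }

  criterion <- NULL
  if (!is.null(raw$criterion)) {
    cr <- raw$criterion
    check_keys(cr, .config_keys$criterion, "criterion")
    if (is.null(cr$kind)) stop("criterion needs `kind`", call. = FALSE)
    criterion <- switch(cr$kind,
      acc = acc_criterion(cr$l0, cr$alpha %||% 0.05),
      alc = alc_criterion(cr$l, cr$alpha0 %||% 0.05),
      apvc = apvc_criterion(cr$eps0),
      stop("criterion `kind` must be acc, alc, or apvc", call. = FALSE))
  }

  structure(list(
    name = raw$name %||% "",
    scenario = scenario(sources, mixture = mixture, s0 = s0,
                        name = raw$name %||% ""),
    variance = variance,
    criterion = criterion,
    strategy = raw$strategy %||% "robust",
    ratio = raw$ratio %||% 1,
    seed = raw$seed %||% NULL
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a run configuration back to a list / file
#'
#' Round-trips with [parse_config()]: `parse_config(serialize_config(cfg,
#' path))` is semantically identical to `cfg`.
#'
#' @param config a `"run_config"`.
#' @param path optional output path (`.yaml`/`.yml` or `.json`); when
#'   omitted the plain list is returned invisibly.
#' @return The configuration as a plain list, invisibly.
#' @export
serialize_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  out <- list(
    name = config$name,
    sources = lapply(seq_len(nrow(sc$sources)), function(i)
      list(mean = sc$sources$mean[i], variance = sc$sources$variance[i],
           w = sc$sources$w[i])),
    mixture = sc$mixture[c("a01", "b01", "a02", "b02")],
    s0 = sc$s0,
    strategy = config$strategy,
    ratio = config$ratio
  )
  if (!is.null(config$variance)) out$variance <- config$variance
  if (!is.null(config$criterion)) {
    cr <- unclass(config$criterion)
    out$criterion <- cr
  }
  if (!is.null(config$seed)) out$seed <- config$seed
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    } else {
      yaml::write_yaml(out, path)
    }
  }
  invisible(out)
}

#' Run the design described by a configuration
#'
#' @param config a `"run_config"` from [parse_config()], or a path.
#' @return An [ssd_design()] result.
#' @export
design_from_config <- function(config) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$criterion))
    stop("config has no `criterion` block", call. = FALSE)
  if (is.null(config$variance) && config$strategy != "optimal")
    stop("config has no `variance` block", call. = FALSE)
  ssd_design(config$scenario, config$criterion,
             variance = config$variance %||% list(kind = "known", sigma02 = 1),
             strategy = config$strategy, ratio = config$ratio)
}

#' Serialise a design result to JSON
#'
#' Writes the design plus full provenance (prior components, variance
#' model, criterion, strategy) so any output can be reproduced exactly.
#'
#' @param design an [ssd_design()] result.
#' @param path output path; when `NULL` the JSON string is returned.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "ssd_design"))
  out <- list(
    Q = design$Q, nA = design$nA, nB = design$nB, total = design$total,
    total_display = round(design$total, 1),
    attained = design$attained,
    strategy = design$strategy,
    criterion = unclass(design$criterion),
    prior = list(mean = design$prior$mean, variance = design$prior$variance,
                 components = design$prior$components),
    variance_model = unclass(design$model),
    ratio = design$ratio,
    package_version = as.character(utils::packageVersion("cssd"))
  )
  if (is.null(path))
    return(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, dataframe = "columns"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
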