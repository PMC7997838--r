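#' Read and write observation time series
#'
#' The package-wide observation format is a plain CSV with a `time_h` column
#' (hours) followed by one column per compound (umol/l). Units are fixed
#' package-wide and never inferred. `read_timeseries()` enforces the
#' invariants of the format — strictly increasing times, no negative
#' readings — and names the offending row and column when it refuses a
#' file. Missing cells are allowed (they are excluded from any RSS).
#'
#' @param path file path.
#' @param data data frame with `time_h` first, as returned by
#'   `read_timeseries()` or built in code.
#' @return `read_timeseries()`: a tibble. `write_timeseries()`: `path`,
#'   invisibly.
#' @export
read_timeseries <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (names(data)[1] != "time_h") {
    abort(paste0("malformed header in ", path, ": first column must be `time_h`"))
  }
  for (col in names(data)) {
    if (!is.numeric(data[[col]])) {
      abort(paste0("non-numeric values in column `", col, "` of ", path))
    }
  }
  bad_t <- which(diff(data$time_h) <= 0)
  if (length(bad_t) > 0) {
    abort(sprintf("time not strictly increasing at row %d of %s",
                  bad_t[1] + 1L, path))
  }
  for (col in setdiff(names(data), "time_h")) {
    neg <- which(data[[col]] < 0)
    if (length(neg) > 0) {
      abort(sprintf("negative reading at row %d, column `%s` of %s",
                    neg[1], col, path))
    }
  }
  data
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Read and write network configuration files
#'
#' Networks are stored as YAML so new pathway hypotheses can be defined
#' without code changes: a `compounds` list (`name`, `class`, `measurable`,
#' `initial_umol_per_l`), a `reactions` list (`substrate`, `product` — null
#' for a terminal sink, `law`, `k`, and `inhibitor` / `k_i` for inhibited
#' laws) and an optional `free_parameters` list (`substrate`, `param`).
#' The shipped case configurations are installed under
#' `system.file("extdata", package = "aromkin")`.
#'
#' @param path file path.
#' @param net an [aromatic_network()].
#' @return `read_network()`: an `aromatic_network`. `write_network()`:
#'   `path`, invisibly.
#' @export
read_network <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$compounds) || is.null(cfg$reactions)) {
    abort(paste0(path, " must define `compounds` and `reactions`"))
  }
  cp <- purrr::map_dfr(cfg$compounds, function(x) {
    tibble::tibble(compound = x$name, class = x$class,
                   measurable = isTRUE(x$measurable),
                   initial = as.numeric(x$initial_umol_per_l))
  })
  rx <- purrr::map_dfr(cfg$reactions, function(x) {
    tibble::tibble(
      substrate = x$substrate,
      product = x$product %||% NA_character_,
      law = x$law,
      k = as.numeric(x$k %||% NA),
      inhibitor = x$inhibitor %||% NA_character_,
      k_i = as.numeric(x$k_i %||% NA)
    )
  })
  fp <- if (!is.null(cfg$free_parameters)) {
    purrr::map_dfr(cfg$free_parameters, function(x) {
      tibble::tibble(substrate = x$substrate, param = x$param)
    })
  } else NULL
  aromatic_network(cp, rx, free_parameters = fp)
}

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  drop_na <- function(x) x[!purrr::map_lgl(x, ~ length(.x) == 1 && is.na(.x))]
  cfg <- list(
    compounds = purrr::pmap(net$compounds, function(compound, class, measurable, initial) {
      list(name = compound, class = class, measurable = measurable,
           initial_umol_per_l = initial)
    }),
    reactions = purrr::pmap(net$reactions, function(substrate, product, law, k, inhibitor, k_i) {
      drop_na(list(substrate = substrate, product = product, law = law, k = k,
                   inhibitor = inhibitor, k_i = k_i))
    }),
    free_parameters = purrr::pmap(net$free_parameters, function(substrate, param) {
      list(substrate = substrate, param = param)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' @param fit an `aromkin_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(
    params = as.list(fit$params),
    rss_per_compound = setNames(as.list(fit$rss_per_compound$rss),
                                fit$rss_per_compound$compound),
    rss_total = fit$rss_total,
    n_evals = fit$n_evals,
    converged = fit$converged,
    seed = fit$seed,
    dt = fit$dt
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the case-comparison report
#'
#' Emits the standard report of a case comparison into a directory: the
#' case-by-compound RSS table (one row per case, compounds in the standard
#' H + G order, `total` last), the fitted parameter table with floor-level
#' rates displayed as 0, and one observed-versus-simulated trajectory panel
#' per case (via [autoplot()]).
#'
#' @param cmp a `case_comparison` from [compare_cases()].
#' @param dir output directory, created if needed.
#' @param plots also write per-case trajectory overlay plots (PNG).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(cmp, dir, plots = TRUE) {
  if (!inherits(cmp, "case_comparison")) {
    abort("`cmp` must come from compare_cases()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "rss_by_case.csv")
  readr::write_csv(tibble::as_tibble(cmp), p)
  paths <- c(paths, p)
  p <- file.path(dir, "parameters_by_case.csv")
  readr::write_csv(parameter_table(cmp), p)
  paths <- c(paths, p)
  if (plots) {
    for (nm in names(attr(cmp, "fits"))) {
      p <- file.path(dir, paste0("trajectories_", nm, ".png"))
      ggplot2::ggsave(p, autoplot(attr(cmp, "fits")[[nm]]),
                      width = 10, height = 7, dpi = 150)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
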