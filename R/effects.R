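# Absolute marginal effects and the exposure -> mediator -> outcome path
# decomposition.

#' Absolute marginal effect of a logistic coefficient
#'
#' Converts a log-odds coefficient into an absolute probability change per
#' unit of the predictor by the logistic derivative evaluated at the outcome
#' prevalence: `dP/dX = beta * P * (1 - P)`, where `P` is the
#' dependent-variable mean of the model's estimation sample. The value is
#' bounded by `|beta| / 4` (attained at P = 0.5) and carries the sign of
#' `beta`.
#'
#' @param beta log-odds coefficient (per unit of X).
#' @param p outcome prevalence in (0, 1).
#' @param term optional term name for labelling.
#' @return An object of class `margpath_margeff`: list with `term`, `beta`,
#'   `p`, and `value` (= `beta * p * (1 - p)`).
#' @examples
#' marginal_effect(0.43, 0.046)$value   # 0.0189, i.e. +1.9 percentage points
#' @export
marginal_effect <- function(beta, p, term = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1L,
            is.numeric(p), length(p) == 1L)
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("p must lie strictly inside (0, 1); got ", p)
  }
  structure(list(term = term, beta = beta, p = p, value = beta * p * (1 - p)),
            class = "margpath_margeff")
}

#' @export
print.margpath_margeff <- function(x, ...) {
  cat(sprintf("<margpath_margeff>%s beta = %.4g at P = %.4g -> dP/dX = %.4g\n",
              if (is.null(x$term)) "" else paste0(" ", x$term),
              x$beta, x$p, x$value))
  invisible(x)
}

#' Marginal effects of every term of a logistic fit
#'
#' Evaluates `beta * P * (1 - P)` for each requested coefficient of a
#' [fit_logistic()] object, with `P` the fit's dependent-variable mean.
#'
#' @param fit a `margpath_logit`.
#' @param terms term names (default: all, including the intercept, as
#'   complication tables print).
#' @return `data.frame` with columns `term`, `beta`, `p` (prevalence used),
#'   `dpdx`.
#' @export
marginal_effects <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "margpath_logit"))
  tt <- fit$terms
  if (!is.null(terms)) {
    missing_terms <- setdiff(terms, tt$term)
    if (length(missing_terms)) {
      stop("terms not in fit: ", paste(missing_terms, collapse = ", "))
    }
    tt <- tt[match(terms, tt$term), , drop = FALSE]
  }
  data.frame(term = tt$term, beta = tt$beta, p = fit$dependent_mean,
             dpdx = tt$beta * fit$dependent_mean * (1 - fit$dependent_mean),
             stringsAsFactors = FALSE)
}

# Coerce the accepted edge-effect inputs (named numeric, margpath_margeff
# list, or data.frame with mediator + value columns) to a named vector.
as_effect_vector <- function(x, value_col = "dpdx") {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (inherits(x, "margpath_margeff")) {
    return(stats::setNames(x$value, x$term))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "margpath_margeff"))) {
    return(vapply(x, function(e) e$value, numeric(1)))
  }
  if (is.data.frame(x)) {
    key <- intersect(c("mediator", "term"), names(x))[1]
    val <- intersect(c(value_col, "value", "beta"), names(x))[1]
    if (is.na(key) || is.na(val)) stop("cannot interpret effect table columns")
    return(stats::setNames(x[[val]], x[[key]]))
  }
  stop("cannot interpret effect input of class ", paste(class(x), collapse = "/"))
}

#' Assemble the exposure -> mediator -> outcome path decomposition
#'
#' Combines, for each mediator complication, the exposure-side marginal
#' effect `a` (probability change in the mediator per unit of exposure) with
#' the outcome-side effects `b` — the mediator's marginal effect on
#' in-hospital mortality (probability), and its OLS coefficients on length of
#' stay (days) and total charges (US dollars) — into per-mediator path
#' products `a * b` and per-outcome totals `sum(a_i * b_i)`. Totals cover the
#' mediated paths only; a direct exposure effect, if estimated, is reported
#' separately by the caller.
#'
#' @param a exposure-to-mediator marginal effects: named numeric vector (one
#'   element per mediator), list of [marginal_effect()] objects, or a
#'   `data.frame` with `mediator`/`term` and `dpdx` columns.
#' @param b_mort mediator-to-mortality marginal effects, same forms.
#' @param b_los,b_chg mediator coefficients on LOS and charges: named numeric
#'   vectors, or [fit_ols()] objects (their non-intercept terms are used;
#'   term names of logical complication flags have the `TRUE` suffix
#'   stripped).
#' @return An object of class `margpath_paths`: list with `paths`
#'   (`data.frame`: `mediator`, `a`, `b_mort`, `b_los`, `b_chg`,
#'   `prod_mort`, `prod_los`, `prod_chg`), `totals` (named vector `mortality`
#'   [probability], `los` [days], `charges` [US dollars]), and `dominant`
#'   (mediator with the largest `|a*b|` per outcome).
#' @examples
#' a <- c(infection = 0.0190, shock = 0.0025)
#' build_paths(a, b_mort = c(infection = 0.0176, shock = 0.0521),
#'             b_los = c(infection = 8.42, shock = 8.68),
#'             b_chg = c(infection = 62169, shock = 85247))
#' @export
build_paths <- function(a, b_mort, b_los, b_chg) {
  a <- as_effect_vector(a)
  b_mort <- as_effect_vector(b_mort)
  b_los <- ols_effect_vector(b_los)
  b_chg <- ols_effect_vector(b_chg)

  med <- names(a)
  for (other in list(b_mort, b_los, b_chg)) {
    if (!setequal(med, names(other))) {
      stop("mediator name sets differ across path layers: {",
           paste(med, collapse = ", "), "} vs {",
           paste(names(other), collapse = ", "), "}")
    }
  }
  paths <- data.frame(
    mediator = med,
    a = unname(a[med]),
    b_mort = unname(b_mort[med]),
    b_los = unname(b_los[med]),
    b_chg = unname(b_chg[med]),
    stringsAsFactors = FALSE)
  paths$prod_mort <- paths$a * paths$b_mort
  paths$prod_los <- paths$a * paths$b_los
  paths$prod_chg <- paths$a * paths$b_chg

  totals <- c(mortality = sum(paths$prod_mort),
              los = sum(paths$prod_los),
              charges = sum(paths$prod_chg))
  dominant <- c(
    mortality = paths$mediator[which.max(abs(paths$prod_mort))],
    los = paths$mediator[which.max(abs(paths$prod_los))],
    charges = paths$mediator[which.max(abs(paths$prod_chg))])
  structure(list(paths = paths, totals = totals, dominant = dominant),
            class = "margpath_paths")
}

ols_effect_vector <- function(x) {
  if (inherits(x, "margpath_ols")) {
    tt <- x$terms[x$terms$term != "(Intercept)", , drop = FALSE]
    nm <- sub("^c_", "", sub("TRUE$", "", tt$term))
    return(stats::setNames(tt$beta, nm))
  }
  as_effect_vector(x, value_col = "beta")
}

#' @export
print.margpath_paths <- function(x, ...) {
  cat("<margpath_paths> exposure -> mediator -> outcome decomposition\n\n")
  p <- x$paths
  cat(sprintf("  %-18s %9s %9s %8s %9s | %11s %9s %9s\n",
              "mediator", "a", "b_mort", "b_los", "b_chg",
              "a*b_mort", "a*b_los", "a*b_chg"))
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-18s %9.4f %9.4f %8.2f %9.0f | %8.2fe-05 %9.3f %9.0f\n",
                p$mediator[i], p$a[i], p$b_mort[i], p$b_los[i], p$b_chg[i],
                1e5 * p$prod_mort[i], p$prod_los[i], p$prod_chg[i]))
  }
  cat(sprintf("\n  totals: mortality %+.2f x 10^-5 (probability), LOS %+.3f days, charges %+.0f USD\n",
              1e5 * x$totals["mortality"], x$totals["los"], x$totals["charges"]))
  cat("  dominant mediator:", x$dominant["mortality"], "(mortality),",
      x$dominant["los"], "(LOS),", x$dominant["charges"], "(charges)\n")
  invisible(x)
}

#' Path decomposition from published coefficient tables (replay mode)
#'
#' Rebuilds the path decomposition from externally supplied per-mediator
#' coefficients instead of microdata: the exposure-side complication table
#' (log-odds `beta` with prevalence `p`, or a precomputed `dpdx`), the
#' mortality table (same forms; a single shared `p` is allowed since all
#' mediators sit in one mortality model), and the linear-model table
#' (`beta_los`, `beta_chg`). This is how a published figure's totals are
#' reproduced without the source admissions data.
#'
#' @param table3 `data.frame` with column `mediator` plus either `dpdx` or
#'   both `beta` and `p` — the exposure-to-complication layer.
#' @param table4 same forms — the complication-to-mortality layer; `p` may be
#'   a single value recycled across mediators.
#' @param table5 `data.frame` with columns `mediator`, `beta_los`, `beta_chg`.
#' @return A `margpath_paths` object (see [build_paths()]).
#' @examples
#' replay <- read_replay_coefficients(
#'   system.file("extdata", "published_effects.csv", package = "margpath"))
#' from_printed_tables(replay$table3, replay$table4, replay$table5)
#' @export
from_printed_tables <- function(table3, table4, table5) {
  layer <- function(tab, what) {
    if (!"mediator" %in% names(tab)) stop(what, " needs a 'mediator' column")
    if ("dpdx" %in% names(tab)) {
      stats::setNames(tab$dpdx, tab$mediator)
    } else if (all(c("beta", "p") %in% names(tab))) {
      vapply(seq_len(nrow(tab)), function(i) {
        marginal_effect(tab$beta[i], tab$p[i])$value
      }, numeric(1)) |> stats::setNames(tab$mediator)
    } else {
      stop(what, " needs either a 'dpdx' column or 'beta' + 'p'")
    }
  }
  a <- layer(table3, "table3")
  b_mort <- layer(table4, "table4")
  if (!all(c("beta_los", "beta_chg") %in% names(table5))) {
    stop("table5 needs 'beta_los' and 'beta_chg' columns")
  }
  build_paths(a, b_mort,
              b_los = stats::setNames(table5$beta_los, table5$mediator),
              b_chg = stats::setNames(table5$beta_chg, table5$mediator))
}

#' Read replay coefficients from CSV
#'
#' Reads a small per-mediator coefficient file with columns `mediator`,
#' `dpdx_exposure` (or `beta_exposure` + `p_exposure`), `dpdx_mortality` (or
#' `beta_mortality` + `p_mortality`), `beta_los`, `beta_chg`, and splits it
#' into the three layer tables expected by [from_printed_tables()].
#'
#' @param path CSV path.
#' @return List with elements `table3`, `table4`, `table5`.
#' @export
read_replay_coefficients <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mediator" %in% names(tab)) stop("replay file needs a 'mediator' column")
  pick <- function(dpdx_col, beta_col, p_col) {
    out <- data.frame(mediator = tab$mediator, stringsAsFactors = FALSE)
    if (dpdx_col %in% names(tab)) {
      out$dpdx <- tab[[dpdx_col]]
    } else if (all(c(beta_col, p_col) %in% names(tab))) {
      out$beta <- tab[[beta_col]]
      out$p <- tab[[p_col]]
    } else {
      stop("replay file needs '", dpdx_col, "' or '", beta_col, "' + '",
           p_col, "'")
    }
    out
  }
  list(
    table3 = pick("dpdx_exposure", "beta_exposure", "p_exposure"),
    table4 = pick("dpdx_mortality", "beta_mortality", "p_mortality"),
    table5 = data.frame(mediator = tab$mediator, beta_los = tab$beta_los,
                        beta_chg = tab$beta_chg, stringsAsFactors = FALSE))
}

#' Serialize a path decomposition
#'
#' `path_summary_json()` writes the per-mediator products and totals as JSON;
#' `path_diagram()` returns the node-edge serialization of the path diagram
#' (exposure, mediators, outcomes; edge weights are the marginal effects /
#' coefficients, path weights the products).
#'
#' @param ps a `margpath_paths` object.
#' @param path output path for the JSON form.
#' @param exposure,outcomes node labels for the diagram.
#' @return `path_diagram()` returns a list with `nodes` and `edges`
#'   `data.frame`s.
#' @export
path_summary_json <- function(ps, path) {
  stopifnot(inherits(ps, "margpath_paths"))
  jsonlite::write_json(
    list(paths = ps$paths, totals = as.list(ps$totals),
         dominant = as.list(ps$dominant)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname path_summary_json
#' @export
path_diagram <- function(ps, exposure = "obesity",
                         outcomes = c(mortality = "in-hospital mortality",
                                      los = "length of stay",
                                      charges = "total charges")) {
  stopifnot(inherits(ps, "margpath_paths"))
  p <- ps$paths
  nodes <- data.frame(
    id = c(exposure, p$mediator, unname(outcomes)),
    role = c("exposure", rep("mediator", nrow(p)),
             rep("outcome", length(outcomes))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = exposure, to = p$mediator, weight = p$a,
               kind = "exposure->mediator", stringsAsFactors = FALSE),
    data.frame(from = p$mediator, to = outcomes[["mortality"]],
               weight = p$b_mort, kind = "mediator->outcome",
               stringsAsFactors = FALSE),
    data.frame(from = p$mediator, to = outcomes[["los"]], weight = p$b_los,
               kind = "mediator->outcome", stringsAsFactors = FALSE),
    data.frame(from = p$mediator, to = outcomes[["charges"]], weight = p$b_chg,
               kind = "mediator->outcome", stringsAsFactors = FALSE))
  list(nodes = nodes, edges = edges)
}
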