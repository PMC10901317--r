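## Orchestration: CIAF aggregation -> weights -> Moran/LISA -> the eight
## model fits -> AIC/BIC comparison -> crude vs fitted relative-risk
## surface, with the screening steps (pairwise correlation check, advisory
## Moran gate) applied along the way.

#' Pairwise correlation screen for the covariate matrix
#'
#' Computes all pairwise Pearson correlations and flags pairs whose absolute
#' correlation meets the threshold. Flagged pairs warn but are not dropped:
#' removing a covariate is a user decision.
#'
#' @param X covariate matrix (at least two non-constant columns).
#' @param threshold flag threshold on `|r|` (default 0.8).
#' @return List with `correlations` (the full matrix) and `flagged` (data
#'   frame of offending pairs, possibly empty).
#' @export
correlation_screen <- function(X, threshold = 0.8) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two covariates")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  ut <- which(upper.tri(R) & abs(R) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(
    var1 = colnames(R)[ut[, 1]],
    var2 = colnames(R)[ut[, 2]],
    r = R[ut],
    stringsAsFactors = FALSE
  )
  if (nrow(flagged))
    warning(nrow(flagged), " covariate pair(s) with |r| >= ", threshold,
            ": ", paste(flagged$var1, flagged$var2, sep = "~", collapse = ", "))
  list(correlations = R, flagged = flagged)
}

#' Rank fitted models by information criteria
#'
#' Ascending AIC; ties (difference below 1e-6) broken by BIC, then by fewer
#' parameters. Non-converged fits are listed last and excluded from
#' selection.
#'
#' @param fits list of `model_fit` objects (at least two converged).
#' @return Data frame with one row per fit: family, loglik, k, aic, bic,
#'   rho, lambda, converged, rank; attribute `"selected"` holds the winning
#'   family.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    family = f$family,
    loglik = f$loglik,
    k = f$k,
    aic = f$aic,
    bic = f$bic,
    rho = if (is.null(f$rho)) NA_real_ else f$rho,
    lambda = if (is.null(f$lambda)) NA_real_ else f$lambda,
    converged = isTRUE(f$converged),
    stringsAsFactors = FALSE
  )))
  if (!any(tab$converged)) stop("all model fits failed to converge")
  conv <- tab[tab$converged, , drop = FALSE]
  aic_key <- round(conv$aic / 1e-6) * 1e-6
  ord <- order(aic_key, conv$bic, conv$k)
  conv <- conv[ord, , drop = FALSE]
  out <- rbind(conv, tab[!tab$converged, , drop = FALSE])
  out$rank <- c(seq_len(nrow(conv)),
                rep(NA_integer_, sum(!tab$converged)))
  rownames(out) <- NULL
  attr(out, "selected") <- conv$family[1]
  out
}

#' Crude and model-predicted relative-risk surface
#'
#' Crude values are the zone standardized morbidity ratios `y/E`. Fitted
#' values back-transform the model's systematic prediction: the reduced-form
#' mean `(I - rho W)^-1 X~ gamma` for families with a response lag, `X~
#' gamma` otherwise.
#'
#' @param fit a converged `model_fit` carrying its spec (from
#'   [fit_model()]).
#' @param zt the zone table the fit used (with `rr`).
#' @param w the `spatial_weights` used.
#' @return Data frame with `zone_id`, `crude_rr`, `fitted_response`,
#'   `fitted_rr`.
#' @export
predicted_risk_surface <- function(fit, zt, w) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  spec <- fit$spec
  if (is.null(spec))
    stop("fit carries no model_spec; use fit_model() for risk surfaces")
  if (!"rr" %in% names(zt))
    stop("zone table lacks rr; run crude_relative_risk first")
  if (w$style != "row-standardized") w <- row_standardize(w)
  mu <- as.numeric(fit$design %*% fit$gamma)
  if (fit$info$has_rho && !is.null(fit$rho) && fit$rho != 0)
    mu <- solve(diag(fit$n) - fit$rho * w$w, mu)
  fitted_rr <- switch(spec$response_transform,
    "log-rr" = exp(mu),
    "prevalence" = {
      rate <- sum(zt$y) / sum(zt$n)
      mu / rate
    },
    "logit-prevalence" = {
      rate <- sum(zt$y) / sum(zt$n)
      stats::plogis(mu) / rate
    }
  )
  data.frame(zone_id = zt$zone_id, crude_rr = zt$rr,
             fitted_response = mu, fitted_rr = fitted_rr,
             stringsAsFactors = FALSE)
}

#' Analysis configuration for the full pipeline
#'
#' Exactly one of `children`/`child_file` or `zone_table`/`zone_file`, and
#' exactly one of `weights`, `gal_file` or `geojson_file`, must be supplied.
#'
#' @param children,child_file child-level records (data frame or path).
#' @param zone_table,zone_file pre-aggregated zone table (data frame or
#'   path) with counts `n`, `y` and covariate columns.
#' @param covariates zone-level covariate table (`zone_id` plus covariate
#'   columns), required with child-level input; ignored when the zone table
#'   already carries covariate columns.
#' @param weights,gal_file,geojson_file the zone adjacency.
#' @param rule contiguity rule for GeoJSON input.
#' @param response_transform response used by the model family.
#' @param families model families to fit (default all eight).
#' @param lag_covariates covariates to lag (default all).
#' @param nperm permutations for Moran/LISA (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed master seed; permutation stages use documented offsets
#'   (global Moran +1, LISA +2).
#' @param moran_gate `"warn"` (default: warn and proceed when global Moran
#'   is not significant) or `"stop"`.
#' @param outdir optional output directory; when set, all tables are written
#'   there as delimited text.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(children = NULL, child_file = NULL,
                            zone_table = NULL, zone_file = NULL,
                            covariates = NULL,
                            weights = NULL, gal_file = NULL,
                            geojson_file = NULL,
                            rule = "queen",
                            response_transform = "log-rr",
                            families = .families,
                            lag_covariates = NULL,
                            nperm = 999, alpha = 0.05, seed = 1,
                            moran_gate = c("warn", "stop"),
                            outdir = NULL) {
  n_child <- sum(!is.null(children), !is.null(child_file))
  n_zone <- sum(!is.null(zone_table), !is.null(zone_file))
  if (n_child + n_zone != 1)
    stop("supply exactly one of child-level or zone-level input")
  n_w <- sum(!is.null(weights), !is.null(gal_file), !is.null(geojson_file))
  if (n_w != 1)
    stop("supply exactly one of weights, gal_file or geojson_file")
  structure(list(children = children, child_file = child_file,
                 zone_table = zone_table, zone_file = zone_file,
                 covariates = covariates,
                 weights = weights, gal_file = gal_file,
                 geojson_file = geojson_file, rule = rule,
                 response_transform = response_transform,
                 families = match.arg(families, .families, several.ok = TRUE),
                 lag_covariates = lag_covariates,
                 nperm = nperm, alpha = alpha, seed = seed,
                 moran_gate = match.arg(moran_gate), outdir = outdir),
            class = "analysis_config")
}

#' Run the full zone-level analysis
#'
#' Classify/aggregate (for child input), expected counts and crude relative
#' risks, weight construction, covariate correlation screen, global Moran
#' (advisory gate at `alpha`), LISA cluster labels, the requested model
#' family fits with standard errors, AIC/BIC comparison, and the crude vs
#' fitted relative-risk surface. Every stage is logged; when `outdir` is
#' set, the tables are written there.
#'
#' @param config an [analysis_config()].
#' @return An `analysis_report` list: `zone_table`, `connectivity`,
#'   `correlation_screen`, `moran`, `lisa`, `fits`, `comparison`,
#'   `selected`, `risk_surface`, `log`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- zone table -----------------------------------------------------
  zt <- stage("input", {
    if (!is.null(config$child_file) || !is.null(config$children)) {
      children <- config$children %||% read_children(config$child_file)
      cls <- classify_children(children)
      excl <- attr(cls, "exclusions")
      say("classified ", nrow(cls), " children (excluded ",
          excl[["missing"]], " missing, ", excl[["implausible"]],
          " implausible)")
      zt <- aggregate_zones(cls)
      if (!is.null(config$covariates)) {
        cv <- config$covariates
        if (!"zone_id" %in% names(cv))
          stop("covariate table must carry a zone_id column")
        i <- match(zt$zone_id, as.character(cv$zone_id))
        if (anyNA(i)) stop("covariate table misses zone(s): ",
                           paste(zt$zone_id[is.na(i)], collapse = ", "))
        zt <- cbind(zt, cv[i, setdiff(names(cv), "zone_id"), drop = FALSE])
        rownames(zt) <- NULL
      }
      zt
    } else {
      zt <- config$zone_table %||% read_zone_table(config$zone_file)
      if (!all(c("n", "y") %in% names(zt)))
        stop("zone input must carry n and y columns")
      zt$prevalence <- zt$y / zt$n
      zt[order(zt$zone_id), , drop = FALSE]
    }
  })
  zt <- stage("expected-counts", crude_relative_risk(expected_counts(zt)))
  say("zone table: ", nrow(zt), " zones, overall CIAF rate ",
      round(100 * sum(zt$y) / sum(zt$n), 2), "%")

  # --- weights --------------------------------------------------------
  w <- stage("weights", {
    w <- if (!is.null(config$weights)) config$weights
    else if (!is.null(config$gal_file)) read_gal(config$gal_file)
    else contiguity_from_polygons(
      read_geojson_zones(config$geojson_file), rule = config$rule)
    if (!identical(sort(w$ids), sort(as.character(zt$zone_id))))
      stop("weights and zone table cover different zones")
    # align the zone table to the weights ordering
    zt <<- zt[match(w$ids, zt$zone_id), , drop = FALSE]
    rownames(zt) <<- NULL
    row_standardize(w)
  })
  conn <- connectivity_report(w)
  say("weights: ", conn$n, " zones, ", conn$edges, " edges, ",
      conn$components, " component(s), mean neighbors ",
      round(conn$mean_neighbors, 2))

  # --- correlation screen --------------------------------------------
  covs <- zone_covariate_columns(zt)
  if (!length(covs)) stop("pipeline stage [screen] failed: no covariates")
  X <- as.matrix(zt[, covs, drop = FALSE])
  screen <- stage("screen", withCallingHandlers(
    correlation_screen(X),
    warning = function(wn) { say("screen: ", conditionMessage(wn))
      invokeRestart("muffleWarning") }))

  # --- autocorrelation ------------------------------------------------
  resp <- stage("response", response_vector(zt, config$response_transform))
  moran <- stage("moran", global_moran(resp, w, inference = "permutation",
                                       nperm = config$nperm,
                                       seed = config$seed + 1L))
  say("global Moran's I = ", round(moran$I, 4), ", pseudo p = ",
      round(moran$p_pseudo, 4), " (", config$nperm, " permutations)")
  if (moran$p_pseudo > config$alpha) {
    if (config$moran_gate == "stop")
      stop("pipeline stage [moran-gate] failed: no significant spatial ",
           "autocorrelation (p = ", round(moran$p_pseudo, 4), ")")
    say("moran-gate: no significant spatial autocorrelation at alpha = ",
        config$alpha, "; proceeding (advisory gate)")
  }
  lisa <- stage("lisa", classify_clusters(
    local_moran(resp, w, nperm = config$nperm, seed = config$seed + 2L),
    alpha = config$alpha))
  say("LISA: ", sum(lisa$cluster == "high-high"), " hot-spot and ",
      sum(lisa$cluster == "low-low"), " cold-spot zone(s) at alpha = ",
      config$alpha)

  # --- model fits -----------------------------------------------------
  fits <- list()
  for (fam in config$families) {
    fits[[fam]] <- stage(paste0("fit-", fam), {
      spec <- model_spec(fam, lag_covariates = config$lag_covariates,
                         response_transform = config$response_transform)
      f <- fit_model(spec, zt, w)
      tryCatch(suppressWarnings(standard_errors(f, w)),
               error = function(e) { say("fit-", fam, ": ",
                                         conditionMessage(e)); f })
    })
  }
  comparison <- stage("compare", compare_models(fits))
  selected <- attr(comparison, "selected")
  say("model comparison: ", selected, " selected by AIC (",
      round(comparison$aic[1], 3), ")")
  risk <- stage("risk-surface",
                predicted_risk_surface(fits[[selected]], zt, w))

  report <- structure(list(
    zone_table = zt, connectivity = conn, correlation_screen = screen,
    moran = moran, lisa = lisa, fits = fits, comparison = comparison,
    selected = selected, risk_surface = risk,
    config = config, log = log_lines
  ), class = "analysis_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$outdir, f)
    write_zone_table(zt, o("zone_table.csv"))
    utils::write.table(lisa, o("lisa.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(comparison, o("model_comparison.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(risk, o("risk_surface.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    writeLines(c(model_table(fits), "", log_lines), o("report.txt"))
    say("outputs written to ", config$outdir)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Zone-level CIAF spatial analysis\n")
  cat("  zones:", nrow(x$zone_table), "  selected model:", x$selected, "\n")
  cat("  Moran's I:", round(x$moran$I, 4),
      " pseudo p:", round(x$moran$p_pseudo, 4), "\n")
  invisible(x)
}

#' Aligned coefficient table across fitted families
#'
#' One row per coefficient, one column per family, `estimate(se)` cells with
#' significance stars, followed by rho, lambda, log-likelihood, AIC and n —
#' the conventional side-by-side layout for the eight-family comparison.
#'
#' @param fits named list of `model_fit` objects.
#' @param digits decimals in the human-readable cells (default 4).
#' @return Character vector of table lines (print with `cat(sep = "\n")`).
#' @export
model_table <- function(fits, digits = 4) {
  fams <- names(fits)
  coef_names <- unique(unlist(lapply(fits, function(f) names(f$gamma))))
  cell <- function(f, nm) {
    if (!nm %in% names(f$gamma)) return("")
    i <- match(nm, param_names(f))
    est <- f$gamma[[nm]]
    if (!is.null(f$se)) {
      sprintf("%.*f(%.*f)%s", digits, est, digits, f$se[[i]],
              significance_stars(f$p_value[[i]]))
    } else sprintf("%.*f", digits, est)
  }
  spatial_cell <- function(f, which) {
    v <- f[[which]]
    if (is.null(v)) return("")
    i <- match(which, param_names(f))
    if (!is.null(f$se))
      sprintf("%.*f(%.*f)%s", digits, v, digits, f$se[[i]],
              significance_stars(f$p_value[[i]]))
    else sprintf("%.*f", digits, v)
  }
  rows <- c(
    lapply(coef_names, function(nm)
      c(nm, vapply(fits, cell, "", nm = nm))),
    list(c("rho", vapply(fits, spatial_cell, "", which = "rho"))),
    list(c("lambda", vapply(fits, spatial_cell, "", which = "lambda"))),
    list(c("logLik", vapply(fits, function(f) sprintf("%.3f", f$loglik), ""))),
    list(c("AIC", vapply(fits, function(f) sprintf("%.3f", f$aic), ""))),
    list(c("BIC", vapply(fits, function(f) sprintf("%.3f", f$bic), ""))),
    list(c("n", vapply(fits, function(f) as.character(f$n), "")))
  )
  m <- do.call(rbind, rows)
  m <- rbind(c("", fams), m)
  widths <- apply(nchar(m), 2, max)
  apply(m, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
}
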