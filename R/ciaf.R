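## CIAF classification and zone aggregation.
##
## The Composite Index of Anthropometric Failure treats a child as
## undernourished if at least one of wasting (WHZ < cutoff), stunting
## (HAZ < cutoff) or underweight (WAZ < cutoff) is present. The eight
## (wasting, stunting, underweight) combinations map to categories:
##   A none; B wasting only; C wasting+underweight; D all three;
##   E stunting+underweight; F stunting only; Y underweight only;
##   X wasting+stunting without underweight.
## X is not part of the classical A-Y roster (it is anthropometrically
## unusual: both wasting and stunting but adequate weight-for-age); it is
## kept as its own labelled category so roster-faithful tallies can be
## recovered, and it counts as failure.

# index = wasting*4 + stunting*2 + underweight (0..7)
.ciaf_codes <- c("A", "Y", "F", "E", "B", "C", "X", "D")

#' Classify one child into a CIAF category
#'
#' Failure on each index uses the strict `z < cutoff` convention (the
#' conventional "< -2 SD" reading): a z-score exactly at the cutoff is not a
#' failure.
#'
#' @param haz,waz,whz height-for-age, weight-for-age and weight-for-height
#'   z-scores (SD units).
#' @param cutoff failure threshold in SD units (default -2; must be negative).
#' @param implausible_warn absolute z beyond which a biological-plausibility
#'   warning is raised (default 6).
#' @return A list with `code` (one of A, B, C, D, E, F, Y, X), `ciaf_flag`
#'   (1 if any failure), and the three indicator booleans.
#' @examples
#' classify_child(haz = -1, waz = -2.5, whz = -2.5)  # wasting + underweight: C
#' @export
classify_child <- function(haz, waz, whz, cutoff = -2, implausible_warn = 6) {
  for (nm in c("haz", "waz", "whz")) {
    v <- get(nm)
    if (length(v) != 1 || !is.numeric(v) || !is.finite(v))
      stop("`", nm, "` must be a finite z-score")
  }
  if (!is.finite(cutoff) || cutoff >= 0) stop("`cutoff` must be negative")
  big <- c(haz = haz, waz = waz, whz = whz)
  big <- big[abs(big) > implausible_warn]
  if (length(big))
    warning("biologically implausible z-score(s): ",
            paste(names(big), round(big, 2), collapse = ", "))
  wasting <- whz < cutoff
  stunting <- haz < cutoff
  underweight <- waz < cutoff
  idx <- wasting * 4L + stunting * 2L + underweight * 1L
  list(code = .ciaf_codes[idx + 1L],
       ciaf_flag = as.integer(idx > 0L),
       wasting = wasting, stunting = stunting, underweight = underweight)
}

#' Classify a table of children, with listwise deletion and plausibility
#' screening
#'
#' Children with any missing or non-finite z-score are dropped (listwise
#' deletion), as are children with any `|z|` beyond `implausible_exclude`;
#' `|z|` beyond `implausible_warn` triggers a warning but keeps the child.
#' Exclusion counts are attached as the `"exclusions"` attribute.
#'
#' @param children data frame with columns `child_id`, `zone_id`, `haz`,
#'   `waz`, `whz` (and optionally `survey_round`).
#' @param cutoff failure threshold (SD units, default -2).
#' @param implausible_warn,implausible_exclude absolute-z screening limits
#'   (defaults 6 and 10).
#' @return The analyzable subset of `children` with added columns `code` and
#'   `ciaf_flag`.
#' @export
classify_children <- function(children, cutoff = -2,
                              implausible_warn = 6, implausible_exclude = 10) {
  req <- c("zone_id", "haz", "waz", "whz")
  miss <- setdiff(req, names(children))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.finite(cutoff) || cutoff >= 0) stop("`cutoff` must be negative")
  z <- as.matrix(children[, c("haz", "waz", "whz")])
  ok_finite <- apply(is.finite(z), 1, all)
  zmax <- suppressWarnings(apply(abs(z), 1, max))
  ok_plaus <- ok_finite & zmax <= implausible_exclude
  n_warn <- sum(ok_plaus & zmax > implausible_warn)
  if (n_warn)
    warning(n_warn, " child(ren) with |z| > ", implausible_warn,
            " retained (hard limit ", implausible_exclude, ")")
  out <- children[ok_plaus, , drop = FALSE]
  z <- z[ok_plaus, , drop = FALSE]
  wasting <- z[, "whz"] < cutoff
  stunting <- z[, "haz"] < cutoff
  underweight <- z[, "waz"] < cutoff
  idx <- wasting * 4L + stunting * 2L + underweight * 1L
  out$code <- .ciaf_codes[idx + 1L]
  out$ciaf_flag <- as.integer(idx > 0L)
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(
    missing = sum(!ok_finite),
    implausible = sum(ok_finite & !ok_plaus)
  )
  out
}

#' Aggregate classified children to the zone level
#'
#' @param classified output of [classify_children()] (must carry `ciaf_flag`).
#' @param min_n zones with fewer analyzable children than this trigger a
#'   warning (default 10).
#' @return A zone table (data frame) with one row per zone, sorted by
#'   `zone_id`: columns `zone_id`, `n`, `y`, `prevalence`.
#' @export
aggregate_zones <- function(classified, min_n = 10) {
  if (!NROW(classified)) stop("no analyzable children to aggregate")
  if (!"ciaf_flag" %in% names(classified))
    stop("`classified` must carry a ciaf_flag column (run classify_children)")
  zid <- as.character(classified$zone_id)
  n_i <- tapply(zid, zid, length)
  y_i <- tapply(classified$ciaf_flag, zid, sum)
  ord <- order(names(n_i))
  zt <- data.frame(
    zone_id = names(n_i)[ord],
    n = as.integer(n_i[ord]),
    y = as.integer(y_i[ord]),
    stringsAsFactors = FALSE
  )
  zt$prevalence <- zt$y / zt$n
  small <- zt$zone_id[zt$n < min_n]
  if (length(small))
    warning("zone(s) with fewer than ", min_n, " children: ",
            paste(small, collapse = ", "))
  rownames(zt) <- NULL
  zt
}

#' Expected CIAF counts under a common overall rate
#'
#' Disease-mapping expected counts: `E_i = n_i * (sum(y) / sum(n))`, so the
#' expected counts conserve the observed total.
#'
#' @param zt zone table with columns `n` and `y`.
#' @return `zt` with an added column `E`.
#' @export
expected_counts <- function(zt) {
  stopifnot(all(c("n", "y") %in% names(zt)))
  if (any(zt$n <= 0)) stop("all zone denominators n must be positive")
  rate <- sum(zt$y) / sum(zt$n)
  zt$E <- zt$n * rate
  zt
}

#' Crude relative risk per zone
#'
#' `rr_i = y_i / E_i`, the standardized morbidity ratio: the zone's observed
#' CIAF count relative to what the overall rate predicts. Its E-weighted
#' mean is exactly 1.
#'
#' @param zt zone table with columns `y` and `E` (see [expected_counts()]).
#' @return `zt` with an added column `rr`.
#' @export
crude_relative_risk <- function(zt) {
  stopifnot(all(c("y", "E") %in% names(zt)))
  bad <- which(zt$E <= 0)
  if (length(bad))
    stop("zero expected count (no cases anywhere?) in zone(s): ",
         paste(zt$zone_id[bad], collapse = ", "))
  zt$rr <- zt$y / zt$E
  zt
}

#' Read a child-level anthropometry file
#'
#' Delimited text with header columns `child_id`, `zone_id`, `haz`, `waz`,
#' `whz` and optionally `survey_round`.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return Data frame of child records.
#' @export
read_children <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = NA)
  req <- c("child_id", "zone_id", "haz", "waz", "whz")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("child file missing column(s): ", paste(miss, collapse = ", "))
  df$zone_id <- as.character(df$zone_id)
  df
}

#' Read / write a zone table
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return `read_zone_table`: data frame with `zone_id` as character;
#'   `write_zone_table`: `path`, invisibly.
#' @export
read_zone_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"zone_id" %in% names(df)) stop("zone file missing zone_id column")
  df$zone_id <- as.character(df$zone_id)
  df
}

#' @rdname read_zone_table
#' @param zt zone table to write.
#' @export
write_zone_table <- function(zt, path, sep = ",") {
  utils::write.table(zt, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
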