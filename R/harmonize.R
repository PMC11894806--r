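# Control-anchored covariate harmonization, effect-size ROI selection and
# atrophy-positive z-scoring.
#
# Regional volumes are corrected for scanner field strength, manufacturer,
# sex, age and TIV by ordinary least squares fitted on the control group
# only, and the fitted model is propagated unchanged to the cases. The
# adjusted volume is residual + control grand mean, which keeps volumes on
# an interpretable mm^3 scale. Z-scores are computed against the control
# distribution of adjusted volumes with the atrophy-positive sign
# convention: z = (control mean - value) / control SD.

#' Combine left/right hemisphere columns into single region volumes
#'
#' Paired regions' `_L`/`_R` columns are replaced by their sum; midline
#' regions pass through unchanged. Total volume is conserved exactly.
#'
#' @param scans raw scan table with per-hemisphere volume columns.
#' @param schema a [region_schema()].
#' @return The scan table with one volume column per schema region.
#' @export
combine_hemispheres <- function(scans, schema) {
  out <- scans[intersect(scan_meta_columns(), names(scans))]
  for (i in seq_len(nrow(schema))) {
    r <- schema$region[i]
    cols <- region_columns(schema, r)
    missing <- setdiff(cols, names(scans))
    if (length(missing)) {
      stop("missing hemisphere column(s) for region '", r, "': ",
           paste(missing, collapse = ", "))
    }
    out[[r]] <- if (length(cols) == 2L) {
      scans[[cols[1L]]] + scans[[cols[2L]]]
    } else {
      scans[[cols]]
    }
  }
  out
}

# Covariate design matrix. Encoding: 0/1 indicators for the non-reference
# level of each categorical, plus age and TIV. Reference levels are chosen
# when fitting (majority level among controls) and reused verbatim when the
# model is propagated to new scans.
build_design <- function(scans, encoding) {
  check_level <- function(col, levels) {
    bad <- setdiff(unique(scans[[col]]), levels)
    if (length(bad)) {
      stop("unseen ", col, " level(s): ", paste(bad, collapse = ", "))
    }
  }
  for (col in names(encoding$levels)) check_level(col, encoding$levels[[col]])
  X <- cbind(
    intercept = 1,
    field_strength = as.numeric(scans$field_strength ==
                                  encoding$nonref["field_strength"]),
    manufacturer = as.numeric(scans$manufacturer ==
                                encoding$nonref["manufacturer"]),
    sex = as.numeric(scans$sex == encoding$nonref["sex"]),
    age = scans$age,
    tiv = scans$tiv
  )
  X
}

majority_level <- function(x) names(which.max(table(x)))

#' Fit the control-anchored covariate model
#'
#' Per-region ordinary least squares of combined volume on scanner field
#' strength, manufacturer, sex, age and TIV, fitted on controls only.
#' Categorical covariates are encoded as 0/1 indicators with the
#' control-majority level as reference. The model stores, per region, the
#' regression coefficients, the control grand mean of the raw volume (used
#' to re-centre adjusted volumes), and the control mean and SD of the
#' adjusted volumes (used for z-scoring).
#'
#' @param controls combined-volume scan table of control scans.
#' @param schema a [region_schema()].
#' @return Object of class `harmonization_model`.
#' @export
fit_covariate_model <- function(controls, schema) {
  if (!all(schema$region %in% names(controls))) {
    stop("controls must be a combined-volume table (one column per region)")
  }
  encoding <- list(
    levels = list(field_strength = unique(controls$field_strength),
                  manufacturer = unique(controls$manufacturer),
                  sex = unique(controls$sex)),
    nonref = c(field_strength = "", manufacturer = "", sex = "")
  )
  single <- character(0)
  for (col in c("field_strength", "manufacturer", "sex")) {
    ref <- majority_level(controls[[col]])
    lev <- setdiff(unique(controls[[col]]), ref)
    if (!length(lev)) single <- c(single, col)
    encoding$nonref[col] <- if (length(lev)) lev[1L] else NA_character_
  }
  if (length(single)) {
    stop("singular covariate design; offending column(s): ",
         paste(single, collapse = ", "),
         " (categorical with a single level among controls)")
  }
  X <- build_design(controls, encoding)
  p <- ncol(X)
  if (nrow(X) < p + 2L) stop("need at least ", p + 2L, " control scans")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("singular covariate design; offending column(s): ",
         paste(bad, collapse = ", "),
         " (a categorical with a single level, or a constant covariate)")
  }
  Y <- as.matrix(controls[schema$region])
  coefs <- qr.coef(qx, Y)                      # p x R
  fitted <- X %*% coefs
  grand_mean <- colMeans(Y)
  adjusted <- Y - fitted + rep(grand_mean, each = nrow(Y))
  # a zero SD (e.g. noiseless simulated controls) only becomes an error
  # when z-scores are requested for that region
  ctrl_sd <- apply(adjusted, 2L, sd)
  structure(list(schema = schema, encoding = encoding, coefficients = coefs,
                 grand_mean = grand_mean,
                 ctrl_mean = colMeans(adjusted), ctrl_sd = ctrl_sd),
            class = "harmonization_model")
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat("harmonization model:", nrow(x$schema), "regions;",
      "reference levels:",
      paste(names(x$encoding$nonref), "!=", x$encoding$nonref,
            collapse = ", "), "\n")
  invisible(x)
}

#' Apply a fitted covariate model to any scan table
#'
#' Adjusted volume = raw - (model fit - control grand mean). The identical
#' transformation is applied to controls and cases; unseen categorical
#' levels raise an error naming the level.
#'
#' @param scans combined-volume scan table (controls and/or cases).
#' @param model a [fit_covariate_model()] result.
#' @return The table with volume columns replaced by adjusted volumes.
#' @export
apply_harmonization <- function(scans, model) {
  schema <- model$schema
  if (!all(schema$region %in% names(scans))) {
    stop("scans must be a combined-volume table")
  }
  X <- build_design(scans, model$encoding)
  fitted <- X %*% model$coefficients
  out <- scans
  adj <- as.matrix(scans[schema$region]) - fitted +
    rep(model$grand_mean, each = nrow(scans))
  out[schema$region] <- as.data.frame(adj)
  out
}

#' Cohen's d effect size between controls and cases
#'
#' d = (control mean - case mean) / pooled SD, pooled with n - 1 weights;
#' positive when cases have smaller volumes than controls.
#'
#' @param cases,controls numeric vectors (at least 2 observations each).
#' @return Effect size d (scalar).
#' @export
cohens_d <- function(cases, controls) {
  n1 <- length(controls); n2 <- length(cases)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  sp2 <- ((n1 - 1) * var(controls) + (n2 - 1) * var(cases)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled SD")
  (mean(controls) - mean(cases)) / sqrt(sp2)
}

#' Select regions of interest by effect size
#'
#' Computes Cohen's d between control and case adjusted volumes at the
#' baseline visit for every schema region, and retains regions with
#' |d| >= threshold, in schema order.
#'
#' @param adjusted combined, covariate-adjusted scan table with `group`
#'   and `visit` columns.
#' @param schema a [region_schema()].
#' @param threshold minimum |d| for selection (default 0.6).
#' @return List of class `roi_selection` with `regions` (character, schema
#'   order) and `d_table` (per-region d and selection flag).
#' @export
select_rois <- function(adjusted, schema, threshold = 0.6) {
  if (threshold < 0) stop("threshold must be non-negative")
  base <- adjusted[adjusted$visit == 0L, ]
  ctl <- base[base$group == "control", ]
  cas <- base[base$group == "case", ]
  d <- vapply(schema$region,
              function(r) cohens_d(cas[[r]], ctl[[r]]), numeric(1))
  keep <- abs(d) >= threshold
  if (!any(keep)) warning("no region reaches |d| >= ", threshold)
  structure(list(regions = schema$region[keep],
                 threshold = threshold,
                 d_table = data.frame(region = schema$region, d = d,
                                      selected = keep,
                                      stringsAsFactors = FALSE)),
            class = "roi_selection")
}

#' @export
print.roi_selection <- function(x, ...) {
  cat("selected", length(x$regions), "of", nrow(x$d_table),
      "regions at |d| >=", x$threshold, "\n")
  invisible(x)
}

#' Convert adjusted volumes to atrophy-positive z-scores
#'
#' z = (control mean - adjusted volume) / control SD of adjusted volumes,
#' so more atrophy (smaller volume) maps to larger positive z.
#'
#' @param adjusted combined, covariate-adjusted scan table.
#' @param model the [fit_covariate_model()] result used for adjustment.
#' @param rois character vector of regions (subset of the schema) or a
#'   [select_rois()] result.
#' @return Numeric matrix scans x ROIs with `scan_id` rownames.
#' @export
to_zscores <- function(adjusted, model, rois) {
  if (inherits(rois, "roi_selection")) rois <- rois$regions
  unknown <- setdiff(rois, model$schema$region)
  if (length(unknown)) stop("unknown ROI(s): ",
                            paste(unknown, collapse = ", "))
  if (any(model$ctrl_sd[rois] <= 0)) stop("zero control SD")
  v <- as.matrix(adjusted[rois])
  z <- (rep(model$ctrl_mean[rois], each = nrow(v)) - v) /
    rep(model$ctrl_sd[rois], each = nrow(v))
  rownames(z) <- adjusted$scan_id
  z
}

#' Laterality index of each scan
#'
#' LI = |sum of left paired volumes - sum of right paired volumes| divided
#' by total brain volume (the sum of all regional volumes), times 100.
#' Computed from raw per-hemisphere volumes. `per_region = TRUE` instead
#' returns a per-region LI matrix (|L - R| / total x 100 per paired
#' region).
#'
#' @param scans raw scan table with per-hemisphere columns.
#' @param schema a [region_schema()].
#' @param per_region return per-region indices instead of the scan-level
#'   hemispheric-sum index?
#' @return Numeric vector (or matrix) of laterality indices in percent.
#' @export
laterality_index <- function(scans, schema, per_region = FALSE) {
  paired <- schema$region[schema$paired]
  lcols <- paste0(paired, "_L")
  rcols <- paste0(paired, "_R")
  missing <- setdiff(c(lcols, rcols), names(scans))
  if (length(missing)) stop("missing hemisphere column(s): ",
                            paste(missing, collapse = ", "))
  total <- rowSums(scans[raw_volume_columns(schema)])
  if (any(total <= 0)) stop("zero total brain volume")
  L <- as.matrix(scans[lcols]); R <- as.matrix(scans[rcols])
  if (per_region) {
    out <- abs(L - R) / total * 100
    colnames(out) <- paired
    rownames(out) <- scans$scan_id
    out
  } else {
    setNames(abs(rowSums(L) - rowSums(R)) / total * 100, scans$scan_id)
  }
}
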