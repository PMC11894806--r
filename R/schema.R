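#' Region schema for regional grey-matter volumes
#'
#' A region schema names the grey-matter regions the pipeline works with,
#' records which regions have separate left/right measurements, and tags
#' each region with its anatomical group. Paired regions appear in raw scan
#' tables as two columns with `_L`/`_R` suffixes and are combined (summed)
#' before harmonization; midline regions have a single column.
#'
#' @param regions character vector of unique region names.
#' @param paired logical vector: does the region have left/right columns?
#' @param group character vector of anatomical group tags (e.g. brainstem,
#'   cerebellar, subcortical, cortical).
#' @return An object of class `region_schema`: a data frame with columns
#'   `region`, `paired`, `group`.
#' @export
region_schema <- function(regions, paired, group) {
  stopifnot(length(regions) == length(paired),
            length(regions) == length(group),
            is.character(regions), is.logical(paired))
  if (anyDuplicated(regions)) stop("region names must be unique")
  out <- data.frame(region = regions, paired = paired, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_schema", "data.frame")
  out
}

#' Default 24-region grey-matter schema
#'
#' The standard atlas used throughout the package: four brainstem regions
#' (medulla, pons, superior cerebellar peduncle, midbrain), three cerebellar
#' (cerebellar cortex, dentate nucleus, vermis), eight subcortical (thalamus,
#' globus pallidus, caudate, putamen, ventral diencephalon, hippocampus,
#' amygdala, nucleus accumbens) and nine cortical (basal forebrain,
#' cingulate, corpus callosum, anterior/posterior frontal, insula, temporal,
#' parietal, occipital). Midline structures (medulla, pons, midbrain,
#' vermis, corpus callosum) are unpaired; all others carry left/right
#' columns.
#'
#' @return A [region_schema()].
#' @export
default_region_schema <- function() {
  region_schema(
    regions = c("medulla", "pons", "scp", "midbrain",
                "cerebellar_cortex", "dentate", "vermis",
                "thalamus", "globus_pallidus", "caudate", "putamen",
                "ventral_dc", "hippocampus", "amygdala", "accumbens",
                "basal_forebrain", "cingulate", "corpus_callosum",
                "frontal_anterior", "frontal_posterior", "insula",
                "temporal", "parietal", "occipital"),
    paired = c(FALSE, FALSE, TRUE, FALSE,
               TRUE, TRUE, FALSE,
               TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, FALSE,
               TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE),
    group = c(rep("brainstem", 4L), rep("cerebellar", 3L),
              rep("subcortical", 8L), rep("cortical", 9L))
  )
}

# Column names a raw scan table uses for one region: region or region_L/_R.
region_columns <- function(schema, region) {
  i <- match(region, schema$region)
  if (is.na(i)) stop("unknown region: ", region)
  if (schema$paired[i]) paste0(region, c("_L", "_R")) else region
}

# All volume columns of a raw (per-hemisphere) scan table, in schema order.
raw_volume_columns <- function(schema) {
  unlist(lapply(schema$region, region_columns, schema = schema),
         use.names = FALSE)
}

# Non-volume columns every scan table carries.
scan_meta_columns <- function() {
  c("subject_id", "scan_id", "visit", "group", "pathology",
    "age", "sex", "tiv", "field_strength", "manufacturer")
}

# Validate a raw scan table against a schema; returns invisibly.
check_scan_table <- function(scans, schema, raw = TRUE) {
  need <- scan_meta_columns()
  vols <- if (raw) raw_volume_columns(schema) else schema$region
  missing <- setdiff(c(need, vols), names(scans))
  if (length(missing)) {
    stop("scan table is missing columns: ", paste(missing, collapse = ", "))
  }
  vm <- as.matrix(scans[vols])
  if (any(!is.finite(vm)) || any(vm <= 0)) {
    stop("volumes must be finite and positive")
  }
  if (any(!is.finite(scans$tiv)) || any(scans$tiv <= 0)) {
    stop("TIV must be finite and positive")
  }
  for (cv in c("age", "sex", "field_strength", "manufacturer")) {
    if (anyNA(scans[[cv]])) stop("covariate '", cv, "' has missing values")
  }
  invisible(scans)
}
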