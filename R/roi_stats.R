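#' Physiologic retention filters for map values
#'
#' Retains map values inside the published acceptance windows, applied
#' with strict inequalities: 30 < T2 < 80 ms, 0 < ADC < 1200 um^2/s,
#' MTR > 0. These remove CSF-dominated voxels and artifacts before ROI
#' averaging.
#'
#' @param values numeric vector of map values.
#' @param parameter `"T2"`, `"ADC"` or `"MTR"`.
#' @return list with `values` (retained, original order) and `n_removed`.
#'   An empty input yields an empty output with a warning.
#' @examples
#' filter_map_values(c(25, 45, 85), "T2")$values   # 45
#' @export
filter_map_values <- function(values, parameter = c("T2", "ADC", "MTR")) {
  parameter <- match.arg(parameter)
  if (!length(values)) {
    warning("empty input to filter_map_values")
    return(list(values = numeric(0), n_removed = 0L))
  }
  keep <- switch(parameter,
    T2  = values > 30 & values < 80,
    ADC = values > 0 & values < 1200,
    MTR = values > 0)
  keep <- keep & !is.na(values)
  list(values = values[keep], n_removed = sum(!keep))
}

#' ROI average of a parametric map
#'
#' Arithmetic mean over the voxels of a mask that are both valid in the
#' map and inside the physiologic retention window of the parameter.
#'
#' @param map a [param_map()].
#' @param mask logical matrix, or an integer label matrix combined with
#'   `label` to select one region.
#' @param parameter filter family; defaults to the map's own parameter.
#' @param label region code to select when `mask` is a label image.
#' @return list with `value` (mean; `NA` if no voxel survives, with the
#'   reason in `reason`) and `n_voxels_used`.
#' @export
roi_mean <- function(map, mask, parameter = map$parameter, label = NULL) {
  stopifnot(inherits(map, "mpmri_map"))
  if (!is.null(label)) mask <- mask == label
  mask <- as.logical(mask)
  if (length(mask) != length(map$values)) stop("mask extent differs from map extent")
  vals <- map$values[mask & map$valid]
  vals <- vals[!is.na(vals)]
  if (parameter %in% c("T2", "ADC", "MTR")) {
    if (!length(vals))
      return(list(value = NA_real_, n_voxels_used = 0L, reason = "no valid voxels"))
    vals <- filter_map_values(vals, parameter)$values
  }
  if (!length(vals))
    return(list(value = NA_real_, n_voxels_used = 0L, reason = "all voxels filtered"))
  list(value = mean(vals), n_voxels_used = length(vals), reason = NA_character_)
}

#' Interquartile-range outlier removal
#'
#' Removes values outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\], with quartiles
#' computed by linear interpolation between order statistics (the
#' `stats::quantile()` type 7 default; configurable). Applied to a data
#' frame, the rule acts independently within each diet x day x region
#' group. Groups with fewer than 4 observations are left untouched
#' (fences are meaningless below that size) and flagged.
#'
#' @param x numeric vector, or a data frame with a `value` column.
#' @param group_cols grouping columns when `x` is a data frame.
#' @param quantile_type passed to [stats::quantile()].
#' @return same shape as the input, outliers removed; the removed values
#'   (or rows) are in `attr(, "removed")`, skipped small groups in
#'   `attr(, "skipped_groups")`.
#' @examples
#' remove_outliers_iqr(c(10, 11, 12, 13, 100))  # drops 100
#' @export
remove_outliers_iqr <- function(x, group_cols = c("diet", "day", "region"),
                                quantile_type = 7) {
  fences <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), type = quantile_type, names = FALSE)
    c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
  }
  if (is.numeric(x)) {
    if (length(x) < 4) {
      out <- x
      attr(out, "removed") <- numeric(0)
      attr(out, "skipped_groups") <- "n < 4"
      return(out)
    }
    f <- fences(x)
    keep <- x >= f[1] & x <= f[2]
    out <- x[keep]
    attr(out, "removed") <- x[!keep]
    attr(out, "skipped_groups") <- character(0)
    return(out)
  }
  stopifnot(is.data.frame(x), "value" %in% names(x))
  group_cols <- intersect(group_cols, names(x))
  if ("parameter" %in% names(x)) group_cols <- union(group_cols, "parameter")
  key <- if (length(group_cols))
    interaction(x[group_cols], drop = TRUE) else factor(rep(1, nrow(x)))
  keep <- rep(TRUE, nrow(x))
  skipped <- character(0)
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- x$value[idx]
    ok <- !is.na(v)
    if (sum(ok) < 4) { skipped <- c(skipped, g); next }
    f <- fences(v[ok])
    keep[idx[ok]] <- v[ok] >= f[1] & v[ok] <= f[2]
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "removed") <- x[!keep, , drop = FALSE]
  attr(out, "skipped_groups") <- skipped
  out
}

#' Build the long-format ROI table from fitted maps
#'
#' Applies [roi_mean()] to every region x parameter of every animal/day
#' record, then the interquartile outlier rule within each
#' diet x day x region (x parameter) group.
#'
#' @param records list of records, each a list with `animal_id`, `sex`,
#'   `diet`, `day`, and `maps` (named list of [param_map()] objects, e.g.
#'   `T2`, `ADC`, `MTR`).
#' @param masks integer label mask from [make_roi_masks()].
#' @param remove_outliers apply the IQR rule (default TRUE).
#' @return data frame: animal_id, sex, diet, day, region, parameter,
#'   value, n_voxels_used. Rows whose ROI mean is undefined are kept with
#'   `NA` value; outlier-removed rows are dropped (and recorded in
#'   `attr(, "removed")`).
#' @export
build_roi_table <- function(records, masks, remove_outliers = TRUE) {
  codes <- attr(masks, "region_codes")
  regions <- names(codes)[!names(codes) %in% c("other_brain", "csf")]
  rows <- list()
  seen <- character(0)
  for (rec in records) {
    for (reg in regions) {
      if (!any(masks == codes[[reg]])) next
      for (par in names(rec$maps)) {
        key <- paste(rec$animal_id, rec$day, reg, par, sep = "|")
        if (key %in% seen)
          stop("duplicate (animal, day, region, parameter) record: ", key)
        seen <- c(seen, key)
        rm <- roi_mean(rec$maps[[par]], masks, parameter = par, label = codes[[reg]])
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = rec$animal_id, sex = rec$sex %||% NA_character_,
          diet = rec$diet, day = rec$day, region = reg, parameter = par,
          value = rm$value, n_voxels_used = rm$n_voxels_used,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (remove_outliers) tab <- remove_outliers_iqr(tab)
  rownames(tab) <- NULL
  tab
}
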